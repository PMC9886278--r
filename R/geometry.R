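# Rotation of picked localizations onto the myofibril axis and projection
# into axial histograms.

#' Construct an axial profile
#'
#' A 1-D histogram of localization positions along the myofibril axis.
#' Bins are uniform and half-open `[left, right)`; counts are integer for
#' raw profiles and real-valued after smoothing.
#'
#' @param edges Strictly increasing, uniformly spaced bin edges (nm).
#' @param counts Per-bin counts, `length(edges) - 1` values, all `>= 0`.
#' @param bin_size_nm Bin spacing (nm).
#' @return An `axial_profile` list with fields `edges`, `counts`,
#'   `bin_size_nm`.
#' @export
axial_profile <- function(edges, counts, bin_size_nm) {
  if (length(edges) < 2) stopf("an axial profile needs at least one bin")
  d <- diff(edges)
  if (any(d <= 0) || max(abs(d - bin_size_nm)) > 1e-9 * max(1, bin_size_nm)) {
    stopf("profile edges must increase uniformly by bin_size_nm")
  }
  if (length(counts) != length(edges) - 1L) {
    stopf("need length(counts) == length(edges) - 1")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stopf("counts must be finite and >= 0")
  }
  structure(
    list(edges = as.numeric(edges), counts = as.numeric(counts),
         bin_size_nm = as.numeric(bin_size_nm)),
    class = "axial_profile"
  )
}

#' @rdname axial_profile
#' @param profile An `axial_profile`.
#' @return `profile_centers()`: numeric vector of bin centers (nm).
#' @export
profile_centers <- function(profile) {
  profile$edges[-length(profile$edges)] + profile$bin_size_nm / 2
}

#' @export
print.axial_profile <- function(x, ...) {
  cat(sprintf(
    "<axial_profile> %d bins of %.3g nm over [%.1f, %.1f] nm, total %.1f\n",
    length(x$counts), x$bin_size_nm, x$edges[1],
    x$edges[length(x$edges)], sum(x$counts)
  ))
  invisible(x)
}

#' Rotate localizations into the frame of a pick
#'
#' Applies `r' = R(-angle) (r - center)` so that the pick's long axis
#' becomes +x, then drops rows outside the axis-aligned rectangle
#' `|x'| <= length/2`, `|y'| <= width/2`. Discarding at rotation time keeps
#' neighbouring myofibrils out of the projection histograms.
#'
#' @param locs A [loc_table()] in image coordinates (camera pixels).
#' @param pick A [pick_region()].
#' @return The retained localizations with `x`, `y` in the pick frame
#'   (camera pixels, origin at the pick center).
#' @export
rotate_to_pick_axis <- function(locs, pick) {
  a <- pick$angle
  dx <- locs$x - pick$center_x
  dy <- locs$y - pick$center_y
  xr <- cos(a) * dx + sin(a) * dy
  yr <- -sin(a) * dx + cos(a) * dy
  keep <- abs(xr) <= pick$length / 2 & abs(yr) <= pick$width / 2
  if (nrow(locs) > 0 && !any(keep)) {
    warnf("no localizations inside the pick rectangle")
  }
  out <- as.data.frame(locs)
  out$x <- xr
  out$y <- yr
  restamp(out[keep, , drop = FALSE], locs)
}

# Histogram a vector of axial positions (nm) with the bin grid anchored at
# 0 nm (edges at integer multiples of the bin size) for reproducibility.
hist_axial <- function(x_nm, bin_size_nm, range_nm = NULL) {
  if (is.null(range_nm)) {
    if (length(x_nm) == 0) {
      stopf("cannot infer a histogram range from zero localizations")
    }
    lo <- floor(min(x_nm) / bin_size_nm) * bin_size_nm
    hi <- (floor(max(x_nm) / bin_size_nm) + 1) * bin_size_nm
  } else {
    lo <- floor(range_nm[1] / bin_size_nm) * bin_size_nm
    hi <- ceiling(range_nm[2] / bin_size_nm) * bin_size_nm
    if (hi <= lo) hi <- lo + bin_size_nm
  }
  nb <- as.integer(round((hi - lo) / bin_size_nm))
  idx <- floor((x_nm - lo) / bin_size_nm) + 1
  counts <- tabulate(idx[idx >= 1 & idx <= nb], nbins = nb)
  axial_profile(lo + bin_size_nm * (0:nb), counts, bin_size_nm)
}

#' Project rotated localizations into an axial histogram
#'
#' Converts the axial coordinate to nm and histograms it with half-open
#' bins on a grid anchored at 0 nm. The default range is the data range
#' expanded to whole bins, so the counts sum to the number of rows; with an
#' explicit range, rows outside it are dropped.
#'
#' @param locs A rotated [loc_table()] (see [rotate_to_pick_axis()]).
#' @param bin_size_nm Bin size in nm. 130 nm (one camera pixel) for the
#'   coarse Z-disc stage; 13 nm for the band stage.
#' @param range_nm Optional `c(lo, hi)` interval in nm.
#' @return An [axial_profile()].
#' @export
project_profile <- function(locs, bin_size_nm = 130, range_nm = NULL) {
  if (!is_scalar_number(bin_size_nm) || bin_size_nm <= 0) {
    stopf("bin_size_nm must be a single positive number")
  }
  x_nm <- locs$x * px_size(locs)
  if (length(x_nm) == 0 && is.null(range_nm)) {
    stopf("empty localization table and no range_nm given")
  }
  hist_axial(x_nm, bin_size_nm, range_nm)
}
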