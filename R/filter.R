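# Multi-emitter filtering.
#
# Localizations produced by two molecules blinking simultaneously within a
# PSF are fitted with inflated Gaussian widths. Single-emitter events
# cluster tightly in (sx, sy) space, so keeping only localizations within a
# small disc around the mode of that distribution removes the contaminating
# population.

#' Parameters of the multi-emitter filter
#'
#' @param radius_px Radius of the acceptance disc in (sx, sy) space, camera
#'   pixels. Default 0.2.
#' @param hist_bin_px Bin of the 2-D histogram used to locate the mode of
#'   the fit-width distribution. Default 0.05 px; must not exceed the
#'   radius.
#' @return A `filter_params` list.
#' @export
filter_params <- function(radius_px = 0.2, hist_bin_px = 0.05) {
  if (!is_scalar_number(radius_px) || radius_px <= 0) {
    stopf("radius_px must be a single positive number")
  }
  if (!is_scalar_number(hist_bin_px) || hist_bin_px <= 0 ||
      hist_bin_px > radius_px) {
    stopf("hist_bin_px must be positive and <= radius_px")
  }
  structure(
    list(radius_px = radius_px, hist_bin_px = hist_bin_px),
    class = "filter_params"
  )
}

#' Locate the mode of the PSF fit-width distribution
#'
#' Bins (sx, sy) into a 2-D histogram of `hist_bin_px` bins and returns the
#' center of the most populated bin. Ties between equally populated bins are
#' broken towards the bin with the smaller `sx^2 + sy^2` (narrower fits are
#' likelier single emitters), then lexicographically.
#'
#' @param locs A [loc_table()] with at least one row.
#' @param params A [filter_params()].
#' @return Named numeric vector `c(sx_mode, sy_mode)` in camera pixels.
#' @export
fit_width_mode <- function(locs, params = filter_params()) {
  if (nrow(locs) == 0) {
    stopf("cannot locate the fit-width mode of an empty localization table")
  }
  b <- params$hist_bin_px
  ix <- floor(locs$sx / b)
  iy <- floor(locs$sy / b)
  key <- paste(ix, iy, sep = ",")
  tab <- table(key)
  top <- names(tab)[tab == max(tab)]
  cent <- do.call(rbind, lapply(strsplit(top, ",", fixed = TRUE), as.numeric))
  cx <- (cent[, 1] + 0.5) * b
  cy <- (cent[, 2] + 0.5) * b
  o <- order(cx^2 + cy^2, cx, cy)
  c(sx_mode = cx[o[1]], sy_mode = cy[o[1]])
}

#' Remove multi-emitter localizations
#'
#' Keeps rows whose (sx, sy) lies within `radius_px` (inclusive) of the
#' fit-width mode; everything else is assumed to stem from overlapping
#' emitters. Row order and all other fields are untouched.
#'
#' @inheritParams fit_width_mode
#' @return The filtered [loc_table()]; empty (with a warning) if every row
#'   was rejected.
#' @export
filter_multi_emitter <- function(locs, params = filter_params()) {
  if (nrow(locs) == 0) stopf("cannot filter an empty localization table")
  mode <- fit_width_mode(locs, params)
  d <- sqrt((locs$sx - mode[["sx_mode"]])^2 + (locs$sy - mode[["sy_mode"]])^2)
  keep <- d <= params$radius_px
  if (!any(keep)) {
    warnf("multi-emitter filter rejected every localization")
  }
  restamp(as.data.frame(locs)[keep, , drop = FALSE], locs)
}
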