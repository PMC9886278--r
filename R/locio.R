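# I/O for localization tables, pick regions and band tables.
#
# Conventions: x, y are continuous camera-pixel coordinates with the origin
# at the top-left pixel corner and pixel centers at half-integers;
# conversion to nanometres multiplies by the attached pixel pitch.
# CSV dialect is comma-separated, '.' decimal, UTF-8, with a mandatory
# header row.

LOC_COLUMNS <- c("frame", "x", "y", "photons", "sx", "sy")

BAND_COLUMNS <- c(
  "myofibril_id", "zdisc_id", "channel_label", "epitope_label", "side",
  "center_nm", "sigma_nm", "amplitude", "n_localizations"
)

#' Construct a localization table
#'
#' Wraps a data frame of per-molecule detections into the container used by
#' the whole pipeline. Required columns are `frame`, `x`, `y`, `photons`,
#' `sx`, `sy` (positions and Gaussian-fit PSF standard deviations, all in
#' camera pixels); extra columns are tolerated and carried along. The
#' physical pixel pitch and a free-text channel label are attached as
#' attributes.
#'
#' @param df Data frame with at least the required columns.
#' @param pixel_size_nm Camera pixel pitch in nm/pixel (default 130, the
#'   effective pitch of a 2x2-binned sCMOS at 100x).
#' @param channel_label Free-text identifier of the imaging channel.
#' @return A `loc_table`, a data frame with `pixel_size_nm` and
#'   `channel_label` attributes.
#' @export
loc_table <- function(df, pixel_size_nm = 130, channel_label = "") {
  missing_cols <- setdiff(LOC_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stopf(
      "localization table is missing required column(s): %s",
      paste(missing_cols, collapse = ", ")
    )
  }
  df <- as.data.frame(df)
  rownames(df) <- NULL
  if (!is_scalar_number(pixel_size_nm) || pixel_size_nm <= 0) {
    stopf("pixel_size_nm must be a single positive number")
  }
  if (nrow(df) > 0) {
    bad <- which(!(df$sx > 0 & df$sy > 0) | !is.finite(df$sx) | !is.finite(df$sy))
    if (length(bad) > 0) {
      stopf(
        "non-positive or non-finite sx/sy at row(s): %s",
        paste(utils::head(bad, 20L), collapse = ", ")
      )
    }
    if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
      stopf("x and y must be finite")
    }
    if (any(df$frame < 0)) stopf("frame indices must be >= 0")
  }
  attr(df, "pixel_size_nm") <- as.numeric(pixel_size_nm)
  attr(df, "channel_label") <- as.character(channel_label)
  class(df) <- c("loc_table", "data.frame")
  df
}

#' @rdname loc_table
#' @param locs A `loc_table`.
#' @export
px_size <- function(locs) attr(locs, "pixel_size_nm")

#' @rdname loc_table
#' @export
channel <- function(locs) attr(locs, "channel_label")

# Re-attach table attributes after a row subset.
restamp <- function(df, template) {
  loc_table(df, px_size(template), channel(template))
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf(
    "<loc_table> %d localizations, pixel %.1f nm, channel '%s'\n",
    nrow(x), px_size(x), channel(x)
  ))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Read a localization table from disk
#'
#' Reads a per-molecule localization table with columns `frame`, `x`, `y`,
#' `photons`, `sx`, `sy` (camera pixels). A YAML sidecar next to the file
#' (`<stem>.yaml` with keys `pixel_size_nm` and `channel_label`) is read if
#' present; explicit arguments override it. Only the CSV dialect is
#' supported; HDF5 containers must be exported to CSV first (for
#' Picasso-style files, export the `locs` dataset with these columns).
#'
#' @param path Path to the CSV file.
#' @param format Input format; only `"csv"` is supported.
#' @param pixel_size_nm Pixel pitch in nm/pixel; overrides the sidecar.
#' @param channel_label Channel identifier; overrides the sidecar.
#' @return A [loc_table()].
#' @export
read_localizations <- function(path, format = c("csv", "hdf5"),
                               pixel_size_nm = NULL, channel_label = NULL) {
  format <- match.arg(format)
  if (format == "hdf5") {
    stopf(paste0(
      "HDF5 localization files are not supported; export the localization ",
      "table to CSV with columns frame,x,y,photons,sx,sy and use ",
      "format = 'csv'"
    ))
  }
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".yaml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  loc_table(
    df,
    pixel_size_nm = pixel_size_nm %||% meta$pixel_size_nm %||% 130,
    channel_label = channel_label %||% meta$channel_label %||% ""
  )
}

#' Write a localization table to CSV with a YAML sidecar
#'
#' The sidecar (`<stem>.yaml`) records `pixel_size_nm` and `channel_label`
#' so that [read_localizations()] restores the table field-by-field.
#'
#' @param path Output CSV path.
#' @param locs A [loc_table()].
#' @export
write_localizations <- function(path, locs) {
  utils::write.csv(as.data.frame(locs), path, row.names = FALSE)
  yaml::write_yaml(
    list(pixel_size_nm = px_size(locs), channel_label = channel(locs)),
    paste0(tools::file_path_sans_ext(path), ".yaml")
  )
  invisible(path)
}

#' Construct a pick region
#'
#' A pick is a rotated rectangle selecting one myofibril in the rendered
#' image; its long axis defines the projection axis of all downstream
#' histograms. Angles are normalized to `(-pi/2, pi/2]`; if `width` exceeds
#' `length` the two are swapped (with a warning) and the angle rotated by
#' a quarter turn, so the long axis always carries the angle.
#'
#' @param center_x,center_y Rectangle center (camera pixels).
#' @param length Long-axis extent (camera pixels).
#' @param width Short-axis extent (camera pixels).
#' @param angle Long-axis orientation versus +x, radians, counter-clockwise.
#' @return A `pick_region` list.
#' @export
pick_region <- function(center_x, center_y, length, width, angle = 0) {
  for (v in list(center_x, center_y, length, width, angle)) {
    if (!is_scalar_number(v)) stopf("pick fields must be single finite numbers")
  }
  if (length <= 0 || width <= 0) stopf("pick length and width must be > 0")
  if (width > length) {
    warnf("pick width (%g) exceeds length (%g); swapping axes", width, length)
    tmp <- length; length <- width; width <- tmp
    angle <- angle + pi / 2
  }
  structure(
    list(
      center_x = center_x, center_y = center_y,
      length = length, width = width,
      angle = normalize_angle(angle)
    ),
    class = "pick_region"
  )
}

#' @export
print.pick_region <- function(x, ...) {
  cat(sprintf(
    "<pick_region> center (%.2f, %.2f) px, %0.1f x %0.1f px, angle %.3f rad\n",
    x$center_x, x$center_y, x$length, x$width, x$angle
  ))
  invisible(x)
}

pick_from_entry <- function(entry, i) {
  if (!is.null(entry$corners)) {
    p <- try(do.call(rbind, lapply(entry$corners, as.numeric)), silent = TRUE)
    if (inherits(p, "try-error") || !is.matrix(p) || nrow(p) != 4L ||
        ncol(p) != 2L || any(!is.finite(p))) {
      stopf("pick entry %d is malformed: corners must be four (x, y) pairs", i)
    }
    e1 <- p[2, ] - p[1, ]
    e2 <- p[3, ] - p[2, ]
    l1 <- sqrt(sum(e1^2)); l2 <- sqrt(sum(e2^2))
    long <- if (l1 >= l2) e1 else e2
    ctr <- colMeans(p)
    return(pick_region(
      center_x = ctr[1], center_y = ctr[2],
      length = max(l1, l2), width = min(l1, l2),
      angle = atan2(long[2], long[1])
    ))
  }
  need <- c("center_x", "center_y", "length", "width", "angle_rad")
  vals <- lapply(need, function(k) entry[[k]])
  if (any(vapply(vals, is.null, logical(1))) ||
      any(!vapply(vals, is_scalar_number, logical(1)))) {
    stopf(
      "pick entry %d is malformed: needs numeric %s (or a 'corners' list)",
      i, paste(need, collapse = ", ")
    )
  }
  pick_region(
    center_x = entry$center_x, center_y = entry$center_y,
    length = entry$length, width = entry$width, angle = entry$angle_rad
  )
}

#' Read pick regions from a YAML file
#'
#' The file is a YAML list of entries, each either
#' `{center_x, center_y, length, width, angle_rad}` (camera pixels,
#' radians) or `{corners: [[x1,y1], ..., [x4,y4]]}`; corner entries are
#' converted to center/length/width/angle internally. Entry order is
#' preserved and all angles are normalized.
#'
#' @param path Path to the YAML pick file.
#' @return List of [pick_region()] objects.
#' @export
read_picks <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  entries <- yaml::read_yaml(path)
  if (is.null(entries)) return(list())
  if (!is.list(entries)) stopf("pick file must be a YAML list of entries")
  lapply(seq_along(entries), function(i) pick_from_entry(entries[[i]], i))
}

#' Write pick regions to a YAML file
#'
#' @param path Output path.
#' @param picks A [pick_region()] or list of them.
#' @export
write_picks <- function(path, picks) {
  if (inherits(picks, "pick_region")) picks <- list(picks)
  yaml::write_yaml(
    lapply(picks, function(p) list(
      center_x = p$center_x, center_y = p$center_y,
      length = p$length, width = p$width, angle_rad = p$angle
    )),
    path
  )
  invisible(path)
}

#' Write a band table to CSV
#'
#' One row per fitted band: identifiers, the side of the Z-disc, the fitted
#' center and width in nm, the amplitude and the localization count inside
#' the fit window. Floats are written with six decimal places (sub-picometre
#' for nm columns).
#'
#' @param path Output CSV path.
#' @param table Data frame with the band-table columns.
#' @export
write_band_table <- function(path, table) {
  missing_cols <- setdiff(BAND_COLUMNS, names(table))
  if (length(missing_cols) > 0) {
    stopf("band table is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  out <- as.data.frame(table)[, BAND_COLUMNS, drop = FALSE]
  for (col in c("center_nm", "sigma_nm", "amplitude")) {
    out[[col]] <- sprintf("%.6f", as.numeric(out[[col]]))
  }
  if (nrow(out) == 0) {
    writeLines(paste(BAND_COLUMNS, collapse = ","), path)
  } else {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a band table written by [write_band_table()]
#'
#' @param path CSV path.
#' @return Data frame with the band-table columns.
#' @export
read_band_table <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  utils::read.csv(path, colClasses = c(
    myofibril_id = "integer", zdisc_id = "integer",
    channel_label = "character", epitope_label = "character",
    side = "character", center_nm = "numeric", sigma_nm = "numeric",
    amplitude = "numeric", n_localizations = "integer"
  ))
}
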