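# Z-disc detection on the coarse axial profile.
#
# Z-discs appear as the strongest periodic peaks of the pixel-binned
# projection histogram. Candidate peaks are filtered by prominence, and
# the returned set is the longest chain of candidates whose successive
# spacings are compatible with the sarcomere period (about 3.5 um in
# flight muscle, with some spread from mounting).

#' Construct a Z-disc set
#'
#' @param positions_nm Strictly increasing Z-disc coordinates along the
#'   myofibril axis (nm).
#' @param expected_sarcomere_nm Nominal sarcomere period (nm).
#' @param tolerance_frac Allowed fractional deviation of neighbour spacing.
#' @param prominences Optional per-disc peak prominences (bookkeeping).
#' @return A `zdisc_set` list.
#' @export
zdisc_set <- function(positions_nm, expected_sarcomere_nm = 3500,
                      tolerance_frac = 0.25, prominences = NULL) {
  if (!is_scalar_number(tolerance_frac) || tolerance_frac <= 0 ||
      tolerance_frac >= 1) {
    stopf("tolerance_frac must lie in (0, 1)")
  }
  if (length(positions_nm) > 1 && any(diff(positions_nm) <= 0)) {
    stopf("Z-disc positions must be strictly increasing")
  }
  structure(
    list(
      positions_nm = as.numeric(positions_nm),
      expected_sarcomere_nm = expected_sarcomere_nm,
      tolerance_frac = tolerance_frac,
      prominences = prominences
    ),
    class = "zdisc_set"
  )
}

#' @export
print.zdisc_set <- function(x, ...) {
  cat(sprintf(
    "<zdisc_set> %d Z-discs, expected period %.0f nm (+/- %.0f%%)\n",
    length(x$positions_nm), x$expected_sarcomere_nm,
    100 * x$tolerance_frac
  ))
  invisible(x)
}

# Longest chain of candidate positions whose successive spacings lie in
# [lo, hi]. Ties on length are broken by highest summed weight
# (prominence), then by the leftmost chain. O(k^2) dynamic programme.
longest_period_chain <- function(pos, weight, lo, hi) {
  k <- length(pos)
  if (k == 0L) return(integer(0))
  len <- rep(1L, k)
  wsum <- weight
  parent <- rep(NA_integer_, k)
  start <- seq_len(k)
  for (i in seq_len(k)) {
    js <- seq_len(i - 1L)
    for (j in js) {
      d <- pos[i] - pos[j]
      if (d >= lo && d <= hi) {
        cand_len <- len[j] + 1L
        cand_w <- wsum[j] + weight[i]
        better <- cand_len > len[i] ||
          (cand_len == len[i] && cand_w > wsum[i]) ||
          (cand_len == len[i] && cand_w == wsum[i] &&
             pos[start[j]] < pos[start[i]])
        if (better) {
          len[i] <- cand_len
          wsum[i] <- cand_w
          parent[i] <- j
          start[i] <- start[j]
        }
      }
    }
  }
  best <- order(-len, -wsum, pos[start], pos)[1]
  chain <- integer(0)
  i <- best
  while (!is.na(i)) {
    chain <- c(i, chain)
    i <- parent[i]
  }
  chain
}

#' Detect Z-discs on a coarse axial profile
#'
#' Candidate peaks are local maxima with topographic prominence of at least
#' `min_prominence_frac` times the profile maximum. Among the candidates,
#' the longest chain whose successive spacings lie within
#' `expected_sarcomere_nm * (1 +/- tolerance_frac)` is returned; a missing
#' Z-disc (spacing near twice the period) splits chains rather than being
#' bridged. Positions are reported at candidate-bin centers, so their
#' accuracy is one coarse bin; the nm-scale reference downstream is the
#' band-pair midpoint, not these peaks.
#'
#' @param profile Coarse (pixel-binned) [axial_profile()].
#' @param expected_sarcomere_nm Nominal period, default 3500 nm.
#' @param tolerance_frac Fractional spacing tolerance, default 0.25.
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   profile maximum, default 0.2.
#' @return A [zdisc_set()]; empty (with a warning) if no candidate peaks.
#' @export
detect_zdiscs <- function(profile, expected_sarcomere_nm = 3500,
                          tolerance_frac = 0.25, min_prominence_frac = 0.2) {
  pks <- find_profile_peaks(profile$counts)
  if (nrow(pks) > 0) {
    pks <- pks[pks$prominence >= min_prominence_frac * max(profile$counts), ,
               drop = FALSE]
  }
  if (nrow(pks) == 0) {
    warnf("no candidate Z-disc peaks found")
    return(zdisc_set(numeric(0), expected_sarcomere_nm, tolerance_frac))
  }
  pos <- profile_centers(profile)[pks$index]
  sel <- longest_period_chain(
    pos, pks$prominence,
    expected_sarcomere_nm * (1 - tolerance_frac),
    expected_sarcomere_nm * (1 + tolerance_frac)
  )
  zdisc_set(pos[sel], expected_sarcomere_nm, tolerance_frac,
            prominences = pks$prominence[sel])
}

#' Sarcomere lengths from consecutive Z-disc spacings
#'
#' @param zdiscs A [zdisc_set()].
#' @return Numeric vector of consecutive spacings (nm); empty with fewer
#'   than two Z-discs.
#' @export
sarcomere_lengths <- function(zdiscs) {
  if (length(zdiscs$positions_nm) < 2) return(numeric(0))
  diff(zdiscs$positions_nm)
}
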