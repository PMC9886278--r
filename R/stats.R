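# Aggregation of per-sarcomere measurements: pooled epitope positions with
# bootstrap confidence intervals, dual-channel ordering statistics,
# composite profiles and the distance-versus-sarcomere-length trend.

#' Pool the half-distances of one epitope
#'
#' Returns every `half_distance_nm` carrying the requested label, pooled
#' across myofibrils and experiments without weighting (each sarcomere
#' counts once), in input order.
#'
#' @param measurements Measurement data frame from
#'   [extract_epitope_pairs()] or [run_pipeline()].
#' @param epitope_label Label to select.
#' @return Numeric vector of half-distances (nm).
#' @export
half_distance_series <- function(measurements, epitope_label) {
  if (nrow(measurements) == 0) return(numeric(0))
  known <- unique(measurements$epitope_label)
  if (!epitope_label %in% known) {
    stopf("unknown epitope label '%s'; known labels: %s",
          epitope_label, paste(known, collapse = ", "))
  }
  measurements$half_distance_nm[measurements$epitope_label == epitope_label]
}

#' Bootstrap mean with percentile confidence interval
#'
#' Draws `n_replicates` resamples of the data with replacement, each the
#' size of the original sample, and reports the sample mean together with
#' the 2.5% and 97.5% empirical quantiles of the replicate means (linear
#' interpolation between order statistics). Deterministic given `seed`; the
#' caller's RNG state is untouched.
#'
#' @param values Nonempty numeric vector (nm).
#' @param n_replicates Number of bootstrap replicates, default 1000.
#' @param seed Integer seed, default 0.
#' @return A `bootstrap_result` with fields `mean_nm`, `ci_low_nm`,
#'   `ci_high_nm`, `n_replicates`, `n_observations`, `seed` and the raw
#'   `replicate_means`.
#' @export
bootstrap_mean <- function(values, n_replicates = 1000, seed = 0) {
  if (length(values) == 0) stopf("bootstrap_mean needs at least one value")
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  n <- length(values)
  if (n == 1L) {
    warnf("bootstrap over a single observation: zero-width interval")
    reps <- rep(values, n_replicates)
  } else {
    reps <- with_seed(seed, {
      idx <- sample.int(n, n * n_replicates, replace = TRUE)
      rowMeans(matrix(values[idx], nrow = n_replicates))
    })
  }
  ci <- unname(stats::quantile(reps, c(0.025, 0.975), type = 7))
  structure(
    list(
      mean_nm = mean(values), ci_low_nm = ci[1], ci_high_nm = ci[2],
      n_replicates = as.integer(n_replicates), n_observations = n,
      seed = as.integer(seed), replicate_means = reps
    ),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> mean %.2f nm, 95%% CI [%.2f, %.2f] nm (n = %d, %d replicates)\n",
    x$mean_nm, x$ci_low_nm, x$ci_high_nm, x$n_observations, x$n_replicates
  ))
  invisible(x)
}

#' Ordering statistic between two epitopes
#'
#' Matches measurements of two epitopes by `(myofibril_id, zdisc_id)` and
#' counts, over the matched Z-discs, how often epitope A lies strictly
#' closer to the Z-disc than epitope B. Ties count as not-closer and are
#' reported in `n_ties`.
#'
#' @param measurements Measurement data frame.
#' @param epitope_a,epitope_b Epitope labels.
#' @return An `ordering_result` with `n_closer`, `n_total`, `n_ties` and
#'   `mean_offset_nm` (mean of B minus A).
#' @export
ordering_fraction <- function(measurements, epitope_a, epitope_b) {
  pick <- function(label) {
    d <- measurements[measurements$epitope_label == label,
                      c("myofibril_id", "zdisc_id", "half_distance_nm")]
    if (nrow(d) == 0) stopf("no measurements for epitope '%s'", label)
    d
  }
  m <- merge(pick(epitope_a), pick(epitope_b),
             by = c("myofibril_id", "zdisc_id"), suffixes = c("_a", "_b"))
  if (nrow(m) == 0) {
    stopf("no Z-disc carries both '%s' and '%s'", epitope_a, epitope_b)
  }
  ties <- sum(m$half_distance_nm_a == m$half_distance_nm_b)
  if (ties > 0) message(sprintf("%d tie(s) counted as not-closer", ties))
  structure(
    list(
      epitope_a = epitope_a, epitope_b = epitope_b,
      n_closer = sum(m$half_distance_nm_a < m$half_distance_nm_b),
      n_total = nrow(m), n_ties = ties,
      mean_offset_nm = mean(m$half_distance_nm_b - m$half_distance_nm_a)
    ),
    class = "ordering_result"
  )
}

#' @export
print.ordering_result <- function(x, ...) {
  cat(sprintf(
    "<ordering_result> '%s' closer than '%s' in %d of %d Z-discs (mean offset %.2f nm)\n",
    x$epitope_a, x$epitope_b, x$n_closer, x$n_total, x$mean_offset_nm
  ))
  invisible(x)
}

#' Align per-Z-disc profiles on their band-pair midpoints and sum them
#'
#' Each window profile is shifted so that its reference center (typically
#' the epitope band-pair midpoint) moves to 0, rounded to the common bin
#' grid, then the profiles are summed bin-wise over a symmetric axis. Used
#' to build composite sarcomere profiles from many Z-discs.
#'
#' @param profiles List of [axial_profile()] objects on the same bin size
#'   and grid phase.
#' @param centers_nm Reference center of each profile (nm).
#' @return An [axial_profile()] with a symmetric axis around 0.
#' @export
align_and_sum_profiles <- function(profiles, centers_nm) {
  if (length(profiles) == 0) stopf("no profiles to sum")
  if (length(centers_nm) != length(profiles)) {
    stopf("need one center per profile")
  }
  bins <- vapply(profiles, function(p) p$bin_size_nm, numeric(1))
  if (diff(range(bins)) > 1e-9) stopf("profiles have inconsistent bin sizes")
  bin <- bins[1]
  lo <- hi <- numeric(length(profiles))
  for (i in seq_along(profiles)) {
    shift <- round(centers_nm[i] / bin) * bin
    lo[i] <- profiles[[i]]$edges[1] - shift
    hi[i] <- profiles[[i]]$edges[length(profiles[[i]]$edges)] - shift
  }
  phase <- (lo / bin) %% 1
  if (diff(range(phase)) > 1e-6) {
    stopf("profiles are not on a common bin grid")
  }
  glo <- min(lo)
  ghi <- max(hi)
  # extend to a symmetric axis when the grid is anchored at 0
  if (min(phase[1], 1 - phase[1]) < 1e-9) {
    M <- ceiling(max(abs(glo), abs(ghi)) / bin - 1e-9) * bin
    glo <- -M
    ghi <- M
  }
  nb <- as.integer(round((ghi - glo) / bin))
  counts <- numeric(nb)
  for (i in seq_along(profiles)) {
    st <- as.integer(round((lo[i] - glo) / bin))
    idx <- st + seq_along(profiles[[i]]$counts)
    counts[idx] <- counts[idx] + profiles[[i]]$counts
  }
  axial_profile(glo + bin * (0:nb), counts, bin)
}

#' Epitope separation versus sarcomere length
#'
#' Fits `separation_nm ~ sarcomere_length_nm` by ordinary least squares.
#' A slope consistent with zero means the epitope distance is constant
#' while sarcomere length varies — the property that justifies pooling
#' measurements across sarcomeres of different lengths.
#'
#' @param sarcomere_length_nm Sarcomere lengths (nm), one per measurement.
#' @param separation_nm Band separations (nm), same length.
#' @return A `length_trend` with `slope`, `slope_se`, `intercept` and the
#'   paired `data`.
#' @export
distance_vs_length <- function(sarcomere_length_nm, separation_nm) {
  if (length(sarcomere_length_nm) != length(separation_nm)) {
    stopf("inputs must be paired")
  }
  ok <- is.finite(sarcomere_length_nm) & is.finite(separation_nm)
  x <- sarcomere_length_nm[ok]
  y <- separation_nm[ok]
  if (length(x) < 3) stopf("need at least 3 pairs")
  if (stats::var(x) < 1e-12) {
    stopf("degenerate sarcomere-length variance")
  }
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  structure(
    list(
      slope = cf["x", "Estimate"], slope_se = cf["x", "Std. Error"],
      intercept = cf["(Intercept)", "Estimate"],
      data = data.frame(sarcomere_length_nm = x, separation_nm = y)
    ),
    class = "length_trend"
  )
}

#' @export
print.length_trend <- function(x, ...) {
  cat(sprintf(
    "<length_trend> slope %.4g +/- %.4g nm/nm over %d sarcomeres\n",
    x$slope, x$slope_se, nrow(x$data)
  ))
  invisible(x)
}
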