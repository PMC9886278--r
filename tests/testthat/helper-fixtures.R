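# Shared fixture builders. Everything is generated in code; no data files.

# Minimal localization table from coordinate vectors.
make_locs <- function(x, y = rep(0, length(x)), sx = rep(1, length(x)),
                      sy = rep(1, length(x)), pixel_size_nm = 130,
                      channel_label = "ch1") {
  n <- length(x)
  loc_table(
    data.frame(
      frame = seq_len(n) - 1L, x = x, y = y,
      photons = rep(5000, n), sx = sx, sy = sy
    ),
    pixel_size_nm = pixel_size_nm, channel_label = channel_label
  )
}

# Profile with Gaussian bumps at given positions (counts are expected
# values, not draws, so tests on it are deterministic).
make_bump_profile <- function(positions_nm, amplitudes, sigma_nm,
                              bin_size_nm, range_nm) {
  lo <- floor(range_nm[1] / bin_size_nm) * bin_size_nm
  hi <- ceiling(range_nm[2] / bin_size_nm) * bin_size_nm
  nb <- round((hi - lo) / bin_size_nm)
  centers <- lo + bin_size_nm * (seq_len(nb) - 0.5)
  counts <- numeric(nb)
  for (i in seq_along(positions_nm)) {
    counts <- counts +
      amplitudes[i] * exp(-(centers - positions_nm[i])^2 / (2 * sigma_nm^2))
  }
  axial_profile(lo + bin_size_nm * (0:nb), counts, bin_size_nm)
}

# Exhaustive chain-search oracle for detect_zdiscs: enumerate all subsets
# of candidate peaks, keep those whose successive spacings are within the
# tolerance, pick the best under the same tie-break (length, then summed
# prominence, then leftmost start).
oracle_best_chain <- function(pos, prom, lo, hi) {
  k <- length(pos)
  stopifnot(k <= 12)
  best <- NULL
  for (mask in seq_len(2^k) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0)
    if (length(sel) == 0) next
    d <- diff(pos[sel])
    if (length(d) > 0 && (any(d < lo) || any(d > hi))) next
    cand <- list(sel = sel, len = length(sel), w = sum(prom[sel]),
                 start = pos[sel[1]])
    if (is.null(best) ||
        cand$len > best$len ||
        (cand$len == best$len && cand$w > best$w) ||
        (cand$len == best$len && cand$w == best$w &&
           cand$start < best$start)) {
      best <- cand
    }
  }
  best$sel
}

# Independent Gaussian + baseline least-squares oracle for refine_band:
# coarse grid over (mu, sigma) with profiled linear (A, c), then a
# Nelder-Mead polish of the full four-parameter SSE.
oracle_gaussian_fit <- function(u, y, mu_range, sigma_range) {
  sse_linear <- function(mu, sig) {
    g <- exp(-(u - mu)^2 / (2 * sig^2))
    X <- cbind(g, 1)
    beta <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(beta)) return(list(sse = Inf))
    r <- y - X %*% beta
    list(sse = sum(r^2), A = beta[1], c0 = beta[2])
  }
  grid_mu <- seq(mu_range[1], mu_range[2], by = 0.5)
  grid_sig <- seq(sigma_range[1], sigma_range[2], by = 0.5)
  best <- list(sse = Inf)
  for (mu in grid_mu) for (sig in grid_sig) {
    s <- sse_linear(mu, sig)
    if (s$sse < best$sse) best <- c(s, list(mu = mu, sig = sig))
  }
  obj <- function(p) sum((y - (p[1] * exp(-(u - p[2])^2 / (2 * p[3]^2)) + p[4]))^2)
  opt <- stats::optim(c(best$A, best$mu, best$sig, best$c0), obj,
                      control = list(maxit = 5000, reltol = 1e-12))
  list(mu = opt$par[2], sigma = abs(opt$par[3]), A = opt$par[1],
       c0 = opt$par[4], sse = opt$value)
}

# Dual-colour simulation + pipeline wrapper used by several tests.
run_two_colour_pipeline <- function(offset_a, offset_b, n_sarcomeres = 20,
                                    seed = 1, label_a = "A", label_b = "B",
                                    ...) {
  cfg_a <- sim_config(
    n_sarcomeres = n_sarcomeres,
    epitopes = list(sim_epitope(label_a, offset_a, channel_label = "ch1", ...)),
    seed = seed
  )
  cfg_b <- sim_config(
    n_sarcomeres = n_sarcomeres,
    epitopes = list(sim_epitope(label_b, offset_b, channel_label = "ch2", ...)),
    seed = seed
  )
  sim <- simulate_two_colour(cfg_a, cfg_b)
  cfg <- pipeline_config(
    channels = list(ch1 = sim$a$locs, ch2 = sim$b$locs),
    picks = sim$a$pick,
    epitope_map = stats::setNames(list(label_a, label_b), c("ch1", "ch2")),
    pairs = list(c(label_a, label_b)),
    seed = seed
  )
  list(sim = sim, result = run_pipeline(cfg))
}
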