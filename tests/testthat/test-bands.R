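test_that("smoothing reproduces the kernel for a delta and conserves counts", {
  n <- 61
  counts <- numeric(n); counts[31] <- 500
  prof <- axial_profile(13 * (0:n), counts, 13)
  sm <- smooth_profile(prof, 25)
  expect_equal(which.max(sm$counts), 31L)
  expect_lt(abs(sum(sm$counts) - 500) / 500, 1e-6)
  # shape matches a sampled Gaussian
  ctr <- profile_centers(sm)
  expect_gt(stats::cor(sm$counts, exp(-(ctr - ctr[31])^2 / (2 * 25^2))), 0.9999)
})

test_that("edge-renormalized smoothing conserves counts on arbitrary profiles", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(10:80, 1)
    counts <- rpois(n, 20)
    prof <- axial_profile(13 * (0:n), counts, 13)
    sm <- smooth_profile(prof, 25)
    expect_lt(abs(sum(sm$counts) - sum(counts)) / max(1, sum(counts)), 1e-6)
  }
  expect_warning(smooth_profile(axial_profile(13 * (0:10), rep(1, 10), 13), 5),
                 "under-smoothing")
})

test_that("rough band finding locates doublets and merges close peaks", {
  params <- band_params()
  two <- make_bump_profile(c(-50, 50), c(100, 100), 15, 13, c(-300, 300))
  pos <- find_rough_bands(smooth_profile(two, 25), params)
  expect_length(pos, 2L)
  expect_lt(abs(pos[1] + 50), 13)
  expect_lt(abs(pos[2] - 50), 13)

  flat <- axial_profile(13 * (0:40), rep(3, 40), 13)
  expect_length(find_rough_bands(smooth_profile(flat, 25), params), 0L)

  close <- make_bump_profile(c(-50, -45), c(100, 90), 15, 13, c(-300, 300))
  got <- find_rough_bands(smooth_profile(close, 25), params)
  expect_length(got, 1L)
})

test_that("Gaussian refinement recovers the center of histogrammed draws", {
  set.seed(21)
  draws <- rnorm(2000, 100, 15)
  prof <- sarcopaint:::hist_axial(draws, 13)
  fit <- refine_band(prof, 100, band_params(fit_half_nm = 50))
  expect_false(is.null(fit))
  expect_lt(abs(fit$center_nm - mean(draws)), 1)
  expect_lt(abs(fit$sigma_nm - 15), 3)
  expect_gt(fit$center_se_nm, 0)
})

test_that("refinement is exact for a symmetric histogram", {
  # symmetric counts around u0 = 130 on a 13 nm grid
  counts <- c(2, 10, 40, 40, 10, 2)
  prof <- axial_profile(130 - 39 + 13 * (0:6), counts, 13)
  u0 <- 130
  fit <- refine_band(prof, u0, band_params(fit_half_nm = 40))
  expect_false(is.null(fit))
  expect_equal(fit$center_nm, u0, tolerance = 1e-6)
})

test_that("refinement matches a brute-force least-squares oracle", {
  set.seed(33)
  worst <- 0
  for (case in 1:20) {
    mu <- runif(1, -120, 120)
    sig <- runif(1, 10, 20)
    n <- sample(500:3000, 1)
    bg <- sample(0:60, 1)
    draws <- c(rnorm(n, mu, sig), runif(bg, mu - 200, mu + 200))
    prof <- sarcopaint:::hist_axial(draws, 13, range_nm = c(mu - 250, mu + 250))
    rough <- mu + runif(1, -6, 6)
    params <- band_params(fit_half_nm = 45)
    fit <- refine_band(prof, rough, params)
    expect_false(is.null(fit))
    ctr <- profile_centers(prof)
    w <- abs(ctr - rough) <= 45
    orc <- oracle_gaussian_fit(ctr[w], prof$counts[w],
                               mu_range = c(rough - 40, rough + 40),
                               sigma_range = c(5, 30))
    worst <- max(worst, abs(fit$center_nm - orc$mu))
  }
  expect_lt(worst, 0.2)
})

test_that("refinement returns NULL on hopeless windows", {
  sparse <- axial_profile(13 * (0:10), c(0, 0, 1, 0, 0, 0, 2, 0, 0, 0), 13)
  expect_null(refine_band(sparse, 65, band_params()))
})

test_that("epitope pairs give separation and half-distance arithmetic", {
  set.seed(4)
  # bands at -98 and +102 nm around a Z-disc at 0
  draws <- c(rnorm(400, -98, 10), rnorm(400, 102, 10))
  locs <- make_locs(x = draws / 130)
  zd <- zdisc_set(0)
  out <- extract_epitope_pairs(locs, zd, band_params(), "E")
  expect_equal(nrow(out$measurements), 1L)
  m <- out$measurements
  expect_lt(abs(m$separation_nm - 200), 3)
  expect_equal(m$half_distance_nm, m$separation_nm / 2)
  expect_lt(abs(m$left_center_nm + 98), 2)
  expect_lt(abs(m$right_center_nm - 102), 2)
  expect_equal(nrow(out$band_table), 2L)
  expect_equal(out$band_table$side, c("left", "right"))
})

test_that("single-colour two-epitope staining assigns inner and outer by topology", {
  set.seed(8)
  draws <- c(
    rnorm(400, -98, 10), rnorm(400, 98, 10),    # inner pair
    rnorm(400, -350, 12), rnorm(400, 350, 12)   # outer pair
  )
  locs <- make_locs(x = draws / 130)
  out <- extract_epitope_pairs(locs, zdisc_set(0), band_params(),
                               c("inner-ep", "outer-ep"))
  m <- out$measurements
  expect_equal(nrow(m), 2L)
  expect_equal(m$epitope_label, c("inner-ep", "outer-ep"))
  expect_lt(abs(m$half_distance_nm[1] - 98), 3)
  expect_lt(abs(m$half_distance_nm[2] - 350), 3)
})

test_that("Z-discs with missing or surplus bands are skipped with a reason", {
  set.seed(15)
  one_side <- make_locs(x = rnorm(400, -98, 10) / 130)
  out <- extract_epitope_pairs(one_side, zdisc_set(0), band_params(), "E")
  expect_equal(nrow(out$measurements), 0L)
  expect_equal(out$skipped$reason, "missing_band")

  four <- make_locs(x = c(rnorm(400, -98, 10), rnorm(400, 98, 10),
                          rnorm(400, -350, 12), rnorm(400, 350, 12)) / 130)
  out2 <- extract_epitope_pairs(four, zdisc_set(0), band_params(), "E")
  expect_equal(out2$skipped$reason, "ambiguous")
})

test_that("measurements are invariant to input row order", {
  set.seed(19)
  draws <- c(rnorm(500, -90, 12), rnorm(500, 90, 12))
  locs <- make_locs(x = draws / 130)
  perm <- sample.int(nrow(locs))
  locs_perm <- sarcopaint:::restamp(as.data.frame(locs)[perm, ], locs)
  a <- extract_epitope_pairs(locs, zdisc_set(0), band_params(), "E")
  b <- extract_epitope_pairs(locs_perm, zdisc_set(0), band_params(), "E")
  expect_equal(a$measurements$separation_nm, b$measurements$separation_nm)
  expect_equal(a$measurements$left_center_nm, b$measurements$left_center_nm)
})

test_that("half-distances track the per-sarcomere ground truth", {
  check_recovery <- function(res, labels, zd_override = NULL) {
    rot <- rotate_to_pick_axis(filter_multi_emitter(res$locs), res$pick)
    zd <- zd_override %||% detect_zdiscs(project_profile(rot, 130))
    out <- extract_epitope_pairs(rot, zd, band_params(), labels)
    o <- order(res$truth$zdisc_axis_nm)
    truth <- res$truth$zdisc_axis_nm[o]
    for (lab in labels) {
      m <- out$measurements[out$measurements$epitope_label == lab, ]
      expect_gte(nrow(m), 10)
      realized <- res$truth$realized_offsets[[lab]][o]
      ti <- vapply(m$zdisc_id, function(j) {
        which.min(abs(truth - zd$positions_nm[j]))
      }, integer(1))
      err <- m$half_distance_nm - realized[ti]
      expect_lt(mean(abs(err)), 3)
      expect_lt(max(abs(err)), 6)
    }
    zd
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  # dual-colour geometries spanning the I-band epitopes
  for (offs in list(c(50, 98), c(90, 110))) {
    cfg_a <- sim_config(
      n_sarcomeres = 12,
      epitopes = list(sim_epitope("E1", offs[1], channel_label = "ch1")),
      seed = 41
    )
    cfg_b <- sim_config(
      n_sarcomeres = 12,
      epitopes = list(sim_epitope("E2", offs[2], channel_label = "ch2")),
      seed = 41
    )
    two <- simulate_two_colour(cfg_a, cfg_b)
    check_recovery(two$a, "E1")
    check_recovery(two$b, "E2")
  }

  # single-colour co-stain with a far A-band epitope (350 nm): the inner
  # bands anchor the Z-discs, as in combined nanobody stains
  cfg <- sim_config(
    n_sarcomeres = 12,
    epitopes = list(
      sim_epitope("inner", 98, channel_label = "ch1"),
      sim_epitope("outer", 350, channel_label = "ch1")
    ),
    seed = 43
  )
  sim <- simulate_myofibril(cfg)
  check_recovery(sim, c("inner", "outer"))
})
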