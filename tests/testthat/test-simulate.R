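test_that("the noiseless limit puts band rows exactly on the true lines", {
  cfg <- sim_config(
    n_sarcomeres = 3,
    epitopes = list(sim_epitope("E", 100, band_sigma_nm = 0,
                                n_locs_per_band = 50, offset_jitter_nm = 0)),
    loc_precision_nm = 0, background_per_um = 0, outlier_frac = 0,
    myofibril_width_nm = 200, seed = 5
  )
  sim <- simulate_myofibril(cfg)
  rot <- rotate_to_pick_axis(sim$locs, sim$pick)
  x_nm <- sort(unique(round(rot$x * px_size(rot), 6)))
  want <- sort(c(sim$truth$zdisc_axis_nm - 100, sim$truth$zdisc_axis_nm + 100))
  expect_equal(x_nm, want, tolerance = 1e-6)
})

test_that("band spread adds in quadrature with localization precision", {
  cfg <- sim_config(
    n_sarcomeres = 1,
    epitopes = list(sim_epitope("E", 300, band_sigma_nm = 10,
                                n_locs_per_band = 1000, offset_jitter_nm = 0)),
    loc_precision_nm = 5, background_per_um = 0, outlier_frac = 0,
    sarcomere_sd_nm = 0, seed = 2
  )
  sim <- simulate_myofibril(cfg)
  rot <- rotate_to_pick_axis(sim$locs, sim$pick)
  x_nm <- rot$x * px_size(rot)
  z1 <- sort(sim$truth$zdisc_axis_nm)[1]
  band <- x_nm[abs(x_nm - (z1 - 300)) < 100]
  expect_gt(length(band), 900)
  expect_lt(abs(stats::sd(band) - sqrt(10^2 + 5^2)) / sqrt(125), 0.15)
})

test_that("simulation is deterministic in the seed and leaves the caller RNG alone", {
  cfg <- sim_config(n_sarcomeres = 2, seed = 9)
  set.seed(1234)
  before <- .Random.seed
  s1 <- simulate_myofibril(cfg)
  expect_identical(.Random.seed, before)
  s2 <- simulate_myofibril(cfg)
  expect_identical(as.data.frame(s1$locs), as.data.frame(s2$locs))
  expect_identical(s1$truth$zdisc_axis_nm, s2$truth$zdisc_axis_nm)
  s3 <- simulate_myofibril(sim_config(n_sarcomeres = 2, seed = 10))
  expect_false(identical(s1$locs$x, s3$locs$x))
})

test_that("per-band provenance counts are exact", {
  cfg <- sim_config(
    n_sarcomeres = 4,
    epitopes = list(
      sim_epitope("A", 50, n_locs_per_band = 120, channel_label = "c"),
      sim_epitope("B", 350, n_locs_per_band = 80, channel_label = "c")
    ),
    seed = 3
  )
  sim <- simulate_myofibril(cfg)
  prov <- sim$truth$provenance
  expect_equal(nrow(prov), nrow(sim$locs))
  band <- prov[prov$tag == "band", ]
  tab <- table(band$epitope_label, band$zdisc_id, band$side)
  expect_true(all(tab["A", , ] == 120))
  expect_true(all(tab["B", , ] == 80))
  expect_equal(
    sort(unique(prov$tag)),
    c("background", "band", "outlier")
  )
  n_core <- sum(prov$tag != "outlier")
  expect_equal(sum(prov$tag == "outlier"), round(0.05 * n_core))
})

test_that("outlier rows carry inflated fit widths that the filter removes", {
  cfg <- sim_config(n_sarcomeres = 5, seed = 6)
  sim <- simulate_myofibril(cfg)
  prov <- sim$truth$provenance
  kept <- filter_multi_emitter(sim$locs)
  # which original rows survived (x is unique with probability 1)
  kept_idx <- match(round(kept$x, 10), round(sim$locs$x, 10))
  expect_false(any(prov$tag[kept_idx] == "outlier"))
  lost_band <- sum(prov$tag == "band") - sum(prov$tag[kept_idx] == "band")
  expect_lt(lost_band / sum(prov$tag == "band"), 0.01)
})

test_that("dual-colour simulations share geometry only when asked", {
  cfg_a <- sim_config(n_sarcomeres = 3,
                      epitopes = list(sim_epitope("A", 90, channel_label = "c1")),
                      seed = 11)
  cfg_b <- sim_config(n_sarcomeres = 3,
                      epitopes = list(sim_epitope("B", 98, channel_label = "c2")),
                      seed = 11)
  two <- simulate_two_colour(cfg_a, cfg_b, shared_geometry = TRUE)
  expect_identical(two$a$truth$zdisc_axis_nm, two$b$truth$zdisc_axis_nm)
  expect_identical(two$a$pick, two$b$pick)
  expect_false(identical(two$a$locs$x, two$b$locs$x))
  expect_identical(channel(two$a$locs), "c1")
  expect_identical(channel(two$b$locs), "c2")

  cfg_c <- sim_config(n_sarcomeres = 4,
                      epitopes = list(sim_epitope("B", 98, channel_label = "c2")),
                      seed = 12)
  free <- simulate_two_colour(cfg_a, cfg_c, shared_geometry = FALSE)
  expect_false(length(free$a$truth$zdisc_axis_nm) ==
                 length(free$b$truth$zdisc_axis_nm) &&
               identical(free$a$truth$zdisc_axis_nm,
                         free$b$truth$zdisc_axis_nm))

  cfg_px <- sim_config(pixel_size_nm = 108, seed = 1)
  expect_error(simulate_two_colour(cfg_a, cfg_px), "pixel_size_nm")
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_epitope("E", -5), "offset_nm")
  expect_error(sim_config(outlier_frac = 1.5), "outlier_frac")
  expect_error(sim_config(sarcomere_sd_nm = 2000), "sarcomere_sd_nm")
  expect_error(sim_config(n_frames = 0), "n_frames")
  expect_error(
    sim_config(epitopes = list(
      sim_epitope("A", 50, channel_label = "x"),
      sim_epitope("B", 98, channel_label = "y")
    )),
    "channel_label"
  )
})
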