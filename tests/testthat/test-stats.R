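fake_measurements <- function(ids, label, values, myo = 1L) {
  data.frame(
    myofibril_id = myo, zdisc_id = ids, epitope_label = label,
    separation_nm = 2 * values, half_distance_nm = values
  )
}

test_that("half-distance series pools by label and rejects unknown labels", {
  m <- rbind(
    fake_measurements(1:3, "A", c(98, 99, 97)),
    fake_measurements(1:2, "B", c(50, 51))
  )
  expect_equal(half_distance_series(m, "A"), c(98, 99, 97))
  expect_equal(half_distance_series(m, "B"), c(50, 51))
  expect_error(half_distance_series(m, "C"), "known labels: A, B")
  expect_equal(half_distance_series(m[0, ], "A"), numeric(0))
})

test_that("bootstrap of a constant sample gives a zero-width interval", {
  b <- bootstrap_mean(rep(42, 20), seed = 1)
  expect_equal(b$mean_nm, 42)
  expect_equal(b$ci_low_nm, 42)
  expect_equal(b$ci_high_nm, 42)
  expect_equal(b$n_replicates, 1000L)
  expect_warning(one <- bootstrap_mean(5), "single")
  expect_equal(c(one$ci_low_nm, one$ci_high_nm), c(5, 5))
})

test_that("bootstrap is reproducible and respects the interval invariant", {
  set.seed(999)  # caller RNG state must not leak in
  v <- rnorm(40, 100, 5)
  b1 <- bootstrap_mean(v, seed = 7)
  b2 <- bootstrap_mean(v, seed = 7)
  expect_identical(b1$replicate_means, b2$replicate_means)
  expect_identical(c(b1$ci_low_nm, b1$ci_high_nm), c(b2$ci_low_nm, b2$ci_high_nm))
  b3 <- bootstrap_mean(v, seed = 8)
  expect_false(identical(b1$ci_low_nm, b3$ci_low_nm))
  expect_lte(b1$ci_low_nm, b1$mean_nm)
  expect_gte(b1$ci_high_nm, b1$mean_nm)
})

test_that("bootstrap CI width matches the analytic standard error", {
  # n = 50 draws from Normal(100, 5): CI width should be near
  # 2 * 1.96 * 5 / sqrt(50) ~ 2.77
  widths <- numeric(200)
  for (s in 1:200) {
    v <- with(list(), { set.seed(10000 + s); rnorm(50, 100, 5) })
    b <- bootstrap_mean(v, n_replicates = 500, seed = s)
    widths[s] <- b$ci_high_nm - b$ci_low_nm
  }
  expect_lt(abs(mean(widths) - 2.77) / 2.77, 0.35)
})

test_that("ordering counts strict inequalities with ties as not-closer", {
  a <- fake_measurements(1:10, "A", rep(95, 10))
  b <- fake_measurements(1:10, "B", rep(100, 10))
  o <- ordering_fraction(rbind(a, b), "A", "B")
  expect_equal(o$n_closer, 10L)
  expect_equal(o$n_total, 10L)
  expect_equal(o$mean_offset_nm, 5)

  tied <- rbind(fake_measurements(1:4, "A", rep(70, 4)),
                fake_measurements(1:4, "B", rep(70, 4)))
  expect_message(ot <- ordering_fraction(tied, "A", "B"), "tie")
  expect_equal(ot$n_closer, 0L)
  expect_equal(ot$mean_offset_nm, 0)
})

test_that("a constructed 42-of-45 dataset is counted exactly", {
  set.seed(77)
  b_vals <- rnorm(45, 98, 2)
  a_vals <- b_vals - 8
  flip <- sample(45, 3)
  a_vals[flip] <- b_vals[flip] + 2      # three reversals
  m <- rbind(fake_measurements(1:45, "A", a_vals),
             fake_measurements(1:45, "B", b_vals))
  o <- ordering_fraction(m, "A", "B")
  expect_equal(o$n_closer, 42L)
  expect_equal(o$n_total, 45L)

  # antisymmetry
  rev <- ordering_fraction(m, "B", "A")
  expect_equal(rev$n_closer, o$n_total - o$n_closer - o$n_ties)
  expect_equal(rev$mean_offset_nm, -o$mean_offset_nm)
})

test_that("ordering requires matched Z-discs", {
  m <- rbind(fake_measurements(1:3, "A", c(1, 2, 3)),
             fake_measurements(4:6, "B", c(1, 2, 3)))
  expect_error(ordering_fraction(m, "A", "B"), "no Z-disc")
})

test_that("aligned profile sums conserve counts and double identical windows", {
  p <- make_bump_profile(0, 100, 20, 13, c(-130, 130))
  s <- align_and_sum_profiles(list(p, p), c(0, 0))
  i0 <- findInterval(profile_centers(p), s$edges)
  expect_equal(s$counts[i0], 2 * p$counts)
  expect_equal(sum(s$counts), 2 * sum(p$counts))
  # symmetric output axis
  expect_equal(s$edges[1], -s$edges[length(s$edges)])

  # mirror-image windows sum to a symmetric profile
  pm <- axial_profile(p$edges, rev(p$counts), 13)
  sm <- align_and_sum_profiles(list(p, pm), c(0, 0))
  expect_equal(sm$counts, rev(sm$counts), tolerance = 1e-12)

  # shifted windows are re-centered before summing
  q <- make_bump_profile(260, 100, 20, 13, c(130, 390))
  sq <- align_and_sum_profiles(list(p, q), c(0, 260))
  expect_equal(sum(sq$counts), sum(p$counts) + sum(q$counts))
  expect_lt(abs(profile_centers(sq)[which.max(sq$counts)]), 13)

  mismatched <- make_bump_profile(0, 10, 20, 10, c(-100, 100))
  expect_error(align_and_sum_profiles(list(p, mismatched), c(0, 0)),
               "bin sizes")
})

test_that("distance versus length recovers injected slopes", {
  set.seed(55)
  x <- runif(60, 3000, 4000)
  const <- distance_vs_length(x, rep(196, 60) + rnorm(60, 0, 2))
  expect_lt(abs(const$slope), 2 * const$slope_se)

  y <- 100 + 0.02 * x + rnorm(60, 0, 2)
  tr <- distance_vs_length(x, y)
  expect_lt(abs(tr$slope - 0.02), 2 * tr$slope_se)
  # closed-form least-squares oracle
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(tr$slope, beta, tolerance = 1e-12)

  expect_error(distance_vs_length(rep(3500, 10), rnorm(10)), "degenerate")
  expect_error(distance_vs_length(1:2, 1:2), "3 pairs")
})

test_that("bootstrap CI coverage is nominal on Gaussian samples", {
  # moderate-n version of the coverage study (the acceptance test runs 500)
  mu <- 100
  hits <- 0
  for (s in 1:200) {
    v <- with(list(), { set.seed(20000 + s); rnorm(30, mu, 5) })
    b <- bootstrap_mean(v, n_replicates = 400, seed = s)
    if (b$ci_low_nm <= mu && mu <= b$ci_high_nm) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.90)
  expect_lte(hits / 200, 0.99)
})
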