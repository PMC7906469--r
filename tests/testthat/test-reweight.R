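test_that("Maclaurin weights track the exponential with known truncation error", {
  kT <- kT_kcal()
  # zero boost -> weight exactly 1, any rank
  for (k in c(0, 3, 10)) expect_identical(unclass(maclaurin_weights(0, kT, k))[1], 1)
  # dV/kT = 1, rank 10: matches e within 3e-8 relative
  w <- maclaurin_weights(kT, kT, 10)
  expect_lt(abs(w[1] - exp(1)) / exp(1), 3e-8)
  # dV/kT = 3, rank 10: within 5e-4 relative (series tail bound)
  w3 <- maclaurin_weights(3 * kT, kT, 10)
  expect_lt(abs(w3[1] - exp(3)) / exp(3), 5e-4)
  expect_error(maclaurin_weights(-0.1, kT), "non-negative")
})

test_that("high-rank Maclaurin converges to exponential weights", {
  kT <- kT_kcal()
  dV <- seq(0, 5 * kT, length.out = 50)
  wm <- maclaurin_weights(dV, kT, k_max = 50)
  we <- exponential_weights(dV, kT)
  expect_lt(max(abs(wm - we) / we), 1e-10)
})

test_that("weighted averages follow the reweighting formula", {
  expect_equal(weighted_average(c(1, 3), c(1, 3)), 2.5)
  x <- rnorm(100)
  expect_equal(weighted_average(x, rep(2, 100)), mean(x))
  expect_error(weighted_average(1:3, c(0, 0, 0)), "zero")
  expect_error(weighted_average(1:3, 1:2), "length")
  r <- weighted_average(c(1, 3), c(1, 3), se = TRUE)
  expect_equal(r$n_eff, 16 / 10)
})

test_that("reweighting an unbiased run is the identity", {
  pot <- toy_potential("double_well_1d")
  run <- sample_langevin(pot, sampler_config(n_steps = 20000, seed = 9))
  w <- maclaurin_weights(run$boosts, kT = run$config$kT)
  expect_true(all(w == 1))
  x <- run$positions[, 1]
  expect_identical(weighted_average(x, w), weighted_average(x, rep(1, length(x))))
  p1 <- reweighted_pmf(x, weights = w, bin_width = 0.2)
  p2 <- reweighted_pmf(x, bin_width = 0.2)
  expect_identical(p1$pmf, p2$pmf)
  expect_identical(p1$count, p2$count)
})

test_that("PMF surfaces behave on analytic inputs", {
  set.seed(4)
  # uniform samples: occupied cells near zero
  u <- runif(20000, 0, 4)
  p <- reweighted_pmf(u, bin_width = 0.5, kT = 1)
  expect_true(all(p$pmf[p$count > 0] < 0.15))
  # Gaussian: quadratic with curvature kT/sigma^2 (fit within 10%)
  sg <- 0.7
  g <- rnorm(2e5, 0, sg)
  kT <- kT_kcal()
  p <- reweighted_pmf(g, bin_width = 0.2, kT = kT)
  mid <- (p$edges1[-1] + p$edges1[-length(p$edges1)]) / 2
  keep <- p$count > 500
  fit <- lm(p$pmf[keep] ~ I(mid[keep]^2))
  expect_equal(unname(coef(fit)[2]), kT / (2 * sg^2), tolerance = 0.1)
  # empty cells are NA, not Inf
  p2 <- reweighted_pmf(c(rep(0.1, 50), rep(3.9, 50)), bin_width = 0.5)
  expect_true(anyNA(p2$pmf))
  expect_false(any(is.infinite(p2$pmf), na.rm = TRUE))
  expect_equal(min(p2$pmf, na.rm = TRUE), 0)
  # all samples in one cell: flat zero with a warning
  expect_warning(p3 <- reweighted_pmf(rep(0.2, 10), bin_width = 1), "one cell")
  expect_equal(p3$pmf[p3$count > 0], 0)
})

test_that("2D PMF separates two occupied basins", {
  set.seed(8)
  cv1 <- c(rnorm(3000, -1, 0.2), rnorm(3000, 1, 0.2))
  cv2 <- c(rnorm(3000, 0, 0.2), rnorm(3000, 2, 0.2))
  p <- reweighted_pmf(cv1, cv2, bin_width = 0.25)
  expect_true(is.matrix(p$pmf))
  expect_equal(min(p$pmf, na.rm = TRUE), 0)
  expect_equal(sum(p$density), 1)
})

test_that("biased plus reweighted recovers the unbiased well gap", {
  pot <- toy_potential("double_well_1d", barrier = 2, separation = 1, tilt = 0.4)
  kT <- kT_kcal()
  bias <- boost_parameters(E_p = potential_energy(pot, 0) + 1, alpha_p = 2)
  gaps <- vapply(20:22, function(s) {
    run <- sample_langevin(pot, sampler_config(n_steps = 6e5, dt = 5e-4,
                                               seed = s, burn_in = 3e4),
                           bias = bias)
    w <- maclaurin_weights(run$boosts, kT = kT)
    well_free_energy_gap(run, weights = w, kT = kT)
  }, numeric(1))
  exact <- -kT * log(boltzmann_well_ratio(pot, kT = kT))
  expect_lt(abs(mean(gaps) - exact), 0.3 * kT)
})

test_that("effective sample size penalises uneven weights", {
  expect_equal(effective_sample_size(rep(3, 50)), 50)
  expect_lt(effective_sample_size(c(rep(1, 49), 100)), 5)
})
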