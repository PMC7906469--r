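test_that("gradients match potentials by central differences", {
  pots <- list(toy_potential("double_well_1d", barrier = 3, tilt = 0.5),
               toy_potential("two_dim_surface", coupling = 0.3),
               toy_potential("harmonic_1d", barrier = 2))
  h <- 1e-5
  for (pot in pots) {
    set.seed(1)
    pts <- matrix(runif(20 * pot$dim, -2, 2), ncol = pot$dim)
    g <- potential_gradient(pot, pts)
    for (d in seq_len(pot$dim)) {
      up <- pts; up[, d] <- up[, d] + h
      dn <- pts; dn[, d] <- dn[, d] - h
      num <- (potential_energy(pot, up) - potential_energy(pot, dn)) / (2 * h)
      expect_equal(g[, d], num, tolerance = 1e-5)
    }
    expect_true(all(is.finite(potential_energy(pot, pts))))
  }
  # dihedral channel: the y term only
  pot2 <- toy_potential("two_dim_surface", coupling = 0.3)
  pts <- matrix(runif(10, -2, 2), ncol = 2)
  expect_equal(dihedral_gradient(pot2, pts)[, 1], rep(0, 5))
  up <- pts; up[, 2] <- up[, 2] + h
  dn <- pts; dn[, 2] <- dn[, 2] - h
  expect_equal(dihedral_gradient(pot2, pts)[, 2],
               (dihedral_energy(pot2, up) - dihedral_energy(pot2, dn)) / (2 * h),
               tolerance = 1e-5)
})

test_that("identical config and seed reproduce the trajectory bitwise", {
  pot <- toy_potential("double_well_1d")
  cfg <- sampler_config(n_steps = 5000, seed = 11)
  r1 <- sample_langevin(pot, cfg)
  r2 <- sample_langevin(pot, cfg)
  expect_identical(r1$positions, r2$positions)
  expect_identical(r1$boosts$dV, r2$boosts$dV)
})

test_that("a bias below the minimum energy never activates", {
  pot <- toy_potential("double_well_1d", barrier = 2, tilt = 0.3)
  cfg <- sampler_config(n_steps = 20000, seed = 5)
  plain <- sample_langevin(pot, cfg)
  off <- sample_langevin(pot, cfg,
                         bias = boost_parameters(E_p = -100, alpha_p = 1))
  expect_identical(plain$positions, off$positions)
  expect_true(all(off$boosts$dV == 0))
})

test_that("unbiased sampling reproduces Boltzmann well occupancies", {
  pot <- toy_potential("double_well_1d", barrier = 1.2, separation = 1,
                       tilt = 0.4)
  ratios <- vapply(1:4, function(s) {
    run <- sample_langevin(pot, sampler_config(n_steps = 4e5, dt = 5e-4,
                                               seed = s, burn_in = 2e4))
    x <- run$positions[, 1]
    mean(x < 0) / mean(x >= 0)
  }, numeric(1))
  truth <- boltzmann_well_ratio(pot)
  se <- sd(log(ratios)) / sqrt(length(ratios))
  expect_lt(abs(mean(log(ratios)) - log(truth)), 3 * se + 0.05)
})

test_that("harmonic-well variance matches kT/k", {
  k <- 3
  pot <- toy_potential("harmonic_1d", barrier = k)
  run <- sample_langevin(pot, sampler_config(n_steps = 4e5, dt = 2e-4,
                                             seed = 3, burn_in = 2e4))
  x <- run$positions[, 1]
  v <- mean(x^2)
  se <- batch_se(x^2)
  expect_lt(abs(v - kT_kcal() / k), 3 * se + 0.02 * kT_kcal() / k)
})

test_that("the boost accelerates barrier crossing", {
  pot <- toy_potential("double_well_1d", barrier = 2.5, separation = 1)
  cfg <- sampler_config(n_steps = 2e5, dt = 5e-4, seed = 7, burn_in = 1e4)
  plain <- sample_langevin(pot, cfg)
  bias <- boost_parameters(E_p = potential_energy(pot, 0) + 1, alpha_p = 2)
  boosted <- sample_langevin(pot, cfg, bias = bias)
  ncross <- function(x) sum(diff(sign(x)) != 0)
  expect_gt(ncross(boosted$positions[, 1]), ncross(plain$positions[, 1]))
  expect_true(all(boosted$boosts$dV >= 0))
})

test_that("dual-boost biasing records both channels on the 2D surface", {
  pot <- toy_potential("two_dim_surface", barrier = 2, barrier_d = 2)
  bias <- boost_parameters(E_p = potential_energy(pot, c(0, 1)) + 1, alpha_p = 2,
                           E_d = 1.5, alpha_d = 1)
  run <- sample_langevin(pot, sampler_config(n_steps = 20000, seed = 2),
                         bias = bias)
  chk <- amd_boost(run$boosts$V, run$boosts$Vd, bias)
  expect_equal(run$boosts$dV, chk$dV, tolerance = 1e-12)
  expect_true(any(chk$dV_dihedral > 0))
})

test_that("a divergent time step fails loudly", {
  pot <- toy_potential("double_well_1d", barrier = 50, separation = 0.3)
  expect_error(sample_langevin(pot, sampler_config(n_steps = 5000, dt = 0.5,
                                                   seed = 1)),
               "step|diverged")
})
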