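# The GCMC/BD checks run short desk-scale simulations; seeds are fixed and
# tolerances follow the analytic references (Poisson reservoir statistics,
# Nernst-Planck closed form, paired-seed monotonicity).

test_that("buffers hold the target concentration", {
  m <- channel_model(radius = 10, voltage_mV = 0)
  res <- run_gcmcbd(m, gcmcbd_config(cycles = 2e5, seed = 41, replicas = 1))
  tr <- buffer_concentration_trace(res)
  means <- colMeans(tr[, -1])
  expect_true(all(abs(means - 150) / 150 < 0.05))
})

test_that("reservoirs stay clamped under applied voltage", {
  m <- channel_model(radius = 10, voltage_mV = 40)
  res <- run_gcmcbd(m, gcmcbd_config(cycles = 2e5, seed = 43, replicas = 1))
  means <- colMeans(buffer_concentration_trace(res)[, -1])
  expect_true(all(abs(means - 150) / 150 < 0.05))
})

test_that("a symmetric model at zero voltage carries no mean current", {
  m <- channel_model(radius = 10, voltage_mV = 0)
  res <- run_gcmcbd(m, gcmcbd_config(cycles = 1.5e5, seed = 47, replicas = 3,
                                     trace_every = 0L))
  se <- res$current_sd / sqrt(nrow(res$replicas))
  expect_lt(abs(res$current_pA), 3 * se + 1.5)
})

test_that("current is odd in voltage for a symmetric model", {
  gp <- run_gcmcbd(channel_model(radius = 10, voltage_mV = 60),
                   gcmcbd_config(cycles = 4e5, seed = 51, replicas = 1,
                                 trace_every = 0L))
  gm <- run_gcmcbd(channel_model(radius = 10, voltage_mV = -60),
                   gcmcbd_config(cycles = 4e5, seed = 51, replicas = 1,
                                 trace_every = 0L))
  expect_gt(gp$current_pA, 0)
  expect_lt(gm$current_pA, 0)
  tot <- abs(gp$current_pA) + abs(gm$current_pA)
  expect_lt(abs(gp$current_pA + gm$current_pA) / tot, 0.35)
})

test_that("a wide cylinder approaches the Nernst-Planck closed form", {
  m <- channel_model(membrane_thickness = 85, radius = 15, voltage_mV = 40)
  res <- run_gcmcbd(m, gcmcbd_config(cycles = 1e6, dt_ps = 2, seed = 53,
                                     replicas = 1, trace_every = 0L))
  gnp <- np_cylinder_conductance(15, 85)
  expect_lt(abs(res$conductance_nS - gnp) / gnp, 0.25)
})

test_that("a steric obstacle strictly reduces the conductance (paired seeds)", {
  cfg <- gcmcbd_config(cycles = 6e5, dt_ps = 2, seed = 59, replicas = 1,
                       trace_every = 0L)
  open <- run_gcmcbd(channel_model(membrane_thickness = 85, radius = 8,
                                   voltage_mV = 40), cfg)
  blocked <- run_gcmcbd(channel_model(membrane_thickness = 85, radius = 8,
                                      voltage_mV = 40,
                                      obstacle_fraction = 0.5), cfg)
  expect_lt(blocked$conductance_nS, open$conductance_nS)
})

test_that("zero-field zero-well dynamics reduce to free diffusion", {
  # pore as wide as the box (the membrane is invisible), grand canonical
  # exchange off: a closed ideal gas diffusing freely
  m <- channel_model(radius = 300, voltage_mV = 0, box = c(80, 80, 100),
                     membrane_thickness = 20)
  cfg <- gcmcbd_config(cycles = 2e4, dt_ps = 2, seed = 61, replicas = 1,
                       gcmc_per_step = 0L, trace_every = 0L,
                       trace_positions_every = 1L,
                       D_cm2s = c(K = 1.5e-5, CL = 1.5e-5))
  res <- run_gcmcbd(m, cfg)
  pos <- res$pos_traces[[1]]
  ok <- apply(pos, 2, function(p) all(is.finite(p)))
  pos <- pos[, ok, , drop = FALSE]
  expect_gt(dim(pos)[2], 20)
  est <- msd_diffusion(pos, max_lag = 20, dt_ns = cfg$dt_ps / 1000)
  # walls are reflective, so only short lags are in the free regime
  expect_equal(est$D_cm2s, 1.5e-5, tolerance = 0.05)
})

test_that("buffer volume is extensive but concentration intensive", {
  m <- channel_model(radius = 10, voltage_mV = 0)
  r1 <- run_gcmcbd(m, gcmcbd_config(cycles = 1e5, buffer = 5, seed = 67,
                                    replicas = 1))
  r2 <- run_gcmcbd(m, gcmcbd_config(cycles = 1e5, buffer = 10, seed = 67,
                                    replicas = 1))
  c1 <- colMeans(buffer_concentration_trace(r1)[, -1])
  c2 <- colMeans(buffer_concentration_trace(r2)[, -1])
  expect_true(all(abs(c1 - 150) / 150 < 0.07))
  expect_true(all(abs(c2 - 150) / 150 < 0.07))
  # mean counts are extensive: doubling the buffer doubles the count
  per_A3 <- 6.02214076e-7
  n1 <- mean(c1) * per_A3 * 85 * 85 * 5
  n2 <- mean(c2) * per_A3 * 85 * 85 * 10
  expect_equal(n2 / n1, 2, tolerance = 0.1)
})

test_that("invalid configurations are rejected with guidance", {
  m <- channel_model(radius = 10)
  expect_error(run_gcmcbd(m, gcmcbd_config(dt_ps = 500)), "grid|dt_ps")
  expect_warning(
    run_gcmcbd(channel_model(radius = 0.5, voltage_mV = 0),
               gcmcbd_config(cycles = 100, dt_ps = 5, replicas = 1,
                             trace_every = 0L)),
    "unreachable|radius")
  expect_error(channel_model(radius = -1), "positive")
  expect_error(channel_model(membrane_thickness = 200), "membrane_thickness")
})
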