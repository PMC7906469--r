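drift_traj <- function(count = 1, drift = 10, D = 0, frames = 2000,
                       dt = 0.05, seed = 1, species = "CL", charge = -1) {
  sp <- data.frame(species = species, charge = charge, count = count,
                   D_cm2s = D, drift_A_ns = drift)
  generate_ion_trajectory(ion_box_spec(species = sp, frames = frames,
                                       dt_ns = dt, seed = seed,
                                       drift_region = "everywhere"))
}

test_that("stationary ions yield no crossing events", {
  traj <- drift_traj(count = 5, drift = 0, D = 0, frames = 100)
  expect_equal(nrow(detect_crossings(traj)$records), 0L)
})

test_that("a deterministic drift path crosses once per pass, direction +z", {
  # one pass: drift 10 A/ns for 9.5 ns covers one box length (95 A)
  traj <- drift_traj(count = 1, drift = 10, frames = 191, dt = 0.05)
  cr <- detect_crossings(traj)
  expect_equal(nrow(cr$records), 1L)
  expect_equal(cr$records$direction, 1L)
  expect_equal(cr$records$transfer, -1)  # anion moving +z
})

test_that("conveyor flux matches the N v / L bookkeeping oracle", {
  traj <- drift_traj(count = 10, drift = 9.5, frames = 4000, dt = 0.05,
                     seed = 4)
  cr <- detect_crossings(traj)
  rate <- nrow(cr$records) / cr$duration_ns
  expect_equal(rate, 10 * 9.5 / 95, tolerance = 0.01)
})

test_that("pure diffusion gives net crossings consistent with zero", {
  sp <- data.frame(species = c("K", "CL"), charge = c(1, -1),
                   count = c(25, 25), D_cm2s = 2e-5, drift_A_ns = 0)
  traj <- generate_ion_trajectory(ion_box_spec(species = sp, frames = 4000,
                                               dt_ns = 0.05, seed = 13))
  cr <- detect_crossings(traj)
  expect_lt(abs(sum(cr$records$direction)), 3 * sqrt(nrow(cr$records)))
})

test_that("the detector agrees with an independent brute-force replay", {
  sp <- data.frame(species = c("K", "CL"), charge = c(1, -1),
                   count = c(25, 25), D_cm2s = 3e-5, drift_A_ns = c(-4, 4))
  traj <- generate_ion_trajectory(ion_box_spec(species = sp, frames = 3000,
                                               dt_ns = 0.05, seed = 7))
  cr <- detect_crossings(traj)
  oracle <- replay_crossings(traj)
  expect_gt(nrow(cr$records), 10)  # the comparison must be non-vacuous
  expect_equal(nrow(cr$records), nrow(oracle))
  expect_equal(cr$records$ion_id, oracle$ion)
  expect_equal(cr$records$frame, oracle$frame)
  expect_equal(cr$records$direction, oracle$direction)
})

test_that("net events equal up-minus-down events on every prefix", {
  traj <- drift_traj(count = 10, drift = 6, D = 1e-5, frames = 2000, seed = 5)
  cr <- detect_crossings(traj)
  rec <- cr$records
  for (f in c(500, 1000, 2000)) {
    sub <- rec[rec$frame <= f, ]
    expect_equal(cr$series$net_events[f],
                 sum(sub$direction == 1) - sum(sub$direction == -1))
  }
})

test_that("current estimation follows the charge-rate definition", {
  # 96 net anion crossings toward +z in 450 ns, factor 1, endpoints
  ser <- data.frame(time_ns = c(0, 450), net_transfer = c(0, -96))
  rep <- estimate_current(ser, estimator = "endpoints")
  expect_equal(rep$slope_e_ns, -96 / 450, tolerance = 1e-12)
  expect_equal(rep$current_pA, 34.17978, tolerance = 1e-4)
  # zero events: zero current
  z <- estimate_current(data.frame(time_ns = 0:10, net_transfer = 0))
  expect_equal(z$current_pA, 0)
  # linearity: doubling events doubles the current
  d <- estimate_current(data.frame(time_ns = c(0, 450), net_transfer = c(0, -192)),
                        estimator = "endpoints")
  expect_equal(d$current_pA, 2 * rep$current_pA)
  # least squares on a straight line agrees with endpoints and reports R^2
  t <- 0:100
  ls <- estimate_current(data.frame(time_ns = t, net_transfer = -0.5 * t))
  expect_equal(ls$slope_e_ns, -0.5, tolerance = 1e-10)
  expect_equal(ls$r_squared, 1)
  # diffusion scaling multiplies
  sc <- diffusion_scaling()
  expect_equal(sc$factor, 1.918e-5 / 3.273e-5)
  rs <- estimate_current(ser, scaling = sc, estimator = "endpoints")
  expect_equal(rs$current_pA, rep$current_pA * sc$factor)
  expect_error(estimate_current(data.frame(time_ns = 0, net_transfer = 0)),
               "2 time points")
})

test_that("endpoint current equals total transfer over duration exactly", {
  traj <- drift_traj(count = 8, drift = 7, D = 1e-5, frames = 1500, seed = 9)
  cr <- detect_crossings(traj)
  rep <- estimate_current(cr, estimator = "endpoints")
  expect_equal(rep$current_pA,
               -sum(cr$records$transfer) / cr$duration_ns * 160.2177,
               tolerance = 1e-9)
})

test_that("conductance arithmetic and sign conventions hold", {
  expect_equal(conductance_nS(34.98, 40), 0.8745)
  expect_equal(round(conductance_nS(34.98, 40), 2), 0.87)
  expect_equal(conductance_nS(0, 40), 0)
  # passive transport stays positive under sign reversal
  expect_equal(conductance_nS(-34.98, -40), 0.8745)
  expect_error(conductance_nS(1, 0), "zero|voltage")
})

test_that("selectivity ratios and low-count caveats behave", {
  s <- selectivity(c(CL = 10, K = 2), charges = c(CL = -1, K = 1))
  expect_equal(s$ratio, 5)
  expect_equal(selectivity(c(CL = 3, K = 3), charges = c(CL = -1, K = 1))$ratio, 1)
  # zero cation flux: undefined, flagged, no crash
  s0 <- selectivity(c(CL = 4, K = 0), charges = c(CL = -1, K = 1))
  expect_true(is.na(s0$ratio))
  expect_true(s0$undefined)
  # low-count flag from a crossing set with < 5 minority events
  sp <- data.frame(species = c("K", "CL"), charge = c(1, -1),
                   count = c(1, 10), D_cm2s = 0, drift_A_ns = c(9.5, 9.5))
  traj <- generate_ion_trajectory(ion_box_spec(species = sp, frames = 500,
                                               dt_ns = 0.05, seed = 3,
                                               drift_region = "everywhere"))
  sel <- selectivity(detect_crossings(traj))
  expect_true(sel$low_count_flag)
})

test_that("midplane density maps are normalised histograms of passages", {
  traj <- drift_traj(count = 1, drift = 10, frames = 191)
  cr <- detect_crossings(traj)
  md <- midplane_density(traj, cr, species = "CL", bin = 2)
  expect_equal(sum(md$density), 1, tolerance = 1e-12)
  expect_equal(md$n_crossings, 1L)
  expect_equal(sum(md$density > 0), 1L)
  # many crossings: total mass still 1
  traj2 <- drift_traj(count = 20, drift = 9.5, D = 5e-6, frames = 2000, seed = 6)
  cr2 <- detect_crossings(traj2)
  md2 <- midplane_density(traj2, cr2)
  expect_equal(sum(md2$density), 1, tolerance = 1e-12)
  expect_equal(md2$n_crossings, nrow(cr2$records))
  # no crossings: explicit zero count
  still <- drift_traj(count = 2, drift = 0, frames = 50)
  md0 <- midplane_density(still, detect_crossings(still), species = "CL")
  expect_equal(md0$n_crossings, 0L)
  expect_equal(sum(md0$density), 0)
})

test_that("MSD estimation recovers generator diffusion coefficients", {
  # static particles: D = 0
  st <- drift_traj(count = 5, drift = 0, D = 0, frames = 200)
  expect_equal(msd_diffusion(st, max_lag = 20)$D_cm2s, 0)
  # Brownian recovery within 5%
  sp <- data.frame(species = "K", charge = 1, count = 40, D_cm2s = 1e-5,
                   drift_A_ns = 0)
  traj <- generate_ion_trajectory(ion_box_spec(species = sp, frames = 5000,
                                               dt_ns = 0.05, seed = 21))
  est <- msd_diffusion(traj, max_lag = 50)
  expect_equal(est$D_cm2s, 1e-5, tolerance = 0.05)
  expect_true(est$reliable)
  # two species with D ratio 2 recovered within 10%
  sp2 <- data.frame(species = c("A", "B"), charge = c(1, -1),
                    count = c(40, 40), D_cm2s = c(1e-5, 2e-5),
                    drift_A_ns = 0)
  tj2 <- generate_ion_trajectory(ion_box_spec(species = sp2, frames = 4000,
                                              dt_ns = 0.05, seed = 22))
  dA <- msd_diffusion(tj2, species = "A", max_lag = 40)$D_cm2s
  dB <- msd_diffusion(tj2, species = "B", max_lag = 40)$D_cm2s
  expect_equal(dB / dA, 2, tolerance = 0.1)
})
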