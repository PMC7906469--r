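test_that("every generator is bitwise reproducible from its seed", {
  ps <- peptide_spec(frames = 20, seed = 31)
  expect_identical(generate_peptide_ensemble(ps)$ensemble$coords,
                   generate_peptide_ensemble(ps)$ensemble$coords)
  is <- ion_box_spec(frames = 50, seed = 31)
  expect_identical(generate_ion_trajectory(is)$z, generate_ion_trajectory(is)$z)
  truth <- data.frame(residue = 1:5, resname = "ALA", nucleus = "CA",
                      ppm = 50 + 1:5)
  expect_identical(generate_shift_table(truth, 1, 10, 31)$table$ppm,
                   generate_shift_table(truth, 1, 10, 31)$table$ppm)
})

test_that("peptide chains respect geometry and the Markov target", {
  out <- generate_peptide_ensemble(peptide_spec(frames = 400, helix_prob = 0.6,
                                                persistence = 0.8, jitter = 0,
                                                seed = 17))
  # fixed C-alpha bond length when jitter is zero
  d <- apply(out$ensemble$coords, 1, function(xyz)
    sqrt(rowSums(diff(xyz)^2)))
  expect_equal(as.vector(d), rep(3.8, length(d)), tolerance = 1e-9)
  # empirical stationary helix fraction within 3 standard errors
  frac <- mean(out$labels)
  per_frame <- rowMeans(out$labels)
  se <- sd(per_frame) / sqrt(length(per_frame))
  expect_lt(abs(frac - 0.6), 3 * se)
  # degenerate persistence rejected
  expect_error(peptide_spec(helix_prob = 0.5, persistence = 1), "cannot mix")
  expect_silent(peptide_spec(helix_prob = 1, persistence = 1, frames = 2))
})

test_that("ion boxes conserve counts and keep positions in bounds", {
  spec <- ion_box_spec(frames = 300, seed = 8)
  traj <- generate_ion_trajectory(spec)
  expect_equal(ncol(traj$z), sum(spec$species$count))
  expect_true(all(traj$z >= -spec$box[3] / 2 & traj$z <= spec$box[3] / 2))
  expect_true(all(traj$x >= 0 & traj$x <= spec$box[1]))
  expect_true(all(traj$y >= 0 & traj$y <= spec$box[2]))
  # undetectable drift rejected
  expect_error(ion_box_spec(species = data.frame(
    species = "CL", charge = -1, count = 1, D_cm2s = 0, drift_A_ns = 2000),
    dt_ns = 0.1), "crossings undetectable")
  expect_error(ion_box_spec(slab = c(-60, 60)), "inside the box")
})

test_that("shift tables are truth plus iid noise", {
  truth <- data.frame(residue = rep(1:8, each = 2), resname = "ALA",
                      nucleus = rep(c("CA", "CB"), 8), ppm = rnorm(16, 45, 5))
  # sigma = 0: every frame equals truth
  st0 <- generate_shift_table(truth, sigma = 0, frames = 5, seed = 1)
  expect_true(all(st0$table$ppm == rep(truth$ppm, 5)))
  # CLT: unweighted ensemble mean within 3 sigma/sqrt(n) per cell
  st <- generate_shift_table(truth, sigma = 1, frames = 400, seed = 2)
  avg <- ensemble_shifts(st$table)
  key <- function(t) paste(t$residue, t$nucleus)
  m <- avg$ppm[match(key(truth), key(avg))]
  expect_true(all(abs(m - truth$ppm) < 3 * 1 / sqrt(400)))
  # glycine CB rejected
  gt <- data.frame(residue = 1, resname = "GLY", nucleus = "CB", ppm = 30)
  expect_error(generate_shift_table(gt, 1, 2, 1), "glycine|CB")
})

test_that("ensembles round-trip through PDB and XYZ within format precision", {
  out <- generate_peptide_ensemble(peptide_spec(frames = 4, seed = 9))
  ens <- out$ensemble
  pdb <- tempfile(fileext = ".pdb")
  write_pdb_ensemble(ens, pdb)
  back <- read_pdb_ensemble(pdb)
  expect_equal(dim(back$coords), dim(ens$coords))
  expect_lt(max(abs(back$coords - ens$coords)), 1e-3)
  xyz <- tempfile(fileext = ".xyz")
  write_xyz_trajectory(ens, xyz)
  back2 <- read_xyz_trajectory(xyz)
  expect_lt(max(abs(back2$coords - ens$coords)), 1e-3)
  expect_equal(back2$time_ns, ens$time_ns, tolerance = 1e-6)
})

test_that("boost and ion CSV round-trips preserve the data", {
  b <- boost_series(1:10 / 10, V = rnorm(10), Vd = rnorm(10), dV = runif(10))
  f <- tempfile(fileext = ".csv")
  write_boost_csv(b, f)
  b2 <- read_boost_csv(f)
  expect_equal(b2$V, b$V)
  expect_equal(b2$dV, b$dV)
  traj <- generate_ion_trajectory(ion_box_spec(frames = 20, seed = 2))
  fx <- tempfile(fileext = ".xyz"); fm <- tempfile(fileext = ".csv")
  write_ion_trajectory(traj, fx, fm)
  back <- read_ion_trajectory(fx, fm, box = traj$box, slab = traj$slab,
                              dt_ns = traj$dt_ns)
  expect_lt(max(abs(back$z - traj$z)), 1e-3)
  expect_equal(back$ions$charge, traj$ions$charge)
})
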