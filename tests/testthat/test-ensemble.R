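test_that("superposition is exact on rigid copies and matches the quaternion oracle", {
  set.seed(2)
  m <- matrix(rnorm(12), 4, 3)
  # identity
  s <- superpose(m, m)
  expect_equal(s$rmsd, 0, tolerance = 1e-12)
  expect_equal(s$rotation, diag(3), tolerance = 1e-8)
  # rigid copy
  ang <- 0.9
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  m2 <- m %*% R + matrix(rep(c(3, -1, 2), each = 4), 4)
  expect_lt(superpose(m2, m)$rmsd, 1e-10)
  # against the independent quaternion method on random 4-point pairs
  for (i in 1:10) {
    A <- matrix(rnorm(12), 4, 3); B <- matrix(rnorm(12), 4, 3)
    expect_equal(superpose(A, B)$rmsd, quaternion_rmsd(A, B), tolerance = 1e-9)
  }
  # degenerate selection
  line <- cbind(1:4, 2 * (1:4), 3 * (1:4))
  expect_error(superpose(line, line), "collinear|degenerate")
})

test_that("superposed RMSD is a pseudo-metric on sampled triples", {
  out <- generate_peptide_ensemble(peptide_spec(helix_prob = 0.5, persistence = 0.5,
                                                frames = 12, seed = 6))
  d <- as.matrix(pairwise_rmsd(out$ensemble))
  expect_equal(d, t(d), tolerance = 1e-9)
  expect_true(all(diag(d) == 0))
  set.seed(1)
  for (k in 1:30) {
    ijk <- sample(nrow(d), 3)
    expect_lte(d[ijk[1], ijk[3]],
               d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-9)
  }
})

test_that("RMSF recovers imposed fluctuation structure", {
  base <- generate_peptide_ensemble(peptide_spec(length = 60, helix_prob = 1,
                                                 frames = 1, jitter = 0,
                                                 seed = 1))$ensemble
  ref <- base$coords[1, , ]
  # static trajectory: all zero
  co <- array(rep(ref, each = 3), c(3, 60, 3))
  expect_equal(unname(rmsf(conformer_ensemble(co))), rep(0, 60), tolerance = 1e-10)
  # isotropic jitter sigma: RMSF = sigma * sqrt(3) within 5%
  set.seed(12)
  sg <- 0.3
  co <- array(rep(ref, each = 2000), c(2000, 60, 3)) +
    array(rnorm(2000 * 60 * 3, 0, sg), c(2000, 60, 3))
  r <- rmsf(conformer_ensemble(co))
  expect_equal(mean(r), sg * sqrt(3), tolerance = 0.05)
  # jitter on half the atoms only: strict ordering
  co2 <- array(rep(ref, each = 500), c(500, 60, 3))
  co2[, 1:30, ] <- co2[, 1:30, ] + array(rnorm(500 * 30 * 3, 0, 0.5), c(500, 30, 3))
  co2[, 31:60, ] <- co2[, 31:60, ] + array(rnorm(500 * 30 * 3, 0, 0.02), c(500, 30, 3))
  r2 <- rmsf(conformer_ensemble(co2))
  expect_gt(min(r2[1:30]), max(r2[31:60]))
  expect_error(rmsf(conformer_ensemble(array(ref, c(1, 60, 3)))), "2 frames")
})

test_that("radius of gyration matches hand calculations", {
  expect_equal(radius_of_gyration(matrix(c(5, 1, 2), 1)), 0)
  two <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 0.5)
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  expect_equal(radius_of_gyration(cube), sqrt(3))
  expect_error(radius_of_gyration(two, masses = c(0, 0)), "mass")
  # mass weighting moves Rg toward the heavy atom
  expect_lt(radius_of_gyration(two, masses = c(10, 1)),
            radius_of_gyration(two))
})

test_that("RMSD clustering separates constructed groups and honours modes", {
  # all frames identical: one cluster, occupancy 1
  one <- conformer_ensemble(array(rep(matrix(rnorm(30), 10, 3), each = 5),
                                  c(5, 10, 3)))
  c1 <- cluster_rmsd(one, threshold = 3)
  expect_equal(length(c1$medoids), 1L)
  expect_equal(c1$occupancy, 1)
  # two well-separated groups at threshold 3
  tg <- two_group_ensemble(n_per = 20)
  cl <- cluster_rmsd(tg$ensemble, threshold = 3)
  expect_equal(length(cl$medoids), 2L)
  expect_equal(length(unique(cl$labels[tg$groups == 1])), 1L)
  expect_equal(length(unique(cl$labels[tg$groups == 2])), 1L)
  expect_false(cl$labels[1] == cl$labels[40])
  # medoid minimises mean within-cluster distance
  dm <- as.matrix(cl$dist)
  for (g in 1:2) {
    idx <- which(cl$labels == cl$labels[c(1, 40)[g]])
    means <- rowMeans(dm[idx, idx])
    expect_equal(cl$medoids[g], idx[which.min(means)])
  }
  # count mode yields the requested number of clusters
  ck <- cluster_rmsd(tg$ensemble, k = 7)
  expect_equal(length(unique(ck$labels)), 7L)
  expect_equal(length(ck$medoids), 7L)
  # ambiguity and occupancy contract
  expect_error(cluster_rmsd(tg$ensemble, threshold = 3, k = 5), "exactly one")
  expect_equal(sum(cl$occupancy), 1, tolerance = 1e-12)
})

test_that("cluster-count convergence curve is non-decreasing", {
  out <- generate_peptide_ensemble(peptide_spec(helix_prob = 0.5, persistence = 0.3,
                                                frames = 40, seed = 3))
  cl <- cluster_rmsd(out$ensemble, threshold = 4, curve_points = 10)
  expect_true(all(diff(cl$curve$n_clusters) >= 0))
  pl <- cluster_plateau(cl)
  expect_type(pl$plateaued, "logical")
})

test_that("helix propensity recovers generator ground truth", {
  # all-helical: interior propensity 1
  h <- generate_peptide_ensemble(peptide_spec(helix_prob = 1, frames = 40,
                                              seed = 2))
  hp <- helix_propensity(h$ensemble)
  expect_true(all(hp[!is.na(hp)] == 1))
  # Markov stationary 0.7 recovered within 0.03
  m <- generate_peptide_ensemble(peptide_spec(helix_prob = 0.7, persistence = 0.9,
                                              frames = 2000, seed = 4))
  hp <- helix_propensity(m$ensemble)
  expect_lt(abs(mean(hp, na.rm = TRUE) - 0.7), 0.03)
  # label route agrees with stationary target too
  expect_lt(abs(mean(helix_propensity(m$labels)) - 0.7), 0.03)
  # coil-only: below the 5% false-positive ceiling
  cl <- generate_peptide_ensemble(peptide_spec(helix_prob = 0, frames = 300,
                                               seed = 5))
  expect_lte(max(helix_propensity(cl$ensemble), na.rm = TRUE), 0.05)
  # short chain: zero with a warning
  expect_warning(z <- helix_propensity(
    generate_peptide_ensemble(peptide_spec(length = 5, frames = 3, seed = 1))$ensemble),
    "short")
  expect_true(all(z == 0))
})

test_that("ellipticity follows the principal-component definition", {
  th <- seq(0, 2 * pi, length.out = 721)[-1]
  circle <- cbind(cos(th), sin(th))
  expect_lt(ellipticity(circle)$per_frame$e, 1e-10)
  el <- cbind(2 * cos(th), sin(th))
  expect_equal(ellipticity(el)$per_frame$e, 0.5, tolerance = 1e-6)
  # rotational invariance
  ang <- 0.6
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  expect_equal(ellipticity(el %*% R)$per_frame$e,
               ellipticity(el)$per_frame$e, tolerance = 1e-10)
  # semi-axes recover a and b, a >= b > 0, 0 <= e < 1
  r <- ellipticity(el)$per_frame
  expect_equal(r$a, 2, tolerance = 1e-3)
  expect_equal(r$b, 1, tolerance = 1e-3)
  # degenerate cloud
  expect_error(ellipticity(cbind(1:10, 2 * (1:10))), "rank|collinear")
  expect_error(ellipticity(circle[1:4, ]), "at least 5")
})

test_that("weighted observables reduce to unweighted under uniform weights", {
  x <- rnorm(200)
  expect_identical(weighted_average(x, rep(1, 200)), weighted_average(x))
  p1 <- reweighted_pmf(x, weights = rep(1, 200), bin_width = 0.5)
  p2 <- reweighted_pmf(x, bin_width = 0.5)
  expect_identical(p1$pmf, p2$pmf)
})
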