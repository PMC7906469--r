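# Independent oracles and fixture builders used across the test files.

# Horn quaternion superposition: maximal eigenvalue of the 4x4 profile
# matrix gives the optimal proper-rotation overlap, hence the minimal RMSD,
# without any SVD.  Independent of the package's Kabsch implementation.
quaternion_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  S <- crossprod(A, B)
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(sum(A^2) + sum(B^2) - 2 * lam, 0) / nrow(A))
}

# Brute-force replay of the slab-crossing state machine, written as an
# explicit per-frame if-chain.  Returns data.frame(ion, frame, direction).
replay_crossings <- function(traj, hysteresis = 2) {
  lo <- traj$slab[1]; hi <- traj$slab[2]; Lz <- traj$box[3]
  out <- list()
  for (i in seq_len(ncol(traj$z))) {
    zi <- traj$z[, i]
    if (zi[1] < lo) { st <- "below"; org <- "below" }
    else if (zi[1] > hi) { st <- "above"; org <- "above" }
    else { st <- "inside"; org <- "none" }
    for (f in 2:length(zi)) {
      if (abs(zi[f] - zi[f - 1]) > Lz / 2) {
        if (zi[f] < lo) { st <- "below"; org <- "below" }
        else if (zi[f] > hi) { st <- "above"; org <- "above" }
        else { st <- "inside"; org <- "none" }
        next
      }
      z <- zi[f]
      if (st == "below") {
        if (z >= lo && z <= hi) { st <- "inside"; org <- "below" }
        else if (z > hi) { st <- "above"; org <- "above" }
      } else if (st == "above") {
        if (z >= lo && z <= hi) { st <- "inside"; org <- "above" }
        else if (z < lo) { st <- "below"; org <- "below" }
      } else {
        if (z > hi + hysteresis) {
          if (org == "below")
            out[[length(out) + 1L]] <- data.frame(ion = traj$ions$ion_id[i],
                                                  frame = f, direction = 1L)
          st <- "above"; org <- "above"
        } else if (z < lo - hysteresis) {
          if (org == "above")
            out[[length(out) + 1L]] <- data.frame(ion = traj$ions$ion_id[i],
                                                  frame = f, direction = -1L)
          st <- "below"; org <- "below"
        }
      }
    }
  }
  if (!length(out)) return(data.frame(ion = integer(0), frame = integer(0),
                                      direction = integer(0)))
  d <- do.call(rbind, out)
  d[order(d$frame, d$ion), ]
}

# Two well-separated conformal groups built from the same chain geometry
# with a large torsion offset; returns a conformer_ensemble plus the true
# group labels.
two_group_ensemble <- function(n_per = 25, seed = 42) {
  g1 <- generate_peptide_ensemble(peptide_spec(helix_prob = 1, frames = n_per,
                                               jitter = 0.05, seed = seed))
  g2 <- generate_peptide_ensemble(peptide_spec(helix_prob = 1, frames = n_per,
                                               jitter = 0.05, seed = seed + 1,
                                               torsion_offset = 120))
  co <- array(NA_real_, c(2 * n_per, dim(g1$ensemble$coords)[2], 3))
  co[seq_len(n_per), , ] <- g1$ensemble$coords
  co[n_per + seq_len(n_per), , ] <- g2$ensemble$coords
  list(ensemble = conformer_ensemble(co),
       groups = rep(1:2, each = n_per))
}

# batch-means standard error for autocorrelated scalar series
batch_se <- function(x, n_batches = 20) {
  m <- floor(length(x) / n_batches)
  bm <- vapply(seq_len(n_batches), function(b) mean(x[((b - 1) * m + 1):(b * m)]),
               numeric(1))
  stats::sd(bm) / sqrt(n_batches)
}
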