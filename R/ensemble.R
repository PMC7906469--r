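# Conformational-ensemble observables: optimal rigid superposition (Kabsch,
# proper rotations only), RMSD/RMSF/Rg, RMSD-threshold hierarchical
# clustering with medoids and convergence curves, helix propensity from
# virtual C-alpha torsions, and barrel ellipticity from ring projections.

#' Conformer ensemble container
#'
#' @param coords A frames x atoms x 3 numeric array (Angstrom), or a single
#'   atoms x 3 matrix (one frame).
#' @param atoms Optional data.frame of atom records (columns such as
#'   \code{name}, \code{resid}, \code{resname}); defaults to generic CA
#'   records.
#' @param time_ns Optional per-frame time stamps (strictly increasing).
#' @param weights Optional per-frame weights.
#' @return An object of class \code{conformer_ensemble}.
#' @export
conformer_ensemble <- function(coords, atoms = NULL, time_ns = NULL,
                               weights = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, nrow(coords), 3L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (any(!is.finite(coords))) stop("NaN/Inf coordinates in ensemble", call. = FALSE)
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  if (is.null(atoms))
    atoms <- data.frame(name = rep("CA", na), resid = seq_len(na),
                        resname = rep("ALA", na))
  stopifnot(nrow(atoms) == na)
  if (is.null(time_ns)) time_ns <- seq_len(nf)
  stopifnot(length(time_ns) == nf)
  if (nf > 1 && any(diff(time_ns) <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  if (!is.null(weights)) stopifnot(length(weights) == nf, all(weights >= 0))
  structure(list(coords = coords, atoms = atoms, time_ns = as.numeric(time_ns),
                 weights = weights),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("Conformer ensemble: %d frames x %d atoms (%s)\n",
              dim(x$coords)[1], dim(x$coords)[2],
              if (is.null(x$weights)) "unweighted" else "weighted"))
  invisible(x)
}

#' @export
dim.conformer_ensemble <- function(x) dim(x$coords)

.frame <- function(ens, i) ens$coords[i, , , drop = TRUE]

.resolve_selection <- function(selection, n_atoms) {
  if (is.null(selection)) return(seq_len(n_atoms))
  sel <- as.integer(selection)
  if (any(sel < 1 | sel > n_atoms)) stop("selection out of range", call. = FALSE)
  sel
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid transform (proper rotation + translation) of
#' \code{mobile} onto \code{reference} over a common atom selection, via
#' SVD of the covariance matrix with a determinant correction so no
#' reflection is ever returned.
#'
#' @param mobile,reference Atom x 3 coordinate matrices (or single-frame
#'   ensembles).
#' @param selection Integer atom indices used for the fit (default all).
#' @return A list with \code{rotation} (3x3), \code{translation} (length
#'   3), \code{rmsd} (after the fit, over the selection) and \code{coords}
#'   (the transformed full mobile frame).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  if (inherits(mobile, "conformer_ensemble")) mobile <- .frame(mobile, 1)
  if (inherits(reference, "conformer_ensemble")) reference <- .frame(reference, 1)
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3, ncol(reference) == 3)
  sel <- .resolve_selection(selection, nrow(mobile))
  if (length(sel) != length(.resolve_selection(selection, nrow(reference))) &&
      nrow(mobile) != nrow(reference))
    stop("selection sizes differ between mobile and reference", call. = FALSE)
  A <- mobile[sel, , drop = FALSE]; B <- reference[sel, , drop = FALSE]
  if (nrow(A) < 3) stop("need at least 3 atoms to superpose", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # collinearity check: rank of the centred selection
  if (qr(A0)$rank < 2 || qr(B0)$rank < 2)
    stop("degenerate (collinear) atom selection for superposition", call. = FALSE)
  H <- crossprod(A0, B0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  moved <- sweep(mobile, 2, ca) %*% t(R)
  moved <- sweep(moved, 2, cb, FUN = "+")
  rmsd <- sqrt(mean(rowSums((moved[sel, , drop = FALSE] - B)^2)))
  list(rotation = R, translation = cb - as.vector(R %*% ca), rmsd = rmsd,
       coords = moved)
}

#' RMSD between two frames after optimal superposition
#'
#' @inheritParams superpose
#' @return RMSD in Angstrom.
#' @export
rmsd_pair <- function(mobile, reference, selection = NULL)
  superpose(mobile, reference, selection)$rmsd

#' All pairwise superposed RMSDs of an ensemble
#'
#' Exact O(n^2) pairwise RMSD with per-pair Kabsch superposition, intended
#' for desk-scale ensembles (up to a few thousand frames).
#'
#' @param ensemble A [conformer_ensemble()].
#' @param selection Atom indices used for fitting and RMSD.
#' @return A \code{dist} object of length n(n-1)/2.
#' @export
pairwise_rmsd <- function(ensemble, selection = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  nf <- dim(ensemble$coords)[1]
  sel <- .resolve_selection(selection, dim(ensemble$coords)[2])
  # pre-centre once; Kabsch per pair on centred coordinates
  frames <- lapply(seq_len(nf), function(i) {
    m <- ensemble$coords[i, sel, , drop = TRUE]
    sweep(m, 2, colMeans(m))
  })
  d <- numeric(nf * (nf - 1) / 2)
  k <- 1L
  for (j in seq_len(nf - 1L)) {
    B <- frames[[j]]
    for (i in seq.int(j + 1L, nf)) {
      d[k] <- .rmsd_centred(frames[[i]], B)
      k <- k + 1L
    }
  }
  attr(d, "Size") <- nf
  attr(d, "Diag") <- FALSE
  attr(d, "Upper") <- FALSE
  attr(d, "method") <- "superposed RMSD"
  class(d) <- "dist"
  d
}

# minimal-RMSD between centred frames via the Kabsch singular values
.rmsd_centred <- function(A, B) {
  sv <- svd(crossprod(A, B))
  s <- sv$d
  if (det(sv$v %*% t(sv$u)) < 0) s[3] <- -s[3]
  msd <- (sum(A^2) + sum(B^2) - 2 * sum(s)) / nrow(A)
  sqrt(max(msd, 0))
}

#' Per-atom root-mean-square fluctuation
#'
#' Each frame is superposed onto the (iteratively refined) ensemble mean
#' over the selection; the RMSF of an atom is the root-mean-square
#' deviation of its position from its time average.
#'
#' @param ensemble A [conformer_ensemble()] with at least 2 frames.
#' @param selection Atom indices to fit on and report (default all).
#' @return Named numeric vector of per-atom RMSF (Angstrom) over the
#'   selection.
#' @export
rmsf <- function(ensemble, selection = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  nf <- dim(ensemble$coords)[1]
  if (nf < 2) stop("RMSF needs at least 2 frames", call. = FALSE)
  sel <- .resolve_selection(selection, dim(ensemble$coords)[2])
  frames <- lapply(seq_len(nf), function(i) ensemble$coords[i, sel, , drop = TRUE])
  ref <- frames[[1]]
  for (iter in 1:2) {   # two refinement passes are ample for RMSF
    fitted <- lapply(frames, function(f) superpose(f, ref)$coords)
    ref <- Reduce(`+`, fitted) / nf
  }
  mean_pos <- ref
  dev2 <- Reduce(`+`, lapply(fitted, function(f) rowSums((f - mean_pos)^2))) / nf
  out <- sqrt(dev2)
  names(out) <- rownames(ensemble$atoms)[sel]
  out
}

#' Radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum_i m_i |r_i - r_{com}|^2 / \sum_i m_i}}.
#'
#' @param x An atoms x 3 coordinate matrix, or a [conformer_ensemble()]
#'   (one value per frame).
#' @param selection Atom indices (default all).
#' @param masses Optional per-atom masses; equal masses when \code{NULL}.
#' @return Rg in Angstrom (scalar, or per-frame vector for an ensemble).
#' @export
radius_of_gyration <- function(x, selection = NULL, masses = NULL) {
  if (inherits(x, "conformer_ensemble")) {
    nf <- dim(x$coords)[1]
    return(vapply(seq_len(nf), function(i)
      radius_of_gyration(.frame(x, i), selection, masses), numeric(1)))
  }
  stopifnot(is.matrix(x), ncol(x) == 3)
  sel <- .resolve_selection(selection, nrow(x))
  x <- x[sel, , drop = FALSE]
  m <- if (is.null(masses)) rep(1, nrow(x)) else rep_len(masses, nrow(x))
  if (!(sum(m) > 0)) stop("zero total mass", call. = FALSE)
  com <- colSums(x * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
}

#' RMSD-threshold hierarchical clustering of an ensemble
#'
#' Agglomerative clustering on pairwise superposed RMSD, cut either at a
#' distance threshold or at a target cluster count (exactly one of the
#' two).  Reports per-cluster occupancies, medoid frames (the member with
#' minimal mean within-cluster RMSD) and the cluster-count-vs-time
#' convergence curve over growing frame prefixes.
#'
#' @param ensemble A [conformer_ensemble()].
#' @param threshold RMSD cut height in Angstrom (threshold mode).
#' @param k Target number of clusters (count mode).
#' @param linkage \code{"average"} (default) or \code{"complete"}.
#' @param selection Atom indices for the RMSD metric.
#' @param curve_points Number of prefix lengths for the convergence curve
#'   (threshold mode only; 0 disables).
#' @return An object of class \code{cluster_result}: \code{labels},
#'   \code{medoids}, \code{occupancy}, \code{threshold}/\code{k},
#'   \code{linkage}, \code{curve} (data.frame frame/time/n_clusters) and
#'   the \code{dist} matrix used.
#' @export
cluster_rmsd <- function(ensemble, threshold = NULL, k = NULL,
                         linkage = c("average", "complete"),
                         selection = NULL, curve_points = 20L) {
  linkage <- match.arg(linkage)
  if (is.null(threshold) == is.null(k))
    stop("give exactly one of 'threshold' (Angstrom) or 'k' (cluster count)",
         call. = FALSE)
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  nf <- dim(ensemble$coords)[1]
  if (!is.null(k) && k > nf)
    stop("requested more clusters than frames", call. = FALSE)
  d <- pairwise_rmsd(ensemble, selection)
  hc <- stats::hclust(d, method = linkage)
  labels <- if (!is.null(threshold)) stats::cutree(hc, h = threshold)
            else stats::cutree(hc, k = k)
  dm <- as.matrix(d)
  clusters <- sort(unique(labels))
  medoids <- vapply(clusters, function(cl) {
    idx <- which(labels == cl)
    if (length(idx) == 1L) return(idx)
    idx[which.min(rowMeans(dm[idx, idx, drop = FALSE]))]
  }, integer(1))
  occupancy <- as.vector(table(labels)[as.character(clusters)]) / nf
  curve <- NULL
  if (!is.null(threshold) && curve_points > 0 && nf > 2) {
    at <- unique(pmax(2L, round(seq(2, nf, length.out = min(curve_points, nf - 1L)))))
    ncl <- vapply(at, function(m) {
      hm <- stats::hclust(stats::as.dist(dm[seq_len(m), seq_len(m)]), method = linkage)
      max(stats::cutree(hm, h = threshold))
    }, integer(1))
    curve <- data.frame(frame = at, time_ns = ensemble$time_ns[at], n_clusters = ncl)
  }
  structure(list(labels = labels, medoids = medoids, occupancy = occupancy,
                 threshold = threshold, k = k, linkage = linkage,
                 curve = curve, dist = d, time_ns = ensemble$time_ns),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("RMSD clustering (%s linkage, %s): %d clusters over %d frames\n",
              x$linkage,
              if (!is.null(x$threshold)) sprintf("threshold %.2f A", x$threshold)
              else sprintf("k = %d", x$k),
              length(x$medoids), length(x$labels)))
  top <- order(x$occupancy, decreasing = TRUE)[seq_len(min(5, length(x$occupancy)))]
  cat("  top occupancies:",
      paste(sprintf("%.1f%%", 100 * x$occupancy[top]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.cluster_result <- function(x, ...) {
  if (is.null(x$curve)) stop("no convergence curve (count mode)", call. = FALSE)
  plot(x$curve$time_ns, x$curve$n_clusters, type = "s",
       xlab = "time (ns)", ylab = "clusters found", ...)
  invisible(x)
}

#' Plateau diagnostic for a cluster convergence curve
#'
#' Reports whether the cluster count grew by no more than
#' \code{tolerance} (fraction of the final count) over the trailing
#' \code{tail_frac} of frames.  Purely diagnostic; never auto-decides.
#'
#' @param result A [cluster_rmsd()] result with a convergence curve.
#' @param tail_frac Trailing fraction of frames examined (default 0.25).
#' @param tolerance Allowed relative growth (default 0.02).
#' @return List with \code{plateaued}, \code{growth}, \code{tail_frac}.
#' @export
cluster_plateau <- function(result, tail_frac = 0.25, tolerance = 0.02) {
  stopifnot(inherits(result, "cluster_result"), !is.null(result$curve))
  cv <- result$curve
  cut <- max(cv$frame) * (1 - tail_frac)
  tail <- cv[cv$frame >= cut, ]
  growth <- (max(tail$n_clusters) - min(tail$n_clusters)) / max(cv$n_clusters)
  list(plateaued = growth <= tolerance, growth = growth, tail_frac = tail_frac)
}

#' Virtual C-alpha torsions of an ensemble
#'
#' Torsion k is defined by atoms (k, k+1, k+2, k+3) of the selection.
#'
#' @param ensemble A [conformer_ensemble()].
#' @param selection Atom indices forming the chain (default all).
#' @return frames x (n-3) matrix of torsions in degrees (-180, 180].
#' @export
virtual_torsions <- function(ensemble, selection = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  sel <- .resolve_selection(selection, dim(ensemble$coords)[2])
  if (length(sel) < 4) stop("need at least 4 chain atoms for torsions", call. = FALSE)
  nf <- dim(ensemble$coords)[1]
  t(vapply(seq_len(nf), function(i) {
    xyz <- ensemble$coords[i, sel, , drop = TRUE]
    .chain_torsions(xyz)
  }, numeric(length(sel) - 3L)))
}

.chain_torsions <- function(xyz) {
  n <- nrow(xyz)
  b1 <- xyz[2:(n - 2), ] - xyz[1:(n - 3), ]
  b2 <- xyz[3:(n - 1), ] - xyz[2:(n - 2), ]
  b3 <- xyz[4:n, ] - xyz[3:(n - 1), ]
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(rowSums(b2^2)))
  x <- rowSums(n1 * n2); y <- rowSums(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' Per-residue helix propensity
#'
#' Fraction of frames each residue is helical.  Input is either a logical
#' / 0-1 label matrix (frames x residues, e.g. generator ground truth) or
#' a [conformer_ensemble()], in which case virtual C-alpha torsions are
#' classified: a residue is helical on a frame iff it belongs to a run of
#' at least \code{min_run} consecutive residues whose torsions lie inside
#' \code{window}.  Torsion k is attributed to residue k; the last three
#' residues of the chain carry no torsion and are reported as \code{NA}.
#'
#' The default window spans +/- 15 degrees around the canonical helical
#' virtual torsion (~52 degrees), about three standard deviations of the
#' torsion noise induced by typical coordinate jitter, so a genuinely
#' helical residue is rarely rejected while extended/coil torsions never
#' enter the window.
#'
#' @param x Label matrix or ensemble.
#' @param window Helical torsion window in degrees (default c(37, 67)).
#' @param min_run Minimum helical stretch in residues (default 3).
#' @param selection Chain atom indices (ensemble input).
#' @return Numeric vector of per-residue propensities in [0, 1].
#' @export
helix_propensity <- function(x, window = c(37, 67), min_run = 3L,
                             selection = NULL) {
  if (inherits(x, "conformer_ensemble")) {
    sel <- .resolve_selection(selection, dim(x$coords)[2])
    n_res <- length(sel)
    if (n_res < min_run + 3L) {
      warning("chain shorter than the minimum helical stretch: zero propensity",
              call. = FALSE)
      return(rep(0, n_res))
    }
    tor <- virtual_torsions(x, selection)
    inw <- tor >= window[1] & tor <= window[2]
    lab <- t(apply(inw, 1, .runs_to_labels, min_run = min_run))
    prop <- colMeans(lab)
    c(prop, rep(NA_real_, 3L))
  } else {
    lab <- as.matrix(x) > 0.5
    colMeans(lab)
  }
}

# mark positions belonging to runs of TRUE with length >= min_run
.runs_to_labels <- function(v, min_run) {
  r <- rle(v)
  keep <- r$values & r$lengths >= min_run
  rep(keep, r$lengths)
}

#' Barrel ellipticity from ring projections
#'
#' Principal-component fit of the (x, y) cloud of barrel anchor points per
#' frame: with eigenvalues \eqn{\lambda_1 \ge \lambda_2} of the 2x2
#' covariance, the semi-axes are \eqn{a = \sqrt{2\lambda_1}},
#' \eqn{b = \sqrt{2\lambda_2}} and the ellipticity \eqn{e = 1 - b/a}.
#'
#' @param rings A frames x points x 2 array, a list of points x 2
#'   matrices, or a single matrix (one frame).  At least 5 ring points per
#'   frame.
#' @return An object of class \code{ellipticity_report}: data.frame
#'   \code{per_frame} (a, b, e) plus \code{mean_e} and \code{sd_e}.
#' @export
ellipticity <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  if (is.array(rings) && length(dim(rings)) == 3L)
    rings <- lapply(seq_len(dim(rings)[1]), function(i) rings[i, , , drop = TRUE])
  per <- t(vapply(rings, function(p) {
    stopifnot(is.matrix(p), ncol(p) == 2)
    if (nrow(p) < 5) stop("need at least 5 ring points per frame", call. = FALSE)
    ev <- eigen(stats::cov(p), symmetric = TRUE)$values
    if (ev[2] <= .Machine$double.eps * max(ev[1], 1))
      stop("rank-deficient ring cloud: points are collinear", call. = FALSE)
    a <- sqrt(2 * ev[1]); b <- sqrt(2 * ev[2])
    c(a = a, b = b, e = 1 - b / a)
  }, numeric(3)))
  per <- as.data.frame(per)
  structure(list(per_frame = per, mean_e = mean(per$e),
                 sd_e = if (nrow(per) > 1) stats::sd(per$e) else NA_real_),
            class = "ellipticity_report")
}

#' @export
print.ellipticity_report <- function(x, ...) {
  cat(sprintf("Ellipticity over %d frames: mean e = %.3f (sd %.3f)\n",
              nrow(x$per_frame), x$mean_e, x$sd_e))
  invisible(x)
}
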