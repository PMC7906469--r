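# Boltzmann reweighting of biased ensembles.  The exact per-frame weight is
# exp(dV/kT); to suppress exponential amplification of boost noise the
# weights are approximated by the truncated Maclaurin series
# sum_{k=0}^{k_max} (dV/kT)^k / k!  (default rank 10).

#' Maclaurin-series reweighting factors
#'
#' Per-frame weights \eqn{w_i = \sum_{k=0}^{k_{max}} (\Delta V_i/kT)^k/k!},
#' accumulated in ascending rank with a running factorial so no large
#' factorial is ever formed explicitly.
#'
#' @param boosts A [boost_series()], a data.frame with a \code{dV} column,
#'   or a numeric vector of per-frame boosts (kcal/mol, all non-negative).
#' @param kT Thermal energy, kcal/mol.
#' @param k_max Truncation rank (default 10).
#' @return An object of class \code{weight_vector}: numeric weights with
#'   attributes \code{kT}, \code{k_max} and \code{scheme}.
#' @examples
#' w <- maclaurin_weights(c(0, 0.5925), kT = 0.5925, k_max = 10)
#' w[1]                    # exactly 1 for zero boost
#' w[2] - exp(1)           # truncation error ~ -2.7e-8
#' @export
maclaurin_weights <- function(boosts, kT = kT_kcal(), k_max = 10L) {
  dV <- .extract_dV(boosts)
  stopifnot(kT > 0, k_max >= 0)
  if (any(dV < 0))
    stop("negative boost dV: reweighting requires a non-negative bias", call. = FALSE)
  u <- dV / kT
  w <- rep(1, length(u))
  term <- rep(1, length(u))
  for (k in seq_len(k_max)) {
    term <- term * u / k
    w <- w + term
  }
  structure(w, kT = kT, k_max = as.integer(k_max), scheme = "maclaurin",
            class = "weight_vector")
}

#' Exact exponential reweighting factors
#'
#' @inheritParams maclaurin_weights
#' @return A \code{weight_vector} with \code{scheme = "exponential"}.
#' @export
exponential_weights <- function(boosts, kT = kT_kcal()) {
  dV <- .extract_dV(boosts)
  stopifnot(kT > 0)
  if (any(dV < 0))
    stop("negative boost dV: reweighting requires a non-negative bias", call. = FALSE)
  structure(exp(dV / kT), kT = kT, k_max = NA_integer_, scheme = "exponential",
            class = "weight_vector")
}

.extract_dV <- function(boosts) {
  if (is.data.frame(boosts)) {
    if (!"dV" %in% names(boosts)) stop("no 'dV' column in boost series", call. = FALSE)
    boosts$dV
  } else if (inherits(boosts, "langevin_run")) {
    boosts$boosts$dV
  } else as.numeric(boosts)
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("Reweighting factors: %d frames, scheme %s%s, kT = %.4f kcal/mol\n",
              length(x), attr(x, "scheme"),
              if (!is.na(attr(x, "k_max"))) sprintf(" (rank %d)", attr(x, "k_max")) else "",
              attr(x, "kT")))
  cat(sprintf("  effective sample size: %.1f\n", effective_sample_size(x)))
  invisible(x)
}

#' Effective sample size of a weight vector
#'
#' Kish effective sample size \eqn{(\sum w)^2 / \sum w^2}, used for the
#' standard errors of reweighted averages.
#'
#' @param weights Numeric weights (e.g. a \code{weight_vector}).
#' @return Effective number of frames.
#' @export
effective_sample_size <- function(weights) {
  w <- as.numeric(weights)
  sum(w)^2 / sum(w^2)
}

#' Reweighted ensemble average of a collective variable
#'
#' \eqn{\langle\xi\rangle = \sum_i w_i \xi_i / \sum_i w_i}.
#'
#' @param values Per-frame collective-variable values.
#' @param weights Per-frame weights (uniform when \code{NULL}).
#' @param se Also return the weighted standard error (via the effective
#'   sample size)?
#' @return The weighted mean, or a list \code{(mean, se, n_eff)} when
#'   \code{se = TRUE}.
#' @examples
#' weighted_average(c(1, 3), c(1, 3))  # 2.5
#' @export
weighted_average <- function(values, weights = NULL, se = FALSE) {
  values <- as.numeric(values)
  w <- if (is.null(weights)) rep(1, length(values)) else as.numeric(weights)
  if (length(w) != length(values))
    stop("values and weights must have equal length", call. = FALSE)
  sw <- sum(w)
  if (!(sw > 0)) stop("weights sum to zero: average undefined", call. = FALSE)
  m <- sum(w * values) / sw
  if (!se) return(m)
  neff <- effective_sample_size(w)
  v <- sum(w * (values - m)^2) / sw
  list(mean = m, se = sqrt(v / neff), n_eff = neff)
}

#' Potential of mean force over one or two collective variables
#'
#' Weighted histogram density \eqn{\rho} over a regular grid, converted to
#' a free-energy surface \eqn{-kT \ln(\rho/\rho_{max})} so the minimum
#' occupied cell is at 0.  Empty cells are reported as \code{NA}
#' (missing), never as \code{Inf}.
#'
#' @param cv1 Per-frame values of the first collective variable.
#' @param cv2 Optional second collective variable (2D surface).
#' @param weights Per-frame weights (uniform when \code{NULL}).
#' @param bin_width Bin width in the CV units (default 0.5, used for both
#'   axes unless \code{breaks1}/\code{breaks2} given).
#' @param breaks1,breaks2 Explicit bin edges overriding \code{bin_width}.
#' @param kT Thermal energy, kcal/mol.
#' @return An object of class \code{pmf_surface}: list with \code{edges1},
#'   \code{edges2} (NULL for 1D), \code{pmf} (vector or matrix, kcal/mol,
#'   NA = unoccupied), \code{count} (unweighted occupancy), \code{density},
#'   \code{kT}.
#' @export
reweighted_pmf <- function(cv1, cv2 = NULL, weights = NULL, bin_width = 0.5,
                           breaks1 = NULL, breaks2 = NULL, kT = kT_kcal()) {
  cv1 <- as.numeric(cv1)
  if (any(!is.finite(cv1))) stop("non-finite values in cv1", call. = FALSE)
  n <- length(cv1)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n) stop("weights length must match frames", call. = FALSE)
  if (!(sum(w) > 0)) stop("weights sum to zero", call. = FALSE)
  edges <- function(x, br) {
    if (!is.null(br)) return(br)
    lo <- floor(min(x) / bin_width) * bin_width
    hi <- ceiling(max(x) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    seq(lo, hi, by = bin_width)
  }
  e1 <- edges(cv1, breaks1)
  i1 <- findInterval(cv1, e1, rightmost.closed = TRUE, all.inside = TRUE)
  if (is.null(cv2)) {
    dens <- as.vector(tapply_sum(i1, w, length(e1) - 1L))
    cnt <- as.vector(tapply_sum(i1, rep(1, n), length(e1) - 1L))
    e2 <- NULL
  } else {
    cv2 <- as.numeric(cv2)
    if (any(!is.finite(cv2))) stop("non-finite values in cv2", call. = FALSE)
    if (length(cv2) != n) stop("cv1 and cv2 must have equal length", call. = FALSE)
    e2 <- edges(cv2, breaks2)
    i2 <- findInterval(cv2, e2, rightmost.closed = TRUE, all.inside = TRUE)
    idx <- i1 + (i2 - 1L) * (length(e1) - 1L)
    dens <- matrix(tapply_sum(idx, w, (length(e1) - 1L) * (length(e2) - 1L)),
                   nrow = length(e1) - 1L)
    cnt <- matrix(tapply_sum(idx, rep(1, n), (length(e1) - 1L) * (length(e2) - 1L)),
                  nrow = length(e1) - 1L)
  }
  dens <- dens / sum(dens)
  occupied <- cnt > 0
  pmf <- dens
  pmf[] <- NA_real_
  if (all(dens[occupied] == dens[occupied][1])) {
    # single occupied cell or perfectly flat: degenerate surface
    pmf[occupied] <- 0
    if (sum(occupied) == 1L)
      warning("all samples fall in one cell: flat zero PMF", call. = FALSE)
  } else {
    pmf[occupied] <- -kT * log(dens[occupied] / max(dens[occupied]))
  }
  structure(list(edges1 = e1, edges2 = e2, pmf = pmf, count = cnt,
                 density = dens, kT = kT),
            class = "pmf_surface")
}

# dense grouped sum (base R workhorse for histogram accumulation)
tapply_sum <- function(index, values, n_cells) {
  out <- numeric(n_cells)
  s <- rowsum(values, group = index)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' @export
print.pmf_surface <- function(x, ...) {
  d <- if (is.null(x$edges2)) 1L else 2L
  occ <- sum(x$count > 0)
  cat(sprintf("PMF surface (%dD): %d occupied / %d cells, kT = %.4f kcal/mol\n",
              d, occ, length(x$count), x$kT))
  cat(sprintf("  range of occupied cells: 0 to %.3f kcal/mol\n",
              max(x$pmf, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.pmf_surface <- function(x, xlab = "CV1", ylab = if (is.null(x$edges2)) "PMF (kcal/mol)" else "CV2", ...) {
  mid <- function(e) (e[-1] + e[-length(e)]) / 2
  if (is.null(x$edges2)) {
    plot(mid(x$edges1), x$pmf, type = "b", xlab = xlab, ylab = ylab, ...)
  } else {
    graphics::image(mid(x$edges1), mid(x$edges2), x$pmf,
                    xlab = xlab, ylab = ylab, ...)
  }
  invisible(x)
}

#' Free-energy gap between the two wells of a 1D run
#'
#' Convenience estimator used in reweighting-recovery checks:
#' \eqn{\Delta G = -kT \ln(P(x<divide)/P(x>divide))} from (optionally
#' weighted) occupancies.
#'
#' @param x Per-frame positions (numeric) or a \code{langevin_run}.
#' @param weights Optional per-frame weights.
#' @param divide Dividing surface (default 0).
#' @param kT Thermal energy.
#' @return Free-energy gap in kcal/mol (left well minus right well).
#' @export
well_free_energy_gap <- function(x, weights = NULL, divide = 0, kT = kT_kcal()) {
  if (inherits(x, "langevin_run")) x <- x$positions[, 1]
  x <- as.numeric(x)
  w <- if (is.null(weights)) rep(1, length(x)) else as.numeric(weights)
  pl <- sum(w[x < divide]); pr <- sum(w[x >= divide])
  if (pl <= 0 || pr <= 0)
    stop("one well is unoccupied: free-energy gap undefined", call. = FALSE)
  -kT * log(pl / pr)
}
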