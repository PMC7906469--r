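# Analytic toy potentials for exercising biased sampling and reweighting.
#
# double_well_1d:  V(x) = barrier * ((x/a)^2 - 1)^2 + tilt * x
#   wells near x = -a and x = +a; 'tilt' breaks the symmetry so the
#   well free-energy gap is non-trivial.
# two_dim_surface: V(x, y) = Vx(x) + Vy(y) + coupling * x * y, with
#   Vx a double well and Vy(y) = barrier_d * ((y/a_d)^2 - 1)^2.
#   Vy is designated the "dihedral" energy channel so the dual-boost code
#   path can be exercised without torsion machinery.

#' Construct an analytic toy potential
#'
#' @param kind \code{"double_well_1d"}, \code{"two_dim_surface"} or
#'   \code{"harmonic_1d"} (for which \code{barrier} is the force constant
#'   k of \eqn{V = k x^2 / 2}, kcal/mol/\eqn{\AA^2}).
#' @param barrier Barrier height of the x double well (kcal/mol).
#' @param separation Half well separation a (\eqn{\AA}-like length); wells
#'   sit near \eqn{\pm a}.
#' @param tilt Linear asymmetry term (kcal/mol per length unit).
#' @param barrier_d,separation_d Double-well parameters of the y
#'   ("dihedral") term of the 2D surface.
#' @param coupling Bilinear x-y coupling constant (2D surface only).
#' @return An object of class \code{toy_potential} with evaluators
#'   accessible through [potential_energy()], [potential_gradient()],
#'   [dihedral_energy()] and [dihedral_gradient()].
#' @examples
#' pot <- toy_potential("double_well_1d", barrier = 3, separation = 1, tilt = 0.5)
#' potential_energy(pot, 0)     # barrier top (plus tilt contribution)
#' @export
toy_potential <- function(kind = c("double_well_1d", "two_dim_surface",
                                   "harmonic_1d"),
                          barrier = 3, separation = 1, tilt = 0,
                          barrier_d = 2, separation_d = 1, coupling = 0) {
  kind <- match.arg(kind)
  for (v in c(barrier, separation, tilt, barrier_d, separation_d, coupling))
    .assert_scalar_finite(v, "toy potential parameter")
  if (separation <= 0 || (kind == "two_dim_surface" && separation_d <= 0))
    stop("well separations must be positive", call. = FALSE)
  structure(list(kind = kind, barrier = barrier, separation = separation,
                 tilt = tilt, barrier_d = barrier_d,
                 separation_d = separation_d, coupling = coupling,
                 dim = if (kind == "two_dim_surface") 2L else 1L),
            class = "toy_potential")
}

#' @export
print.toy_potential <- function(x, ...) {
  cat(sprintf("Toy potential '%s' (%dD): barrier %.3g, separation %.3g, tilt %.3g",
              x$kind, x$dim, x$barrier, x$separation, x$tilt))
  if (x$kind == "two_dim_surface")
    cat(sprintf("; dihedral term barrier %.3g, separation %.3g, coupling %.3g",
                x$barrier_d, x$separation_d, x$coupling))
  cat("\n")
  invisible(x)
}

.dw <- function(x, h, a) h * ((x / a)^2 - 1)^2
.dw_grad <- function(x, h, a) 4 * h * x * (x^2 - a^2) / a^4

#' Evaluate a toy potential
#'
#' @param pot A [toy_potential()] object.
#' @param x Position: a numeric vector of length \code{pot$dim}, or a
#'   matrix with one row per point.
#' @return Potential value(s) in kcal/mol.
#' @export
potential_energy <- function(pot, x) {
  stopifnot(inherits(pot, "toy_potential"))
  x <- .as_points(x, pot$dim)
  if (pot$kind == "harmonic_1d")
    return(0.5 * pot$barrier * x[, 1]^2 + pot$tilt * x[, 1])
  v <- .dw(x[, 1], pot$barrier, pot$separation) + pot$tilt * x[, 1]
  if (pot$dim == 2L)
    v <- v + .dw(x[, 2], pot$barrier_d, pot$separation_d) +
      pot$coupling * x[, 1] * x[, 2]
  v
}

#' @rdname potential_energy
#' @return For [potential_gradient()], a matrix (points x dim) of gradients.
#' @export
potential_gradient <- function(pot, x) {
  stopifnot(inherits(pot, "toy_potential"))
  x <- .as_points(x, pot$dim)
  if (pot$kind == "harmonic_1d")
    return(cbind(pot$barrier * x[, 1] + pot$tilt))
  g1 <- .dw_grad(x[, 1], pot$barrier, pot$separation) + pot$tilt
  if (pot$dim == 1L) return(cbind(g1))
  g1 <- g1 + pot$coupling * x[, 2]
  g2 <- .dw_grad(x[, 2], pot$barrier_d, pot$separation_d) +
    pot$coupling * x[, 1]
  cbind(g1, g2)
}

#' Dihedral-channel energy of a toy potential
#'
#' The y-axis double-well term of the 2D surface plays the role of the
#' dihedral energy for dual-boost tests; it is identically zero for the 1D
#' potential.
#'
#' @inheritParams potential_energy
#' @return Dihedral energy value(s), kcal/mol.
#' @export
dihedral_energy <- function(pot, x) {
  stopifnot(inherits(pot, "toy_potential"))
  x <- .as_points(x, pot$dim)
  if (pot$dim == 1L) return(numeric(nrow(x)))
  .dw(x[, 2], pot$barrier_d, pot$separation_d)
}

#' @rdname dihedral_energy
#' @export
dihedral_gradient <- function(pot, x) {
  stopifnot(inherits(pot, "toy_potential"))
  x <- .as_points(x, pot$dim)
  if (pot$dim == 1L) return(cbind(numeric(nrow(x))))
  cbind(0, .dw_grad(x[, 2], pot$barrier_d, pot$separation_d))
}

.as_points <- function(x, dim) {
  if (is.matrix(x)) {
    if (ncol(x) != dim) stop("point matrix has wrong dimensionality", call. = FALSE)
    x
  } else {
    if (length(x) %% dim != 0L) stop("point vector has wrong dimensionality", call. = FALSE)
    matrix(x, ncol = dim, byrow = TRUE)
  }
}

#' Boltzmann well-occupancy ratio by quadrature
#'
#' Independent reference for sampler tests: the equilibrium probability
#' ratio of the left well region (x < divide) to the right well region,
#' computed by numerical quadrature of \eqn{e^{-V/kT}} along x.  For the 2D
#' surface with zero coupling the y term separates and cancels.
#'
#' @param pot A [toy_potential()] (x-term is used).
#' @param kT Thermal energy, kcal/mol.
#' @param divide Dividing surface (default 0).
#' @param lim Integration half-width (default 5 well separations).
#' @return P(x < divide) / P(x > divide).
#' @export
boltzmann_well_ratio <- function(pot, kT = kT_kcal(), divide = 0,
                                 lim = 5 * pot$separation) {
  f <- function(x) exp(-(.dw(x, pot$barrier, pot$separation) + pot$tilt * x) / kT)
  left <- stats::integrate(f, -lim, divide, rel.tol = 1e-10)$value
  right <- stats::integrate(f, divide, lim, rel.tol = 1e-10)$value
  left / right
}

#' Configuration for the overdamped Langevin sampler
#'
#' Euler-Maruyama overdamped dynamics
#' \eqn{x' = x - (\Delta t/\gamma)\nabla V + \sqrt{2 kT \Delta t/\gamma}\,\xi}
#' in reduced time units.
#'
#' @param temperature Temperature in K (kT anchored to 0.5925 kcal/mol at
#'   298 K).
#' @param dt Reduced time step.
#' @param n_steps Number of integration steps.
#' @param seed Integer seed; identical configs give identical trajectories.
#' @param friction Reduced friction coefficient \eqn{\gamma}.
#' @param x0 Starting point (defaults to the positive well).
#' @param burn_in Number of leading steps discarded from the output.
#' @param save_every Keep every \code{save_every}-th step.
#' @return An object of class \code{sampler_config}.
#' @export
sampler_config <- function(temperature = 298, dt = 5e-4, n_steps = 1e5,
                           seed = 1, friction = 1, x0 = NULL,
                           burn_in = 0, save_every = 1L) {
  stopifnot(temperature > 0, dt > 0, n_steps >= 1, friction > 0,
            burn_in >= 0, burn_in < n_steps, save_every >= 1)
  structure(list(temperature = temperature, kT = kT_kcal(temperature),
                 dt = dt, n_steps = as.integer(n_steps),
                 seed = as.integer(seed), friction = friction, x0 = x0,
                 burn_in = as.integer(burn_in),
                 save_every = as.integer(save_every)),
            class = "sampler_config")
}

#' Sample a toy potential with overdamped Langevin dynamics
#'
#' Integrates Euler-Maruyama overdamped dynamics on an analytic toy
#' potential, optionally under a dual-boost bias.  When biased, forces use
#' the boost-corrected gradient: the total-potential channel scales the
#' full gradient by \eqn{\alpha_p^2/(\alpha_p + E_p - V)^2} below threshold
#' and the dihedral channel rescales the dihedral-term gradient
#' analogously.  Per-frame total potential, dihedral energy and boost are
#' recorded so the run can be reweighted.
#'
#' @param potential A [toy_potential()].
#' @param config A [sampler_config()].
#' @param bias Optional [boost_parameters()]; \code{NULL} samples the
#'   unbiased potential (boost identically zero).
#' @return A list of class \code{langevin_run} with elements
#'   \code{positions} (frames x dim matrix), \code{boosts} (a
#'   [boost_series()]), \code{potential}, \code{config}, \code{bias}.
#' @examples
#' pot <- toy_potential("double_well_1d", barrier = 2)
#' run <- sample_langevin(pot, sampler_config(n_steps = 2000, seed = 7))
#' mean(run$positions[, 1] > 0)
#' @export
sample_langevin <- function(potential, config, bias = NULL) {
  stopifnot(inherits(potential, "toy_potential"),
            inherits(config, "sampler_config"))
  if (!is.null(bias)) stopifnot(inherits(bias, "boost_parameters"))
  x0 <- config$x0 %||% if (potential$kind == "harmonic_1d") 0 else
    c(potential$separation, if (potential$dim == 2L) potential$separation_d)
  x0 <- as.numeric(x0)
  if (length(x0) != potential$dim)
    stop("x0 has wrong dimensionality for this potential", call. = FALSE)
  b <- bias %||% boost_parameters()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  res <- cpp_sample_langevin(
    kind = match(potential$kind,
                 c("double_well_1d", "two_dim_surface", "harmonic_1d")),
    params = c(potential$barrier, potential$separation, potential$tilt,
               potential$barrier_d, potential$separation_d, potential$coupling),
    x0 = x0, dt = config$dt, n_steps = config$n_steps,
    friction = config$friction, kT = config$kT,
    E_p = ifelse(is.na(b$E_p), NA_real_, b$E_p),
    alpha_p = ifelse(is.na(b$alpha_p), NA_real_, b$alpha_p),
    E_d = ifelse(is.na(b$E_d), NA_real_, b$E_d),
    alpha_d = ifelse(is.na(b$alpha_d), NA_real_, b$alpha_d),
    burn_in = config$burn_in, save_every = config$save_every)
  if (res$error_frame >= 0)
    stop(sprintf(paste0("non-finite energy at integration step %d: ",
                        "time step too large or potential diverged"),
                 res$error_frame + 1L), call. = FALSE)
  n <- nrow(res$positions)
  time <- (config$burn_in + seq_len(n) * config$save_every) * config$dt
  structure(list(positions = res$positions,
                 boosts = boost_series(time, V = res$V, Vd = res$Vd, dV = res$dV),
                 potential = potential, config = config, bias = bias),
            class = "langevin_run")
}

#' @export
print.langevin_run <- function(x, ...) {
  cat(sprintf("Langevin run: %d frames (%dD), %s, kT = %.4f kcal/mol\n",
              nrow(x$positions), ncol(x$positions),
              if (is.null(x$bias)) "unbiased" else "dual-boost biased",
              x$config$kT))
  if (!is.null(x$bias))
    cat(sprintf("  mean boost dV = %.4g kcal/mol (max %.4g)\n",
                mean(x$boosts$dV), max(x$boosts$dV)))
  invisible(x)
}
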