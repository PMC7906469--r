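# Dual-boost accelerated-dynamics bias: whenever an energy channel falls
# below its threshold E the non-negative boost (E - V)^2 / (alpha + E - V)
# is added.  Two independent channels: total potential (E_p, alpha_p) and
# dihedral energy (E_d, alpha_d).

#' Boost parameters for dual-boost accelerated dynamics
#'
#' Container for the thresholds and smoothing coefficients of the two boost
#' channels.  A channel is inactive when its threshold/coefficient pair is
#' \code{NA}; an active channel requires \code{alpha > 0} (the boost is
#' otherwise ill-posed).
#'
#' @param E_p,alpha_p Threshold and coefficient (kcal/mol) of the
#'   total-potential channel, or \code{NA} to disable it.
#' @param E_d,alpha_d Threshold and coefficient (kcal/mol) of the dihedral
#'   channel, or \code{NA} to disable it.
#' @return An object of class \code{boost_parameters}.
#' @seealso [amd_parameters()] for the system-size selection rule,
#'   [amd_boost()] for evaluating the boost.
#' @export
boost_parameters <- function(E_p = NA_real_, alpha_p = NA_real_,
                             E_d = NA_real_, alpha_d = NA_real_) {
  chk <- function(E, a, ch) {
    if (is.na(E) != is.na(a))
      stop(sprintf("channel '%s': threshold and alpha must both be given or both NA", ch),
           call. = FALSE)
    if (!is.na(E)) {
      .assert_scalar_finite(E, paste0("E_", ch))
      .assert_scalar_finite(a, paste0("alpha_", ch))
      if (a <= 0)
        stop(sprintf("channel '%s': alpha must be > 0 for an active boost channel", ch),
             call. = FALSE)
    }
  }
  chk(E_p, alpha_p, "p")
  chk(E_d, alpha_d, "d")
  structure(list(E_p = E_p, alpha_p = alpha_p, E_d = E_d, alpha_d = alpha_d),
            class = "boost_parameters")
}

#' @export
print.boost_parameters <- function(x, ...) {
  cat("Dual-boost parameters (kcal/mol)\n")
  fmt <- function(E, a, ch) {
    if (is.na(E)) cat(sprintf("  %s channel: inactive\n", ch))
    else cat(sprintf("  %s channel: E = %.4g, alpha = %.4g\n", ch, E, a))
  }
  fmt(x$E_p, x$alpha_p, "total-potential")
  fmt(x$E_d, x$alpha_d, "dihedral")
  invisible(x)
}

#' Select dual-boost parameters from system size
#'
#' Standard selection rule for the dual-boost thresholds and coefficients:
#' \deqn{E_p = E_{p,0} + \gamma_p n_{atoms}, \quad \alpha_p = \gamma_p n_{atoms}}
#' \deqn{E_d = E_{d,0} + \gamma_d n_{res} + \gamma_d' n_{lip}, \quad
#'       \alpha_d = 0.2 (\gamma_d n_{res} + \gamma_d' n_{lip})}
#' with \eqn{\gamma_p} = 0.16 kcal/mol/atom, \eqn{\gamma_d} = 3.5
#' kcal/mol/residue and \eqn{\gamma_d'} = 30.0 kcal/mol/lipid.
#' \code{E_p0}/\code{E_d0} are the average total-potential and dihedral
#' energies of an unbiased (equilibration) run; see
#' [estimate_reference_energies()].
#'
#' @param n_atoms Number of atoms, solvent included.
#' @param n_residues Number of protein residues.
#' @param n_lipids Number of lipid molecules.
#' @param E_p0,E_d0 Unbiased average total-potential / dihedral energies
#'   (kcal/mol).  Leave \code{NA} to disable the corresponding channel.
#' @param gamma_p,gamma_d,gamma_dl Per-atom, per-residue and per-lipid
#'   coefficients (kcal/mol each).
#' @return A [boost_parameters()] object.
#' @examples
#' amd_parameters(n_atoms = 1000, E_p0 = -5000)           # E_p = -4840, alpha_p = 160
#' amd_parameters(n_atoms = 0, n_residues = 25, E_d0 = 100)  # E_d = 187.5, alpha_d = 17.5
#' @export
amd_parameters <- function(n_atoms = 0, n_residues = 0, n_lipids = 0,
                           E_p0 = NA_real_, E_d0 = NA_real_,
                           gamma_p = 0.16, gamma_d = 3.5, gamma_dl = 30.0) {
  for (n in c(n_atoms, n_residues, n_lipids))
    if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
      stop("system counts must be non-negative integers", call. = FALSE)
  E_p <- alpha_p <- NA_real_
  if (!is.na(E_p0)) {
    .assert_scalar_finite(E_p0, "E_p0")
    if (n_atoms == 0)
      stop("total-potential boost requested but n_atoms = 0 (alpha_p would be 0)",
           call. = FALSE)
    alpha_p <- gamma_p * n_atoms
    E_p <- E_p0 + alpha_p
  }
  E_d <- alpha_d <- NA_real_
  if (!is.na(E_d0)) {
    .assert_scalar_finite(E_d0, "E_d0")
    lvl <- gamma_d * n_residues + gamma_dl * n_lipids
    if (lvl <= 0)
      stop("dihedral boost requested but n_residues and n_lipids are both 0",
           call. = FALSE)
    E_d <- E_d0 + lvl
    alpha_d <- 0.2 * lvl
  }
  boost_parameters(E_p = E_p, alpha_p = alpha_p, E_d = E_d, alpha_d = alpha_d)
}

.boost_channel <- function(V, E, alpha) {
  # (E - V)^2 / (alpha + E - V) below threshold, 0 above; also the force
  # scale alpha^2 / (alpha + E - V)^2 (1 above threshold).
  dV <- numeric(length(V))
  scale <- rep(1, length(V))
  below <- V < E
  if (any(below)) {
    gap <- E - V[below]
    den <- alpha + gap
    if (any(den <= 0))
      stop("ill-posed boost: alpha + E - V <= 0 in an active channel", call. = FALSE)
    dV[below] <- gap^2 / den
    scale[below] <- alpha^2 / den^2
  }
  list(dV = dV, scale = scale)
}

#' Evaluate the dual boost
#'
#' Computes the non-negative boost added to a configuration with total
#' potential \code{V} and dihedral energy \code{V_d}: each active channel
#' contributes \eqn{(E - V)^2 / (\alpha + E - V)} when \eqn{V < E} and zero
#' otherwise, and the total boost is their sum.  The returned per-channel
#' force-scale factors \eqn{\alpha^2/(\alpha + E - V)^2} multiply the
#' corresponding gradient in a biased integrator.
#'
#' @param V Total potential energy, kcal/mol (vectorised).
#' @param V_d Dihedral energy, kcal/mol (vectorised, recycled).
#' @param params A [boost_parameters()] object.
#' @return A data.frame with columns \code{dV}, \code{dV_total},
#'   \code{dV_dihedral}, \code{scale_total}, \code{scale_dihedral}.
#' @examples
#' p <- boost_parameters(E_p = 10, alpha_p = 10)
#' amd_boost(V = 0, params = p)$dV  # (10)^2 / (10 + 10) = 5
#' @export
amd_boost <- function(V, V_d = 0, params) {
  stopifnot(inherits(params, "boost_parameters"))
  if (any(!is.finite(V)) || any(!is.finite(V_d)))
    stop("non-finite energies passed to amd_boost", call. = FALSE)
  n <- max(length(V), length(V_d))
  V <- rep_len(V, n); V_d <- rep_len(V_d, n)
  tot <- if (!is.na(params$E_p)) .boost_channel(V, params$E_p, params$alpha_p)
         else list(dV = numeric(n), scale = rep(1, n))
  dih <- if (!is.na(params$E_d)) .boost_channel(V_d, params$E_d, params$alpha_d)
         else list(dV = numeric(n), scale = rep(1, n))
  data.frame(dV = tot$dV + dih$dV,
             dV_total = tot$dV, dV_dihedral = dih$dV,
             scale_total = tot$scale, scale_dihedral = dih$scale)
}

#' Estimate unbiased reference energies from an equilibration series
#'
#' Mean total-potential and dihedral energies over the frames after a
#' burn-in, for use as \code{E_p0}/\code{E_d0} in [amd_parameters()].
#'
#' @param series A data.frame with columns \code{V} and optionally
#'   \code{Vd} (e.g. a \code{boost_series} from an unbiased run).
#' @param burn_in_frac Fraction of leading frames discarded before
#'   averaging (default 0.1).
#' @return A list with \code{E_p0}, \code{E_d0} (NA when \code{Vd} absent)
#'   and \code{n_used}.
#' @export
estimate_reference_energies <- function(series, burn_in_frac = 0.1) {
  stopifnot(is.data.frame(series), "V" %in% names(series))
  if (burn_in_frac < 0 || burn_in_frac >= 1)
    stop("burn_in_frac must be in [0, 1)", call. = FALSE)
  n <- nrow(series)
  keep <- seq.int(floor(burn_in_frac * n) + 1L, n)
  list(E_p0 = mean(series$V[keep]),
       E_d0 = if ("Vd" %in% names(series)) mean(series$Vd[keep]) else NA_real_,
       n_used = length(keep))
}

#' Per-frame boost bookkeeping
#'
#' @param time_ns Frame time stamps (ns), strictly increasing.
#' @param V,Vd,dV Per-frame total potential, dihedral energy and boost
#'   (kcal/mol).  \code{dV} must be non-negative.
#' @return A data.frame of class \code{boost_series}.
#' @export
boost_series <- function(time_ns, V, Vd = 0, dV = 0) {
  n <- length(time_ns)
  Vd <- rep_len(Vd, n); dV <- rep_len(dV, n)
  stopifnot(length(V) == n)
  if (n > 1 && any(diff(time_ns) <= 0))
    stop("time stamps must be strictly increasing", call. = FALSE)
  if (any(dV < 0)) stop("boost dV must be non-negative on every frame", call. = FALSE)
  structure(data.frame(frame = seq_len(n), time_ns = time_ns, V = V, Vd = Vd, dV = dV),
            class = c("boost_series", "data.frame"))
}
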