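# Simplified GCMC/BD permeation simulator for static channel models.
# Ions are ideal point charges; the channel enters only through a hard-wall
# pore profile, optional smooth energy wells and a linear voltage ramp.
# The principal fidelity gap relative to full continuum-electrostatics
# GCMC/BD machinery is the omission of ion-ion and dielectric-boundary
# forces; see the package vignette.

#' Static channel model for GCMC/BD
#'
#' @param membrane_thickness Membrane slab thickness, Angstrom (default
#'   35); the slab is centred at z = 0.
#' @param radius Pore radius: a scalar (cylinder), a function of z, or a
#'   numeric vector tabulated on the model grid across the membrane.
#' @param well_depth Named per-species axial well depths (kcal/mol,
#'   positive = attractive), e.g. \code{c(K = 0, CL = 0.5)}; a smooth
#'   Gaussian profile centred mid-membrane.
#' @param voltage_mV Applied voltage; the electric potential ramps
#'   linearly across the membrane and the +z side is the positive side.
#' @param box Box dimensions, Angstrom (default 85 x 85 x 95).
#' @param grid Grid spacing for tabulated potentials/profiles, Angstrom
#'   (default 0.5).
#' @param obstacle_fraction Fraction of the pore cross-section occluded by
#'   a concentric hard post (0 = open pore).
#' @return An object of class \code{channel_model}.
#' @export
channel_model <- function(membrane_thickness = 35, radius = 12,
                          well_depth = c(K = 0, CL = 0), voltage_mV = 0,
                          box = c(85, 85, 95), grid = 0.5,
                          obstacle_fraction = 0) {
  stopifnot(membrane_thickness > 0, membrane_thickness < box[3],
            length(box) == 3, all(box > 0), grid > 0,
            obstacle_fraction >= 0, obstacle_fraction < 1)
  zg <- seq(-membrane_thickness / 2, membrane_thickness / 2, by = grid)
  rz <- if (is.function(radius)) vapply(zg, radius, numeric(1))
        else if (length(radius) == 1L) rep(as.numeric(radius), length(zg))
        else {
          if (length(radius) != length(zg))
            stop(sprintf("tabulated radius must have %d values (grid %.2f A across the membrane)",
                         length(zg), grid), call. = FALSE)
          as.numeric(radius)
        }
  if (any(rz <= 0)) stop("pore radius must be positive across the membrane", call. = FALSE)
  wd <- c(K = 0, CL = 0)
  wd[names(well_depth)] <- well_depth
  structure(list(membrane_thickness = membrane_thickness, radius_profile = rz,
                 grid_z = zg, well_depth = wd, voltage_mV = voltage_mV,
                 box = box, grid = grid, obstacle_fraction = obstacle_fraction),
            class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf("Channel model: %.1f-A membrane in %g x %g x %g A box, pore radius %.2f-%.2f A, V = %+g mV\n",
              x$membrane_thickness, x$box[1], x$box[2], x$box[3],
              min(x$radius_profile), max(x$radius_profile), x$voltage_mV))
  if (x$obstacle_fraction > 0)
    cat(sprintf("  concentric obstacle occluding %.0f%% of the pore area\n",
                100 * x$obstacle_fraction))
  invisible(x)
}

#' GCMC/BD run configuration
#'
#' @param conc_mM Target reservoir KCl concentration (default 150 mM).
#' @param buffer Buffer-slab thickness at each z end of the box, Angstrom
#'   (default 5).
#' @param dt_ps BD time step, ps (default 5).
#' @param cycles Number of BD cycles (one GCMC sweep per BD step; default
#'   1e6).
#' @param gcmc_per_step GCMC sweeps per BD step (default 1; 0 disables the
#'   grand canonical exchange for closed-system diagnostics).
#' @param temperature Temperature, K.
#' @param D_cm2s Named per-species diffusion coefficients, cm^2/s.
#' @param seed Integer seed.
#' @param replicas Independent replicas to average (default 3).
#' @param trace_every Record buffer counts every this many cycles
#'   (default 100; 0 disables).
#' @param trace_positions_every Record all ion positions every this many
#'   cycles (0 disables; used for MSD diagnostics and ion-path export).
#' @return An object of class \code{gcmcbd_config}.
#' @export
gcmcbd_config <- function(conc_mM = 150, buffer = 5, dt_ps = 5,
                          cycles = 1e6, gcmc_per_step = 1L,
                          temperature = 298,
                          D_cm2s = c(K = 1.96e-5, CL = 2.03e-5),
                          seed = 1L, replicas = 3L, trace_every = 100L,
                          trace_positions_every = 0L) {
  stopifnot(conc_mM > 0, buffer > 0, dt_ps > 0, cycles >= 1,
            gcmc_per_step >= 0, temperature > 0, replicas >= 1)
  D <- c(K = NA_real_, CL = NA_real_)
  D[names(D_cm2s)] <- D_cm2s
  stopifnot(all(is.finite(D)), all(D > 0))
  structure(list(conc_mM = conc_mM, buffer = buffer, dt_ps = dt_ps,
                 cycles = as.integer(cycles),
                 gcmc_per_step = as.integer(gcmc_per_step),
                 temperature = temperature, D_cm2s = D,
                 seed = as.integer(seed), replicas = as.integer(replicas),
                 trace_every = as.integer(trace_every),
                 trace_positions_every = as.integer(trace_positions_every)),
            class = "gcmcbd_config")
}

#' Run the GCMC/BD permeation simulator
#'
#' Propagates ideal K+ and Cl- ions by overdamped Brownian dynamics in the
#' static channel model (hard-wall collisions resolved by move rejection)
#' while grand canonical insertions/deletions in the two buffer slabs
#' clamp the reservoir concentration with the ideal-gas acceptance rule.
#' Per-species membrane crossings are counted by a three-state machine;
#' the conductance is the summed K+ and Cl- current divided by the
#' applied voltage, and the anion/cation ratio is the Cl-/K+ flux ratio.
#' The exact flux-balance bookkeeping identity
#' (count change = insertions - deletions + net boundary entries, per
#' buffer and species) is asserted on every run.
#'
#' @param model A [channel_model()].
#' @param config A [gcmcbd_config()].
#' @return An object of class \code{gcmcbd_result}: per-replica data.frame
#'   \code{replicas} (current_pA, conductance_nS, ratio, per-species
#'   fluxes), pooled \code{conductance_nS} / \code{conductance_sd},
#'   \code{ratio}, \code{low_count_flag}, buffer concentration traces and
#'   (optionally) position traces.
#' @export
run_gcmcbd <- function(model, config) {
  stopifnot(inherits(model, "channel_model"), inherits(config, "gcmcbd_config"))
  conv <- unit_conventions()
  kT <- kT_kcal(config$temperature)
  D_ps <- config$D_cm2s * conv$cm2s_to_A2ns / 1000   # A^2/ps
  step <- sqrt(2 * max(D_ps) * config$dt_ps)
  if (step > 4 * model$grid)
    stop(sprintf("BD step displacement %.2f A exceeds 4 x grid spacing: reduce dt_ps", step),
         call. = FALSE)
  if (min(model$radius_profile) < step)
    warning("pore radius below the BD step length: pore may be unreachable (zero flux)",
            call. = FALSE)
  V <- model$voltage_mV
  # q * V across the membrane in kcal/mol, per species (K = +1, CL = -1):
  # the +z side is the positive electrode.
  volt_kcal <- c(K = 1, CL = -1) * (V / 1000) * conv$kcal_per_e_volt
  nbar <- config$conc_mM * conv$number_per_A3_per_mM *
    model$box[1] * model$box[2] * config$buffer
  capacity <- max(64L, as.integer(8 * nbar +
    4 * config$conc_mM * conv$number_per_A3_per_mM * prod(model$box)))
  reps <- vector("list", config$replicas)
  for (r in seq_len(config$replicas)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(config$seed + r - 1L)
    raw <- cpp_run_gcmcbd(
      box = model$box, half_mem = model$membrane_thickness / 2,
      rz = model$radius_profile, grid = model$grid,
      obstacle_r_frac = sqrt(model$obstacle_fraction),
      volt_kcal = unname(volt_kcal[c("K", "CL")]),
      well = unname(model$well_depth[c("K", "CL")]),
      well_sigma = model$membrane_thickness / 6,
      D_A2ps = unname(D_ps[c("K", "CL")]), kT = kT, dt_ps = config$dt_ps,
      buffer = config$buffer, nbar_buffer = nbar,
      cycles = config$cycles, gcmc_per_step = config$gcmc_per_step,
      trace_every = config$trace_every,
      pos_trace_every = config$trace_positions_every,
      capacity = capacity)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    # exact flux-balance bookkeeping identity
    imbalance <- raw$buffer_n_end - raw$buffer_n_start -
      (raw$insertions - raw$deletions + raw$net_entries)
    if (any(imbalance != 0L))
      stop("internal flux-balance bookkeeping violated", call. = FALSE)
    reps[[r]] <- raw
  }
  dur_ns <- config$cycles * config$dt_ps / 1000
  per <- do.call(rbind, lapply(seq_along(reps), function(r) {
    cr <- reps[[r]]$crossings   # rows K, CL; cols -z, +z
    net <- cr[, 2] - cr[, 1]    # net +z crossings per species
    tot <- cr[, 1] + cr[, 2]
    q <- c(1, -1)
    # electrode convention: positive current = positive charge toward -z
    I_e_ns <- -sum(q * net) / dur_ns
    I_pA <- I_e_ns * unit_conventions()$pA_per_e_ns
    data.frame(replica = r,
               events_K = tot[1], events_CL = tot[2],
               net_K = net[1], net_CL = net[2],
               flux_K = abs(net[1]) / dur_ns, flux_CL = abs(net[2]) / dur_ns,
               current_pA = I_pA,
               conductance_nS = if (V != 0) I_pA / V else NA_real_,
               ratio = if (abs(net[1]) > 0) abs(net[2]) / abs(net[1]) else NA_real_)
  }))
  traces <- lapply(reps, function(x) {
    tr <- x$conc_trace
    if (!nrow(tr)) return(NULL)
    vol <- model$box[1] * model$box[2] * config$buffer
    f <- 1 / (unit_conventions()$number_per_A3_per_mM * vol)
    data.frame(cycle = tr[, 1],
               bottom_K_mM = tr[, 2] * f, bottom_CL_mM = tr[, 3] * f,
               top_K_mM = tr[, 4] * f, top_CL_mM = tr[, 5] * f)
  })
  pos <- lapply(reps, function(x) {
    if (x$n_pos_trace == 0) return(NULL)
    arr <- array(x$pos_trace, c(x$n_pos_trace, 3, x$capacity))
    aperm(arr, c(1, 3, 2))   # frames x slots x dims
  })
  low <- any(pmin(abs(per$net_K), abs(per$net_CL)) < 5)
  structure(list(replicas = per,
                 current_pA = mean(per$current_pA),
                 current_sd = stats::sd(per$current_pA),
                 conductance_nS = mean(per$conductance_nS),
                 conductance_sd = stats::sd(per$conductance_nS),
                 ratio = mean(per$ratio),
                 low_count_flag = low,
                 conc_traces = traces, pos_traces = pos,
                 duration_ns = dur_ns, model = model, config = config),
            class = "gcmcbd_result")
}

#' @export
print.gcmcbd_result <- function(x, ...) {
  cat(sprintf("GCMC/BD: %d replica(s) x %.3g ns (dt %.1f ps), V = %+g mV\n",
              nrow(x$replicas), x$duration_ns, x$config$dt_ps,
              x$model$voltage_mV))
  cat(sprintf("  current %.2f +/- %.2f pA", x$current_pA,
              ifelse(is.na(x$current_sd), 0, x$current_sd)))
  if (!is.na(x$conductance_nS))
    cat(sprintf("; conductance %.3f +/- %.3f nS", x$conductance_nS,
                ifelse(is.na(x$conductance_sd), 0, x$conductance_sd)))
  cat("\n")
  if (!is.na(x$ratio))
    cat(sprintf("  anion/cation ratio %.2f%s\n", x$ratio,
                if (isTRUE(x$low_count_flag)) " [low-count caveat]" else ""))
  invisible(x)
}

#' Buffer concentration traces of a GCMC/BD run
#'
#' Instantaneous per-buffer, per-species concentrations computed from the
#' recorded buffer counts.
#'
#' @param result A [run_gcmcbd()] result.
#' @param replica Which replica (default 1).
#' @return data.frame with cycle and the four buffer concentrations (mM).
#' @export
buffer_concentration_trace <- function(result, replica = 1L) {
  stopifnot(inherits(result, "gcmcbd_result"))
  tr <- result$conc_traces[[replica]]
  if (is.null(tr)) stop("no concentration trace was recorded (trace_every = 0)",
                        call. = FALSE)
  tr
}

#' Nernst-Planck conductance of an ideal cylindrical pore
#'
#' Closed-form reference for an ideal cylinder in which the full voltage
#' drops across the pore and the reservoirs are perfectly mixed:
#' \deqn{G = \sum_s q^2 D_s c A / (k_B T L)}
#' Access (spreading) resistance at the pore mouths is not included, so a
#' simulated wide-pore conductance is expected a little below this bound.
#'
#' @param radius Pore radius, Angstrom.
#' @param length Pore length, Angstrom.
#' @param conc_mM Per-species concentration, mM.
#' @param D_cm2s Named per-species diffusion coefficients, cm^2/s.
#' @param temperature Temperature, K.
#' @return Conductance in nS.
#' @export
np_cylinder_conductance <- function(radius, length, conc_mM = 150,
                                    D_cm2s = c(K = 1.96e-5, CL = 2.03e-5),
                                    temperature = 298) {
  conv <- unit_conventions()
  kT <- kT_kcal(temperature)
  A <- pi * radius^2
  c_A3 <- conc_mM * conv$number_per_A3_per_mM
  # per 1 mV applied: energy drop q*1mV in kcal/mol
  e_mV <- conv$kcal_per_e_volt / 1000
  G_nS <- sum(vapply(D_cm2s, function(D) {
    D_A2ns <- D * conv$cm2s_to_A2ns
    v <- D_A2ns * e_mV / length / kT          # drift speed at 1 mV, A/ns
    (c_A3 * A * v) * conv$pA_per_e_ns          # pA per mV = nS
  }, numeric(1)))
  G_nS
}
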