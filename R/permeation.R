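# Ion-permeation analysis: translocation detection with a per-ion
# three-state machine, current/conductance from the slope of the
# net-crossing-events curve, anion/cation selectivity, midplane density
# maps, and MSD-based diffusion estimation for the current scaling factor.
#
# Sign conventions (see unit_conventions()): the membrane normal is z and
# the positive-voltage (cis) side is +z.  Crossing records store
# transfer = charge x z-direction; the reported current is positive when
# net positive charge moves from +z to -z, i.e. I ~ -d(sum q dir)/dt, so
# passive transport always gives G = I/V > 0.

#' Detect ion translocation events
#'
#' Replays a three-state machine (below / inside / above the slab) per
#' ion.  A crossing is recorded only on a complete traversal
#' (below -> inside -> above, or the reverse); to suppress boundary
#' chatter the outer states require the ion to be beyond the slab edge by
#' a hysteresis buffer.  Periodic z jumps larger than half the box are
#' treated as wraps (the state is re-seeded from the new side, never
#' credited as a traversal).
#'
#' @param traj An \code{ion_trajectory}.
#' @param hysteresis Buffer width beyond the slab edges, Angstrom
#'   (default 2).
#' @return An object of class \code{crossing_set}: \code{records}
#'   (data.frame ion_id, species, charge, direction, frame, time_ns,
#'   transfer), \code{series} (per-frame cumulative data.frame with net
#'   event and signed-transfer columns, total and per species) and the
#'   originating geometry.
#' @export
detect_crossings <- function(traj, hysteresis = 2) {
  stopifnot(inherits(traj, "ion_trajectory"))
  z <- traj$z
  nf <- nrow(z); ni <- ncol(z)
  lo <- traj$slab[1]; hi <- traj$slab[2]
  Lz <- traj$box[3]
  blo <- lo - hysteresis; bhi <- hi + hysteresis
  region <- function(zv) ifelse(zv < lo, 1L, ifelse(zv > hi, 3L, 2L)) # 1 below, 2 in, 3 above
  outer_region <- function(zv) ifelse(zv < blo, 1L, ifelse(zv > bhi, 3L, 2L))
  recs <- vector("list", ni)
  for (i in seq_len(ni)) {
    zi <- z[, i]
    state <- region(zi[1])          # 2 at t0 counts as no origin
    origin <- if (state == 2L) 0L else state
    ev_frame <- integer(0); ev_dir <- integer(0)
    for (f in 2:nf) {
      dz <- zi[f] - zi[f - 1]
      if (abs(dz) > Lz / 2) {       # periodic wrap: reset, no traversal
        state <- region(zi[f])
        origin <- if (state == 2L) 0L else state
        next
      }
      r <- region(zi[f])
      if (state != 2L) {
        if (r == 2L) { origin <- state; state <- 2L }
        else state <- r             # below<->above without entering: impossible unless huge step
      } else {
        # inside: leave only when beyond the hysteresis buffer
        ro <- outer_region(zi[f])
        if (ro != 2L) {
          if (origin != 0L && ro != origin) {
            ev_frame <- c(ev_frame, f)
            ev_dir <- c(ev_dir, if (ro == 3L) 1L else -1L)
          }
          state <- ro
          origin <- ro
        }
      }
    }
    if (length(ev_frame))
      recs[[i]] <- data.frame(ion_id = traj$ions$ion_id[i],
                              species = traj$ions$species[i],
                              charge = traj$ions$charge[i],
                              direction = ev_dir, frame = ev_frame,
                              time_ns = traj$time_ns[ev_frame])
  }
  records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(records))
    records <- data.frame(ion_id = integer(0), species = character(0),
                          charge = numeric(0), direction = integer(0),
                          frame = integer(0), time_ns = numeric(0))
  records <- records[order(records$frame, records$ion_id), , drop = FALSE]
  rownames(records) <- NULL
  records$transfer <- records$charge * records$direction
  series <- .crossing_series(records, traj$time_ns)
  structure(list(records = records, series = series, slab = traj$slab,
                 box = traj$box, dt_ns = traj$dt_ns,
                 duration_ns = traj$time_ns[nf] - traj$time_ns[1],
                 hysteresis = hysteresis),
            class = "crossing_set")
}

.crossing_series <- function(records, time_ns) {
  nf <- length(time_ns)
  cum_at <- function(frames, values) {
    v <- numeric(nf)
    if (length(frames)) v[frames] <- v[frames] + 0 # placeholder
    for (k in seq_along(frames)) v[frames[k]] <- v[frames[k]] + values[k]
    cumsum(v)
  }
  out <- data.frame(frame = seq_len(nf), time_ns = time_ns,
                    net_events = cum_at(records$frame, records$direction),
                    net_transfer = cum_at(records$frame, records$transfer))
  for (sp in unique(records$species)) {
    r <- records[records$species == sp, ]
    out[[paste0("net_events_", sp)]] <- cum_at(r$frame, r$direction)
    out[[paste0("events_", sp)]] <- cum_at(r$frame, rep(1, nrow(r)))
  }
  out
}

#' @export
print.crossing_set <- function(x, ...) {
  cat(sprintf("Crossing events: %d over %.3g ns", nrow(x$records), x$duration_ns))
  if (nrow(x$records)) {
    tb <- table(x$records$species, factor(x$records$direction, c(-1, 1)))
    cat(" (", paste(sprintf("%s: %d up / %d down", rownames(tb), tb[, "1"], tb[, "-1"]),
                    collapse = "; "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Diffusion scaling factor for current estimation
#'
#' Simulated water models overestimate ion diffusion; the ratio
#' D_exp / D_sim multiplies the raw crossing-rate current.  Defaults are
#' the bulk KCl coefficients 3.273e-5 (simulated) and 1.918e-5
#' (experimental) cm^2/s.
#'
#' @param D_sim,D_exp Simulated and experimental bulk diffusion
#'   coefficients, cm^2/s.
#' @param r_squared Optional regression R^2 of the MSD fit behind D_sim.
#' @return An object of class \code{diffusion_scaling} with the
#'   multiplicative \code{factor}.
#' @export
diffusion_scaling <- function(D_sim = 3.273e-5, D_exp = 1.918e-5,
                              r_squared = NA_real_) {
  stopifnot(D_sim > 0, D_exp > 0)
  structure(list(D_sim = D_sim, D_exp = D_exp, factor = D_exp / D_sim,
                 r_squared = r_squared),
            class = "diffusion_scaling")
}

#' Estimate the ionic current from crossing events
#'
#' The net signed charge-transfer rate (e/ns) is the slope of the
#' cumulative transfer-vs-time curve, by least squares or from the line
#' connecting the first and last points; the current is
#' slope x 160.2177 x scaling factor (pA), with the sign convention that
#' positive charge moving toward -z (away from the positive-voltage +z
#' side) is positive current.
#'
#' @param crossings A [detect_crossings()] result, or a data.frame with
#'   \code{time_ns} and \code{net_transfer} columns.
#' @param scaling A [diffusion_scaling()] object or a bare numeric factor
#'   (default 1).
#' @param estimator \code{"least_squares"} (default) or
#'   \code{"endpoints"}.
#' @param voltage_mV Optional applied voltage; when given, the conductance
#'   I/V (nS) and the anion/cation ratio are included in the report.
#' @return An object of class \code{current_report}: \code{slope_e_ns},
#'   \code{current_pA}, \code{r_squared} (least squares only),
#'   \code{factor}, \code{estimator}, \code{voltage_mV},
#'   \code{conductance_nS}, \code{flux_by_species} (events/ns),
#'   \code{anion_cation_ratio}, \code{low_count_flag}.
#' @export
estimate_current <- function(crossings, scaling = 1,
                             estimator = c("least_squares", "endpoints"),
                             voltage_mV = NULL) {
  estimator <- match.arg(estimator)
  fac <- if (inherits(scaling, "diffusion_scaling")) scaling$factor else as.numeric(scaling)
  .assert_scalar_finite(fac, "scaling factor")
  if (inherits(crossings, "crossing_set")) {
    ser <- crossings$series
  } else {
    ser <- crossings
    stopifnot(is.data.frame(ser), all(c("time_ns", "net_transfer") %in% names(ser)))
  }
  if (nrow(ser) < 2) stop("need at least 2 time points", call. = FALSE)
  t <- ser$time_ns; q <- ser$net_transfer
  if (estimator == "endpoints") {
    slope <- (q[length(q)] - q[1]) / (t[length(t)] - t[1])
    r2 <- NA_real_
  } else {
    fit <- stats::lm.fit(cbind(1, t), q)
    slope <- fit$coefficients[2]
    ss_res <- sum(fit$residuals^2); ss_tot <- sum((q - mean(q))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  }
  # axis slope (q dir) -> electrode convention: positive toward -z
  current <- -slope * unit_conventions()$pA_per_e_ns * fac
  sel <- NULL
  if (inherits(crossings, "crossing_set")) sel <- selectivity(crossings)
  g <- if (!is.null(voltage_mV)) conductance_nS(current, voltage_mV) else NA_real_
  structure(list(slope_e_ns = unname(slope), current_pA = unname(current),
                 r_squared = unname(r2), factor = fac, estimator = estimator,
                 voltage_mV = voltage_mV %||% NA_real_, conductance_nS = g,
                 flux_by_species = if (!is.null(sel)) sel$flux_by_species else NULL,
                 anion_cation_ratio = if (!is.null(sel)) sel$ratio else NA_real_,
                 low_count_flag = if (!is.null(sel)) sel$low_count_flag else NA),
            class = "current_report")
}

#' @export
print.current_report <- function(x, ...) {
  cat(sprintf("Current report (%s): slope %.4g e/ns, factor %.3f -> I = %.3f pA",
              x$estimator, x$slope_e_ns, x$factor, x$current_pA))
  if (!is.na(x$voltage_mV))
    cat(sprintf(" at %+g mV -> G = %.3f nS", x$voltage_mV, x$conductance_nS))
  cat("\n")
  if (!is.na(x$r_squared)) cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  if (!is.na(x$anion_cation_ratio))
    cat(sprintf("  anion/cation ratio = %.3g%s\n", x$anion_cation_ratio,
                if (isTRUE(x$low_count_flag)) " [low-count caveat]" else ""))
  invisible(x)
}

#' Conductance from current and voltage
#'
#' G (nS) = I (pA) / V (mV); positive for passive transport under the
#' package sign conventions.
#'
#' @param current_pA Current in pA (or a \code{current_report}).
#' @param voltage_mV Applied voltage in mV (non-zero).
#' @return Conductance in nS.
#' @examples
#' conductance_nS(34.98, 40)   # 0.8745
#' @export
conductance_nS <- function(current_pA, voltage_mV) {
  if (inherits(current_pA, "current_report")) current_pA <- current_pA$current_pA
  .assert_scalar_finite(current_pA, "current_pA")
  if (!is.numeric(voltage_mV) || voltage_mV == 0)
    stop("zero applied voltage: conductance undefined; use equilibrium flux analysis instead",
         call. = FALSE)
  current_pA / voltage_mV
}

#' Anion/cation selectivity from crossing events
#'
#' Ratio of the absolute anion flux to the absolute cation flux
#' (events/ns over the same window).  A caveat flag is raised when the
#' minority species has fewer than \code{min_events} crossings, since
#' small counts overestimate selectivity.
#'
#' @param crossings A [detect_crossings()] result, or a named numeric
#'   vector of per-species fluxes with an accompanying \code{charges}
#'   vector.
#' @param charges Named charges per species (crossing-set input infers
#'   them).
#' @param min_events Low-count threshold (default 5).
#' @return List with \code{ratio} (NA when the cation flux is zero),
#'   \code{flux_by_species}, \code{events_by_species},
#'   \code{low_count_flag}, \code{undefined}.
#' @export
selectivity <- function(crossings, charges = NULL, min_events = 5L) {
  if (inherits(crossings, "crossing_set")) {
    rec <- crossings$records
    dur <- crossings$duration_ns
    events <- table(rec$species)
    charges <- tapply(rec$charge, rec$species, function(x) x[1])
    # physical flux is the net (directional) crossing rate per species
    net <- tapply(rec$direction, rec$species, sum)
    flux <- abs(as.numeric(net)) / dur
    names(flux) <- names(net)
  } else {
    flux <- abs(as.numeric(crossings))
    names(flux) <- names(crossings)
    if (is.null(charges)) stop("charges needed with raw flux input", call. = FALSE)
    events <- flux * NA
  }
  an <- sum(flux[names(flux) %in% names(charges)[charges < 0]])
  ca <- sum(flux[names(flux) %in% names(charges)[charges > 0]])
  undefined <- !(ca > 0)
  ratio <- if (undefined) NA_real_ else an / ca
  ev <- suppressWarnings(as.numeric(events))
  low <- if (all(is.na(ev))) NA else any(ev < min_events) || length(ev) < 2
  list(ratio = ratio, flux_by_species = flux,
       events_by_species = events, low_count_flag = low,
       undefined = undefined)
}

#' Midplane density map of crossing ions
#'
#' (x, y) histogram of each crossing ion's position at the first frame of
#' its recorded traversal at which it passes the slab midplane, divided by
#' the total number of crossings of the species (the map sums to 1).
#'
#' @param traj The \code{ion_trajectory} the crossings came from.
#' @param crossings A [detect_crossings()] result.
#' @param species Species to map (default: the anion-like species with
#'   most events).
#' @param bin Grid spacing, Angstrom (default 2).
#' @return List with \code{density} (matrix summing to 1, or empty),
#'   \code{x_edges}, \code{y_edges}, \code{n_crossings}, \code{points}.
#' @export
midplane_density <- function(traj, crossings, species = NULL, bin = 2) {
  stopifnot(inherits(traj, "ion_trajectory"), inherits(crossings, "crossing_set"))
  rec <- crossings$records
  if (is.null(species)) {
    if (!nrow(rec)) species <- NA_character_
    else species <- names(sort(table(rec$species), decreasing = TRUE))[1]
  }
  rec <- rec[rec$species %in% species, , drop = FALSE]
  xe <- seq(0, traj$box[1] + bin - 1e-9, by = bin)
  ye <- seq(0, traj$box[2] + bin - 1e-9, by = bin)
  if (!nrow(rec))
    return(list(density = matrix(0, length(xe) - 1, length(ye) - 1),
                x_edges = xe, y_edges = ye, n_crossings = 0L,
                points = data.frame(x = numeric(0), y = numeric(0))))
  mid <- mean(traj$slab)
  pts <- do.call(rbind, lapply(seq_len(nrow(rec)), function(k) {
    i <- match(rec$ion_id[k], traj$ions$ion_id)
    f_end <- rec$frame[k]
    # walk back through the traversal to the first midplane passage
    zi <- traj$z[, i]
    f_start <- f_end
    while (f_start > 1 &&
           zi[f_start - 1] >= traj$slab[1] - crossings$hysteresis &&
           zi[f_start - 1] <= traj$slab[2] + crossings$hysteresis &&
           abs(zi[f_start] - zi[f_start - 1]) <= traj$box[3] / 2)
      f_start <- f_start - 1L
    seg <- f_start:f_end
    side <- sign(zi[seg] - mid)
    pass <- which(side == sign(rec$direction[k]))[1]
    f_mid <- seg[if (is.na(pass)) length(seg) else pass]
    data.frame(x = traj$x[f_mid, i], y = traj$y[f_mid, i])
  }))
  ix <- findInterval(pts$x, xe, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(pts$y, ye, rightmost.closed = TRUE, all.inside = TRUE)
  dens <- matrix(0, length(xe) - 1, length(ye) - 1)
  for (k in seq_along(ix)) dens[ix[k], iy[k]] <- dens[ix[k], iy[k]] + 1
  dens <- dens / nrow(pts)
  list(density = dens, x_edges = xe, y_edges = ye, n_crossings = nrow(pts),
       points = pts)
}

#' Diffusion coefficient from mean-squared displacement
#'
#' Average MSD over ions and time origins at a set of lags, least-squares
#' slope over the linear regime, D = slope / (2 x dimensionality).  A
#' convexity check flags ballistic (non-diffusive) signatures.
#'
#' @param traj An \code{ion_trajectory} (unwrapped z is used together
#'   with x and y), or a frames x ions x dims array of unwrapped
#'   positions.
#' @param max_lag Maximum lag in frames (default: a quarter of the run,
#'   at least 10).
#' @param species Restrict to one species (trajectory input).
#' @param dt_ns Frame interval (required for array input).
#' @return List with \code{D_A2ns}, \code{D_cm2s}, \code{r_squared},
#'   \code{msd} (data.frame lag_ns/msd), \code{reliable} (FALSE when the
#'   MSD curve fails the convexity test).
#' @export
msd_diffusion <- function(traj, max_lag = NULL, species = NULL, dt_ns = NULL) {
  if (inherits(traj, "ion_trajectory")) {
    keep <- if (is.null(species)) seq_len(ncol(traj$z)) else which(traj$ions$species %in% species)
    xs <- traj$x_unwrapped %||% traj$x
    ys <- traj$y_unwrapped %||% traj$y
    pos <- array(c(xs[, keep], ys[, keep], traj$z_unwrapped[, keep]),
                 c(nrow(traj$z), length(keep), 3))
    dt_ns <- traj$dt_ns
  } else {
    pos <- traj
    stopifnot(is.array(pos), length(dim(pos)) == 3L, !is.null(dt_ns))
  }
  nf <- dim(pos)[1]; nd <- dim(pos)[3]
  if (is.null(max_lag)) max_lag <- max(10L, nf %/% 4L)
  max_lag <- min(max_lag, nf - 1L)
  if (max_lag < 10L) stop("need at least 10 lags for an MSD fit", call. = FALSE)
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(l) {
    d <- pos[(1 + l):nf, , , drop = FALSE] - pos[1:(nf - l), , , drop = FALSE]
    mean(apply(d^2, c(1, 2), sum))
  }, numeric(1))
  tl <- lags * dt_ns
  fit <- stats::lm(msd ~ tl)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  # convexity check: second differences should not be systematically positive
  sd2 <- diff(msd, differences = 2)
  reliable <- !(mean(sd2 > 0) > 0.75 && slope > 0 && length(sd2) >= 8)
  D <- max(slope, 0) / (2 * nd)
  list(D_A2ns = D, D_cm2s = D / unit_conventions()$cm2s_to_A2ns,
       r_squared = r2, msd = data.frame(lag_ns = tl, msd = msd),
       reliable = reliable)
}
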