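# Synthetic generators with known ground truth: peptide C-alpha ensembles
# with controllable helicity/cluster structure, drift-diffusion ion boxes
# with known expected flux, and noisy per-frame chemical-shift tables.

#' Specification of a synthetic peptide ensemble
#'
#' Per frame, an independent two-state (helix/coil) Markov chain is run
#' along the residues with stationary helix probability \code{helix_prob}
#' and persistence \code{persistence} (transition matrix
#' P(h|h) = persistence + (1-persistence) * helix_prob, etc.).  C-alpha
#' coordinates are built from virtual internals: fixed 3.8-Angstrom bonds,
#' fixed virtual bond angle, and a virtual torsion that takes
#' \code{helical_torsion} when the originating residue is helical and is
#' drawn from a broad coil distribution (excluding the helical window)
#' otherwise.  Isotropic Gaussian jitter of width \code{jitter} is added
#' to every coordinate.
#'
#' @param length Chain length in residues (>= 4).
#' @param helix_prob Stationary helix probability in [0, 1].
#' @param persistence Markov persistence in [0, 1); 1 is rejected for
#'   mixed targets because the chain cannot mix.
#' @param frames Number of frames.
#' @param jitter Coordinate jitter sigma, Angstrom.
#' @param seed Integer seed.
#' @param helical_torsion Virtual torsion of helical residues, degrees.
#' @param torsion_offset Constant offset added to every torsion; two specs
#'   differing by a large offset yield well-separated conformal groups for
#'   clustering tests.
#' @param bond_length Consecutive C-alpha distance, Angstrom.
#' @param bond_angle Virtual bond angle, degrees.
#' @return An object of class \code{peptide_spec}.
#' @export
peptide_spec <- function(length = 25L, helix_prob = 0.7, persistence = 0.9,
                         frames = 500L, jitter = 0.15, seed = 1L,
                         helical_torsion = 52, torsion_offset = 0,
                         bond_length = 3.8, bond_angle = 91) {
  stopifnot(length >= 4, frames >= 1, jitter >= 0,
            helix_prob >= 0, helix_prob <= 1,
            persistence >= 0, persistence <= 1)
  if (persistence >= 1 && helix_prob > 0 && helix_prob < 1)
    stop("persistence = 1 with a mixed helix target: the chain cannot mix",
         call. = FALSE)
  structure(list(length = as.integer(length), helix_prob = helix_prob,
                 persistence = persistence, frames = as.integer(frames),
                 jitter = jitter, seed = as.integer(seed),
                 helical_torsion = helical_torsion,
                 torsion_offset = torsion_offset,
                 bond_length = bond_length, bond_angle = bond_angle),
            class = "peptide_spec")
}

#' Generate a synthetic peptide C-alpha ensemble
#'
#' @param spec A [peptide_spec()].
#' @return A list with \code{ensemble} (a [conformer_ensemble()]) and
#'   \code{labels} (frames x residues 0/1 ground-truth helix labels).
#' @examples
#' out <- generate_peptide_ensemble(peptide_spec(frames = 50, seed = 3))
#' colMeans(out$labels)
#' @export
generate_peptide_ensemble <- function(spec) {
  stopifnot(inherits(spec, "peptide_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  L <- spec$length; nf <- spec$frames
  p <- spec$helix_prob; lam <- spec$persistence
  # per-frame Markov chains along the chain
  labels <- matrix(0L, nf, L)
  for (f in seq_len(nf)) {
    s <- integer(L)
    s[1] <- stats::rbinom(1, 1, p)
    if (L > 1) {
      u <- stats::runif(L - 1)
      for (i in 2:L) {
        ph <- lam * s[i - 1] + (1 - lam) * p
        s[i] <- as.integer(u[i - 1] < ph)
      }
    }
    labels[f, ] <- s
  }
  coords <- array(0, c(nf, L, 3))
  n_tor <- L - 3L
  for (f in seq_len(nf)) {
    tor <- numeric(n_tor)
    hel <- labels[f, seq_len(n_tor)] == 1L
    tor[hel] <- spec$helical_torsion
    if (any(!hel)) tor[!hel] <- .coil_torsion(sum(!hel), spec$helical_torsion)
    tor <- tor + spec$torsion_offset
    coords[f, , ] <- .build_chain(L, spec$bond_length, spec$bond_angle, tor)
  }
  if (spec$jitter > 0)
    coords <- coords + array(stats::rnorm(length(coords), 0, spec$jitter), dim(coords))
  atoms <- data.frame(name = "CA", resid = seq_len(L), resname = "ALA")
  list(ensemble = conformer_ensemble(coords, atoms), labels = labels)
}

# coil torsions: extended-dominated (|tau| in 100..180), emulating the
# expanded character of disordered chains (excluded volume is not
# modelled, so unrestricted random torsions would collapse the coil);
# also keeps coil torsions far outside the helical window
.coil_torsion <- function(n, helical, lo = 100) {
  sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, lo, 180)
}

# NeRF-style chain build from fixed bond length/angle and torsion series
.build_chain <- function(L, b, theta_deg, torsions) {
  th <- theta_deg * pi / 180
  xyz <- matrix(0, L, 3)
  xyz[2, ] <- c(b, 0, 0)
  xyz[3, ] <- xyz[2, ] + b * c(-cos(th), sin(th), 0)
  for (i in 4:L) {
    tau <- torsions[i - 3] * pi / 180
    A <- xyz[i - 3, ]; B <- xyz[i - 2, ]; C <- xyz[i - 1, ]
    bc <- C - B; bc <- bc / sqrt(sum(bc^2))
    ab <- B - A
    n <- c(ab[2] * bc[3] - ab[3] * bc[2],
           ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
    n <- n / sqrt(sum(n^2))
    m <- c(n[2] * bc[3] - n[3] * bc[2],
           n[3] * bc[1] - n[1] * bc[3],
           n[1] * bc[2] - n[2] * bc[1])
    d <- c(-b * cos(th), b * sin(th) * cos(tau), b * sin(th) * sin(tau))
    xyz[i, ] <- C + d[1] * bc + d[2] * m - d[3] * n
  }
  xyz
}

#' Specification of a drift-diffusion ion box
#'
#' Tagged charged particles in a rectangular box with a membrane slab:
#' Brownian displacements with per-species diffusion coefficient
#' (variance 2 D dt per axis) plus a constant drift along z applied while
#' the ion is inside the slab.  z is periodic (ions re-inject across the
#' z faces); x and y are reflective.
#'
#' @param box Box dimensions c(Lx, Ly, Lz), Angstrom.
#' @param slab Slab bounds c(z_lo, z_hi), Angstrom, strictly inside the
#'   box (z spans -Lz/2..Lz/2).
#' @param species data.frame with columns \code{species}, \code{charge}
#'   (+1/-1), \code{count}, \code{D_cm2s}, \code{drift_A_ns}.
#' @param frames Number of saved frames.
#' @param dt_ns Frame interval, ns.
#' @param seed Integer seed.
#' @param drift_region \code{"slab"} (drift acts only inside the membrane
#'   slab, the default) or \code{"everywhere"} (uniform conveyor drift:
#'   with periodic z and N driven ions the expected crossing rate is
#'   exactly N v_z / L_z).
#' @return An object of class \code{ion_box_spec}.
#' @export
ion_box_spec <- function(box = c(85, 85, 95), slab = c(-17.5, 17.5),
                         species = data.frame(
                           species = c("K", "CL"), charge = c(1, -1),
                           count = c(20, 20),
                           D_cm2s = c(1.96e-5, 2.03e-5),
                           drift_A_ns = c(0, 0)),
                         frames = 1000L, dt_ns = 0.1, seed = 1L,
                         drift_region = c("slab", "everywhere")) {
  drift_region <- match.arg(drift_region)
  stopifnot(length(box) == 3, all(box > 0), length(slab) == 2,
            slab[1] < slab[2], frames >= 2, dt_ns > 0)
  if (slab[1] <= -box[3] / 2 || slab[2] >= box[3] / 2)
    stop("slab must lie strictly inside the box along z", call. = FALSE)
  need <- c("species", "charge", "count", "D_cm2s", "drift_A_ns")
  stopifnot(is.data.frame(species), all(need %in% names(species)))
  if (!all(species$charge %in% c(-1, 1)))
    stop("charges must be +1 or -1", call. = FALSE)
  if (any(species$D_cm2s < 0)) stop("diffusion coefficients must be >= 0", call. = FALSE)
  if (any(abs(species$drift_A_ns) * dt_ns > box[3]))
    stop("drift moves an ion farther than the box per frame: crossings undetectable",
         call. = FALSE)
  structure(list(box = box, slab = slab, species = species,
                 frames = as.integer(frames), dt_ns = dt_ns,
                 seed = as.integer(seed), drift_region = drift_region),
            class = "ion_box_spec")
}

#' Generate a drift-diffusion ion trajectory
#'
#' @param spec An [ion_box_spec()].
#' @return An object of class \code{ion_trajectory}: list with \code{ions}
#'   (data.frame ion_id/species/charge), \code{x}, \code{y}, \code{z}
#'   (frames x ions wrapped coordinates), \code{z_unwrapped}, \code{box},
#'   \code{slab}, \code{dt_ns}, \code{time_ns}.
#' @export
generate_ion_trajectory <- function(spec) {
  stopifnot(inherits(spec, "ion_box_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  conv <- unit_conventions()
  sp <- spec$species
  ions <- do.call(rbind, lapply(seq_len(nrow(sp)), function(i)
    data.frame(ion_id = NA_integer_, species = sp$species[i],
               charge = sp$charge[i], D_A2ns = sp$D_cm2s[i] * conv$cm2s_to_A2ns,
               drift = sp$drift_A_ns[i],
               stringsAsFactors = FALSE)[rep(1, sp$count[i]), ]))
  n <- nrow(ions)
  ions$ion_id <- seq_len(n)
  rownames(ions) <- NULL
  nf <- spec$frames; dt <- spec$dt_ns
  Lx <- spec$box[1]; Ly <- spec$box[2]; Lz <- spec$box[3]
  x <- y <- z <- xu <- yu <- zu <- matrix(0, nf, n)
  # initial positions: uniform, outside the slab (bulk start)
  x[1, ] <- stats::runif(n, 0, Lx)
  y[1, ] <- stats::runif(n, 0, Ly)
  z0 <- stats::runif(n, -Lz / 2, Lz / 2)
  inside <- z0 > spec$slab[1] & z0 < spec$slab[2]
  while (any(inside)) {
    z0[inside] <- stats::runif(sum(inside), -Lz / 2, Lz / 2)
    inside <- z0 > spec$slab[1] & z0 < spec$slab[2]
  }
  z[1, ] <- zu[1, ] <- z0
  xu[1, ] <- x[1, ]; yu[1, ] <- y[1, ]
  sig <- sqrt(2 * ions$D_A2ns * dt)
  for (f in 2:nf) {
    dx <- stats::rnorm(n, 0, sig); dy <- stats::rnorm(n, 0, sig)
    dz <- stats::rnorm(n, 0, sig)
    if (spec$drift_region == "everywhere") {
      dz <- dz + ions$drift * dt
    } else {
      in_slab <- z[f - 1, ] >= spec$slab[1] & z[f - 1, ] <= spec$slab[2]
      dz <- dz + ifelse(in_slab, ions$drift * dt, 0)
    }
    x[f, ] <- .reflect(x[f - 1, ] + dx, 0, Lx)
    y[f, ] <- .reflect(y[f - 1, ] + dy, 0, Ly)
    xu[f, ] <- xu[f - 1, ] + dx
    yu[f, ] <- yu[f - 1, ] + dy
    zu[f, ] <- zu[f - 1, ] + dz
    z[f, ] <- .wrap(z[f - 1, ] + dz, -Lz / 2, Lz / 2)
  }
  structure(list(ions = ions[, c("ion_id", "species", "charge")],
                 x = x, y = y, z = z,
                 x_unwrapped = xu, y_unwrapped = yu, z_unwrapped = zu,
                 box = spec$box, slab = spec$slab, dt_ns = dt,
                 time_ns = (seq_len(nf) - 1L) * dt, spec = spec),
            class = "ion_trajectory")
}

#' Assemble an ion trajectory from raw coordinate matrices
#'
#' Low-level constructor for deterministic or externally read ion paths
#' (the generator [generate_ion_trajectory()] is the usual entry point).
#'
#' @param ions data.frame with \code{ion_id}, \code{species}, \code{charge}.
#' @param x,y,z frames x ions wrapped coordinate matrices (Angstrom);
#'   z spans -Lz/2..Lz/2.
#' @param box,slab Box dimensions and slab bounds as in [ion_box_spec()].
#' @param dt_ns Frame interval, ns.
#' @param z_unwrapped Optional unwrapped z bookkeeping (defaults to z).
#' @return An \code{ion_trajectory} object.
#' @export
ion_trajectory <- function(ions, x, y, z, box, slab, dt_ns,
                           z_unwrapped = z) {
  stopifnot(is.data.frame(ions),
            all(c("ion_id", "species", "charge") %in% names(ions)),
            is.matrix(z), ncol(z) == nrow(ions),
            all(dim(x) == dim(z)), all(dim(y) == dim(z)),
            length(box) == 3, slab[1] < slab[2], dt_ns > 0)
  structure(list(ions = ions, x = x, y = y, z = z, z_unwrapped = z_unwrapped,
                 box = box, slab = slab, dt_ns = dt_ns,
                 time_ns = (seq_len(nrow(z)) - 1L) * dt_ns, spec = NULL),
            class = "ion_trajectory")
}

.wrap <- function(v, lo, hi) lo + (v - lo) %% (hi - lo)

.reflect <- function(v, lo, hi) {
  span <- hi - lo
  v <- (v - lo) %% (2 * span)
  lo + ifelse(v > span, 2 * span - v, v)
}

#' @export
print.ion_trajectory <- function(x, ...) {
  cat(sprintf("Ion trajectory: %d ions (%s), %d frames x %.3g ns, slab z in [%.1f, %.1f]\n",
              nrow(x$ions),
              paste(sprintf("%d %s", table(x$ions$species),
                            names(table(x$ions$species))), collapse = ", "),
              length(x$time_ns), x$dt_ns, x$slab[1], x$slab[2]))
  invisible(x)
}

#' Generate a noisy per-frame chemical-shift table
#'
#' Frame-level shifts are the supplied truth plus iid Gaussian noise.
#'
#' @param truth data.frame with columns \code{residue}, \code{resname},
#'   \code{nucleus} (CA/CB) and \code{ppm}; glycine must carry no CB row.
#' @param sigma Frame noise standard deviation, ppm (>= 0).
#' @param frames Number of frames.
#' @param seed Integer seed.
#' @return A list with \code{table} (long data.frame frame/residue/
#'   resname/nucleus/ppm) and \code{truth} (the input).
#' @export
generate_shift_table <- function(truth, sigma = 1, frames = 100L, seed = 1L) {
  need <- c("residue", "resname", "nucleus", "ppm")
  stopifnot(is.data.frame(truth), all(need %in% names(truth)), sigma >= 0,
            frames >= 1)
  key <- paste(truth$residue, truth$nucleus)
  if (anyDuplicated(key)) stop("duplicate (residue, nucleus) keys in truth", call. = FALSE)
  if (any(truth$resname == "GLY" & truth$nucleus == "CB"))
    stop("glycine has no CB nucleus", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- nrow(truth)
  tab <- truth[rep(seq_len(n), times = frames), need]
  tab$frame <- rep(seq_len(frames), each = n)
  tab$ppm <- tab$ppm + stats::rnorm(nrow(tab), 0, sigma)
  rownames(tab) <- NULL
  list(table = tab[, c("frame", "residue", "resname", "nucleus", "ppm")],
       truth = truth)
}
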