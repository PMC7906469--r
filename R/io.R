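# Plain-text interchange: multi-model PDB and XYZ for ensembles, CSV for
# boost series, shift tables and ion metadata.  Reading PDB goes through
# bio3d; the multi-model writer is in-package (one MODEL block per frame,
# fixed-width ATOM records at 3-decimal precision).

#' Write a conformer ensemble as a multi-model PDB file
#'
#' @param ensemble A [conformer_ensemble()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  nf <- dim(ensemble$coords)[1]; na <- dim(ensemble$coords)[2]
  at <- ensemble$atoms
  name <- format(substr(at$name %||% rep("CA", na), 1, 4), width = 4)
  resname <- format(substr(at$resname %||% rep("ALA", na), 1, 3), width = 3)
  resid <- at$resid %||% seq_len(na)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ensemble$coords[f, , , drop = TRUE]
    writeLines(sprintf("ATOM  %5d %s %s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                       seq_len(na), name, resname, resid,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file into a conformer ensemble
#'
#' @param path PDB file with one or more MODEL blocks.
#' @return A [conformer_ensemble()].
#' @export
read_pdb_ensemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  na <- ncol(xyz) / 3
  coords <- array(NA_real_, c(nrow(xyz), na, 3))
  for (f in seq_len(nrow(xyz)))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  atoms <- data.frame(name = trimws(pdb$atom$elety), resid = pdb$atom$resno,
                      resname = trimws(pdb$atom$resid))
  conformer_ensemble(coords, atoms[seq_len(na), ])
}

#' Write a conformer ensemble as an XYZ trajectory
#'
#' Plain XYZ: per frame, an atom count line, a comment line, then
#' \code{element x y z} records.
#'
#' @param ensemble A [conformer_ensemble()].
#' @param path Output file.
#' @param element Element symbol per atom (default "C").
#' @return \code{path}, invisibly.
#' @export
write_xyz_trajectory <- function(ensemble, path, element = "C") {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  nf <- dim(ensemble$coords)[1]; na <- dim(ensemble$coords)[2]
  el <- rep_len(element, na)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(as.character(na), con)
    writeLines(sprintf("frame %d t= %.6f ns", f, ensemble$time_ns[f]), con)
    xyz <- ensemble$coords[f, , , drop = TRUE]
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", el, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path XYZ trajectory file.
#' @return A [conformer_ensemble()] (times parsed from \code{t=} comment
#'   fields when present).
#' @export
read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  i <- 1L; frames <- list(); times <- numeric(0)
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    na <- as.integer(trimws(lines[i]))
    cmt <- lines[i + 1L]
    tm <- regmatches(cmt, regexpr("t= *[-0-9.eE+]+", cmt))
    times <- c(times, if (length(tm)) as.numeric(sub("t= *", "", tm)) else NA_real_)
    block <- lines[(i + 2L):(i + 1L + na)]
    parts <- do.call(rbind, strsplit(trimws(block), "[[:space:]]+"))
    frames[[length(frames) + 1L]] <-
      matrix(as.numeric(parts[, 2:4]), ncol = 3)
    i <- i + 2L + na
  }
  nf <- length(frames); na <- nrow(frames[[1]])
  coords <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
  if (any(is.na(times))) times <- seq_len(nf)
  conformer_ensemble(coords, time_ns = times)
}

#' Write / read a boost series as CSV
#'
#' Columns: frame, time_ns, V, Vd, dV.
#'
#' @param boosts A [boost_series()].
#' @param path CSV file.
#' @return \code{path} (writer) or a \code{boost_series} (reader).
#' @export
write_boost_csv <- function(boosts, path) {
  stopifnot(inherits(boosts, "boost_series"))
  utils::write.csv(as.data.frame(boosts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boost_csv
#' @export
read_boost_csv <- function(path) {
  d <- utils::read.csv(path)
  boost_series(d$time_ns, V = d$V, Vd = d$Vd, dV = d$dV)
}

#' Write / read shift tables as CSV
#'
#' Per-frame tables carry columns frame, residue, resname, nucleus, ppm;
#' averaged/experimental tables omit \code{frame}.
#'
#' @param table A shift table data.frame.
#' @param path CSV file.
#' @return \code{path} (writer) or a data.frame (reader).
#' @export
write_shift_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shift_csv
#' @export
read_shift_csv <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Write an ion trajectory as XYZ plus a metadata CSV
#'
#' @param traj An \code{ion_trajectory}.
#' @param xyz_path XYZ trajectory output (wrapped coordinates).
#' @param meta_path Metadata CSV (ion_id, species, charge).
#' @return \code{xyz_path}, invisibly.
#' @export
write_ion_trajectory <- function(traj, xyz_path, meta_path) {
  stopifnot(inherits(traj, "ion_trajectory"))
  nf <- nrow(traj$z); ni <- ncol(traj$z)
  coords <- array(c(traj$x, traj$y, traj$z), c(nf, ni, 3))
  ens <- conformer_ensemble(coords, time_ns = traj$time_ns)
  write_xyz_trajectory(ens, xyz_path, element = substr(traj$ions$species, 1, 2))
  utils::write.csv(traj$ions, meta_path, row.names = FALSE)
  invisible(xyz_path)
}

#' Read an ion trajectory written by [write_ion_trajectory()]
#'
#' @param xyz_path,meta_path Files written by the writer.
#' @param box,slab,dt_ns Geometry and frame interval of the original run.
#' @return An \code{ion_trajectory}.
#' @export
read_ion_trajectory <- function(xyz_path, meta_path, box, slab, dt_ns) {
  ens <- read_xyz_trajectory(xyz_path)
  ions <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  ion_trajectory(ions, x = ens$coords[, , 1], y = ens$coords[, , 2],
                 z = ens$coords[, , 3], box = box, slab = slab, dt_ns = dt_ns)
}
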