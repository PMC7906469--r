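# End-to-end orchestration of the two workflows:
#   peptide — biased toy sampling -> Maclaurin reweighting -> PMF ->
#             peptide ensemble -> clustering/helicity -> shift comparison;
#   channel — drift-diffusion ion trajectory -> crossings/current ->
#             GCMC/BD screening of conformer channel models.
# Every stage seed is recorded in the manifest; unknown config keys are
# rejected; re-running an identical config reproduces identical outputs.

.default_config <- function() {
  list(
    seed = 1L,
    outdir = tempfile("idrchannel_run_"),
    toy = list(barrier = 3, separation = 1, tilt = 0.4, n_steps = 2e5L,
               burn_in = 2e4L, save_every = 10L, dt = 5e-4,
               boost_level = 2.5, k_max = 10L, bin_width = 0.25),
    peptide = list(length = 25L, helix_prob = 0.7, persistence = 0.9,
                   frames = 300L, jitter = 0.15,
                   cluster_threshold = 3, shift_sigma = 0.8),
    ions = list(frames = 4000L, dt_ns = 0.05, count = 25L,
                drift_A_ns = 8, voltage_mV = 40),
    gcmcbd = list(n_conformers = 5L, cycles = 5e4L, dt_ps = 5,
                  radii = NULL, voltage_mV = 40,
                  conductance_threshold = 0.6, ratio_threshold = 4)
  )
}

.merge_config <- function(user, defaults = .default_config()) {
  if (is.null(user)) return(defaults)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      badk <- setdiff(names(user[[k]]), names(defaults[[k]]))
      if (length(badk))
        stop(sprintf("unknown config key(s) in section '%s': %s", k,
                     paste(badk, collapse = ", ")), call. = FALSE)
      defaults[[k]][names(user[[k]])] <- user[[k]]
    } else defaults[[k]] <- user[[k]]
  }
  defaults
}

.file_hash <- function(paths) unname(tools::md5sum(paths))

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run an end-to-end workflow
#'
#' Executes the stages of the requested workflow in dependency order,
#' writing every intermediate artifact into the configured output
#' directory, and returns a machine-readable manifest (config snapshot,
#' per-stage seeds, output paths and md5 hashes).  Identical config and
#' seed reproduce identical artifacts.
#'
#' @param config A nested configuration list (unknown keys are rejected),
#'   or a path to a YAML file holding one; \code{NULL} uses the built-in
#'   desk-scale defaults.
#' @param workflow \code{"peptide"} or \code{"channel"}.
#' @return An object of class \code{run_manifest}.
#' @export
run_workflow <- function(config = NULL, workflow = c("peptide", "channel")) {
  workflow <- match.arg(workflow)
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- .merge_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    res
  }
  outputs <- list()
  results <- list()
  if (workflow == "peptide") {
    pot <- toy_potential("double_well_1d", barrier = cfg$toy$barrier,
                         separation = cfg$toy$separation, tilt = cfg$toy$tilt)
    stage("bias", function() {
      E0 <- potential_energy(pot, pot$separation)
      bias <- boost_parameters(E_p = E0 + cfg$toy$boost_level,
                               alpha_p = cfg$toy$boost_level)
      run <- sample_langevin(pot, sampler_config(
        n_steps = cfg$toy$n_steps, burn_in = cfg$toy$burn_in,
        save_every = cfg$toy$save_every, dt = cfg$toy$dt,
        seed = cfg$seed), bias = bias)
      p <- file.path(cfg$outdir, "boosts.csv")
      write_boost_csv(run$boosts, p)
      outputs$boosts <<- p
      results$biased_run <<- run
      invisible(NULL)
    })
    stage("reweight", function() {
      run <- results$biased_run
      w <- maclaurin_weights(run$boosts, kT = run$config$kT,
                             k_max = cfg$toy$k_max)
      pmf <- reweighted_pmf(run$positions[, 1], weights = w,
                            bin_width = cfg$toy$bin_width, kT = run$config$kT)
      p <- file.path(cfg$outdir, "pmf.csv")
      utils::write.csv(data.frame(
        cv_lo = pmf$edges1[-length(pmf$edges1)], cv_hi = pmf$edges1[-1],
        pmf_kcal = pmf$pmf, count = pmf$count), p, row.names = FALSE)
      outputs$pmf <<- p
      results$weights <<- w
      results$gap_kcal <<- well_free_energy_gap(run, weights = w,
                                                kT = run$config$kT)
      invisible(NULL)
    })
    stage("ensemble", function() {
      pep <- generate_peptide_ensemble(peptide_spec(
        length = cfg$peptide$length, helix_prob = cfg$peptide$helix_prob,
        persistence = cfg$peptide$persistence, frames = cfg$peptide$frames,
        jitter = cfg$peptide$jitter, seed = cfg$seed + 1L))
      cl <- cluster_rmsd(pep$ensemble, threshold = cfg$peptide$cluster_threshold)
      pc <- file.path(cfg$outdir, "clusters.csv")
      utils::write.csv(data.frame(
        frame = seq_along(cl$labels), cluster = cl$labels,
        is_medoid = seq_along(cl$labels) %in% cl$medoids), pc, row.names = FALSE)
      pm <- file.path(cfg$outdir, "medoids.pdb")
      med <- conformer_ensemble(
        pep$ensemble$coords[cl$medoids, , , drop = FALSE], pep$ensemble$atoms)
      write_pdb_ensemble(med, pm)
      hp <- helix_propensity(pep$labels)
      ph <- file.path(cfg$outdir, "helicity.csv")
      utils::write.csv(data.frame(residue = seq_along(hp), propensity = hp),
                       ph, row.names = FALSE)
      outputs$clusters <<- pc; outputs$medoids <<- pm; outputs$helicity <<- ph
      results$clusters <<- cl
      results$helicity <<- hp
      invisible(NULL)
    })
    stage("shifts", function() {
      L <- cfg$peptide$length
      truth <- data.frame(residue = rep(seq_len(L), each = 2),
                          resname = "ALA",
                          nucleus = rep(c("CA", "CB"), L),
                          ppm = c(rbind(52 + 2 * sin(seq_len(L)),
                                        19 + 1.5 * cos(seq_len(L)))))
      st <- generate_shift_table(truth, sigma = cfg$peptide$shift_sigma,
                                 frames = 200L, seed = cfg$seed + 2L)
      avg <- ensemble_shifts(st$table)
      cmpr <- compare_shifts(avg, truth)
      p <- file.path(cfg$outdir, "shift_comparison.json")
      jsonlite::write_json(list(by_nucleus = cmpr$by_nucleus,
                                pooled_rmse = cmpr$pooled_rmse),
                           p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      outputs$shifts <<- p
      results$shift_comparison <<- cmpr
      invisible(NULL)
    })
  } else {
    stage("permeation", function() {
      sp <- data.frame(species = c("K", "CL"), charge = c(1, -1),
                       count = c(cfg$ions$count, cfg$ions$count),
                       D_cm2s = c(1.96e-5, 2.03e-5),
                       drift_A_ns = c(-cfg$ions$drift_A_ns / 4, cfg$ions$drift_A_ns))
      traj <- generate_ion_trajectory(ion_box_spec(
        species = sp, frames = cfg$ions$frames, dt_ns = cfg$ions$dt_ns,
        seed = cfg$seed))
      cr <- detect_crossings(traj)
      pe <- file.path(cfg$outdir, "events.csv")
      utils::write.csv(cr$records[, c("ion_id", "species", "direction", "time_ns")],
                       pe, row.names = FALSE)
      rep <- estimate_current(cr, scaling = diffusion_scaling(),
                              voltage_mV = cfg$ions$voltage_mV)
      pr <- file.path(cfg$outdir, "current_report.json")
      jsonlite::write_json(rep[c("slope_e_ns", "r_squared", "factor",
                                 "current_pA", "conductance_nS",
                                 "anion_cation_ratio", "low_count_flag")],
                           pr, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      outputs$events <<- pe; outputs$current <<- pr
      results$current_report <<- rep
      invisible(NULL)
    })
    stage("gcmcbd", function() {
      n <- cfg$gcmcbd$n_conformers
      radii <- cfg$gcmcbd$radii %||% seq(4, 10, length.out = n)
      reports <- lapply(seq_len(n), function(i) {
        m <- channel_model(radius = radii[i],
                           voltage_mV = cfg$gcmcbd$voltage_mV)
        r <- run_gcmcbd(m, gcmcbd_config(cycles = cfg$gcmcbd$cycles,
                                         dt_ps = cfg$gcmcbd$dt_ps,
                                         seed = cfg$seed + 10L + i,
                                         replicas = 1L, trace_every = 0L))
        list(conformer = i, radius = radii[i],
             conductance_nS = r$conductance_nS, ratio = r$ratio,
             voltage_mV = cfg$gcmcbd$voltage_mV)
      })
      flagged <- screen_conformers(reports,
                                   conductance_threshold = cfg$gcmcbd$conductance_threshold,
                                   ratio_threshold = cfg$gcmcbd$ratio_threshold)
      p <- file.path(cfg$outdir, "gcmcbd_screen.json")
      jsonlite::write_json(list(reports = reports,
                                flagged = vapply(flagged, `[[`, 1, "conformer")),
                           p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      outputs$gcmcbd <<- p
      results$gcmcbd_reports <<- reports
      results$flagged <<- flagged
      invisible(NULL)
    })
  }
  files <- unlist(outputs)
  manifest <- structure(list(
    workflow = workflow,
    config = cfg,
    config_hash = .config_hash(cfg),
    seed = cfg$seed,
    outputs = files,
    hashes = .file_hash(files),
    results = results,
    version = as.character(utils::packageVersion("idrchannel"))),
    class = "run_manifest")
  jsonlite::write_json(list(workflow = workflow, config_hash = manifest$config_hash,
                            seed = cfg$seed, outputs = as.list(files),
                            hashes = as.list(manifest$hashes),
                            version = manifest$version),
                       file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Run manifest: %s workflow, seed %d, config %s\n",
              x$workflow, x$seed, substr(x$config_hash, 1, 8)))
  for (i in seq_along(x$outputs))
    cat(sprintf("  %-12s %s\n", names(x$outputs)[i], x$outputs[i]))
  invisible(x)
}

#' Screen conformer reports for low-conducting / low-selectivity states
#'
#' Pure filter keeping the reports whose conductance falls below the
#' conductance threshold OR whose anion/cation ratio falls below the
#' ratio threshold (defaults 0.6 nS and 4).  All reports must share the
#' same applied voltage.
#'
#' @param reports List of report lists, each with \code{conductance_nS},
#'   \code{ratio} and \code{voltage_mV}.
#' @param conductance_threshold Conductance cut, nS (default 0.6).
#' @param ratio_threshold Anion/cation ratio cut (default 4).
#' @return The flagged subset of \code{reports} (possibly empty).
#' @examples
#' reps <- list(list(conductance_nS = 0.5, ratio = 5, voltage_mV = 40),
#'              list(conductance_nS = 0.9, ratio = 3, voltage_mV = 40),
#'              list(conductance_nS = 0.9, ratio = 5, voltage_mV = 40))
#' length(screen_conformers(reps))  # 2
#' @export
screen_conformers <- function(reports, conductance_threshold = 0.6,
                              ratio_threshold = 4) {
  if (!length(reports)) return(reports[0])
  volts <- vapply(reports, function(r) as.numeric(r$voltage_mV %||% NA_real_),
                  numeric(1))
  if (length(unique(volts[!is.na(volts)])) > 1)
    stop("reports were obtained at different voltages; screening is undefined",
         call. = FALSE)
  keep <- vapply(reports, function(r) {
    g <- r$conductance_nS; rt <- r$ratio
    (!is.na(g) && g < conductance_threshold) ||
      (!is.na(rt) && rt < ratio_threshold)
  }, logical(1))
  reports[keep]
}
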