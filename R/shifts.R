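# Ensemble-averaged chemical shifts and their comparison with experiment.
# Per-structure predictions (e.g. from an external shift predictor) enter
# as long-format tables keyed by (residue, resname, nucleus); averaging is
# plain or reweighted; scoring is per-nucleus RMSE and Pearson R.

.shift_key <- function(tab) paste(tab$residue, tab$resname, tab$nucleus, sep = "|")

.check_shift_table <- function(tab, per_frame = FALSE) {
  need <- c("residue", "resname", "nucleus", "ppm")
  if (per_frame) need <- c("frame", need)
  if (!is.data.frame(tab) || !all(need %in% names(tab)))
    stop("shift table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(tab$resname == "GLY" & tab$nucleus == "CB"))
    stop("glycine has no CB nucleus", call. = FALSE)
  if (!per_frame && anyDuplicated(.shift_key(tab)))
    stop("duplicate (residue, resname, nucleus) keys", call. = FALSE)
  invisible(tab)
}

#' Ensemble-average a per-frame chemical-shift table
#'
#' Per-key weighted mean over frames; uniform weights give the simple
#' average.  Every frame must carry the same key set.
#'
#' @param frame_table Long data.frame with columns \code{frame},
#'   \code{residue}, \code{resname}, \code{nucleus}, \code{ppm}.
#' @param weights Optional per-frame weights (e.g. a
#'   [maclaurin_weights()] vector), indexed by the sorted unique frames.
#' @return A shift table (residue, resname, nucleus, ppm) of weighted
#'   means.
#' @examples
#' tab <- data.frame(frame = c(1, 2), residue = 1, resname = "ALA",
#'                   nucleus = "CA", ppm = c(50, 54))
#' ensemble_shifts(tab, weights = c(1, 3))$ppm  # 53
#' @export
ensemble_shifts <- function(frame_table, weights = NULL) {
  .check_shift_table(frame_table, per_frame = TRUE)
  frames <- sort(unique(frame_table$frame))
  key <- .shift_key(frame_table)
  keys <- unique(key)
  # key-set consistency across frames
  counts <- table(key)
  if (any(counts != length(frames))) {
    bad <- names(counts)[counts != length(frames)]
    stop("keys not present on every frame: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, length(frames)) else as.numeric(weights)
  if (length(w) != length(frames))
    stop("weights length must equal the number of frames", call. = FALSE)
  if (!(sum(w) > 0)) stop("weights sum to zero", call. = FALSE)
  wf <- w[match(frame_table$frame, frames)]
  num <- rowsum(frame_table$ppm * wf, key)
  den <- rowsum(wf, key)
  first <- frame_table[match(rownames(num), key), c("residue", "resname", "nucleus")]
  out <- data.frame(first, ppm = num[, 1] / den[, 1], row.names = NULL)
  out[order(out$residue, out$nucleus), ]
}

#' Compare predicted and experimental shift tables
#'
#' Key-exact match on (residue, resname, nucleus); per-nucleus RMSE (ppm)
#' and Pearson correlation over matched cells, plus a pooled RMSE.
#' Unmatched keys are reported, never silently dropped.  Zero variance in
#' either vector makes R "undefined" (NA with a reason), not an error.
#'
#' @param predicted,experimental Shift tables (residue, resname, nucleus,
#'   ppm).
#' @return An object of class \code{shift_comparison}: data.frame
#'   \code{by_nucleus} (nucleus, n, rmse, r, r_reason), \code{pooled_rmse},
#'   \code{unmatched} (list of key vectors), \code{matched} (joined table).
#' @export
compare_shifts <- function(predicted, experimental) {
  .check_shift_table(predicted)
  .check_shift_table(experimental)
  kp <- .shift_key(predicted); ke <- .shift_key(experimental)
  common <- intersect(kp, ke)
  m <- data.frame(predicted[match(common, kp), c("residue", "resname", "nucleus")],
                  ppm_pred = predicted$ppm[match(common, kp)],
                  ppm_exp = experimental$ppm[match(common, ke)],
                  row.names = NULL)
  by_nuc <- lapply(split(m, m$nucleus), function(g) {
    if (nrow(g) < 3)
      return(data.frame(nucleus = g$nucleus[1], n = nrow(g),
                        rmse = sqrt(mean((g$ppm_pred - g$ppm_exp)^2)),
                        r = NA_real_, r_reason = "fewer than 3 matched cells"))
    r_reason <- ""
    r <- if (stats::sd(g$ppm_pred) == 0 || stats::sd(g$ppm_exp) == 0) {
      r_reason <- "zero variance in one vector"
      NA_real_
    } else stats::cor(g$ppm_pred, g$ppm_exp)
    data.frame(nucleus = g$nucleus[1], n = nrow(g),
               rmse = sqrt(mean((g$ppm_pred - g$ppm_exp)^2)),
               r = r, r_reason = r_reason)
  })
  by_nuc <- do.call(rbind, by_nuc)
  rownames(by_nuc) <- NULL
  structure(list(by_nucleus = by_nuc,
                 pooled_rmse = if (nrow(m)) sqrt(mean((m$ppm_pred - m$ppm_exp)^2)) else NA_real_,
                 unmatched = list(predicted_only = setdiff(kp, ke),
                                  experimental_only = setdiff(ke, kp)),
                 matched = m),
            class = "shift_comparison")
}

#' @export
print.shift_comparison <- function(x, ...) {
  cat("Chemical-shift comparison\n")
  for (i in seq_len(nrow(x$by_nucleus))) {
    b <- x$by_nucleus[i, ]
    cat(sprintf("  %s: n = %d, RMSE = %.3f ppm, R = %s\n", b$nucleus, b$n, b$rmse,
                if (is.na(b$r)) paste0("undefined (", b$r_reason, ")")
                else sprintf("%.3f", b$r)))
  }
  nun <- lengths(x$unmatched)
  if (any(nun > 0))
    cat(sprintf("  unmatched keys: %d predicted-only, %d experimental-only\n",
                nun[1], nun[2]))
  invisible(x)
}
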