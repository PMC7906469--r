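# Sequence-level disorder indicator: prevalence of the eight
# disorder-promoting residues (G, A, S, P, R, Q, E, K), the amino acids
# found enriched in experimentally characterised disordered segments.

#' Count disorder-promoting residues in a sequence
#'
#' @param sequence Amino-acid sequence: a single string or a character
#'   vector of one-letter codes.
#' @param promoting The disorder-promoting residue set (default
#'   G, A, S, P, R, Q, E, K).
#' @return A list with \code{count}, \code{length}, \code{fraction},
#'   \code{which} (positions) and \code{promoting}.
#' @examples
#' disorder_promoting_count("MAVPPTYADLGKSARDVFTKGYGFG")$count  # 13
#' @export
disorder_promoting_count <- function(sequence,
                                     promoting = c("G", "A", "S", "P",
                                                   "R", "Q", "E", "K")) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(sequence)
  if (!all(sequence %in% LETTERS))
    stop("sequence must contain one-letter amino-acid codes", call. = FALSE)
  hit <- sequence %in% toupper(promoting)
  list(count = sum(hit), length = length(sequence),
       fraction = mean(hit), which = which(hit), promoting = promoting)
}
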