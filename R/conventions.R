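#' Unit and sign conventions
#'
#' Single source of the numeric conventions used throughout the package.
#' All modules share one axis/sign/unit table:
#' \itemize{
#'   \item lengths in Angstrom, times in ns (BD steps in ps), energies in
#'     kcal/mol, temperatures in K, charges in elementary charges.
#'   \item the membrane normal is the z axis; the positive-voltage (cis)
#'     side is +z.
#'   \item \code{kT} at 298 K is fixed at 0.5925 kcal/mol; other
#'     temperatures scale linearly.
#'   \item a net charge-transfer rate of 1 e/ns equals 160.2177 pA.
#'   \item current is reported positive when net positive charge moves from
#'     the +z (positive-voltage) side to the -z side, so that passive
#'     transport yields a positive conductance G = I/V.
#'   \item 1 mM of a species is 6.02214076e-7 particles per cubic Angstrom.
#' }
#'
#' @return A named list of the constants above.
#' @examples
#' unit_conventions()$kT298
#' @export
unit_conventions <- function() {
  list(
    kT298           = 0.5925,      # kcal/mol at 298 K (package convention)
    pA_per_e_ns     = 160.2177,    # 1 e/ns in pA
    kcal_per_e_volt = 23.0605,     # e * 1 V in kcal/mol
    number_per_A3_per_mM = 6.02214076e-7,
    cm2s_to_A2ns    = 1e7,         # 1 cm^2/s in A^2/ns
    axis            = "z",
    positive_side   = "+z"
  )
}

#' Thermal energy in kcal/mol
#'
#' @param temperature Temperature in K.
#' @return kT in kcal/mol, anchored to 0.5925 kcal/mol at 298 K.
#' @export
kT_kcal <- function(temperature = 298) {
  stopifnot(is.numeric(temperature), temperature > 0)
  0.5925 * temperature / 298
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_scalar_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
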