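#' Physical constants in the package's unit system
#'
#' Units are fixed project-wide: lengths in Angstrom, energies in kcal/mol,
#' rates in 1/s, temperatures in K and forces in pN. `kB` is the Boltzmann
#' constant in kcal/(mol K) and `h` the Planck constant in kcal s / mol, so
#' `kB * T / h` is the transition-state-theory attempt frequency in 1/s.
#'
#' @param kB Boltzmann constant, kcal mol^-1 K^-1.
#' @param h Planck constant, kcal mol^-1 s.
#' @param T Temperature, K.
#' @return An object of class `rx_constants`.
#' @examples
#' co <- constants()
#' co$kB * co$T / co$h # attempt frequency at 300 K, about 6.25e12 / s
#' @export
constants <- function(kB = 0.0019872, h = 9.5306e-14, T = 300) {
  stopifnot(kB > 0, h > 0, T > 0)
  structure(list(kB = kB, h = h, T = T), class = "rx_constants")
}

# 1 kcal/mol = 69.48 pN * Angstrom; converts thermal energy to mechanical units
KCAL_PER_MOL_IN_PN_A <- 69.48

#' @export
print.rx_constants <- function(x, ...) {
  cat(sprintf("constants: kB = %g kcal/mol/K, h = %g kcal s/mol, T = %g K\n",
              x$kB, x$h, x$T))
  invisible(x)
}
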