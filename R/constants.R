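#' Physical constants used throughout
#'
#' Boltzmann constant in kcal mol^-1 K^-1 and the Avogadro constant.
#' Energies are kcal/mol, lengths Angstrom, angles degrees everywhere in the
#' package; these values fix the unit system.
#'
#' @name usdimer-constants
#' @keywords internal
NULL

.kB <- 0.0019872041      # kcal / (mol K)
.NA_AVOGADRO <- 6.02214076e23  # 1 / mol

#' Thermodynamic state
#'
#' Bundles the temperature with the Boltzmann constant and the derived
#' inverse temperature \eqn{\beta = 1/(k_B T)} used by every Boltzmann
#' weight in the package.
#'
#' @param temperature temperature in Kelvin (default 300 K).
#' @return An object of class `thermo_state` with elements `temperature`
#'   (K), `kB` (kcal mol^-1 K^-1), `kT` (kcal/mol) and `beta` (mol/kcal).
#' @examples
#' st <- thermo_state()
#' st$beta * st$kT  # == 1
#' @export
thermo_state <- function(temperature = 300) {
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      !is.finite(temperature) || temperature <= 0)
    stop("`temperature` must be a single positive number (Kelvin)")
  kT <- .kB * temperature
  structure(
    list(temperature = temperature, kB = .kB, kT = kT, beta = 1 / kT),
    class = "thermo_state")
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("thermo_state: T = %g K, kT = %.5f kcal/mol\n",
              x$temperature, x$kT))
  invisible(x)
}

#' Standard state for binding free energies
#'
#' The standard volume per molecule corresponding to a chosen standard
#' concentration; for 1 mol/L this is approximately 1661 Angstrom^3.
#'
#' @param standard_concentration standard concentration in mol/L (default 1).
#' @return Object of class `standard_state` with `concentration` (mol/L),
#'   `volume` (A^3 per molecule) and `avogadro`.
#' @export
standard_state <- function(standard_concentration = 1) {
  if (standard_concentration <= 0) stop("standard concentration must be > 0")
  structure(
    list(concentration = standard_concentration,
         volume = standard_volume(standard_concentration),
         avogadro = .NA_AVOGADRO),
    class = "standard_state")
}

#' Standard volume per molecule
#'
#' Computes the volume per molecule (in Angstrom^3) at a given standard
#' concentration: \eqn{V_0 = 10^{27} / (N_A c^0)} with \eqn{c^0} in mol/L.
#' At 1 mol/L it rounds to 1661 A^3.
#'
#' @param standard_concentration standard concentration in mol/L.
#' @return Volume in Angstrom^3.
#' @examples
#' round(standard_volume())  # 1661
#' @export
standard_volume <- function(standard_concentration = 1) {
  if (standard_concentration <= 0) stop("standard concentration must be > 0")
  1e27 / (.NA_AVOGADRO * standard_concentration)
}
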