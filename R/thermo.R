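# Standard dimerization thermodynamics from a 1D free-energy profile:
# K = (V_box/V0) * P_b/(1 - P_b) with P_b the Boltzmann fraction of the
# profile below the dimeric boundary R, then dG0 = -kT ln K and the
# two-state mass balance 2M <=> D for concentration-dependent fractions.

#' Dimerization constant from a 1D profile
#'
#' Integrates the Boltzmann factor of the (plateau-zeroed) profile over the
#' dimeric state \eqn{\xi < R} to get the bound probability \eqn{P_b}, then
#' forms the unitless dimerization constant
#' \eqn{K = (V_{box}/V_0)\, P_b/(1-P_b)}.  The profile's zero convention is
#' re-applied internally, so a constant shift of the input leaves K
#' unchanged.
#'
#' @param profile an [fe_profile()] covering \[min xi, beyond R\].
#' @param state a [thermo_state()].
#' @param R upper distance boundary of the dimeric state (A), default 11.
#' @param box_volume simulation-box volume (A^3) the profile was sampled in.
#' @param V0 standard volume per molecule (A^3), default [standard_volume()].
#' @return List of class `dimerization_result`: `K`, `delta_g` (kcal/mol),
#'   `P_b`, `R`, `box_volume`, `V0`, `temperature`, and the convention tag.
#' @export
dimerization_constant <- function(profile, state = thermo_state(), R = 11,
                                  box_volume = 62.5^3,
                                  V0 = standard_volume()) {
  xi <- profile$xi
  G <- profile$G
  if (R <= min(xi) || R >= max(xi))
    stop("`R` must lie strictly inside the profile range [",
         min(xi), ", ", max(xi), "]")
  pf <- attr(profile, "plateau_from")
  if (is.null(pf)) pf <- 20
  G <- .plateau_zero(xi, G, pf)
  w <- exp(-state$beta * G)
  total <- .trapz(xi, w)
  sel <- xi <= R
  # split the boundary bin exactly at R
  xb <- c(xi[sel], R)
  wb <- c(w[sel], approx(xi, w, R)$y)
  bound <- .trapz(xb, wb)
  P_b <- bound / total
  if (P_b >= 1 - 1e-12)
    stop("bound state saturates the profile (P_b ~ 1); K is undefined")
  K <- (box_volume / V0) * P_b / (1 - P_b)
  structure(list(K = K, delta_g = standard_free_energy(K, state),
                 P_b = P_b, R = R, box_volume = box_volume, V0 = V0,
                 temperature = state$temperature,
                 convention = "K = (V_box/V0) * P_b/(1-P_b), plateau-zero, no symmetry factor"),
            class = "dimerization_result")
}

#' @export
print.dimerization_result <- function(x, ...) {
  cat(sprintf("Dimerization: K = %.4g, dG0 = %.3f kcal/mol (R = %g A, T = %g K)\n",
              x$K, x$delta_g, x$R, x$temperature))
  cat(sprintf("  P_b = %.4g, V_box = %.4g A^3, V0 = %.4g A^3\n",
              x$P_b, x$box_volume, x$V0))
  invisible(x)
}

#' Standard free energy from the dimerization constant
#'
#' \eqn{\Delta G^0 = -k_BT \ln K}.
#'
#' @param K unitless dimerization constant (> 0).
#' @param state a [thermo_state()].
#' @return Free energy in kcal/mol.
#' @export
standard_free_energy <- function(K, state = thermo_state()) {
  if (!is.numeric(K) || any(K <= 0)) stop("`K` must be positive")
  -state$kT * log(K)
}

.K_from_dg <- function(delta_g, state) exp(-state$beta * delta_g)

#' Fraction of molecules in dimeric form
#'
#' Solves the two-state mass balance 2M <=> D at total monomer-equivalent
#' concentration c: with the molar constant K (1 M standard state),
#' \eqn{[M] = (-1 + \sqrt{1 + 8Kc})/(4K)} and the dimeric fraction is
#' \eqn{2[D]/c}.  Assumes no higher-order aggregation.
#'
#' @param delta_g standard dimerization free energy (kcal/mol).
#' @param total_concentration total concentration in mol/L (vectorized).
#' @param state a [thermo_state()].
#' @return Fraction(s) in (0, 1).
#' @export
dimer_fraction <- function(delta_g, total_concentration,
                           state = thermo_state()) {
  if (any(total_concentration <= 0)) stop("concentration must be positive")
  K <- .K_from_dg(delta_g, state)
  c0 <- total_concentration
  M <- (-1 + sqrt(1 + 8 * K * c0)) / (4 * K)
  (c0 - M) / c0
}

#' Onset concentration for a target dimeric fraction
#'
#' Closed form of the inverted mass balance:
#' \eqn{c = f / (2 (1-f)^2 K)} (mol/L).
#'
#' @param delta_g standard dimerization free energy (kcal/mol).
#' @param target_fraction target fraction of molecules in dimeric form,
#'   in (0, 1); default 0.10, the conventional onset of dimerization.
#' @param state a [thermo_state()].
#' @return Concentration in mol/L.
#' @export
onset_concentration <- function(delta_g, target_fraction = 0.10,
                                state = thermo_state()) {
  f <- target_fraction
  if (any(f <= 0 | f >= 1)) stop("`target_fraction` must be in (0, 1)")
  K <- .K_from_dg(delta_g, state)
  f / (2 * (1 - f)^2 * K)
}
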