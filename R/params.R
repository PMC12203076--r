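#' Model parameters for the anammox isotope mass-balance model
#'
#' Collects every rate and isotope effect of the three-branch anammox model:
#' the zero-order nitrogen fluxes of ammonium oxidation to N2 (`F_AMO`),
#' nitrite reduction to N2 (`F_NIR`) and nitrite oxidation to nitrate
#' (`F_NXR`); the nitrogen kinetic isotope effects `e15_AMO`, `e15_NIR`,
#' `e15_NXR` (per mil; `e15_NXR` is inverse, i.e. negative); the oxygen
#' kinetic isotope effects `e18_NIR`, `e18_NXR` and `e18_H2O` (the latter for
#' the one water-derived O atom incorporated during nitrite oxidation); the
#' first-order nitrite-water oxygen exchange rate constants `k_eq_abio` and
#' `k_eq_AMX` (per hour), sharing the equilibrium isotope effect `e18_eq`;
#' the (fixed, infinite-pool) medium water `d18_H2O`; and the optional
#' backward-flux ratio `phi` of nitrate reduction to nitrite oxidation.
#'
#' Defaults are the batch-culture study conditions for the marine anammox
#' bacterium *Ca.* Scalindua sp.: abiotic exchange `k_eq_abio` = 1.13e-2
#' per hour with `e18_eq` = 11.9 per mil, pooled-mean nitrogen effects and
#' the unlabeled-water oxygen effect estimates (see
#' [reference_isotope_effects()]), and fluxes consistent with the measured
#' consumption stoichiometry and a 5-7 h nitrite exhaustion time.
#'
#' @param F_AMO,F_NIR,F_NXR Zero-order N fluxes, mmol-N L^-1 h^-1.
#' @param e15_AMO,e15_NIR,e15_NXR Nitrogen isotope effects, per mil.
#' @param e18_NIR,e18_NXR,e18_H2O Oxygen isotope effects, per mil.
#' @param k_eq_abio,k_eq_AMX Exchange rate constants, h^-1.
#' @param e18_eq Equilibrium isotope effect of nitrite-water exchange, per mil.
#' @param d18_H2O Medium water d18O, per mil vs VSMOW.
#' @param phi Backward flux / nitrite-oxidation flux ratio in [0, 1).
#' @return An object of class `amx_params` (a named list).
#' @examples
#' p <- model_params(d18_H2O = 110.1)
#' p$k_eq_AMX
#' @export
model_params <- function(F_AMO = 0.24,
                         F_NIR = (1.38 - 0.33) * F_AMO,
                         F_NXR = 0.33 * F_AMO,
                         e15_AMO = 30.9, e15_NIR = 9.7, e15_NXR = -17.3,
                         e18_NIR = 10.6, e18_NXR = -2.9, e18_H2O = 19.2,
                         k_eq_abio = 1.13e-2, k_eq_AMX = 13.56e-2,
                         e18_eq = 11.9, d18_H2O = -12.6, phi = 0) {
  p <- list(F_AMO = F_AMO, F_NIR = F_NIR, F_NXR = F_NXR,
            e15_AMO = e15_AMO, e15_NIR = e15_NIR, e15_NXR = e15_NXR,
            e18_NIR = e18_NIR, e18_NXR = e18_NXR, e18_H2O = e18_H2O,
            k_eq_abio = k_eq_abio, k_eq_AMX = k_eq_AMX,
            e18_eq = e18_eq, d18_H2O = d18_H2O, phi = phi)
  for (nm in names(p)) .check_finite(p[[nm]], nm)
  if (any(c(F_AMO, F_NIR, F_NXR) < 0)) stop("fluxes must be >= 0", call. = FALSE)
  if (k_eq_abio < 0 || k_eq_AMX < 0) stop("exchange rate constants must be >= 0", call. = FALSE)
  if (phi < 0 || phi >= 1) stop("phi must lie in [0, 1)", call. = FALSE)
  structure(p, class = "amx_params")
}

#' @export
print.amx_params <- function(x, ...) {
  cat("anammox model parameters\n")
  cat(sprintf("  fluxes (mmol-N/L/h): F_AMO = %.4g, F_NIR = %.4g, F_NXR = %.4g\n",
              x$F_AMO, x$F_NIR, x$F_NXR))
  cat(sprintf("  15e (permil): AMO = %.3g, NIR = %.3g, NXR = %.3g\n",
              x$e15_AMO, x$e15_NIR, x$e15_NXR))
  cat(sprintf("  18e (permil): NIR = %.3g, NXR = %.3g, H2O = %.3g\n",
              x$e18_NIR, x$e18_NXR, x$e18_H2O))
  cat(sprintf("  exchange: k_abio = %.4g /h, k_AMX = %.4g /h, e18_eq = %.3g permil\n",
              x$k_eq_abio, x$k_eq_AMX, x$e18_eq))
  cat(sprintf("  water d18O = %.4g permil; backflux phi = %.3g\n", x$d18_H2O, x$phi))
  invisible(x)
}

#' Derive branch fluxes from consumption stoichiometry
#'
#' Batch cultures constrain the ratio of consumed nitrite to consumed
#' ammonium (measured 1.38 +/- 0.10) and of produced nitrate to consumed
#' ammonium (0.33 +/- 0.04). Given the ammonium-oxidation flux, these
#' ratios fix the two nitrite-consuming fluxes:
#' `F_NXR = dNO3_dNH4 * F_AMO` and `F_NIR = (dNO2_dNH4 - dNO3_dNH4) * F_AMO`.
#'
#' @param F_AMO Ammonium oxidation flux, mmol-N L^-1 h^-1.
#' @param dNO2_dNH4 Consumed-NO2-/consumed-NH4+ ratio (default 1.38).
#' @param dNO3_dNH4 Produced-NO3-/consumed-NH4+ ratio (default 0.33).
#' @return Named list with `F_NIR` and `F_NXR`.
#' @examples
#' fluxes_from_stoichiometry(0.4)
#' @export
fluxes_from_stoichiometry <- function(F_AMO, dNO2_dNH4 = 1.38, dNO3_dNH4 = 0.33) {
  .check_finite(c(F_AMO, dNO2_dNH4, dNO3_dNH4), "stoichiometric inputs")
  if (!(dNO2_dNH4 > dNO3_dNH4 && dNO3_dNH4 >= 0))
    stop("need dNO2_dNH4 > dNO3_dNH4 >= 0", call. = FALSE)
  list(F_NIR = (dNO2_dNH4 - dNO3_dNH4) * F_AMO,
       F_NXR = dNO3_dNH4 * F_AMO)
}

#' Reference isotope-effect estimates for Ca. Scalindua sp. batch cultures
#'
#' Posterior mean +/- SD estimates of the anammox nitrogen and oxygen
#' isotope effects and the anammox-mediated nitrite-water oxygen exchange
#' rate constant, per medium-water d18O level and pooled, as obtained from
#' triplicate batch cultures of the marine anammox bacterium
#' *Ca.* Scalindua sp. These serve as the package's generating truth for
#' synthetic experiments and as reference values for recovery exercises.
#'
#' @return A list with components `nitrogen` (data frame: `d18_H2O`,
#'   `e15_AMO`, `e15_NIR`, `e15_NXR` and their SDs; last row is the pooled
#'   average) and `oxygen` (data frame: `d18_H2O`, `e18_NIR`, `e18_NXR`,
#'   `e18_H2O`, `k_eq_AMX` in 1e-2 h^-1, and their SDs).
#' @examples
#' reference_isotope_effects()$oxygen
#' @export
reference_isotope_effects <- function() {
  nitrogen <- data.frame(
    d18_H2O = c(-12.6, 25.9, 56.7, 110.1, NA),
    label   = c("-12.6", "25.9", "56.7", "110.1", "average"),
    e15_AMO    = c(30.2, 33.7, 28.9, 30.9, 30.9),
    e15_AMO_sd = c(3.1, 3.0, 1.8, 3.0, 3.3),
    e15_NIR    = c(11.7, 10.2, 8.4, 8.5, 9.7),
    e15_NIR_sd = c(0.6, 1.1, 1.3, 0.7, 1.7),
    e15_NXR    = c(-16.9, -17.0, -17.6, -17.9, -17.3),
    e15_NXR_sd = c(1.0, 1.0, 1.4, 1.0, 1.2))
  oxygen <- data.frame(
    d18_H2O = c(-12.6, 25.9, 56.7, 110.1),
    e18_NIR    = c(10.6, 12.1, 13.8, 16.1),
    e18_NIR_sd = c(2.5, 2.5, 2.6, 3.2),
    e18_NXR    = c(-2.9, -6.3, -9.8, -11.0),
    e18_NXR_sd = c(1.9, 2.5, 2.5, 2.1),
    e18_H2O    = c(19.2, 17.7, 17.3, 16.4),
    e18_H2O_sd = c(3.8, 4.3, 4.2, 4.0),
    k_eq_AMX    = c(13.56, 8.44, 11.28, 12.44),
    k_eq_AMX_sd = c(5.38, 4.63, 2.54, 3.13))
  list(nitrogen = nitrogen, oxygen = oxygen)
}
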