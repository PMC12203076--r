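# Closed-form nitrite-water oxygen-isotope equilibration kinetics and the
# labelled-water regression calculus (final d18O vs medium-water d18O).

#' Oxygen-isotope equilibrium between nitrite and water
#'
#' The d18O of NO2- at isotopic equilibrium with ambient water, using the
#' exact multiplicative alpha convention:
#' d_eq = ((1 + d18_H2O/1000) * (1 + e18_eq/1000) - 1) * 1000.
#'
#' @param d18_H2O Water d18O, per mil vs VSMOW.
#' @param e18_eq Equilibrium isotope effect, per mil (default 11.9).
#' @return Equilibrium NO2- d18O, per mil.
#' @examples
#' equilibrium_delta(110.1)  # labelled-water batch
#' @export
equilibrium_delta <- function(d18_H2O, e18_eq = 11.9) {
  .check_finite(c(d18_H2O, e18_eq), "equilibrium inputs")
  ((1 + d18_H2O / 1000) * (1 + e18_eq / 1000) - 1) * 1000
}

#' First-order relaxation of nitrite d18O towards equilibrium
#'
#' With water an infinite pool, the NO2- bulk 18O atom fraction relaxes
#' exponentially towards the equilibrium fraction at rate `k`; delta values
#' are converted at the boundary. Abiotically (k = 1.13e-2 per hour at pH
#' 7.5, 30 C) equilibration takes hundreds of hours; anammox-mediated
#' exchange is an order of magnitude faster.
#'
#' @param d0 Initial NO2- d18O, per mil.
#' @param t Time, hours (vectorised).
#' @param k First-order exchange rate constant, h^-1.
#' @inheritParams equilibrium_delta
#' @return NO2- d18O at time `t`, per mil.
#' @examples
#' relax(0, c(0, 61.34, 650), k = 1.13e-2, d18_H2O = 110.1)
#' @export
relax <- function(d0, t, k, d18_H2O, e18_eq = 11.9) {
  .check_finite(c(d0, t, k, d18_H2O, e18_eq), "relaxation inputs")
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  y0 <- delta_to_fraction(d0, R18_VSMOW)
  y_eq <- ratio_to_fraction(alpha_of(e18_eq) * delta_to_ratio(d18_H2O, R18_VSMOW))
  y <- y_eq + (y0 - y_eq) * exp(-k * t)
  fraction_to_delta(y, R18_VSMOW)
}

#' Fraction of nitrite O atoms exchanged, from the labelled-water slope
#'
#' In labelled-water experiments the final d18O of the nitrate produced by
#' nitrite oxidation is regressed against the medium-water d18O. Of
#' nitrate's three O atoms, one always comes from water and two from NO2-;
#' if a fraction f of nitrite O has equilibrated with water before
#' oxidation, the regression slope is s = (1 + 2f)/3. Inverting,
#' f = (3s - 1)/2: s = 1/3 means no exchange (33% water-derived O), s = 1
#' full exchange (100%).
#'
#' @param s Regression slope of final d18O against water d18O.
#' @return Fraction of NO2- oxygen exchanged with water, in [0, 1] for
#'   slopes in [1/3, 1]; values outside that range are returned with a
#'   warning (extrapolation).
#' @examples
#' fraction_exchanged_from_slope(0.563)  # ~0.34
#' @export
fraction_exchanged_from_slope <- function(s) {
  .check_finite(s, "slope")
  f <- (3 * s - 1) / 2
  if (any(s < 1 / 3 - 1e-12 | s > 1 + 1e-12))
    warning("slope outside [1/3, 1]; exchange fraction is an extrapolation")
  f
}

#' Regression of final delta values on medium-water d18O
#'
#' Ordinary least squares of per-batch final d18O values (of NO3- or NO2-)
#' against the medium d18O_H2O levels; the slope feeds
#' [fraction_exchanged_from_slope()].
#'
#' @param d18_H2O Water d18O of each batch, per mil; at least 3 distinct
#'   levels required.
#' @param final_delta Final d18O values, per mil (same length).
#' @return List with `slope`, `intercept`, `r_squared`, `slope_se` and the
#'   fitted `lm` object.
#' @export
final_delta_regression <- function(d18_H2O, final_delta) {
  .check_finite(c(d18_H2O, final_delta), "regression inputs")
  if (length(d18_H2O) != length(final_delta))
    stop("inputs must have equal length", call. = FALSE)
  if (length(unique(d18_H2O)) < 3)
    stop("need at least 3 distinct d18O_H2O levels", call. = FALSE)
  fit <- stats::lm(final_delta ~ d18_H2O)
  co <- stats::coef(summary(fit))
  list(slope = unname(co["d18_H2O", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r_squared = summary(fit)$r.squared,
       slope_se = unname(co["d18_H2O", "Std. Error"]),
       fit = fit)
}
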