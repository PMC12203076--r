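#' Reference isotope ratios
#'
#' Absolute heavy/light abundance ratios of the international reference
#' scales used throughout the package: atmospheric N2 (AIR) for 15N/14N and
#' Vienna Standard Mean Ocean Water (VSMOW) for 18O/16O. Natural-abundance
#' delta values are insensitive to the exact constants; they are needed only
#' to make atom-fraction pool bookkeeping exact.
#'
#' @format Named numeric scalars.
#' @name reference-ratios
NULL

#' @rdname reference-ratios
#' @export
R15_AIR <- 0.0036765

#' @rdname reference-ratios
#' @export
R18_VSMOW <- 0.0020052

.check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(what, " must be finite numeric", call. = FALSE)
  invisible(x)
}

#' Convert between delta values, isotope ratios and atom fractions
#'
#' `delta_to_ratio()` applies the definition of the delta notation,
#' r = ref * (1 + d/1000); `ratio_to_delta()` is its inverse.
#' `ratio_to_fraction()` maps a heavy/light abundance ratio r to the
#' heavy-isotope atom fraction x = r/(1+r); `fraction_to_ratio()` inverts it.
#' `delta_to_fraction()` and `fraction_to_delta()` compose the two.
#'
#' All conversions are exact (no delta-linear approximation) and mutually
#' inverse to machine precision, which is what makes mixing and mass-balance
#' bookkeeping in atom-fraction space conservative.
#'
#' @param d Delta value in per mil; must exceed -1000.
#' @param r Heavy/light abundance ratio, > 0.
#' @param x Heavy-isotope atom fraction, in (0, 1).
#' @param ref Reference ratio of the scale (e.g. [R15_AIR], [R18_VSMOW]).
#' @return A numeric vector of the converted quantity.
#' @examples
#' delta_to_ratio(11.9, R18_VSMOW)
#' fraction_to_delta(delta_to_fraction(25, R15_AIR), R15_AIR)
#' @export
delta_to_ratio <- function(d, ref) {
  .check_finite(d, "delta value")
  .check_finite(ref, "reference ratio")
  if (any(d <= -1000)) stop("delta value must exceed -1000 per mil", call. = FALSE)
  if (any(ref <= 0)) stop("reference ratio must be positive", call. = FALSE)
  ref * (1 + d / 1000)
}

#' @rdname delta_to_ratio
#' @export
ratio_to_delta <- function(r, ref) {
  .check_finite(r, "isotope ratio")
  if (any(r <= 0)) stop("isotope ratio must be positive", call. = FALSE)
  (r / ref - 1) * 1000
}

#' @rdname delta_to_ratio
#' @export
ratio_to_fraction <- function(r) {
  .check_finite(r, "isotope ratio")
  if (any(r <= 0)) stop("isotope ratio must be positive", call. = FALSE)
  r / (1 + r)
}

#' @rdname delta_to_ratio
#' @export
fraction_to_ratio <- function(x) {
  .check_finite(x, "atom fraction")
  if (any(x <= 0 | x >= 1)) stop("atom fraction must lie in (0, 1)", call. = FALSE)
  x / (1 - x)
}

#' @rdname delta_to_ratio
#' @export
delta_to_fraction <- function(d, ref) {
  ratio_to_fraction(delta_to_ratio(d, ref))
}

#' @rdname delta_to_ratio
#' @export
fraction_to_delta <- function(x, ref) {
  ratio_to_delta(fraction_to_ratio(x), ref)
}

#' Kinetic fractionation-factor algebra
#'
#' A kinetic isotope effect epsilon (per mil) is defined from the rate
#' constants of the light and heavy isotopologues as
#' epsilon = (k_L/k_H - 1) * 1000, with fractionation factor
#' alpha = 1 + epsilon/1000. `apply_kinetic_effect()` returns the
#' instantaneous-product isotope ratio, substrate ratio / alpha: a normal
#' effect (epsilon > 0) yields an isotopically lighter product, an inverse
#' effect (epsilon < 0, as in nitrite oxidation by anammox bacteria) a
#' heavier one.
#'
#' @param r Substrate isotope ratio (> 0).
#' @param epsilon Kinetic isotope effect in per mil.
#' @return Instantaneous product isotope ratio.
#' @examples
#' # a 30 per mil normal effect on a substrate at 0 per mil
#' ratio_to_delta(apply_kinetic_effect(delta_to_ratio(0, R15_AIR), 30), R15_AIR)
#' @export
apply_kinetic_effect <- function(r, epsilon) {
  .check_finite(r, "substrate ratio")
  .check_finite(epsilon, "epsilon")
  if (any(r <= 0)) stop("substrate ratio must be positive", call. = FALSE)
  a <- alpha_of(epsilon)
  r / a
}

#' @rdname apply_kinetic_effect
#' @export
alpha_of <- function(epsilon) {
  .check_finite(epsilon, "epsilon")
  a <- 1 + epsilon / 1000
  if (any(a <= 0)) stop("epsilon implies non-positive alpha", call. = FALSE)
  a
}

#' @rdname apply_kinetic_effect
#' @param alpha Fractionation factor (> 0).
#' @export
epsilon_of <- function(alpha) {
  .check_finite(alpha, "alpha")
  if (any(alpha <= 0)) stop("alpha must be positive", call. = FALSE)
  (alpha - 1) * 1000
}
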