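# Derived calculations and simulation exercises: produced-nitrate d15N,
# two-pool mixing, the combined oxygen effect of nitrite oxidation, the
# dual-isotope (Dd18O : Dd15N) nitrate trajectory under full nitrite-water
# equilibrium, and the backward-flux falsification run.

#' d15N of newly produced nitrate
#'
#' Mass-balance difference formula for the accumulating product pool:
#' (Ct * dt - C0 * d0) / (Ct - C0). Undefined at t = 0 by construction
#' (it is computed from the difference from the initial value).
#'
#' @param C0,d0 Initial concentration and d15N of the pool.
#' @param Ct,dt Concentration and d15N at time t; requires Ct > C0.
#' @return d15N of the newly produced fraction, per mil.
#' @examples
#' delta15N_produced(1, 100, 2, 60)  # 20
#' @export
delta15N_produced <- function(C0, d0, Ct, dt) {
  .check_finite(c(C0, d0, Ct, dt), "inputs")
  if (any(C0 < 0)) stop("C0 must be >= 0", call. = FALSE)
  if (any(Ct <= C0)) stop("requires Ct > C0", call. = FALSE)
  (Ct * dt - C0 * d0) / (Ct - C0)
}

#' Mix two pools by amount-weighted isotope mass balance
#'
#' Exact mixing in atom-fraction space (amount-weighted heavy-isotope
#' balance), e.g. spiking a seawater nitrate background with an isotope
#' standard.
#'
#' @param c1,c2 Concentrations (any shared unit, e.g. mM).
#' @param v1,v2 Volumes (any shared unit, e.g. ml).
#' @param d1,d2 Delta values, per mil.
#' @param ref Reference ratio of the isotope system (default [R15_AIR]).
#' @return List with mixed `conc` and `delta`.
#' @examples
#' mix_pools(0.02, 800, 20, 5, 8, 180)  # ~0.069 mM, ~134 per mil
#' @export
mix_pools <- function(c1, v1, d1, c2, v2, d2, ref = R15_AIR) {
  .check_finite(c(c1, v1, d1, c2, v2, d2), "inputs")
  if (any(c(c1, v1, c2, v2) < 0)) stop("concentrations and volumes must be >= 0", call. = FALSE)
  m1 <- c1 * v1; m2 <- c2 * v2
  if (m1 + m2 <= 0) stop("total amount is zero", call. = FALSE)
  if (m1 == 0) return(list(conc = c2 * v2 / (v1 + v2), delta = d2))
  if (m2 == 0) return(list(conc = c1 * v1 / (v1 + v2), delta = d1))
  x <- (m1 * delta_to_fraction(d1, ref) + m2 * delta_to_fraction(d2, ref)) / (m1 + m2)
  list(conc = (m1 + m2) / (v1 + v2), delta = fraction_to_delta(x, ref))
}

#' Combined oxygen isotope effect of nitrite oxidation
#'
#' Of nitrate's three O atoms, two are inherited from NO2- (subject to
#' e18_NXR) and one is incorporated from water (subject to e18_H2O), so the
#' combined effect is 2/3 * e18_NXR + 1/3 * e18_H2O.
#'
#' @param e18_NXR Nitrite-oxidation oxygen effect, per mil.
#' @param e18_H2O Water-incorporation oxygen effect, per mil.
#' @return Combined effect, per mil.
#' @examples
#' combined_o_effect(-2.9, 19.2)
#' @export
combined_o_effect <- function(e18_NXR, e18_H2O) {
  .check_finite(c(e18_NXR, e18_H2O), "inputs")
  2 / 3 * e18_NXR + 1 / 3 * e18_H2O
}

#' Pooled reference parameter set
#'
#' [model_params()] populated with the pooled-mean nitrogen effects and the
#' across-level means of the oxygen effects from
#' [reference_isotope_effects()], used for scenario exercises.
#'
#' @param ... Overrides passed on to [model_params()].
#' @return An `amx_params` object.
#' @export
pooled_reference_params <- function(...) {
  ref <- reference_isotope_effects()
  n <- ref$nitrogen[ref$nitrogen$label == "average", ]
  o <- ref$oxygen
  args <- list(e15_AMO = n$e15_AMO, e15_NIR = n$e15_NIR, e15_NXR = n$e15_NXR,
               e18_NIR = mean(o$e18_NIR), e18_NXR = mean(o$e18_NXR),
               e18_H2O = mean(o$e18_H2O), k_eq_AMX = mean(o$k_eq_AMX) / 100)
  args[names(list(...))] <- list(...)
  do.call(model_params, args)
}

# instantaneous-product composition of nitrate at the start of a run
.initial_product_deltas <- function(p, d15_B0, d18_NO2) {
  r15 <- apply_kinetic_effect(delta_to_ratio(d15_B0, R15_AIR), p$e15_NXR)
  y2 <- ratio_to_fraction(apply_kinetic_effect(delta_to_ratio(d18_NO2, R18_VSMOW), p$e18_NXR))
  y1 <- ratio_to_fraction(apply_kinetic_effect(delta_to_ratio(p$d18_H2O, R18_VSMOW), p$e18_H2O))
  list(d15 = ratio_to_delta(r15, R15_AIR),
       d18 = fraction_to_delta((2 * y2 + y1) / 3, R18_VSMOW))
}

#' Dual-isotope nitrate trajectory exercise
#'
#' Simulates the Dd18O_NO3 : Dd15N_NO3 trajectory of the nitrate produced
#' during anammox for a grid of medium-water d18O values, assuming complete
#' oxygen-isotope equilibrium between NO2- and water (NO2- d18O pinned at
#' [equilibrium_delta()]). Delta differences are measured from the initial
#' nitrate composition, which defaults to the instantaneous-product
#' composition at t = 0 (a tiny seed pool), so the trajectory reflects the
#' evolving produced nitrate rather than an arbitrary background. The ratio
#' is evaluated only where |Dd15N| exceeds `floor` (per mil) to avoid the
#' ill-defined onset.
#'
#' @param p Parameter set (default [pooled_reference_params()]).
#' @param d18_grid Medium-water d18O grid, per mil.
#' @param times Output times, hours.
#' @param floor Dd15N magnitude floor, per mil.
#' @param pin_equilibrium Pin NO2- d18O at equilibrium with water (the
#'   exercise's stated assumption); set `FALSE` to let it evolve freely.
#' @param init Optional initial [batch_state()] overriding the default.
#' @return List with `curves` (data frame: d18_H2O, time_h, dd15N, dd18O,
#'   ratio) and `max_ratio` (the global maximum of the ratio).
#' @examples
#' ex <- trajectory_exercise(times = seq(0, 5.8, length.out = 15))
#' ex$max_ratio
#' @export
trajectory_exercise <- function(p = pooled_reference_params(),
                                d18_grid = seq(-7.7, 1.8, length.out = 5),
                                times = seq(0, 5.8, length.out = 40),
                                floor = 1, pin_equilibrium = TRUE,
                                init = NULL) {
  curves <- list()
  for (w in d18_grid) {
    pw <- p
    pw$d18_H2O <- w
    pin <- if (pin_equilibrium) equilibrium_delta(w, p$e18_eq) else NULL
    if (is.null(init)) {
      prod0 <- .initial_product_deltas(pw, 0, if (is.null(pin)) 0 else pin)
      init_w <- batch_state(A = 2.5, B = 2.0, C = 1e-3,
                            d15_B = 0, d15_C = prod0$d15,
                            d18_B = if (is.null(pin)) 0 else pin,
                            d18_C = prod0$d18)
    } else init_w <- init
    tr <- simulate_batch(pw, init_w, times, pin_d18_NO2 = pin)
    dd15 <- tr$d15N_NO3 - tr$d15N_NO3[1]
    dd18 <- tr$d18O_NO3 - tr$d18O_NO3[1]
    ratio <- ifelse(abs(dd15) >= floor, dd18 / dd15, NA_real_)
    curves[[as.character(w)]] <- data.frame(d18_H2O = w, time_h = tr$time_h,
                                            dd15N = dd15, dd18O = dd18,
                                            ratio = ratio)
  }
  curves <- do.call(rbind, curves)
  rownames(curves) <- NULL
  if (all(is.na(curves$ratio)))
    stop("Dd15N never exceeds the floor; ratio undefined everywhere", call. = FALSE)
  list(curves = curves, max_ratio = max(curves$ratio, na.rm = TRUE))
}

#' Backward-flux falsification exercise
#'
#' Asks whether a backward flux of nitrite oxidation (nitrate reduction
#' returning N and O to the NO2- pool) can, by itself, drive NO2- d18O to
#' oxygen-isotope equilibrium with water within a batch run when
#' anammox-mediated exchange is off (k_eq_AMX = 0). For each backward-flux
#' ratio phi the model is run on the labelled-water design to just before
#' nitrite exhaustion and the remaining offset of d18O_NO2 from the
#' equilibrium value is reported.
#'
#' @param phi Grid of backward-flux ratios in [0, 1).
#' @param p Parameter set; defaults to [pooled_reference_params()] with
#'   k_eq_AMX = 0 and the most strongly labelled water (110.1 per mil).
#' @param init Initial state (default study conditions).
#' @return Data frame with `phi`, `final_d18O_NO2`, `d18O_eq` and `offset`
#'   (equilibrium minus final, per mil).
#' @export
backflux_exercise <- function(phi = c(0, 0.25, 0.5, 0.75),
                              p = pooled_reference_params(k_eq_AMX = 0,
                                                          d18_H2O = 110.1),
                              init = batch_state(A = 2.5, B = 2.0, C = 1e-3,
                                                 d15_C = 20, d18_C = 15)) {
  if (any(phi < 0 | phi >= 1)) stop("phi must lie in [0, 1)", call. = FALSE)
  d_eq <- equilibrium_delta(p$d18_H2O, p$e18_eq)
  out <- lapply(phi, function(ph) {
    pp <- p
    pp$phi <- ph
    t_ex <- unname(init["B"]) / (pp$F_NIR + pp$F_NXR - ph * pp$F_NXR)
    tr <- simulate_batch(pp, init, seq(0, 0.995 * t_ex, length.out = 30))
    fin <- tr$d18O_NO2[nrow(tr)]
    data.frame(phi = ph, final_d18O_NO2 = fin, d18O_eq = d_eq,
               offset = d_eq - fin)
  })
  do.call(rbind, out)
}
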