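# Synthetic batch-culture generator: forward simulations with the study's
# experimental design (initial substrate loads, labelled-water levels,
# triplicates, 5-7 h nitrite exhaustion) and i.i.d. Gaussian analytical
# noise at the stated per-variable precisions.

#' Experimental design of a labelled-water batch-culture study
#'
#' Defaults emulate the batch experiments: 2.5 mmol L^-1 (NH4)2SO4-derived
#' NH4+ and 2.0 mmol-N L^-1 NO2- at start, a small seawater NO3- background,
#' four medium-water d18O levels, triplicates, and ~10 samples over the run
#' up to just before nitrite exhaustion. Initial d15N of NH4+ and NO2- and
#' d18O of NO2- default to 0 per mil (reagent-like); absolute starting
#' deltas shift the curves but not the isotope-effect inference.
#'
#' @param d18_H2O Medium-water d18O levels, per mil (default the four study
#'   levels -12.6, 25.9, 56.7, 110.1).
#' @param replicates Batches per level (default 3).
#' @param A0,B0,C0 Initial NH4+, NO2-, NO3- concentrations, mmol-N L^-1.
#' @param d15_A0,d15_B0,d15_C0,d18_B0,d18_C0 Initial delta values, per mil.
#' @param times Sampling schedule, hours.
#' @param lag_points Number of leading sampling intervals with reduced
#'   activity (to exercise lag trimming); 0 for none.
#' @param lag_factor Flux multiplier during the lag segment.
#' @param seed Random seed for noise generation.
#' @return An `amx_design` list.
#' @export
experiment_design <- function(d18_H2O = c(-12.6, 25.9, 56.7, 110.1),
                              replicates = 3,
                              A0 = 2.5, B0 = 2.0, C0 = 0.02,
                              d15_A0 = 0, d15_B0 = 0, d15_C0 = 20,
                              d18_B0 = 0, d18_C0 = 15,
                              times = seq(0, 5.8, length.out = 10),
                              lag_points = 0, lag_factor = 0.2,
                              seed = 1L) {
  if (length(times) < 2) stop("need at least 2 sampling times", call. = FALSE)
  if (anyDuplicated(d18_H2O)) stop("d18_H2O levels must be distinct", call. = FALSE)
  structure(list(d18_H2O = d18_H2O, replicates = replicates,
                 A0 = A0, B0 = B0, C0 = C0,
                 d15_A0 = d15_A0, d15_B0 = d15_B0, d15_C0 = d15_C0,
                 d18_B0 = d18_B0, d18_C0 = d18_C0,
                 times = times, lag_points = lag_points,
                 lag_factor = lag_factor, seed = as.integer(seed)),
            class = "amx_design")
}

#' Analytical noise model
#'
#' One-sigma analytical precisions of the isotope measurements (per mil) and
#' a relative SD for the colorimetric/chromatographic concentration assays.
#'
#' @param d15N_NH4,d15N_NO2,d15N_NO3,d18O_NO2,d18O_NO3 Isotope SDs, per mil.
#' @param d18O_H2O Water d18O SD, per mil.
#' @param conc_rel Relative SD of concentration measurements.
#' @return An `amx_noise` list.
#' @export
noise_model <- function(d15N_NH4 = 0.3, d15N_NO2 = 0.2, d15N_NO3 = 0.2,
                        d18O_NO2 = 0.3, d18O_NO3 = 0.5, d18O_H2O = 0.20,
                        conc_rel = 0.02) {
  n <- list(d15N_NH4 = d15N_NH4, d15N_NO2 = d15N_NO2, d15N_NO3 = d15N_NO3,
            d18O_NO2 = d18O_NO2, d18O_NO3 = d18O_NO3, d18O_H2O = d18O_H2O,
            conc_rel = conc_rel)
  if (any(unlist(n) < 0)) stop("noise SDs must be >= 0", call. = FALSE)
  structure(n, class = "amx_noise")
}

.ISO_VARS <- c("d15N_NH4", "d15N_NO2", "d15N_NO3", "d18O_NO2", "d18O_NO3")
.CONC_VARS <- c("conc_NH4", "conc_NO2", "conc_NO3")
.ALL_VARS <- c(.CONC_VARS, .ISO_VARS)

# simulate with an optional reduced-activity lag over the first k sampling
# intervals; returns the clean trajectory at design times
.simulate_design <- function(p, design) {
  init <- batch_state(design$A0, design$B0, design$C0,
                      design$d15_A0, design$d15_B0, design$d15_C0,
                      design$d18_B0, design$d18_C0)
  times <- design$times
  k <- design$lag_points
  if (k > 0) {
    p_lag <- p
    for (f in c("F_AMO", "F_NIR", "F_NXR")) p_lag[[f]] <- p[[f]] * design$lag_factor
    t1 <- times[seq_len(k + 1)]
    tr1 <- simulate_batch(p_lag, init, t1)
    y_mid <- attr(tr1, "state")[length(t1), -1]
    names(y_mid) <- .STATE_NAMES
    t2 <- times[(k + 1):length(times)]
    tr2 <- simulate_batch(p, y_mid, t2)
    rbind(tr1[seq_len(k), ], tr2)
  } else {
    simulate_batch(p, init, times)
  }
}

.noisy_long <- function(traj, noise, batch, replicate, d18_H2O) {
  rows <- list()
  for (v in .ALL_VARS) {
    clean <- traj[[v]]
    if (v %in% .CONC_VARS) {
      sd_abs <- noise$conc_rel * clean
      value <- pmax(clean + stats::rnorm(length(clean), 0, 1) * sd_abs, 0)
    } else {
      sd_abs <- rep(noise[[v]], length(clean))
      value <- clean + stats::rnorm(length(clean), 0, sd_abs)
    }
    rows[[v]] <- data.frame(batch = batch, replicate = replicate,
                            time_h = traj$time_h, variable = v,
                            value = value, sd = sd_abs, d18O_H2O = d18_H2O)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic labelled-water batch-culture dataset
#'
#' Runs the forward model once per replicate and water level (same
#' generating truth, independent Gaussian measurement noise) and returns a
#' long-format dataset ready for [fit_rates()] and the staged inference.
#' The same model parameters `p` are used at every level except for the
#' medium-water d18O, which is set per level; pass `params_by_level` to use
#' level-specific oxygen parameters.
#'
#' @param p An [model_params()] object (generating truth).
#' @param design An [experiment_design()].
#' @param noise An [noise_model()]; use all-zero SDs for a clean dataset.
#' @param params_by_level Optional list of [model_params()], one per
#'   `design$d18_H2O` level, overriding `p`.
#' @return Long-format data frame (columns batch, replicate, time_h,
#'   variable, value, sd, d18O_H2O) of class `amx_dataset`.
#' @examples
#' ds <- generate_dataset(model_params(), experiment_design(d18_H2O = -12.6))
#' head(ds)
#' @export
generate_dataset <- function(p, design = experiment_design(),
                             noise = noise_model(),
                             params_by_level = NULL) {
  set.seed(design$seed)
  out <- list()
  for (i in seq_along(design$d18_H2O)) {
    w <- design$d18_H2O[i]
    pl <- if (!is.null(params_by_level)) params_by_level[[i]] else p
    pl$d18_H2O <- w
    t_exhaust <- design$B0 / (pl$F_NIR + pl$F_NXR - pl$phi * pl$F_NXR)
    if (t_exhaust <= design$times[2])
      stop("parameters exhaust NO2- before the second sample", call. = FALSE)
    traj <- .simulate_design(pl, design)
    batch <- paste0("w", w)
    for (r in seq_len(design$replicates))
      out[[paste(batch, r)]] <- .noisy_long(traj, noise, batch, r, w)
  }
  ds <- do.call(rbind, out)
  rownames(ds) <- NULL
  class(ds) <- c("amx_dataset", "data.frame")
  ds
}

#' Generate the 15N-tracer nitrite/nitrate exchange experiment
#'
#' Emulates the single-run tracer experiment probing nitrogen isotope
#' exchange between NO2- and NO3-: 15N-poor nitrite (d15N = -35.5 per mil)
#' and a small 15N-rich nitrate pool (USGS32-spiked seawater), initial
#' concentrations 2.5 / 1.88 / 0.05 mM for NH4+ / NO2- / NO3-, unlabeled
#' water. The model contains no NO2-/NO3- nitrogen exchange term, so the
#' generated series show no abrupt delta changes; the initial mixed nitrate
#' d15N defaults to the two-pool mixing calculation of [mix_pools()].
#'
#' @param p Model parameters (defaults as [model_params()] with unlabeled
#'   water).
#' @param noise An [noise_model()].
#' @param d15_C0 Initial mixed NO3- d15N; default computed by [mix_pools()]
#'   from the seawater background (0.02 mM at 20 per mil, 800 ml) and the
#'   USGS32 spike (5 mM at 180 per mil, 8 ml).
#' @param seed Random seed.
#' @param times Sampling schedule, hours.
#' @return Long-format `amx_dataset` with one replicate.
#' @export
generate_tracer_experiment <- function(p = model_params(d18_H2O = -12.6),
                                       noise = noise_model(),
                                       d15_C0 = mix_pools(0.02, 800, 20, 5, 8, 180)$delta,
                                       seed = 1L,
                                       times = seq(0, 5.2, length.out = 10)) {
  design <- experiment_design(d18_H2O = p$d18_H2O, replicates = 1,
                              A0 = 2.5, B0 = 1.88, C0 = 0.05,
                              d15_A0 = 0, d15_B0 = -35.5, d15_C0 = d15_C0,
                              d18_B0 = 0, d18_C0 = 25.7,
                              times = times, seed = seed)
  generate_dataset(p, design, noise)
}
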