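# Staged Bayesian estimation of the anammox isotope effects:
#   stage 1  fit_rates        least-squares zero-order fluxes per replicate
#   stage 2  fit_n_isotopes   MCMC over the three nitrogen isotope effects
#   stage 3  fit_o_isotopes   MCMC over the three oxygen effects + k_eq_AMX
# with uniform priors, a Gaussian likelihood at the per-variable analytical
# SDs, and pooling of the thinned post-burn-in draws across replicates.

#' Uniform priors for the isotope-effect parameters
#'
#' Nitrogen stage: 0 < e15_AMO < 60, 0 < e15_NIR < 60, -60 < e15_NXR < 0
#' (per mil). Oxygen stage: 5 < e18_NIR < 20, -15 < e18_NXR < 0,
#' 10 < e18_H2O < 25 (per mil), and k_eq_AMX uniform on (0, `k_upper`)
#' h^-1 — an uninformative but proper bound an order of magnitude above the
#' largest plausible exchange rate.
#'
#' @param k_upper Upper bound for k_eq_AMX, h^-1.
#' @return Data frame with columns `param`, `lower`, `upper`.
#' @export
priors_nitrogen <- function() {
  data.frame(param = c("e15_AMO", "e15_NIR", "e15_NXR"),
             lower = c(0, 0, -60), upper = c(60, 60, 0))
}

#' @rdname priors_nitrogen
#' @export
priors_oxygen <- function(k_upper = 0.5) {
  data.frame(param = c("e18_NIR", "e18_NXR", "e18_H2O", "k_eq_AMX"),
             lower = c(5, -15, 10, 0), upper = c(20, 0, 25, k_upper))
}

#' MCMC sampler settings
#'
#' `n_iter` counts post-burn-in iterations (the chain runs for
#' `burn_in + n_iter` steps in total); the proposal covariance is adapted
#' during burn-in only and frozen afterwards.
#'
#' @param n_iter Post-burn-in iterations (default 100000).
#' @param burn_in Burn-in iterations (default 50000).
#' @param thin Thinning interval (default 5).
#' @param seed Optional integer seed set before each replicate chain.
#' @param adapt_start,adapt_every Burn-in iteration at which covariance
#'   adaptation starts, and its cadence.
#' @return An `amx_mcmc_settings` list.
#' @export
mcmc_settings <- function(n_iter = 100000L, burn_in = 50000L, thin = 5L,
                          seed = NULL, adapt_start = 500L, adapt_every = 200L) {
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  if (burn_in < 0 || n_iter < 1) stop("invalid iteration counts", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed,
                 adapt_start = as.integer(adapt_start),
                 adapt_every = as.integer(adapt_every)),
            class = "amx_mcmc_settings")
}

#' Zero-order fluxes from concentration time series
#'
#' Least-squares slopes of [NH4+], [NO2-] and [NO3-] against time per
#' replicate (zero-order kinetics: linear consumption/production), mapped
#' to the three branch fluxes: F_AMO = -slope(NH4+),
#' F_NXR = slope(NO3-), F_NIR = -slope(NO2-) - F_NXR.
#'
#' @param ds A (lag-trimmed) `amx_dataset`.
#' @return Data frame per (batch, replicate) with fluxes, the implied
#'   stoichiometric ratios and residual standard errors.
#' @export
fit_rates <- function(ds) {
  validate_dataset(ds)
  out <- list()
  for (b in unique(ds$batch)) {
    for (r in unique(ds$replicate[ds$batch == b])) {
      sel <- ds$batch == b & ds$replicate == r
      slope <- resid_sd <- numeric(3)
      names(slope) <- names(resid_sd) <- .CONC_VARS
      for (v in .CONC_VARS) {
        d <- ds[sel & ds$variable == v, ]
        fit <- stats::lm(value ~ time_h, data = d)
        slope[v] <- stats::coef(fit)[["time_h"]]
        resid_sd[v] <- stats::sigma(fit)
      }
      if (slope["conc_NO2"] >= 0)
        warning("non-decreasing NO2- in batch ", b, " replicate ", r)
      F_AMO <- -slope["conc_NH4"]
      F_NXR <- slope["conc_NO3"]
      F_NIR <- -slope["conc_NO2"] - F_NXR
      out[[paste(b, r)]] <- data.frame(
        batch = b, replicate = r,
        F_AMO = F_AMO, F_NIR = F_NIR, F_NXR = F_NXR,
        dNO2_dNH4 = -slope["conc_NO2"] / F_AMO,
        dNO3_dNH4 = F_NXR / F_AMO,
        resid_NH4 = resid_sd["conc_NH4"], resid_NO2 = resid_sd["conc_NO2"],
        resid_NO3 = resid_sd["conc_NO3"], row.names = NULL)
    }
  }
  do.call(rbind, out)
}

# ---- likelihood machinery -------------------------------------------------

# observations of one replicate, in solver-ready form; t0 observations are
# retained in the likelihood so that free initial-state parameters are
# constrained by them
.replicate_obs <- function(ds, b, r, vars) {
  sel <- ds$batch == b & ds$replicate == r
  rep_ds <- ds[sel, ]
  t0 <- min(rep_ds$time_h)
  at0 <- function(v, col = "value") {
    x <- rep_ds[[col]][rep_ds$variable == v & rep_ds$time_h == t0]
    if (!length(x)) stop("replicate lacks ", v, " at its first time point", call. = FALSE)
    x[1]
  }
  t0val <- vapply(.ALL_VARS, at0, numeric(1))
  t0sd <- vapply(.ALL_VARS, at0, numeric(1), col = "sd")
  init <- batch_state(A = t0val[["conc_NH4"]], B = t0val[["conc_NO2"]],
                      C = t0val[["conc_NO3"]],
                      d15_A = t0val[["d15N_NH4"]], d15_B = t0val[["d15N_NO2"]],
                      d15_C = t0val[["d15N_NO3"]],
                      d18_B = t0val[["d18O_NO2"]], d18_C = t0val[["d18O_NO3"]])
  obs <- rep_ds[rep_ds$variable %in% vars & rep_ds$sd > 0, ]
  times <- sort(unique(c(t0, obs$time_h)))
  idx <- match(obs$time_h, times)
  list(init = init, times = times, var = obs$variable, idx = idx,
       value = obs$value, sd = obs$sd, d18_H2O = rep_ds$d18O_H2O[1],
       t0val = t0val, t0sd = t0sd)
}

# Gaussian log-likelihood of one replicate given full parameter set.
# Works on the raw solver matrix (no data-frame construction) for speed.
.loglik_traj <- function(obs, p) {
  pvec <- .parms_vector(p)
  out <- try(.simulate_raw(obs$init, obs$times, pvec, rtol = 1e-7, atol = 1e-9),
             silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(obs$times)) return(-Inf)
  m <- unclass(out)
  conv <- function(x, ref) (x / (1 - x) / ref - 1) * 1000
  pred <- numeric(length(obs$value))
  for (v in unique(obs$var)) {
    j <- obs$var == v
    i <- obs$idx[j]
    pred[j] <- switch(v,
      conc_NH4 = m[i, 2], conc_NO2 = m[i, 3], conc_NO3 = m[i, 4],
      d15N_NH4 = conv(m[i, 5] / m[i, 2], R15_AIR),
      d15N_NO2 = conv(m[i, 6] / m[i, 3], R15_AIR),
      d15N_NO3 = conv(m[i, 7] / m[i, 4], R15_AIR),
      d18O_NO2 = conv(m[i, 8] / (2 * m[i, 3]), R18_VSMOW),
      d18O_NO3 = conv(m[i, 9] / (3 * m[i, 4]), R18_VSMOW))
  }
  if (any(!is.finite(pred))) return(-Inf)
  sum(stats::dnorm(obs$value, pred, obs$sd, log = TRUE))
}

#' Adaptive random-walk Metropolis sampler
#'
#' Multivariate Gaussian random walk whose proposal covariance is adapted
#' during burn-in to 2.38^2/d times the empirical covariance of the chain
#' so far (plus a small jitter), then frozen. Uniform priors are enforced
#' by rejecting proposals outside the support.
#'
#' @param logpost Log-posterior function of the parameter vector (uniform
#'   priors: the log-likelihood).
#' @param lower,upper Prior support bounds.
#' @param settings An [mcmc_settings()].
#' @param init Optional start point (default: support midpoint).
#' @return List with `draws` (thinned post-burn-in matrix), `acceptance`
#'   (post-burn-in acceptance rate) and `last` (final state).
#' @export
adaptive_metropolis <- function(logpost, lower, upper, settings = mcmc_settings(),
                                init = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  th <- if (is.null(init)) (lower + upper) / 2 else init
  lp <- logpost(th)
  if (!is.finite(lp)) stop("log-posterior not finite at the start point", call. = FALSE)
  total <- settings$burn_in + settings$n_iter
  keep_n <- settings$n_iter %/% settings$thin
  draws <- matrix(NA_real_, keep_n, d)
  hist <- matrix(NA_real_, settings$burn_in, d)
  R <- diag((upper - lower) / 50, d)   # Cholesky factor of proposal cov
  n_acc <- 0L; kept <- 0L
  sc <- 2.38^2 / d                     # Gelman-Roberts-Gilks base scale
  step <- 1                            # scalar tuned on recent acceptance
  acc_win <- 0L
  for (i in seq_len(total)) {
    prop <- th + drop(crossprod(R, stats::rnorm(d)))
    if (all(prop > lower & prop < upper)) {
      lp_prop <- logpost(prop)
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
        th <- prop; lp <- lp_prop
        acc_win <- acc_win + 1L
        if (i > settings$burn_in) n_acc <- n_acc + 1L
      }
    }
    if (i <= settings$burn_in) {
      hist[i, ] <- th
      if (i >= settings$adapt_start && i %% settings$adapt_every == 0) {
        # covariance from the trailing half of the chain so far (the early
        # transit from the start point would otherwise inflate it), with a
        # scalar step size steered towards ~30% acceptance
        win <- hist[(i %/% 2):i, , drop = FALSE]
        rate <- acc_win / settings$adapt_every
        step <- step * exp(min(max(rate - 0.3, -0.5), 0.5))
        acc_win <- 0L
        S <- step * sc * stats::cov(win) + diag(1e-10, d)
        R <- chol(S)
      }
    } else if ((i - settings$burn_in) %% settings$thin == 0) {
      kept <- kept + 1L
      draws[kept, ] <- th
    }
  }
  list(draws = draws[seq_len(kept), , drop = FALSE],
       acceptance = n_acc / settings$n_iter, last = th)
}

# effective sample size via the initial positive sequence of the ACF
.ess <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  a <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(a < 0)
  if (length(pos)) a <- a[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(a))
}

.pool_posterior <- function(chains, params, settings, priors) {
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  colnames(draws) <- params
  acc <- vapply(chains, `[[`, numeric(1), "acceptance")
  if (any(acc < 0.1 | acc > 0.6))
    warning("post-adaptation acceptance rate outside [0.1, 0.6]: ",
            paste(sprintf("%.2f", acc), collapse = ", "))
  sm <- data.frame(
    param = params,
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    q2.5 = apply(draws, 2, stats::quantile, 0.025),
    q97.5 = apply(draws, 2, stats::quantile, 0.975),
    ess = apply(draws, 2, .ess), row.names = NULL)
  structure(list(draws = draws, summary = sm, acceptance = acc,
                 settings = settings, priors = priors,
                 n_replicates = length(chains),
                 by_replicate = chains),
            class = "amx_posterior")
}

#' @export
print.amx_posterior <- function(x, ...) {
  cat(sprintf("Pooled posterior over %d replicate chain(s), %d draws\n",
              x$n_replicates, nrow(x$draws)))
  print(x$summary, digits = 4)
  cat(sprintf("acceptance: %s\n", paste(sprintf("%.2f", x$acceptance), collapse = ", ")))
  invisible(x)
}

# Shared staged-MCMC driver. Besides the stage's isotope parameters the
# sampler marginalises, per replicate, the three zero-order fluxes and the
# full initial state (pool concentrations and the stage-relevant initial
# delta values) as nuisance parameters, with uniform windows around the
# stage-1 least-squares estimates / the observed t0 values; the t0
# observations remain in the likelihood, so the windows act only as
# truncation. Holding rates and initial state at their noisy point
# estimates instead would treat the trajectory of reaction progress and
# its isotopic anchor as exactly known; the measurement noise then leaks
# into the steep near-exhaustion part of the isotope curves and biases
# the exchange rate constant upward.
.fit_stage <- function(ds, rates, priors, settings, vars, build_params,
                       nuisance = TRUE, flux_window = 0.3,
                       conc_window = 0.1, delta_window = 4) {
  reps <- unique(ds[, c("batch", "replicate")])
  if (nrow(reps) == 0) {   # prior-only limit: sample the uniform prior
    logpost <- function(theta) 0
    chain <- adaptive_metropolis(logpost, priors$lower, priors$upper, settings)
    return(.pool_posterior(list(chain), priors$param, settings, priors))
  }
  d_iso <- length(priors$param)
  delta_vars <- intersect(vars, .ISO_VARS)
  chains <- list()
  for (i in seq_len(nrow(reps))) {
    b <- reps$batch[i]; r <- reps$replicate[i]
    obs <- .replicate_obs(ds, b, r, vars)
    rr <- rates[rates$batch == b & rates$replicate == r, ]
    if (nrow(rr) != 1) stop("no fitted rates for batch ", b, " replicate ", r, call. = FALSE)
    if (nuisance) {
      fl <- c(rr$F_AMO, rr$F_NIR, rr$F_NXR)
      c0 <- obs$t0val[.CONC_VARS]
      dv <- delta_vars[obs$t0sd[delta_vars] > 0]
      d0 <- obs$t0val[dv]
      dw <- delta_window * obs$t0sd[dv]
      lower <- c(priors$lower, fl * (1 - flux_window),
                 c0 * (1 - conc_window), d0 - dw)
      upper <- c(priors$upper, fl * (1 + flux_window),
                 c0 * (1 + conc_window), d0 + dw)
      start <- c((priors$lower + priors$upper) / 2, fl, c0, d0)
      logpost <- function(theta) {
        p <- build_params(theta[seq_len(d_iso)], rr, obs)
        p$F_AMO <- theta[d_iso + 1]
        p$F_NIR <- theta[d_iso + 2]
        p$F_NXR <- theta[d_iso + 3]
        t0v <- obs$t0val
        t0v[.CONC_VARS] <- theta[d_iso + 4:6]
        if (length(dv)) t0v[dv] <- theta[d_iso + 6 + seq_along(dv)]
        o <- obs
        o$init <- batch_state(A = t0v[["conc_NH4"]], B = t0v[["conc_NO2"]],
                              C = t0v[["conc_NO3"]],
                              d15_A = t0v[["d15N_NH4"]],
                              d15_B = t0v[["d15N_NO2"]],
                              d15_C = t0v[["d15N_NO3"]],
                              d18_B = t0v[["d18O_NO2"]],
                              d18_C = t0v[["d18O_NO3"]])
        .loglik_traj(o, p)
      }
    } else {
      lower <- priors$lower; upper <- priors$upper; start <- NULL
      logpost <- function(theta) .loglik_traj(obs, build_params(theta, rr, obs))
    }
    if (!is.null(settings$seed)) set.seed(settings$seed + i)
    ch <- adaptive_metropolis(logpost, lower, upper, settings, init = start)
    ch$nuisance <- if (nuisance) {
      nd <- ch$draws[, -seq_len(d_iso), drop = FALSE]
      colnames(nd) <- c("F_AMO", "F_NIR", "F_NXR", .CONC_VARS, dv)
      nd
    } else NULL
    ch$draws <- ch$draws[, seq_len(d_iso), drop = FALSE]
    chains[[i]] <- ch
  }
  .pool_posterior(chains, priors$param, settings, priors)
}

#' Stage 2: nitrogen isotope effects by MCMC
#'
#' Samples the three nitrogen isotope effects against the concentration and
#' d15N time series of NH4+, NO2- and NO3-, with the analytical SDs carried
#' in the dataset. The zero-order fluxes and the initial NO2- pool are
#' marginalised as per-replicate nuisance parameters around their
#' [fit_rates()] estimates, so that the uncertainty of the reaction
#' progress propagates into the isotope-effect posteriors. Thinned
#' post-burn-in draws are pooled across replicates and summarised as mean,
#' SD and a 95% credible interval.
#'
#' @param ds A (lag-trimmed) `amx_dataset` of one water level (or several;
#'   all replicates present are fitted and pooled).
#' @param rates Output of [fit_rates()].
#' @param priors Data frame of uniform bounds ([priors_nitrogen()]).
#' @param settings An [mcmc_settings()].
#' @param base_params Baseline [model_params()] supplying the parameters
#'   not being sampled.
#' @return An `amx_posterior`.
#' @export
fit_n_isotopes <- function(ds, rates = fit_rates(ds), priors = priors_nitrogen(),
                           settings = mcmc_settings(),
                           base_params = model_params()) {
  validate_dataset(ds)
  build <- function(theta, rr, obs) {
    p <- base_params
    p$F_AMO <- rr$F_AMO; p$F_NIR <- rr$F_NIR; p$F_NXR <- rr$F_NXR
    p$e15_AMO <- theta[1]; p$e15_NIR <- theta[2]; p$e15_NXR <- theta[3]
    p$d18_H2O <- obs$d18_H2O
    p
  }
  .fit_stage(ds, rates, priors, settings,
             c(.CONC_VARS, "d15N_NH4", "d15N_NO2", "d15N_NO3"), build)
}

#' Stage 3: oxygen isotope effects and the exchange rate constant by MCMC
#'
#' With the nitrogen effects fixed at their stage-2 pooled means, samples
#' the three oxygen isotope effects and (unless `k_fixed` is given) the
#' anammox-mediated nitrite-water exchange rate constant against all
#' measured series (the d15N series sharpen the constraint on reaction
#' progress), marginalising the same flux / initial-pool nuisance
#' parameters as stage 2.
#'
#' @inheritParams fit_n_isotopes
#' @param n_effects Named vector of fixed nitrogen effects (e15_AMO,
#'   e15_NIR, e15_NXR), typically stage-2 pooled means.
#' @param priors Uniform bounds ([priors_oxygen()]); the k_eq_AMX row is
#'   dropped automatically when `k_fixed` is given.
#' @param k_fixed Optional fixed k_eq_AMX (h^-1), e.g. from the sensitivity
#'   grid c(10.8, 12.0, 13.2, 15.0, 18.0) * 1e-2.
#' @return An `amx_posterior` (3 or 4 parameters).
#' @export
fit_o_isotopes <- function(ds, rates = fit_rates(ds), n_effects = NULL,
                           priors = priors_oxygen(), settings = mcmc_settings(),
                           base_params = model_params(), k_fixed = NULL) {
  validate_dataset(ds)
  if (!is.null(k_fixed)) priors <- priors[priors$param != "k_eq_AMX", ]
  build <- function(theta, rr, obs) {
    p <- base_params
    p$F_AMO <- rr$F_AMO; p$F_NIR <- rr$F_NIR; p$F_NXR <- rr$F_NXR
    if (!is.null(n_effects)) {
      p$e15_AMO <- n_effects[["e15_AMO"]]
      p$e15_NIR <- n_effects[["e15_NIR"]]
      p$e15_NXR <- n_effects[["e15_NXR"]]
    }
    p$e18_NIR <- theta[1]; p$e18_NXR <- theta[2]; p$e18_H2O <- theta[3]
    p$k_eq_AMX <- if (is.null(k_fixed)) theta[4] else k_fixed
    p$d18_H2O <- obs$d18_H2O
    p
  }
  .fit_stage(ds, rates, priors, settings, .ALL_VARS, build)
}

#' Run the full staged inference
#'
#' Convenience wrapper: [fit_rates()], then [fit_n_isotopes()], then
#' [fit_o_isotopes()] with the nitrogen pooled means plugged in.
#'
#' @inheritParams fit_n_isotopes
#' @param settings_n,settings_o MCMC settings for the two stages.
#' @param k_fixed Optional fixed k_eq_AMX passed to stage 3.
#' @return List with `rates`, `nitrogen` and `oxygen` components.
#' @export
fit_staged <- function(ds, settings_n = mcmc_settings(),
                       settings_o = settings_n,
                       base_params = model_params(), k_fixed = NULL) {
  rates <- fit_rates(ds)
  post_n <- fit_n_isotopes(ds, rates, settings = settings_n,
                           base_params = base_params)
  n_eff <- stats::setNames(post_n$summary$mean, post_n$summary$param)
  post_o <- fit_o_isotopes(ds, rates, n_effects = n_eff,
                           settings = settings_o, base_params = base_params,
                           k_fixed = k_fixed)
  list(rates = rates, nitrogen = post_n, oxygen = post_o)
}

#' Joint (non-staged) fit of all seven isotope parameters
#'
#' Samples the nitrogen and oxygen effects and k_eq_AMX in one chain per
#' replicate against all isotope series simultaneously. Provided as a
#' cross-check on the staged default.
#'
#' @inheritParams fit_n_isotopes
#' @return An `amx_posterior` over 7 parameters.
#' @export
fit_isotopes_joint <- function(ds, rates = fit_rates(ds),
                               settings = mcmc_settings(),
                               base_params = model_params()) {
  validate_dataset(ds)
  priors <- rbind(priors_nitrogen(), priors_oxygen())
  build <- function(theta, rr, obs) {
    p <- base_params
    p$F_AMO <- rr$F_AMO; p$F_NIR <- rr$F_NIR; p$F_NXR <- rr$F_NXR
    p$e15_AMO <- theta[1]; p$e15_NIR <- theta[2]; p$e15_NXR <- theta[3]
    p$e18_NIR <- theta[4]; p$e18_NXR <- theta[5]; p$e18_H2O <- theta[6]
    p$k_eq_AMX <- theta[7]
    p$d18_H2O <- obs$d18_H2O
    p
  }
  .fit_stage(ds, rates, priors, settings, .ALL_VARS, build)
}

#' Export posterior draws and summary
#'
#' @param post An `amx_posterior`.
#' @param draws_csv,summary_json Output paths (either may be `NULL`).
#' @return Invisibly, the summary list written to JSON.
#' @export
export_posterior <- function(post, draws_csv = NULL, summary_json = NULL) {
  if (!is.null(draws_csv))
    utils::write.csv(as.data.frame(post$draws), draws_csv, row.names = FALSE)
  out <- list(summary = post$summary, acceptance = post$acceptance,
              n_draws = nrow(post$draws), n_replicates = post$n_replicates)
  if (!is.null(summary_json))
    jsonlite::write_json(out, summary_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(out)
}
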