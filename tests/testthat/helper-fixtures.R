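# Shared fixtures: small, fast configurations of the study conditions.

zero_noise <- function() noise_model(0, 0, 0, 0, 0, 0, 0)

# single-level design at unlabeled water, default schedule
design_unlabeled <- function(...) experiment_design(d18_H2O = -12.6, ...)

# short MCMC settings for unit tests (not the study-scale settings)
settings_tiny <- function(seed = 1) {
  mcmc_settings(n_iter = 3000L, burn_in = 2000L, thin = 5L, seed = seed,
                adapt_start = 200L, adapt_every = 100L)
}

# closed-form Rayleigh residual-substrate delta (independent oracle)
rayleigh_delta <- function(f, delta0, epsilon) {
  a <- 1 + epsilon / 1000
  (1000 + delta0) * f^(1 / a - 1) - 1000
}

# pull one variable of one replicate as a time-ordered data frame
series <- function(ds, var, rep = 1, batch = NULL) {
  d <- as.data.frame(ds)
  if (!is.null(batch)) d <- d[d$batch == batch, ]
  d <- d[d$replicate == rep & d$variable == var, ]
  d[order(d$time_h), c("time_h", "value")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
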