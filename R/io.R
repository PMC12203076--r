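# Tidy (long) CSV schema for batch-culture time series, with validation and
# lag trimming. Long format is used because replicates have unequal
# sampling times.

.REQUIRED_COLS <- c("batch", "replicate", "time_h", "variable", "value",
                    "sd", "d18O_H2O")

#' Validate a batch-culture dataset
#'
#' Checks the long-format schema: required columns, known variable names,
#' non-negative times and concentrations, and uniqueness of
#' (batch, replicate, time, variable) keys. Violations are reported with
#' row numbers.
#'
#' @param ds Data frame to validate.
#' @return The dataset, invisibly, with class `amx_dataset`.
#' @export
validate_dataset <- function(ds) {
  missing <- setdiff(.REQUIRED_COLS, names(ds))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  bad_var <- !ds$variable %in% .ALL_VARS
  if (any(bad_var))
    stop("unknown variable name(s) at row(s) ",
         paste(utils::head(which(bad_var), 5), collapse = ", "), call. = FALSE)
  if (any(ds$time_h < 0))
    stop("negative time at row(s) ",
         paste(utils::head(which(ds$time_h < 0), 5), collapse = ", "), call. = FALSE)
  neg_conc <- ds$variable %in% .CONC_VARS & ds$value < 0
  if (any(neg_conc))
    stop("negative concentration at row(s) ",
         paste(utils::head(which(neg_conc), 5), collapse = ", "), call. = FALSE)
  key <- paste(ds$batch, ds$replicate, ds$time_h, ds$variable)
  if (anyDuplicated(key))
    stop("duplicate (batch, replicate, time, variable) key at row(s) ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "), call. = FALSE)
  class(ds) <- unique(c("amx_dataset", class(ds)))
  invisible(ds)
}

#' Read / write batch-culture datasets
#'
#' Lossless CSV round trip of the long-format schema (UTF-8, decimal
#' point). `read_dataset()` validates on read.
#'
#' @param path File path.
#' @param ds Dataset to write.
#' @return `read_dataset()` returns a validated `amx_dataset`;
#'   `write_dataset()` returns `path` invisibly.
#' @export
read_dataset <- function(path) {
  ds <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_dataset(ds)
  class(ds) <- c("amx_dataset", "data.frame")
  ds
}

#' @rdname read_dataset
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds)
  utils::write.csv(as.data.frame(ds)[, .REQUIRED_COLS], path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Exclude the initial lag / low-activity phase
#'
#' The zero-order kinetics assumption holds only once anammox activity is
#' fully established, so leading low-activity samples are excluded before
#' parameter estimation. Mode `"manual"` drops the listed leading sample
#' indices in every replicate; mode `"auto"` drops leading points while the
#' local NO2- consumption rate is below `threshold` (default 50%) of the
#' median consumption rate over the remaining window.
#'
#' @param ds An `amx_dataset`.
#' @param mode `"auto"` or `"manual"`.
#' @param drop Leading sample indices to drop in manual mode.
#' @param threshold Auto-mode rate threshold relative to the median.
#' @param quiet Suppress the trimming message.
#' @return The trimmed dataset; the per-replicate number of dropped points
#'   is attached as attribute `"trimmed"`.
#' @export
trim_lag <- function(ds, mode = c("auto", "manual"), drop = integer(),
                     threshold = 0.5, quiet = FALSE) {
  mode <- match.arg(mode)
  validate_dataset(ds)
  keep <- rep(TRUE, nrow(ds))
  trimmed <- list()
  for (b in unique(ds$batch)) {
    for (r in unique(ds$replicate[ds$batch == b])) {
      sel <- ds$batch == b & ds$replicate == r
      tt <- sort(unique(ds$time_h[sel]))
      if (length(tt) < 4) stop("need at least 4 points per replicate", call. = FALSE)
      if (mode == "manual") {
        if (length(drop) && (any(drop < 1) || any(drop > length(tt))))
          stop("manual drop indices out of range", call. = FALSE)
        k <- length(drop)
        drop_times <- tt[drop]
      } else {
        no2 <- ds[sel & ds$variable == "conc_NO2", ]
        no2 <- no2[order(no2$time_h), ]
        rate <- -diff(no2$value) / diff(no2$time_h)
        k <- 0
        while (k < length(rate) - 2) {
          med <- stats::median(rate[(k + 1):length(rate)])
          if (rate[k + 1] < threshold * med) k <- k + 1 else break
        }
        drop_times <- tt[seq_len(k)]
      }
      if (length(tt) - length(drop_times) < 3)
        stop("trimming would leave fewer than 3 points", call. = FALSE)
      keep[sel & ds$time_h %in% drop_times] <- FALSE
      trimmed[[paste(b, r)]] <- length(drop_times)
    }
  }
  n_drop <- sum(!keep)
  if (!quiet && n_drop > 0)
    message("trim_lag: dropped ", n_drop, " rows across ",
            sum(unlist(trimmed) > 0), " replicate(s)")
  out <- ds[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trimmed") <- unlist(trimmed)
  class(out) <- c("amx_dataset", "data.frame")
  out
}
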