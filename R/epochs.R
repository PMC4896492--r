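#' Trial-epoched voltage recordings for one electrode
#'
#' An `epoch_set` bundles the raw (or filtered) voltage epochs recorded at a
#' single intracranial electrode: a trials-by-samples matrix on a common time
#' axis relative to stimulus onset, the per-trial stimulus category, and a
#' rejected-trial mask carried through the whole signal chain.
#'
#' @param voltages Numeric matrix, trials x samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param category Character or factor of length `nrow(voltages)`: stimulus
#'   category of each trial.
#' @param t0 Time (s) of the first sample relative to stimulus onset. Ignored
#'   when `time` is supplied.
#' @param time Optional explicit time axis (s), length `ncol(voltages)`,
#'   strictly increasing with uniform spacing `1/fs`.
#' @param electrode,subject Identifiers carried into downstream tables.
#' @param rejected Logical mask of length `nrow(voltages)`; rejected trials are
#'   excluded from every across-trial statistic. Default: none rejected.
#'
#' @return An object of class `epoch_set`.
#' @examples
#' fs <- 1000
#' t <- seq(-1, 2, by = 1 / fs)
#' v <- matrix(rnorm(10 * length(t)), nrow = 10)
#' ep <- epoch_set(v, fs, category = rep(c("face", "place"), 5))
#' ep
#' @export
epoch_set <- function(voltages, fs, category, t0 = -1, time = NULL,
                      electrode = NA_character_, subject = NA_character_,
                      rejected = NULL) {
  voltages <- as.matrix(voltages)
  if (!is.numeric(voltages)) abort("`voltages` must be a numeric matrix.")
  n_trials <- nrow(voltages)
  n_samples <- ncol(voltages)
  if (is.null(time)) {
    i0 <- round(t0 * fs)
    time <- (i0 + seq_len(n_samples) - 1) / fs
  }
  if (length(time) != n_samples) {
    abort("`time` must have one entry per sample column.")
  }
  dt <- diff(time)
  if (any(dt <= 0) || max(abs(dt - 1 / fs)) > 1e-6 / fs) {
    abort("`time` must be strictly increasing with uniform spacing 1/fs.")
  }
  category <- as.character(category)
  if (length(category) != n_trials) {
    abort("`category` must have one label per trial row.")
  }
  if (is.null(rejected)) rejected <- rep(FALSE, n_trials)
  if (length(rejected) != n_trials || !is.logical(rejected)) {
    abort("`rejected` must be a logical vector with one entry per trial.")
  }
  structure(
    list(
      voltages = voltages, time = as.numeric(time), fs = fs,
      category = category, electrode = as.character(electrode),
      subject = as.character(subject), rejected = rejected
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> electrode %s (subject %s): %d trials x %d samples @ %g Hz, t in [%.3f, %.3f] s\n",
    x$electrode, x$subject, nrow(x$voltages), ncol(x$voltages), x$fs,
    min(x$time), max(x$time)
  ))
  tb <- table(x$category[!x$rejected])
  cat("  retained trials:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$voltages)

# replace the voltage matrix, keeping all metadata
set_voltages <- function(epochs, voltages) {
  epochs$voltages <- voltages
  epochs
}

stopifnot_epoch_set <- function(x, arg = "epochs") {
  if (!inherits(x, "epoch_set")) {
    abort(sprintf("`%s` must be an <epoch_set> (see ?epoch_set).", arg))
  }
  invisible(x)
}
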