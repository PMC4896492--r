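#' Signal chain: line-noise removal, gamma band-pass, analytic amplitude
#'
#' These operations transform an [epoch_set()] in place (same trials, same time
#' axis) and are applied per trial with zero-phase (forward-backward)
#' filtering. Epochs are reflection-padded before filtering and the padding is
#' discarded afterwards, so filter transients never reach the epoch edges.
#'
#' @name signal_chain
NULL

# Reflect-pad each row by at least `pad` samples, apply fn(row), trim. The
# padded length is rounded up to a 5-smooth number so FFT-based steps stay
# O(n log n) for any epoch length.
filter_rows <- function(voltages, pad, fn) {
  n <- ncol(voltages)
  m <- stats::nextn(n + 2L * min(pad, n - 1L), c(2, 3, 5))
  pad_l <- min(n - 1L, (m - n) %/% 2L)
  pad_r <- min(n - 1L, m - n - pad_l)
  idx_pre <- if (pad_l > 0L) seq(pad_l + 1L, 2L) else integer(0)
  idx_post <- if (pad_r > 0L) seq(n - 1L, n - pad_r) else integer(0)
  out <- voltages
  for (i in seq_len(nrow(voltages))) {
    x <- voltages[i, ]
    # odd (point-symmetric) reflection: continuous in value and slope at the
    # epoch edges, so filter transients stay in the discarded padding
    xp <- c(2 * x[1] - x[idx_pre], x, 2 * x[n] - x[idx_post])
    out[i, ] <- fn(xp)[pad_l + seq_len(n)]
  }
  out
}

pad_samples <- function(fs, pad_s = 0.5) as.integer(round(pad_s * fs))

#' Remove power-line noise and its harmonics
#'
#' Applies second-order IIR notch filters (2 Hz bandwidth, zero-phase) at the
#' line frequency and every harmonic up to `max_hz` (default: the upper edge of
#' the gamma band, 120 Hz).
#'
#' @param epochs An [epoch_set()].
#' @param line_hz Line frequency (Hz), default 60.
#' @param max_hz Highest harmonic to notch (Hz).
#' @param bandwidth_hz -3 dB notch width (Hz).
#' @param pad_s Reflection padding (s) applied before filtering.
#' @return An [epoch_set()] with notched voltages.
#' @rdname signal_chain
#' @export
notch_line_noise <- function(epochs, line_hz = 60, max_hz = 120,
                             bandwidth_hz = 2, pad_s = 1) {
  stopifnot_epoch_set(epochs)
  fs <- epochs$fs
  freqs <- seq(line_hz, max_hz, by = line_hz)
  if (any(freqs >= fs / 2)) {
    abort("Notch frequency at or above Nyquist; raise the sampling rate or lower `max_hz`.")
  }
  filters <- lapply(freqs, notch_biquad, fs = fs, bw = bandwidth_hz)
  pad <- pad_samples(fs, pad_s)
  v <- filter_rows(epochs$voltages, pad, function(x) {
    for (f in filters) x <- signal::filtfilt(f$b, f$a, x)
    x
  })
  set_voltages(epochs, v)
}

# standard constrained biquad notch: zeros on the unit circle at w0,
# poles at radius r inside; r set from the -3 dB bandwidth
notch_biquad <- function(f0, fs, bw = 2) {
  w0 <- 2 * pi * f0 / fs
  r <- 1 - tan(pi * bw / fs) / (tan(pi * bw / fs) + 1)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  # unity gain at DC (or at Nyquist if the notch sits at DC)
  g <- sum(a) / sum(b)
  list(b = b * g, a = a)
}

#' Band-pass filter into the broadband gamma range
#'
#' Designs a minimum-order elliptical (Cauer) IIR filter with `ripple_db`
#' passband ripple reaching `stop_db` attenuation at transition edges
#' `trans_hz` outside the band, and applies it forward-backward (zero phase).
#'
#' @param band Passband edges in Hz, default `c(60, 120)`.
#' @param ripple_db Passband ripple of the one-way design (dB).
#' @param stop_db Stopband attenuation of the one-way design (dB).
#' @param trans_hz Transition width outside each band edge (Hz).
#' @rdname signal_chain
#' @export
bandpass_gamma <- function(epochs, band = c(60, 120), ripple_db = 0.5,
                           stop_db = 30, trans_hz = 5, pad_s = 0.5) {
  stopifnot_epoch_set(epochs)
  fs <- epochs$fs
  if (length(band) != 2 || band[1] >= band[2] || band[1] <= 0 || band[2] >= fs / 2) {
    abort("`band` must be increasing and lie strictly inside (0, Nyquist).")
  }
  flt <- design_gamma_filter(fs, band, ripple_db, stop_db, trans_hz)
  pad <- pad_samples(fs, pad_s)
  v <- filter_rows(epochs$voltages, pad, function(x) signal::filtfilt(flt, x))
  set_voltages(epochs, v)
}

design_gamma_filter <- function(fs, band = c(60, 120), ripple_db = 0.5,
                                stop_db = 30, trans_hz = 5) {
  nyq <- fs / 2
  wp <- band / nyq
  ws <- c(band[1] - trans_hz, band[2] + trans_hz) / nyq
  signal::ellip(signal::ellipord(wp, ws, ripple_db, stop_db))
}

#' Analytic amplitude (Hilbert envelope) with Savitzky-Golay smoothing
#'
#' Computes the magnitude of the analytic signal of each (already band-limited)
#' trial via the FFT construction of the Hilbert transform, then smooths it
#' with a Savitzky-Golay FIR filter (polynomial order `sg_order`).
#'
#' The smoothing frame is given as a duration (`sg_frame_s`, default 0.155 s,
#' converted to the nearest odd sample count at the epoch's sampling rate) or,
#' with `sg_frame_samples`, as an exact sample count for strict replication of
#' fixed-sample conventions.
#'
#' @param sg_order Savitzky-Golay polynomial order.
#' @param sg_frame_s Smoothing frame length as a duration (s).
#' @param sg_frame_samples Optional smoothing frame length in samples
#'   (overrides `sg_frame_s`; made odd if even).
#' @rdname signal_chain
#' @export
analytic_amplitude <- function(epochs, sg_order = 5, sg_frame_s = 0.155,
                               sg_frame_samples = NULL, pad_s = 0.5) {
  stopifnot_epoch_set(epochs)
  fs <- epochs$fs
  n <- if (is.null(sg_frame_samples)) round(sg_frame_s * fs) else sg_frame_samples
  n <- as.integer(n)
  if (n %% 2L == 0L) n <- n + 1L
  if (n <= sg_order + 1L) abort("Smoothing frame too short for the polynomial order.")
  if (n >= ncol(epochs$voltages)) {
    abort("Epoch shorter than the smoothing frame; lengthen the epoch or shorten the frame.")
  }
  pad <- pad_samples(fs, pad_s)
  sg <- signal::sgolay(p = sg_order, n = n) # design once, apply per trial
  v <- filter_rows(epochs$voltages, pad, function(x) {
    apply_sgolay(hilbert_amplitude(x), sg, n)
  })
  set_voltages(epochs, v)
}

# Savitzky-Golay smoothing with a precomputed projection matrix; the steady
# state is a single FIR pass, the first/last half-frames use the edge rows
apply_sgolay <- function(x, sg, n) {
  len <- length(x)
  k <- floor(n / 2)
  z <- stats::filter(x, sg[k + 1, n:1], sides = 1)
  c(sg[1:k, ] %*% x[1:n], z[n:len], sg[(k + 2):n, ] %*% x[(len - n + 1):len])
}

# |analytic signal| via the standard FFT construction: double positive
# frequencies, zero negative ones
hilbert_amplitude <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}
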