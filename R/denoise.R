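#' Filter specification for ECG denoising
#'
#' Bundles the passband and mains-notch settings used by [denoise()]. The
#' defaults target resting ECG contaminated by 50 Hz mains pickup, baseline
#' drift and high-frequency muscle noise: a 0.5--45 Hz Butterworth passband
#' applied forward-backward (zero phase, so fiducial timing is unbiased)
#' plus a narrow notch (quality factor 30) at the mains frequency.
#'
#' @param notch_hz Mains frequency to notch out, Hz (default 50; set 60 for
#'   North-American recordings, or `NA` to skip the notch).
#' @param bandpass_lo_hz,bandpass_hi_hz Passband edges, Hz.
#' @param order Low-pass Butterworth order (the high-pass stage is fixed at
#'   order 2 for numerical stability at very low normalized cutoffs).
#' @param notch_q Notch quality factor (centre frequency / -3 dB width).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(notch_hz = 50, bandpass_lo_hz = 0.5,
                        bandpass_hi_hz = 45, order = 4, notch_q = 30) {
  if (!is.na(notch_hz) && notch_hz <= 0) {
    abort("signal_io: notch_hz must be positive (or NA to disable).")
  }
  if (bandpass_lo_hz <= 0 || bandpass_hi_hz <= bandpass_lo_hz) {
    abort("signal_io: need 0 < bandpass_lo_hz < bandpass_hi_hz.")
  }
  if (order < 1) abort("signal_io: filter order must be >= 1.")
  structure(list(notch_hz = notch_hz, bandpass_lo_hz = bandpass_lo_hz,
                 bandpass_hi_hz = bandpass_hi_hz, order = order,
                 notch_q = notch_q),
            class = "filter_spec")
}

# RBJ audio-EQ-cookbook biquad notch; returns list(b, a)
notch_coefficients <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# zero-phase filtering with odd (anti-symmetric) edge extension, so ramps and
# step-like baselines do not ring at the record boundaries
filtfilt_padded <- function(b, a, x, pad_n) {
  n <- length(x)
  pad_n <- min(pad_n, n - 1L)
  if (pad_n > 0) {
    left <- 2 * x[1] - x[seq(pad_n + 1L, 2L)]
    right <- 2 * x[n] - x[seq(n - 1L, n - pad_n)]
    xp <- c(left, x, right)
  } else {
    xp <- x
  }
  # forward-backward pass done explicitly; subtracting the edge value before
  # each pass puts the filter state at its DC steady state, and the remaining
  # zero-initial-condition transients land inside the pads and are trimmed
  flt <- signal::Arma(b = b, a = a)
  g0 <- sum(b) / sum(a)  # DC gain
  one_pass <- function(v) {
    c0 <- v[1]
    as.numeric(signal::filter(flt, v - c0)) + c0 * g0
  }
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[seq(pad_n + 1L, pad_n + n)]
}

#' Denoise an ECG record
#'
#' Applies, per lead and with zero phase (forward-backward filtering over an
#' odd-extended signal): a second-order Butterworth high-pass at the lower
#' passband edge (baseline drift), a Butterworth low-pass at the upper edge
#' (EMG/high-frequency noise), and a biquad notch at the mains frequency.
#' Because every stage is linear and time-invariant, `denoise` is linear in
#' its input and approximately idempotent on in-band content.
#'
#' @param rec An [ecg_record()].
#' @param spec A [filter_spec()].
#' @return A denoised `ecg_record` of the same shape.
#' @export
denoise <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!inherits(spec, "filter_spec")) abort("signal_io: `spec` must be a filter_spec.")
  fs <- ecg_fs(rec)
  nyq <- fs / 2
  if (spec$bandpass_hi_hz >= nyq) {
    abort(sprintf(
      "signal_io: passband edge %g Hz is not below the Nyquist frequency %g Hz.",
      spec$bandpass_hi_hz, nyq))
  }
  if (!is.na(spec$notch_hz) && spec$notch_hz >= nyq) {
    abort("signal_io: notch frequency must be below Nyquist.")
  }
  hp <- signal::butter(2, spec$bandpass_lo_hz / nyq, type = "high")
  lp <- signal::butter(spec$order, spec$bandpass_hi_hz / nyq, type = "low")
  nc <- if (!is.na(spec$notch_hz)) {
    notch_coefficients(spec$notch_hz, fs, spec$notch_q)
  }
  pad_n <- as.integer(round(2 * fs))
  filtered <- purrr::map(as.list(rec), function(x) {
    y <- filtfilt_padded(hp$b, hp$a, x, pad_n)
    y <- filtfilt_padded(lp$b, lp$a, y, pad_n)
    if (!is.null(nc)) y <- filtfilt_padded(nc$b, nc$a, y, pad_n)
    y
  })
  ecg_record(as_tibble(filtered), fs = fs, subject_id = ecg_subject(rec))
}
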