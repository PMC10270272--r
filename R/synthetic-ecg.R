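# run code under a locally-seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# canonical per-lead wave amplitudes (mV) of a normal sinus beat; rows are
# the 12 leads, columns the P, Q, R, S, T Gaussian bumps plus a smaller,
# later repolarization component T2 whose per-lead pattern differs from T --
# this opens the vectorcardiographic T loop (real T loops are open curves,
# not a line traced out and back)
default_wave_amplitudes <- function() {
  m <- rbind(
    I   = c( 0.08, -0.05,  0.70, -0.12,  0.25,  0.04),
    II  = c( 0.15, -0.08,  1.20, -0.18,  0.35,  0.10),
    III = c( 0.07, -0.04,  0.50, -0.10,  0.12,  0.08),
    aVR = c(-0.12,  0.04, -0.95,  0.15, -0.30, -0.07),
    aVL = c( 0.02, -0.02,  0.15, -0.05,  0.08, -0.02),
    aVF = c( 0.11, -0.06,  0.85, -0.14,  0.24,  0.09),
    V1  = c( 0.05,  0.00,  0.25, -1.10, -0.10,  0.08),
    V2  = c( 0.08,  0.00,  0.55, -1.60,  0.45,  0.15),
    V3  = c( 0.10, -0.02,  0.90, -1.10,  0.50,  0.12),
    V4  = c( 0.12, -0.06,  1.50, -0.60,  0.45,  0.08),
    V5  = c( 0.12, -0.08,  1.30, -0.35,  0.35,  0.04),
    V6  = c( 0.10, -0.06,  1.00, -0.20,  0.28,  0.02)
  )
  colnames(m) <- c("P", "Q", "R", "S", "T", "T2")
  m
}

#' Synthetic beat template
#'
#' Gaussian-wave beat model: each wave (P, Q, R, S, T) is a Gaussian bump
#' with a shared center and width (seconds from beat onset) and a per-lead
#' amplitude from a canonical normal-morphology table. With the default
#' timing the R peak sits 0.210 s after beat onset, the true J point at
#' R + 40 ms, the T apex at R + 240 ms, and the tangent-rule T end
#' (apex + two T widths) at R + 360 ms — these are the ground-truth
#' fiducials the generator emits.
#'
#' @param heart_rate Beats per minute, in 30--180.
#' @param amplitudes 12 x 5 amplitude matrix (mV), rows named by lead,
#'   columns P, Q, R, S, T, T2 (T2 is the secondary repolarization component
#'   that opens the T loop; set its column to zero for a degenerate flat loop).
#' @param centers_s,widths_s Named numeric vectors of wave centers and widths
#'   in seconds from beat onset.
#' @return A list of class `beat_template`.
#' @export
beat_template <- function(heart_rate = 60,
                          amplitudes = default_wave_amplitudes(),
                          centers_s = c(P = 0.110, Q = 0.196, R = 0.210,
                                        S = 0.235, T = 0.450, T2 = 0.475),
                          widths_s = c(P = 0.022, Q = 0.008, R = 0.011,
                                       S = 0.009, T = 0.060, T2 = 0.045)) {
  if (heart_rate < 30 || heart_rate > 180) {
    abort("synthetic_data: heart_rate must be in 30-180 bpm.")
  }
  if (any(widths_s <= 0)) abort("synthetic_data: wave widths must be positive.")
  if (centers_s["T"] <= centers_s["R"]) {
    abort("synthetic_data: T center must follow R center.")
  }
  structure(list(heart_rate = heart_rate, amplitudes = amplitudes,
                 centers_s = centers_s, widths_s = widths_s),
            class = "beat_template")
}

#' Repolarization dispersion specification
#'
#' Controls how much the ST-T segment varies from beat to beat in the
#' synthetic ECG, plus the usual nuisance components. `stt_jitter` is the
#' coefficient of variation of per-beat multiplicative noise on the T-wave
#' amplitude and width (the knob that emulates inconsistent beat-to-beat
#' repolarization); `st_shift_mv` adds a systematic ST-segment deviation;
#' `alternans` alternates two T morphologies on even/odd beats.
#'
#' @param stt_jitter Relative SD of per-beat T amplitude/width factors (>= 0).
#' @param st_shift_mv Systematic ST deviation, mV.
#' @param alternans Flag: alternate T amplitude by +/-15% between beats.
#' @param noise_mv SD of additive Gaussian noise, mV.
#' @param baseline_wander_mv Amplitude of 0.15 Hz sinusoidal baseline wander.
#' @param seed RNG seed for the per-beat draws (NULL = use current RNG).
#' @return A list of class `dispersion_spec`.
#' @export
dispersion_spec <- function(stt_jitter = 0, st_shift_mv = 0, alternans = FALSE,
                            noise_mv = 0, baseline_wander_mv = 0, seed = NULL) {
  if (stt_jitter < 0 || noise_mv < 0 || baseline_wander_mv < 0) {
    abort("synthetic_data: dispersion scales must be non-negative.")
  }
  structure(list(stt_jitter = stt_jitter, st_shift_mv = st_shift_mv,
                 alternans = alternans, noise_mv = noise_mv,
                 baseline_wander_mv = baseline_wander_mv, seed = seed),
            class = "dispersion_spec")
}

# smooth plateau used for the systematic ST shift: cosine ramps over
# [j, j+ramp] and [t_end-ramp, t_end]
st_window <- function(t, j_s, t_end_s, ramp = 0.03) {
  w <- numeric(length(t))
  up <- t >= j_s & t < j_s + ramp
  mid <- t >= j_s + ramp & t <= t_end_s - ramp
  down <- t > t_end_s - ramp & t <= t_end_s
  w[up] <- 0.5 * (1 - cos(pi * (t[up] - j_s) / ramp))
  w[mid] <- 1
  w[down] <- 0.5 * (1 - cos(pi * (t_end_s - t[down]) / ramp))
  w
}

#' Simulate a 12-lead ECG with known ground truth
#'
#' Sums per-wave Gaussians on a regular beat grid, applies the requested
#' beat-to-beat repolarization dispersion, and adds noise and baseline
#' wander. Returns the record together with the exact fiducials of every
#' generated beat (R peak, J point = R + 40 ms, T apex, and the analytical
#' tangent-rule T end = apex + 2 T widths), so detector and estimator stages
#' can be scored against truth. Fully deterministic for a fixed seed.
#'
#' @param template A [beat_template()].
#' @param dispersion A [dispersion_spec()].
#' @param duration_s Record length, seconds.
#' @param fs Sampling rate, Hz.
#' @param subject_id Identifier stored on the record.
#' @return A list of class `synthetic_ecg` with elements `record`
#'   (an [ecg_record()]) and `truth` (tibble of per-beat fiducial sample
#'   indices and the applied T-wave factors; beats whose T end falls past
#'   the record edge are flagged `truncated`).
#' @export
simulate_ecg <- function(template = beat_template(),
                         dispersion = dispersion_spec(),
                         duration_s = 20, fs = 1000,
                         subject_id = "synthetic") {
  stopifnot(inherits(template, "beat_template"),
            inherits(dispersion, "dispersion_spec"))
  period <- 60 / template$heart_rate
  if (duration_s < period) {
    abort("synthetic_data: duration too short for a single beat.")
  }
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  # beats whose QRS completes inside the record are generated; a final beat
  # whose T wave runs past the record edge is emitted flagged `truncated`
  onsets <- seq(0, by = period,
                length.out = floor((duration_s - 0.3) / period) + 1)
  n_beats <- length(onsets)

  with_local_seed(dispersion$seed, {
    amp_f <- rep(1, n_beats)
    wid_f <- rep(1, n_beats)
    if (dispersion$stt_jitter > 0) {
      amp_f <- pmax(0.3, 1 + dispersion$stt_jitter * rnorm(n_beats))
      wid_f <- pmax(0.3, 1 + dispersion$stt_jitter * rnorm(n_beats))
    }
    if (dispersion$alternans) {
      amp_f <- amp_f * ifelse(seq_len(n_beats) %% 2 == 0, 1.15, 0.85)
    }
    leads <- template$amplitudes
    waves <- colnames(leads)
    sig <- matrix(0, n, nrow(leads), dimnames = list(NULL, rownames(leads)))
    for (b in seq_len(n_beats)) {
      on <- onsets[b]
      for (w in waves) {
        cw <- on + template$centers_s[[w]]
        ww <- template$widths_s[[w]]
        aw <- 1
        if (w %in% c("T", "T2")) { ww <- ww * wid_f[b]; aw <- amp_f[b] }
        lo <- max(1L, floor((cw - 8 * ww) * fs) + 1L)
        hi <- min(n, ceiling((cw + 8 * ww) * fs) + 1L)
        if (lo > n || hi < 1) next
        g <- exp(-0.5 * ((t[lo:hi] - cw) / ww)^2)
        sig[lo:hi, ] <- sig[lo:hi, ] + outer(g * aw, leads[, w])
      }
      if (dispersion$st_shift_mv != 0) {
        j_s <- on + template$centers_s[["R"]] + 0.040
        te_s <- on + template$centers_s[["T"]] + 2 * template$widths_s[["T"]] * wid_f[b]
        wshape <- st_window(t, j_s, te_s)
        profile <- ifelse(rownames(leads) == "aVR", -1, 1)
        sig <- sig + outer(wshape * dispersion$st_shift_mv, profile)
      }
    }
    if (dispersion$noise_mv > 0) {
      sig <- sig + matrix(rnorm(length(sig), sd = dispersion$noise_mv),
                          nrow = n)
    }
    if (dispersion$baseline_wander_mv > 0) {
      phases <- runif(ncol(sig), 0, 2 * pi)
      for (k in seq_len(ncol(sig))) {
        sig[, k] <- sig[, k] +
          dispersion$baseline_wander_mv * sin(2 * pi * 0.15 * t + phases[k])
      }
    }

    r_s <- onsets + template$centers_s[["R"]]
    ta_s <- onsets + template$centers_s[["T"]]
    te_T <- ta_s + 2 * template$widths_s[["T"]] * wid_f
    te_s <- te_T
    if ("T2" %in% names(template$centers_s) &&
        any(template$amplitudes[, "T2"] != 0)) {
      te_T2 <- onsets + template$centers_s[["T2"]] +
        2 * template$widths_s[["T2"]] * wid_f
      te_s <- pmax(te_T, te_T2)
    }
    truth <- tibble(
      beat = seq_len(n_beats),
      r_peak = round(r_s * fs) + 1L,
      j_point = round((r_s + 0.040) * fs) + 1L,
      t_apex = round(ta_s * fs) + 1L,
      t_end = round(te_s * fs) + 1L,
      t_amp_factor = amp_f,
      t_width_factor = wid_f,
      truncated = round(te_s * fs) + 1L > n
    )
    truth <- truth[truth$r_peak <= n, ]

    structure(
      list(record = ecg_record(as.data.frame(sig), fs = fs,
                               subject_id = subject_id),
           truth = truth, template = template, dispersion = dispersion),
      class = "synthetic_ecg")
  })
}
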