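vcg_magnitude <- function(vcg) sqrt(vcg$x^2 + vcg$y^2 + vcg$z^2)

# centered moving average, same length
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2)) -> y
  # fill edge NAs with nearest computed value
  first_ok <- which(!is.na(y))[1]
  last_ok <- tail(which(!is.na(y)), 1)
  y[seq_len(first_ok - 1L)] <- y[first_ok]
  if (last_ok < length(y)) y[seq(last_ok + 1L, length(y))] <- y[last_ok]
  y
}

#' Detect R peaks on a vectorcardiogram
#'
#' Pan--Tompkins-style detector run on the VCG magnitude
#' \eqn{\sqrt{X^2+Y^2+Z^2}} (or, optionally, on the single VCG lead with the
#' largest median absolute R deflection): zero-phase 5--15 Hz band-pass,
#' derivative, squaring, 150 ms moving-window integration, then peak picking
#' with an adaptive (purely relative, hence amplitude-scale-invariant)
#' threshold and a 200 ms refractory period. Each detection is refined to the
#' local maximum of the raw magnitude.
#'
#' @param vcg A [vcg_record()] of at least 2 s.
#' @param channel `"magnitude"` (default) or `"dominant_lead"`.
#' @param refractory_s Minimum inter-beat spacing, seconds.
#' @param threshold_frac Detection threshold as a fraction of the upper-
#'   percentile integrator amplitude.
#' @return Sorted integer vector of R-peak sample indices (1-based).
#' @export
detect_r_peaks <- function(vcg, channel = c("magnitude", "dominant_lead"),
                           refractory_s = 0.2, threshold_frac = 0.3) {
  stopifnot(inherits(vcg, "vcg_record"))
  channel <- match.arg(channel)
  fs <- attr(vcg, "fs")
  if (nrow(vcg) < 2 * fs) abort("fiducials: record shorter than 2 s.")
  m <- if (channel == "magnitude") {
    vcg_magnitude(vcg)
  } else {
    amps <- vapply(vcg[c("x", "y", "z")], function(v) median(abs(v)) + max(abs(v)),
                   numeric(1))
    abs(vcg[[names(which.max(amps))]])
  }
  if (sd(m) < 1e-7) {
    abort("fiducials: flat signal, no beats detectable.",
          class = "cardiodyn_no_beats_error")
  }
  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  f <- filtfilt_padded(bp$b, bp$a, m - mean(m), as.integer(fs))
  integ <- moving_average(c(diff(f), 0)^2, round(0.15 * fs))
  thr <- threshold_frac * quantile(integ, 0.99, names = FALSE)
  n <- length(integ)
  is_peak <- c(FALSE, integ[2:(n - 1)] > integ[1:(n - 2)] &
                 integ[2:(n - 1)] >= integ[3:n], FALSE) & integ > thr
  cand <- which(is_peak)
  if (!length(cand)) {
    abort("fiducials: no QRS-like activity above threshold.",
          class = "cardiodyn_no_beats_error")
  }
  # greedy refractory enforcement, strongest peaks first
  keep <- logical(length(cand))
  ord <- order(integ[cand], decreasing = TRUE)
  taken <- integer(0)
  gap <- refractory_s * fs
  for (i in ord) {
    if (!length(taken) || all(abs(cand[i] - taken) >= gap)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  cand <- sort(cand[keep])
  # refine each detection to the raw-magnitude maximum nearby
  half <- round(0.1 * fs)
  r <- vapply(cand, function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    lo + which.max(m[lo:hi]) - 1
  }, numeric(1))
  sort(unique(as.integer(r)))
}

#' Locate per-beat fiducial points
#'
#' For each detected R peak, locates the J point (first point after R where
#' the magnitude-signal slope stays small for 10 ms, searched in
#' R+20..R+80 ms, falling back to R+40 ms), the T apex (largest absolute
#' deflection of the dominant T lead in the repolarization window) and the
#' T end (tangent method on the dominant T lead: the baseline crossing of
#' the tangent at the steepest post-apex slope). Beats whose window is
#' truncated by the record edge or whose ordering cannot be resolved are
#' dropped.
#'
#' @param vcg A [vcg_record()].
#' @param r_peaks Integer R-peak indices from [detect_r_peaks()].
#' @return A tibble of class `fiducial_set` with columns `beat`, `r_peak`,
#'   `j_point`, `t_apex`, `t_end` (1-based sample indices) and attribute
#'   `fs`; invariant `r_peak < j_point < t_apex < t_end` per row.
#' @export
locate_fiducials <- function(vcg, r_peaks) {
  stopifnot(inherits(vcg, "vcg_record"))
  if (!length(r_peaks)) abort("fiducials: need at least one R peak.")
  fs <- attr(vcg, "fs")
  n <- nrow(vcg)
  m <- vcg_magnitude(vcg)
  slope <- c(diff(m), 0) * fs
  rr <- if (length(r_peaks) > 1) median(diff(r_peaks)) else fs
  hold <- max(1L, round(0.010 * fs))

  one_beat <- function(r, next_r) {
    j_lo <- r + round(0.020 * fs); j_hi <- r + round(0.080 * fs)
    if (j_hi + hold > n) return(NULL)
    qrs_slope <- max(abs(slope[max(1L, r - round(0.06 * fs)):j_hi]))
    j <- NA_integer_
    for (i in j_lo:j_hi) {
      if (max(abs(slope[i:(i + hold - 1L)])) < 0.05 * qrs_slope) { j <- i; break }
    }
    if (is.na(j)) j <- r + round(0.040 * fs)
    t_nom <- r + round(0.55 * rr)
    if (t_nom > n) return(NULL)  # repolarization window truncated by record edge
    t_hi <- min(t_nom, if (is.na(next_r)) n else next_r - round(0.08 * fs))
    t_lo <- j + round(0.060 * fs)
    if (t_hi - t_lo < round(0.05 * fs)) return(NULL)
    win <- t_lo:t_hi
    dom <- names(which.max(vapply(vcg[c("x", "y", "z")],
                                  function(v) max(abs(v[win])), numeric(1))))
    s <- vcg[[dom]]
    if (s[win[which.max(abs(s[win]))]] < 0) s <- -s
    t_apex <- win[which.max(s[win])]
    d_hi <- min(t_apex + round(0.20 * fs), n - 1L,
                if (is.na(next_r)) n - 1L else next_r - 1L)
    if (d_hi <= t_apex + 1L) return(NULL)
    seg <- (t_apex + 1L):d_hi
    ds <- (s[seg + 1L] - s[seg]) * fs
    i_star <- seg[which.min(ds)]
    sl <- (s[i_star + 1L] - s[i_star]) * fs
    if (sl >= 0) return(NULL)
    # tangent rule relative to the local baseline (TP segment before this
    # beat's P wave)
    base_win <- max(1L, r - round(0.200 * fs)):max(1L, r - round(0.140 * fs))
    baseline <- median(s[base_win])
    t_end <- i_star + as.integer(round((s[i_star] - baseline) / (-sl) * fs))
    if (!is.na(next_r)) t_end <- min(t_end, next_r - 1L)
    if (t_end > n || t_end <= t_apex || j >= t_apex || r >= j) return(NULL)
    c(r_peak = r, j_point = j, t_apex = t_apex, t_end = t_end)
  }

  rows <- purrr::compact(purrr::map(seq_along(r_peaks), function(b) {
    one_beat(r_peaks[b],
             if (b < length(r_peaks)) r_peaks[b + 1L] else NA_integer_)
  }))
  if (!length(rows)) {
    abort("fiducials: no beat yielded a resolvable fiducial set.",
          class = "cardiodyn_fiducial_error")
  }
  out <- as_tibble(do.call(rbind, rows))
  out <- dplyr::mutate(out, beat = dplyr::row_number(), .before = 1)
  attr(out, "fs") <- fs
  attr(out, "subject_id") <- attr(vcg, "subject_id")
  class(out) <- c("fiducial_set", class(out))
  out
}

#' Export fiducials as CSV
#'
#' @param fids A `fiducial_set` from [locate_fiducials()].
#' @param path Output file.
#' @export
write_fiducials <- function(fids, path) {
  readr::write_csv(as_tibble(as.data.frame(fids)), path, progress = FALSE)
  invisible(path)
}

#' Extract per-beat ST-T loops from a vectorcardiogram
#'
#' Cuts the segment from J point to T end (inclusive) out of each beat and
#' resamples it, per axis and by linear interpolation, to exactly `n_points`
#' points, producing the per-beat 3-D repolarization loops that the
#' cardiodynamics model is trained on. If `n_points` exceeds the raw segment
#' length the loop is interpolated upward with a warning.
#'
#' @param vcg A [vcg_record()].
#' @param fids A `fiducial_set`.
#' @param n_points Points per loop (L), at least 16; default 100.
#' @return A tibble of class `stt_loops` with columns `beat`, `point`,
#'   `x`, `y`, `z` and attributes `L`, `n_beats`, `fs`.
#' @export
extract_stt_loops <- function(vcg, fids, n_points = 100) {
  stopifnot(inherits(vcg, "vcg_record"), inherits(fids, "fiducial_set"))
  if (!nrow(fids)) abort("fiducials: empty fiducial set.")
  if (n_points < 16) abort("fiducials: n_points must be >= 16.")
  raw_lens <- fids$t_end - fids$j_point + 1L
  if (any(raw_lens < n_points)) {
    warn("fiducials: some ST-T segments are shorter than n_points; interpolating upward.")
  }
  loops <- purrr::map_dfr(seq_len(nrow(fids)), function(b) {
    idx <- fids$j_point[b]:fids$t_end[b]
    u <- seq(0, 1, length.out = length(idx))
    v <- seq(0, 1, length.out = n_points)
    tibble(
      beat = b, point = seq_len(n_points),
      x = approx(u, vcg$x[idx], xout = v)$y,
      y = approx(u, vcg$y[idx], xout = v)$y,
      z = approx(u, vcg$z[idx], xout = v)$y
    )
  })
  attr(loops, "L") <- as.integer(n_points)
  attr(loops, "n_beats") <- nrow(fids)
  attr(loops, "fs") <- attr(vcg, "fs")
  attr(loops, "subject_id") <- attr(vcg, "subject_id")
  class(loops) <- c("stt_loops", class(loops))
  loops
}

# N x 3 matrix of loop points in beat order
loops_matrix <- function(loops) {
  cbind(x = loops$x, y = loops$y, z = loops$z)
}

#' Construct a fiducial set from explicit indices
#'
#' Builds the `fiducial_set` container from per-beat indices, e.g. the
#' ground-truth fiducials emitted by [simulate_ecg()], so downstream stages
#' can be driven by known-true beat anatomy instead of the detector.
#'
#' @param data Data frame with columns `r_peak`, `j_point`, `t_apex`,
#'   `t_end` (1-based sample indices).
#' @param fs Sampling rate, Hz.
#' @param subject_id Identifier.
#' @return A `fiducial_set` tibble.
#' @export
as_fiducial_set <- function(data, fs, subject_id = "anonymous") {
  need <- c("r_peak", "j_point", "t_apex", "t_end")
  stopifnot(is.data.frame(data), all(need %in% names(data)))
  out <- as_tibble(data[, need])
  ok <- out$r_peak < out$j_point & out$j_point < out$t_apex &
    out$t_apex < out$t_end
  if (!all(ok)) {
    abort("fiducials: rows must satisfy r_peak < j_point < t_apex < t_end.",
          class = "cardiodyn_fiducial_error")
  }
  out <- dplyr::mutate(out, beat = dplyr::row_number(), .before = 1)
  attr(out, "fs") <- fs
  attr(out, "subject_id") <- subject_id
  class(out) <- c("fiducial_set", class(out))
  out
}
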