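traj_matrix <- function(traj) {
  if (inherits(traj, "cdg_trajectory") || is.data.frame(traj)) {
    cbind(x = traj$x, y = traj$y, z = traj$z)
  } else {
    as.matrix(traj)
  }
}

#' Spatial heterogeneity index (SHI)
#'
#' Lyapunov-style mean log divergence of the CDG trajectory:
#' \deqn{SHI = \frac{1}{N'} \sum_n \ln(d_{n2} / d_{n1})}
#' where \eqn{d_{n1}} is the distance from point \eqn{n} to its nearest
#' neighbour \eqn{j} (temporal neighbours within the Theiler window excluded)
#' and \eqn{d_{n2}} the distance between the two points `step_k` steps later.
#' Points whose forward index falls outside the trajectory, or whose log
#' ratio is not finite (coincident points), are skipped and \eqn{N'} adjusted.
#' A zero nearest-neighbour distance falls through to the next-nearest
#' distinct neighbour.
#'
#' SHI is invariant under uniform scaling and translation of the trajectory.
#'
#' @param traj A `cdg_trajectory` (or any data frame / matrix of 3-D points).
#' @param step_k Divergence horizon in steps (default 10).
#' @param theiler Temporal exclusion half-width for the neighbour search;
#'   default one loop length when the trajectory carries an `L` attribute,
#'   otherwise 0 (literal nearest point).
#' @return The scalar SHI.
#' @export
compute_shi <- function(traj, step_k = 10, theiler = NULL) {
  P <- traj_matrix(traj)
  N <- nrow(P)
  if (N < step_k + 2) {
    abort("heterogeneity: trajectory too short for the requested horizon.",
          class = "cardiodyn_size_error")
  }
  theiler <- theiler %||% attr(traj, "L") %||% 0
  D <- as.matrix(stats::dist(P))
  if (all(D < .Machine$double.eps)) {
    abort("heterogeneity: degenerate trajectory (all points coincide).",
          class = "cardiodyn_degenerate_error")
  }
  idx <- seq_len(N)
  logs <- vapply(idx, function(n) {
    if (n + step_k > N) return(NA_real_)
    d_row <- D[n, ]
    valid <- abs(idx - n) > theiler & (idx + step_k) <= N
    if (!any(valid)) return(NA_real_)
    cand <- idx[valid]
    cand <- cand[order(d_row[cand])]
    # skip coincident neighbours: take the nearest with d > 0
    cand <- cand[d_row[cand] > 0]
    if (!length(cand)) return(NA_real_)
    j <- cand[1]
    d1 <- d_row[j]
    d2 <- sqrt(sum((P[n + step_k, ] - P[j + step_k, ])^2))
    val <- log(d2 / d1)
    if (is.finite(val)) val else NA_real_
  }, numeric(1))
  logs <- logs[is.finite(logs)]
  if (!length(logs)) {
    abort("heterogeneity: no point has a valid neighbour pair.",
          class = "cardiodyn_degenerate_error")
  }
  mean(logs)
}

#' Temporal heterogeneity index (THI)
#'
#' Minimiser of an exponentially damped Fourier objective over a grid of
#' candidate frequency-bin indices:
#' \deqn{THI = \arg\min_{\lambda_i} |F(\lambda_i)| e^{-0.1 \lambda_i}}
#' where, in the default `"norm"` mode, \eqn{F} is the magnitude spectrum of
#' the mean-removed Euclidean norm series \eqn{\|p_n\|} of the trajectory
#' (bin \eqn{\lambda} is the \eqn{\lambda}-th discrete Fourier coefficient).
#' The alternative `"per_axis"` mode averages the magnitude spectra of the
#' three coordinate series. Exact ties break to the smallest candidate.
#'
#' @param traj A `cdg_trajectory` (or data frame / matrix of 3-D points).
#' @param lambda_grid Sorted ascending candidate bin indices; default
#'   `1:floor(N/2)`.
#' @param spectrum_mode `"norm"` (default) or `"per_axis"`.
#' @return The selected \eqn{\lambda} (a scalar from `lambda_grid`).
#' @export
compute_thi <- function(traj, lambda_grid = NULL,
                        spectrum_mode = c("norm", "per_axis")) {
  spectrum_mode <- match.arg(spectrum_mode)
  P <- traj_matrix(traj)
  N <- nrow(P)
  if (N < 2) abort("heterogeneity: trajectory too short.")
  lambda_grid <- lambda_grid %||% seq_len(N %/% 2)
  if (!length(lambda_grid)) abort("heterogeneity: empty lambda grid.")
  if (is.unsorted(lambda_grid, strictly = TRUE)) {
    abort("heterogeneity: lambda_grid must be sorted strictly ascending.")
  }
  if (any(lambda_grid < 0) || any(lambda_grid > N - 1)) {
    abort("heterogeneity: lambda_grid indices must lie in 0..N-1.")
  }
  spec <- if (spectrum_mode == "norm") {
    s <- sqrt(rowSums(P^2))
    Mod(fft(s - mean(s)))
  } else {
    rowMeans(vapply(1:3, function(k) Mod(fft(P[, k] - mean(P[, k]))),
                    numeric(N)))
  }
  objective <- spec[lambda_grid + 1L] * exp(-0.1 * lambda_grid)
  lambda_grid[which.min(objective)]  # which.min already ties to the first
}

#' Compute both heterogeneity indices
#'
#' Convenience wrapper returning SHI and THI as a one-row tibble suitable
#' for piping into [cdg_score()].
#'
#' @inheritParams compute_shi
#' @inheritParams compute_thi
#' @return A tibble with columns `subject_id`, `shi`, `thi`, `n_points`,
#'   `step_k`.
#' @export
heterogeneity_indices <- function(traj, step_k = 10, theiler = NULL,
                                  lambda_grid = NULL,
                                  spectrum_mode = c("norm", "per_axis")) {
  tibble(
    subject_id = attr(traj, "subject_id") %||% NA_character_,
    shi = compute_shi(traj, step_k = step_k, theiler = theiler),
    thi = compute_thi(traj, lambda_grid = lambda_grid,
                      spectrum_mode = spectrum_mode),
    n_points = nrow(traj),
    step_k = step_k
  )
}
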