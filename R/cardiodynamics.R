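#' Build a radial-basis-function lattice over ST-T loops
#'
#' Places Gaussian kernel centers on a regular 3-D lattice covering the
#' bounding box of the loop points expanded by one lattice spacing on every
#' side, with all output weights initialised to zero. The default spacing is
#' one fifth of the largest axis range, which yields roughly 8 centers along
#' the longest axis (on the order of 8^3 for roughly isotropic loops). The
#' kernel width defaults to 1.5 lattice spacings; kernels are truncated at
#' three widths, so activation is exactly local.
#'
#' @param loops An `stt_loops` tibble from [extract_stt_loops()].
#' @param spacing Lattice spacing in mV; default `max(axis range) / 5`.
#' @param width Kernel width in mV; default `1.5 * spacing`.
#' @param max_centers Cap on the number of centers; exceeding it is an error.
#' @return A list of class `rbf_network` with elements `centers` (M x 3),
#'   `width`, `weights` (M x 3, zeros), `wbar` (M x 3, zeros), `spacing`.
#' @export
rbf_lattice <- function(loops, spacing = NULL, width = NULL,
                        max_centers = 20000) {
  P <- loops_matrix(loops)
  if (!nrow(P)) abort("cardiodynamics: empty loop set.")
  rng <- apply(P, 2, range)
  if (is.null(spacing)) {
    spacing <- max(rng[2, ] - rng[1, ]) / 5
    if (spacing <= 0) spacing <- 1
  }
  if (spacing <= 0) abort("cardiodynamics: spacing must be positive.")
  axes <- lapply(1:3, function(k) {
    lo <- rng[1, k] - spacing
    hi <- rng[2, k] + spacing
    n_axis <- floor((hi - lo) / spacing + 1e-9) + 1L
    lo + spacing * (seq_len(n_axis) - 1L)
  })
  m_total <- prod(lengths(axes))
  if (m_total > max_centers) {
    abort(sprintf(
      "cardiodynamics: spacing %g would create %d centers (cap %d).",
      spacing, m_total, max_centers), class = "cardiodyn_size_error")
  }
  centers <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
  dimnames(centers) <- list(NULL, c("x", "y", "z"))
  structure(
    list(centers = centers, width = width %||% (1.5 * spacing),
         weights = matrix(0, nrow(centers), 3),
         wbar = matrix(0, nrow(centers), 3),
         spacing = spacing, params = NULL),
    class = "rbf_network")
}

#' @export
print.rbf_network <- function(x, ...) {
  cat(sprintf("<rbf_network> %d centers, width %.4g mV, %s\n",
              nrow(x$centers), x$width,
              if (is.null(x$params)) "untrained" else "trained"))
  invisible(x)
}

#' Kernel activations of an RBF network
#'
#' @param net An `rbf_network`.
#' @param points N x 3 matrix of query points.
#' @return N x M design matrix of truncated-Gaussian activations.
#' @export
rbf_activations <- function(net, points) {
  .rbf_design(as.matrix(points), net$centers, net$width)
}

#' Learn ST-T loop dynamics by deterministic learning
#'
#' Trains the RBF network to approximate the per-step state change of the
#' concatenated ST-T loop orbit using a discrete-time observer with a
#' sigma-modified gradient weight update:
#' \deqn{\hat x(k+1) = \hat x(k) - a(\hat x(k) - x(k)) + W^\top S(x(k))}
#' \deqn{W(k+1) = W(k) - \gamma S(x(k)) (\hat x(k+1)-x(k+1))^\top - \gamma\sigma W(k)}
#' where \eqn{S} are the Gaussian kernel activations. The weight update is
#' driven by the posterior (one-step-ahead) error, so each regressor is
#' paired with the error it produced. With `normalized = TRUE` (the
#' default) the adaptation gain is divided by \eqn{1 + \|S(x(k))\|^2} each
#' step, which keeps the discrete-time update stable regardless of kernel
#' overlap; the plain gradient (`normalized = FALSE`) diverges for
#' strongly overlapping kernels and then raises an instability error.
#' Training is fully deterministic.
#'
#' The learned dynamics reported downstream use the time average of the
#' weights over the final epoch, which smooths residual adaptation ripple.
#'
#' @param loops An `stt_loops` tibble (the training orbit, beats concatenated
#'   in order; the observer is re-initialised at each loop seam so the
#'   artificial jump between consecutive loops is never a training target).
#' @param net An `rbf_network` covering the loops.
#' @param gain_a Observer gain per step, in (0, 2).
#' @param gamma Adaptation rate, > 0.
#' @param sigma Weight-leakage rate, >= 0.
#' @param epochs Passes over the concatenated orbit, >= 1.
#' @param normalized Normalise the adaptation gain by the squared activation
#'   norm (recommended).
#' @param weight_cap Abort if the Frobenius norm of the weights exceeds this.
#' @return The network with trained `weights`, the final-epoch average
#'   `wbar`, and the training parameters recorded in `$params`.
#' @export
learn_dynamics <- function(loops, net, gain_a = 0.5, gamma = 0.5,
                           sigma = 1e-4, epochs = 20, normalized = TRUE,
                           weight_cap = 1e6) {
  stopifnot(inherits(net, "rbf_network"))
  if (gain_a <= 0 || gamma < 0 || sigma < 0 || epochs < 1) {
    abort("cardiodynamics: invalid learning parameters.")
  }
  P <- loops_matrix(loops)
  S <- rbf_activations(net, P)
  L <- as.integer(attr(loops, "L") %||% nrow(P))
  fit <- tryCatch(
    .dl_train(S, P, L, gain_a, gamma, sigma, as.integer(epochs), normalized,
              weight_cap),
    error = function(e) {
      abort(paste0("cardiodynamics: ", conditionMessage(e)),
            class = "cardiodyn_instability_error")
    })
  net$weights <- fit$weights
  net$wbar <- fit$wbar
  net$params <- list(gain_a = gain_a, gamma = gamma, sigma = sigma,
                     epochs = epochs, normalized = normalized)
  net
}

#' Generate the cardiodynamicsgram trajectory
#'
#' Evaluates the learned dynamics \eqn{\bar W^\top S(x)} at every point of
#' the ST-T orbit, in beat order, producing the N = n_beats x L 3-D points
#' whose spatial dispersion indexes repolarization heterogeneity. A network
#' with all-zero weights yields an all-zero trajectory with a warning.
#'
#' @param net A trained `rbf_network`.
#' @param loops The `stt_loops` the trajectory is evaluated along.
#' @return A tibble of class `cdg_trajectory` with columns `n`, `beat`,
#'   `point`, `x`, `y`, `z` and attributes `L`, `n_beats`, `subject_id`.
#' @export
generate_cdg <- function(net, loops) {
  stopifnot(inherits(net, "rbf_network"))
  P <- loops_matrix(loops)
  if (all(net$wbar == 0)) {
    warn("cardiodynamics: network weights are all zero; trajectory is identically zero.")
  }
  D <- rbf_activations(net, P) %*% net$wbar
  out <- tibble(
    n = seq_len(nrow(P)),
    beat = loops$beat, point = loops$point,
    x = D[, 1], y = D[, 2], z = D[, 3]
  )
  attr(out, "L") <- attr(loops, "L")
  attr(out, "n_beats") <- attr(loops, "n_beats")
  attr(out, "subject_id") <- attr(loops, "subject_id")
  class(out) <- c("cdg_trajectory", class(out))
  out
}

#' One-step dynamics prediction error of a trained network
#'
#' Root-mean-square difference between the learned per-step state change
#' \eqn{\bar W^\top S(x_k)} and the observed change \eqn{x_{k+1}-x_k} along
#' the training orbit (loop-seam steps excluded), expressed relative to the
#' mean step magnitude. Used as the self-consistency measure of
#' deterministic learning.
#'
#' @param net A trained `rbf_network`.
#' @param loops The training `stt_loops`.
#' @return A list with `rmse`, `mean_step` and their ratio `relative`.
#' @export
prediction_error <- function(net, loops) {
  P <- loops_matrix(loops)
  L <- attr(loops, "L") %||% nrow(P)
  pred <- rbf_activations(net, P) %*% net$wbar
  actual <- diff(P)
  within <- which(seq_len(nrow(P) - 1) %% L != 0)  # drop loop-seam steps
  resid <- pred[within, , drop = FALSE] - actual[within, , drop = FALSE]
  rmse <- sqrt(mean(rowSums(resid^2)))
  mean_step <- mean(sqrt(rowSums(actual[within, , drop = FALSE]^2)))
  list(rmse = rmse, mean_step = mean_step, relative = rmse / mean_step)
}

#' Serialize / restore a trained RBF network
#'
#' Writes centers, width, weights, weight average and training parameters to
#' a single JSON archive.
#'
#' @param net An `rbf_network`.
#' @param path JSON file path.
#' @export
write_rbf_network <- function(net, path) {
  jsonlite::write_json(
    list(centers = net$centers, width = net$width, weights = net$weights,
         wbar = net$wbar, spacing = net$spacing, params = net$params),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rbf_network
#' @export
read_rbf_network <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(centers = as.matrix(j$centers), width = j$width,
         weights = as.matrix(j$weights), wbar = as.matrix(j$wbar),
         spacing = j$spacing, params = j$params),
    class = "rbf_network")
}
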