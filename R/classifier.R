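#' The CDG linear classifier
#'
#' The CDG value is the signed distance-like score of a patient's
#' heterogeneity indices from a linear decision boundary in (THI, SHI)
#' space:
#' \deqn{CDG = w_{THI} \cdot THI + w_{SHI} \cdot SHI + b}
#' The shipped default (`version = "paper-2023"`) freezes the published
#' coefficients \eqn{-0.0556 \cdot THI + 30.8131 \cdot SHI - 2.7719} with
#' decision threshold 0 (score >= 0 is called positive).
#'
#' @param w_thi Coefficient per THI unit.
#' @param w_shi Coefficient per SHI unit.
#' @param bias Intercept.
#' @param threshold Decision cut on the score.
#' @param version Version tag recorded with the model.
#' @return A list of class `cdg_classifier`.
#' @export
cdg_classifier <- function(w_thi = -0.0556, w_shi = 30.8131, bias = -2.7719,
                           threshold = 0, version = "paper-2023") {
  vals <- c(w_thi, w_shi, bias, threshold)
  if (!all(is.finite(vals))) abort("classifier: coefficients must be finite.")
  structure(list(w_thi = w_thi, w_shi = w_shi, bias = bias,
                 threshold = threshold, version = version),
            class = "cdg_classifier")
}

#' @export
print.cdg_classifier <- function(x, ...) {
  cat(sprintf("<cdg_classifier %s> score = %.4f*THI + %.4f*SHI + %.4f; positive iff score >= %g\n",
              x$version, x$w_thi, x$w_shi, x$bias, x$threshold))
  invisible(x)
}

#' CDG value and binary call from heterogeneity indices
#'
#' `cdg_score()` is data-frame-first: given a tibble with `shi` and `thi`
#' columns (e.g. from [heterogeneity_indices()]) it appends `cdg_value` and
#' `call`. `cdg_value()` and `classify_cdg()` are the scalar-friendly
#' primitives.
#'
#' @param data Data frame with numeric columns `shi` and `thi`.
#' @param classifier A [cdg_classifier()].
#' @return `data` with `cdg_value` (numeric) and `call`
#'   (`"positive"`/`"negative"`) columns appended.
#' @export
cdg_score <- function(data, classifier = cdg_classifier()) {
  stopifnot(is.data.frame(data), all(c("shi", "thi") %in% names(data)))
  dplyr::mutate(
    as_tibble(data),
    cdg_value = cdg_value(.data$shi, .data$thi, classifier),
    call = classify_cdg(.data$cdg_value, classifier)
  )
}

#' @rdname cdg_score
#' @param shi,thi Numeric vectors of index values.
#' @export
cdg_value <- function(shi, thi, classifier = cdg_classifier()) {
  if (!all(is.finite(shi)) || !all(is.finite(thi))) {
    abort("classifier: SHI/THI must be finite.")
  }
  classifier$w_thi * thi + classifier$w_shi * shi + classifier$bias
}

#' @rdname cdg_score
#' @param score Numeric vector of CDG values.
#' @export
classify_cdg <- function(score, classifier = cdg_classifier()) {
  if (!all(is.finite(score))) abort("classifier: scores must be finite.")
  ifelse(score >= classifier$threshold, "positive", "negative")
}

#' Retrain the CDG classifier (research mode)
#'
#' Fits a linear-kernel support vector machine on (THI, SHI) features and
#' converts the fitted hyperplane to a [cdg_classifier()]. This reproduces
#' the training procedure, not the shipped coefficients (their training
#' population is not distributed with the package).
#'
#' @param data Data frame with columns `shi`, `thi` and `label` (0/1 or
#'   logical; 1 = positive class).
#' @param cost SVM cost parameter.
#' @return A `cdg_classifier` with `version = "retrained"`.
#' @export
train_cdg_classifier <- function(data, cost = 1) {
  stopifnot(is.data.frame(data), all(c("shi", "thi", "label") %in% names(data)))
  y <- as.integer(data$label)
  if (length(unique(y)) < 2) {
    abort("classifier: need both classes to train.",
          class = "cardiodyn_training_error")
  }
  X <- cbind(thi = data$thi, shi = data$shi)
  fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                    cost = cost, scale = FALSE)
  # hyperplane: f(x) = w.x - rho, with f > 0 predicting the class libsvm
  # saw first (fit$labels[1]); flip so a positive score means class "1"
  w <- colSums(fit$coefs[, 1] * fit$SV)
  b <- -fit$rho
  if (fit$levels[fit$labels[1]] == "0") { w <- -w; b <- -b }
  cdg_classifier(w_thi = unname(w["thi"]), w_shi = unname(w["shi"]),
                 bias = b, threshold = 0, version = "retrained")
}

#' Serialize / restore a CDG classifier
#' @param classifier A `cdg_classifier`.
#' @param path JSON file.
#' @export
write_cdg_classifier <- function(classifier, path) {
  jsonlite::write_json(unclass(classifier), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cdg_classifier
#' @export
read_cdg_classifier <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cdg_classifier(j$w_thi, j$w_shi, j$bias, j$threshold, j$version)
}
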