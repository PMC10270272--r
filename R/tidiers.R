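#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a CDG classifier
#'
#' @param x A [cdg_classifier()].
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @method tidy cdg_classifier
#' @export
tidy.cdg_classifier <- function(x, ...) {
  tibble(term = c("thi", "shi", "(Intercept)"),
         estimate = c(x$w_thi, x$w_shi, x$bias))
}

#' @rdname tidy.cdg_classifier
#' @method glance cdg_classifier
#' @export
glance.cdg_classifier <- function(x, ...) {
  tibble(version = x$version, threshold = x$threshold)
}

#' Tidy a cohort evaluation
#'
#' `tidy()` returns one row per diagnostic metric; `glance()` returns the
#' one-row summary (counts, metrics, AUC, Spearman rho).
#'
#' @param x A `cdg_eval` from [run_cohort()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cdg_eval
#' @export
tidy.cdg_eval <- function(x, ...) {
  m <- x$metrics
  tibble(
    metric = c("sensitivity", "specificity", "ppv", "npv", "accuracy", "auc"),
    value = c(m$sensitivity, m$specificity, m$ppv, m$npv, m$accuracy,
              x$auc$auc)
  )
}

#' @rdname tidy.cdg_eval
#' @method glance cdg_eval
#' @export
glance.cdg_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble(standard = x$standard, calls = x$calls),
    x$metrics,
    dplyr::rename(x$auc, auc_ci_lo = "ci_lo", auc_ci_hi = "ci_hi"),
    dplyr::rename(x$spearman, spearman_rho = "rho", spearman_p = "p")
  )
}
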