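#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_path geom_point
#'   facet_wrap facet_grid labs theme_minimal geom_abline coord_equal vars
NULL

#' Plot an ECG record
#'
#' Stacked per-lead voltage traces over a time window.
#'
#' @param object An [ecg_record()].
#' @param t_max Seconds to show from the start of the record.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecg_record
#' @export
autoplot.ecg_record <- function(object, t_max = 5, ...) {
  fs <- ecg_fs(object)
  df <- as_tibble(as.data.frame(object))
  df$time_s <- (seq_len(nrow(df)) - 1) / fs
  df <- dplyr::filter(df, .data$time_s <= t_max)
  long <- tidyr::pivot_longer(df, -"time_s", names_to = "lead",
                              values_to = "mV")
  long$lead <- factor(long$lead, levels = intersect(LEADS_12, unique(long$lead)))
  ggplot(long, aes(x = .data$time_s, y = .data$mV)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(vars(.data$lead), ncol = 2, scales = "free_y") +
    labs(x = "time (s)", y = "voltage (mV)",
         title = paste("ECG record", ecg_subject(object))) +
    theme_minimal()
}

# long form of a 3-D point tibble as its three planar projections
projections_long <- function(df) {
  dplyr::bind_rows(
    tibble(plane = "X-Y", h = df$x, v = df$y, beat = df$beat),
    tibble(plane = "X-Z", h = df$x, v = df$z, beat = df$beat),
    tibble(plane = "Y-Z", h = df$y, v = df$z, beat = df$beat)
  )
}

#' Plot ST-T loops
#'
#' The per-beat 3-D loops shown as their three planar projections, coloured
#' by beat, so beat-to-beat repolarization dispersion is visible directly.
#'
#' @param object An `stt_loops` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stt_loops
#' @export
autoplot.stt_loops <- function(object, ...) {
  ggplot(projections_long(object),
         aes(x = .data$h, y = .data$v, group = .data$beat,
             colour = .data$beat)) +
    geom_path(alpha = 0.6, linewidth = 0.3) +
    facet_wrap(vars(.data$plane), scales = "free") +
    labs(x = "mV", y = "mV", colour = "beat", title = "ST-T loops") +
    theme_minimal()
}

#' Plot a CDG trajectory
#'
#' The learned cardiodynamics trajectory as its three planar projections.
#' A tight, regular (annular) figure indicates consistent beat-to-beat
#' repolarization; a scattered, irregular figure indicates heterogeneity.
#'
#' @param object A `cdg_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cdg_trajectory
#' @export
autoplot.cdg_trajectory <- function(object, ...) {
  ggplot(projections_long(object),
         aes(x = .data$h, y = .data$v, group = .data$beat,
             colour = .data$beat)) +
    geom_path(alpha = 0.6, linewidth = 0.3) +
    facet_wrap(vars(.data$plane), scales = "free") +
    labs(x = "learned dynamics", y = "learned dynamics", colour = "beat",
         title = paste("CDG trajectory", attr(object, "subject_id") %||% "")) +
    theme_minimal()
}

#' Plot the ROC curve of a cohort evaluation
#'
#' @param object A `cdg_eval` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cdg_eval
#' @export
autoplot.cdg_eval <- function(object, ...) {
  truths <- normalize_truths(object$truths)
  if (length(unique(truths)) < 2) {
    abort("cohort_eval: cannot draw a ROC curve for a single-class cohort.")
  }
  r <- pROC::roc(response = truths, predictor = object$scores,
                 levels = c("negative", "positive"), direction = "<",
                 quiet = TRUE)
  df <- tibble(fpr = 1 - r$specificities, tpr = r$sensitivities)
  df <- dplyr::arrange(df, .data$fpr, .data$tpr)
  ggplot(df, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_path() +
    coord_equal() +
    labs(x = "1 - specificity", y = "sensitivity",
         title = sprintf("ROC, reference standard %d (AUC %.3f)",
                         object$standard, object$auc$auc)) +
    theme_minimal()
}
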