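#' Stenosis bands
#'
#' CCTA stenosis severity is recorded as one of six ordered bands; band
#' comparisons against a percentage cut use the band's lower edge, so
#' "stenosis >= 50%" selects bands 50-69, 70-99 and 100.
#'
#' @format Character vector of band labels in increasing severity.
#' @export
STENOSIS_BANDS <- c("0", "1-24", "25-49", "50-69", "70-99", "100")

#' Lower edge of a stenosis band
#'
#' @param band Character vector of [STENOSIS_BANDS] labels.
#' @return Numeric vector of band lower edges in percent.
#' @export
stenosis_lower_edge <- function(band) {
  edges <- c("0" = 0, "1-24" = 1, "25-49" = 25, "50-69" = 50,
             "70-99" = 70, "100" = 100)
  bad <- setdiff(unique(band), names(edges))
  if (length(bad)) {
    abort(paste0("cohort_eval: unknown stenosis band(s): ",
                 paste(bad, collapse = ", ")))
  }
  unname(edges[band])
}

#' Reference standards for CAD positivity
#'
#' Each standard combines an anatomical cut on CCTA stenosis with a
#' hemodynamic cut on CT-FFR; a patient is positive when either arm fires:
#' standard 1 = (>= 50%, <= 0.8), 2 = (>= 50%, <= 0.7), 3 = (>= 70%, <= 0.8),
#' 4 = (>= 70%, <= 0.7).
#'
#' @param standard Integer 1--4.
#' @return A list with `stenosis_cut` (%) and `ctffr_cut`.
#' @export
reference_standard <- function(standard = 1) {
  if (!standard %in% 1:4) abort("cohort_eval: standard must be 1, 2, 3 or 4.")
  list(
    stenosis_cut = c(50, 50, 70, 70)[standard],
    ctffr_cut = c(0.8, 0.7, 0.8, 0.7)[standard]
  )
}

#' Label a cohort for CAD by a reference standard
#'
#' Appends a `cad_label` column: positive iff the stenosis band's lower edge
#' meets the stenosis cut OR CT-FFR is at or below the CT-FFR cut. Occluded
#' vessels are assigned a CT-FFR of 0.5 before comparison.
#'
#' @param data Cohort data frame with columns `stenosis_band`, `ctffr`, and
#'   optionally `occluded` (logical).
#' @param standard Integer 1--4, or a list from [reference_standard()].
#' @return `data` with `cad_label` (`"positive"`/`"negative"`) appended.
#' @export
label_cad <- function(data, standard = 1) {
  stopifnot(is.data.frame(data))
  std <- if (is.list(standard)) standard else reference_standard(standard)
  if (!all(c("stenosis_band", "ctffr") %in% names(data))) {
    abort("cohort_eval: cohort needs `stenosis_band` and `ctffr` columns.")
  }
  occluded <- if ("occluded" %in% names(data)) {
    data$occluded %in% TRUE
  } else {
    rep(FALSE, nrow(data))
  }
  ctffr <- ifelse(occluded, 0.5, data$ctffr)
  edge <- stenosis_lower_edge(data$stenosis_band)
  if (any(is.na(edge) & is.na(ctffr))) {
    abort("cohort_eval: rows with neither stenosis nor CT-FFR cannot be labeled.",
          class = "cardiodyn_label_error")
  }
  pos <- (!is.na(edge) & edge >= std$stenosis_cut) |
    (!is.na(ctffr) & ctffr <= std$ctffr_cut)
  dplyr::mutate(as_tibble(data),
                cad_label = ifelse(pos, "positive", "negative"))
}

# lead pairs regarded as anatomically adjacent for ischemia criteria
ADJACENT_LEAD_PAIRS <- list(
  c("V1", "V2"), c("V2", "V3"), c("V3", "V4"), c("V4", "V5"), c("V5", "V6"),
  c("II", "III"), c("III", "aVF"), c("II", "aVF"), c("I", "aVL")
)

#' Physician-style ischemia call from per-lead ST/T measurements
#'
#' Applies the resting-ECG ischemia criteria to measured features: (1) ST
#' elevation at or above 0.2 mV (men) / 0.15 mV (women) in V2--V3, or at or
#' above 0.1 mV in any other lead; (2) horizontal or down-sloping ST
#' depression of at least 0.05 mV in two adjacent leads; (3) T-wave
#' inversion of at least 0.1 mV in two adjacent leads with a prominent R
#' wave (R amplitude >= 0.5 mV) or R/S ratio > 1.
#'
#' @param features Data frame with one row per lead and columns `lead`,
#'   `st_dev_mv` (ST deviation, positive = elevation), `st_slope`
#'   (`"horizontal"`, `"downsloping"`, `"upsloping"`), `t_amp_mv`,
#'   `r_amp_mv`, `s_amp_mv`.
#' @param sex `"male"` or `"female"` (the V2--V3 elevation cut is
#'   sex-specific).
#' @return One-row tibble with the overall `call` and per-criterion flags.
#' @export
ecg_ischemia_call <- function(features, sex = c("male", "female")) {
  sex <- match.arg(sex)
  stopifnot(is.data.frame(features))
  need <- c("lead", "st_dev_mv", "st_slope", "t_amp_mv", "r_amp_mv", "s_amp_mv")
  if (!all(need %in% names(features))) {
    abort(paste0("cohort_eval: features must have columns ",
                 paste(need, collapse = ", ")))
  }
  bad <- setdiff(features$lead, LEADS_12)
  if (length(bad)) {
    abort(paste0("cohort_eval: unknown lead(s): ", paste(bad, collapse = ", ")))
  }
  f <- features
  v23_cut <- if (sex == "male") 0.20 else 0.15
  cut <- ifelse(f$lead %in% c("V2", "V3"), v23_cut, 0.10)
  st_elev <- any(f$st_dev_mv >= cut)

  pair_present <- function(flag) {
    ok <- f$lead[flag]
    any(vapply(ADJACENT_LEAD_PAIRS, function(p) all(p %in% ok), logical(1)))
  }
  st_dep <- pair_present(
    f$st_dev_mv <= -0.05 & f$st_slope %in% c("horizontal", "downsloping"))
  t_inv <- pair_present(
    f$t_amp_mv <= -0.10 &
      (f$r_amp_mv >= 0.5 | (abs(f$s_amp_mv) > 0 & f$r_amp_mv / abs(f$s_amp_mv) > 1)))

  tibble(
    call = if (st_elev || st_dep || t_inv) "positive" else "negative",
    st_elevation = st_elev, st_depression = st_dep, t_inversion = t_inv
  )
}

#' Confusion counts
#'
#' @param calls,truths Equal-length vectors of `"positive"`/`"negative"`.
#' @return One-row tibble with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(calls, truths) {
  if (length(calls) != length(truths)) {
    abort("cohort_eval: calls and truths must have equal length.")
  }
  tibble(
    tp = sum(calls == "positive" & truths == "positive"),
    tn = sum(calls == "negative" & truths == "negative"),
    fp = sum(calls == "positive" & truths == "negative"),
    fn = sum(calls == "negative" & truths == "positive")
  )
}

# half-up rounding to `digits` decimals (matches clinical-table formatting;
# base round() is round-half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity, specificity, PPV, NPV and accuracy as percentages rounded
#' half-up to two decimals. A metric with a zero denominator is reported as
#' `NA`, never as 0.
#'
#' @param tp,tn,fp,fn Confusion counts (scalars), or pass a one-row data
#'   frame with those columns as `tp`.
#' @return One-row tibble with the counts and the five metrics.
#' @export
diagnostic_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.data.frame(tp)) {
    cc <- tp
    tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  }
  n <- tp + tn + fp + fn
  if (n <= 0) abort("cohort_eval: empty confusion table.")
  pct <- function(num, den) if (den > 0) round_half_up(100 * num / den) else NA_real_
  tibble(
    tp = tp, tn = tn, fp = fp, fn = fn, n = n,
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    ppv = pct(tp, tp + fp),
    npv = pct(tn, tn + fn),
    accuracy = pct(tp + tn, n)
  )
}

#' ROC area under the curve with confidence interval
#'
#' Empirical (trapezoidal) AUC of a continuous score against binary truth,
#' oriented so that higher scores indicate the positive class, with a 95%
#' DeLong or stratified-bootstrap confidence interval.
#'
#' @param scores Numeric scores (e.g. CDG values).
#' @param truths `"positive"`/`"negative"` (or logical/0-1) truth labels.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param boot_n Bootstrap replicates when `ci_method = "bootstrap"`.
#' @return One-row tibble with `auc`, `ci_lo`, `ci_hi`.
#' @export
roc_auc <- function(scores, truths, ci_method = c("delong", "bootstrap"),
                    boot_n = 2000) {
  ci_method <- match.arg(ci_method)
  truths <- normalize_truths(truths)
  if (length(unique(truths)) < 2) {
    abort("cohort_eval: both classes must be present for ROC analysis.",
          class = "cardiodyn_single_class_error")
  }
  r <- pROC::roc(response = truths, predictor = as.numeric(scores),
                 levels = c("negative", "positive"), direction = "<",
                 quiet = TRUE)
  ci <- suppressWarnings(pROC::ci.auc(
    r, method = if (ci_method == "delong") "delong" else "bootstrap",
    boot.n = boot_n, progress = "none"))
  tibble(auc = as.numeric(pROC::auc(r)),
         ci_lo = as.numeric(ci[1]), ci_hi = as.numeric(ci[3]))
}

normalize_truths <- function(truths) {
  if (is.logical(truths)) return(ifelse(truths, "positive", "negative"))
  if (is.numeric(truths)) return(ifelse(truths > 0, "positive", "negative"))
  as.character(truths)
}

#' Spearman rank correlation
#'
#' Rank correlation (average ranks for ties) between two numeric vectors,
#' typically CDG values and CT-FFR. Returns `NA` with a warning when either
#' vector is constant.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return One-row tibble with `rho` and `p`.
#' @export
spearman_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("cohort_eval: need at least 3 paired observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("cohort_eval: constant vector; Spearman correlation undefined.")
    return(tibble(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(rho = unname(ct$estimate), p = ct$p.value)
}
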