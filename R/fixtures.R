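#' Frozen reference tables of the paper-2023 evaluation cohort
#'
#' The published summary tables that accompany the frozen `paper-2023`
#' classifier are shipped as in-package constants for exact regression
#' tests: `table2_counts()` returns the 2 x 4 cross-tabulation of CDG call
#' against the CCTA-50% / CT-FFR-0.8 cells (n = 362), and `table3_counts()`
#' the TP/TN/FP/FN rows of the physician ECG reading and of the CDG under
#' the four reference standards.
#'
#' @return `table2_counts()`: a 2 x 4 integer matrix with CDG calls as rows.
#'   `table3_counts()`: a tibble with columns `row`, `tp`, `tn`, `fp`, `fn`.
#' @export
table2_counts <- function() {
  m <- rbind(
    cdg_negative = c(161L, 7L, 6L, 28L),
    cdg_positive = c(33L, 36L, 9L, 82L)
  )
  colnames(m) <- c("ccta_lt50_ffr_gt0.8", "ccta_lt50_ffr_le0.8",
                   "ccta_ge50_ffr_gt0.8", "ccta_ge50_ffr_le0.8")
  m
}

#' @rdname table2_counts
#' @export
table3_counts <- function() {
  tibble(
    row = c("ecg", "standard1", "standard2", "standard3", "standard4"),
    tp = c(64L, 127L, 119L, 120L, 112L),
    tn = c(119L, 161L, 168L, 165L, 180L),
    fp = c(75L, 33L, 41L, 40L, 48L),
    fn = c(104L, 41L, 34L, 37L, 22L)
  )
}

#' Synthetic per-patient cohort consistent with the frozen reference tables
#'
#' Reconstructs a 362-row per-patient table whose cell counts reproduce the
#' published cross-tabulation exactly and whose within-cell stenosis-band /
#' CT-FFR assignments are chosen so that labeling under every reference
#' standard (1--4) reproduces the published TP/TN/FP/FN rows, and the
#' simulated physician ECG calls reproduce the published ECG confusion row.
#' The individual rows are synthetic (the patient-level data are not
#' distributed); only the aggregate counts are anchored.
#'
#' Representative CT-FFR values encode the cells: 0.85 for "> 0.8", 0.75 for
#' "(0.7, 0.8]", 0.60 for "<= 0.7"; occluded vessels carry `occluded = TRUE`
#' (CT-FFR treated as 0.5 by [label_cad()]).
#'
#' @return A tibble with columns `subject_id`, `stenosis_band`, `ctffr`,
#'   `occluded`, `ecg_call`, `cdg_value`.
#' @export
fixture_cohort <- function() {
  cell <- function(n, cdg_sign, band, ctffr, occluded = FALSE) {
    tibble(n = n, cdg_sign = cdg_sign, stenosis_band = band, ctffr = ctffr,
           occluded = occluded)
  }
  cells <- dplyr::bind_rows(
    # CDG-negative rows (202)
    cell(86, -1, "0", 0.85), cell(50, -1, "1-24", 0.85), cell(25, -1, "25-49", 0.85),
    cell(7, -1, "25-49", 0.75),
    cell(4, -1, "50-69", 0.85), cell(2, -1, "70-99", 0.85),
    cell(8, -1, "50-69", 0.75), cell(6, -1, "50-69", 0.60),
    cell(14, -1, "70-99", 0.60),
    # CDG-positive rows (160)
    cell(9, 1, "0", 0.85), cell(10, 1, "1-24", 0.85), cell(14, 1, "25-49", 0.85),
    cell(6, 1, "1-24", 0.60), cell(22, 1, "25-49", 0.60), cell(8, 1, "25-49", 0.75),
    cell(7, 1, "50-69", 0.85), cell(2, 1, "70-99", 0.85),
    cell(40, 1, "50-69", 0.60), cell(18, 1, "70-99", 0.60),
    cell(12, 1, "70-99", 0.75), cell(12, 1, "100", 0.50, occluded = TRUE)
  )
  rows <- tidyr::uncount(cells, weights = .data$n)
  # deterministic graded CDG values inside each sign class
  neg <- rows$cdg_sign < 0
  rows$cdg_value <- NA_real_
  rows$cdg_value[neg] <- seq(-5, -0.01, length.out = sum(neg))
  rows$cdg_value[!neg] <- seq(0.01, 3, length.out = sum(!neg))
  # physician ECG calls reproducing the published ECG confusion row against
  # standard-1 truth: 64 of 168 positives and 75 of 194 negatives read positive
  truth1 <- label_cad(rows, standard = 1)$cad_label
  rows$ecg_call <- "negative"
  ipos <- which(truth1 == "positive")
  ineg <- which(truth1 == "negative")
  rows$ecg_call[ipos[seq_len(64)]] <- "positive"
  rows$ecg_call[ineg[seq_len(75)]] <- "positive"
  dplyr::select(
    dplyr::mutate(rows, subject_id = sprintf("fix%03d", dplyr::row_number())),
    "subject_id", "stenosis_band", "ctffr", "occluded", "ecg_call", "cdg_value"
  )
}
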