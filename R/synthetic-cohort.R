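#' Simulate a diagnostic cohort table
#'
#' Draws a joint distribution of latent CAD status, CDG value, CT-FFR,
#' CCTA stenosis band and physician ECG call that mirrors the structure of a
#' suspected-CAD screening cohort: positives (by reference standard 1)
#' receive a higher mean CDG value and lower CT-FFR, stenosis bands are
#' sampled from class-conditional frequencies, and CT-FFR is rank-coupled to
#' the CDG value within class so the overall association is negative.
#' By construction, standard-1 labeling of the emitted rows recovers the
#' latent status exactly.
#'
#' @param n Number of patients (>= 10).
#' @param prevalence Fraction positive, in (0, 1).
#' @param effect Mean CDG-value separation between classes (mV-free score
#'   units; the class SD is 1.5, so `effect = 4.5` is a 3-SD separation).
#' @param rho_target Desired (negative) CDG--CT-FFR rank association; the
#'   achievable strength is limited by the class structure, so targets
#'   beyond -0.9 trigger a best-effort warning.
#' @param ecg_sens,ecg_fpr Sensitivity and false-positive rate of the
#'   simulated physician ECG reading.
#' @param seed RNG seed.
#' @return A tibble with columns `subject_id`, `stenosis_band`, `ctffr`,
#'   `occluded`, `ecg_call`, `cdg_value`.
#' @export
simulate_cohort <- function(n = 362, prevalence = 0.4641, effect = 3.11,
                            rho_target = -0.395, ecg_sens = 0.381,
                            ecg_fpr = 0.387, seed = NULL) {
  if (n < 10) abort("synthetic_data: n must be >= 10.")
  if (prevalence <= 0 || prevalence >= 1) {
    abort("synthetic_data: prevalence must be in (0, 1).")
  }
  if (rho_target > 0) {
    warn("synthetic_data: rho_target is expected to be negative (higher CDG, lower CT-FFR).")
  }
  if (abs(rho_target) > 0.9) {
    warn("synthetic_data: |rho_target| > 0.9 is infeasible under the class structure; using best effort.")
  }
  couple <- min(abs(rho_target), 0.9)
  sd_class <- 1.5

  with_local_seed(seed, {
    pos <- rbinom(n, 1, prevalence) == 1
    cdg <- rnorm(n, mean = ifelse(pos, -2.24 + effect, -2.24), sd = sd_class)
    # rank-couple CT-FFR to CDG within class via a Gaussian copula
    z <- numeric(n)
    for (cls in c(TRUE, FALSE)) {
      i <- which(pos == cls)
      if (length(i) < 2) { z[i] <- rnorm(length(i)); next }
      zc <- scale(cdg[i])[, 1]
      z[i] <- couple * zc + sqrt(1 - couple^2) * rnorm(length(i))
    }
    u <- stats::pnorm(z)  # high u ~ high CDG ~ low FFR
    ctffr <- numeric(n)
    band <- character(n)
    # negatives: no obstructive stenosis, CT-FFR above 0.8
    i <- which(!pos)
    ctffr[i] <- 0.81 + 0.14 * (1 - u[i])
    band[i] <- sample(c("0", "1-24", "25-49"), length(i), replace = TRUE,
                      prob = c(0.44, 0.31, 0.25))
    # positives: ~9% have preserved CT-FFR but obstructive stenosis
    i <- which(pos)
    preserved <- runif(length(i)) < 0.09
    ctffr[i[preserved]] <- runif(sum(preserved), 0.81, 0.92)
    band[i[preserved]] <- sample(c("50-69", "70-99"), sum(preserved),
                                 replace = TRUE, prob = c(0.6, 0.4))
    low <- i[!preserved]
    ctffr[low] <- pmax(0.05, 0.80 - 0.60 * u[low])
    band[low] <- sample(STENOSIS_BANDS, length(low), replace = TRUE,
                        prob = c(0.05, 0.03, 0.17, 0.39, 0.29, 0.07))
    occluded <- band == "100"
    ctffr[occluded] <- 0.5
    ecg_call <- ifelse(
      runif(n) < ifelse(pos, ecg_sens, ecg_fpr), "positive", "negative")

    tibble(
      subject_id = sprintf("sim%04d", seq_len(n)),
      stenosis_band = band, ctffr = ctffr, occluded = occluded,
      ecg_call = ecg_call, cdg_value = cdg
    )
  })
}

#' Read or write a cohort table
#'
#' The cohort CSV schema is `subject_id, stenosis_band, ctffr, occluded,
#' ecg_call, cdg_value`.
#'
#' @param path CSV file.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("cohort_eval: file not found: ", path))
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "stenosis_band", "ctffr", "occluded", "ecg_call",
            "cdg_value")
  missing <- setdiff(need, names(dat))
  if (length(missing)) {
    abort(paste0("cohort_eval: cohort CSV is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  dat
}

#' @rdname read_cohort
#' @param cohort Cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}
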