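default_config <- function() {
  list(
    io = list(fs = 1000, format = "csv"),
    preprocess = list(notch_hz = 50, bandpass_lo_hz = 0.5,
                      bandpass_hi_hz = 45, order = 4, notch_q = 30),
    vcg = list(matrix_file = NULL),
    fiducials = list(channel = "magnitude", refractory_s = 0.2,
                     threshold_frac = 0.3, n_points = 100, min_beats = 8),
    rbf = list(spacing = NULL, width = NULL, max_centers = 20000,
               gain_a = 0.5, gamma = 0.5, sigma = 1e-4, epochs = 20,
               normalized = TRUE),
    shi = list(step_k = 10, theiler = NULL),
    thi = list(grid_max = NULL, spectrum_mode = "norm"),
    classifier = list(model = "paper-2023", path = NULL),
    evaluate = list(standard = 1, ci_method = "delong"),
    version = "cardiodyn-0.1"
  )
}

merge_validated <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(paste0("pipeline: unknown config key(s): ",
                 paste0(path, unknown, collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]])) {
        abort(paste0("pipeline: config section `", path, k, "` must be a mapping."))
      }
      defaults[k] <- list(merge_validated(defaults[[k]], user[[k]],
                                          paste0(path, k, ".")))
    } else {
      # `[<-` with a wrapped list keeps explicit NULLs (a plain [[<- NULL
      # assignment would delete the key, e.g. for YAML `~` values)
      defaults[k] <- list(user[[k]])
    }
  }
  defaults
}

#' Pipeline configuration
#'
#' `cdg_config()` returns the complete default configuration, optionally
#' overridden section by section; unknown keys are rejected. `read_config()`
#' loads overrides from a YAML file, `write_config()` emits the full default
#' YAML, and `config_hash()` gives a stable digest recorded in every report.
#'
#' @param ... Named sections (`io`, `preprocess`, `vcg`, `fiducials`, `rbf`,
#'   `shi`, `thi`, `classifier`, `evaluate`, `version`) given as lists of
#'   overrides.
#' @return A list of class `cdg_config`.
#' @export
cdg_config <- function(...) {
  user <- list(...)
  cfg <- merge_validated(default_config(), user)
  structure(cfg, class = "cdg_config")
}

#' @rdname cdg_config
#' @param path YAML file.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  structure(merge_validated(default_config(), user), class = "cdg_config")
}

#' @rdname cdg_config
#' @param config A `cdg_config`.
#' @export
write_config <- function(config = cdg_config(), path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname cdg_config
#' @export
config_hash <- function(config) rlang::hash(unclass(config))

config_classifier <- function(config) {
  if (!is.null(config$classifier$path)) {
    read_cdg_classifier(config$classifier$path)
  } else if (identical(config$classifier$model, "paper-2023")) {
    cdg_classifier()
  } else {
    abort(paste0("classifier: unknown model tag: ", config$classifier$model))
  }
}

#' Run the full CDG pipeline on one subject
#'
#' Chains every stage: denoise, Kors transform, R-peak detection, fiducial
#' location, ST-T loop extraction, RBF deterministic learning, CDG
#' trajectory generation, heterogeneity indices and the classifier. The run
#' is deterministic given the configuration and input. Stage failures
#' propagate with a message naming the failing module.
#'
#' @param ecg An [ecg_record()] or a path to an ECG CSV (sampling rate then
#'   taken from `config$io$fs`).
#' @param config A [cdg_config()].
#' @param out_dir Optional directory; when given, writes `indices.csv`,
#'   `trajectory.csv` and `result.json` artifacts.
#' @return A list of class `cdg_subject` with elements `result` (one-row
#'   tibble: subject_id, shi, thi, n_points, step_k, cdg_value, call),
#'   `trajectory`, `loops`, `network`, `fiducials`, `config_hash`.
#' @export
run_subject <- function(ecg, config = cdg_config(), out_dir = NULL) {
  if (is.character(ecg)) {
    ecg <- read_ecg(ecg, fs = config$io$fs, format = config$io$format)
  }
  stopifnot(inherits(ecg, "ecg_record"))
  pp <- config$preprocess
  clean <- denoise(ecg, filter_spec(pp$notch_hz, pp$bandpass_lo_hz,
                                    pp$bandpass_hi_hz, pp$order, pp$notch_q))
  m <- if (!is.null(config$vcg$matrix_file)) {
    read_kors_matrix(config$vcg$matrix_file)
  } else {
    kors_matrix()
  }
  vcg <- kors_transform(clean, m)
  fd <- config$fiducials
  r <- detect_r_peaks(vcg, channel = fd$channel,
                      refractory_s = fd$refractory_s,
                      threshold_frac = fd$threshold_frac)
  fids <- locate_fiducials(vcg, r)
  if (nrow(fids) < fd$min_beats) {
    abort(sprintf("fiducials: only %d resolvable beat(s); need >= %d.",
                  nrow(fids), fd$min_beats),
          class = "cardiodyn_fiducial_error")
  }
  loops <- extract_stt_loops(vcg, fids, n_points = fd$n_points)
  rb <- config$rbf
  net <- rbf_lattice(loops, spacing = rb$spacing, width = rb$width,
                     max_centers = rb$max_centers)
  net <- learn_dynamics(loops, net, gain_a = rb$gain_a, gamma = rb$gamma,
                        sigma = rb$sigma, epochs = rb$epochs,
                        normalized = rb$normalized)
  traj <- generate_cdg(net, loops)
  grid <- if (!is.null(config$thi$grid_max)) seq_len(config$thi$grid_max)
  idx <- heterogeneity_indices(traj, step_k = config$shi$step_k,
                               theiler = config$shi$theiler,
                               lambda_grid = grid,
                               spectrum_mode = config$thi$spectrum_mode)
  clf <- config_classifier(config)
  result <- cdg_score(idx, clf)
  out <- structure(
    list(result = result, trajectory = traj, loops = loops, network = net,
         fiducials = fids, classifier = clf,
         config_hash = config_hash(config)),
    class = "cdg_subject")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(result, file.path(out_dir, "indices.csv"), progress = FALSE)
    readr::write_csv(as_tibble(as.data.frame(traj)),
                     file.path(out_dir, "trajectory.csv"), progress = FALSE)
    jsonlite::write_json(
      c(as.list(result), list(config_hash = out$config_hash)),
      file.path(out_dir, "result.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.cdg_subject <- function(x, ...) {
  r <- x$result
  cat(sprintf(
    "<cdg_subject %s> SHI %.4f, THI %g over %d points -> CDG value %.4f (%s)\n",
    r$subject_id, r$shi, r$thi, r$n_points, r$cdg_value, r$call))
  invisible(x)
}

validate_cohort <- function(cohort) {
  need <- c("subject_id", "stenosis_band", "ctffr", "occluded", "ecg_call",
            "cdg_value")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    abort(paste0("cohort_eval: cohort is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  occ <- cohort$occluded %in% TRUE
  bad <- which(
    !(cohort$stenosis_band %in% STENOSIS_BANDS) |
      (!occ & (!is.finite(cohort$ctffr) | cohort$ctffr < 0 | cohort$ctffr > 1)) |
      !(cohort$ecg_call %in% c("positive", "negative")) |
      !is.finite(cohort$cdg_value)
  )
  if (length(bad)) {
    abort(paste0("cohort_eval: invalid cohort row(s): ",
                 paste(utils::head(bad, 20), collapse = ", ")))
  }
  invisible(cohort)
}

#' Evaluate CDG (or physician ECG) calls against a reference standard
#'
#' Labels every patient by the chosen reference standard, derives binary
#' calls from the CDG values (or uses the recorded physician ECG calls),
#' and reports confusion counts, the five diagnostic metrics, the ROC AUC
#' of the continuous CDG value with its 95% CI (reported missing when only
#' one class is present), and the Spearman correlation between CDG value
#' and CT-FFR.
#'
#' @param cohort Cohort tibble (schema of [simulate_cohort()]) or CSV path.
#' @param standard Reference standard 1--4.
#' @param calls `"cdg"` (threshold the CDG value at the classifier cut) or
#'   `"ecg"` (use the recorded physician calls).
#' @param config A [cdg_config()] (classifier threshold, CI method).
#' @return A list of class `cdg_eval` with `metrics` (one-row tibble),
#'   `auc`, `spearman`, `standard`, `n`, `config_hash`, plus the scores and
#'   truth labels used.
#' @export
run_cohort <- function(cohort, standard = 1, calls = c("cdg", "ecg"),
                       config = cdg_config()) {
  calls <- match.arg(calls)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  validate_cohort(cohort)
  labeled <- label_cad(cohort, standard = standard)
  clf <- config_classifier(config)
  call_vec <- if (calls == "cdg") {
    classify_cdg(cohort$cdg_value, clf)
  } else {
    cohort$ecg_call
  }
  cc <- confusion_counts(call_vec, labeled$cad_label)
  metrics <- diagnostic_metrics(cc)
  auc <- tryCatch(
    roc_auc(cohort$cdg_value, labeled$cad_label,
            ci_method = config$evaluate$ci_method),
    cardiodyn_single_class_error = function(e) {
      warn("cohort_eval: single-class cohort; AUC reported missing.")
      tibble(auc = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_)
    })
  rho <- spearman_corr(cohort$cdg_value, ifelse(cohort$occluded %in% TRUE,
                                                0.5, cohort$ctffr))
  structure(
    list(standard = standard, calls = calls, n = nrow(cohort),
         metrics = metrics, auc = auc, spearman = rho,
         scores = cohort$cdg_value, truths = labeled$cad_label,
         config_hash = config_hash(config)),
    class = "cdg_eval")
}

#' @export
print.cdg_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<cdg_eval> %s calls vs reference standard %d (n = %d)\n",
              x$calls, x$standard, x$n))
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d\n", m$tp, m$tn, m$fp, m$fn))
  cat(sprintf("  sensitivity %.2f  specificity %.2f  PPV %s  NPV %s  accuracy %.2f\n",
              m$sensitivity, m$specificity,
              format(m$ppv), format(m$npv), m$accuracy))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)  Spearman rho %.3f\n",
              x$auc$auc, x$auc$ci_lo, x$auc$ci_hi, x$spearman$rho))
  invisible(x)
}

#' Write a cohort evaluation report
#'
#' Emits a CSV of the metrics row and a JSON summary (counts, metrics, AUC,
#' Spearman, configuration hash).
#'
#' @param eval A `cdg_eval` from [run_cohort()].
#' @param dir Output directory.
#' @export
write_eval_report <- function(eval, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(eval$metrics, file.path(dir, "metrics.csv"), progress = FALSE)
  jsonlite::write_json(
    list(standard = eval$standard, calls = eval$calls, n = eval$n,
         metrics = as.list(eval$metrics), auc = as.list(eval$auc),
         spearman = as.list(eval$spearman), config_hash = eval$config_hash),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
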