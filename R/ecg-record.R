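#' Lead sets of the standard 12-lead ECG
#'
#' `LEADS_12` is the conventional ordering of the twelve standard leads;
#' `LEADS_INDEPENDENT` is the subset of eight linearly independent leads
#' (the limb pair I, II plus the six chest leads) from which the remaining
#' four are derived and on which the vectorcardiogram transform operates.
#'
#' @format Character vectors of lead names.
#' @export
LEADS_12 <- c("I", "II", "III", "aVR", "aVL", "aVF",
              "V1", "V2", "V3", "V4", "V5", "V6")

#' @rdname LEADS_12
#' @export
LEADS_INDEPENDENT <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

#' Construct a 12-lead ECG record
#'
#' An `ecg_record` is a tibble with one numeric column per lead (voltages in
#' millivolts) and one row per sample, carrying the sampling rate and a
#' subject identifier as attributes. At least the eight independent leads
#' (I, II, V1--V6) must be present; derived limb leads are optional.
#'
#' @param data Data frame of lead columns, voltages in mV.
#' @param fs Sampling rate in Hz (scalar, > 0).
#' @param subject_id Opaque subject identifier string.
#' @return A tibble of class `ecg_record` with attributes `fs` and
#'   `subject_id`.
#' @examples
#' x <- matrix(0, 100, 8, dimnames = list(NULL, LEADS_INDEPENDENT))
#' rec <- ecg_record(as.data.frame(x), fs = 500)
#' ecg_duration(rec)
#' @export
ecg_record <- function(data, fs, subject_id = "anonymous") {
  if (!is.data.frame(data)) {
    abort("signal_io: `data` must be a data frame of lead columns.")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("signal_io: `fs` must be a single positive number (Hz).")
  }
  nm <- names(data)
  if (anyDuplicated(nm)) {
    abort("signal_io: duplicated lead names in record.")
  }
  missing <- setdiff(LEADS_INDEPENDENT, nm)
  if (length(missing)) {
    abort(
      paste0("signal_io: record is missing required lead(s): ",
             paste(missing, collapse = ", ")),
      class = "cardiodyn_lead_error"
    )
  }
  if (!all(vapply(data, is.numeric, logical(1)))) {
    abort("signal_io: all lead columns must be numeric (mV).")
  }
  out <- as_tibble(data)
  attr(out, "fs") <- as.numeric(fs)
  attr(out, "subject_id") <- as.character(subject_id)
  class(out) <- c("ecg_record", class(out))
  out
}

#' @rdname ecg_record
#' @param rec An `ecg_record`.
#' @export
ecg_fs <- function(rec) attr(rec, "fs")

#' @rdname ecg_record
#' @export
ecg_subject <- function(rec) attr(rec, "subject_id")

#' @rdname ecg_record
#' @export
ecg_duration <- function(rec) nrow(rec) / ecg_fs(rec)

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> subject %s: %d leads, %d samples @ %g Hz (%.2f s)\n",
              ecg_subject(x), ncol(x), nrow(x), ecg_fs(x), ecg_duration(x)))
  NextMethod()
}

#' Read a 12-lead ECG recording
#'
#' Reads the package CSV dialect: one header row of lead names, one numeric
#' column per lead, voltages in millivolts. The sampling rate is not stored
#' in the CSV and must be supplied.
#'
#' @param path File to read.
#' @param fs Sampling rate of the recording in Hz.
#' @param format Only `"csv"` is supported; `"wfdb"` is recognised but not
#'   available in this build and raises an error.
#' @param subject_id Subject identifier; defaults to the file base name.
#' @return An [ecg_record()].
#' @export
read_ecg <- function(path, fs, format = c("csv", "wfdb"), subject_id = NULL) {
  format <- match.arg(format)
  if (format == "wfdb") {
    abort("signal_io: WFDB input is not supported by this build; use the CSV dialect.")
  }
  if (!file.exists(path)) {
    abort(paste0("signal_io: file not found: ", path))
  }
  dat <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    name_repair = "minimal"),
    error = function(e) abort(paste0("signal_io: cannot parse CSV: ", conditionMessage(e)))
  )
  if (nrow(readr::problems(dat)) > 0 || anyNA(dat)) {
    abort("signal_io: malformed CSV (ragged rows or non-numeric cells).",
          class = "cardiodyn_format_error")
  }
  ecg_record(dat, fs = fs,
             subject_id = subject_id %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a 12-lead ECG recording
#'
#' Inverse of [read_ecg()]: writes the lead columns as CSV with full double
#' precision so a read/write round trip is lossless to < 1e-9 mV.
#'
#' @param rec An [ecg_record()].
#' @param path Output file.
#' @param format Only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
write_ecg <- function(rec, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "wfdb") {
    abort("signal_io: WFDB output is not supported by this build; use the CSV dialect.")
  }
  stopifnot(inherits(rec, "ecg_record"))
  readr::write_csv(as_tibble(as.data.frame(rec)), path, progress = FALSE)
  invisible(path)
}
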