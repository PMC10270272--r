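#' The Kors regression matrix
#'
#' Returns the standard Kors regression coefficients mapping the eight
#' independent ECG leads (I, II, V1--V6, in that column order) to the
#' orthogonal vectorcardiogram leads X, Y, Z (rows, in that order). The
#' coefficients are shipped as configuration: pass a different 3 x 8 matrix
#' (or a CSV file of one, via [read_kors_matrix()]) to use another dialect.
#'
#' @return A 3 x 8 numeric matrix with dimnames.
#' @export
kors_matrix <- function() {
  m <- rbind(
    X = c(0.38, -0.07, -0.13,  0.05, -0.01,  0.14,  0.06,  0.54),
    Y = c(-0.07, 0.93,  0.06, -0.02, -0.05,  0.06, -0.17,  0.13),
    Z = c(0.11, -0.23, -0.43, -0.06, -0.14, -0.20, -0.11,  0.31)
  )
  colnames(m) <- LEADS_INDEPENDENT
  m
}

#' @rdname kors_matrix
#' @param path CSV with 3 rows (X, Y, Z) and 8 columns (I, II, V1..V6),
#'   no header.
#' @export
read_kors_matrix <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  if (!identical(dim(m), c(3L, 8L)) || !all(is.finite(m))) {
    abort("vcg_transform: matrix file must be a finite 3 x 8 numeric table.")
  }
  dimnames(m) <- list(c("X", "Y", "Z"), LEADS_INDEPENDENT)
  m
}

#' Construct a vectorcardiogram record
#'
#' A `vcg_record` is a tibble with numeric columns `x`, `y`, `z` (mV) and
#' attributes `fs` and `subject_id`.
#'
#' @param x,y,z Equal-length numeric voltage series in mV.
#' @param fs Sampling rate, Hz.
#' @param subject_id Identifier string.
#' @export
vcg_record <- function(x, y, z, fs, subject_id = "anonymous") {
  if (!(length(x) == length(y) && length(y) == length(z))) {
    abort("vcg_transform: x, y, z must have equal lengths.")
  }
  out <- tibble(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  attr(out, "fs") <- as.numeric(fs)
  attr(out, "subject_id") <- as.character(subject_id)
  class(out) <- c("vcg_record", class(out))
  out
}

#' @export
print.vcg_record <- function(x, ...) {
  cat(sprintf("<vcg_record> subject %s: %d samples @ %g Hz\n",
              attr(x, "subject_id"), nrow(x), attr(x, "fs")))
  NextMethod()
}

#' Kors transform: 12-lead ECG to 3-lead vectorcardiogram
#'
#' Maps each sample of the eight independent leads through the Kors matrix
#' to the orthogonal X, Y, Z leads. Leads are matched by name, so column
#' order in the record is irrelevant; derived leads (III, aVR, aVL, aVF) are
#' ignored even when present.
#'
#' @param rec An [ecg_record()] containing leads I, II, V1--V6.
#' @param m A 3 x 8 transform matrix, default [kors_matrix()].
#' @return A [vcg_record()] of the same length and sampling rate.
#' @examples
#' x <- matrix(rnorm(800), 100, 8, dimnames = list(NULL, LEADS_INDEPENDENT))
#' vcg <- kors_transform(ecg_record(as.data.frame(x), fs = 500))
#' @export
kors_transform <- function(rec, m = kors_matrix()) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!is.matrix(m) || !identical(dim(m), c(3L, 8L)) || !all(is.finite(m))) {
    abort("vcg_transform: transform matrix must be a finite 3 x 8 matrix.")
  }
  missing <- setdiff(LEADS_INDEPENDENT, names(rec))
  if (length(missing)) {
    abort(paste0("vcg_transform: record is missing lead(s): ",
                 paste(missing, collapse = ", ")),
          class = "cardiodyn_lead_error")
  }
  lead_mat <- as.matrix(as.data.frame(rec)[, LEADS_INDEPENDENT, drop = FALSE])
  xyz <- lead_mat %*% t(m)  # n x 3
  vcg_record(xyz[, 1], xyz[, 2], xyz[, 3], fs = ecg_fs(rec),
             subject_id = ecg_subject(rec))
}
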