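## Core data model: a labelled tri-axial IMU recording.

#' Construct an IMU recording
#'
#' The universal input of every detector: a uniformly sampled tri-axial
#' acceleration (units of g) and angular velocity (rad/s) time series with
#' an activity label.
#'
#' @param A numeric matrix with `n` rows and 3 columns (`ax`, `ay`, `az`),
#'   acceleration in g.
#' @param G numeric matrix with `n` rows and 3 columns (`gx`, `gy`, `gz`),
#'   angular velocity in rad/s.
#' @param fs sampling rate in Hz (> 0).
#' @param t optional vector of sample times in seconds; defaults to
#'   `(0:(n-1))/fs`.  Must be strictly increasing with constant step `1/fs`
#'   (tolerance 1e-9 s).
#' @param label activity class label (e.g. `"fall_forward"`, `"walking"`).
#' @param is_fall logical; whether the recording contains a fall.  Defaults
#'   to `grepl("^fall", label)`.
#' @param subject_id opaque subject identifier.
#' @return an object of class `imu_recording`: a list with fields
#'   `subject_id`, `label`, `is_fall`, `fs`, `t`, `A`, `G`.
#' @export
imu_recording <- function(A, G, fs, t = NULL, label = "unknown",
                          is_fall = grepl("^fall", label),
                          subject_id = "anon") {
  A <- as.matrix(A); G <- as.matrix(G)
  storage.mode(A) <- "double"; storage.mode(G) <- "double"
  if (ncol(A) != 3L || ncol(G) != 3L)
    ff_contract_error("A and G must have 3 columns")
  n <- nrow(A)
  if (nrow(G) != n)
    ff_contract_error("A and G must have identical length")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    ff_contract_error("fs must be a positive finite scalar")
  if (is.null(t)) t <- (seq_len(n) - 1) / fs
  if (length(t) != n)
    ff_contract_error("t must have one entry per sample")
  if (n > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) ff_data_error("sample times must be strictly increasing")
    if (any(abs(dt - 1 / fs) > 1e-9))
      ff_data_error("sample times must be uniformly spaced at 1/fs")
  }
  if (n > 0 && (!all(is.finite(A)) || !all(is.finite(G)) || !all(is.finite(t))))
    ff_data_error("all samples must be finite")
  colnames(A) <- c("ax", "ay", "az")
  colnames(G) <- c("gx", "gy", "gz")
  structure(
    list(subject_id = subject_id, label = label, is_fall = isTRUE(is_fall),
         fs = fs, t = as.numeric(t), A = A, G = G),
    class = "imu_recording"
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf(
    "<imu_recording> %s (%s), %d samples @ %g Hz (%.2f s), subject %s\n",
    x$label, if (x$is_fall) "fall" else "ADL", nrow(x$A), x$fs,
    nrow(x$A) / x$fs, x$subject_id))
  invisible(x)
}

#' @export
length.imu_recording <- function(x) nrow(x$A)

#' Dataset dialects
#'
#' A dialect describes how a CSV layout maps onto the canonical recording
#' fields: column names, acceleration unit, and the native sampling rate.
#' Shipped dialects: `generic` (canonical header
#' `time_s,ax_g,ay_g,az_g,gx_rads,gy_rads,gz_rads`, already in g/rad/s),
#' `mobiact`, `dlr`, and `umafall` (acceleration in m/s^2 at their
#' published native rates).  Any other layout can be described with a
#' custom dialect or a JSON dialect file (see [read_dialect()]).
#'
#' @param name dialect name.
#' @param columns named character vector mapping the canonical fields
#'   `time`, `ax`, `ay`, `az`, `gx`, `gy`, `gz` to file column names.
#' @param accel_unit `"g"` or `"ms2"`; `"ms2"` columns are divided by
#'   9.80665 on load.
#' @param native_fs nominal sampling rate of the source files in Hz.
#' @return an object of class `imu_dialect`.
#' @export
imu_dialect <- function(name, columns, accel_unit = c("g", "ms2"),
                        native_fs = 50) {
  accel_unit <- match.arg(accel_unit)
  need <- c("time", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(columns)))
    ff_config_error(paste0("dialect must map columns: ",
                           paste(setdiff(need, names(columns)), collapse = ", ")))
  if (native_fs <= 0) ff_config_error("native_fs must be positive")
  structure(list(name = name, columns = columns[need],
                 accel_unit = accel_unit, native_fs = native_fs),
            class = "imu_dialect")
}

#' @rdname imu_dialect
#' @param dialect name of a shipped dialect.
#' @export
dialect <- function(dialect = c("generic", "mobiact", "dlr", "umafall")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    generic = imu_dialect("generic",
      c(time = "time_s", ax = "ax_g", ay = "ay_g", az = "az_g",
        gx = "gx_rads", gy = "gy_rads", gz = "gz_rads"),
      accel_unit = "g", native_fs = 50),
    mobiact = imu_dialect("mobiact",
      c(time = "rel_time", ax = "acc_x", ay = "acc_y", az = "acc_z",
        gx = "gyro_x", gy = "gyro_y", gz = "gyro_z"),
      accel_unit = "ms2", native_fs = 100),
    dlr = imu_dialect("dlr",
      c(time = "time", ax = "ax", ay = "ay", az = "az",
        gx = "gx", gy = "gy", gz = "gz"),
      accel_unit = "ms2", native_fs = 100),
    umafall = imu_dialect("umafall",
      c(time = "timestamp", ax = "x_accel", ay = "y_accel", az = "z_accel",
        gx = "x_gyro", gy = "y_gyro", gz = "z_gyro"),
      accel_unit = "ms2", native_fs = 200))
}

#' @rdname imu_dialect
#' @param path path to a JSON file with fields `name`, `columns`,
#'   `accel_unit`, `native_fs`.
#' @export
read_dialect <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  imu_dialect(d$name, unlist(d$columns), d$accel_unit, d$native_fs)
}

#' Load a recording from CSV
#'
#' Reads a CSV file under a dataset dialect's column map, converts units to
#' the canonical g / rad/s, and validates the sampling grid.  If a JSON
#' sidecar `<path>.json` exists (as written by [write_recording()]), the
#' label, subject and sampling rate are taken from it; otherwise the label
#' comes from `label` or from the file-name convention `FALL_*` / `ADL_*`.
#'
#' @param path CSV file path.
#' @param dialect an [imu_dialect] (default: generic).
#' @param label optional label override.
#' @return an [imu_recording].
#' @export
load_recording <- function(path, dialect = fallfusion::dialect("generic"),
                           label = NULL) {
  if (!file.exists(path)) ff_format_error(paste("file not found:", path))
  df <- utils::read.csv(path, check.names = FALSE)
  cols <- dialect$columns
  missing_cols <- setdiff(unname(cols), names(df))
  if (length(missing_cols))
    ff_format_error(paste0("missing column(s) in ", basename(path), ": ",
                           paste(missing_cols, collapse = ", ")))
  t <- df[[cols[["time"]]]]
  if (any(diff(t) <= 0))
    ff_data_error("non-monotone timestamps")
  A <- as.matrix(df[, cols[c("ax", "ay", "az")]])
  G <- as.matrix(df[, cols[c("gx", "gy", "gz")]])
  if (dialect$accel_unit == "ms2") A <- A / STANDARD_GRAVITY

  sidecar <- paste0(path, ".json")
  subject <- "anon"; fs <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(label)) label <- meta$label
    subject <- meta$subject_id %||% subject
    fs <- meta$fs
  }
  if (is.null(label)) {
    bn <- toupper(basename(path))
    label <- if (startsWith(bn, "FALL")) "fall" else "adl"
  }
  if (is.null(fs)) fs <- 1 / stats::median(diff(t))
  imu_recording(A, G, fs = fs, t = t - t[1], label = label,
                subject_id = subject)
}

#' Write a recording to CSV (canonical generic dialect)
#'
#' Writes the canonical header
#' `time_s,ax_g,ay_g,az_g,gx_rads,gy_rads,gz_rads` plus a JSON sidecar
#' `<path>.json` holding `subject_id`, `label`, `is_fall` and `fs`.
#'
#' @param rec an [imu_recording].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(time_s = rec$t,
                   ax_g = rec$A[, 1], ay_g = rec$A[, 2], az_g = rec$A[, 3],
                   gx_rads = rec$G[, 1], gy_rads = rec$G[, 2],
                   gz_rads = rec$G[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(subject_id = rec$subject_id, label = rec$label,
         is_fall = rec$is_fall, fs = rec$fs),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
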