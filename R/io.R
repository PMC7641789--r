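# Readers and writers for raw recordings, subject metadata, and long-format
# feature tables. All files are delimited UTF-8 text with a header row; the
# delimiter is configurable. Acceleration is accepted in g or m/s^2 and the
# unit travels with the object so downstream code can canonicalise.

valid_placements <- c("lumbar", "sternum", "wrist_l", "wrist_r", "foot_l", "foot_r")

#' Construct a gait recording
#'
#' A gait recording is a tibble with columns `time`, `ax`, `ay`, `az` plus
#' metadata attributes: sampling rate `fs` (Hz), acceleration `units`
#' (`"g"` or `"m/s2"`), body `placement`, and subject/visit identifiers.
#' Time is seconds from the start of the recording and must be strictly
#' increasing; the median sampling interval must agree with `1/fs` within 10%.
#'
#' @param data Data frame with numeric columns `time`, `ax`, `ay`, `az`.
#' @param fs Sampling rate in Hz. Inferred from the median time step if `NULL`.
#' @param units `"g"` or `"m/s2"`.
#' @param placement Device placement; the pipeline expects `"lumbar"`.
#' @param subject_id,visit_id Identifiers carried through to feature records.
#' @return A `gait_recording` tibble.
#' @export
gait_recording <- function(data, fs = NULL, units = c("m/s2", "g"),
                           placement = "lumbar", subject_id = NA_character_,
                           visit_id = NA_integer_) {
  units <- arg_match(units)
  placement <- arg_match(placement, valid_placements)
  need <- c("time", "ax", "ay", "az")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(sprintf("recording is missing columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)[need]
  if (nrow(data) == 0) abort("recording is empty")
  for (cn in need) stopifnot_finite(data[[cn]], cn)
  dt <- diff(data$time)
  if (any(dt <= 0)) abort("non-monotone time")
  med_dt <- median(dt)
  if (is.null(fs)) fs <- 1 / med_dt
  if (abs(med_dt - 1 / fs) >= 0.1 / fs) {
    abort("median sampling interval disagrees with `fs` by more than 10%")
  }
  # flag gaps: intervals more than 1.5x the nominal step
  gap_idx <- which(dt > 1.5 / fs)
  gaps <- tibble::tibble(
    start = data$time[gap_idx],
    end = data$time[gap_idx + 1],
    duration = dt[gap_idx]
  )
  structure(data,
    fs = fs, units = units, placement = placement,
    subject_id = subject_id, visit_id = visit_id, gaps = gaps,
    class = c("gait_recording", class(data))
  )
}

#' Read a raw accelerometer recording
#'
#' Parses a delimited text export with a timestamp column and three
#' acceleration columns. Wall-clock timestamps (parsed datetimes or numeric
#' epochs) are converted to seconds from recording start. Timestamp gaps
#' larger than 1.5 sampling intervals are recorded in the `gaps` attribute.
#'
#' @param path File path.
#' @param format_spec Named list mapping the canonical names `time`, `ax`,
#'   `ay`, `az` to the column names present in the file.
#' @param units Acceleration unit of the file, `"g"` or `"m/s2"`.
#' @param fs Sampling rate in Hz; inferred from timestamps when `NULL`.
#' @param delim Field delimiter.
#' @inheritParams gait_recording
#' @return A [gait_recording()].
#' @export
read_gait_recording <- function(path,
                                format_spec = list(time = "time", ax = "ax",
                                                   ay = "ay", az = "az"),
                                units = c("m/s2", "g"), fs = NULL,
                                delim = ",", placement = "lumbar",
                                subject_id = NA_character_,
                                visit_id = NA_integer_) {
  units <- arg_match(units)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, comment = "#")
  if (nrow(raw) == 0) abort("empty file")
  missing_cols <- setdiff(unlist(format_spec), names(raw))
  if (length(missing_cols)) {
    abort(sprintf("missing columns: %s", paste(missing_cols, collapse = ", ")))
  }
  tm <- raw[[format_spec$time]]
  if (inherits(tm, c("POSIXct", "POSIXt"))) tm <- as.numeric(tm)
  if (!is.numeric(tm)) abort("time column is not numeric or datetime")
  df <- tibble::tibble(
    time = tm - tm[1],
    ax = as.numeric(raw[[format_spec$ax]]),
    ay = as.numeric(raw[[format_spec$ay]]),
    az = as.numeric(raw[[format_spec$az]])
  )
  gait_recording(df, fs = fs, units = units, placement = placement,
                 subject_id = subject_id, visit_id = visit_id)
}

#' Read a subject metadata table
#'
#' One row per subject and visit with demographics, covariates, medication
#' state, and the clinician gait impairment score (ordinal 0-4). Missing
#' covariates are preserved as `NA`; a score outside 0-4 or a duplicated
#' (subject, visit) pair is an error.
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return Tibble with columns `subject_id`, `age`, `gender`, `height`, `bmi`,
#'   `years_since_first_symptoms`, `visit`, `med_state`, `updrs_gait`.
#' @export
read_subject_metadata <- function(path, delim = ",") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  meta <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE,
                            col_types = readr::cols(
                              subject_id = readr::col_character(),
                              gender = readr::col_character(),
                              med_state = readr::col_character(),
                              .default = readr::col_double()
                            ))
  validate_subject_metadata(meta)
}

validate_subject_metadata <- function(meta) {
  meta <- tibble::as_tibble(meta)
  need <- c("subject_id", "visit")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    abort(sprintf("metadata missing columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  key <- paste(meta$subject_id, meta$visit)
  if (anyDuplicated(key)) {
    abort("duplicate (subject_id, visit) rows in metadata")
  }
  if ("updrs_gait" %in% names(meta)) {
    bad <- !is.na(meta$updrs_gait) &
      (!meta$updrs_gait %in% 0:4)
    if (any(bad)) abort("updrs_gait outside 0-4")
  }
  if ("height" %in% names(meta)) {
    if (any(!is.na(meta$height) & meta$height <= 0)) abort("height must be > 0")
  }
  meta
}

#' Write and read long-format feature tables
#'
#' Feature records are long-format rows keyed by
#' (`subject_id`, `visit`, `device_config`, `feature_name`); keys must be
#' unique and values finite. `write_feature_table()` and
#' `read_feature_table()` round-trip losslessly.
#'
#' @param records Feature tibble with columns `subject_id`, `visit`,
#'   `med_state`, `device_config`, `feature_name`, `value`.
#' @param path File path.
#' @param delim Field delimiter.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the validated tibble.
#' @export
write_feature_table <- function(records, path, delim = ",") {
  records <- validate_feature_records(records)
  readr::write_delim(records, path, delim = delim)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, delim = ",") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  rec <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(
                             subject_id = readr::col_character(),
                             med_state = readr::col_character(),
                             device_config = readr::col_character(),
                             feature_name = readr::col_character(),
                             visit = readr::col_double(),
                             value = readr::col_double()
                           ))
  validate_feature_records(rec)
}

validate_feature_records <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("subject_id", "visit", "med_state", "device_config",
            "feature_name", "value")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    abort(sprintf("feature records missing columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  key <- paste(records$subject_id, records$visit, records$device_config,
               records$feature_name)
  if (anyDuplicated(key)) {
    abort("duplicate (subject, visit, config, feature) keys")
  }
  if (any(!is.finite(records$value))) abort("feature values must be finite")
  if (!all(records$device_config %in% c("one", "three", "six"))) {
    abort("device_config must be one of \"one\", \"three\", \"six\"")
  }
  records[need]
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> %s, %.5g Hz, %s, %.1f s, %d gap(s)\n",
              attr(x, "placement"), attr(x, "fs"), attr(x, "units"),
              diff(range(x$time)), nrow(attr(x, "gaps"))))
  NextMethod()
}
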