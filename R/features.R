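# Bout-level aggregation: medians of per-stride measures, plus asymmetry
# (between alternating pseudo-sides) and variability (within-bout spread).
# Device-configuration feature rosters select which features a 1-, 3-, or
# 6-device setup can provide; multi-device values are never computed here,
# only ingested from external tables.

base_features <- c("stride_time", "step_time", "stance_time", "swing_time",
                   "double_support_time", "stride_length", "step_length",
                   "gait_speed", "cadence")
asym_features <- c("step_time", "stance_time", "swing_time")
var_features <- c("stride_time", "step_time", "stance_time", "swing_time",
                  "stride_length", "step_length", "gait_speed")

#' Step-to-step asymmetry between pseudo-sides
#'
#' The magnitude of the difference between per-side location estimates, in the
#' feature's own units. The default compares medians; a mean-based variant is
#' selectable. Requires at least two values per side.
#'
#' @param a,b Numeric per-stride series for pseudo-sides A and B.
#' @param method `"median_diff"` or `"mean_diff"`.
#' @return Scalar asymmetry.
#' @export
asymmetry <- function(a, b, method = c("median_diff", "mean_diff")) {
  method <- arg_match(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("need at least 2 values per pseudo-side")
  }
  loc <- if (method == "median_diff") median else mean
  abs(loc(a) - loc(b))
}

#' Within-bout variability of a per-stride series
#'
#' @param x Numeric per-stride series of at least 3 values.
#' @param method `"sd"` (sample standard deviation) or `"cv"` (coefficient of
#'   variation, SD / mean).
#' @return Scalar variability.
#' @export
variability <- function(x, method = c("sd", "cv")) {
  method <- arg_match(method)
  x <- x[!is.na(x)]
  if (length(x) < 3) abort("need at least 3 values")
  s <- sd(x)
  if (method == "cv") s / mean(x) else s
}

#' Aggregate a bout of strides into feature records
#'
#' The median of each per-stride measure over valid strides, plus asymmetry
#' features (pseudo-side median differences for step, stance, and swing time)
#' and variability features (within-bout SD). Requires at least 3 valid
#' strides.
#'
#' @param strides A `gait_strides` tibble (spatial columns present).
#' @param subject_id,visit,med_state Keys copied into the feature records;
#'   defaults are taken from the stride table's attributes where present.
#' @param asymmetry_method,variability_method See [asymmetry()] and
#'   [variability()].
#' @return A feature record tibble (see [write_feature_table()]) with
#'   `device_config = "one"`; the number of strides used is attached as the
#'   `n_strides` attribute.
#' @export
aggregate_bout <- function(strides, subject_id = NULL, visit = NULL,
                           med_state = NA_character_,
                           asymmetry_method = "median_diff",
                           variability_method = "sd") {
  subject_id <- subject_id %||% attr(strides, "subject_id") %||% NA_character_
  visit <- visit %||% attr(strides, "visit_id") %||% NA_integer_
  ok <- strides[strides$valid, ]
  if (nrow(ok) < 3) abort("too few valid strides (need at least 3)")

  # per-stride step time: average of the two steps; per-side series for
  # asymmetry use the step beginning at the stride's defining contact
  ok$step_time <- (ok$step_time0 + ok$step_time1) / 2
  vals <- c(
    vapply(base_features, function(f) median(ok[[f]], na.rm = TRUE),
           numeric(1)),
    setNames(vapply(asym_features, function(f) {
      x <- if (f == "step_time") ok$step_time0 else ok[[f]]
      asymmetry(x[ok$side == "A"], x[ok$side == "B"],
                method = asymmetry_method)
    }, numeric(1)), paste0(asym_features, "_asymmetry")),
    setNames(vapply(var_features, function(f) {
      variability(ok[[f]], method = variability_method)
    }, numeric(1)), paste0(var_features, "_variability"))
  )
  rec <- tibble::tibble(
    subject_id = as.character(subject_id), visit = as.numeric(visit),
    med_state = med_state, device_config = "one",
    feature_name = names(vals), value = unname(vals)
  )
  structure(validate_feature_records(rec), n_strides = nrow(ok))
}

#' Feature rosters per device configuration
#'
#' The one-device roster contains only features derivable from a lumbar
#' accelerometer. The three-device roster (lumbar + both feet) adds lower-limb
#' and lumbar range-of-motion features; the six-device roster adds trunk and
#' upper-limb features. Multi-device names are representative of a
#' commercial multi-sensor gait system and are used for selecting and
#' validating ingested feature tables, never computed internally.
#'
#' @param device_config `"one"`, `"three"`, or `"six"`.
#' @return List with elements `device_config` and `feature_names`.
#' @export
feature_set <- function(device_config = c("one", "three", "six")) {
  device_config <- arg_match(device_config)
  one <- c(base_features, paste0(asym_features, "_asymmetry"),
           paste0(var_features, "_variability"))
  lower_limb <- c("pitch_at_initial_contact", "pitch_at_toe_off",
                  "maximum_pitch", "initial_mid_swing_duration",
                  "lumbar_sagittal_range_of_motion",
                  "pitch_at_toe_off_variability", "maximum_pitch_variability",
                  "initial_mid_swing_duration_asymmetry")
  trunk_upper <- c("trunk_sagittal_average_angle",
                   "trunk_sagittal_average_angle_variability",
                   "upper_limb_foot_phase_difference", "arm_swing_amplitude",
                   "arm_swing_amplitude_asymmetry")
  names_by_config <- list(one = one,
                          three = c(one, lower_limb),
                          six = c(one, lower_limb, trunk_upper))
  list(device_config = device_config,
       feature_names = names_by_config[[device_config]])
}

#' Filter feature records to a device-configuration roster
#'
#' @param records Long-format feature records.
#' @param spec A [feature_set()].
#' @return Records restricted to `spec$feature_names`. Requested features not
#'   present in `records` are reported in the `missing_features` attribute
#'   (with a warning); an empty selection is an error.
#' @export
select_feature_set <- function(records, spec) {
  records <- validate_feature_records(records)
  keep <- records$feature_name %in% spec$feature_names
  missing <- setdiff(spec$feature_names, records$feature_name)
  if (!any(keep)) abort("no requested features present in records")
  if (length(missing)) {
    warn(sprintf("%d requested feature(s) missing from records: %s",
                 length(missing),
                 paste(head(missing, 5), collapse = ", ")))
  }
  structure(records[keep, ], missing_features = missing)
}
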