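# Event-to-stride assembly, per-stride quality control, and spatial measures
# from the inverted-pendulum model.

#' Stride quality-control configuration
#'
#' @param stride_time_range Plausible stride time bounds in seconds; covers
#'   pathological through brisk healthy gait.
#' @param stance_frac_range Plausible stance time as a fraction of stride time.
#' @param turn_factor Strides whose stride time exceeds the bout median by this
#'   factor are marked as turn strides (the 10-m back-and-forth task has a
#'   turnaround roughly every 10 strides and no heading sensor is available).
#' @return Named list of configuration values.
#' @export
stride_config <- function(stride_time_range = c(0.4, 2.25),
                          stance_frac_range = c(0.4, 0.8),
                          turn_factor = 1.4) {
  list(stride_time_range = stride_time_range,
       stance_frac_range = stance_frac_range,
       turn_factor = turn_factor)
}

#' Assemble strides from detected gait events
#'
#' A candidate stride starts at each IC with two following ICs: `ic0` (defining
#' contact), `ic1` (contralateral), `ic2` (next ipsilateral). Temporal
#' measures follow the event bookkeeping: `stride_time = ic2 - ic0`,
#' `step_time0 = ic1 - ic0`, `step_time1 = ic2 - ic1`,
#' `stance_time = fc_ipsi - ic0` with `fc_ipsi` the FC in `(ic1, ic2)`,
#' `swing_time = stride_time - stance_time`, and
#' `double_support_time = (fc_contra - ic0) + (fc_ipsi - ic1)` with
#' `fc_contra` the FC in `(ic0, ic1)`. Strides failing the QC bounds are kept
#' but marked invalid with a reason.
#'
#' @param events A `gait_events` tibble satisfying the IC/FC interleaving
#'   invariant.
#' @param config See [stride_config()].
#' @return A `gait_strides` tibble, one row per candidate stride, with the
#'   temporal columns above plus `side`, `valid`, and `invalid_reason`.
#'   Spatial columns are added by [compute_stride_features()].
#' @export
assemble_strides <- function(events, config = stride_config()) {
  ics <- events[events$kind == "IC", ]
  fcs <- events[events$kind == "FC", ]
  if (nrow(ics) < 3) abort("fewer than 1 complete stride")
  n_str <- nrow(ics) - 2L
  res <- vector("list", n_str)
  for (i in seq_len(n_str)) {
    ic0 <- ics$t[i]; ic1 <- ics$t[i + 1]; ic2 <- ics$t[i + 2]
    fc_contra <- fcs$t[fcs$t > ic0 & fcs$t < ic1]
    fc_ipsi <- fcs$t[fcs$t > ic1 & fcs$t < ic2]
    fc_contra <- if (length(fc_contra)) fc_contra[1] else NA_real_
    fc_ipsi <- if (length(fc_ipsi)) fc_ipsi[1] else NA_real_
    stride_time <- ic2 - ic0
    stance <- fc_ipsi - ic0
    res[[i]] <- tibble::tibble(
      side = ics$side[i], ic0 = ic0, ic1 = ic1, ic2 = ic2,
      fc_contra = fc_contra, fc_ipsi = fc_ipsi,
      stride_time = stride_time,
      step_time0 = ic1 - ic0, step_time1 = ic2 - ic1,
      stance_time = stance, swing_time = stride_time - stance,
      double_support_time = (fc_contra - ic0) + (fc_ipsi - ic1)
    )
  }
  strides <- dplyr::bind_rows(res)

  reason <- rep(NA_character_, n_str)
  flag <- function(bad, why) ifelse(bad & is.na(reason), why, reason)
  reason <- flag(is.na(strides$fc_ipsi) | is.na(strides$fc_contra), "missing FC")
  reason <- flag(strides$stride_time < config$stride_time_range[1] |
                   strides$stride_time > config$stride_time_range[2],
                 "stride time out of range")
  sf <- strides$stance_time / strides$stride_time
  reason <- flag(!is.na(sf) & (sf < config$stance_frac_range[1] |
                                 sf > config$stance_frac_range[2]),
                 "stance fraction out of range")
  med_st <- median(strides$stride_time)
  reason <- flag(strides$stride_time > config$turn_factor * med_st, "turn")
  strides$valid <- is.na(reason)
  strides$invalid_reason <- reason
  structure(strides,
            fs = attr(events, "fs"), config = config,
            class = c("gait_strides", class(tibble::tibble())))
}

#' Vertical excursion of the centre of mass over one stride
#'
#' Double-integrates the raw (unfiltered) vertical acceleration over the
#' stride window and returns the peak-to-peak excursion of the position
#' series. Integration drift is bounded by per-stride linear detrending at
#' every stage: a least-squares line is removed from the windowed
#' acceleration (killing constant bias and linear drift exactly, and
#' phase-neutral for stride-periodic content), and endpoint-anchored lines
#' are removed from the velocity and position series (the body returns to
#' the same posture at consecutive ipsilateral contacts, so like-phase
#' endpoints should match).
#'
#' @param sig The `vertical_signal` the stride was detected on.
#' @param ic0,ic2 Stride window boundaries in seconds.
#' @return Vertical excursion `h` in metres.
#' @export
stride_vertical_displacement <- function(sig, ic0, ic2) {
  fs <- attr(sig, "fs")
  if (ic0 < sig$time[1] - 1e-9 || ic2 > sig$time[nrow(sig)] + 1e-9) {
    abort("stride window extends past the signal")
  }
  idx <- which(sig$time >= ic0 - 1e-9 & sig$time <= ic2 + 1e-9)
  a <- detrend_linear(sig$a_v[idx])
  v <- detrend_endpoint(cumtrapz(a, 1 / fs))
  p <- detrend_endpoint(cumtrapz(v, 1 / fs))
  max(p) - min(p)
}

#' Inverted-pendulum stride length
#'
#' Treats the body as a rigid pendulum of length `l` pivoting over the stance
#' foot; a vertical excursion `h` of the pendulum pivot corresponds to a
#' stride length of `2 * sqrt(2 * l * h - h^2)`.
#'
#' @param h Vertical centre-of-mass excursion in metres, `0 <= h <= l`.
#' @param l Pendulum length in metres (height of the lumbar sensor above
#'   ground; about 0.53 x body height).
#' @return Stride length in metres.
#' @export
inverted_pendulum_stride_length <- function(h, l) {
  if (any(l <= 0)) abort("pendulum length must be positive")
  if (any(h < 0)) abort("vertical excursion must be non-negative")
  if (any(h > l)) abort("vertical excursion cannot exceed pendulum length")
  2 * sqrt(2 * l * h - h^2)
}

#' Complete per-stride spatial and rate measures
#'
#' Adds the inverted-pendulum stride length, the symmetric step length
#' (`stride_length / 2`; a single lumbar device cannot resolve per-side step
#' lengths), gait speed (`stride_length / stride_time`) and cadence
#' (`60 / mean(step_time)` steps per minute) to an assembled stride table.
#'
#' @param strides A `gait_strides` tibble.
#' @param sig The `vertical_signal` used for detection (raw, unfiltered
#'   orientation output), covering all stride windows.
#' @param l Pendulum length in metres; defaults to `0.53 * height`.
#' @param height Subject height in metres (used only when `l` is `NULL`).
#' @return The stride tibble with columns `h`, `stride_length`, `step_length`,
#'   `gait_speed`, `cadence` added.
#' @export
compute_stride_features <- function(strides, sig, l = NULL, height = NULL) {
  if (is.null(l)) {
    if (is.null(height)) abort("supply either `l` or `height`")
    l <- 0.53 * height
  }
  h <- vapply(seq_len(nrow(strides)), function(i) {
    if (!strides$valid[i]) return(NA_real_)
    stride_vertical_displacement(sig, strides$ic0[i], strides$ic2[i])
  }, numeric(1))
  # excursions beyond the pendulum length fail QC rather than erroring
  bad_h <- !is.na(h) & (h > l)
  if (any(bad_h)) {
    strides$valid[bad_h] <- FALSE
    strides$invalid_reason[bad_h] <- "implausible vertical excursion"
    h[bad_h] <- NA_real_
  }
  strides$h <- h
  sl <- rep(NA_real_, length(h))
  ok <- !is.na(h)
  if (any(ok)) sl[ok] <- inverted_pendulum_stride_length(h[ok], l)
  strides$stride_length <- sl
  strides$step_length <- strides$stride_length / 2
  strides$gait_speed <- strides$stride_length / strides$stride_time
  strides$cadence <- 60 / ((strides$step_time0 + strides$step_time1) / 2)
  attr(strides, "l") <- l
  strides
}

#' Run the full single-device extraction pipeline
#'
#' Convenience chain: unit conversion, vertical orientation, event detection,
#' stride assembly, vertical-excursion integration, and spatial measures.
#'
#' @param rec A [gait_recording()].
#' @param l,height Pendulum geometry, as in [compute_stride_features()].
#' @param event_cfg,stride_cfg Module configurations.
#' @return A `gait_strides` tibble with all temporal and spatial columns; the
#'   detected events and vertical signal are attached as attributes `events`
#'   and `signal`.
#' @export
extract_gait <- function(rec, l = NULL, height = NULL,
                         event_cfg = event_config(),
                         stride_cfg = stride_config()) {
  sig <- orient_vertical(convert_units(rec))
  events <- detect_gait_events(sig, config = event_cfg)
  strides <- assemble_strides(events, config = stride_cfg)
  strides <- compute_stride_features(strides, sig, l = l, height = height)
  attr(strides, "events") <- events
  attr(strides, "signal") <- sig
  attr(strides, "subject_id") <- attr(rec, "subject_id")
  attr(strides, "visit_id") <- attr(rec, "visit_id")
  strides
}

#' Export per-stride measures to a delimited file
#'
#' @param strides A `gait_strides` tibble.
#' @param path File path.
#' @param delim Field delimiter.
#' @export
write_strides <- function(strides, path, delim = ",") {
  readr::write_delim(tibble::as_tibble(strides), path, delim = delim)
  invisible(path)
}
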