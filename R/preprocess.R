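# From a raw triaxial recording to a clean vertical-acceleration series.
#
# The vertical channel is defined by the direction of the mean specific-force
# (gravity) vector over the recording: stationary wear reads +1 g along it.
# After gravity removal the series is re-signed so that positive values point
# DOWN (along gravity). Under that convention, and with the centre of mass at
# its lowest around initial contact, the wavelet-differentiated series used by
# the event detector has minima at initial contacts.

#' Convert acceleration units to m/s^2
#'
#' @param rec A [gait_recording()].
#' @return The recording with all axes in m/s^2.
#' @export
convert_units <- function(rec) {
  units <- attr(rec, "units")
  if (is.null(units) || !units %in% c("g", "m/s2")) {
    abort(sprintf("unknown acceleration unit: %s", units %||% "<none>"))
  }
  if (units == "g") {
    rec$ax <- rec$ax * .g0
    rec$ay <- rec$ay * .g0
    rec$az <- rec$az * .g0
    attr(rec, "units") <- "m/s2"
  }
  rec
}

#' Extract the gravity-removed vertical acceleration
#'
#' Identifies the vertical direction as the unit vector of the mean
#' (equivalently, 0.25 Hz low-passed) specific force over the recording, which
#' must be within 30% of standard gravity in magnitude -- otherwise the device
#' was likely not worn or the units are wrong. The triaxial signal is projected
#' onto that direction, the gravity component subtracted, and the result signed
#' so that positive acceleration points down (along gravity).
#'
#' Because the projection uses the recording's own mean vector, the result is
#' invariant under any fixed rotation of the device axes.
#'
#' @param rec A [gait_recording()] in m/s^2 with at least 2 s of data.
#' @param max_gravity_dev Maximum relative deviation of the mean specific-force
#'   magnitude from standard gravity (default 0.3).
#' @return A `vertical_signal` tibble with columns `time`, `a_v` and attributes
#'   `fs` and `provenance`.
#' @export
orient_vertical <- function(rec, max_gravity_dev = 0.3) {
  if (attr(rec, "units") != "m/s2") {
    abort("recording must be in m/s2; call convert_units() first")
  }
  if (diff(range(rec$time)) < 2) abort("need at least 2 s of data")
  gvec <- c(mean(rec$ax), mean(rec$ay), mean(rec$az))
  gmag <- sqrt(sum(gvec^2))
  if (abs(gmag - .g0) > max_gravity_dev * .g0) {
    abort(sprintf(
      "no axis combination within %d%% of gravity magnitude (found %.2f m/s2); device not worn or wrong units",
      round(100 * max_gravity_dev), gmag
    ))
  }
  ghat <- gvec / gmag
  p <- rec$ax * ghat[1] + rec$ay * ghat[2] + rec$az * ghat[3]
  a_v <- -(p - mean(p)) # positive down, gravity removed
  vertical_signal(tibble::tibble(time = rec$time, a_v = a_v),
                  fs = attr(rec, "fs"),
                  provenance = list(gravity_vector = gvec,
                                    gravity_magnitude = gmag,
                                    subject_id = attr(rec, "subject_id"),
                                    visit_id = attr(rec, "visit_id")))
}

vertical_signal <- function(data, fs, provenance = list()) {
  structure(tibble::as_tibble(data),
            fs = fs, provenance = provenance,
            class = c("vertical_signal", class(tibble::tibble())))
}

#' Zero-phase band-pass filter a vertical signal
#'
#' Butterworth design applied forward and backward (`signal::filtfilt`) so
#' event timing is not phase-shifted.
#'
#' @param sig A `vertical_signal`.
#' @param low_hz,high_hz Band edges in Hz; `0 <= low_hz < high_hz < fs/2`.
#' @param order Butterworth order of the one-pass design (default 2; the
#'   forward-backward pass doubles the effective order).
#' @return Filtered `vertical_signal` with provenance updated.
#' @export
filter_signal <- function(sig, low_hz = 0.25, high_hz = 3, order = 2) {
  fs <- attr(sig, "fs")
  if (low_hz < 0 || low_hz >= high_hz) abort("need 0 <= low_hz < high_hz")
  if (high_hz >= fs / 2) abort("cutoff at or above Nyquist frequency")
  if (low_hz > 0) {
    bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  } else {
    bf <- signal::butter(order, high_hz / (fs / 2), type = "low")
  }
  out <- sig
  out$a_v <- signal::filtfilt(bf, sig$a_v)
  prov <- attr(sig, "provenance")
  prov$filter <- list(low_hz = low_hz, high_hz = high_hz, order = order,
                      zero_phase = TRUE)
  attr(out, "provenance") <- prov
  out
}

#' Resample a vertical signal to a new uniform rate
#'
#' Cubic-spline interpolation onto a uniform grid. Errors if a substantial
#' share of signal power lies above the target Nyquist frequency (the
#' dominant gait content would alias).
#'
#' @param sig A `vertical_signal`.
#' @param fs_target Target sampling rate in Hz.
#' @param max_alias_power Maximum tolerated fraction of spectral power above
#'   the target Nyquist (default 0.1).
#' @return Resampled `vertical_signal`.
#' @export
resample_signal <- function(sig, fs_target, max_alias_power = 0.1) {
  fs <- attr(sig, "fs")
  if (fs_target <= 0) abort("fs_target must be positive")
  if (isTRUE(all.equal(fs_target, fs))) return(sig)
  x <- sig$a_v - mean(sig$a_v)
  if (any(x != 0)) {
    pw <- Mod(fft(x))^2
    n <- length(x)
    freqs <- (seq_len(n) - 1) * fs / n
    half <- freqs <= fs / 2
    above <- sum(pw[half & freqs > fs_target / 2]) / sum(pw[half])
    if (above > max_alias_power) {
      abort("fs_target too low: dominant signal content would alias")
    }
  }
  t_new <- seq(sig$time[1], sig$time[nrow(sig)], by = 1 / fs_target)
  a_new <- stats::spline(sig$time, sig$a_v, xout = t_new, method = "fmm")$y
  prov <- attr(sig, "provenance")
  prov$resample <- list(fs_from = fs, fs_to = fs_target, method = "spline")
  vertical_signal(tibble::tibble(time = t_new, a_v = a_new),
                  fs = fs_target, provenance = prov)
}

#' @export
print.vertical_signal <- function(x, ...) {
  cat(sprintf("<vertical_signal> %.5g Hz, %.1f s\n",
              attr(x, "fs"), diff(range(x$time))))
  NextMethod()
}
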