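# Wavelet-based detection of initial contacts (IC) and final contacts (FC)
# from gravity-aligned vertical acceleration.
#
# Pipeline: band-pass the signal inside the gait band, integrate it over time,
# differentiate the integrand with a Gaussian-derivative continuous wavelet at
# a scale tied to the dominant step frequency (minima = ICs, refined at a finer
# scale), differentiate once more at twice the scale (maxima = FCs), then
# assign alternating pseudo-sides to successive ICs. A single lumbar device
# cannot label anatomical left/right; alternation is all the asymmetry
# features need.

#' Event-detection configuration
#'
#' @param ic_scale_factor Wavelet scale for IC detection as a multiple of
#'   `fs / f_step` samples.
#' @param fc_scale_factor Scale multiple for the second (FC) differentiation,
#'   relative to `fs / f_step`.
#' @param refine_scale_factor Finer scale used to re-localise each IC within a
#'   fifth of a step period of its coarse position; small scales track
#'   step-to-step timing asymmetry that heavier smoothing averages away.
#' @param min_separation_frac Minimum separation between accepted extrema, as
#'   a fraction of the dominant step period.
#' @param prominence_frac Minimum topographic prominence of an accepted
#'   extremum, as a fraction of the series' median absolute deviation.
#' @param band,filter_order Zero-phase band-pass applied before integration.
#' @return A named list of configuration values.
#' @export
event_config <- function(ic_scale_factor = 1, fc_scale_factor = 2,
                         refine_scale_factor = 0.35,
                         min_separation_frac = 0.25, prominence_frac = 0.2,
                         band = c(0.25, 3), filter_order = 2) {
  list(ic_scale_factor = ic_scale_factor, fc_scale_factor = fc_scale_factor,
       refine_scale_factor = refine_scale_factor,
       min_separation_frac = min_separation_frac,
       prominence_frac = prominence_frac, band = band,
       filter_order = filter_order)
}

#' Dominant step frequency of a walking bout
#'
#' Peak of the periodogram within the gait band (0.5-3 Hz by default), after
#' smoothing to a resolution of about 0.1 Hz. The smoothed peak must stand
#' well clear of the in-band noise floor (median smoothed power) -- a
#' broadband spectrum without periodicity, or a flat signal, is judged to
#' contain no gait.
#'
#' @param sig A `vertical_signal` of at least 5 s.
#' @param fmin,fmax Search band in Hz.
#' @param min_peak_ratio Minimum ratio of smoothed peak power to the median
#'   in-band smoothed power.
#' @return Frequency in Hz.
#' @export
dominant_step_frequency <- function(sig, fmin = 0.5, fmax = 3,
                                    min_peak_ratio = 10) {
  fs <- attr(sig, "fs")
  if (diff(range(sig$time)) < 5) abort("need at least 5 s of signal")
  x <- sig$a_v - mean(sig$a_v)
  n <- length(x)
  pw <- Mod(fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  # moving-average smoothing to ~0.1 Hz so a single large noise bin cannot
  # pose as a periodicity
  df <- fs / n
  k <- max(3, 2 * floor(0.05 / df) + 1)
  pw_s <- as.numeric(stats::filter(pw, rep(1 / k, k), sides = 2))
  inband <- which(freqs >= fmin & freqs <= fmax & !is.na(pw_s))
  if (!length(inband) || all(pw_s[inband] == 0)) {
    abort("no dominant gait frequency")
  }
  peak <- inband[which.max(pw_s[inband])]
  if (pw_s[peak] < min_peak_ratio * median(pw_s[inband])) {
    abort("no dominant gait frequency")
  }
  freqs[peak]
}

#' Detect initial and final contacts
#'
#' @param sig An oriented, gravity-removed `vertical_signal` (see
#'   [orient_vertical()]).
#' @param config See [event_config()].
#' @param f_step Dominant step frequency in Hz; estimated from the signal via
#'   [dominant_step_frequency()] when `NULL`.
#' @return A `gait_events` tibble with columns `t` (s), `kind` (`"IC"`/`"FC"`),
#'   `side` (`"A"`/`"B"` pseudo-sides for ICs, `NA` for FCs), and
#'   `scale_used` (samples). Events are time-ordered; at most one FC is kept
#'   strictly between each consecutive IC pair (the strongest candidate).
#' @export
detect_gait_events <- function(sig, config = event_config(), f_step = NULL) {
  fs <- attr(sig, "fs")
  if (sd(sig$a_v) == 0) {
    abort("fewer than 3 ICs detected (no analyzable gait)")
  }
  if (is.null(f_step)) f_step <- dominant_step_frequency(sig)
  filt <- filter_signal(sig, config$band[1], config$band[2],
                        config$filter_order)
  v <- cumtrapz(filt$a_v - mean(filt$a_v), 1 / fs)

  step_samples <- fs / f_step
  s_ic <- config$ic_scale_factor * step_samples
  s_fc <- config$fc_scale_factor * step_samples
  s_rf <- config$refine_scale_factor * step_samples
  w1 <- wavelet_differentiate(v, s_ic)
  wr <- wavelet_differentiate(v, s_rf)
  w2 <- wavelet_differentiate(w1, s_fc)

  min_sep <- config$min_separation_frac * step_samples
  ic_i <- find_extrema(w1, minima = TRUE, min_sep = min_sep,
                       prominence_frac = config$prominence_frac)
  # refine each IC on the finer-scale series
  half <- floor(0.2 * step_samples)
  ic_i <- vapply(ic_i, function(i) {
    lo <- max(1L, i - half)
    hi <- min(length(wr), i + half)
    as.integer(lo + which.min(wr[lo:hi]) - 1L)
  }, integer(1))
  fc_i <- find_extrema(w2, minima = FALSE, min_sep = min_sep,
                       prominence_frac = config$prominence_frac)

  # discard events inside the kernel edge region
  edge <- ceiling(4 * s_fc / 4)
  keep_interior <- function(i) i[i > edge & i <= length(v) - edge]
  ic_i <- keep_interior(ic_i)
  fc_i <- keep_interior(fc_i)
  ic_i <- sort(unique(ic_i))
  if (length(ic_i) < 3) {
    abort("fewer than 3 ICs detected (no analyzable gait)")
  }
  # keep the strongest FC candidate strictly inside each IC-to-IC gap
  fc_keep <- integer(0)
  for (j in seq_len(length(ic_i) - 1)) {
    cand <- fc_i[fc_i > ic_i[j] & fc_i < ic_i[j + 1]]
    if (length(cand)) fc_keep <- c(fc_keep, cand[which.max(w2[cand])])
  }

  t0 <- sig$time[1]
  events <- dplyr::bind_rows(
    tibble::tibble(t = t0 + (ic_i - 1) / fs, kind = "IC",
                   side = rep(c("A", "B"), length.out = length(ic_i)),
                   scale_used = s_ic),
    tibble::tibble(t = t0 + (fc_keep - 1) / fs, kind = "FC",
                   side = NA_character_, scale_used = s_fc)
  )
  events <- dplyr::arrange(events, .data$t)
  structure(events,
            fs = fs, f_step = f_step, config = config,
            class = c("gait_events", class(tibble::tibble())))
}

#' Export detected events to a delimited file
#'
#' @param events A `gait_events` tibble.
#' @param path File path.
#' @param delim Field delimiter.
#' @export
write_gait_events <- function(events, path, delim = ",") {
  readr::write_delim(events, path, delim = delim)
  invisible(path)
}
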