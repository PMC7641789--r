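# Ground-truth generators. simulate_walk() produces a raw triaxial recording
# of a 2-minute walk with known event times; simulate_cohort() produces
# feature/score tables with the longitudinal structure the mixed model
# assumes. Both are pure functions of their parameters and seed.

#' Simulate a lumbar accelerometer recording of level walking
#'
#' The vertical centre-of-mass trajectory is one cosine arc per step
#' (inverted-pendulum kinematics): height is minimal at each initial contact
#' and the peak-to-peak excursion is `h0`. Per-step durations alternate
#' `stride_time/2 + step_asymmetry/2` (pseudo-side A) and
#' `stride_time/2 - step_asymmetry/2` (side B). The measured specific force is
#' gravity plus the analytic second derivative of the trajectory, plus a
#' decaying 12 Hz impact transient at each initial contact and white noise;
#' the three world axes are mixed by a fixed random device rotation drawn
#' from the seed.
#'
#' Ground-truth final contacts are placed a quarter step-period after each
#' initial contact - the instant the smooth trajectory's jerk peaks, implying
#' a double-support time of about a quarter of the stride (physiological).
#'
#' @param stride_time Stride duration in seconds, within 0.4-2.25.
#' @param step_asymmetry Side A minus side B step-time offset in seconds.
#' @param h0 Peak-to-peak vertical excursion in metres, `0 < h0 < l`.
#' @param l Pendulum length in metres (lumbar sensor height).
#' @param duration Recording length in seconds.
#' @param fs Sampling rate in Hz (>= 20).
#' @param noise_sd White-noise SD per axis in m/s^2 (see [walk_noise_sd()] to
#'   set it from a target signal-to-noise ratio).
#' @param impact_amplitude Initial-contact transient amplitude in m/s^2.
#' @param units Units of the emitted recording (device exports are in g).
#' @param subject_id,visit_id Identifiers stamped on the recording.
#' @param seed Integer seed; identical parameters and seed give identical
#'   recordings.
#' @return List with elements `recording` (a [gait_recording()]), `events`
#'   (ground-truth tibble `t`, `kind`, `side`), `strides` (ground-truth
#'   per-stride measures), and `params`.
#' @export
simulate_walk <- function(stride_time = 1.1, step_asymmetry = 0, h0 = 0.04,
                          l = 1.0, duration = 120, fs = 128, noise_sd = 0.1,
                          impact_amplitude = 1.5, units = c("g", "m/s2"),
                          subject_id = "sim", visit_id = 1L, seed = 1L) {
  units <- arg_match(units)
  if (stride_time < 0.4 || stride_time > 2.25) {
    abort("stride_time must lie in [0.4, 2.25] s")
  }
  if (h0 <= 0 || h0 >= l) abort("need 0 < h0 < l")
  if (fs < 20) abort("fs must be at least 20 Hz")
  if (abs(step_asymmetry) >= stride_time / 2) {
    abort("step_asymmetry too large for the stride time")
  }
  params <- list(stride_time = stride_time, step_asymmetry = step_asymmetry,
                 h0 = h0, l = l, duration = duration, fs = fs,
                 noise_sd = noise_sd, impact_amplitude = impact_amplitude,
                 units = units, seed = seed)

  t_step <- stride_time / 2
  step_dur <- function(j) {
    ifelse(j %% 2 == 1, t_step + step_asymmetry / 2,
           t_step - step_asymmetry / 2)
  }
  # full steps fitting inside the recording, plus one partial tail step so
  # the trajectory is defined through the end; an initial contact occurs at
  # every step boundary inside the signal, including the last one
  n_full <- 0L
  while (sum(step_dur(seq_len(n_full + 1L))) <= duration) n_full <- n_full + 1L
  durs <- step_dur(seq_len(n_full + 1L))
  ic <- c(0, cumsum(durs)) # boundaries; ic[n_full + 1] <= duration
  n_ic <- n_full + 1L
  sides <- rep(c("A", "B"), length.out = n_ic)

  n <- floor(duration * fs) + 1L
  t <- (seq_len(n) - 1) / fs
  k <- pmin(pmax(findInterval(t, ic), 1L), n_full + 1L)
  tau <- t - ic[k]
  w <- 2 * pi / durs[k]
  # height (up): minimal at ICs; specific force (up) = g + second derivative
  dd_up <- (h0 / 2) * w^2 * cos(w * tau)
  a_up <- .g0 + dd_up

  sim <- with_local_seed(seed, {
    if (impact_amplitude > 0) {
      for (ti in ic[seq_len(n_ic)]) {
        idx <- which(t >= ti & t < ti + 0.15)
        a_up[idx] <- a_up[idx] - impact_amplitude *
          exp(-(t[idx] - ti) / 0.03) * sin(2 * pi * 12 * (t[idx] - ti))
      }
    }
    world <- cbind(rnorm(n, 0, noise_sd), rnorm(n, 0, noise_sd),
                   a_up + rnorm(n, 0, noise_sd))
    rot <- random_rotation()
    list(acc = world %*% t(rot), rot = rot)
  })
  acc <- sim$acc
  if (units == "g") acc <- acc / .g0

  rec <- gait_recording(
    tibble::tibble(time = t, ax = acc[, 1], ay = acc[, 2], az = acc[, 3]),
    fs = fs, units = units, placement = "lumbar",
    subject_id = subject_id, visit_id = visit_id
  )

  ic_t <- ic[seq_len(n_ic)]
  fc_t <- ic_t + durs[seq_len(n_ic)] / 4
  fc_t <- fc_t[fc_t <= duration]
  events <- dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(t = ic_t, kind = "IC", side = sides),
    tibble::tibble(t = fc_t, kind = "FC", side = NA_character_)
  ), .data$t)

  n_str <- n_ic - 2L
  stride_len <- inverted_pendulum_stride_length(h0, l)
  strides <- tibble::tibble(
    side = sides[seq_len(n_str)],
    ic0 = ic_t[seq_len(n_str)],
    ic1 = ic_t[seq_len(n_str) + 1L],
    ic2 = ic_t[seq_len(n_str) + 2L],
    fc_contra = fc_t[seq_len(n_str)],
    fc_ipsi = fc_t[seq_len(n_str) + 1L]
  )
  strides$stride_time <- strides$ic2 - strides$ic0
  strides$step_time0 <- strides$ic1 - strides$ic0
  strides$step_time1 <- strides$ic2 - strides$ic1
  strides$stance_time <- strides$fc_ipsi - strides$ic0
  strides$swing_time <- strides$stride_time - strides$stance_time
  strides$double_support_time <-
    (strides$fc_contra - strides$ic0) + (strides$fc_ipsi - strides$ic1)
  strides$h <- h0
  strides$stride_length <- stride_len
  strides$step_length <- stride_len / 2
  strides$gait_speed <- stride_len / strides$stride_time
  strides$cadence <- 60 / ((strides$step_time0 + strides$step_time1) / 2)

  list(recording = rec, events = events, strides = strides, params = params)
}

#' Noise level for a target signal-to-noise ratio
#'
#' The simulated vertical acceleration is (piecewise) sinusoidal with
#' amplitude `(h0/2) * (2 * pi / (stride_time/2))^2`; this returns the
#' white-noise SD giving the requested SNR in decibels against its RMS.
#'
#' @param h0,stride_time As in [simulate_walk()].
#' @param snr_db Target SNR in dB.
#' @return Noise SD in m/s^2.
#' @export
walk_noise_sd <- function(h0, stride_time, snr_db) {
  amp <- (h0 / 2) * (2 * pi / (stride_time / 2))^2
  (amp / sqrt(2)) / 10^(snr_db / 20)
}

# Uniform random rotation matrix (axis-angle via Rodrigues' formula).
random_rotation <- function() {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

default_feature_defs <- function() {
  tibble::tibble(
    feature_name = c("gait_speed", "stride_length", "step_length",
                     "stride_time", "stance_time", "cadence"),
    intercept = c(1.20, 1.30, 0.65, 1.10, 0.68, 110),
    slope = c(-0.20, -0.15, -0.075, 0.05, 0.04, -4)
  )
}

#' Simulate a longitudinal cohort of gait features and clinician scores
#'
#' Two generative directions are available. `"feature_response"` mirrors the
#' clinical data structure: each subject draws a clinician gait score (0-4)
#' per visit (an On and an Off visit in randomized order, with a programmed
#' expected On-to-Off score increase) and each gait feature is
#' `intercept + slope * score + subject intercept + noise`.
#' `"score_response"` generates standardized features and a continuous score
#' `X beta + subject intercept + noise`, the direction in which mixed-model
#' estimation, leave-one-subject-out error, and marginal R-squared have known
#' targets.
#'
#' @param n_subjects Number of subjects.
#' @param visits Visits per subject.
#' @param score_probs Probabilities of baseline scores 0-4. The default is the
#'   0/1/2/3 score frequency profile typical of a mild-to-moderate Parkinson
#'   cohort (17:27:18:6).
#' @param direction `"feature_response"` or `"score_response"` (see above).
#' @param feature_defs Tibble with `feature_name`, `intercept`, `slope`
#'   (feature_response direction).
#' @param beta Named coefficient vector over features (score_response).
#' @param random_intercept_sd,residual_sd Variance components of the noise
#'   model, in the units of the generated response.
#' @param onoff_shift Expected On-to-Off increase of the clinician score.
#' @param cohort `"pd"` (scored, on/off states) or `"healthy"` (no score, two
#'   identical-condition visits).
#' @param seed Integer seed.
#' @return List with `features` (long feature records), `meta` (subject
#'   metadata incl. `updrs_gait` and `med_state` per visit), and `params`.
#' @export
simulate_cohort <- function(n_subjects = 34, visits = 2,
                            score_probs = c(17, 27, 18, 6, 0) / 68,
                            direction = c("feature_response", "score_response"),
                            feature_defs = default_feature_defs(),
                            beta = c(gait_speed = -0.8, cadence = 0.6),
                            random_intercept_sd = 0.15, residual_sd = 0.2,
                            onoff_shift = 0.4, cohort = c("pd", "healthy"),
                            seed = 1L) {
  direction <- arg_match(direction)
  cohort <- arg_match(cohort)
  if (abs(sum(score_probs) - 1) > 1e-8) abort("score_probs must sum to 1")
  if (random_intercept_sd < 0 || residual_sd < 0) abort("SDs must be >= 0")
  params <- list(n_subjects = n_subjects, visits = visits,
                 score_probs = score_probs, direction = direction,
                 random_intercept_sd = random_intercept_sd,
                 residual_sd = residual_sd, onoff_shift = onoff_shift,
                 cohort = cohort, seed = seed)

  with_local_seed(seed, {
    ids <- sprintf("S%03d", seq_len(n_subjects))
    if (cohort == "pd") {
      age <- rnorm(n_subjects, 68.1, 8.1)
      male <- rbinom(n_subjects, 1, 23 / 34)
      bmi <- pmax(rnorm(n_subjects, 28.9, 7.1), 16)
      ysfs <- round(pmax(rnorm(n_subjects, 6, 3), 0.5), 1)
    } else {
      age <- rnorm(n_subjects, 44.4, 10.5)
      male <- rbinom(n_subjects, 1, 27 / 59)
      bmi <- pmax(rnorm(n_subjects, 25.3, 4.8), 16)
      ysfs <- rep(NA_real_, n_subjects)
    }
    height <- rnorm(n_subjects, 1.7, 0.1)

    base_score <- sample(0:4, n_subjects, replace = TRUE, prob = score_probs)
    off_first <- rbinom(n_subjects, 1, 0.5) == 1

    meta <- purrr::map_dfr(seq_len(n_subjects), function(i) {
      vis <- seq_len(visits)
      if (cohort == "pd") {
        state <- if (off_first[i]) c("Off", "On") else c("On", "Off")
        state <- rep(state, length.out = visits)
        score <- ifelse(state == "Off",
                        pmin(base_score[i] + rbinom(visits, 1, onoff_shift), 4),
                        base_score[i])
      } else {
        state <- rep(NA_character_, visits)
        score <- rep(NA_real_, visits)
      }
      tibble::tibble(
        subject_id = ids[i], age = age[i],
        gender = ifelse(male[i] == 1, "M", "F"), height = height[i],
        bmi = bmi[i], years_since_first_symptoms = ysfs[i],
        visit = vis, med_state = state, updrs_gait = score
      )
    })

    if (direction == "feature_response") {
      score_num <- ifelse(is.na(meta$updrs_gait), 0, meta$updrs_gait)
      features <- purrr::map_dfr(seq_len(nrow(feature_defs)), function(f) {
        b_i <- rnorm(n_subjects, 0, random_intercept_sd)
        tibble::tibble(
          subject_id = meta$subject_id, visit = meta$visit,
          med_state = meta$med_state, device_config = "one",
          feature_name = feature_defs$feature_name[f],
          value = feature_defs$intercept[f] +
            feature_defs$slope[f] * score_num +
            b_i[match(meta$subject_id, ids)] +
            rnorm(nrow(meta), 0, residual_sd)
        )
      })
    } else {
      fnames <- names(beta)
      X <- matrix(rnorm(nrow(meta) * length(beta)), nrow(meta), length(beta),
                  dimnames = list(NULL, fnames))
      b_i <- rnorm(n_subjects, 0, random_intercept_sd)
      meta$updrs_gait <- as.numeric(X %*% beta) +
        b_i[match(meta$subject_id, ids)] +
        rnorm(nrow(meta), 0, residual_sd)
      features <- tibble::as_tibble(X) |>
        dplyr::mutate(subject_id = meta$subject_id, visit = meta$visit,
                      med_state = meta$med_state, device_config = "one") |>
        tidyr::pivot_longer(dplyr::all_of(fnames),
                            names_to = "feature_name", values_to = "value")
    }
    list(features = validate_feature_records(features), meta = meta,
         params = params)
  })
}
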