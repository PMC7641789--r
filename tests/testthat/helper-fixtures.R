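# Shared fixture builders. Everything is generated in code at test time.

# A bare vertical_signal from a numeric series.
make_signal <- function(a_v, fs = 128, t0 = 0) {
  gaitwave:::vertical_signal(
    tibble::tibble(time = t0 + (seq_along(a_v) - 1) / fs, a_v = a_v),
    fs = fs
  )
}

# Pure sinusoid vertical signal.
sine_signal <- function(freq, fs = 128, duration = 30, amp = 1) {
  t <- seq(0, duration, by = 1 / fs)
  make_signal(amp * sin(2 * pi * freq * t), fs = fs)
}

# Simulated walk at a given SNR, plus its oriented vertical signal.
walk_fixture <- function(stride_time = 1.1, h0 = 0.04, duration = 60,
                         snr_db = 20, step_asymmetry = 0, seed = 1,
                         impact_amplitude = 1.5) {
  noise <- if (is.finite(snr_db)) walk_noise_sd(h0, stride_time, snr_db) else 0
  sim <- simulate_walk(stride_time = stride_time, h0 = h0,
                       duration = duration, noise_sd = noise,
                       step_asymmetry = step_asymmetry,
                       impact_amplitude = impact_amplitude, seed = seed)
  sim$signal <- orient_vertical(convert_units(sim$recording))
  sim
}

# Match detected IC times against truth within the detector's reporting span.
# Returns per-true-IC absolute errors (s) and the spurious-detection count.
match_ic <- function(detected_t, true_t, fs, tol_samples = 2) {
  span <- range(detected_t)
  truth <- true_t[true_t >= span[1] - 0.5 / fs & true_t <= span[2] + 0.5 / fs]
  err <- vapply(truth, function(x) min(abs(detected_t - x)), numeric(1))
  spurious <- sum(vapply(detected_t,
                         function(x) min(abs(true_t - x)),
                         numeric(1)) > tol_samples / fs)
  list(err = err, spurious = spurious, n_true = length(truth))
}

# Aggregate a ground-truth stride table the same way as a detected bout.
truth_features <- function(sim, subject_id, visit = 1) {
  st <- sim$strides
  st$valid <- TRUE
  st$invalid_reason <- NA_character_
  aggregate_bout(st, subject_id = subject_id, visit = visit)
}

# Random complete subjects-by-raters table.
random_icc_table <- function(n, k, subject_sd = 1, rater_sd = 0.3,
                             noise_sd = 0.5) {
  subj <- rnorm(n, 0, subject_sd)
  rater <- rnorm(k, 0, rater_sd)
  outer(subj, rater, "+") + matrix(rnorm(n * k, 0, noise_sd), n, k)
}

# Independent ICC(2,1) oracle: two-way ANOVA mean squares via aov(), then the
# variance-components ratio sigma2_subject / (sigma2_subject + sigma2_rater
# + sigma2_error).
icc_oracle_aov <- function(m) {
  df <- expand.grid(S = factor(seq_len(nrow(m))), R = factor(seq_len(ncol(m))))
  df$y <- as.vector(m)
  ms <- summary(stats::aov(y ~ S + R, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(m); k <- ncol(m)
  s2_s <- (msr - mse) / k
  s2_r <- (msc - mse) / n
  s2_s / (s2_s + s2_r + mse)
}

# Wide modelling frame from a simulate_cohort() result.
cohort_frame <- function(cohort) {
  wide <- tidyr::pivot_wider(cohort$features,
                             id_cols = c("subject_id", "visit"),
                             names_from = "feature_name",
                             values_from = "value")
  dplyr::inner_join(wide, cohort$meta, by = c("subject_id", "visit"))
}
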