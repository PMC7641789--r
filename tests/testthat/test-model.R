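test_that("standardization produces exact z-scores and rejects constants", {
  d <- tibble::tibble(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- standardize_features(d)
  expect_equal(z$a, c(-1, 0, 1))
  expect_equal(mean(z$b), 0)
  expect_equal(sd(z$b), 1)
  expect_equal(standardize_features(z)$a, z$a, tolerance = 1e-12)
  expect_error(standardize_features(tibble::tibble(a = rep(2, 4))), "constant")
})

test_that("correlation pruning removes the worst offender of each pair", {
  gaitwave:::with_local_seed(5, {
    x <- rnorm(50)
    d <- tibble::tibble(a = x, b = x, c = rnorm(50))
    pr <- prune_correlated(d, threshold = 0.9)
    expect_equal(sort(c(pr$retained, pr$dropped$column)), c("a", "b", "c"))
    expect_equal(nrow(pr$dropped), 1)

    ortho <- tibble::tibble(a = rnorm(100), b = rnorm(100), c = rnorm(100))
    expect_equal(prune_correlated(ortho, threshold = 0.9)$retained,
                 c("a", "b", "c"))

    y <- rnorm(200)
    four <- tibble::tibble(p = y, q = y + rnorm(200, 0, 0.2),
                           r = rnorm(200), s = rnorm(200))
    stopifnot(abs(cor(four$p, four$q)) > 0.9)
    pr4 <- prune_correlated(four, threshold = 0.9)
    expect_equal(length(pr4$retained), 3)
  })
})

test_that("mixed-model estimates recover simulated fixed effects", {
  co <- simulate_cohort(n_subjects = 40, direction = "score_response",
                        beta = c(gait_speed = -0.5),
                        random_intercept_sd = 0.3, residual_sd = 0.2,
                        seed = 7)
  d <- cohort_frame(co)
  m <- fit_longitudinal_model(d, features = "gait_speed",
                              covariates = character(0))
  td <- tidy(m)
  est <- td$estimate[td$term == "gait_speed"]
  se <- td$std_error[td$term == "gait_speed"]
  expect_lt(abs(est - (-0.5)), 3 * se)
  vc <- nlme::VarCorr(m$fit)
  expect_equal(as.numeric(vc["(Intercept)", "StdDev"]), 0.3, tolerance = 0.35)
  expect_equal(m$fit$sigma, 0.2, tolerance = 0.25)
})

test_that("a constant response yields zero slopes", {
  d <- tibble::tibble(subject_id = rep(sprintf("S%d", 1:15), each = 2),
                      visit = rep(1:2, 15),
                      x = gaitwave:::with_local_seed(1, rnorm(30)),
                      updrs_gait = 2)
  m <- fit_longitudinal_model(d, features = "x", covariates = character(0))
  expect_lt(abs(tidy(m)$estimate[2]), 1e-8)
})

test_that("single observations per subject degrade to a fixed-effects fit", {
  d <- tibble::tibble(subject_id = sprintf("S%d", 1:20), visit = 1,
                      x = gaitwave:::with_local_seed(2, rnorm(20)))
  d$updrs_gait <- 1 + 0.5 * d$x + rnorm(20, 0, 0.1)
  expect_warning(m <- fit_longitudinal_model(d, features = "x",
                                             covariates = character(0)),
                 "repeated")
  expect_equal(m$engine, "lm")
  expect_equal(unname(coef(m$fit)["x"]), 0.5, tolerance = 0.2)
})

test_that("stepwise AIC drops null features and keeps strong ones", {
  dropped <- kept <- 0
  for (seed in 1:8) {
    co <- simulate_cohort(n_subjects = 60, direction = "score_response",
                          beta = c(f_strong = -0.8, f_null = 0),
                          random_intercept_sd = 0.3, residual_sd = 0.3,
                          seed = 100 + seed)
    d <- cohort_frame(co)
    m <- fit_longitudinal_model(d, features = c("f_strong", "f_null"),
                                covariates = character(0))
    sel <- stepwise_aic_select(m)
    if (!"f_null" %in% sel$selected_terms) dropped <- dropped + 1
    if ("f_strong" %in% sel$selected_terms) kept <- kept + 1
    expect_lte(AIC(sel$fit), AIC(m$fit))
  }
  expect_gte(dropped, 6)
  expect_equal(kept, 8)
})

test_that("stepwise selection is a fixed point on a minimal model", {
  co <- simulate_cohort(n_subjects = 50, direction = "score_response",
                        beta = c(gait_speed = -0.9),
                        random_intercept_sd = 0.2, residual_sd = 0.2,
                        seed = 13)
  d <- cohort_frame(co)
  m <- fit_longitudinal_model(d, features = "gait_speed",
                              covariates = character(0))
  sel <- stepwise_aic_select(m)
  expect_equal(sel$selected_terms, "gait_speed")
})

test_that("Type-III Wald statistics equal (estimate/SE)^2 for scalar terms", {
  co <- simulate_cohort(n_subjects = 40, direction = "score_response",
                        beta = c(gait_speed = -0.5, cadence = 0.3),
                        seed = 17)
  d <- cohort_frame(co)
  m <- fit_longitudinal_model(d, features = c("gait_speed", "cadence"),
                              covariates = c("age", "gender"))
  t3 <- type3_tests(m)
  td <- tidy(m)
  for (tm in c("gait_speed", "cadence", "age")) {
    expect_equal(t3$chisq[t3$term == tm],
                 (td$estimate[td$term == tm] / td$std_error[td$term == tm])^2,
                 tolerance = 1e-10)
  }
  expect_true(all(t3$df == 1))
  skip_if_not_installed("car")
  ca <- car::Anova(m$fit, type = 3)
  expect_equal(t3$chisq, unname(ca$Chisq[rownames(ca) != "(Intercept)"]),
               tolerance = 1e-6)
})

test_that("marginal R-squared follows the variance decomposition", {
  # perfect fixed-effects fit: no random or residual variance
  d <- tibble::tibble(subject_id = sprintf("S%d", 1:20), visit = 1,
                      x = gaitwave:::with_local_seed(3, rnorm(20)))
  d$updrs_gait <- 2 * d$x
  suppressWarnings(m0 <- fit_longitudinal_model(d, features = "x",
                                                covariates = character(0)))
  expect_equal(marginal_r2(m0), 1, tolerance = 1e-6)

  # no fixed effect: all variance is subject + residual
  co <- simulate_cohort(n_subjects = 60, direction = "score_response",
                        beta = c(gait_speed = 0), random_intercept_sd = 0.5,
                        residual_sd = 0.5, seed = 19)
  m1 <- fit_longitudinal_model(cohort_frame(co), features = "gait_speed",
                               covariates = character(0))
  expect_lt(marginal_r2(m1), 0.05)

  # plug-in value at programmed variance components, averaged over replicates
  r2s <- vapply(1:3, function(s) {
    co2 <- simulate_cohort(n_subjects = 150, direction = "score_response",
                           beta = c(a = sqrt(0.5), b = sqrt(0.5)),
                           random_intercept_sd = sqrt(0.5),
                           residual_sd = sqrt(0.5), seed = 20 + s)
    d2 <- standardize_features(cohort_frame(co2), cols = c("a", "b"))
    m2 <- fit_longitudinal_model(d2, features = c("a", "b"),
                                 covariates = character(0))
    marginal_r2(m2)
  }, numeric(1))
  expect_equal(mean(r2s), 0.5, tolerance = 0.05)
})

test_that("LOSO prediction is honest: zero-noise recovery and no leakage", {
  co <- simulate_cohort(n_subjects = 25, direction = "score_response",
                        beta = c(gait_speed = 1), random_intercept_sd = 0,
                        residual_sd = 0, seed = 23)
  d <- cohort_frame(co)
  suppressWarnings({
    m <- fit_longitudinal_model(d, features = "gait_speed",
                                covariates = character(0))
    ev <- loso_predict(m)
  })
  expect_lt(ev$rmse, 1e-6)

  co2 <- simulate_cohort(n_subjects = 20, direction = "score_response",
                         beta = c(gait_speed = -0.6, cadence = 0.4),
                         random_intercept_sd = 0.3, residual_sd = 0.3,
                         seed = 29)
  d2 <- cohort_frame(co2)
  m2 <- fit_longitudinal_model(d2, features = c("gait_speed", "cadence"),
                               covariates = character(0))
  ev2 <- loso_predict(m2)

  # perturbing the held-out subject's response cannot reach its own fold:
  # the fold's model is trained without it and its features are unchanged
  d3 <- d2
  tamper <- d3$subject_id == "S001"
  d3$updrs_gait[tamper] <- d3$updrs_gait[tamper] + 100
  m3 <- fit_longitudinal_model(d3, features = c("gait_speed", "cadence"),
                               covariates = character(0))
  ev3 <- loso_predict(m3)
  held <- ev2$predictions$subject_id == "S001"
  expect_equal(ev3$predictions$predicted[held],
               ev2$predictions$predicted[held], tolerance = 1e-10)
  expect_false(isTRUE(all.equal(ev3$predictions$observed[held],
                                ev2$predictions$observed[held])))
})

test_that("pure-noise scores are predicted no better than their spread", {
  co <- simulate_cohort(n_subjects = 40, direction = "score_response",
                        beta = c(gait_speed = 0), random_intercept_sd = 0,
                        residual_sd = 1, seed = 31)
  d <- cohort_frame(co)
  m <- fit_longitudinal_model(d, features = "gait_speed",
                              covariates = character(0))
  ev <- loso_predict(m)
  expect_equal(ev$rmse, sd(d$updrs_gait), tolerance = 0.15)
  expect_lt(ev$marginal_r2, 0.1)
})

test_that("paired Wilcoxon matches exact enumeration and handles edge cases", {
  on <- c(1.2, 2.1, 0.4, 3.3, 2.2, 1.7)
  res <- paired_wilcoxon(on + 1, on, alternative = "greater")
  expect_equal(res$p_value, 1 / 64)
  expect_equal(res$method, "exact")

  res2 <- paired_wilcoxon(c(1, 2), c(2, 1))
  expect_equal(res2$p_value, 1)

  expect_error(paired_wilcoxon(1:5, 1:5), "all differences are zero")
  expect_error(paired_wilcoxon(1:3, 1:2), "equal length")
})
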