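# broom-style tidiers for the fitted result objects.

#' @exportS3Method generics::tidy
tidy.gait_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 category = x$category, n = x$n, k = x$k)
}

#' @exportS3Method generics::glance
glance.gait_icc <- function(x, ...) tidy.gait_icc(x)

#' @exportS3Method generics::tidy
tidy.gait_lmm <- function(x, ...) {
  b <- gait_lmm_fixef(x)
  se <- sqrt(diag(as.matrix(vcov(x$fit))))
  tibble::tibble(term = names(b), estimate = unname(b), std_error = unname(se),
                 statistic = unname(b / se),
                 p_value = 2 * stats::pnorm(abs(b / se), lower.tail = FALSE))
}

#' @exportS3Method generics::glance
glance.gait_lmm <- function(x, ...) {
  tibble::tibble(aic = AIC(x$fit), log_lik = as.numeric(logLik(x$fit)),
                 marginal_r2 = marginal_r2(x),
                 sigma = if (x$engine == "lme") x$fit$sigma
                         else summary(x$fit)$sigma,
                 n_obs = nrow(x$data),
                 n_subjects = length(unique(x$data[[x$subject]])))
}

#' @exportS3Method generics::tidy
tidy.gait_model_eval <- function(x, ...) x$predictions

#' @exportS3Method generics::glance
glance.gait_model_eval <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, marginal_r2 = x$marginal_r2,
                 n_subjects = x$n_subjects,
                 n_failed_folds = length(x$failed_folds))
}

#' @exportS3Method generics::tidy
tidy.gait_criterion <- function(x, ...) x$type3

#' @exportS3Method generics::glance
glance.gait_criterion <- function(x, ...) {
  dplyr::mutate(glance(x$eval), device_config = x$device_config,
                n_terms = length(x$model$selected_terms))
}
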