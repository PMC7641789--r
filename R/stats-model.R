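# Criterion-validity modelling: feature standardization and correlation
# pruning, the longitudinal mixed-effects model of the clinician gait score,
# stepwise AIC selection, Type-III Wald tests, leave-one-subject-out
# cross-validation, marginal R-squared, and the paired On/Off comparison.

#' Standardize feature columns to zero mean and unit variance
#'
#' @param data Data frame.
#' @param cols Character vector of columns to standardize; all numeric
#'   columns by default.
#' @return `data` with the chosen columns z-scored; centers and scales are
#'   attached as attributes `center` and `scale`. A constant column is an
#'   error.
#' @export
standardize_features <- function(data, cols = NULL) {
  if (is.null(cols)) {
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  ctr <- scl <- setNames(numeric(length(cols)), cols)
  for (cn in cols) {
    x <- data[[cn]]
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) abort(sprintf("column `%s` is constant", cn))
    ctr[cn] <- mean(x, na.rm = TRUE)
    scl[cn] <- s
    data[[cn]] <- (x - ctr[cn]) / s
  }
  structure(data, center = ctr, scale = scl)
}

#' Greedy pruning of highly correlated features
#'
#' While any pair of retained columns has `|r| >= threshold`, the member of
#' the worst-offending pair with the higher mean absolute correlation to all
#' other retained columns is dropped (ties broken by column order, the
#' later column dropped).
#'
#' @param data Data frame.
#' @param cols Columns to consider; all numeric columns by default.
#' @param threshold Absolute-correlation threshold (default 0.9).
#' @return List with `retained` (character), and `dropped` (tibble of the
#'   removal log: column, the partner it collided with, and their r).
#' @export
prune_correlated <- function(data, cols = NULL, threshold = 0.9) {
  if (is.null(cols)) {
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  if (length(cols) < 2) {
    return(list(retained = cols,
                dropped = tibble::tibble(column = character(),
                                         partner = character(),
                                         r = numeric())))
  }
  cm <- abs(cor(data[cols], use = "pairwise.complete.obs"))
  diag(cm) <- 0
  log <- list()
  repeat {
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    if (cm[worst[1], worst[2]] < threshold) break
    i <- worst[1]; j <- worst[2]
    mi <- mean(cm[i, -i]); mj <- mean(cm[j, -j])
    drop <- if (mi > mj) i else if (mj > mi) j else max(i, j)
    keep_p <- if (drop == i) j else i
    log[[length(log) + 1]] <- tibble::tibble(
      column = colnames(cm)[drop], partner = colnames(cm)[keep_p],
      r = cm[i, j])
    cm <- cm[-drop, -drop, drop = FALSE]
    if (ncol(cm) < 2) break
  }
  list(retained = colnames(cm) %||% character(),
       dropped = dplyr::bind_rows(log))
}

#' Fit the longitudinal mixed-effects model of the clinician gait score
#'
#' Linear mixed model with the gait features and the clinical covariates
#' (age, gender, visit number, BMI, years since first symptoms) as fixed
#' effects and a per-participant random intercept, fitted by maximum
#' likelihood (so stepwise AIC comparisons are valid). If no participant has
#' repeated observations the random intercept is unidentifiable and the model
#' degenerates to a fixed-effects fit with a warning.
#'
#' @param data One row per observation (subject-visit), containing the
#'   response, features, covariates, and subject identifier. Features should
#'   be standardized ([standardize_features()]).
#' @param features Character vector of feature column names.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param response Response column (clinician gait score, treated as
#'   numeric).
#' @param subject Subject identifier column.
#' @return A `gait_lmm` object wrapping the fit.
#' @export
fit_longitudinal_model <- function(data, features,
                                   covariates = c("age", "gender", "visit",
                                                  "bmi",
                                                  "years_since_first_symptoms"),
                                   response = "updrs_gait",
                                   subject = "subject_id") {
  covariates <- intersect(covariates, names(data))
  terms_all <- c(features, covariates)
  need <- c(response, terms_all, subject)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(sprintf("data missing columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  data <- as.data.frame(data)
  data[[subject]] <- as.character(data[[subject]])
  if (is.character(data$gender %||% NULL)) data$gender <- factor(data$gender)
  cc <- stats::complete.cases(data[need])
  data <- data[cc, , drop = FALSE]
  fixed <- stats::as.formula(paste(response, "~",
                                   paste(terms_all, collapse = " + ")))
  random <- stats::as.formula(paste("~ 1 |", subject))
  repeated <- any(table(data[[subject]]) >= 2)
  engine <- "lme"
  if (!repeated) {
    warn("no participant has repeated observations; random-intercept variance is at the boundary (fixed-effects fit)")
    fit <- do.call(stats::lm, list(formula = fixed, data = data))
    engine <- "lm"
  } else {
    fit <- fit_lme(fixed, data, random)
  }
  structure(list(fit = fit, data = data, features = features,
                 covariates = covariates, response = response,
                 subject = subject, engine = engine),
            class = "gait_lmm")
}

#' Bidirectional stepwise AIC selection over fixed effects
#'
#' Starts from the full model and searches additions and deletions of fixed
#' effects with AIC as the cost, via [MASS::stepAIC()]. The per-participant
#' random intercept is never dropped. Deterministic given the input term
#' order.
#'
#' @param model A `gait_lmm`.
#' @return A `gait_lmm` wrapping the reduced fit; the selected fixed-effect
#'   terms are in `$selected_terms`.
#' @export
stepwise_aic_select <- function(model) {
  red <- MASS::stepAIC(model$fit, direction = "both", trace = 0)
  terms_kept <- attr(terms(stats::formula(red)), "term.labels")
  out <- model
  out$fit <- red
  out$features <- intersect(model$features, terms_kept)
  out$covariates <- intersect(model$covariates, terms_kept)
  out$selected_terms <- terms_kept
  out
}

# Maximum-likelihood lme fit whose stored call embeds the data and names the
# function as nlme::lme, so downstream update()/stepAIC() re-evaluation works
# without nlme on the search path.
fit_lme <- function(fixed, data, random) {
  cl <- as.call(list(
    quote(nlme::lme), fixed = fixed, data = data, random = random,
    method = "ML", na.action = quote(stats::na.omit),
    control = nlme::lmeControl(maxIter = 100, msMaxIter = 100,
                               returnObject = TRUE)
  ))
  fit <- eval(cl)
  # the stored call must re-evaluate inside update()/stepAIC() without nlme
  # attached, so give it a namespaced head
  fit$call[[1]] <- quote(nlme::lme)
  fit
}

gait_lmm_fixef <- function(model) {
  if (model$engine == "lme") nlme::fixef(model$fit) else coef(model$fit)
}

#' Type-III Wald chi-square tests of the fixed effects
#'
#' Each term is tested given all others: for the coefficient group of a term,
#' `chi2 = b' V^-1 b` on as many degrees of freedom as coefficients (1 for a
#' scalar term, where the statistic reduces to `(estimate / SE)^2`).
#'
#' @param model A `gait_lmm`.
#' @return Tibble with `term`, `df`, `chisq`, `p_value`.
#' @export
type3_tests <- function(model) {
  b <- gait_lmm_fixef(model)
  V <- as.matrix(vcov(model$fit))
  tl <- attr(terms(stats::formula(model$fit)), "term.labels")
  asgn <- attr(
    if (model$engine == "lme") {
      model.matrix(stats::formula(model$fit), model$data)
    } else {
      model.matrix(model$fit)
    }, "assign")
  purrr::map_dfr(seq_along(tl), function(i) {
    idx <- which(asgn == i)
    chi2 <- as.numeric(t(b[idx]) %*% solve(V[idx, idx, drop = FALSE]) %*% b[idx])
    tibble::tibble(term = tl[i], df = length(idx), chisq = chi2,
                   p_value = pchisq(chi2, length(idx), lower.tail = FALSE))
  })
}

#' Marginal R-squared of a mixed model
#'
#' Variance of the fixed-effects predictions divided by the total of
#' fixed-effects, random-intercept, and residual variances: the share of
#' outcome variance explained by the fixed effects alone.
#'
#' @param model A `gait_lmm`.
#' @return Fraction in `[0, 1]`.
#' @export
marginal_r2 <- function(model) {
  if (model$engine == "lme") {
    pf_ <- as.numeric(predict(model$fit, level = 0))
    vc <- nlme::VarCorr(model$fit)
    s2_int <- as.numeric(vc["(Intercept)", "Variance"])
    s2_res <- model$fit$sigma^2
  } else {
    pf_ <- as.numeric(stats::fitted(model$fit))
    s2_int <- 0
    s2_res <- summary(model$fit)$sigma^2
  }
  vf <- var(pf_)
  tot <- vf + s2_int + s2_res
  if (tot == 0) abort("zero total variance")
  vf / tot
}

#' Leave-one-subject-out cross-validated prediction
#'
#' For each subject, the model (its current fixed-effects formula) is refitted
#' on all other subjects and the held-out subject's observations are predicted
#' from the fixed effects only (a new subject's random intercept is unknown).
#' Reports the RMSE over all held-out predictions and the marginal R-squared
#' of the full-data fit. A fold whose refit fails is skipped with a warning.
#'
#' @param model A `gait_lmm` (typically after [stepwise_aic_select()]).
#' @return A `gait_model_eval` object: list with `predictions` (tibble:
#'   subject, observed, predicted), `rmse`, `marginal_r2`, `n_subjects`,
#'   `failed_folds`.
#' @export
loso_predict <- function(model) {
  data <- model$data
  subj <- model$subject
  ids <- unique(data[[subj]])
  if (length(ids) < 3) abort("need at least 3 subjects")
  fixed <- stats::formula(model$fit)
  random <- stats::as.formula(paste("~ 1 |", subj))
  failed <- character(0)
  preds <- purrr::map_dfr(ids, function(id) {
    train <- data[data[[subj]] != id, , drop = FALSE]
    test <- data[data[[subj]] == id, , drop = FALSE]
    fold <- tryCatch({
      if (model$engine == "lme") {
        fit <- fit_lme(fixed, train, random)
        as.numeric(predict(fit, newdata = test, level = 0))
      } else {
        fit <- do.call(stats::lm, list(formula = fixed, data = train))
        as.numeric(predict(fit, newdata = test))
      }
    }, error = function(e) NULL)
    if (is.null(fold)) {
      failed <<- c(failed, id)
      return(NULL)
    }
    tibble::tibble(subject_id = id, visit = test$visit %||% NA,
                   med_state = test$med_state %||% NA_character_,
                   observed = test[[model$response]], predicted = fold)
  })
  if (length(failed)) {
    warn(sprintf("%d LOSO fold(s) failed and were skipped: %s",
                 length(failed), paste(failed, collapse = ", ")))
  }
  rmse <- sqrt(mean((preds$observed - preds$predicted)^2))
  structure(list(predictions = preds, rmse = rmse,
                 marginal_r2 = marginal_r2(model),
                 n_subjects = length(ids), failed_folds = failed),
            class = "gait_model_eval")
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are excluded (Wilcoxon's rule) and ties among absolute
#' differences receive mid-ranks. For up to 25 non-zero differences the p
#' value is exact, from the full distribution of the signed-rank sum over all
#' sign assignments (computed by dynamic programming, so ties are handled
#' exactly); above that the normal approximation with continuity correction
#' is used (via [stats::wilcox.test()]).
#'
#' @param x,y Paired series of equal length (at least 2); not all differences
#'   may be zero.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return Tibble with `statistic` (V, rank sum of positive differences),
#'   `p_value`, `n` (non-zero pairs), `method`, `alternative`.
#' @export
paired_wilcoxon <- function(x, y, alternative = c("two.sided", "greater",
                                                  "less")) {
  alternative <- arg_match(alternative)
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2) abort("need at least 2 pairs")
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) abort("all differences are zero")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (length(d) <= 25) {
    p <- exact_signrank_p(d, alternative)
    method <- "exact"
  } else {
    wt <- suppressWarnings(
      wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE,
                  alternative = alternative))
    p <- wt$p.value
    method <- "normal approximation"
  }
  tibble::tibble(statistic = v, p_value = p, n = length(d),
                 method = method, alternative = alternative)
}

# Exact null distribution of the signed-rank sum over all 2^n sign patterns,
# on doubled mid-ranks (integers even under ties), by dynamic programming.
exact_signrank_p <- function(d, alternative) {
  r2 <- round(2 * rank(abs(d)))
  v2 <- sum(r2[d > 0])
  tot <- sum(r2)
  cnt <- numeric(tot + 1)
  cnt[1] <- 1
  for (w in r2) {
    cnt <- cnt + c(rep(0, w), cnt[seq_len(tot + 1 - w)])
  }
  probs <- cnt / 2^length(r2)
  p_ge <- sum(probs[seq(v2 + 1, tot + 1)])
  p_le <- sum(probs[seq(1, v2 + 1)])
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

#' @export
print.gait_lmm <- function(x, ...) {
  cat(sprintf("<gait_lmm> %s fit: %s + (1 | %s); %d obs, %d subjects\n",
              x$engine, deparse(stats::formula(x$fit)), x$subject,
              nrow(x$data), length(unique(x$data[[x$subject]]))))
  invisible(x)
}

#' @export
print.gait_model_eval <- function(x, ...) {
  cat(sprintf("<gait_model_eval> LOSO RMSE = %.3f, marginal R2 = %.3f over %d subjects\n",
              x$rmse, x$marginal_r2, x$n_subjects))
  invisible(x)
}
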