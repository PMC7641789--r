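# Agreement and group-difference statistics: ICC(2,1) with F-based confidence
# bounds, Bland-Altman limits of agreement, Kruskal-Wallis, Conover-Iman
# post hocs, and Benjamini-Hochberg FDR adjustment.

#' Two-way random-effects, absolute-agreement, single-measurement ICC
#'
#' ICC(2,1): both subjects and raters (methods, or visits) are treated as
#' random samples and systematic rater differences count against agreement.
#' Computed from the two-way mean-squares decomposition
#' `n (MSR - MSE) / (n MSR + k MSC + (n k - n - k) MSE)`; the confidence
#' interval uses the F-distribution construction with a Satterthwaite
#' approximation for the denominator degrees of freedom.
#'
#' @param table Numeric matrix or data frame, subjects in rows and the `k`
#'   raters/methods/visits in columns; complete, `n >= 3`, `k >= 2`.
#' @param conf_level Confidence level for the bounds (default 0.95).
#' @return A `gait_icc` object: list with `icc`, `ci_low`, `ci_high`,
#'   `category`, `n`, `k`, `conf_level`, and the mean squares.
#' @export
icc_2_1 <- function(table, conf_level = 0.95) {
  m <- as.matrix(table)
  storage.mode(m) <- "double"
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3 || k < 2) abort("need at least 3 subjects and 2 raters")
  if (anyNA(m)) abort("table must be complete (no missing cells)")
  gm <- mean(m)
  if (all(m == gm)) abort("zero total variance")
  rm_ <- rowMeans(m)
  cm_ <- colMeans(m)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm_ - gm)^2) / (k - 1)
  sse <- sum((m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))

  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  denom_tail <- k * msc + (k * n - k - n) * mse
  ci_low <- n * (msr - f_l * mse) / (f_l * denom_tail + n * msr)
  ci_high <- n * (f_u * msr - mse) / (denom_tail + n * f_u * msr)

  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high,
                 category = classify_icc(icc), n = n, k = k,
                 conf_level = conf_level,
                 ms = c(msr = msr, msc = msc, mse = mse)),
            class = "gait_icc")
}

#' Benchmark category of an ICC value
#'
#' Standard reliability benchmarks: at or below 0.4 is poor, 0.4 to 0.59
#' moderate, 0.6 to 0.74 good, and 0.75 to 1 excellent.
#'
#' @param icc Numeric vector of ICC values (each at most 1).
#' @return Character vector of categories.
#' @export
classify_icc <- function(icc) {
  if (any(icc > 1 + 1e-12, na.rm = TRUE)) abort("ICC cannot exceed 1")
  dplyr::case_when(
    icc <= 0.4 ~ "poor",
    icc < 0.6 ~ "moderate",
    icc < 0.75 ~ "good",
    TRUE ~ "excellent"
  )
}

#' Bland-Altman mean difference and 95% limits of agreement
#'
#' @param x,y Paired measurement series of equal length (at least 2).
#' @return Tibble with `mean_diff`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2) abort("need at least 2 pairs")
  d <- x - y
  md <- mean(d)
  s <- sd(d)
  tibble::tibble(mean_diff = md, loa_low = md - 1.96 * s,
                 loa_high = md + 1.96 * s, sd_diff = s, n = length(d))
}

#' Kruskal-Wallis rank test across score groups
#'
#' Tie-corrected H statistic referred to a chi-square distribution with
#' `groups - 1` degrees of freedom (via [stats::kruskal.test()]).
#'
#' @param data Data frame in long format.
#' @param value,group Columns holding the response and the grouping variable.
#' @return Tibble with `statistic` (H), `df`, `p_value`, `n_groups`.
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  g <- droplevels(g)
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (length(unique(v)) == 1) {
    abort("all values identical; H undefined after tie correction")
  }
  kt <- kruskal.test(v, g)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value, n_groups = nlevels(g))
}

#' Conover-Iman post-hoc pairwise comparisons
#'
#' t statistics on the pooled ranks using the Conover-Iman pooled variance
#' with tie correction: for groups i, j the statistic is
#' `(Rbar_i - Rbar_j) / sqrt(S2 * (N - 1 - H) / (N - g) * (1/n_i + 1/n_j))`
#' with `S2` the variance of the mid-ranks and `H` the (tie-corrected)
#' Kruskal-Wallis statistic, referred to a t distribution on `N - g` degrees
#' of freedom (two-sided).
#'
#' @inheritParams kruskal_wallis
#' @param p_adjust Adjustment method for the pairwise p values (`"none"` or
#'   any [stats::p.adjust()] method; the study convention is `"BH"`).
#' @return Tibble with one row per unordered pair: `group1`, `group2`,
#'   `statistic`, `df`, `p_value`, `p_adjusted`.
#' @export
conover_iman <- function(data, value, group, p_adjust = "none") {
  v <- dplyr::pull(data, {{ value }})
  g <- droplevels(as.factor(dplyr::pull(data, {{ group }})))
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (length(unique(v)) == 1) {
    abort("all values identical; H undefined after tie correction")
  }
  N <- length(v)
  ng <- nlevels(g)
  r <- rank(v)
  h <- unname(kruskal.test(v, g)$statistic)
  s2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  rbar <- tapply(r, g, mean)
  nn <- tapply(r, g, length)
  df <- N - ng
  pairs <- utils::combn(levels(g), 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    se <- sqrt(s2 * ((N - 1 - h) / (N - ng)) * (1 / nn[[i]] + 1 / nn[[j]]))
    tstat <- (rbar[[i]] - rbar[[j]]) / se
    tibble::tibble(group1 = i, group2 = j, statistic = tstat, df = df,
                   p_value = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
  })
  out$p_adjusted <- if (p_adjust == "none") out$p_value else
    p.adjust(out$p_value, method = p_adjust)
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement; invariant to input
#' permutation and idempotent.
#'
#' @param pvals Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values in the input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' @export
print.gait_icc <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f (%g%% CI %.3f to %.3f), %s; n = %d, k = %d\n",
              x$icc, 100 * x$conf_level, x$ci_low, x$ci_high, x$category,
              x$n, x$k))
  invisible(x)
}
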