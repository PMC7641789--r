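test_that("ICC(2,1) matches the variance-components oracle on random tables", {
  gaitwave:::with_local_seed(11, {
    for (i in 1:25) {
      n <- sample(4:10, 1)
      k <- sample(2:4, 1)
      m <- random_icc_table(n, k)
      res <- icc_2_1(m)
      expect_lt(abs(res$icc - icc_oracle_aov(m)), 1e-10)
      expect_lte(res$ci_low, res$icc)
      expect_lte(res$icc, res$ci_high)
    }
  })
})

test_that("perfect agreement gives ICC 1 and offsets are penalized", {
  m <- cbind(1:6, 1:6)
  res <- icc_2_1(m)
  expect_equal(res$icc, 1)
  expect_equal(res$category, "excellent")

  shifted <- cbind(1:6, 1:6 + 2)
  res2 <- icc_2_1(shifted)
  expect_lt(res2$icc, 1)
  expect_lt(abs(res2$icc - icc_oracle_aov(shifted)), 1e-10)

  expect_error(icc_2_1(cbind(1:2, 1:2)), "at least 3")
  expect_error(icc_2_1(matrix(5, 4, 2)), "zero total variance")
  expect_error(icc_2_1(cbind(c(1, NA, 3), 1:3)), "complete")
})

test_that("a null subject effect yields near-zero ICC on average", {
  means <- gaitwave:::with_local_seed(12, replicate(500, {
    icc_2_1(matrix(runif(10), 5, 2))$icc
  }))
  expect_lt(abs(mean(means)), 0.08)
})

test_that("ICC categories reproduce the reliability benchmarks", {
  expect_equal(classify_icc(0.39), "poor")
  expect_equal(classify_icc(0.40), "poor")
  expect_equal(classify_icc(0.5), "moderate")
  expect_equal(classify_icc(0.59), "moderate")
  expect_equal(classify_icc(0.6), "good")
  expect_equal(classify_icc(0.74), "good")
  expect_equal(classify_icc(0.75), "excellent")
  expect_equal(classify_icc(1), "excellent")
  expect_error(classify_icc(1.2), "exceed")
})

test_that("Bland-Altman limits follow the paired-difference arithmetic", {
  x <- c(1, 2, 3, 4)
  ba <- bland_altman(x, x)
  expect_equal(unlist(ba[c("mean_diff", "loa_low", "loa_high")]),
               c(mean_diff = 0, loa_low = 0, loa_high = 0))

  ba2 <- bland_altman(x + 1, x)
  expect_equal(unlist(ba2[c("mean_diff", "loa_low", "loa_high")]),
               c(mean_diff = 1, loa_low = 1, loa_high = 1))

  ba3 <- bland_altman(c(0, 1, 2), c(1, 1, 1)) # d = -1, 0, 1; SD = 1
  expect_equal(ba3$mean_diff, 0)
  expect_equal(c(ba3$loa_low, ba3$loa_high), c(-1.96, 1.96))

  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("Kruskal-Wallis H matches the rank-sum arithmetic", {
  d <- tibble::tibble(v = 1:9, g = rep(c("a", "b", "c"), each = 3))
  kw <- kruskal_wallis(d, v, g)
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2)

  d2 <- tibble::tibble(v = rep(1:3, 2), g = rep(c("a", "b"), each = 3))
  expect_equal(kruskal_wallis(d2, v, g)$statistic, 0)

  expect_error(kruskal_wallis(tibble::tibble(v = 1:3, g = "a"), v, g),
               "2 groups")
  expect_error(kruskal_wallis(tibble::tibble(v = rep(1, 6),
                                             g = rep(c("a", "b"), 3)), v, g),
               "identical")
})

test_that("Conover-Iman contrasts rank separation between group pairs", {
  d <- tibble::tibble(v = c(1, 2, 3, 1, 2, 3, 10, 11, 12),
                      g = rep(c("a", "b", "c"), each = 3))
  ci <- conover_iman(d, v, g)
  expect_equal(nrow(ci), 3)
  p_ab <- ci$p_value[ci$group1 == "a" & ci$group2 == "b"]
  expect_gt(p_ab, 0.9) # identical groups
  expect_lt(ci$p_value[ci$group2 == "c"][1], 0.05)

  sep <- tibble::tibble(v = c(1:3, 11:13, 21:23),
                        g = rep(c("a", "b", "c"), each = 3))
  inter <- tibble::tibble(v = c(1, 4, 7, 2, 5, 8, 3, 6, 9),
                          g = rep(c("a", "b", "c"), each = 3))
  expect_true(all(conover_iman(sep, v, g)$p_value <
                    conover_iman(inter, v, g)$p_value))

  ci_adj <- conover_iman(d, v, g, p_adjust = "BH")
  expect_equal(ci_adj$p_adjusted, p.adjust(ci_adj$p_value, "BH"))
})

test_that("FDR adjustment follows the step-up rule and is stable", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)

  p <- gaitwave:::with_local_seed(3, runif(20)^2)
  adj <- bh_fdr(p)
  expect_true(all(adj <= 1))
  expect_true(all(adj >= p))
  # permutation invariance and monotonicity in the raw ranks
  perm <- sample(20)
  expect_equal(bh_fdr(p[perm]), adj[perm])
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
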