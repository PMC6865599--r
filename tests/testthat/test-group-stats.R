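test_that("permutation two-sample test behaves at the extremes", {
  set.seed(20)
  x <- rnorm(20)
  # identical samples: no group structure
  expect_gt(permutation_two_sample(x, x, n_perm = 500, seed = 1)$p_value, 0.9)
  # complete separation: minimum attainable p
  a <- rnorm(30)
  b <- rnorm(30, mean = 5)
  res <- permutation_two_sample(a, b, n_perm = 1000, seed = 2)
  expect_equal(res$p_value, 1 / 1001)
  # determinism and the p floor
  res2 <- permutation_two_sample(a, b, n_perm = 1000, seed = 2)
  expect_identical(res$p_value, res2$p_value)
  expect_gte(res$p_value, 1 / 1001)
  expect_lte(res$p_value, 1)
  # NA dropping and insufficient data
  expect_error(permutation_two_sample(c(1, NA, NA), c(1, 2, 3), 100),
               "insufficient")
})

test_that("permutation p-values are scale-invariant", {
  set.seed(21)
  a <- rnorm(15)
  b <- rnorm(12, 0.8)
  p1 <- permutation_two_sample(a, b, n_perm = 500, seed = 5)$p_value
  p2 <- permutation_two_sample(a * 1000, b * 1000, n_perm = 500,
                               seed = 5)$p_value
  expect_identical(p1, p2)
})

test_that("bonferroni threshold divides alpha by the partition size", {
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 20), 0.0025)
})

test_that("hedges g matches the direct formula and is antisymmetric", {
  a <- c(0, 0, 1, 1)
  b <- c(1, 1, 2, 2)
  # oracle: direct formula evaluation
  sp <- sqrt((3 * var(a) + 3 * var(b)) / 6)
  g_o <- (mean(a) - mean(b)) / sp * (1 - 3 / (4 * 8 - 9))
  expect_equal(hedges_g(a, b), g_o, tolerance = 1e-12)
  expect_equal(hedges_g(b, a), -hedges_g(a, b), tolerance = 1e-12)
  expect_equal(hedges_g(c(1, 2, 3), c(2, 1, 3)), 0)
  expect_error(hedges_g(c(1, 1), c(1, 1)), "zero pooled SD")
})

test_that("type-I error of the permutation test is calibrated", {
  # 400 null datasets at alpha = 0.05; binomial 95% band
  n_rep <- 400
  seeds <- leidar:::derive_seeds(100, 2 * n_rep)
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    set.seed(seeds[2 * i - 1])
    a <- rnorm(20)
    b <- rnorm(20)
    rej[i] <- permutation_two_sample(a, b, n_perm = 200,
                                     seed = seeds[2 * i])$p_value < 0.05
  }
  band <- 1.96 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rej) - 0.05), band + 0.005)
})

test_that("paired sign-flip test behaves on degenerate designs", {
  x <- rnorm(12)
  expect_equal(paired_permutation_within(x, x, n_perm = 200,
                                         seed = 3)$p_value, 1)
  # all differences +1: only all-same-sign flips reach |obs|
  res <- paired_permutation_within(x + 1, x, n_perm = 2000, seed = 4)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$statistic, 1)
  # pairing invariance: shuffling subjects jointly leaves p unchanged
  set.seed(9)
  y <- rnorm(12)
  ord <- sample(12)
  p1 <- paired_permutation_within(x, y, n_perm = 500, seed = 6)$p_value
  p2 <- paired_permutation_within(x[ord], y[ord], n_perm = 500,
                                  seed = 6)$p_value
  expect_identical(p1, p2)
  expect_error(paired_permutation_within(c(1, NA), c(NA, 2), 100),
               "insufficient")
})

test_that("covariate-adjusted test reduces to the unadjusted one under a
          constant covariate and ignores pure covariate structure", {
  set.seed(30)
  g <- rep(c("A", "B"), c(25, 20))
  y <- rnorm(45) + (g == "A") * 1.2
  const <- rep(3, 45)
  adj <- covariate_adjusted_test(y, g, const + rnorm(45, sd = 1e-9),
                                 n_perm = 500, seed = 7)
  raw <- permutation_two_sample(y[g == "A"], y[g == "B"], n_perm = 500,
                                seed = 7)
  expect_lt(abs(adj$p_perm - raw$p_value), 0.05)
  # metric fully explained by the covariate, groups random -> null group p
  set.seed(31)
  ps <- replicate(20, {
    x <- rnorm(45)
    covariate_adjusted_test(2 * x, sample(g), x + rnorm(45, sd = 1e-6),
                            n_perm = 200, seed = sample.int(1e6, 1))$p_perm
  })
  expect_gte(mean(ps > 0.1), 0.9)
  expect_error(covariate_adjusted_test(y, g, as.numeric(g == "A"), 100),
               "collinear")
})

test_that("covariate-adjusted test recovers a planted group effect", {
  set.seed(32)
  g <- rep(c("A", "B"), c(50, 35))
  hits <- replicate(20, {
    cov <- rnorm(85)
    y <- 1.0 * (g == "A") + 0.5 * cov + rnorm(85)
    covariate_adjusted_test(y, g, cov, n_perm = 200,
                            seed = sample.int(1e6, 1))$p_perm < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("interaction test is null-calibrated and powered for a planted
          interaction at study size", {
  g <- rep(c("A", "B"), c(50, 35))
  set.seed(40)
  # no interaction: common condition effect in both groups
  p_null <- replicate(20, {
    base <- rnorm(85)
    v1 <- base + rnorm(85, sd = 0.5)
    v2 <- base + 1 + rnorm(85, sd = 0.5)
    group_by_condition_interaction(v1, v2, g, n_perm = 200,
                                   seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(mean(p_null), 0.3)
  # planted interaction: condition effect only in group A
  hits <- replicate(20, {
    v1 <- rnorm(85, sd = 0.5)
    v2 <- v1 + (g == "A") * 0.5 + rnorm(85, sd = 0.5)
    group_by_condition_interaction(v1, v2, g, n_perm = 200,
                                   seed = sample.int(1e6, 1))$p_value < 0.05
  })
  expect_gte(mean(hits), 0.8)
  # incomplete subjects are dropped with a warning
  v1 <- rnorm(85); v2 <- rnorm(85); v2[3] <- NA
  expect_warning(group_by_condition_interaction(v1, v2, g, n_perm = 100,
                                                seed = 1), "dropped")
})

test_that("larger planted differences do not raise the median p-value", {
  set.seed(50)
  med_p <- vapply(c(0, 0.5, 1.5), function(eff) {
    ps <- replicate(25, {
      a <- rnorm(30, mean = eff)
      b <- rnorm(30)
      permutation_two_sample(a, b, n_perm = 200,
                             seed = sample.int(1e6, 1))$p_value
    })
    median(ps)
  }, numeric(1))
  expect_true(all(diff(med_p) <= 0))
})

test_that("compare_all output is reproducible and correctly flagged", {
  tx <- tiny_sample()
  m <- cluster_eigenvectors(tx$sample, k = 3, seed = 1, n_replicates = 3)
  c1 <- compare_all(tx$sample, list(k3 = m), selected_k = 3, n_perm = 200,
                    seed = 13)
  c2 <- compare_all(tx$sample, list(k3 = m), selected_k = 3, n_perm = 200,
                    seed = 13)
  expect_identical(c1$results, c2$results)
  r <- c1$results
  expect_true(all(r$p_value >= 1 / 201 & r$p_value <= 1))
  expect_identical(r$significant_corrected, r$p_value < r$alpha_corrected)
  expect_true(all(r$alpha_corrected == 0.05 / 3))
  # transition rows present for the selected k
  expect_true(any(grepl("^transition", r$metric_name)))
})
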