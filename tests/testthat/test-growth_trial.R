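test_that("treatment summaries compute mean and SE per cell", {
  rec <- simulate_trial(trial_sim_config(replicates = 3, noise_cv = 0.1,
                                         seed = 5))
  summ <- summarize_treatments(rec)
  expect_true(all(summ$n == 3))
  # cross-check one cell against a direct computation
  cell <- rec[rec$treatment == "T1" & rec$timepoint == 35, "shoot_length"]
  row <- summ[summ$treatment == "T1" & summ$timepoint == 35 &
                summ$parameter == "shoot_length", ]
  expect_equal(row$mean, mean(cell))
  expect_equal(row$se, sd(cell) / sqrt(3))

  const <- data.frame(treatment = "control", timepoint = 35, replicate = 1:3)
  for (p in GROWTH_PARAMETERS) const[[p]] <- 2
  s2 <- summarize_treatments(const)
  expect_true(all(s2$mean == 2) && all(s2$se == 0))

  one_rep <- const[1, ]
  expect_error(summarize_treatments(one_rep), "insufficient")
})

test_that("log2 fold change behaves like a logarithm of the mean ratio", {
  expect_equal(log2_fold_change(3, 3), 0)
  expect_equal(log2_fold_change(4, 1), 2)
  expect_equal(log2_fold_change(2.5, 1.0), 1.321928, tolerance = 1e-6)
  # antisymmetry
  expect_equal(log2_fold_change(1.7, 0.4), -log2_fold_change(0.4, 1.7))
  expect_error(log2_fold_change(0, 1), "positive")
})

test_that("one-way ANOVA matches a hand sums-of-squares oracle", {
  # identical groups: no between-group variance at all
  a0 <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(a0$F, 0)

  groups <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  a <- one_way_anova(groups)
  expect_equal(a$F, 3)
  expect_equal(a$df_between, 2L)
  expect_equal(a$df_within, 6L)
  # independent F-distribution oracle for the p-value
  expect_equal(a$p, pf(3, 2, 6, lower.tail = FALSE))
  expect_equal(a$p, 0.125, tolerance = 5e-3)

  # oracle: explicit Fisher decomposition on random groups
  set.seed(13)
  for (i in 1:10) {
    g <- lapply(1:3, function(j) rnorm(5, j))
    res <- one_way_anova(g)
    grand <- mean(unlist(g))
    ssb <- sum(sapply(g, function(v) 5 * (mean(v) - grand)^2))
    ssw <- sum(sapply(g, function(v) sum((v - mean(v))^2)))
    expect_equal(res$F, (ssb / 2) / (ssw / 12), tolerance = 1e-10)
  }

  # degenerate: zero within-group variance with unequal means
  inf_case <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_equal(inf_case$F, Inf)
  expect_equal(inf_case$p, 0)
  flat <- one_way_anova(list(c(2, 2), c(2, 2)))
  expect_equal(flat$F, 0)
  expect_equal(flat$p, 1)
  expect_error(one_way_anova(list(1:3)), ">= 2 groups")
  expect_error(one_way_anova(list(1, 1:3)), ">= 2 values")
})

test_that("ANOVA F is invariant under location and positive scale changes", {
  set.seed(21)
  g <- lapply(1:4, function(j) rnorm(5, j / 2))
  f0 <- one_way_anova(g)$F
  expect_equal(one_way_anova(lapply(g, function(v) v + 100))$F, f0)
  expect_equal(one_way_anova(lapply(g, function(v) v * 3.7))$F, f0)
})

test_that("null simulations reject at close to the nominal 5% rate", {
  # small-scale calibration run (the acceptance suite runs the full one)
  set.seed(31)
  n_sim <- 500
  rejections <- sum(replicate(n_sim, {
    g <- lapply(1:3, function(j) rnorm(5))
    one_way_anova(g)$p < 0.05
  }))
  rate <- rejections / n_sim
  expect_lt(abs(rate - 0.05), 0.03)
})

test_that("PCA explained variances come from the correlation spectrum", {
  # rank-1: two perfectly correlated columns
  x <- cbind(a = 1:10, b = 2 * (1:10))
  p1 <- pca_params(x)
  expect_equal(p1$explained_variance_pct[1], 100)

  # independent equal-variance columns split roughly evenly
  set.seed(8)
  x2 <- cbind(rnorm(4000), rnorm(4000))
  p2 <- pca_params(x2)
  expect_lt(abs(p2$explained_variance_pct[1] - 50), 5)

  # dense eigensolver oracle on a fixed 4x3 matrix
  x3 <- matrix(c(1, 2, 3, 4,
                 2, 1, 4, 3,
                 5, 2, 8, 1), nrow = 4)
  p3 <- pca_params(x3)
  ev <- eigen(cor(x3), symmetric = TRUE)$values
  expect_equal(p3$explained_variance_pct, 100 * ev / sum(ev),
               tolerance = 1e-8)

  # explained percentages sum to 100 and are non-increasing
  set.seed(9)
  for (i in 1:10) {
    m <- matrix(rnorm(90), nrow = 10)
    p <- pca_params(m)
    expect_equal(sum(p$explained_variance_pct), 100, tolerance = 1e-6)
    expect_true(all(diff(p$explained_variance_pct) <= 1e-12))
  }

  xc <- cbind(a = 1:5, b = rep(2, 5))
  expect_error(pca_params(xc), "degenerate column.*b")
  expect_error(pca_params(matrix(1:3, ncol = 1)), ">= 2")
})

test_that("full trial analysis recovers configured fold changes", {
  # noiseless: fold changes equal configuration exactly
  cfg0 <- trial_sim_config(noise_cv = 0, seed = 3)
  fc0 <- fold_change_table(simulate_trial(cfg0))
  for (trt in cfg0$treatments) {
    expect_true(all(abs(fc0$fold_change[fc0$treatment == trt] -
                          cfg0$fold_changes[trt, 1]) < 1e-12))
  }

  # noisy: recovered log2 fold change within 3 SE of configuration
  cfg <- trial_sim_config(fold_changes = c(T1 = 1.3, T2 = 4, consortium = 5.3),
                          noise_cv = 0.08, replicates = 5, seed = 17)
  rec <- simulate_trial(cfg)
  res <- analyze_trial(rec)
  sigma <- sqrt(log(1 + cfg$noise_cv^2))
  se_log2 <- sigma / log(2) * sqrt(2 / 5)  # SE of a difference of two means of 5 logs
  for (trt in cfg$treatments) {
    got <- res$fold_changes$log2_fc[res$fold_changes$treatment == trt]
    expect_true(all(abs(got - log2(cfg$fold_changes[trt, 1])) < 3 * se_log2))
  }
  expect_equal(names(res$pca), c("35", "70"))
  expect_true(all(res$anova$significant))
})
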