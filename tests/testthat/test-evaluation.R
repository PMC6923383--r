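test_that("score_auc matches hand-computed and brute-force values", {
  expect_equal(score_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(score_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  # 3 of the 4 positive/negative pairs correctly ordered
  expect_equal(score_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_error(score_auc(c(1, 2), c(1, 1)), "both classes")

  # exact agreement with all-pairs counting on random instances with ties
  set.seed(20)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), sample(0:2, 1))
    expect_identical(score_auc(scores, labels), brute_auc(scores, labels))
  }
})

test_that("score_auc is invariant to strictly increasing score transforms", {
  set.seed(21)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.4)
  labels[1:2] <- c(0, 1)
  a <- score_auc(scores, labels)
  expect_identical(score_auc(exp(scores), labels), a)
  expect_identical(score_auc(3 * scores + 7, labels), a)
  expect_identical(score_auc(rank(scores), labels), a)
})

test_that("score_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  scores <- round(rnorm(50), 1)
  labels <- c(0, 1, rbinom(48, 1, 0.35))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(score_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("the logistic scorer recovers known coefficients and handles degeneracy", {
  sim <- sim_logistic(500, c(1, -1), seed = 23)
  sc <- fit_glm(sim$X, sim$y)
  ref <- glm(sim$y ~ sim$X, family = binomial())
  se <- summary(ref)$coefficients[-1, "Std. Error"]
  expect_true(all(abs(sc$coef[-1] - c(1, -1)) < 3 * se))

  # a feature identical to the outcome: training scores perfectly ordered
  Xs <- cbind(f = as.numeric(sim$y))
  scs <- fit_glm(Xs, sim$y)
  expect_true(scs$fallback)
  s <- predict_scorer(scs, Xs)
  expect_equal(score_auc(s, sim$y), 1.0)

  # intercept-only model: constant scores
  sc0 <- fit_glm(matrix(numeric(0), nrow = 500, ncol = 0), sim$y)
  expect_equal(length(unique(predict_scorer(sc0, sim$X[, 0, drop = FALSE]))), 1L)

  expect_error(fit_glm(sim$X, rep(0, 500)), "both classes")
})

test_that("a perfect predictor gives AUC 1 in every real-label resample", {
  set.seed(24)
  y <- rep(c(0, 1), each = 15)
  X <- cbind(perfect = as.numeric(y), noise = rnorm(30))
  tab <- tiny_cohort(X, y)
  cfg <- eval_config(n_resamples = 50, n_permutation_resamples = 10, seed = 25)
  aucs <- resampled_auc(tab, "perfect", cfg, permute = FALSE)
  expect_true(all(aucs == 1))
})

test_that("permuted labels center the AUC distribution at one half", {
  spec <- planted_spec(seed = 26, n_features = 5, n_markers = 1, d = 2)
  tab <- preprocessed_cohort(spec)
  cfg <- eval_config(n_resamples = 10, n_permutation_resamples = 1000,
                     seed = 27)
  perm <- resampled_auc(tab, colnames(tab$X)[1:3], cfg, permute = TRUE)
  expect_equal(mean(perm), 0.5, tolerance = 0.05)
})

test_that("permutation p-values follow their defining count", {
  real <- c(0.9, 0.92, 0.88)
  below <- runif(1000, 0.3, 0.7)
  pv <- permutation_pvalue(real, below)
  expect_identical(pv$p, 0)
  expect_equal(pv$p_corrected, 1 / 1001)

  # permuted sample identical to real: p is the fraction above the mean
  pv2 <- permutation_pvalue(real, real)
  expect_equal(pv2$p, mean(real > mean(real)))

  # symmetric null around the real mean: p near one half
  set.seed(28)
  sym <- 0.5 + rnorm(2000, sd = 0.05)
  pv3 <- permutation_pvalue(0.5, sym)
  expect_equal(pv3$p, 0.5, tolerance = 0.05)
})

test_that("informative panels stochastically dominate their permutation null", {
  spec <- planted_spec(seed = 29, n_features = 10, n_markers = 2, d = 2)
  gen <- generate_cohort(spec)
  tab <- preprocess_cohort(gen$cohort)$table
  panel <- gen$truth$informative$name
  cfg <- eval_config(n_resamples = 150, n_permutation_resamples = 150,
                     seed = 30)
  ev <- evaluate_panel(tab, panel, cfg)
  qs <- seq(0.1, 0.9, 0.2)
  expect_true(all(quantile(ev$real_aucs, qs) >= quantile(ev$permuted_aucs, qs)))
  expect_lt(ev$p_value, 0.01)
  # every AUC is a probability; counts match the config
  expect_true(all(ev$real_aucs >= 0 & ev$real_aucs <= 1))
  expect_length(ev$real_aucs, 150)
  expect_length(ev$permuted_aucs, 150)
})

test_that("evaluation is deterministic given the seed", {
  spec <- planted_spec(seed = 31, n_features = 6, n_markers = 1, d = 1.5)
  tab <- preprocessed_cohort(spec)
  cfg <- eval_config(n_resamples = 40, n_permutation_resamples = 40, seed = 32)
  e1 <- evaluate_panel(tab, colnames(tab$X)[1:2], cfg)
  e2 <- evaluate_panel(tab, colnames(tab$X)[1:2], cfg)
  expect_identical(e1$real_aucs, e2$real_aucs)
  expect_identical(e1$permuted_aucs, e2$permuted_aucs)
  expect_identical(e1$p_value, e2$p_value)
})

test_that("univariate and multivariate evaluations rank signal above noise", {
  spec <- planted_spec(seed = 33, n_features = 6, n_markers = 1, d = 2)
  gen <- generate_cohort(spec)
  tab <- preprocess_cohort(gen$cohort)$table
  mk <- gen$truth$informative$name[1]
  noise <- setdiff(colnames(tab$X), mk)[1]
  cfg <- eval_config(n_resamples = 100, n_permutation_resamples = 20,
                     seed = 34)
  up <- univariate_panel(tab, c(mk, noise), cfg)
  expect_gt(up$univariate[[mk]]$mean_real, up$univariate[[noise]]$mean_real)
  expect_equal(nrow(up$dumbbell), 3L)
  expect_identical(up$dumbbell$feature[3], "Multivariate")

  # a single-feature panel: univariate and multivariate results coincide
  up1 <- univariate_panel(tab, mk, cfg)
  expect_identical(up1$univariate[[mk]]$real_aucs,
                   up1$multivariate$real_aucs)

  # improvement statistic in percentage points
  imp <- auc_improvement(up$multivariate, up$univariate[[noise]])
  expect_type(imp, "double")
  expect_gt(imp, 0)
})

test_that("time-point group tests behave like Welch t-tests with safe degeneracy", {
  x <- c(1.1, 2.3, 0.7, 1.9, 1.4)
  same <- timepoint_group_test(c(x, x), rep(c("t1", "t2"), each = 5))
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  set.seed(35)
  a <- rnorm(30); b <- rnorm(30, 3)
  strong <- timepoint_group_test(c(a, b), rep(c("t1", "t2"), each = 30))
  expect_lt(strong$p_value, 1e-6)
  swapped <- timepoint_group_test(c(b, a), rep(c("t1", "t2"), each = 30))
  expect_equal(strong$p_value, swapped$p_value)

  # degenerate group: NA marker, not an exception
  deg <- timepoint_group_test(c(1, 1, 1, 1, 2, 1), rep(c("g1", "g2"), each = 3))
  expect_true(is.data.frame(deg))
  const <- timepoint_group_test(c(1, 1, 1, 1, 1, 1), rep(c("g1", "g2"), each = 3))
  expect_true(is.na(const$p_value))
})
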