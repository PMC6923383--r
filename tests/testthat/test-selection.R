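test_that("at lambda = 0 the penalized fit matches the unpenalized logistic model", {
  sim <- sim_logistic(40, c(1, -0.5, 0.25), seed = 1)
  fit <- fit_penalized(sim$X, sim$y, alpha = 1, lambda = 0)
  ref <- glm(sim$y ~ sim$X, family = binomial())
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-4)
  expect_equal(unname(fit$beta), unname(coef(ref)[-1]), tolerance = 1e-4)
})

test_that("at or above lambda_max every coefficient is exactly zero", {
  sim <- sim_logistic(60, c(1.5, -1, 0.5, 0), seed = 2)
  for (alpha in c(1, 0.5)) {
    lmax <- modspanel:::lambda_max(sim$X, sim$y, alpha)
    # numerically verify lambda_max is the KKT boundary: just above zeroes
    # everything, well below does not
    at <- fit_penalized(sim$X, sim$y, alpha, lmax)
    expect_identical(unname(at$beta), rep(0, 4))
    below <- fit_penalized(sim$X, sim$y, alpha, lmax * 0.5)
    expect_gt(sum(below$beta != 0), 0)
  }
})

test_that("Gaussian LASSO on an orthonormal design equals the soft-threshold closed form", {
  set.seed(3)
  n <- 40; p <- 5
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  X <- Q * sqrt(n)                       # crossprod(X) = n * I
  colnames(X) <- paste0("x", 1:p)
  beta_true <- c(2, -1, 0.5, 0, 0)
  y <- drop(X %*% beta_true) + rnorm(n, sd = 0.5)
  b_ols <- drop(crossprod(X, y)) / n
  for (lambda in c(0.1, 0.6, 1.5)) {
    fit <- fit_penalized(X, y, alpha = 1, lambda = lambda,
                         family = "gaussian", intercept = FALSE)
    expect_equal(unname(fit$beta), unname(soft_threshold(b_ols, lambda)),
                 tolerance = 1e-6)
  }
})

test_that("penalized fits reject degenerate inputs", {
  sim <- sim_logistic(30, c(1, 1), seed = 4)
  expect_error(fit_penalized(sim$X, rep(1, 30), alpha = 1, lambda = 0.1),
               "both classes")
  Xbad <- sim$X; Xbad[1, 1] <- NA
  expect_error(fit_penalized(Xbad, sim$y, alpha = 1, lambda = 0.1),
               "non-finite")
})

test_that("sparsity is monotone along the penalty grid", {
  sim <- sim_logistic(80, c(1.5, -1, 0.8, 0.4, 0, 0), seed = 5)
  grid <- modspanel:::lambda_grid(sim$X, sim$y, alpha = 1)
  at_max <- fit_penalized(sim$X, sim$y, 1, grid[1])
  at_min <- fit_penalized(sim$X, sim$y, 1, grid[length(grid)])
  expect_lte(sum(at_max$beta != 0), sum(at_min$beta != 0))
})

test_that("cross-validated lambda is deterministic given the seed", {
  sim <- sim_logistic(80, c(1, -1, 0, 0), seed = 6)
  l1 <- cv_optimize_lambda(sim$X, sim$y, alpha = 1, seed = 99)
  l2 <- cv_optimize_lambda(sim$X, sim$y, alpha = 1, seed = 99)
  expect_identical(l1, l2)
  l3 <- cv_optimize_lambda(sim$X, sim$y, alpha = 1, seed = 100)
  expect_true(is.numeric(l3) && length(l3) == 1)
})

test_that("on pure noise the tuned penalty sits in the sparser half of the grid", {
  hits <- 0L
  n_rep <- 100L
  for (s in seq_len(n_rep)) {
    set.seed(300 + s)
    X <- matrix(rnorm(60 * 30), 60, dimnames = list(NULL, paste0("x", 1:30)))
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) next
    grid <- modspanel:::lambda_grid(X, y, alpha = 1)
    lam <- cv_optimize_lambda(X, y, alpha = 1, seed = 300 + s, grid = grid)
    if (which.min(abs(grid - lam)) <= 50) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.80)
})

test_that("a single strong marker survives penalty tuning in nearly every replicate", {
  hits <- 0L
  n_rep <- 50L
  for (s in seq_len(n_rep)) {
    gen <- generate_cohort(planted_spec(400 + s, n = 200, n_features = 11,
                                        n_markers = 1, d = 2))
    X <- scale(gen$cohort$X)
    y <- gen$cohort$outcome
    mk <- gen$truth$informative$name[1]
    lam <- cv_optimize_lambda(X, y, alpha = 1, seed = 400 + s)
    fit <- fit_penalized(X, y, alpha = 1, lambda = lam)
    if (fit$beta[mk] != 0) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("upper-quantile thresholding follows the documented quantile rule", {
  # a single dominant feature is the only selection
  f1 <- c(a = 0, b = 0, c = 0, d = 100)
  uq1 <- upper_quantile_threshold(f1, 0.75)
  expect_identical(uq1$selected, "d")

  # all frequencies equal: nothing strictly exceeds the quantile
  f2 <- c(a = 40, b = 40, c = 40)
  expect_identical(upper_quantile_threshold(f2, 0.75)$selected, character(0))

  # type-7 interpolation: quantile(c(10,20,80,90), .75) = 82.5
  f3 <- c(a = 10, b = 20, c = 80, d = 90)
  uq3 <- upper_quantile_threshold(f3, 0.75)
  expect_equal(uq3$threshold, 82.5)
  expect_identical(uq3$selected, "d")

  expect_error(upper_quantile_threshold(numeric(0)), "empty")
})

test_that("a single stability iteration yields 0/1 appearance indicators", {
  spec <- planted_spec(seed = 7, n_features = 12, n_markers = 2, d = 2)
  tab <- preprocessed_cohort(spec)
  cfg <- selection_config(n_iterations = 1, seed = 8)
  res <- stability_select(tab, cfg)
  expect_true(all(res$frequencies %in% c(0L, 1L)))
  expect_equal(max(res$frequencies), 1L)
})

test_that("stability selection is deterministic and exchangeable under feature relabeling", {
  spec <- planted_spec(seed = 9, n_features = 10, n_markers = 1, d = 2)
  tab <- preprocessed_cohort(spec)
  cfg <- selection_config(n_iterations = 5, cv_folds = 5, seed = 10)
  res1 <- stability_select(tab, cfg)
  res2 <- stability_select(tab, cfg)
  expect_identical(res1$frequencies, res2$frequencies)
  expect_identical(res1$combined, res2$combined)

  # permuting feature columns permutes frequencies identically
  perm <- rev(seq_len(ncol(tab$X)))
  tabp <- cohort_table(tab$X[, perm], outcome = tab$outcome,
                       patients = tab$patients,
                       timepoint = tab$features$timepoint[perm],
                       role = tab$features$role[perm])
  resp <- stability_select(tabp, cfg)
  expect_identical(resp$frequencies[rownames(res1$frequencies), ],
                   res1$frequencies)
})

test_that("planted markers dominate the appearance frequencies", {
  spec <- planted_spec(seed = 12, n_features = 30, n_markers = 3, d = 1.5)
  gen <- generate_cohort(spec)
  tab <- preprocess_cohort(gen$cohort)$table
  markers <- gen$truth$informative$name
  cfg <- selection_config(n_iterations = 25, seed = 13)
  res <- stability_select(tab, cfg)
  pooled <- apply(res$frequencies, 1, max)
  expect_true(all(pooled[markers] >= quantile(pooled, 0.75)))
  expect_true(all(markers %in% res$combined))
})

test_that("outcome permutation destroys the planted markers' selection advantage", {
  spec <- planted_spec(seed = 14, n_features = 20, n_markers = 2, d = 1.5)
  gen <- generate_cohort(spec)
  tab <- preprocess_cohort(gen$cohort)$table
  markers <- gen$truth$informative$name
  set.seed(15)
  tab_null <- tab
  tab_null$outcome <- sample(tab$outcome)
  cfg <- selection_config(n_iterations = 15, seed = 16)
  real <- stability_select(tab, cfg)
  null <- stability_select(tab_null, cfg)
  real_rank <- mean(apply(real$frequencies, 1, max)[markers])
  null_freqs <- apply(null$frequencies, 1, max)
  # under the null the former markers behave like any other feature
  expect_gt(real_rank, mean(null_freqs[markers]))
  expect_lt(mean(null_freqs[markers]), quantile(null_freqs, 0.95) + 1)
})

test_that("selection results serialize to regenerable tables", {
  spec <- planted_spec(seed = 17, n_features = 8, n_markers = 1, d = 2)
  tab <- preprocessed_cohort(spec)
  res <- stability_select(tab, selection_config(n_iterations = 3, seed = 18))
  dir <- withr::local_tempdir()
  write_selection_result(res, dir)
  freq <- read.csv(file.path(dir, "frequencies.csv"), check.names = FALSE)
  expect_equal(freq$lasso, unname(res$frequencies[, "lasso"]))
  coefs <- read.csv(file.path(dir, "coefficients.csv"))
  expect_true(all(coefs$feature %in% rownames(res$frequencies)))
})
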