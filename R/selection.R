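#' Dual LASSO / Elastic-Net stability selection
#'
#' Candidate biomarkers are nominated by repeating a sparse penalized
#' logistic fit over random 75/25 patient subsamples (penalty strength
#' tuned by 10-fold cross-validation inside each training set), tallying
#' how often each feature receives a nonzero coefficient, and keeping the
#' features whose appearance frequency exceeds an upper quantile of the
#' frequency distribution. The mixing parameter alpha blends the penalties:
#' alpha = 1 is the pure LASSO, alpha = 0.5 the Elastic Net used alongside
#' it; both are run by default and their selections combined.
#'
#' @name selection
NULL

# At n << p the tail of the lambda grid approaches the saturated logistic
# fit and glmnet may hit maxit there; it returns the converged solutions for
# all larger lambdas, which are the only ones cross-validation can select,
# so that particular warning is noise.
quiet_glmnet <- function(expr) {
  withCallingHandlers(
    expr,
    warning = function(w) {
      if (grepl("lambda value not reached", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

# Smallest penalty that zeroes every coefficient, from the KKT stationarity
# condition at the intercept-only fit: lambda_max = max_j |x_j' r| / (n a)
# with r the null-model residual. For alpha near 0 the L1 part vanishes and
# the usual glmnet floor of alpha = 1e-3 is applied.
lambda_max <- function(X, y, alpha, family = c("binomial", "gaussian"),
                       intercept = TRUE) {
  family <- match.arg(family)
  n <- nrow(X)
  if (family == "binomial") {
    p0 <- if (intercept) mean(y) else 0.5
    r <- y - p0
  } else {
    r <- if (intercept) y - mean(y) else y
    if (intercept) X <- scale(X, center = TRUE, scale = FALSE)
  }
  max(abs(crossprod(X, r))) / (n * max(alpha, 1e-3))
}

# Descending grid of n_lambda log-spaced penalties from lambda_max down to
# ratio * lambda_max (the convention of the glmnet stack).
lambda_grid <- function(X, y, alpha, family = "binomial",
                        n_lambda = 100, ratio = 1e-3) {
  lmax <- lambda_max(X, y, alpha, family)
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

#' Fit a penalized generalized linear model
#'
#' Solves the penalized-likelihood problem at a single (alpha, lambda):
#' binomial deviance (or squared error for the Gaussian family) plus
#' lambda * (alpha * L1 + (1 - alpha)/2 * L2) on the coefficients. With any
#' L1 weight, exact zeros occur; at alpha = 1 the fit is the LASSO, at
#' alpha = 0.5 the Elastic Net. The solver is coordinate descent via
#' glmnet, warm-started along a descending path ending at the requested
#' lambda.
#'
#' @param X Numeric matrix (no missing values), features standardized; at
#'   least two columns.
#' @param y Binary 0/1 outcome (binomial family) or numeric response
#'   (Gaussian family, provided for closed-form checks).
#' @param alpha Penalty mixing parameter in `[0, 1]`.
#' @param lambda Penalty strength, >= 0.
#' @param family `"binomial"` (default) or `"gaussian"`.
#' @param intercept Fit an unpenalized intercept (default `TRUE`).
#' @return List with `intercept`, named coefficient vector `beta`, and the
#'   `alpha`, `lambda`, `family` used.
#' @export
fit_penalized <- function(X, y, alpha, lambda,
                          family = c("binomial", "gaussian"),
                          intercept = TRUE) {
  family <- match.arg(family)
  if (!is.matrix(X) || ncol(X) < 2) stop("X must be a matrix with >= 2 columns")
  if (anyNA(X) || !all(is.finite(X))) stop("X contains non-finite entries")
  if (anyNA(y) || !all(is.finite(y))) stop("y contains non-finite entries")
  if (family == "binomial" && length(unique(y)) < 2) {
    stop("y must contain both classes")
  }
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (!is.numeric(lambda) || lambda < 0) stop("lambda must be >= 0")

  lmax <- lambda_max(X, y, alpha, family, intercept)
  if (lambda >= lmax) {
    path <- c(lmax * 1.01, lambda)
  } else {
    path <- exp(seq(log(lmax), log(max(lambda, lmax * 1e-4)),
                    length.out = 50))
    if (lambda < path[length(path)]) path <- c(path, lambda)
  }
  path <- rev(sort(unique(path)))
  fit <- glmnet::glmnet(
    X, y, family = family, alpha = alpha, lambda = path,
    standardize = FALSE, intercept = intercept,
    thresh = 1e-12, maxit = 1e7
  )
  i <- which.min(abs(fit$lambda - lambda))
  beta <- as.numeric(fit$beta[, i])
  names(beta) <- rownames(fit$beta)
  list(intercept = unname(fit$a0[i]), beta = beta,
       alpha = alpha, lambda = lambda, family = family)
}

#' Tune the penalty strength by cross-validation
#'
#' Picks, from a descending log-spaced grid, the lambda minimizing the mean
#' held-out loss over stratified k folds (binomial deviance by default,
#' AUC maximization optionally). Fold assignment is stratified by outcome
#' so every fold carries both classes whenever the minority class allows,
#' and is reproducible from the seed.
#'
#' @param X Standardized feature matrix.
#' @param y Binary 0/1 outcome.
#' @param alpha Penalty mixing parameter.
#' @param cv_folds Number of folds (default 10).
#' @param seed Optional integer seed for the fold draw; when `NULL` the
#'   current RNG stream is used.
#' @param grid Optional descending lambda grid; default
#'   100 log-spaced values from lambda_max down to lambda_max / 1000.
#' @param measure `"deviance"` (default) or `"auc"`.
#' @return The selected lambda (numeric scalar).
#' @export
cv_optimize_lambda <- function(X, y, alpha, cv_folds = 10, seed = NULL,
                               grid = NULL, measure = c("deviance", "auc")) {
  measure <- match.arg(measure)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(grid)) grid <- lambda_grid(X, y, alpha)
  if (is.unsorted(rev(grid))) stop("lambda grid must be strictly descending")
  foldid <- stratified_folds(y, cv_folds)
  cv <- quiet_glmnet(glmnet::cv.glmnet(
    X, y, family = "binomial", alpha = alpha, lambda = grid,
    foldid = foldid, standardize = FALSE, type.measure = measure
  ))
  cv$lambda.min
}

#' Configuration for stability selection
#'
#' Defaults follow the original pipeline: 100 iterations of a random 75/25
#' training split, 10-fold cross-validated penalty tuning, LASSO
#' (alpha = 1) and Elastic Net (alpha = 0.5) run side by side, and a
#' threshold at the upper quartile of the appearance-frequency
#' distribution. The `stringent` preset raises the quantile to 0.90 and is
#' used for the integrated (all time points) analysis, where the larger
#' feature pool warrants a harder cut.
#'
#' @param n_iterations Number of subsampling iterations (default 100).
#' @param train_fraction Fraction of patients in each training draw
#'   (default 0.75).
#' @param cv_folds Folds for penalty tuning (default 10).
#' @param alphas Named vector of mixing parameters (default
#'   `c(lasso = 1, en = 0.5)`).
#' @param threshold_level Quantile level of the frequency distribution used
#'   as selection threshold (default 0.75, the "first upper quantile").
#' @param stringent If `TRUE`, use `stringent_level` instead.
#' @param stringent_level Quantile for the stringent preset (default 0.90).
#' @param combine `"union"` (default) or `"intersection"` of the per-alpha
#'   selected sets.
#' @param measure Cross-validation loss, `"deviance"` or `"auc"`.
#' @param stratified Stratify splits and folds by outcome (default `TRUE`;
#'   set `FALSE` to mimic fully random splits).
#' @param fold_preprocess If `TRUE`, minimum-imputation and autoscaling are
#'   recomputed inside every training draw instead of once on the full
#'   table, avoiding the information leakage of the global procedure. The
#'   default `FALSE` replicates the original design (preprocess once,
#'   then resample).
#' @param seed Integer master seed for the module.
#' @return A `selection_config` list.
#' @export
selection_config <- function(n_iterations = 100, train_fraction = 0.75,
                             cv_folds = 10, alphas = c(lasso = 1, en = 0.5),
                             threshold_level = 0.75, stringent = FALSE,
                             stringent_level = 0.90,
                             combine = c("union", "intersection"),
                             measure = c("deviance", "auc"),
                             stratified = TRUE, fold_preprocess = FALSE,
                             seed = 1L) {
  combine <- match.arg(combine)
  measure <- match.arg(measure)
  check_field(n_iterations >= 1, "n_iterations", "must be >= 1")
  check_field(train_fraction > 0 && train_fraction < 1,
              "train_fraction", "must lie strictly between 0 and 1")
  check_field(cv_folds >= 2, "cv_folds", "must be >= 2")
  check_field(is.numeric(alphas) && all(alphas >= 0 & alphas <= 1),
              "alphas", "must lie in [0, 1]")
  if (is.null(names(alphas))) names(alphas) <- paste0("alpha", alphas)
  check_field(threshold_level >= 0 && threshold_level <= 1,
              "threshold_level", "must lie in [0, 1]")
  structure(
    list(
      n_iterations = as.integer(n_iterations),
      train_fraction = train_fraction, cv_folds = as.integer(cv_folds),
      alphas = alphas, threshold_level = threshold_level,
      stringent = isTRUE(stringent), stringent_level = stringent_level,
      combine = combine, measure = measure,
      stratified = isTRUE(stratified),
      fold_preprocess = isTRUE(fold_preprocess),
      seed = as.integer(seed)
    ),
    class = "selection_config"
  )
}

#' Threshold appearance frequencies at an upper quantile
#'
#' The threshold is the empirical quantile (type 7, R's default linear
#' interpolation) of the full per-feature frequency vector — zeros
#' included — at `level`; features strictly above it are selected. When
#' every frequency is equal nothing exceeds the quantile and the selection
#' is empty.
#'
#' @param frequencies Named nonnegative vector of per-feature appearance
#'   counts.
#' @param level Quantile level (default 0.75).
#' @return List with `threshold` (numeric) and `selected` (character
#'   vector of feature names).
#' @export
upper_quantile_threshold <- function(frequencies, level = 0.75) {
  if (length(frequencies) == 0) stop("empty frequency vector")
  if (any(frequencies < 0)) stop("frequencies must be nonnegative")
  thr <- unname(stats::quantile(frequencies, level, type = 7))
  list(threshold = thr,
       selected = names(frequencies)[frequencies > thr])
}

# One subsampling iteration: split, tune lambda per alpha on the training
# portion (same folds for both alphas), fit, return nonzero coefficients.
one_stability_iter <- function(X, y, config, seed) {
  set.seed(seed)
  n <- length(y)
  if (config$stratified) {
    train <- stratified_train_idx(y, config$train_fraction)
  } else {
    train <- sort(sample.int(n, round(config$train_fraction * n)))
  }
  ytr <- y[train]
  if (length(unique(ytr)) < 2) stop("single-class training draw")
  Xtr <- X[train, , drop = FALSE]

  if (config$fold_preprocess) {
    obs <- colSums(!is.na(Xtr)) > 0
    Xtr <- Xtr[, obs, drop = FALSE]
    mins <- apply(Xtr, 2, min, na.rm = TRUE)
    for (j in seq_len(ncol(Xtr))) {
      nas <- is.na(Xtr[, j])
      if (any(nas)) Xtr[nas, j] <- mins[j]
    }
    sds <- apply(Xtr, 2, stats::sd)
    keep <- sds > 0
    Xtr <- scale(Xtr[, keep, drop = FALSE])
  }

  foldid <- stratified_folds(ytr, config$cv_folds)
  out <- list()
  for (a in names(config$alphas)) {
    alpha <- config$alphas[[a]]
    grid <- lambda_grid(Xtr, ytr, alpha)
    cv <- quiet_glmnet(glmnet::cv.glmnet(
      Xtr, ytr, family = "binomial", alpha = alpha, lambda = grid,
      foldid = foldid, standardize = FALSE, type.measure = config$measure
    ))
    fit <- quiet_glmnet(glmnet::glmnet(
      Xtr, ytr, family = "binomial", alpha = alpha, lambda = grid,
      standardize = FALSE
    ))
    beta <- fit$beta[, which.min(abs(fit$lambda - cv$lambda.min))]
    nz <- beta[beta != 0]
    out[[a]] <- nz
  }
  out
}

#' Stability selection over repeated subsamples
#'
#' For each of `n_iterations` iterations: draw a random (stratified) 75/25
#' patient split, tune lambda by 10-fold cross-validation on the training
#' portion, fit LASSO and Elastic Net at their tuned penalties, and record
#' which features carry nonzero coefficients. Appearance frequencies are
#' then thresholded at the configured upper quantile per method, and the
#' per-method selections combined.
#'
#' Iterations that fail (e.g. a single-class draw in unstratified mode) are
#' logged and redrawn with a fresh derived seed, capped at five times
#' `n_iterations` attempts in total.
#'
#' @param table A preprocessed [cohort_table] (complete, standardized),
#'   unless `fold_preprocess` is set in the config, in which case a
#'   filtered-but-unscaled table is expected.
#' @param config A [selection_config()].
#' @return A `selection_result`: per-alpha frequency matrix, long-format
#'   per-iteration coefficient records, per-alpha thresholds and selected
#'   sets, the combined set, and redraw counts.
#' @export
stability_select <- function(table, config = selection_config()) {
  stopifnot(inherits(table, "cohort_table"),
            inherits(config, "selection_config"))
  X <- table$X
  y <- table$outcome
  if (!config$fold_preprocess && anyNA(X)) {
    stop("table has missing values; preprocess it or set fold_preprocess")
  }
  feats <- colnames(X)
  n_alpha <- length(config$alphas)
  freq <- matrix(0L, nrow = length(feats), ncol = n_alpha,
                 dimnames = list(feats, names(config$alphas)))
  recs <- vector("list", config$n_iterations * n_alpha)
  ri <- 0L
  redraws <- 0L
  max_attempts <- 5L * config$n_iterations
  attempts <- 0L

  for (it in seq_len(config$n_iterations)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("stability_select: exceeded ", max_attempts, " attempts")
      }
      seed_it <- derive_seed(config$seed,
                             sprintf("select/iter%04d/try%d", it, attempts))
      res <- tryCatch(one_stability_iter(X, y, config, seed_it),
                      error = function(e) e)
      if (!inherits(res, "error")) break
      redraws <- redraws + 1L
    }
    for (a in names(res)) {
      nz <- res[[a]]
      if (length(nz)) {
        freq[names(nz), a] <- freq[names(nz), a] + 1L
        ri <- ri + 1L
        recs[[ri]] <- data.frame(
          iteration = it, alpha = a, feature = names(nz),
          beta = unname(nz), stringsAsFactors = FALSE
        )
      }
    }
  }

  level <- if (config$stringent) config$stringent_level else config$threshold_level
  thresholds <- numeric(n_alpha)
  names(thresholds) <- names(config$alphas)
  selected <- list()
  for (a in names(config$alphas)) {
    uq <- upper_quantile_threshold(stats::setNames(freq[, a], feats), level)
    thresholds[a] <- uq$threshold
    selected[[a]] <- uq$selected
  }
  combined <- Reduce(if (config$combine == "union") union else intersect,
                     selected)
  structure(
    list(
      frequencies = freq,
      coefficients = if (ri) do.call(rbind, recs[seq_len(ri)]) else
        data.frame(iteration = integer(0), alpha = character(0),
                   feature = character(0), beta = numeric(0)),
      threshold = thresholds, threshold_level = level,
      selected = selected, combined = combined,
      n_iterations = config$n_iterations, redraws = redraws,
      config = config
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %d features, %d iterations (threshold: quantile %.2f)\n",
    nrow(x$frequencies), x$n_iterations, x$threshold_level
  ))
  for (a in colnames(x$frequencies)) {
    cat(sprintf("  %s (threshold %.1f): %s\n", a, x$threshold[a],
                if (length(x$selected[[a]])) {
                  paste(x$selected[[a]], collapse = ", ")
                } else "none"))
  }
  cat("  combined (", x$config$combine, "): ",
      if (length(x$combined)) paste(x$combined, collapse = ", ") else "none",
      "\n", sep = "")
  if (x$redraws > 0) cat("  redrawn iterations:", x$redraws, "\n")
  invisible(x)
}

#' Write a selection result to disk
#'
#' Emits `frequencies.csv` (feature x method appearance counts),
#' `coefficients.csv` (long-format per-iteration nonzero coefficients,
#' enough to redraw frequency/beta plots), and `selection.json`
#' (thresholds and selected sets).
#'
#' @param result A `selection_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_selection_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  freq_df <- data.frame(feature = rownames(result$frequencies),
                        result$frequencies, check.names = FALSE)
  utils::write.csv(freq_df, file.path(dir, "frequencies.csv"),
                   row.names = FALSE)
  utils::write.csv(result$coefficients, file.path(dir, "coefficients.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(threshold = as.list(result$threshold),
         threshold_level = result$threshold_level,
         selected = result$selected, combined = result$combined,
         n_iterations = result$n_iterations, redraws = result$redraws),
    file.path(dir, "selection.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
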