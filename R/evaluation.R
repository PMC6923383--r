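#' Permutation-calibrated AUC evaluation of candidate panels
#'
#' A candidate panel is judged by the distribution of test-set ROC AUC
#' values of an unpenalized logistic model over many random 65/35
#' train/test splits, set against the same distribution recomputed after
#' permuting the outcome labels. The permutation p-value is the fraction
#' of permuted AUCs exceeding the mean real AUC.
#'
#' @name evaluation
NULL

#' Configuration for panel evaluation
#'
#' @param n_resamples Number of real-label train/test resamples
#'   (default 1000).
#' @param train_fraction Training fraction per resample (default 0.65).
#' @param n_permutation_resamples Number of permuted-label resamples
#'   (default 1000), each with a fresh label permutation.
#' @param ci_level Level of the empirical confidence interval on the real
#'   AUC sample (default 0.95).
#' @param stratified Stratify splits by outcome (default `TRUE`), which
#'   guarantees both classes in train and test at small n.
#' @param seed Integer master seed for the module.
#' @return An `eval_config` list.
#' @export
eval_config <- function(n_resamples = 1000, train_fraction = 0.65,
                        n_permutation_resamples = 1000, ci_level = 0.95,
                        stratified = TRUE, seed = 1L) {
  check_field(n_resamples >= 1, "n_resamples", "must be >= 1")
  check_field(train_fraction > 0 && train_fraction < 1,
              "train_fraction", "must lie strictly between 0 and 1")
  check_field(n_permutation_resamples >= 1, "n_permutation_resamples",
              "must be >= 1")
  check_field(ci_level > 0 && ci_level < 1, "ci_level",
              "must lie strictly between 0 and 1")
  structure(
    list(n_resamples = as.integer(n_resamples),
         train_fraction = train_fraction,
         n_permutation_resamples = as.integer(n_permutation_resamples),
         ci_level = ci_level, stratified = isTRUE(stratified),
         seed = as.integer(seed)),
    class = "eval_config"
  )
}

#' Fit an unpenalized logistic scorer
#'
#' Fits a binomial GLM of the outcome on the panel features and returns a
#' scorer mapping feature rows to the linear predictor. Zero features give
#' an intercept-only model (constant scores). If the fit separates
#' perfectly (fitted probabilities at 0/1 or non-convergence), a
#' ridge-stabilized fit with a tiny L2 penalty replaces it — the
#' coefficient magnitudes are then shrunk but the score ordering, which is
#' all the AUC uses, is preserved; the fallback is flagged on the result.
#'
#' @param X_train Numeric matrix of training rows (0 or more columns).
#' @param y_train Binary 0/1 outcome with both classes present.
#' @return A `glm_scorer`: list with `coef` (intercept first), `features`,
#'   and `fallback` (logical). Score new rows with [predict_scorer()].
#' @export
fit_glm <- function(X_train, y_train) {
  if (length(unique(y_train)) < 2) stop("y_train must contain both classes")
  p <- ncol(X_train) %||% 0
  if (p == 0) {
    co <- c("(Intercept)" = stats::qlogis(mean(y_train)))
    return(structure(list(coef = co, features = character(0),
                          fallback = FALSE), class = "glm_scorer"))
  }
  Xd <- cbind("(Intercept)" = 1, X_train)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(Xd, y_train, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!sep && fit$converged) {
    co <- fit$coefficients
    co[is.na(co)] <- 0
    return(structure(list(coef = co, features = colnames(X_train),
                          fallback = FALSE), class = "glm_scorer"))
  }
  # ridge-stabilized fallback for separated fits
  if (p >= 2) {
    rfit <- glmnet::glmnet(X_train, y_train, family = "binomial", alpha = 0,
                           lambda = 1e-3, standardize = FALSE)
    co <- c(unname(rfit$a0), as.numeric(rfit$beta))
  } else {
    # one separating feature: its own values are a perfect training scorer,
    # oriented by the direction of separation
    dir <- sign(mean(X_train[y_train == 1, 1]) - mean(X_train[y_train == 0, 1]))
    if (dir == 0) dir <- 1
    co <- c(0, dir)
  }
  names(co) <- c("(Intercept)", colnames(X_train))
  structure(list(coef = co, features = colnames(X_train), fallback = TRUE),
            class = "glm_scorer")
}

#' Score rows with a fitted logistic scorer
#' @param scorer A `glm_scorer` from [fit_glm()].
#' @param X Numeric matrix with the scorer's feature columns.
#' @return Numeric vector of linear-predictor scores.
#' @export
predict_scorer <- function(scorer, X) {
  stopifnot(inherits(scorer, "glm_scorer"))
  if (length(scorer$features) == 0) {
    return(rep(scorer$coef[1], nrow(X)))
  }
  drop(X[, scorer$features, drop = FALSE] %*%
         scorer$coef[scorer$features] + scorer$coef[1])
}

#' ROC AUC via the Mann-Whitney statistic
#'
#' The AUC is the probability that a random positive is scored above a
#' random negative, with ties given half credit:
#' (#\{pos > neg\} + 0.5 #\{pos = neg\}) / (n_pos n_neg). Computed from
#' midranks, so it is exact and invariant to any strictly increasing
#' transform of the scores.
#'
#' @param scores Numeric score per sample.
#' @param labels Binary 0/1 label per sample; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
score_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("labels must contain both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Test-set AUC over repeated random splits
#'
#' For each resample: optionally permute the outcome labels (a fresh
#' uniform permutation per resample), draw a stratified train/test split at
#' the configured fraction, fit the unpenalized logistic model on the
#' training rows, and score the test rows with the Mann-Whitney AUC.
#'
#' @param table A preprocessed [cohort_table].
#' @param features Character vector of panel feature names.
#' @param config An [eval_config()].
#' @param permute If `TRUE`, labels are permuted before every resample,
#'   giving the null AUC distribution.
#' @return Numeric vector of AUCs (length `n_resamples` or
#'   `n_permutation_resamples`), with attributes `fallbacks` (count of
#'   ridge-stabilized fits) and `redraws` (failed resamples redrawn).
#' @export
resampled_auc <- function(table, features, config = eval_config(),
                          permute = FALSE) {
  stopifnot(inherits(table, "cohort_table"), inherits(config, "eval_config"))
  missing_feats <- setdiff(features, colnames(table$X))
  if (length(missing_feats)) {
    stop("features not in table: ", paste(missing_feats, collapse = ", "))
  }
  X <- table$X[, features, drop = FALSE]
  y <- table$outcome
  n <- length(y)
  B <- if (permute) config$n_permutation_resamples else config$n_resamples
  tag <- if (permute) "eval/perm" else "eval/real"
  aucs <- numeric(B)
  fallbacks <- 0L
  redraws <- 0L
  for (b in seq_len(B)) {
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      if (attempt > 50L) stop("resampled_auc: resample ", b, " kept failing")
      set.seed(derive_seed(config$seed, sprintf("%s/%05d/%d", tag, b, attempt)))
      yb <- if (permute) sample(y) else y
      res <- tryCatch({
        train <- if (config$stratified) {
          stratified_train_idx(yb, config$train_fraction)
        } else {
          sort(sample.int(n, round(config$train_fraction * n)))
        }
        test <- setdiff(seq_len(n), train)
        if (length(unique(yb[train])) < 2 || length(unique(yb[test])) < 2) {
          stop("single-class split")
        }
        scorer <- fit_glm(X[train, , drop = FALSE], yb[train])
        list(auc = score_auc(predict_scorer(scorer, X[test, , drop = FALSE]),
                             yb[test]),
             fallback = scorer$fallback)
      }, error = function(e) e)
      if (!inherits(res, "error")) break
      redraws <- redraws + 1L
    }
    aucs[b] <- res$auc
    if (res$fallback) fallbacks <- fallbacks + 1L
  }
  structure(aucs, fallbacks = fallbacks, redraws = redraws)
}

#' Permutation p-value of a panel's AUC
#'
#' The empirical p-value is the fraction of permuted-label AUCs that
#' exceed the mean of the real-label AUC sample. The bias-corrected
#' variant (k + 1)/(n + 1), which can never be exactly zero, is reported
#' alongside.
#'
#' @param real_aucs Numeric vector of real-label AUCs.
#' @param permuted_aucs Numeric vector of permuted-label AUCs.
#' @return List with `p` and `p_corrected`.
#' @export
permutation_pvalue <- function(real_aucs, permuted_aucs) {
  if (length(real_aucs) == 0 || length(permuted_aucs) == 0) {
    stop("both AUC samples must be nonempty")
  }
  k <- sum(permuted_aucs > mean(real_aucs))
  n <- length(permuted_aucs)
  list(p = k / n, p_corrected = (k + 1) / (n + 1))
}

#' Evaluate one panel against its permutation null
#'
#' Runs [resampled_auc()] with real and permuted labels and summarizes:
#' means and SDs of both AUC distributions, the empirical confidence
#' interval of the real AUCs, and the permutation p-value.
#'
#' @param table A preprocessed [cohort_table].
#' @param features Panel feature names.
#' @param config An [eval_config()].
#' @return An `eval_result`.
#' @export
evaluate_panel <- function(table, features, config = eval_config()) {
  real <- resampled_auc(table, features, config, permute = FALSE)
  perm <- resampled_auc(table, features, config, permute = TRUE)
  a <- (1 - config$ci_level) / 2
  pv <- permutation_pvalue(real, perm)
  structure(
    list(
      features = features,
      real_aucs = as.numeric(real), permuted_aucs = as.numeric(perm),
      mean_real = mean(real), sd_real = stats::sd(real),
      mean_permuted = mean(perm), sd_permuted = stats::sd(perm),
      ci = unname(stats::quantile(real, c(a, 1 - a), type = 7)),
      ci_level = config$ci_level,
      p_value = pv$p, p_value_corrected = pv$p_corrected,
      fallbacks = attr(real, "fallbacks") + attr(perm, "fallbacks"),
      redraws = attr(real, "redraws") + attr(perm, "redraws"),
      config = config
    ),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> panel of %d feature(s)\n", length(x$features)))
  cat(sprintf("  real AUC:     %.3f +/- %.3f  (%.0f%% CI %.3f-%.3f)\n",
              x$mean_real, x$sd_real, 100 * x$ci_level, x$ci[1], x$ci[2]))
  cat(sprintf("  permuted AUC: %.3f +/- %.3f\n",
              x$mean_permuted, x$sd_permuted))
  cat(sprintf("  permutation p = %.4g (corrected %.4g)\n",
              x$p_value, x$p_value_corrected))
  invisible(x)
}

#' Univariate and multivariate panel evaluation
#'
#' Evaluates each panel feature on its own and the full panel together,
#' producing the data behind the dumbbell (per-feature mean real vs
#' permuted AUC) and density (AUC sample) displays.
#'
#' @param table A preprocessed [cohort_table].
#' @param features Panel feature names (>= 1).
#' @param config An [eval_config()].
#' @return List with `univariate` (named list of `eval_result`),
#'   `multivariate` (one `eval_result`), and `dumbbell` (data frame:
#'   feature, mean_real_auc, mean_permuted_auc; the multivariate row is
#'   labelled `"Multivariate"`).
#' @export
univariate_panel <- function(table, features, config = eval_config()) {
  if (length(features) < 1) stop("at least one feature required")
  uni <- lapply(features, function(f) evaluate_panel(table, f, config))
  names(uni) <- features
  multi <- evaluate_panel(table, features, config)
  dumbbell <- data.frame(
    feature = c(features, "Multivariate"),
    mean_real_auc = c(vapply(uni, function(e) e$mean_real, numeric(1)),
                      multi$mean_real),
    mean_permuted_auc = c(vapply(uni, function(e) e$mean_permuted, numeric(1)),
                          multi$mean_permuted),
    stringsAsFactors = FALSE
  )
  list(univariate = uni, multivariate = multi, dumbbell = dumbbell)
}

#' Improvement of a multivariate panel over a single reference feature
#'
#' The difference in mean real AUC, expressed in percentage points — the
#' statistic behind statements like "an 8% improvement over the
#' Probability of Survival".
#'
#' @param multivariate An `eval_result` for the panel.
#' @param univariate An `eval_result` for the reference feature.
#' @return Numeric, percentage points of AUC.
#' @export
auc_improvement <- function(multivariate, univariate) {
  100 * (multivariate$mean_real - univariate$mean_real)
}

#' Pairwise group comparisons across time points
#'
#' Welch's unpaired two-sample t-test between every pair of groups (time
#' points, or MODS vs non-MODS), as used to annotate per-marker box
#' plots. Degenerate pairs (fewer than two observations, or zero variance
#' in both groups) yield `NA` rather than an error.
#'
#' @param values Numeric vector of marker values.
#' @param groups Group label per value (factor or character).
#' @return Data frame with columns `group1`, `group2`, `p_value`.
#' @export
timepoint_group_test <- function(values, groups) {
  if (length(values) != length(groups)) stop("values and groups differ in length")
  groups <- as.character(groups)
  gs <- unique(groups)
  if (length(gs) < 2) stop("need at least two groups")
  pairs <- utils::combn(gs, 2)
  p <- apply(pairs, 2, function(pr) {
    a <- values[groups == pr[1]]
    b <- values[groups == pr[2]]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    tryCatch(stats::t.test(a, b, var.equal = FALSE)$p.value,
             error = function(e) NA_real_)
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p_value = p,
             stringsAsFactors = FALSE)
}

#' Write an evaluation result to disk
#'
#' Emits `auc_samples.csv` (long format: sample index, condition, AUC) and
#' `eval_summary.json` (means, SDs, CI, p-values, panel).
#'
#' @param result An `eval_result`.
#' @param dir Output directory (created if needed).
#' @param prefix Optional file-name prefix.
#' @return `dir`, invisibly.
#' @export
write_eval_result <- function(result, dir, prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- data.frame(
    sample = c(seq_along(result$real_aucs), seq_along(result$permuted_aucs)),
    condition = rep(c("real", "permuted"),
                    c(length(result$real_aucs), length(result$permuted_aucs))),
    auc = c(result$real_aucs, result$permuted_aucs)
  )
  utils::write.csv(samples, file.path(dir, paste0(prefix, "auc_samples.csv")),
                   row.names = FALSE)
  jsonlite::write_json(
    list(features = result$features,
         mean_real = result$mean_real, sd_real = result$sd_real,
         mean_permuted = result$mean_permuted,
         sd_permuted = result$sd_permuted,
         ci = result$ci, ci_level = result$ci_level,
         p_value = result$p_value,
         p_value_corrected = result$p_value_corrected,
         fallbacks = result$fallbacks, redraws = result$redraws),
    file.path(dir, paste0(prefix, "eval_summary.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
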