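# Shared fixtures and independent oracles, all built in code.

# Brute-force all-pairs AUC: the independent oracle for score_auc.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (a in pos) {
    s <- s + sum(a > neg) + 0.5 * sum(a == neg)
  }
  s / (length(pos) * length(neg))
}

# Soft-threshold operator, the closed-form LASSO solution on an
# orthonormal design.
soft_threshold <- function(z, lambda) sign(z) * pmax(abs(z) - lambda, 0)

# Small complete cohort with hand-set values.
tiny_cohort <- function(X, outcome, timepoint = "t1", role = "immune") {
  cohort_table(X, outcome = outcome, timepoint = timepoint, role = role)
}

# Study-shaped complete tables (no missingness): three time-point tables of
# 61 patients x 68/68/67 features, 3 clinical scores repeated at each.
study_tables_complete <- function(seed = 1) {
  spec <- study_spec(seed = seed, missing_rates = 0)
  split_timepoints(generate_cohort(spec)$cohort)
}

# Retention fixture: 89 patients measured at t1, of whom 61 complete all
# three time points (14 drop out after t1, 14 after t2).
retention_tables <- function(seed = 5) {
  set.seed(seed)
  pats <- sprintf("P%02d", 1:89)
  y <- rbinom(89, 1, 0.35)
  mk <- function(ids, tp) {
    X <- matrix(rnorm(length(ids) * 4), ncol = 4,
                dimnames = list(NULL, paste0("F", 1:4, "_", tp)))
    cohort_table(X, outcome = y[match(ids, pats)], patients = ids,
                 timepoint = tp)
  }
  list(t1 = mk(pats, "t1"),
       t2 = mk(pats[1:75], "t2"),
       t3 = mk(pats[c(1:61, 76:89)], "t3"))
}

# Logistic-model data with known coefficients.
sim_logistic <- function(n, beta, seed = 1, intercept = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(beta)), n,
              dimnames = list(NULL, paste0("x", seq_along(beta))))
  y <- rbinom(n, 1, plogis(intercept + drop(X %*% beta)))
  list(X = X, y = y)
}

# Single-time-point spec with k planted markers among noise features.
planted_spec <- function(seed, n = 61, n_features = 63, n_markers = 3,
                         d = 1.5, prevalence = 0.35) {
  synthetic_spec(
    n_patients = n, prevalence = prevalence,
    timepoints = "t1", n_features = n_features,
    planted_markers = if (n_markers > 0) {
      data.frame(timepoint = "t1", effect = rep(d, n_markers))
    } else NULL,
    seed = seed
  )
}

# Preprocessed single-table cohort from a spec (complete data path).
preprocessed_cohort <- function(spec) {
  preprocess_cohort(generate_cohort(spec)$cohort)$table
}
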