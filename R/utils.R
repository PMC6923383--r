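# Internal helpers shared across modules.

#' Derive a child seed from a master seed and a stage tag
#'
#' Stages of the pipeline (cohort generation, each selection iteration,
#' each evaluation resample, ...) draw from their own RNG streams so that
#' any stage can be re-run in isolation without disturbing the others.
#' The child seed is a deterministic hash of the master seed and a short
#' string tag, kept inside the 32-bit signed integer range.
#'
#' @param seed Master seed (integer).
#' @param tag Character tag naming the stage (e.g. `"select/iter007"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  bytes <- utf8ToInt(tag)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (b in bytes) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h)
}

# Stratified train indices: samples round(frac * n_c) per class c, clamped so
# both classes appear on both sides of the split. Uses the current RNG stream.
stratified_train_idx <- function(y, frac) {
  idx <- seq_along(y)
  train <- integer(0)
  for (cls in sort(unique(y))) {
    ic <- idx[y == cls]
    n_tr <- round(frac * length(ic))
    n_tr <- max(1L, min(length(ic) - 1L, n_tr))
    train <- c(train, sample(ic, n_tr))
  }
  sort(train)
}

# Stratified fold assignment for k-fold CV: shuffles within each class then
# deals folds cyclically, so every fold carries both classes whenever the
# minority class has >= k members.
stratified_folds <- function(y, k) {
  if (k < 2) stop("cv_folds must be at least 2")
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    ic <- which(y == cls)
    foldid[ic[sample.int(length(ic))]] <- rep_len(seq_len(k), length(ic))
  }
  foldid
}

# Validation helper: stop with a message naming the offending field.
check_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
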