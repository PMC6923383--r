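#' Cohort preprocessing
#'
#' The canonical preprocessing chain mirrors the original analysis: keep
#' only patients followed at every time point, drop features with more than
#' 70% missing values, impute remaining gaps with the per-feature minimum,
#' autoscale each feature to mean 0 / sd 1 (per time-point table), then
#' integrate time points into one wide matrix.
#'
#' @name preprocess
NULL

new_preprocess_report <- function(dropped = NULL, impute_values = NULL,
                                  centers = NULL, scales = NULL,
                                  n_patients = NA_integer_,
                                  collapsed = character(0)) {
  structure(
    list(
      dropped = dropped %||% data.frame(name = character(0),
                                        missing_fraction = numeric(0)),
      impute_values = impute_values, centers = centers, scales = scales,
      n_patients = n_patients, collapsed = collapsed
    ),
    class = "preprocess_report"
  )
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report>\n")
  cat(sprintf("  retained patients: %s\n", x$n_patients))
  cat(sprintf("  dropped features:  %d\n", nrow(x$dropped)))
  if (nrow(x$dropped)) {
    print(x$dropped, row.names = FALSE)
  }
  if (length(x$collapsed)) {
    cat("  collapsed clinical columns:",
        paste(x$collapsed, collapse = ", "), "\n")
  }
  invisible(x)
}

# Merge stagewise reports into one.
merge_reports <- function(...) {
  rs <- list(...)
  out <- new_preprocess_report()
  for (r in rs) {
    if (is.null(r)) next
    if (nrow(r$dropped)) out$dropped <- rbind(out$dropped, r$dropped)
    out$impute_values <- r$impute_values %||% out$impute_values
    out$centers <- r$centers %||% out$centers
    out$scales <- r$scales %||% out$scales
    if (!is.na(r$n_patients)) out$n_patients <- r$n_patients
    out$collapsed <- union(out$collapsed, r$collapsed)
  }
  out
}

#' Keep only patients observed at every time point
#'
#' @param tables List of [cohort_table] objects, one per time point.
#' @return List of cohort tables restricted to the patients present (with
#'   outcome) in all of them, identically ordered across tables (order of
#'   the first table).
#' @export
retain_complete_patients <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1,
            all(vapply(tables, inherits, logical(1), "cohort_table")))
  keep <- Reduce(intersect, lapply(tables, function(t) t$patients))
  if (length(keep) == 0) {
    stop("no patient is present at every time point")
  }
  keep <- tables[[1]]$patients[tables[[1]]$patients %in% keep]
  lapply(tables, function(t) {
    i <- match(keep, t$patients)
    cohort_table(t$X[i, , drop = FALSE], outcome = t$outcome[i],
                 patients = keep, timepoint = t$features$timepoint,
                 role = t$features$role)
  })
}

#' Drop features with excessive missingness
#'
#' Features whose missing fraction is strictly greater than `threshold` are
#' removed ("more than 70% missing" read literally: a feature missing
#' exactly 70% of its entries is retained).
#'
#' @param table A [cohort_table].
#' @param threshold Maximum tolerated missing fraction, default 0.70.
#' @return List with `table` (filtered cohort) and `report` (a
#'   `preprocess_report` listing each dropped feature with its missing
#'   fraction).
#' @export
filter_missing <- function(table, threshold = 0.70) {
  stopifnot(inherits(table, "cohort_table"))
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]")
  }
  frac <- colMeans(is.na(table$X))
  drop <- frac > threshold
  if (all(drop)) stop("all features exceed the missingness threshold")
  report <- new_preprocess_report(
    dropped = data.frame(name = colnames(table$X)[drop],
                         missing_fraction = unname(frac[drop])),
    n_patients = nrow(table$X)
  )
  out <- cohort_table(
    table$X[, !drop, drop = FALSE], outcome = table$outcome,
    patients = table$patients,
    timepoint = table$features$timepoint[!drop],
    role = table$features$role[!drop]
  )
  list(table = out, report = report)
}

#' Impute missing entries with the per-feature minimum
#'
#' Every `NA` in feature j is replaced by the minimum observed value of
#' feature j — the convention for assays where absence of signal reads as
#' the low end of the dynamic range.
#'
#' @param table A [cohort_table]; every feature must have at least one
#'   observed value (run [filter_missing()] first).
#' @return List with `table` (complete cohort) and `report` recording the
#'   imputation value per feature.
#' @export
impute_min <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  X <- table$X
  all_na <- colSums(!is.na(X)) == 0
  if (any(all_na)) {
    stop("feature(s) with no observed values: ",
         paste(colnames(X)[all_na], collapse = ", "))
  }
  mins <- apply(X, 2, min, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mins[j]
  }
  out <- table
  out$X <- X
  list(table = out,
       report = new_preprocess_report(impute_values = mins,
                                      n_patients = nrow(X)))
}

#' Autoscale features to mean 0, standard deviation 1
#'
#' Standardizes each feature with the sample standard deviation
#' (denominator n - 1). Scaling parameters are recorded so the transform
#' can be inverted or reapplied to new data.
#'
#' @param table A complete [cohort_table] (no missing entries).
#' @return List with `table` (scaled cohort) and `report` carrying per-
#'   feature centers and scales.
#' @export
autoscale <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  if (anyNA(table$X)) stop("autoscale requires a complete table; impute first")
  sds <- apply(table$X, 2, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    stop("zero-variance feature(s): ",
         paste(colnames(table$X)[zero], collapse = ", "))
  }
  centers <- colMeans(table$X)
  out <- table
  out$X <- scale(table$X, center = centers, scale = sds)
  attr(out$X, "scaled:center") <- NULL
  attr(out$X, "scaled:scale") <- NULL
  list(table = out,
       report = new_preprocess_report(centers = centers, scales = sds,
                                      n_patients = nrow(table$X)))
}

#' Undo autoscaling
#'
#' @param table A scaled [cohort_table].
#' @param report The `preprocess_report` from [autoscale()].
#' @return The cohort on its original (imputed) scale.
#' @export
unscale <- function(table, report) {
  stopifnot(inherits(table, "cohort_table"),
            inherits(report, "preprocess_report"))
  out <- table
  out$X <- sweep(sweep(table$X, 2, report$scales[colnames(table$X)], `*`),
                 2, report$centers[colnames(table$X)], `+`)
  out
}

#' Integrate time-point tables into one wide matrix
#'
#' Concatenates per-time-point tables horizontally. Clinical-score columns
#' that repeat at every time point with identical values (the same score
#' measured once per patient) are collapsed to a single column named by the
#' base score name and tagged with time point `"all"`; this is how
#' 68 + 68 + 67 = 203 columns reduce to 197 when three clinical scores
#' repeat three times.
#'
#' @param tables List of [cohort_table] objects sharing the same patients
#'   in the same order.
#' @return A single integrated `cohort_table`. The collapsed column names
#'   are recorded in the `"collapsed"` attribute.
#' @export
integrate_timepoints <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1,
            all(vapply(tables, inherits, logical(1), "cohort_table")))
  if (length(tables) == 1) return(tables[[1]])
  pats <- tables[[1]]$patients
  for (t in tables[-1]) {
    if (!identical(t$patients, pats)) {
      stop("patient order mismatch across time-point tables; ",
           "run retain_complete_patients() first")
    }
    if (!identical(t$outcome, tables[[1]]$outcome)) {
      stop("outcome mismatch across time-point tables")
    }
  }
  X <- do.call(cbind, lapply(tables, function(t) t$X))
  tp <- unlist(lapply(tables, function(t) t$features$timepoint))
  role <- unlist(lapply(tables, function(t) t$features$role))
  name <- colnames(X)

  # collapse clinical columns duplicated (same base name, identical values)
  # across time points
  collapsed <- character(0)
  base <- sub("_t[0-9]+$", "", name)
  drop <- logical(length(name))
  for (b in unique(base[role == "clinical"])) {
    idx <- which(base == b & role == "clinical")
    if (length(idx) < 2) next
    vals <- X[, idx, drop = FALSE]
    if (all(vals == vals[, 1])) {
      drop[idx[-1]] <- TRUE
      name[idx[1]] <- b
      tp[idx[1]] <- "all"
      collapsed <- c(collapsed, b)
    }
  }
  X <- X[, !drop, drop = FALSE]
  colnames(X) <- name[!drop]
  if (anyDuplicated(colnames(X))) {
    stop("duplicate feature names after integration: ",
         paste(unique(colnames(X)[duplicated(colnames(X))]), collapse = ", "))
  }
  out <- cohort_table(X, outcome = tables[[1]]$outcome, patients = pats,
                      timepoint = tp[!drop], role = role[!drop])
  attr(out, "collapsed") <- collapsed
  out
}

#' Run the canonical preprocessing chain on one table
#'
#' [filter_missing()], then [impute_min()], then [autoscale()], in that
#' order. The output has no missing values and unit-variance columns.
#'
#' @param table A [cohort_table].
#' @param threshold Missingness threshold passed to [filter_missing()].
#' @return List with `table` and a merged `report`.
#' @export
preprocess_cohort <- function(table, threshold = 0.70) {
  f <- filter_missing(table, threshold)
  i <- impute_min(f$table)
  s <- autoscale(i$table)
  list(table = s$table,
       report = merge_reports(f$report, i$report, s$report))
}

#' Serialize a preprocess report to JSON
#' @param report A `preprocess_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_preprocess_report <- function(report, path) {
  jsonlite::write_json(
    list(
      dropped = report$dropped,
      impute_values = as.list(report$impute_values %||% list()),
      centers = as.list(report$centers %||% list()),
      scales = as.list(report$scales %||% list()),
      n_patients = report$n_patients,
      collapsed = report$collapsed
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
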