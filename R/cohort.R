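#' Patient-by-feature cohort tables
#'
#' A `cohort_table` holds a numeric patient-by-feature matrix (missing
#' entries permitted), a binary outcome vector (1 = developed MODS,
#' 0 = did not), and per-feature metadata: the time point each feature was
#' measured at and its role (`"immune"` readout, `"clinical"` score such as
#' NISS or PS14, or `"other"`).
#'
#' @param X Numeric matrix, patients in rows, features in columns. Column
#'   names are the feature names and must be unique; row names, if absent,
#'   are taken from `patients`.
#' @param outcome Integer/numeric vector of 0/1 outcomes, one per patient.
#' @param patients Character vector of patient identifiers.
#' @param timepoint Character vector, one time-point label per feature
#'   (recycled if length 1).
#' @param role Character vector, one of `"immune"`, `"clinical"`, `"other"`
#'   per feature (recycled if length 1).
#' @return An object of class `cohort_table`.
#' @examples
#' X <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("F", 1:4)))
#' cohort_table(X, outcome = c(0, 1, 0, 1, 0), patients = paste0("P", 1:5))
#' @export
cohort_table <- function(X, outcome, patients = rownames(X),
                         timepoint = "t1", role = "immune") {
  if (!is.matrix(X) || !is.numeric(X)) stop("X must be a numeric matrix")
  if (is.null(colnames(X))) stop("X must have feature (column) names")
  if (anyDuplicated(colnames(X))) stop("feature names must be unique")
  if (is.null(patients)) patients <- paste0("P", seq_len(nrow(X)))
  if (length(patients) != nrow(X)) stop("patients must match nrow(X)")
  if (length(outcome) != nrow(X)) stop("outcome must be defined for every patient")
  if (anyNA(outcome) || !all(outcome %in% c(0, 1))) {
    stop("outcome must be 0/1 with no missing values")
  }
  p <- ncol(X)
  timepoint <- rep_len(as.character(timepoint), p)
  role <- rep_len(as.character(role), p)
  if (!all(role %in% c("immune", "clinical", "other"))) {
    stop("role must be one of 'immune', 'clinical', 'other'")
  }
  rownames(X) <- patients
  structure(
    list(
      X = X,
      outcome = as.integer(outcome),
      patients = as.character(patients),
      features = data.frame(
        name = colnames(X), timepoint = timepoint, role = role,
        stringsAsFactors = FALSE
      )
    ),
    class = "cohort_table"
  )
}

#' @export
dim.cohort_table <- function(x) dim(x$X)

#' @export
print.cohort_table <- function(x, ...) {
  tp <- table(x$features$timepoint)
  cat(sprintf(
    "<cohort_table> %d patients x %d features (%d MODS / %d non-MODS)\n",
    nrow(x$X), ncol(x$X), sum(x$outcome == 1), sum(x$outcome == 0)
  ))
  cat("  features per time point: ",
      paste(sprintf("%s=%d", names(tp), tp), collapse = ", "), "\n", sep = "")
  n_miss <- sum(is.na(x$X))
  if (n_miss > 0) {
    cat(sprintf("  missing entries: %d (%.1f%%)\n", n_miss,
                100 * n_miss / length(x$X)))
  }
  invisible(x)
}

#' Split a cohort into one table per time point
#'
#' @param cohort A [cohort_table].
#' @return Named list of `cohort_table` objects, one per time-point label, in
#'   the order the labels first appear. Clinical-score features tagged with
#'   time point `"all"` are copied into every table.
#' @export
split_timepoints <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  tps <- unique(cohort$features$timepoint)
  shared <- cohort$features$timepoint == "all"
  tps <- setdiff(tps, "all")
  out <- lapply(tps, function(tp) {
    keep <- cohort$features$timepoint == tp | shared
    cohort_table(
      cohort$X[, keep, drop = FALSE],
      outcome = cohort$outcome,
      patients = cohort$patients,
      timepoint = ifelse(shared[keep], tp, cohort$features$timepoint[keep]),
      role = cohort$features$role[keep]
    )
  })
  names(out) <- tps
  out
}

#' Write a cohort to CSV
#'
#' Layout: first column `PatientID`, second column `MODS` (the binary
#' outcome), then one column per feature. Feature columns carry their
#' time-point suffix (e.g. `_t1`) in the name; the role of clinical-score
#' columns is recovered on read via the `clinical` argument of
#' [read_cohort_csv()].
#'
#' @param cohort A [cohort_table].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- data.frame(
    PatientID = cohort$patients,
    MODS = cohort$outcome,
    cohort$X,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Inverse of [write_cohort_csv()]. The time point of each feature is parsed
#' from a trailing `_t<k>` suffix on its column name; unsuffixed columns get
#' time point `"all"`.
#'
#' @param path CSV file path.
#' @param clinical Character vector of clinical-score feature names (base
#'   names, without time-point suffix) to tag with role `"clinical"`.
#' @return A [cohort_table].
#' @export
read_cohort_csv <- function(path, clinical = character(0)) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("PatientID", "MODS") %in% names(df))) {
    stop("cohort CSV must have 'PatientID' and 'MODS' columns")
  }
  feat <- setdiff(names(df), c("PatientID", "MODS"))
  X <- as.matrix(df[, feat, drop = FALSE])
  storage.mode(X) <- "double"
  has_suffix <- grepl("_t[0-9]+$", feat)
  tp <- ifelse(has_suffix, sub("^.*_(t[0-9]+)$", "\\1", feat), "all")
  base <- ifelse(has_suffix, sub("_t[0-9]+$", "", feat), feat)
  role <- ifelse(base %in% clinical, "clinical", "immune")
  cohort_table(X, outcome = df$MODS, patients = as.character(df$PatientID),
               timepoint = tp, role = role)
}
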