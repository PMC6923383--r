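#' Specify a synthetic trauma cohort
#'
#' Describes a synthetic patient cohort with the statistical structure the
#' downstream analysis assumes: a binary MODS outcome drawn at a fixed
#' prevalence, a few planted informative markers (group-conditional
#' Gaussians separated by an effect size `d`, the standardized mean
#' difference between outcome groups), clinical-score features measured once
#' per patient but reported at every time point, blocks of correlated noise
#' features, and per-feature missingness.
#'
#' @param n_patients Number of patients (positive integer).
#' @param prevalence Outcome prevalence, strictly between 0 and 1.
#' @param timepoints Character vector of ordered time-point labels.
#' @param n_features Integer vector, total feature count per time point
#'   (clinical-score columns included), same length as `timepoints`.
#' @param planted_markers Data frame with columns `timepoint` and `effect`
#'   (standardized mean difference `d`), one row per planted marker. May be
#'   `NULL` for a no-signal cohort.
#' @param clinical_scores Data frame with columns `name` and `effect`, one
#'   row per clinical score (e.g. NISS, PS14). Scores are generated once and
#'   replicated at every time point. May be `NULL`.
#' @param block_rho Within-block correlation of noise features, in `[0, 1)`.
#' @param block_size Number of noise features sharing one latent factor.
#' @param missing_rates Per-feature missing fractions, all in `[0, 1]`.
#'   Either a single number (applied to every immune feature; clinical
#'   scores stay complete), a named numeric vector keyed by final feature
#'   name (unnamed features default to 0), or a list with components `base`
#'   (rate for immune features), `clinical` (rate for clinical columns),
#'   `n_high` and `high_rate` (this many noise features are raised to
#'   `high_rate`, e.g. above the 70% removal threshold).
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @seealso [study_spec()] for the defaults mirroring the motivating study,
#'   [generate_cohort()] to draw a cohort.
#' @export
synthetic_spec <- function(n_patients, prevalence,
                           timepoints = c("t1", "t2", "t3"),
                           n_features = c(68, 68, 67),
                           planted_markers = NULL,
                           clinical_scores = NULL,
                           block_rho = 0, block_size = 1,
                           missing_rates = 0, seed = 1L) {
  check_field(is.numeric(n_patients) && length(n_patients) == 1 &&
                n_patients >= 1 && n_patients == round(n_patients),
              "n_patients", "must be a positive integer")
  check_field(is.numeric(prevalence) && length(prevalence) == 1 &&
                prevalence > 0 && prevalence < 1,
              "prevalence", "must be strictly between 0 and 1")
  check_field(is.character(timepoints) && length(timepoints) >= 1 &&
                !anyDuplicated(timepoints),
              "timepoints", "must be distinct labels")
  check_field(is.numeric(n_features) &&
                length(n_features) == length(timepoints) &&
                all(n_features >= 1) && all(n_features == round(n_features)),
              "n_features", "must give a positive count per time point")
  n_clin <- 0L
  if (!is.null(clinical_scores)) {
    check_field(is.data.frame(clinical_scores) &&
                  all(c("name", "effect") %in% names(clinical_scores)) &&
                  !anyDuplicated(clinical_scores$name),
                "clinical_scores", "needs unique 'name' and 'effect' columns")
    n_clin <- nrow(clinical_scores)
  }
  if (!is.null(planted_markers)) {
    check_field(is.data.frame(planted_markers) &&
                  all(c("timepoint", "effect") %in% names(planted_markers)),
                "planted_markers", "needs 'timepoint' and 'effect' columns")
    check_field(all(planted_markers$timepoint %in% timepoints),
                "planted_markers", "timepoint labels must exist in the spec")
    check_field(nrow(planted_markers) + n_clin <= sum(n_features),
                "planted_markers", "more planted markers than features")
    for (tp in timepoints) {
      n_mk <- sum(planted_markers$timepoint == tp)
      check_field(n_mk + n_clin <= n_features[match(tp, timepoints)],
                  "planted_markers",
                  sprintf("time point '%s' cannot hold %d markers", tp, n_mk))
    }
  } else {
    check_field(n_clin <= min(n_features), "clinical_scores",
                "more clinical scores than features at some time point")
  }
  check_field(is.numeric(block_rho) && block_rho >= 0 && block_rho < 1,
              "block_rho", "must lie in [0, 1)")
  check_field(is.numeric(block_size) && block_size >= 1,
              "block_size", "must be a positive integer")
  rates <- if (is.list(missing_rates)) unlist(missing_rates) else missing_rates
  check_field(is.numeric(rates) && all(rates >= 0) &&
                all(rates[!grepl("n_high", names(rates) %||% "")] <= 1),
              "missing_rates", "all rates must lie in [0, 1]")
  check_field(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed", "must be a single integer")
  structure(
    list(
      n_patients = as.integer(n_patients), prevalence = prevalence,
      timepoints = timepoints, n_features = as.integer(n_features),
      planted_markers = planted_markers, clinical_scores = clinical_scores,
      block_rho = block_rho, block_size = as.integer(block_size),
      missing_rates = missing_rates, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Study-shaped synthetic cohort specification
#'
#' Defaults that emulate the motivating study's design: 61 trauma patients
#' followed over three time points (<1 h, 4-12 h, 48-72 h post-injury) with
#' 68/68/67 features per time point, a MODS prevalence of 0.35 (MODS
#' develops in roughly 30-40% of severe trauma patients), three strongly
#' informative immune markers (d = 1.5; one at the first time point, two at
#' the third, echoing the monocyte/CD62L/CD63 panel), three clinical scores
#' replicated at every time point (NISS, PS14 and ISS, so that time-point
#' integration collapses 68+68+67 = 203 columns to 197), correlated noise
#' blocks, and per-feature missingness with a few features above the 70%
#' removal threshold.
#'
#' Clinical-score separations are chosen through the binormal identity
#' AUC = pnorm(d / sqrt(2)): d = 0.8 gives a univariate AUC near 0.71 (NISS),
#' d = 1.1 near 0.78 (PS14).
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
study_spec <- function(seed = 1L, ...) {
  args <- list(
    n_patients = 61, prevalence = 0.35,
    timepoints = c("t1", "t2", "t3"),
    n_features = c(68, 68, 67),
    planted_markers = data.frame(
      timepoint = c("t1", "t3", "t3"),
      effect = c(1.5, 1.5, 1.5)
    ),
    clinical_scores = data.frame(
      name = c("NISS", "PS14", "ISS"),
      effect = c(0.8, 1.1, 0.7)
    ),
    block_rho = 0.5, block_size = 5,
    missing_rates = list(base = 0.05, clinical = 0, n_high = 3,
                         high_rate = 0.8),
    seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_spec, args)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws outcomes as independent Bernoulli(prevalence) labels, planted
#' markers and clinical scores from group-conditional Gaussians
#' `N(d * outcome, 1)`, and noise features independent of outcome with
#' within-block correlation induced by one shared latent factor per block.
#' Marker positions are shuffled among the immune columns of their time
#' point. The same spec and seed always reproduce the cohort exactly.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with components `cohort` (a [cohort_table] holding all
#'   time points, complete — apply [inject_missingness()] for missing data)
#'   and `truth` (a `ground_truth` object: data frame `informative` with
#'   columns name/timepoint/effect/role, and character vector `noise`;
#'   together they partition all features, clinical scores counted as
#'   informative).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$seed, "cohort"))
  n <- spec$n_patients
  outcome <- stats::rbinom(n, 1L, spec$prevalence)

  clin <- spec$clinical_scores
  clin_vals <- NULL
  if (!is.null(clin) && nrow(clin) > 0) {
    clin_vals <- vapply(
      seq_len(nrow(clin)),
      function(i) stats::rnorm(n) + clin$effect[i] * outcome,
      numeric(n)
    )
    colnames(clin_vals) <- clin$name
  }
  n_clin <- if (is.null(clin_vals)) 0L else ncol(clin_vals)

  cols <- list(); tps <- character(0); roles <- character(0)
  info <- list()
  noise_names <- character(0)
  for (k in seq_along(spec$timepoints)) {
    tp <- spec$timepoints[k]
    p_tot <- spec$n_features[k]
    if (n_clin > 0) {
      cn <- paste0(colnames(clin_vals), "_", tp)
      for (j in seq_len(n_clin)) cols[[cn[j]]] <- clin_vals[, j]
      tps <- c(tps, rep(tp, n_clin)); roles <- c(roles, rep("clinical", n_clin))
      info[[length(info) + 1L]] <- data.frame(
        name = cn, timepoint = tp, effect = clin$effect, role = "clinical",
        stringsAsFactors = FALSE
      )
    }
    p_imm <- p_tot - n_clin
    mk <- spec$planted_markers
    mk <- if (is.null(mk)) mk else mk[mk$timepoint == tp, , drop = FALSE]
    n_mk <- if (is.null(mk)) 0L else nrow(mk)

    # noise matrix with latent-factor block correlation
    n_noise <- p_imm - n_mk
    noise <- matrix(0, n, n_noise)
    if (n_noise > 0) {
      block <- ceiling(seq_len(n_noise) / spec$block_size)
      g <- matrix(stats::rnorm(n * max(block)), n, max(block))
      eps <- matrix(stats::rnorm(n * n_noise), n, n_noise)
      noise <- sqrt(spec$block_rho) * g[, block, drop = FALSE] +
        sqrt(1 - spec$block_rho) * eps
    }

    imm <- matrix(NA_real_, n, p_imm)
    imm_names <- sprintf("F%03d_%s", seq_len(p_imm), tp)
    mk_pos <- if (n_mk > 0) sort(sample.int(p_imm, n_mk)) else integer(0)
    if (n_mk > 0) {
      for (j in seq_len(n_mk)) {
        imm[, mk_pos[j]] <- stats::rnorm(n) + mk$effect[j] * outcome
      }
      info[[length(info) + 1L]] <- data.frame(
        name = imm_names[mk_pos], timepoint = tp, effect = mk$effect,
        role = "immune", stringsAsFactors = FALSE
      )
    }
    imm[, setdiff(seq_len(p_imm), mk_pos)] <- noise
    noise_names <- c(noise_names, imm_names[setdiff(seq_len(p_imm), mk_pos)])
    for (j in seq_len(p_imm)) cols[[imm_names[j]]] <- imm[, j]
    tps <- c(tps, rep(tp, p_imm)); roles <- c(roles, rep("immune", p_imm))
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  cohort <- cohort_table(
    X, outcome = outcome, patients = sprintf("P%03d", seq_len(n)),
    timepoint = tps, role = roles
  )
  informative <- if (length(info)) {
    do.call(rbind, info)
  } else {
    data.frame(name = character(0), timepoint = character(0),
               effect = numeric(0), role = character(0))
  }
  truth <- structure(list(informative = informative, noise = noise_names),
                     class = "ground_truth")
  list(cohort = cohort, truth = truth)
}

# Resolve the spec's missing_rates field into one rate per feature.
resolve_missing_rates <- function(cohort, spec, truth = NULL) {
  mr <- spec$missing_rates
  feat <- cohort$features
  rates <- stats::setNames(numeric(nrow(feat)), feat$name)
  if (is.list(mr)) {
    base <- mr$base %||% 0
    rates[feat$role == "immune"] <- base
    rates[feat$role != "immune"] <- mr$clinical %||% 0
    n_high <- mr$n_high %||% 0
    if (n_high > 0) {
      pool <- if (!is.null(truth)) truth$noise else feat$name[feat$role == "immune"]
      if (n_high > length(pool)) {
        stop("n_high exceeds the number of eligible noise features")
      }
      rates[sample(pool, n_high)] <- mr$high_rate %||% 0.8
    }
  } else if (!is.null(names(mr))) {
    unknown <- setdiff(names(mr), feat$name)
    if (length(unknown)) {
      stop("missing_rates names not in cohort: ", paste(unknown, collapse = ", "))
    }
    rates[names(mr)] <- mr
  } else {
    rates[feat$role == "immune"] <- mr[1]
  }
  if (any(rates < 0 | rates > 1)) {
    stop("invalid 'missing_rates': all rates must lie in [0, 1]")
  }
  rates
}

#' Mask cohort entries as missing
#'
#' Each entry of feature j is independently set to `NA` with that feature's
#' missing rate (missing completely at random). Masking is reproducible
#' from the spec's seed and independent of the draw in [generate_cohort()],
#' so the same cohort values underlie any missingness pattern.
#'
#' @param cohort A [cohort_table].
#' @param spec The [synthetic_spec()] supplying `missing_rates` and `seed`.
#' @param truth Optional `ground_truth` from [generate_cohort()]; when the
#'   spec asks for `n_high` high-missingness features these are then drawn
#'   from the noise features only, so planted markers survive filtering.
#' @return A `cohort_table` with `NA` entries.
#' @export
inject_missingness <- function(cohort, spec, truth = NULL) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$seed, "missingness"))
  rates <- resolve_missing_rates(cohort, spec, truth)
  X <- cohort$X
  for (j in seq_len(ncol(X))) {
    if (rates[j] > 0) {
      X[stats::runif(nrow(X)) < rates[j], j] <- NA_real_
    }
  }
  out <- cohort
  out$X <- X
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d informative features, %d noise features\n",
              nrow(x$informative), length(x$noise)))
  if (nrow(x$informative)) {
    print(x$informative, row.names = FALSE)
  }
  invisible(x)
}

#' Write ground truth as a JSON sidecar
#' @param truth A `ground_truth` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(informative = truth$informative, noise = truth$noise),
    path, auto_unbox = FALSE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
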