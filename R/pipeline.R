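#' Pipeline orchestration
#'
#' One configuration object drives the whole analysis: obtain per-time-point
#' cohort tables (synthetic or from CSV), retain complete-follow-up
#' patients, preprocess each table, run stability selection, and evaluate
#' the nominated panel (optionally augmented with clinical scores) against
#' its permutation null. The four analyses of the original design — one per
#' time point plus the integrated matrix — are all expressible.
#'
#' @name cli_report
NULL

#' Configure a pipeline run
#'
#' @param input Either a [synthetic_spec()], a character vector of cohort
#'   CSV paths (one per time point, as written by [write_cohort_csv()]), or
#'   a list of [cohort_table] objects.
#' @param mode `"integrated"` (select on the combined time-point matrix,
#'   the default), `"per-timepoint"` (one analysis per time point), or
#'   `"all"` (both).
#' @param missing_threshold Missingness filter threshold (default 0.70).
#' @param selection A [selection_config()]; its seed is re-derived from the
#'   master seed per analysis.
#' @param evaluation An [eval_config()]; likewise re-seeded per analysis.
#' @param clinical_scores Base names of clinical-score features (default
#'   `c("PS14", "NISS")`). In integrated mode each one present in the table
#'   is appended to the selected panel for an augmented model, mirroring
#'   the "markers + PS14" / "markers + NISS" comparisons.
#' @param clinical_in_selection If `FALSE` (default) clinical-score columns
#'   are excluded from stability selection and only re-enter at evaluation;
#'   they otherwise dominate the selections at every time point.
#' @param stringent_integrated Use the stringent threshold preset for the
#'   integrated analysis (default `TRUE`).
#' @param seed Master seed; every stage derives its own stream from it.
#' @param out_dir Optional output directory for [export_report()].
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(input,
                            mode = c("integrated", "per-timepoint", "all"),
                            missing_threshold = 0.70,
                            selection = selection_config(),
                            evaluation = eval_config(),
                            clinical_scores = c("PS14", "NISS"),
                            clinical_in_selection = FALSE,
                            stringent_integrated = TRUE,
                            seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  ok_input <- inherits(input, "synthetic_spec") || is.character(input) ||
    (is.list(input) && all(vapply(input, inherits, logical(1), "cohort_table")))
  check_field(ok_input, "input",
              "must be a synthetic_spec, CSV paths, or cohort_table list")
  check_field(missing_threshold >= 0 && missing_threshold <= 1,
              "missing_threshold", "must lie in [0, 1]")
  stopifnot(inherits(selection, "selection_config"),
            inherits(evaluation, "eval_config"))
  structure(
    list(input = input, mode = mode, missing_threshold = missing_threshold,
         selection = selection, evaluation = evaluation,
         clinical_scores = clinical_scores,
         clinical_in_selection = isTRUE(clinical_in_selection),
         stringent_integrated = isTRUE(stringent_integrated),
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `input` (list of CSV paths, or a `synthetic`
#' block passed to [synthetic_spec()] / [study_spec()]), `mode`,
#' `missing_threshold`, `selection`, `evaluation`, `clinical_scores`,
#' `clinical_in_selection`, `stringent_integrated`, `seed`, `out_dir`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  input <- if (!is.null(y$input$synthetic)) {
    syn <- y$input$synthetic
    if (isTRUE(syn$study)) {
      syn$study <- NULL
      do.call(study_spec, syn)
    } else {
      for (f in c("planted_markers", "clinical_scores")) {
        if (!is.null(syn[[f]])) syn[[f]] <- as.data.frame(syn[[f]])
      }
      do.call(synthetic_spec, syn)
    }
  } else {
    unlist(y$input)
  }
  args <- list(input = input)
  if (!is.null(y$selection)) {
    args$selection <- do.call(selection_config, y$selection)
  }
  if (!is.null(y$evaluation)) {
    args$evaluation <- do.call(eval_config, y$evaluation)
  }
  for (f in c("mode", "missing_threshold", "clinical_scores",
              "clinical_in_selection", "stringent_integrated", "seed",
              "out_dir")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  do.call(pipeline_config, args)
}

# Restrict a cohort to the given roles.
subset_roles <- function(table, roles) {
  keep <- table$features$role %in% roles
  cohort_table(table$X[, keep, drop = FALSE], outcome = table$outcome,
               patients = table$patients,
               timepoint = table$features$timepoint[keep],
               role = table$features$role[keep])
}

# Run selection + evaluation on one preprocessed table.
run_one_analysis <- function(name, table, config, stringent = FALSE) {
  sel_table <- if (config$clinical_in_selection) {
    table
  } else {
    subset_roles(table, c("immune", "other"))
  }
  sel_cfg <- config$selection
  sel_cfg$stringent <- stringent
  sel_cfg$seed <- derive_seed(config$seed, paste0("select/", name))
  sel <- stability_select(sel_table, sel_cfg)
  panel <- sel$combined

  ev_cfg <- config$evaluation
  ev_cfg$seed <- derive_seed(config$seed, paste0("eval/", name))
  evaluation <- NULL
  clinical_evals <- list()
  if (length(panel) > 0) {
    evaluation <- univariate_panel(table, panel, ev_cfg)
    for (cs in config$clinical_scores) {
      hit <- intersect(c(cs, paste0(cs, "_", unique(table$features$timepoint))),
                       colnames(table$X))
      if (length(hit) == 0) next
      cs_cfg <- ev_cfg
      cs_cfg$seed <- derive_seed(config$seed,
                                 paste0("eval/", name, "/+", cs))
      clinical_evals[[paste0("+", cs)]] <-
        evaluate_panel(table, union(panel, hit[1]), cs_cfg)
    }
  }
  list(name = name, dim = dim(table), table = table, selection = sel,
       panel = panel, evaluation = evaluation,
       clinical_evals = clinical_evals)
}

#' Run the full pipeline
#'
#' Synthesize or load the per-time-point tables, keep complete-follow-up
#' patients, preprocess each table (missingness filter, minimum
#' imputation, autoscaling), then run the configured analyses: stability
#' selection followed by permutation-calibrated evaluation of the selected
#' panel, with clinical-score-augmented models in integrated mode. Fully
#' reproducible from the master seed.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result`: named list of analyses (each holding the
#'   `selection_result`, the panel, and the evaluation bundle), the
#'   preprocessing reports, a reproducibility manifest, and — for synthetic
#'   input — the ground truth.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (inherits(config$input, "synthetic_spec")) {
    spec <- config$input
    gen <- generate_cohort(spec)
    truth <- gen$truth
    cohort <- inject_missingness(gen$cohort, spec, gen$truth)
    tables <- split_timepoints(cohort)
  } else if (is.character(config$input)) {
    tables <- lapply(config$input, read_cohort_csv,
                     clinical = config$clinical_scores)
    names(tables) <- vapply(tables, function(t)
      setdiff(unique(t$features$timepoint), "all")[1], character(1))
  } else {
    tables <- config$input
    if (is.null(names(tables))) {
      names(tables) <- vapply(tables, function(t)
        setdiff(unique(t$features$timepoint), "all")[1], character(1))
    }
  }

  n_before <- length(tables[[1]]$patients)
  tables <- retain_complete_patients(tables)
  n_after <- length(tables[[1]]$patients)

  prep <- lapply(tables, preprocess_cohort,
                 threshold = config$missing_threshold)
  ptables <- lapply(prep, `[[`, "table")
  reports <- lapply(prep, `[[`, "report")

  analyses <- list()
  if (config$mode %in% c("per-timepoint", "all")) {
    for (tp in names(ptables)) {
      analyses[[tp]] <- run_one_analysis(tp, ptables[[tp]], config,
                                         stringent = FALSE)
    }
  }
  if (config$mode %in% c("integrated", "all")) {
    integrated <- integrate_timepoints(unname(ptables))
    analyses[["integrated"]] <- run_one_analysis(
      "integrated", integrated, config,
      stringent = config$stringent_integrated
    )
    analyses[["integrated"]]$collapsed <- attr(integrated, "collapsed")
  }

  manifest <- list(
    package = "modspanel",
    version = as.character(utils::packageVersion("modspanel")),
    seed = config$seed,
    mode = config$mode,
    input = if (inherits(config$input, "synthetic_spec")) {
      unclass(config$input)
    } else if (is.character(config$input)) {
      config$input
    } else {
      sprintf("in-memory cohort tables (%d)", length(config$input))
    },
    missing_threshold = config$missing_threshold,
    selection = unclass(config$selection),
    evaluation = unclass(config$evaluation),
    clinical_scores = config$clinical_scores,
    clinical_in_selection = config$clinical_in_selection,
    stringent_integrated = config$stringent_integrated,
    patients_before_retention = n_before,
    patients_retained = n_after,
    dropped_features = lapply(reports, function(r) r$dropped$name),
    warnings = list(
      selection_redraws = vapply(analyses, function(a)
        a$selection$redraws, integer(1)),
      evaluation_fallbacks = vapply(analyses, function(a)
        if (is.null(a$evaluation)) 0L else
          as.integer(a$evaluation$multivariate$fallbacks), integer(1)),
      leakage_mode = !config$selection$fold_preprocess
    )
  )

  structure(
    list(analyses = analyses, preprocess_reports = reports,
         manifest = manifest, truth = truth, config = config),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d analysis/-es, %d patients retained\n",
              length(x$analyses), x$manifest$patients_retained))
  for (a in x$analyses) {
    cat(sprintf("  [%s] %d x %d; panel: %s\n", a$name, a$dim[1], a$dim[2],
                if (length(a$panel)) paste(a$panel, collapse = ", ")
                else "(no features selected)"))
    if (!is.null(a$evaluation)) {
      m <- a$evaluation$multivariate
      cat(sprintf("      multivariate AUC %.3f +/- %.3f (permuted %.3f, p = %.4g)\n",
                  m$mean_real, m$sd_real, m$mean_permuted, m$p_value))
    }
  }
  invisible(x)
}

#' Export a pipeline result to disk
#'
#' Writes, per analysis: the selection frequencies and coefficient records,
#' the dumbbell table, AUC samples and evaluation summaries (including the
#' clinical-score-augmented models), plus a run manifest
#' (`manifest.json`) and a human-readable `summary.txt` at the top level.
#' Output is deterministic — no timestamps — so reruns with the same seed
#' are byte-identical.
#'
#' @param bundle A `pipeline_result`.
#' @param out_dir Output directory (created if needed); defaults to the
#'   config's `out_dir`.
#' @return `out_dir`, invisibly.
#' @export
export_report <- function(bundle, out_dir = NULL) {
  stopifnot(inherits(bundle, "pipeline_result"))
  out_dir <- out_dir %||% bundle$config$out_dir
  if (is.null(out_dir)) stop("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  lines <- c("modspanel pipeline summary", "==========================", "")
  for (a in bundle$analyses) {
    adir <- file.path(out_dir, a$name)
    write_selection_result(a$selection, adir)
    lines <- c(lines, sprintf("[%s]  table %d x %d", a$name, a$dim[1], a$dim[2]))
    if (length(a$panel) == 0) {
      lines <- c(lines, "  no features selected", "")
      next
    }
    lines <- c(lines,
               sprintf("  selected panel: %s", paste(a$panel, collapse = ", ")))
    if (!is.null(a$evaluation)) {
      utils::write.csv(a$evaluation$dumbbell,
                       file.path(adir, "dumbbell.csv"), row.names = FALSE)
      write_eval_result(a$evaluation$multivariate, adir, "multivariate_")
      m <- a$evaluation$multivariate
      lines <- c(lines, sprintf(
        "  multivariate AUC %.3f +/- %.3f | permuted %.3f +/- %.3f | p = %.4g",
        m$mean_real, m$sd_real, m$mean_permuted, m$sd_permuted, m$p_value))
      for (cn in names(a$clinical_evals)) {
        ce <- a$clinical_evals[[cn]]
        write_eval_result(ce, adir, paste0("panel", cn, "_"))
        lines <- c(lines, sprintf(
          "  panel %s AUC %.3f +/- %.3f | permuted %.3f +/- %.3f | p = %.4g",
          cn, ce$mean_real, ce$sd_real, ce$mean_permuted, ce$sd_permuted,
          ce$p_value))
      }
    }
    lines <- c(lines, "")
  }
  writeLines(lines, file.path(out_dir, "summary.txt"))
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}
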