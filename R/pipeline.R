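#' Read and write labeled 3x3 confusion-matrix CSVs
#'
#' Schema: a `device_output` column with rows `positive`, `indeterminate`,
#' `negative`, and the three reference-category columns `ASD_positive`,
#' `ASD_negative_other_condition`, `ASD_negative_neurotypical`. Round-trips
#' exactly.
#'
#' @param path File path.
#' @param C A [confusion3x3()].
#' @return `read_confusion_csv` returns a [confusion3x3()];
#'   `write_confusion_csv` returns `path` invisibly.
#' @export
read_confusion_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"device_output" %in% names(df) ||
      !all(ref_categories %in% names(df))) {
    stop("confusion CSV header must contain 'device_output' and columns: ",
         paste(ref_categories, collapse = ", "))
  }
  if (!setequal(df$device_output, device_outputs) || nrow(df) != 3) {
    stop("confusion CSV must contain exactly the rows: ",
         paste(device_outputs, collapse = ", "))
  }
  m <- as.matrix(df[, ref_categories])
  rownames(m) <- df$device_output
  for (i in seq_len(3)) {
    for (j in seq_len(3)) {
      v <- m[i, j]
      if (is.na(v) || v < 0 || v != round(v)) {
        stop("invalid count in confusion CSV at row '", rownames(m)[i],
             "', column '", ref_categories[j], "'")
      }
    }
  }
  confusion3x3(m)
}

#' @rdname read_confusion_csv
#' @export
write_confusion_csv <- function(C, path) {
  stopifnot(inherits(C, "confusion3x3"))
  df <- data.frame(device_output = rownames(C), as.data.frame(unclass(C)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a metrics report
#'
#' JSON schema: `{metric: {num, den, point, ci_lo, ci_hi, undefined}}`.
#' Markdown emits a human-readable table with percentages to one decimal and
#' exact fractions.
#'
#' @param report A `metrics_report` data frame (see [evaluate_confusion()]).
#' @param path Output file path.
#' @param format `"json"`, `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- lapply(seq_len(nrow(report)), function(i) {
      r <- report[i, ]
      list(num = r$num, den = r$den, point = r$point,
           ci_lo = r$ci_lo, ci_hi = r$ci_hi, undefined = r$undefined)
    })
    names(obj) <- report$metric
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else if (format == "csv") {
    write.csv(report, path, row.names = FALSE)
  } else {
    lines <- c(
      "| Metric | Estimate | 95% CI | Fraction |",
      "|---|---|---|---|",
      vapply(seq_len(nrow(report)), function(i) {
        r <- report[i, ]
        if (r$undefined) {
          sprintf("| %s | -- | -- | %d/%d |", r$metric, r$num, r$den)
        } else {
          sprintf("| %s | %.1f%% | (%.1f%%, %.1f%%) | %d/%d |", r$metric,
                  100 * r$point, 100 * r$ci_lo, 100 * r$ci_hi, r$num, r$den)
        }
      }, "")
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Format a proportion in a printed-report style
#'
#' `"percent1"` renders percentages to one decimal (confusion-table style);
#' `"percent0"` to whole percents (stratified-table style).
#'
#' @param x Proportion(s) in \[0, 1\].
#' @param style `"percent1"` or `"percent0"`.
#' @return Character vector.
#' @export
format_percent <- function(x, style = c("percent1", "percent0")) {
  style <- match.arg(style)
  digits <- if (style == "percent1") 1 else 0
  sprintf(paste0("%.", digits, "f%%"), round(100 * x, digits))
}

#' Run configuration for the end-to-end pipeline
#'
#' @param mode `"simulate_full"` (generate cohort, adjudicate, fit, calibrate,
#'   evaluate), `"evaluate_records"` (analyze a per-subject record CSV with
#'   `device_output` and `ref_category` columns) or `"evaluate_confusion"`
#'   (analyze a 3x3 confusion CSV).
#' @param seed Integer seed (mandatory for `simulate_full`).
#' @param input Path to the records or confusion CSV (evaluate modes).
#' @param cohort A [cohort_config()] or arguments for one (simulate mode);
#'   if a plain list, `seed` is injected.
#' @param floors A [floor_spec()].
#' @param learner,hyperparams Passed to [cv_oof_scores()].
#' @param stratify_by Covariate columns for stratified reports.
#' @param alpha Significance level.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate_full", "evaluate_records",
                                "evaluate_confusion"),
                       seed = NULL, input = NULL, cohort = NULL,
                       floors = floor_spec(), learner = "xgboost",
                       hyperparams = list(),
                       stratify_by = c("sex", "race_ethnicity", "income_band",
                                       "education_band", "age_years_band"),
                       alpha = 0.05) {
  mode <- match.arg(mode)
  if (mode == "simulate_full") {
    if (is.null(seed)) stop("seed is mandatory in simulate_full mode")
    if (is.null(cohort)) {
      cohort <- cohort_config(n_subjects = 425, seed = seed)
    } else if (!inherits(cohort, "cohort_config")) {
      args <- cohort
      if (is.null(args$seed)) args$seed <- seed
      cohort <- do.call(cohort_config, args)
    }
    if (cohort$n_subjects < 1) {
      stop("simulate_full requires n_subjects >= 1")
    }
  } else {
    if (is.null(input)) stop(mode, " mode requires an input path")
  }
  structure(list(mode = mode, seed = seed, input = input, cohort = cohort,
                 floors = floors, learner = learner, hyperparams = hyperparams,
                 stratify_by = stratify_by, alpha = alpha),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The document maps directly onto the [run_config()] arguments; `cohort` and
#' `floors` sub-documents map onto [cohort_config()] and [floor_spec()]
#' arguments.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- raw
  if (!is.null(raw$floors)) args$floors <- do.call(floor_spec, raw$floors)
  if (!is.null(raw$cohort)) {
    co <- raw$cohort
    for (nm in c("class_probs", "age_range_months", "age_band_weights",
                 "comorbidity_probs")) {
      if (!is.null(co[[nm]])) co[[nm]] <- unlist(co[[nm]])
    }
    if (!is.null(co$class_latent_params)) {
      co$class_latent_params <- lapply(co$class_latent_params, unlist)
    }
    if (is.null(co$seed) && !is.null(raw$seed)) co$seed <- raw$seed
    args$cohort <- co
  }
  do.call(run_config, args)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  plain <- rapply(unclass(config), function(x) x, how = "replace")
  jsonlite::write_json(plain, tf, auto_unbox = TRUE, digits = 12,
                       force = TRUE, na = "null")
  unname(tools::md5sum(tf))
}

#' Run the full pipeline
#'
#' `simulate_full`: generate the synthetic cohort, adjudicate it through the
#' specialist panel, obtain out-of-fold device scores per age band, calibrate
#' abstention thresholds against the reference labels under the configured
#' floors, apply them, and evaluate. `evaluate_records` /
#' `evaluate_confusion`: skip simulation and evaluate a supplied record table
#' or confusion matrix. Every artifact is reproducible from (config, seed);
#' the log records the config hash, seed, package version and calibration
#' decisions.
#'
#' @param config A [run_config()] (or a path readable by
#'   [read_run_config()]).
#' @param out_dir Output directory (created if needed). Artifacts: cohort and
#'   scored-record CSVs (simulate mode), `confusion.csv`, `metrics.json`,
#'   `report.md`, stratified CSVs, `calibration.json`, `log.txt`.
#' @return Invisibly, a list with the confusion matrix, metrics report,
#'   calibration result (simulate mode), stratified tables and paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  loglines <- c(
    sprintf("abstaindx %s", as.character(packageVersion("abstaindx"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("mode: %s", config$mode),
    sprintf("seed: %s", ifelse(is.null(config$seed), "NA", config$seed)),
    sprintf("config hash: %s", config_hash(config))
  )
  calib <- NULL
  records <- NULL

  if (config$mode == "simulate_full") {
    cohort <- generate_cohort(config$cohort)
    cohort <- adjudicate_cohort(cohort, config$cohort$panel, seed = config$seed)
    qn <- sprintf("q%02d", 1:64)
    y <- cohort$ref_label == "ASD_positive"
    scores <- rep(NA_real_, nrow(cohort))
    folds <- rep(NA_integer_, nrow(cohort))
    for (b in unique(cohort$age_band)) {
      idx <- cohort$age_band == b
      oof <- cv_oof_scores(cohort[idx, qn], y[idx],
                           folds = config$floors$cv_folds,
                           learner = config$learner,
                           hyperparams = config$hyperparams,
                           seed = config$seed + match(b, c("A", "B")))
      scores[idx] <- as.numeric(oof)
      folds[idx] <- attr(oof, "fold") + 10L * match(b, c("A", "B"))
    }
    calib <- calibrate_thresholds(scores, y, config$floors, folds = folds)
    loglines <- c(loglines,
      sprintf("calibration: %s", if (calib$feasible) "feasible" else "FAILED"),
      if (calib$feasible) sprintf(
        "  t_neg=%.6f t_pos=%.6f determinate_rate=%.4f feasible_pairs=%d",
        calib$thresholds$t_neg, calib$thresholds$t_pos,
        calib$determinate_rate, calib$n_feasible)
      else sprintf("  reason: %s", calib$reason))
    cohort$score <- scores
    cohort$device_output <- if (calib$feasible) {
      as.character(apply_thresholds(scores, calib$thresholds))
    } else {
      rep("indeterminate", nrow(cohort))
    }
    cohort$age_years_band <- ifelse(cohort$age_months < 36, "under_3",
                                    "3_and_over")
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    records <- cohort
    records$ref_category <- cohort$ref_label
    jsonlite::write_json(
      list(feasible = calib$feasible,
           t_neg = if (calib$feasible) calib$thresholds$t_neg else NULL,
           t_pos = if (calib$feasible) calib$thresholds$t_pos else NULL,
           determinate_rate = calib$determinate_rate, ppv = calib$ppv,
           npv = calib$npv, n_feasible = calib$n_feasible),
      file.path(out_dir, "calibration.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
    C <- build_confusion(records$device_output, records$ref_category)
  } else if (config$mode == "evaluate_records") {
    records <- read.csv(config$input, stringsAsFactors = FALSE)
    if (!all(c("device_output", "ref_category") %in% names(records))) {
      stop("records CSV needs device_output and ref_category columns")
    }
    C <- build_confusion(records$device_output, records$ref_category)
  } else {
    C <- read_confusion_csv(config$input)
  }

  report <- evaluate_confusion(C, config$alpha)
  write_confusion_csv(C, file.path(out_dir, "confusion.csv"))
  write_report(report, file.path(out_dir, "metrics.json"), "json")
  write_report(report, file.path(out_dir, "report.md"), "markdown")

  strat <- list()
  if (!is.null(records)) {
    for (cv in intersect(config$stratify_by, names(records))) {
      st <- stratified_metrics(records, cv, config$alpha)
      write.csv(st, file.path(out_dir, paste0("stratified_", cv, ".csv")),
                row.names = FALSE)
      strat[[cv]] <- st
    }
  }
  writeLines(loglines, file.path(out_dir, "log.txt"))
  message(paste(loglines, collapse = "\n"))
  invisible(list(confusion = C, metrics = report, calibration = calib,
                 stratified = strat, records = records, out_dir = out_dir))
}
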