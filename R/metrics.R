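device_outputs <- c("positive", "indeterminate", "negative")

#' 3x3 confusion matrix for an abstaining diagnostic device
#'
#' Device outputs (positive / indeterminate / negative) cross-tabulated
#' against the clinical reference standard (ASD positive / ASD negative with
#' another condition / ASD negative and neurotypical).
#'
#' @param counts 3x3 non-negative integer matrix. Rows must be (or will be
#'   reordered to) `positive`, `indeterminate`, `negative`; columns
#'   `ASD_positive`, `ASD_negative_other_condition`,
#'   `ASD_negative_neurotypical`.
#' @return An object of class `confusion3x3` (an integer matrix).
#' @export
confusion3x3 <- function(counts) {
  m <- as.matrix(counts)
  if (!all(dim(m) == c(3, 3))) stop("confusion matrix must be 3x3")
  if (is.null(rownames(m))) rownames(m) <- device_outputs
  if (is.null(colnames(m))) colnames(m) <- ref_categories
  if (!setequal(rownames(m), device_outputs)) {
    stop("rows must be named: ", paste(device_outputs, collapse = ", "))
  }
  if (!setequal(colnames(m), ref_categories)) {
    stop("columns must be named: ", paste(ref_categories, collapse = ", "))
  }
  m <- m[device_outputs, ref_categories]
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("invalid count at row '", device_outputs[bad[1, 1]], "', column '",
         ref_categories[bad[1, 2]], "': counts must be non-negative integers")
  }
  storage.mode(m) <- "integer"
  structure(m, class = c("confusion3x3", class(m)))
}

#' Tally device outputs against reference categories
#'
#' @param device_output Vector of `positive` / `indeterminate` / `negative`.
#' @param ref_category Vector of `ASD_positive` /
#'   `ASD_negative_other_condition` / `ASD_negative_neurotypical`.
#' @return A [confusion3x3()] whose grand total equals the record count.
#' @export
build_confusion <- function(device_output, ref_category) {
  if (length(device_output) != length(ref_category)) {
    stop("device_output and ref_category differ in length")
  }
  bad <- setdiff(unique(as.character(device_output)), device_outputs)
  if (length(bad) > 0) stop("unknown device output label: ", bad[1])
  bad <- setdiff(unique(as.character(ref_category)), ref_categories)
  if (length(bad) > 0) stop("unknown reference category label: ", bad[1])
  tab <- table(factor(device_output, levels = device_outputs),
               factor(ref_category, levels = ref_categories))
  confusion3x3(unclass(as.matrix(tab)))
}

cell <- function(C, row, cols) sum(C[row, cols])

confusion_cells <- function(C) {
  non_asd <- c("ASD_negative_other_condition", "ASD_negative_neurotypical")
  list(
    tp = cell(C, "positive", "ASD_positive"),
    fp = cell(C, "positive", non_asd),
    fn = cell(C, "negative", "ASD_positive"),
    tn = cell(C, "negative", non_asd),
    ind_asd = cell(C, "indeterminate", "ASD_positive"),
    ind_other = cell(C, "indeterminate", "ASD_negative_other_condition"),
    ind_nt = cell(C, "indeterminate", "ASD_negative_neurotypical"),
    all_asd = sum(C[, "ASD_positive"]),
    all_non_asd = sum(C[, non_asd]),
    total = sum(C)
  )
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Central exact interval obtained by inverting the binomial tail
#' probabilities (computed via the beta-quantile identity). `lo = 0` exactly
#' when `x = 0`, and `hi = 1` exactly when `x = n`.
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (>= 1).
#' @param conf_level Two-sided confidence level (default 0.95).
#' @return Named numeric vector `c(lo, hi)`.
#' @examples
#' round(clopper_pearson(63, 78), 3)  # c(0.703, 0.888)
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  if (length(x) != 1 || length(n) != 1 || is.na(x) || is.na(n)) {
    stop("x and n must be single non-missing values")
  }
  if (n < 1 || x < 0 || x > n || x != round(x) || n != round(n)) {
    stop("need integers 0 <= x <= n with n >= 1")
  }
  stopifnot(conf_level > 0, conf_level < 1)
  alpha <- 1 - conf_level
  lo <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lo = lo, hi = hi)
}

metric_row <- function(name, num, den, alpha) {
  if (den == 0) {
    data.frame(metric = name, num = num, den = den, point = NA_real_,
               ci_lo = NA_real_, ci_hi = NA_real_, undefined = TRUE,
               stringsAsFactors = FALSE)
  } else {
    ci <- clopper_pearson(num, den, 1 - alpha)
    data.frame(metric = name, num = num, den = den, point = num / den,
               ci_lo = ci[["lo"]], ci_hi = ci[["hi"]], undefined = FALSE,
               stringsAsFactors = FALSE)
  }
}

#' Determinate-subset accuracy metrics with exact intervals
#'
#' PPV, NPV, sensitivity and specificity restricted to determinate outputs,
#' plus the determinate rate, each with a two-sided exact Clopper-Pearson
#' interval. Both non-ASD reference categories (other condition and
#' neurotypical) pool into the negative reference class. A metric with an
#' empty denominator is flagged `undefined` rather than dropped.
#'
#' @param C A [confusion3x3()].
#' @param alpha Significance level (default 0.05 for 95% CIs).
#' @return A `metrics_report` data frame with columns `metric`, `num`, `den`,
#'   `point`, `ci_lo`, `ci_hi`, `undefined`.
#' @export
determinate_metrics <- function(C, alpha = 0.05) {
  stopifnot(inherits(C, "confusion3x3"))
  cc <- confusion_cells(C)
  if (cc$total == 0) stop("confusion matrix has a zero grand total")
  out <- rbind(
    metric_row("ppv", cc$tp, cc$tp + cc$fp, alpha),
    metric_row("npv", cc$tn, cc$tn + cc$fn, alpha),
    metric_row("sensitivity", cc$tp, cc$tp + cc$fn, alpha),
    metric_row("specificity", cc$tn, cc$tn + cc$fp, alpha),
    metric_row("determinate_rate", cc$tp + cc$fp + cc$tn + cc$fn, cc$total,
               alpha)
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' No-abstention counterfactual sensitivity and specificity
#'
#' What sensitivity and specificity would be if the indeterminate safety
#' mechanism were removed and abstentions counted as failures for both
#' classes: `se_all = TP / (all reference-positive subjects)` and
#' `sp_all = TN / (all reference-negative subjects)`.
#'
#' @inheritParams determinate_metrics
#' @return A `metrics_report` data frame with rows
#'   `no_abstention_sensitivity` and `no_abstention_specificity`.
#' @export
no_abstention_metrics <- function(C, alpha = 0.05) {
  stopifnot(inherits(C, "confusion3x3"))
  cc <- confusion_cells(C)
  if (cc$total == 0) stop("confusion matrix has a zero grand total")
  out <- rbind(
    metric_row("no_abstention_sensitivity", cc$tp, cc$all_asd, alpha),
    metric_row("no_abstention_specificity", cc$tn, cc$all_non_asd, alpha)
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' Composition of the indeterminate (abstention) group
#'
#' Fraction of indeterminate outputs whose reference diagnosis includes at
#' least one neurodevelopmental or behavioral condition (ASD or non-ASD), and
#' the full three-way breakdown of the indeterminate row.
#'
#' @param C A [confusion3x3()].
#' @return List with `fraction_neurodev` (with `num`/`den`), `breakdown`
#'   (named fractions over the three reference categories) and `undefined`
#'   (TRUE when the indeterminate row is empty).
#' @export
indeterminate_composition <- function(C) {
  stopifnot(inherits(C, "confusion3x3"))
  row <- C["indeterminate", ]
  tot <- sum(row)
  if (tot == 0) {
    return(list(fraction_neurodev = NA_real_, num = NA_integer_,
                den = 0L, breakdown = setNames(rep(NA_real_, 3),
                                               ref_categories),
                undefined = TRUE))
  }
  num <- row[["ASD_positive"]] + row[["ASD_negative_other_condition"]]
  list(fraction_neurodev = num / tot, num = num, den = tot,
       breakdown = row / tot, undefined = FALSE)
}

#' Full evaluation of a 3x3 confusion matrix
#'
#' Combines [determinate_metrics()], [no_abstention_metrics()], the observed
#' ASD prevalence, and the indeterminate neurodevelopmental fraction into one
#' report.
#'
#' @inheritParams determinate_metrics
#' @return A `metrics_report` data frame.
#' @export
evaluate_confusion <- function(C, alpha = 0.05) {
  cc <- confusion_cells(C)
  comp <- indeterminate_composition(C)
  out <- rbind(
    determinate_metrics(C, alpha),
    no_abstention_metrics(C, alpha),
    metric_row("prevalence", cc$all_asd, cc$total, alpha),
    metric_row("indeterminate_neurodev_fraction",
               if (comp$undefined) 0L else comp$num, comp$den, alpha)
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' Covariate-stratified performance metrics
#'
#' One metrics report per covariate stratum. Set-valued covariates
#' (semicolon-joined, e.g. non-exclusive race/ethnicity) contribute the
#' subject to every category in the set. Strata with empty denominators
#' appear with undefined-flagged metrics rather than being dropped. The CI
#' overlap indicator across strata is the comparability check used when a
#' study is not powered for formal subgroup inference.
#'
#' @param records Data frame with columns `device_output`, `ref_category` and
#'   the covariate.
#' @param covariate Name of the covariate column.
#' @param alpha Significance level.
#' @return Data frame with a `stratum` column followed by the metric columns;
#'   attribute `ci_overlap` gives, per metric, whether all stratum CIs
#'   pairwise overlap.
#' @export
stratified_metrics <- function(records, covariate, alpha = 0.05) {
  if (!covariate %in% names(records)) {
    stop("covariate column not found: ", covariate)
  }
  vals <- as.character(records[[covariate]])
  if (anyNA(vals)) stop("covariate must be present on every record")
  sets <- strsplit(vals, ";", fixed = TRUE)
  strata <- sort(unique(unlist(sets)))
  out <- do.call(rbind, lapply(strata, function(st) {
    idx <- vapply(sets, function(s) st %in% s, TRUE)
    rep <- evaluate_confusion(
      build_confusion(records$device_output[idx], records$ref_category[idx]),
      alpha
    )
    cbind(stratum = st, n = sum(idx), rep)
  }))
  ov <- vapply(unique(out$metric), function(m) {
    rows <- out[out$metric == m & !out$undefined, ]
    if (nrow(rows) < 2) return(TRUE)
    ci_overlap_all(rows$ci_lo, rows$ci_hi)
  }, TRUE)
  attr(out, "ci_overlap") <- ov
  out
}

ci_overlap_all <- function(lo, hi) {
  k <- length(lo)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (lo[i] > hi[j]) return(FALSE)
    }
  }
  TRUE
}
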