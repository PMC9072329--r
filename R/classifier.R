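#' Fit the probabilistic score model
#'
#' The device analogue: a learner mapping the 64-item response vector to a
#' score in \[0, 1\] (higher = more ASD-like). Gradient-boosted trees
#' (xgboost) are the default, matching the class of model such devices
#' deploy; a plain logistic regression is available as a fast, fully
#' reproducible alternative. Identical data and seed give identical scores.
#'
#' @param features Numeric matrix or data frame, one row per subject
#'   (typically the `q01..q64` columns of a cohort). Missing responses are
#'   median-imputed for the logistic learner and passed through to xgboost,
#'   which handles them natively.
#' @param labels Logical or 0/1 vector: reference-positive for ASD.
#' @param learner `"xgboost"` or `"logistic"`.
#' @param hyperparams Named list; for xgboost: `nrounds` (default 80),
#'   `max_depth` (3), `eta` (0.15).
#' @param seed Integer seed for the learner substream.
#' @return An object of class `score_model` with a [predict()] method
#'   returning scores in \[0, 1\].
#' @export
fit_score_model <- function(features, labels,
                            learner = c("xgboost", "logistic"),
                            hyperparams = list(), seed = 1) {
  learner <- match.arg(learner)
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- as.integer(as.logical(labels))
  if (nrow(X) != length(y)) stop("features and labels differ in length")
  if (anyNA(y)) stop("labels must not contain NA")
  if (length(unique(y)) < 2) {
    stop("training set contains a single class; need both ASD and non-ASD")
  }
  hp <- utils::modifyList(list(nrounds = 80, max_depth = 3, eta = 0.15),
                          hyperparams)
  fit <- with_substream(seed, "learner", {
    if (learner == "xgboost") {
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                      eta = hp$eta, nthread = 1, seed = derive_seed(seed, "learner")),
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
        nrounds = hp$nrounds, verbose = 0
      )
    } else {
      med <- apply(X, 2, function(col) {
        m <- stats::median(col, na.rm = TRUE)
        if (is.na(m)) 0 else m
      })
      Xi <- impute_median(X, med)
      # drop zero-variance columns; an all-constant design reduces to the
      # intercept-only (prevalence) model
      keep <- apply(Xi, 2, function(col) stats::var(col) > 0)
      fit <- if (any(keep)) {
        df <- as.data.frame(Xi[, keep, drop = FALSE])
        suppressWarnings(glm(y ~ ., data = cbind(df, y = y),
                             family = binomial()))
      } else {
        suppressWarnings(glm(y ~ 1, data = data.frame(y = y),
                             family = binomial()))
      }
      list(glm = fit, keep = keep)
    }
  })
  structure(list(
    learner = learner, fit = fit, hyperparams = hp, seed = seed,
    n_features = ncol(X),
    impute_medians = if (learner == "logistic") {
      apply(X, 2, function(col) {
        m <- stats::median(col, na.rm = TRUE); if (is.na(m)) 0 else m
      })
    } else NULL,
    train_fingerprint = fingerprint_matrix(X)
  ), class = "score_model")
}

impute_median <- function(X, med) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- med[j]
  }
  X
}

fingerprint_matrix <- function(X) {
  c(nrow(X), round(sum(X, na.rm = TRUE), 6))
}

#' Predict scores from a fitted score model
#'
#' @param object A `score_model`.
#' @param newdata Feature matrix/data frame with the same number of columns as
#'   at training time.
#' @param ... Unused.
#' @return Numeric scores in \[0, 1\]. Scores computed on the model's own
#'   training data carry the attribute `in_fold = TRUE`, which
#'   [calibrate_thresholds()] refuses (thresholds must be calibrated on
#'   out-of-fold scores).
#' @export
predict.score_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (ncol(X) != object$n_features) {
    stop("feature-length mismatch: model expects ", object$n_features,
         " columns, got ", ncol(X))
  }
  s <- if (object$learner == "xgboost") {
    predict(object$fit, xgboost::xgb.DMatrix(X, nthread = 1))
  } else {
    Xi <- impute_median(X, object$impute_medians)
    keep <- object$fit$keep
    df <- if (any(keep)) as.data.frame(Xi[, keep, drop = FALSE]) else
      data.frame(.dummy = numeric(nrow(Xi)))
    suppressWarnings(as.numeric(predict(object$fit$glm, newdata = df,
                                        type = "response")))
  }
  s <- pmin(1, pmax(0, s))
  if (identical(fingerprint_matrix(X), object$train_fingerprint)) {
    attr(s, "in_fold") <- TRUE
  }
  s
}

#' Out-of-fold scores by stratified cross-validation
#'
#' Splits subjects into `folds` class-stratified folds, fits the score model
#' on each training portion and scores the held-out portion, so every subject
#' receives a score from a model that never saw it. These are the scores on
#' which abstention thresholds are calibrated.
#'
#' @inheritParams fit_score_model
#' @param folds Number of folds (>= 2, default 5).
#' @return Numeric vector of out-of-fold scores with attributes `fold`
#'   (fold assignments), `in_fold = FALSE` and class `oof_scores`.
#' @export
cv_oof_scores <- function(features, labels, folds = 5,
                          learner = c("xgboost", "logistic"),
                          hyperparams = list(), seed = 1) {
  learner <- match.arg(learner)
  X <- as.matrix(features)
  y <- as.logical(labels)
  n <- nrow(X)
  stopifnot(folds >= 2)
  if (n < 2 * folds) stop("too few subjects for ", folds, "-fold CV")
  fold <- with_substream(seed, "folds", {
    f <- integer(n)
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    f
  })
  scores <- numeric(n)
  for (k in seq_len(folds)) {
    tr <- fold != k
    if (length(unique(y[tr])) < 2) {
      stop("fold ", k, " leaves a single-class training set")
    }
    m <- fit_score_model(X[tr, , drop = FALSE], y[tr], learner = learner,
                         hyperparams = hyperparams, seed = seed + k)
    s <- predict(m, X[!tr, , drop = FALSE])
    attr(s, "in_fold") <- NULL
    scores[!tr] <- s
  }
  structure(scores, fold = fold, in_fold = FALSE, class = "oof_scores")
}

#' Abstention threshold pair
#'
#' The dual thresholds `0 <= t_neg <= t_pos <= 1` partition scores into
#' negative (`score < t_neg`), indeterminate (`t_neg <= score < t_pos`) and
#' positive (`score >= t_pos`).
#'
#' @param t_neg,t_pos Thresholds in \[0, 1\] with `t_neg <= t_pos`.
#' @return An object of class `threshold_pair`.
#' @export
threshold_pair <- function(t_neg, t_pos) {
  stopifnot(length(t_neg) == 1, length(t_pos) == 1)
  if (is.na(t_neg) || is.na(t_pos) || t_neg < 0 || t_pos > 1 || t_neg > t_pos) {
    stop("need 0 <= t_neg <= t_pos <= 1")
  }
  structure(list(t_neg = t_neg, t_pos = t_pos), class = "threshold_pair")
}

#' Apply abstention thresholds to scores
#'
#' Boundary convention: negative iff `score < t_neg`; positive iff
#' `score >= t_pos`; indeterminate otherwise. With `t_neg == t_pos` the
#' device never abstains and reduces to a standard binary classifier.
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param thresholds A [threshold_pair()].
#' @return Factor with levels `negative`, `indeterminate`, `positive`.
#' @export
apply_thresholds <- function(scores, thresholds) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  s <- as.numeric(scores)
  if (anyNA(s) || any(s < 0) || any(s > 1)) {
    stop("scores must lie in [0, 1] with no missing values")
  }
  out <- ifelse(s < thresholds$t_neg, "negative",
                ifelse(s >= thresholds$t_pos, "positive", "indeterminate"))
  factor(out, levels = c("negative", "indeterminate", "positive"))
}

#' Predictive-value floors and calibration settings
#'
#' The regulatory constraints governing threshold calibration: abstention
#' thresholds must keep the positive predictive value above `ppv_floor` and
#' the negative predictive value above `npv_floor` (defaults 0.65 and 0.85,
#' the floors negotiated for the device this package emulates), evaluated on
#' out-of-fold scores either pooled across folds (`pooled_oof`, default) or
#' within every fold (`per_fold`).
#'
#' @param ppv_floor,npv_floor Floors in (0, 1).
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param constraint_mode `"pooled_oof"` or `"per_fold"`.
#' @return An object of class `floor_spec`.
#' @export
floor_spec <- function(ppv_floor = 0.65, npv_floor = 0.85, cv_folds = 5,
                       constraint_mode = c("pooled_oof", "per_fold")) {
  constraint_mode <- match.arg(constraint_mode)
  stopifnot(ppv_floor > 0, ppv_floor < 1, npv_floor > 0, npv_floor < 1,
            cv_folds >= 2)
  structure(list(ppv_floor = ppv_floor, npv_floor = npv_floor,
                 cv_folds = as.integer(cv_folds),
                 constraint_mode = constraint_mode),
            class = "floor_spec")
}

#' Calibrate abstention thresholds under predictive-value floors
#'
#' Searches all candidate threshold pairs (t_neg, t_pos) drawn from the
#' midpoints between consecutive sorted unique out-of-fold scores plus
#' \{0, 1\} — a finite sufficient grid, since the induced partition only
#' changes at observed scores — and returns the pair that maximizes the
#' determinate rate subject to PPV >= `ppv_floor` and NPV >= `npv_floor`.
#' A feasible pair must produce at least one positive and one negative output
#' overall, with both floors met where they are evaluated; in `per_fold` mode
#' a fold in which a region happens to be empty contributes no constraint for
#' that region. Ties are broken toward the widest abstention band, then the
#' lowest `t_neg` (the most conservative feasible device).
#'
#' When no candidate pair satisfies the floors, a calibration-failure value is
#' returned rather than an error: infeasibility is a meaningful outcome for
#' strongly overlapping populations.
#'
#' @param scores Out-of-fold scores ([cv_oof_scores()]) or a plain numeric
#'   vector in \[0, 1\]. Scores tagged as in-fold (computed on their own
#'   training data) are rejected.
#' @param labels Logical or 0/1 reference labels (TRUE = ASD).
#' @param floors A [floor_spec()].
#' @param folds Optional fold assignment (needed for `per_fold` mode when
#'   `scores` does not carry one).
#' @return An object of class `threshold_calibration`: list with `feasible`,
#'   `thresholds` (a [threshold_pair()] or NULL), `determinate_rate`, `ppv`,
#'   `npv`, `n_feasible` (number of feasible candidate pairs) and the floors
#'   used. When infeasible the class also includes `calibration_failure`.
#' @export
calibrate_thresholds <- function(scores, labels, floors = floor_spec(),
                                 folds = NULL) {
  stopifnot(inherits(floors, "floor_spec"))
  if (isTRUE(attr(scores, "in_fold"))) {
    stop("scores were computed in-fold (on their own training data); ",
         "calibrate thresholds on out-of-fold scores")
  }
  if (is.null(folds)) folds <- attr(scores, "fold")
  s <- as.numeric(scores)
  y <- as.logical(labels)
  if (length(s) == 0) stop("empty score vector")
  if (length(s) != length(y)) stop("scores and labels differ in length")
  if (anyNA(s) || any(s < 0) || any(s > 1)) stop("scores must lie in [0, 1]")
  if (floors$constraint_mode == "per_fold" && is.null(folds)) {
    stop("per_fold constraint mode requires fold assignments")
  }

  u <- sort(unique(s))
  cand <- sort(unique(c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1)))
  m <- length(cand)
  n <- length(s)

  group_ok <- function(idx) {
    # For threshold t: negative region = {s < t}, positive region = {s >= t}.
    # Cumulative counts over the candidate grid for the subjects in idx.
    si <- s[idx]; yi <- y[idx]
    neg_tot <- vapply(cand, function(t) sum(si < t), 0)
    neg_fn <- vapply(cand, function(t) sum(si < t & yi), 0)
    pos_tot <- length(si) - neg_tot
    pos_tp <- sum(yi) - neg_fn
    npv <- ifelse(neg_tot > 0, (neg_tot - neg_fn) / neg_tot, NA)
    ppv <- ifelse(pos_tot > 0, pos_tp / pos_tot, NA)
    list(ok_n = is.na(npv) | npv >= floors$npv_floor,
         ok_p = is.na(ppv) | ppv >= floors$ppv_floor)
  }

  if (floors$constraint_mode == "pooled_oof") {
    ok <- group_ok(seq_len(n))
    ok_n <- ok$ok_n; ok_p <- ok$ok_p
  } else {
    ok_n <- rep(TRUE, m); ok_p <- rep(TRUE, m)
    for (k in unique(folds)) {
      ok <- group_ok(which(folds == k))
      ok_n <- ok_n & ok$ok_n
      ok_p <- ok_p & ok$ok_p
    }
  }

  det_neg <- vapply(cand, function(t) sum(s < t), 0)   # determinate negatives
  det_pos <- vapply(cand, function(t) sum(s >= t), 0)  # determinate positives

  # a calibration must actually emit both output types overall
  feas <- outer(ok_n & det_neg > 0, ok_p & det_pos > 0, "&") &
    outer(cand, cand, "<=")
  if (!any(feas)) {
    return(structure(list(
      feasible = FALSE, thresholds = NULL, determinate_rate = NA_real_,
      ppv = NA_real_, npv = NA_real_, n_feasible = 0L, floors = floors,
      n = n, reason = "no threshold pair satisfies the floors"
    ), class = c("calibration_failure", "threshold_calibration")))
  }
  det <- outer(det_neg, det_pos, "+")
  det[!feas] <- -1L
  best_det <- max(det)
  cand_idx <- which(det == best_det, arr.ind = TRUE)
  width <- cand[cand_idx[, 2]] - cand[cand_idx[, 1]]
  cand_idx <- cand_idx[order(-width, cand[cand_idx[, 1]]), , drop = FALSE]
  i <- cand_idx[1, 1]; j <- cand_idx[1, 2]
  tp <- threshold_pair(cand[i], cand[j])

  out <- apply_thresholds(s, tp)
  pos <- out == "positive"; neg <- out == "negative"
  structure(list(
    feasible = TRUE, thresholds = tp,
    determinate_rate = best_det / n,
    ppv = if (any(pos)) sum(y[pos]) / sum(pos) else NA_real_,
    npv = if (any(neg)) sum(!y[neg]) / sum(neg) else NA_real_,
    n_feasible = sum(feas), floors = floors, n = n
  ), class = "threshold_calibration")
}

#' @rdname calibrate_thresholds
#' @param x Object to test.
#' @export
is_calibration_failure <- function(x) inherits(x, "calibration_failure")

#' @export
print.threshold_calibration <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf(
      "Calibrated thresholds: t_neg = %.4f, t_pos = %.4f\n", x$thresholds$t_neg,
      x$thresholds$t_pos))
    cat(sprintf("  determinate rate %.3f, PPV %.3f, NPV %.3f (%d feasible pairs)\n",
                x$determinate_rate, x$ppv, x$npv, x$n_feasible))
  } else {
    cat(sprintf(
      "Calibration failure: no threshold pair attains PPV >= %.2f and NPV >= %.2f\n",
      x$floors$ppv_floor, x$floors$npv_floor))
  }
  invisible(x)
}
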