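# Independent oracles and fixtures used across the suite. Everything here is
# deliberately naive (loops, enumeration, bisection) and never calls the code
# path it is used to check.

# Published pivotal-trial confusion matrix of an abstaining ASD diagnostic
# aid (425 completers), used as a worked fixture throughout.
pivotal_confusion <- function() {
  confusion3x3(matrix(
    c(63, 15, 0,
      58, 206, 26,
      1, 42, 14),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("positive", "indeterminate", "negative"),
                    c("ASD_positive", "ASD_negative_other_condition",
                      "ASD_negative_neurotypical"))
  ))
}

# Expand a 3x3 count matrix into one record per subject.
expand_records <- function(C) {
  rows <- rownames(C); cols <- colnames(C)
  out <- do.call(rbind, lapply(rows, function(r) {
    do.call(rbind, lapply(cols, function(cl) {
      k <- C[r, cl]
      if (k == 0) return(NULL)
      data.frame(device_output = rep(r, k), ref_category = rep(cl, k),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

# Naive per-record metric counting (no matrix algebra shared with the
# package implementation).
naive_determinate_metrics <- function(records) {
  pos <- records$device_output == "positive"
  neg <- records$device_output == "negative"
  asd <- records$ref_category == "ASD_positive"
  c(ppv = sum(pos & asd) / sum(pos),
    npv = sum(neg & !asd) / sum(neg),
    sensitivity = sum(pos & asd) / sum((pos | neg) & asd),
    specificity = sum(neg & !asd) / sum((pos | neg) & !asd),
    determinate_rate = sum(pos | neg) / nrow(records))
}

# Clopper-Pearson bounds by direct bisection on the binomial tail conditions
# P(X >= x | p = lo) = alpha/2 and P(X <= x | p = hi) = alpha/2.
cp_bisection <- function(x, n, alpha = 0.05) {
  lo <- if (x == 0) 0 else {
    uniroot(function(p) 1 - pbinom(x - 1, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  hi <- if (x == n) 1 else {
    uniroot(function(p) pbinom(x, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lo = lo, hi = hi)
}

# Full-enumeration Boschloo oracle: for every outcome of the two binomials,
# order by stats::fisher.test p-values, then maximize the rejection-region
# probability over the same bare nuisance grid the implementation uses.
boschloo_enumeration <- function(x1, n1, x2, n2,
                                 alternative = "two_sided", grid_size = 201) {
  alt <- switch(alternative, two_sided = "two.sided", alternative)
  pmat <- matrix(NA_real_, n1 + 1, n2 + 1)
  for (a in 0:n1) {
    for (b in 0:n2) {
      tab <- matrix(c(a, n1 - a, b, n2 - b), 2, 2)
      pmat[a + 1, b + 1] <- stats::fisher.test(tab, alternative = alt)$p.value
    }
  }
  p_obs <- pmat[x1 + 1, x2 + 1]
  region <- pmat <= p_obs * (1 + 1e-7)
  grid <- seq(1 / (grid_size + 1), grid_size / (grid_size + 1),
              length.out = grid_size)
  best <- 0
  for (pi0 in grid) {
    tot <- 0
    for (a in 0:n1) {
      for (b in 0:n2) {
        if (region[a + 1, b + 1]) {
          tot <- tot + dbinom(a, n1, pi0) * dbinom(b, n2, pi0)
        }
      }
    }
    best <- max(best, tot)
  }
  best
}

# Record set consistent with the published sex-stratified performance table:
# females 20 positive (12 TP), 25 negative (24 TN), 109 indeterminate;
# males 58 positive (51 TP), 32 negative (32 TN), 181 indeterminate.
sex_records <- function() {
  mk <- function(sex, out, ref, k) {
    if (k == 0) return(NULL)
    data.frame(sex = sex, device_output = out, ref_category = ref)[rep(1, k), ]
  }
  out <- rbind(
    mk("female", "positive", "ASD_positive", 12),
    mk("female", "positive", "ASD_negative_other_condition", 8),
    mk("female", "negative", "ASD_positive", 1),
    mk("female", "negative", "ASD_negative_other_condition", 20),
    mk("female", "negative", "ASD_negative_neurotypical", 4),
    mk("female", "indeterminate", "ASD_negative_other_condition", 109),
    mk("male", "positive", "ASD_positive", 51),
    mk("male", "positive", "ASD_negative_other_condition", 7),
    mk("male", "negative", "ASD_negative_other_condition", 28),
    mk("male", "negative", "ASD_negative_neurotypical", 4),
    mk("male", "indeterminate", "ASD_negative_other_condition", 181)
  )
  rownames(out) <- NULL
  out
}

# Exhaustive-search calibration oracle over all candidate threshold pairs,
# mirroring the documented semantics: candidates are midpoints of sorted
# unique scores plus {0, 1}; a feasible pair must emit at least one positive
# and one negative output overall (per-fold empty regions are vacuous); ties
# break to the widest band, then the lowest t_neg.
brute_force_calibration <- function(scores, labels, ppv_floor = 0.65,
                                    npv_floor = 0.85, folds = NULL,
                                    per_fold = FALSE) {
  s <- as.numeric(scores); y <- as.logical(labels)
  u <- sort(unique(s))
  cand <- sort(unique(c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1)))
  ok_pair <- function(tn, tp, idx) {
    si <- s[idx]; yi <- y[idx]
    neg <- si < tn; pos <- si >= tp
    ppv <- if (sum(pos) > 0) sum(yi[pos]) / sum(pos) else NA
    npv <- if (sum(neg) > 0) sum(!yi[neg]) / sum(neg) else NA
    (is.na(ppv) || ppv >= ppv_floor) && (is.na(npv) || npv >= npv_floor)
  }
  best <- NULL
  for (tn in cand) {
    for (tp in cand[cand >= tn]) {
      if (sum(s < tn) == 0 || sum(s >= tp) == 0) next
      groups <- if (per_fold) split(seq_along(s), folds) else
        list(seq_along(s))
      if (!all(vapply(groups, function(idx) ok_pair(tn, tp, idx), TRUE))) next
      det <- sum(s < tn) + sum(s >= tp)
      cur <- list(tn = tn, tp = tp, det = det, width = tp - tn)
      if (is.null(best) || det > best$det ||
          (det == best$det && (cur$width > best$width ||
                               (cur$width == best$width && tn < best$tn)))) {
        best <- cur
      }
    }
  }
  best
}
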