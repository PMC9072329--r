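test_that("perfectly separated scores calibrate to full coverage", {
  s <- c(rep(0.9, 30), rep(0.1, 70))
  y <- c(rep(TRUE, 30), rep(FALSE, 70))
  cal <- calibrate_thresholds(s, y, floor_spec())
  expect_false(is_calibration_failure(cal))
  expect_equal(cal$determinate_rate, 1)
  expect_equal(cal$ppv, 1)
  expect_equal(cal$npv, 1)
  expect_gt(cal$thresholds$t_neg, 0.1)
  expect_lte(cal$thresholds$t_pos, 0.9)
})

test_that("a 12-point worked grid matches exhaustive search", {
  s <- c(0.05, 0.10, 0.20, 0.30, 0.35, 0.40, 0.55, 0.60, 0.70, 0.80, 0.90, 0.95)
  y <- c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE,
         TRUE, TRUE)
  cal <- calibrate_thresholds(s, y, floor_spec(ppv_floor = 0.65,
                                               npv_floor = 0.85))
  oracle <- brute_force_calibration(s, y)
  expect_false(is_calibration_failure(cal))
  expect_equal(cal$thresholds$t_neg, oracle$tn)
  expect_equal(cal$thresholds$t_pos, oracle$tp)
  expect_equal(cal$determinate_rate, oracle$det / length(s))
})

test_that("calibration matches the exhaustive oracle on random small grids", {
  set.seed(808)
  for (rep in 1:25) {
    m <- sample(4:20, 1)
    s <- round(runif(m), 2)
    y <- runif(m) < plogis(4 * (s - 0.5))
    if (length(unique(y)) < 2) next
    pf <- runif(1, 0.4, 0.9); nf <- runif(1, 0.5, 0.95)
    cal <- calibrate_thresholds(s, y, floor_spec(ppv_floor = pf, npv_floor = nf))
    oracle <- brute_force_calibration(s, y, ppv_floor = pf, npv_floor = nf)
    if (is.null(oracle)) {
      expect_true(is_calibration_failure(cal))
    } else {
      expect_false(is_calibration_failure(cal))
      expect_equal(cal$thresholds$t_neg, oracle$tn)
      expect_equal(cal$thresholds$t_pos, oracle$tp)
    }
  }
})

test_that("per-fold constraints match the oracle and imply pooled-style checks", {
  set.seed(909)
  for (rep in 1:10) {
    m <- 24
    s <- round(runif(m), 2)
    y <- runif(m) < plogis(5 * (s - 0.5))
    if (length(unique(y)) < 2) next
    folds <- rep(1:3, length.out = m)
    fl <- floor_spec(ppv_floor = 0.6, npv_floor = 0.7,
                     constraint_mode = "per_fold")
    cal <- calibrate_thresholds(s, y, fl, folds = folds)
    oracle <- brute_force_calibration(s, y, ppv_floor = 0.6, npv_floor = 0.7,
                                      folds = folds, per_fold = TRUE)
    if (is.null(oracle)) {
      expect_true(is_calibration_failure(cal))
    } else {
      expect_equal(cal$thresholds$t_neg, oracle$tn)
      expect_equal(cal$thresholds$t_pos, oracle$tp)
    }
  }
})

test_that("returned thresholds always satisfy the floors when recomputed", {
  set.seed(313)
  hits <- 0
  for (rep in 1:40) {
    n <- 120
    s <- runif(n)
    y <- runif(n) < plogis(6 * (s - 0.6))
    if (length(unique(y)) < 2) next
    fl <- floor_spec()
    cal <- calibrate_thresholds(s, y, fl)
    if (is_calibration_failure(cal)) next
    hits <- hits + 1
    out <- apply_thresholds(s, cal$thresholds)
    pos <- out == "positive"; neg <- out == "negative"
    if (any(pos)) expect_gte(sum(y[pos]) / sum(pos), fl$ppv_floor)
    if (any(neg)) expect_gte(sum(!y[neg]) / sum(neg), fl$npv_floor)
    expect_equal(mean(out != "indeterminate"), cal$determinate_rate)
  }
  expect_gt(hits, 5)
})

test_that("widening the abstention band never increases coverage", {
  set.seed(99)
  s <- runif(300)
  base <- threshold_pair(0.4, 0.6)
  det_base <- mean(apply_thresholds(s, base) != "indeterminate")
  for (d in seq(0, 0.4, by = 0.1)) {
    wide <- threshold_pair(0.4 - d, 0.6 + d)
    det_wide <- mean(apply_thresholds(s, wide) != "indeterminate")
    expect_lte(det_wide, det_base)
    # supersets: every indeterminate under the base band stays indeterminate
    ind_base <- apply_thresholds(s, base) == "indeterminate"
    ind_wide <- apply_thresholds(s, wide) == "indeterminate"
    expect_true(all(ind_wide[ind_base]))
  }
})

test_that("pure-noise scores never calibrate to substantial coverage", {
  # labels independent of scores at prevalence 0.29 < the 0.65 PPV floor:
  # any feasible pair can only be a small-region fluke of the pooled
  # point-estimate constraints, never a genuine operating point
  set.seed(515)
  for (rep in 1:20) {
    s <- runif(400)
    y <- runif(400) < 0.29
    cal <- calibrate_thresholds(s, y, floor_spec())
    if (!is_calibration_failure(cal)) {
      expect_lt(cal$determinate_rate, 0.25)
      expect_gte(cal$ppv, 0.65)
      expect_gte(cal$npv, 0.85)
    }
  }
})

test_that("in-fold scores and degenerate inputs are rejected", {
  coh <- generate_cohort(cohort_config(n_subjects = 100, seed = 8))
  X <- coh[, sprintf("q%02d", 1:64)]
  y <- coh$true_class == "asd"
  m <- fit_score_model(X, y, learner = "logistic", seed = 1)
  s_in <- predict(m, X)
  expect_error(calibrate_thresholds(s_in, y, floor_spec()), "in-fold")
  expect_error(calibrate_thresholds(numeric(0), logical(0), floor_spec()),
               "empty")
  expect_error(
    calibrate_thresholds(c(0.2, 0.8), c(TRUE, FALSE),
                         floor_spec(constraint_mode = "per_fold")),
    "fold assignments"
  )
})

test_that("calibrated coverage rises monotonically with class separation", {
  seps <- c(0, 0.75, 1.5, 2.25, 3)
  n_rep <- 10
  mean_det <- numeric(length(seps))
  for (i in seq_along(seps)) {
    d <- seps[i]
    rates <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      cfg <- cohort_config(
        n_subjects = 300,
        class_latent_params = list(
          asd = c(mean = d, sd = 1),
          comorbid_only = c(mean = 0, sd = 1),
          neurotypical = c(mean = -d, sd = 1)
        ),
        seed = 5000 + 100 * i + r
      )
      coh <- generate_cohort(cfg)
      y <- coh$true_class == "asd"
      oof <- cv_oof_scores(coh[, sprintf("q%02d", 1:64)], y, folds = 5,
                           learner = "xgboost", seed = 600 + r)
      cal <- calibrate_thresholds(oof, y, floor_spec())
      rates[r] <- if (is_calibration_failure(cal)) 0 else cal$determinate_rate
    }
    mean_det[i] <- mean(rates)
  }
  rho <- cor(seps, mean_det, method = "spearman")
  expect_gt(rho, 0.9)
})
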