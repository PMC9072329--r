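test_that("build_confusion tallies records exactly", {
  C <- pivotal_confusion()
  rec <- expand_records(C)
  rebuilt <- build_confusion(rec$device_output, rec$ref_category)
  expect_equal(unclass(rebuilt), unclass(C), ignore_attr = TRUE)
  expect_equal(sum(rebuilt["indeterminate", ]), 290)
  expect_equal(sum(rebuilt), 425)
  expect_equal(unname(colSums(rebuilt)), c(122L, 263L, 40L))

  empty <- build_confusion(character(0), character(0))
  expect_true(all(empty == 0))

  expect_error(build_confusion("maybe", "ASD_positive"),
               "unknown device output label: maybe")
  expect_error(build_confusion("positive", "ASD"),
               "unknown reference category label: ASD")
})

test_that("determinate metrics reproduce the worked confusion matrix", {
  rep <- determinate_metrics(pivotal_confusion())
  get <- function(m) rep[rep$metric == m, ]
  expect_equal(get("ppv")$point, 63 / 78)
  expect_equal(get("npv")$point, 56 / 57)
  expect_equal(get("sensitivity")$point, 63 / 64)
  expect_equal(get("specificity")$point, 56 / 71)
  expect_equal(get("determinate_rate")$point, 135 / 425)
  expect_true(all(!rep$undefined))

  # diagonal-only matrix: everything perfect, full coverage
  D <- confusion3x3(matrix(c(10, 0, 0, 0, 0, 0, 0, 5, 3), 3, byrow = TRUE))
  repD <- determinate_metrics(D)
  expect_true(all(repD$point == 1))
})

test_that("metrics equal naive per-record counting on random matrices", {
  set.seed(21)
  for (i in 1:20) {
    M <- matrix(rpois(9, 12) + 1, 3, 3)
    C <- confusion3x3(M)
    rec <- expand_records(C)
    rep <- determinate_metrics(C)
    oracle <- naive_determinate_metrics(rec)
    for (m in names(oracle)) {
      expect_equal(rep[rep$metric == m, "point"], oracle[[m]])
    }
  }
})

test_that("zero denominators are flagged undefined, not dropped", {
  M <- matrix(c(0, 0, 0, 5, 6, 2, 0, 0, 0), 3, byrow = TRUE)
  rep <- determinate_metrics(confusion3x3(M))
  expect_true(rep[rep$metric == "ppv", "undefined"])
  expect_true(rep[rep$metric == "npv", "undefined"])
  expect_equal(rep[rep$metric == "determinate_rate", "point"], 0)
  comp <- indeterminate_composition(confusion3x3(matrix(0L, 3, 3,
    dimnames = list(c("positive", "indeterminate", "negative"), NULL))))
  expect_true(comp$undefined)
})

test_that("no-abstention counterfactual counts abstentions as failures", {
  rep <- no_abstention_metrics(pivotal_confusion())
  expect_equal(rep[rep$metric == "no_abstention_sensitivity", "point"], 63 / 122)
  expect_equal(rep[rep$metric == "no_abstention_specificity", "point"], 56 / 303)

  # no indeterminate row: counterfactual equals the determinate metrics
  M <- matrix(c(20, 4, 1, 0, 0, 0, 3, 30, 9), 3, byrow = TRUE)
  C <- confusion3x3(M)
  det <- determinate_metrics(C)
  noab <- no_abstention_metrics(C)
  expect_equal(noab[1, "point"], det[det$metric == "sensitivity", "point"])
  expect_equal(noab[2, "point"], det[det$metric == "specificity", "point"])

  # denominators only grow: counterfactual never exceeds determinate metrics
  set.seed(4)
  for (i in 1:10) {
    C <- confusion3x3(matrix(rpois(9, 8) + 1, 3, 3))
    det <- determinate_metrics(C)
    noab <- no_abstention_metrics(C)
    expect_lte(noab[1, "point"], det[det$metric == "sensitivity", "point"])
    expect_lte(noab[2, "point"], det[det$metric == "specificity", "point"])
  }
})

test_that("Clopper-Pearson matches tail-inversion bisection for all n <= 25", {
  for (n in 1:25) {
    for (x in 0:n) {
      got <- clopper_pearson(x, n)
      want <- cp_bisection(x, n)
      expect_equal(got[["lo"]], want[["lo"]], tolerance = 1e-6)
      expect_equal(got[["hi"]], want[["hi"]], tolerance = 1e-6)
    }
  }
  expect_identical(clopper_pearson(0, 57)[["lo"]], 0)
  expect_identical(clopper_pearson(57, 57)[["hi"]], 1)
  expect_error(clopper_pearson(5, 4), "0 <= x <= n")
  expect_error(clopper_pearson(-1, 4), "0 <= x <= n")
})

test_that("Clopper-Pearson intervals achieve nominal coverage", {
  set.seed(17)
  for (n in c(10, 50, 200)) {
    for (p in c(0.1, 0.5, 0.9)) {
      x <- rbinom(2000, n, p)
      lo <- ifelse(x == 0, 0, qbeta(0.025, x, n - x + 1))
      hi <- ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
      # vectorized bounds agree with the scalar implementation
      i <- sample.int(2000, 5)
      for (k in i) {
        expect_equal(unname(clopper_pearson(x[k], n)), c(lo[k], hi[k]))
      }
      expect_gte(mean(lo <= p & p <= hi), 0.95)
    }
  }
})

test_that("indeterminate composition matches the worked fixture", {
  comp <- indeterminate_composition(pivotal_confusion())
  expect_equal(comp$fraction_neurodev, 264 / 290)
  expect_equal(unname(comp$breakdown),
               c(58 / 290, 206 / 290, 26 / 290))

  # all-neurotypical indeterminate row
  M <- matrix(c(1, 0, 0, 0, 0, 7, 0, 0, 1), 3, byrow = TRUE)
  expect_equal(indeterminate_composition(confusion3x3(M))$fraction_neurodev, 0)

  # complement identity on random rows
  set.seed(31)
  for (i in 1:10) {
    M <- matrix(rpois(9, 6), 3, 3); M[2, ] <- M[2, ] + 1
    comp <- indeterminate_composition(confusion3x3(M))
    expect_equal(comp$fraction_neurodev,
                 1 - comp$breakdown[["ASD_negative_neurotypical"]])
  }
})

test_that("stratified metrics reproduce subgroup sensitivities", {
  st <- stratified_metrics(sex_records(), "sex")
  fem_se <- st[st$stratum == "female" & st$metric == "sensitivity", ]
  expect_equal(fem_se$point, 12 / 13)
  expect_equal(fem_se$num, 12)
  male_se <- st[st$stratum == "male" & st$metric == "sensitivity", ]
  expect_equal(male_se$point, 1)
  expect_true(attr(st, "ci_overlap")[["sensitivity"]])
})

test_that("single-stratum and non-exclusive stratifications behave", {
  rec <- expand_records(pivotal_confusion())
  rec$site <- "all"
  st <- stratified_metrics(rec, "site")
  overall <- evaluate_confusion(pivotal_confusion())
  expect_equal(st$point, overall$point)

  # non-exclusive sets: multi-category subjects count in every category
  rec2 <- expand_records(confusion3x3(matrix(c(4, 1, 0, 2, 6, 1, 0, 3, 3),
                                             3, byrow = TRUE)))
  race <- rep(c("white", "black", "white;black"), length.out = nrow(rec2))
  rec2$race <- race
  st2 <- stratified_metrics(rec2, "race")
  den_sum <- sum(st2[st2$metric == "determinate_rate", "den"])
  expect_gte(den_sum, nrow(rec2))
  expect_error(stratified_metrics(rec2, "absent_col"), "not found")
})
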