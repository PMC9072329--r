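#' Configuration of a synthetic developmental-delay cohort
#'
#' Describes a cohort of 18-72-month-olds referred for developmental-delay
#' concerns, as seen in primary-care screening studies of abstaining ASD
#' diagnostic aids. Three latent clinical classes are simulated: ASD,
#' non-ASD developmental/behavioral conditions ("comorbid_only") and
#' neurotypical. Each subject carries a one-dimensional latent severity trait
#' `z` with class-conditional normal distributions; the comorbid class sits
#' between neurotypical and ASD, which is what makes abstention necessary.
#'
#' @param n_subjects Number of subjects (>= 0).
#' @param class_probs Named probabilities for `asd`, `comorbid_only`,
#'   `neurotypical`; must sum to 1 (tolerance 1e-12). Defaults reproduce the
#'   28.7% / 61.9% / 9.4% class mix observed in primary-care referral
#'   populations.
#' @param age_range_months Inclusive integer bounds, within \[18, 72\].
#' @param age_band_weights Sampling weights for the yearly age bands
#'   18-23, 24-35, 36-47, 48-59, 60-72 months; ages are uniform within a
#'   yearly band. Defaults follow the age mix of a primary-care referral
#'   cohort (13.2/30.4/24.2/21.2/11.1%).
#' @param class_latent_params Named list per class of `c(mean, sd)` for the
#'   latent trait z.
#' @param item_bank An [item_bank()] (default [default_item_bank()]).
#' @param panel A [panel_params()] object describing the specialist panel.
#' @param covariate_probs Named list of category-to-probability mappings for
#'   `sex`, `race_ethnicity`, `income_band`, `education_band`, plus
#'   `multi_race_prob`, the probability that a subject reports a second
#'   race/ethnicity category (race/ethnicity is non-exclusive).
#' @param comorbidity_probs Named per-condition probabilities used for
#'   comorbid-class subjects (and, at half rate, ASD subjects).
#' @param missing_prob Per-item probability of a missing response (default 0).
#' @param seed Mandatory integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects,
                          class_probs = c(asd = 0.287, comorbid_only = 0.619,
                                          neurotypical = 0.094),
                          age_range_months = c(18L, 72L),
                          age_band_weights = c(0.132, 0.304, 0.242, 0.212, 0.110),
                          class_latent_params = list(
                            asd = c(mean = 1.5, sd = 1),
                            comorbid_only = c(mean = 0, sd = 1),
                            neurotypical = c(mean = -2.5, sd = 1)
                          ),
                          item_bank = default_item_bank(),
                          panel = panel_params(),
                          covariate_probs = default_covariate_probs(),
                          comorbidity_probs = default_comorbidity_probs(),
                          missing_prob = 0,
                          seed) {
  if (missing(seed)) stop("seed is mandatory in cohort_config")
  stopifnot(length(n_subjects) == 1, n_subjects >= 0,
            n_subjects == as.integer(n_subjects))
  if (!all(c("asd", "comorbid_only", "neurotypical") %in% names(class_probs))) {
    stop("class_probs must be named asd, comorbid_only, neurotypical")
  }
  class_probs <- class_probs[c("asd", "comorbid_only", "neurotypical")]
  if (any(class_probs < 0) || any(class_probs > 1)) {
    stop("class probabilities must lie in [0, 1]")
  }
  if (abs(sum(class_probs) - 1) > 1e-12) {
    stop("class_probs must sum to 1 (tolerance 1e-12)")
  }
  if (length(age_range_months) != 2 ||
      age_range_months[1] < 18 || age_range_months[2] > 72 ||
      age_range_months[1] > age_range_months[2]) {
    stop("age_range_months must be inclusive bounds within [18, 72]")
  }
  stopifnot(length(age_band_weights) == 5, all(age_band_weights >= 0),
            sum(age_band_weights) > 0)
  for (cl in c("asd", "comorbid_only", "neurotypical")) {
    p <- class_latent_params[[cl]]
    if (is.null(p) || length(p) != 2 || p[2] <= 0) {
      stop("class_latent_params$", cl, " must be c(mean, sd) with sd > 0")
    }
  }
  stopifnot(inherits(item_bank, "item_bank"), inherits(panel, "panel_params"))
  stopifnot(missing_prob >= 0, missing_prob <= 1)
  structure(list(
    n_subjects = as.integer(n_subjects),
    class_probs = class_probs,
    age_range_months = as.integer(age_range_months),
    age_band_weights = age_band_weights / sum(age_band_weights),
    class_latent_params = class_latent_params,
    item_bank = item_bank,
    panel = panel,
    covariate_probs = covariate_probs,
    comorbidity_probs = comorbidity_probs,
    missing_prob = missing_prob,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default covariate category probabilities
#'
#' Covariates are sampled independently of the clinical class (the matching
#' null for a study that found no performance differences by covariate).
#' Category frequencies emulate a large multi-site US primary-care referral
#' cohort.
#'
#' @return Named list of probability vectors plus `multi_race_prob`.
#' @export
default_covariate_probs <- function() {
  list(
    sex = c(female = 0.362, male = 0.638),
    race_ethnicity = c(
      non_hispanic_white = 0.560, black = 0.155, hispanic_or_latino = 0.140,
      asian = 0.055, american_indian = 0.005, hawaiian_or_pacific_islander = 0.005,
      other = 0.030, unknown = 0.050
    ),
    income_band = c(
      lt_25k = 0.087, i25_50k = 0.200, i50_75k = 0.195, i75_100k = 0.188,
      i100_150k = 0.146, ge_150k = 0.094, unknown = 0.090
    ),
    education_band = c(
      some_high_school = 0.031, high_school = 0.104, some_college = 0.226,
      associate = 0.125, bachelor = 0.320, graduate = 0.184, unknown = 0.010
    ),
    multi_race_prob = 0.134
  )
}

#' Default comorbidity label probabilities
#'
#' Marginal frequencies of specialist-diagnosed non-ASD neurodevelopmental and
#' behavioral conditions, scaled to the comorbid class. Comorbid-class
#' subjects draw each condition independently and are guaranteed at least one;
#' ASD subjects draw at half these rates and may have none.
#'
#' @return Named probability vector.
#' @export
default_comorbidity_probs <- function() {
  c(
    language_disorder = 0.60, global_developmental_delay = 0.33,
    adhd = 0.26, phonological_disorder = 0.17, anxiety_disorder = 0.09,
    odd = 0.04, stereotypic_movement_disorder = 0.03, mood_disorder = 0.02,
    separation_anxiety_disorder = 0.02, intellectual_disability = 0.015,
    learning_disorder = 0.015, selective_mutism = 0.01, tic_disorder = 0.005
  )
}

sample_category <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Generate a synthetic cohort
#'
#' Draws classes, ages, covariates, latent traits, DSM-5 severity levels
#' (ASD subjects only; tertile of z within the ASD class, independently
#' jittered), comorbidity sets, and 64 graded item responses per subject
#' (band-dependent). Fully reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A data frame with one row per subject: `id`, `age_months`,
#'   `age_band`, `sex`, `race_ethnicity` (semicolon-joined set),
#'   `income_band`, `education_band`, `true_class`, `z`, `sc_severity`,
#'   `rrb_severity` (NA unless ASD), `comorbidities` (semicolon-joined set,
#'   possibly empty), and response columns `q01..q64`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  qn <- sprintf("q%02d", 1:64)
  if (n == 0) {
    out <- data.frame(
      id = character(), age_months = integer(), age_band = character(),
      sex = character(), race_ethnicity = character(), income_band = character(),
      education_band = character(), true_class = character(), z = numeric(),
      sc_severity = integer(), rrb_severity = integer(),
      comorbidities = character(), stringsAsFactors = FALSE
    )
    out[qn] <- lapply(qn, function(q) integer())
    return(out)
  }
  with_substream(config$seed, "cohort", {
    classes <- sample_category(n, config$class_probs)
    age <- sample_ages(n, config)
    band <- ifelse(age < 48, "A", "B")
    lat <- config$class_latent_params
    mu <- vapply(classes, function(cl) lat[[cl]][["mean"]], 0)
    sd <- vapply(classes, function(cl) lat[[cl]][["sd"]], 0)
    z <- rnorm(n, mu, sd)

    cp <- config$covariate_probs
    sex <- sample_category(n, cp$sex)
    race <- sample_race(n, cp)
    income <- sample_category(n, cp$income_band)
    education <- sample_category(n, cp$education_band)

    sev <- assign_severities(classes, z)
    com <- assign_comorbidities(classes, config$comorbidity_probs)
    resp <- sample_responses(z, band, config$item_bank, config$missing_prob)

    out <- data.frame(
      id = sprintf("S%05d", seq_len(n)), age_months = as.integer(age),
      age_band = band, sex = sex, race_ethnicity = race, income_band = income,
      education_band = education, true_class = classes, z = z,
      sc_severity = sev$sc, rrb_severity = sev$rrb, comorbidities = com,
      stringsAsFactors = FALSE
    )
    out[qn] <- as.data.frame(resp)
    rownames(out) <- NULL
    out
  })
}

sample_ages <- function(n, config) {
  edges <- list(c(18, 23), c(24, 35), c(36, 47), c(48, 59), c(60, 72))
  lo <- config$age_range_months[1]; hi <- config$age_range_months[2]
  # clip bands to the configured range and renormalize weights
  keep <- vapply(edges, function(e) e[2] >= lo && e[1] <= hi, TRUE)
  edges <- lapply(edges[keep], function(e) c(max(e[1], lo), min(e[2], hi)))
  w <- config$age_band_weights[keep]
  b <- sample.int(length(edges), n, replace = TRUE, prob = w)
  los <- vapply(edges, `[`, 0, 1)
  widths <- vapply(edges, function(e) e[2] - e[1] + 1, 0)
  as.integer(los[b] + floor(runif(n) * widths[b]))
}

sample_race <- function(n, cp) {
  probs <- cp$race_ethnicity
  first <- sample_category(n, probs)
  out <- first
  known <- setdiff(names(probs), "unknown")
  extra <- which(runif(n) < cp$multi_race_prob & first != "unknown")
  if (length(extra) > 0) {
    second <- sample_category(length(extra), probs[known] / sum(probs[known]))
    for (round in 1:20) {
      clash <- second == first[extra]
      if (!any(clash)) break
      second[clash] <- sample_category(sum(clash),
                                       probs[known] / sum(probs[known]))
    }
    keep <- second != first[extra]
    i <- extra[keep]; s2 <- second[keep]
    out[i] <- ifelse(first[i] < s2, paste(first[i], s2, sep = ";"),
                     paste(s2, first[i], sep = ";"))
  }
  out
}

# DSM-5 support-need levels 1-3 from the within-class tertile of z, each
# domain independently jittered by +/-1 with probability 0.2 (clamped).
assign_severities <- function(classes, z) {
  n <- length(classes)
  sc <- rep(NA_integer_, n); rrb <- rep(NA_integer_, n)
  idx <- which(classes == "asd")
  if (length(idx) > 0) {
    zc <- z[idx]
    if (length(idx) >= 3) {
      cuts <- quantile(zc, c(1 / 3, 2 / 3), names = FALSE, type = 7)
      base <- 1L + (zc > cuts[1]) + (zc > cuts[2])
    } else {
      base <- rep(2L, length(idx))
    }
    jitter1 <- sample(c(-1L, 0L, 1L), length(idx), replace = TRUE,
                      prob = c(0.1, 0.8, 0.1))
    jitter2 <- sample(c(-1L, 0L, 1L), length(idx), replace = TRUE,
                      prob = c(0.1, 0.8, 0.1))
    sc[idx] <- pmin(3L, pmax(1L, base + jitter1))
    rrb[idx] <- pmin(3L, pmax(1L, base + jitter2))
  }
  list(sc = sc, rrb = rrb)
}

assign_comorbidities <- function(classes, probs) {
  n <- length(classes)
  out <- character(n)
  labs <- names(probs)
  nc <- length(probs)
  rate <- matrix(0, n, nc)
  rate[classes == "comorbid_only", ] <- rep(probs, each = sum(classes == "comorbid_only"))
  rate[classes == "asd", ] <- rep(probs / 2, each = sum(classes == "asd"))
  hits <- matrix(runif(n * nc), n, nc) < rate
  # guarantee at least one condition for the comorbid class
  empty <- which(classes == "comorbid_only" & rowSums(hits) == 0)
  if (length(empty) > 0) {
    forced <- sample.int(nc, length(empty), replace = TRUE, prob = probs)
    hits[cbind(empty, forced)] <- TRUE
  }
  any_hit <- which(rowSums(hits) > 0)
  out[any_hit] <- vapply(any_hit, function(i) {
    paste(labs[hits[i, ]], collapse = ";")
  }, "")
  out
}

sample_responses <- function(z, band, bank, missing_prob) {
  n <- length(z)
  resp <- matrix(NA_integer_, n, 64)
  for (b in c("A", "B")) {
    idx <- which(band == b)
    if (length(idx) == 0) next
    items <- bank$bands[[b]]
    th <- as.matrix(items[, grep("^b[0-9]+$", names(items)), drop = FALSE])
    for (j in seq_len(nrow(items))) {
      resp[idx, j] <- item_response(z[idx], items$a[j], th[j, ])
    }
  }
  if (missing_prob > 0) {
    resp[matrix(runif(n * 64) < missing_prob, n, 64)] <- NA_integer_
  }
  resp
}

#' Read or write a cohort table as CSV
#'
#' One row per subject; set-valued fields (race/ethnicity, comorbidities) are
#' semicolon-joined; responses occupy the 64 numbered columns `q01..q64`;
#' header row mandatory; UTF-8.
#'
#' @param cohort A cohort data frame (see [generate_cohort()]).
#' @param path File path.
#' @return `read_cohort_csv` returns the cohort data frame;
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
           colClasses = c(id = "character"))
}
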