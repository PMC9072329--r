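#' Specialist panel parameters
#'
#' Parameters of the consensus clinical reference standard: a diagnosing
#' specialist, a blinded reviewing specialist, and (only on disagreement) a
#' second reviewer; the majority of the individual binary ASD calls fixes the
#' reference diagnosis. Two simulation modes are supported:
#'
#' * `"agreement"` (default) draws reviewer behavior directly from the
#'   observed agreement marginals: the first reviewer agrees with the
#'   diagnosing specialist with probability `reviewer1_agreement` (default
#'   0.79) and, on disagreement, the tie-breaking specialist sides with the
#'   diagnosing specialist with probability `tiebreak_split` (default 0.43).
#' * `"error_model"` draws every specialist's call independently from the
#'   subject's true class with per-class error `specialist_error`, letting
#'   reference-label noise interact with truth (majority voting then reduces
#'   the error to roughly `eps^2 * (3 - 2*eps)`).
#'
#' @param mode `"agreement"` or `"error_model"`.
#' @param specialist_error Named per-true-class probabilities that an
#'   individual specialist's binary ASD call differs from truth. In agreement
#'   mode only the diagnosing specialist uses it.
#' @param reviewer1_agreement Probability the first reviewer agrees with the
#'   diagnosing specialist (agreement mode).
#' @param tiebreak_split Probability the tie-breaking specialist sides with
#'   the diagnosing specialist given disagreement (agreement mode).
#' @param certainty_probs Named list per final-diagnosis category
#'   (`asd_positive`, `other_condition`, `neurotypical`) of distributions over
#'   the 4-point certainty Likert scale (1 = completely uncertain,
#'   4 = completely certain). Defaults are calibrated so specialists are
#'   "somewhat" or "completely certain" 95% of the time for every category,
#'   and completely certain 67% / 74% / 95% of the time for ASD,
#'   other-condition and neurotypical conclusions respectively.
#' @return An object of class `panel_params`.
#' @export
panel_params <- function(mode = c("agreement", "error_model"),
                         specialist_error = c(asd = 0.05, comorbid_only = 0.05,
                                              neurotypical = 0.05),
                         reviewer1_agreement = 0.79,
                         tiebreak_split = 0.43,
                         certainty_probs = default_certainty_probs()) {
  mode <- match.arg(mode)
  stopifnot(all(c("asd", "comorbid_only", "neurotypical") %in%
                  names(specialist_error)))
  probs <- c(specialist_error, reviewer1_agreement, tiebreak_split)
  if (any(probs < 0) || any(probs > 1)) {
    stop("panel probabilities must lie in [0, 1]")
  }
  for (cat in names(certainty_probs)) {
    p <- certainty_probs[[cat]]
    if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("certainty_probs$", cat,
           " must be a length-4 distribution over Likert levels 1-4")
    }
  }
  structure(list(
    mode = mode, specialist_error = specialist_error,
    reviewer1_agreement = reviewer1_agreement, tiebreak_split = tiebreak_split,
    certainty_probs = certainty_probs
  ), class = "panel_params")
}

#' Default diagnostic-certainty distributions
#'
#' Per final-diagnosis category, distribution over Likert levels 1-4. Each
#' category places 95% mass on levels 3-4 ("somewhat" or "completely
#' certain"); the completely-certain share is 0.67 for ASD conclusions, 0.74
#' when ruling out ASD with another condition suspected, and 0.95 for
#' neurotypical conclusions.
#'
#' @return Named list of length-4 probability vectors.
#' @export
default_certainty_probs <- function() {
  list(
    asd_positive = c(0.01, 0.04, 0.28, 0.67),
    other_condition = c(0.01, 0.04, 0.21, 0.74),
    neurotypical = c(0.01, 0.04, 0.00, 0.95)
  )
}

ref_categories <- c("ASD_positive", "ASD_negative_other_condition",
                    "ASD_negative_neurotypical")

#' Adjudicate a cohort through the simulated specialist panel
#'
#' For each subject: the diagnosing specialist's binary ASD call is sampled
#' from the true class with per-class error; the first (blinded) reviewer
#' either agrees with a configured probability (agreement mode) or calls
#' independently (error-model mode); a tie-breaking specialist is consulted
#' only when the first two calls disagree, and the majority decision fixes the
#' reference ASD status. Non-ASD final diagnoses are split into
#' "other condition" versus "neurotypical" by the subject's record: subjects
#' with any comorbidity (and ASD-class subjects adjudicated negative who carry
#' comorbidities) are labeled `ASD_negative_other_condition`, otherwise
#' `ASD_negative_neurotypical`. A certainty Likert score is then drawn from
#' the final category's configured distribution.
#'
#' @param cohort Cohort data frame from [generate_cohort()] (needs columns
#'   `true_class` and `comorbidities`).
#' @param panel A [panel_params()].
#' @param seed Integer seed for the panel substream.
#' @return The cohort with appended columns `diagnosing_call`,
#'   `reviewer1_call`, `n_reviewers` (1 or 2), `ref_label` (one of
#'   `ASD_positive`, `ASD_negative_other_condition`,
#'   `ASD_negative_neurotypical`) and `certainty` (integer 1-4).
#' @export
adjudicate_cohort <- function(cohort, panel = panel_params(), seed) {
  stopifnot(inherits(panel, "panel_params"),
            all(c("true_class", "comorbidities") %in% names(cohort)))
  if (missing(seed)) stop("seed is mandatory in adjudicate_cohort")
  n <- nrow(cohort)
  with_substream(seed, "panel", {
    truth <- cohort$true_class == "asd"
    err <- panel$specialist_error[cohort$true_class]
    diagnosing <- xor(truth, runif(n) < err)
    if (panel$mode == "agreement") {
      agree1 <- runif(n) < panel$reviewer1_agreement
      reviewer1 <- ifelse(agree1, diagnosing, !diagnosing)
      side_diag <- runif(n) < panel$tiebreak_split
      final <- ifelse(agree1, diagnosing,
                      ifelse(side_diag, diagnosing, reviewer1))
    } else {
      reviewer1 <- xor(truth, runif(n) < err)
      agree1 <- diagnosing == reviewer1
      tiebreak <- xor(truth, runif(n) < err)
      final <- ifelse(agree1, diagnosing, tiebreak)
    }
    has_comorbidity <- !is.na(cohort$comorbidities) & cohort$comorbidities != ""
    ref <- ifelse(final, "ASD_positive",
                  ifelse(cohort$true_class == "comorbid_only" | has_comorbidity,
                         "ASD_negative_other_condition",
                         "ASD_negative_neurotypical"))
    cat_of <- c(ASD_positive = "asd_positive",
                ASD_negative_other_condition = "other_condition",
                ASD_negative_neurotypical = "neurotypical")
    certainty <- certainty_score(cat_of[ref], panel)
    out <- cohort
    out$diagnosing_call <- diagnosing
    out$reviewer1_call <- reviewer1
    out$n_reviewers <- ifelse(agree1, 1L, 2L)
    out$ref_label <- ref
    out$certainty <- certainty
    out
  })
}

#' Sample diagnostic-certainty Likert scores
#'
#' @param final_category Character vector of final-diagnosis categories
#'   (`asd_positive`, `other_condition`, `neurotypical`).
#' @param panel A [panel_params()] supplying `certainty_probs`.
#' @return Integer vector of Likert levels 1-4. Draws from the current RNG
#'   state.
#' @export
certainty_score <- function(final_category, panel = panel_params()) {
  probs <- panel$certainty_probs
  missing_cat <- setdiff(unique(final_category), names(probs))
  if (length(missing_cat) > 0) {
    stop("no certainty distribution configured for category: ",
         paste(missing_cat, collapse = ", "))
  }
  cum <- t(vapply(probs, cumsum, numeric(4)))  # category x level
  rows <- match(final_category, rownames(cum))
  u <- runif(length(final_category))
  lev <- 1L + (u > cum[rows, 1]) + (u > cum[rows, 2]) + (u > cum[rows, 3])
  as.integer(lev)
}
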