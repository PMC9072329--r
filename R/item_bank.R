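#' Age-band assignment for the multimodal questionnaire
#'
#' The simulated diagnostic aid administers one of two age-dependent
#' questionnaire versions. Children aged 18-47 months receive band "A"
#' (caregiver 18, video-analyst 33, clinician 13 items); children aged
#' 48-72 months receive band "B" (21, 28, 15). Both bands total 64 items.
#'
#' @param age_months Age in whole months; must lie in \[18, 72\].
#' @return A list with elements `band` ("A" or "B"), `counts` (named integer
#'   vector over the three input channels) and `total` (always 64).
#' @examples
#' assign_age_band(36)$counts
#' assign_age_band(48)$band
#' @export
assign_age_band <- function(age_months) {
  if (length(age_months) != 1 || is.na(age_months) || !is.numeric(age_months)) {
    stop("age_months must be a single number")
  }
  if (age_months < 18 || age_months > 72) {
    stop("age_months must be in the supported range [18, 72] months, got ",
         age_months)
  }
  if (age_months < 48) {
    counts <- c(caregiver = 18L, video_analyst = 33L, hcp = 13L)
    band <- "A"
  } else {
    counts <- c(caregiver = 21L, video_analyst = 28L, hcp = 15L)
    band <- "B"
  }
  list(band = band, counts = counts, total = sum(counts))
}

band_channel_counts <- function(band) {
  switch(band,
    A = c(caregiver = 18L, video_analyst = 33L, hcp = 13L),
    B = c(caregiver = 21L, video_analyst = 28L, hcp = 15L),
    stop("unknown age band: ", band)
  )
}

#' Construct an item bank for the two questionnaire bands
#'
#' Items follow a graded (ordinal logistic) response model with `K` ordered
#' levels: item j has discrimination `a_j > 0` and strictly increasing
#' thresholds `b_j1 < ... < b_j,K-1`, and
#' `P(level >= k) = plogis(a_j * (z - b_jk))` for a subject with latent
#' trait `z`.
#'
#' @param bands A named list with elements `A` and `B`, each a data frame with
#'   columns `channel`, `a`, and threshold columns `b1..b{K-1}`. Row counts
#'   must match the band's channel totals (64 items per band).
#' @return An object of class `item_bank`.
#' @seealso [default_item_bank()]
#' @export
item_bank <- function(bands) {
  stopifnot(is.list(bands), all(c("A", "B") %in% names(bands)))
  for (b in c("A", "B")) {
    items <- bands[[b]]
    counts <- band_channel_counts(b)
    if (!is.data.frame(items) || nrow(items) != sum(counts)) {
      stop("band ", b, " must have ", sum(counts), " items")
    }
    got <- table(factor(items$channel, levels = names(counts)))
    if (!all(got == counts)) {
      stop("band ", b, " channel item counts must be (",
           paste(counts, collapse = ", "), ")")
    }
    th <- as.matrix(items[, grep("^b[0-9]+$", names(items)), drop = FALSE])
    if (ncol(th) < 1) stop("band ", b, ": items need at least one threshold")
    if (any(items$a <= 0)) stop("band ", b, ": discriminations must be > 0")
    inc <- apply(th, 1, function(r) all(diff(r) > 0))
    if (!all(inc)) {
      stop("band ", b, ": item thresholds must be strictly increasing (item ",
           which(!inc)[1], ")")
    }
  }
  structure(list(bands = bands, K = ncol(as.matrix(
    bands$A[, grep("^b[0-9]+$", names(bands$A)), drop = FALSE])) + 1L),
    class = "item_bank")
}

#' Default item bank
#'
#' Deterministic parameters: discriminations ramp over \[0.8, 2\] within each
#' band and item locations sweep \[-1, 1\], so items differ in difficulty and
#' informativeness but every item loads on the single latent trait. The
#' questionnaire's real item content is proprietary; items here are
#' exchangeable within channel.
#'
#' @param K Number of ordered response levels per item (default 5,
#'   Likert-style).
#' @return An `item_bank` object.
#' @export
default_item_bank <- function(K = 5) {
  stopifnot(K >= 2)
  mk_band <- function(band) {
    counts <- band_channel_counts(band)
    n <- sum(counts)
    a <- seq(0.8, 2.0, length.out = n)
    shift <- seq(-1, 1, length.out = n)
    base <- seq(-1.5, 1.5, length.out = K - 1)
    th <- outer(shift, rep(1, K - 1)) + outer(rep(1, n), base)
    items <- data.frame(channel = rep(names(counts), counts), a = a)
    colnames(th) <- paste0("b", seq_len(K - 1))
    cbind(items, as.data.frame(th))
  }
  item_bank(list(A = mk_band("A"), B = mk_band("B")))
}

#' Graded-model category probabilities
#'
#' Closed-form probabilities of each ordinal level `0..K-1` for latent trait
#' `z` under the graded response model
#' `P(level >= k) = plogis(a * (z - b_k))`.
#'
#' @param z Latent trait value(s).
#' @param a Item discrimination (> 0).
#' @param thresholds Strictly increasing numeric vector of length K-1.
#' @return A matrix with `length(z)` rows and K columns of level
#'   probabilities.
#' @export
graded_category_probs <- function(z, a, thresholds) {
  if (any(diff(thresholds) <= 0)) {
    stop("item thresholds must be strictly increasing")
  }
  if (a <= 0) stop("item discrimination must be > 0")
  surv <- cbind(1, plogis(a * outer(z, thresholds, "-")), 0)
  p <- surv[, -ncol(surv), drop = FALSE] - surv[, -1, drop = FALSE]
  colnames(p) <- paste0("level", seq_len(ncol(p)) - 1)
  p
}

#' Sample graded item responses
#'
#' @inheritParams graded_category_probs
#' @return Integer vector of levels in `0..K-1`, one per element of `z`.
#'   Sampling consumes `length(z)` uniform draws from the current RNG state.
#' @export
item_response <- function(z, a, thresholds) {
  if (any(diff(thresholds) <= 0)) {
    stop("item thresholds must be strictly increasing")
  }
  if (a <= 0) stop("item discrimination must be > 0")
  # inverse-CDF via the survival curves: level >= k iff u < P(level >= k)
  surv <- plogis(a * outer(z, thresholds, "-"))
  u <- runif(length(z))
  as.integer(rowSums(u < surv))
}
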