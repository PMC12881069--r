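#' INFLA-score: a decile composite of low-grade systemic inflammation
#'
#' Four established markers of systemic inflammation — C-reactive protein
#' (CRP, mg/L), white blood cell count (10^9/L), platelet count (10^9/L) and
#' the neutrophil-to-lymphocyte ratio — are each scored by decile of a
#' reference distribution: deciles 1-4 score -4..-1, deciles 5-6 score 0,
#' deciles 7-10 score +1..+4. The INFLA-score is the sum of the four marker
#' scores and ranges from -16 to +16; higher values reflect more systemic
#' inflammation.
#'
#' @name infla
NULL

#' Neutrophil-to-lymphocyte ratio
#'
#' @param neutrophils,lymphocytes Concentrations in 10^9/L. Lymphocytes must
#'   be strictly positive; non-positive values yield `NA` (the participant's
#'   INFLA-score becomes missing) unless every value is non-positive, which is
#'   an error.
#' @return Numeric vector of ratios.
#' @export
compute_nlr <- function(neutrophils, lymphocytes) {
  assert_that(length(neutrophils) == length(lymphocytes),
              "neutrophils and lymphocytes must have equal length")
  bad <- !is.na(lymphocytes) & lymphocytes <= 0
  if (all(bad) && length(bad) > 0) {
    rlang::abort("all lymphocyte counts are <= 0; ratio undefined")
  }
  out <- neutrophils / lymphocytes
  out[bad] <- NA_real_
  if (any(bad)) {
    rlang::warn(sprintf("%d participant(s) with lymphocytes <= 0; ratio set to NA",
                        sum(bad)))
  }
  out
}

#' Decile cut points of a reference distribution
#'
#' The 10th..90th percentiles (R's default type-7 quantile definition),
#' monotone non-decreasing by construction.
#'
#' @param values Numeric vector with at least 10 non-missing values.
#' @return Numeric vector of 9 cut points.
#' @export
decile_cutpoints <- function(values) {
  values <- values[!is.na(values)]
  assert_that(length(values) >= 10,
              "at least 10 non-missing values needed for decile cut points (got %d)",
              length(values))
  unname(stats::quantile(values, probs = 1:9 / 10, type = 7))
}

#' Decile rank and integer score of a marker value
#'
#' The decile rank of value v is the smallest k with v <= cutpoint_k, else
#' 10; ties at a cut point fall into the lower decile. Scores: rank 1-4 ->
#' -4..-1, rank 5-6 -> 0, rank 7-10 -> +1..+4.
#'
#' @param value Numeric vector of marker values (`NA`/non-finite -> `NA` score).
#' @param cutpoints 9 monotone non-decreasing cut points.
#' @return Integer score vector with attribute `"decile"` (the ranks).
#' @export
score_marker <- function(value, cutpoints) {
  assert_that(length(cutpoints) == 9, "cutpoints must have length 9")
  assert_that(!is.unsorted(cutpoints), "cutpoints must be non-decreasing")
  k <- rep(NA_integer_, length(value))
  ok <- is.finite(value)
  # rank = 1 + number of cut points strictly below the value
  k[ok] <- 1L + as.integer(rowSums(outer(value[ok], cutpoints, ">")))
  score <- ifelse(k <= 4, k - 5L, ifelse(k >= 7, k - 6L, 0L))
  score <- as.integer(score)
  attr(score, "decile") <- k
  score
}

#' Decile cut points for the four INFLA markers
#'
#' Computed from the analysis sample by default; pass the result to
#' [compute_infla()] to score a different subset against the same reference.
#'
#' @param blood Data frame with columns `participant_id`, `crp`, `wbc`,
#'   `platelets`, `neutrophils`, `lymphocytes`.
#' @return Named list of 9-point cut vectors: `crp`, `wbc`, `platelets`, `nlr`.
#' @export
infla_cutpoints <- function(blood) {
  check_columns(blood, c("crp", "wbc", "platelets", "neutrophils", "lymphocytes"),
                "blood markers")
  nlr <- compute_nlr(blood$neutrophils, blood$lymphocytes)
  list(crp = decile_cutpoints(blood$crp),
       wbc = decile_cutpoints(blood$wbc),
       platelets = decile_cutpoints(blood$platelets),
       nlr = decile_cutpoints(nlr))
}

#' Compute the INFLA-score
#'
#' @param blood Data frame with columns `participant_id`, `crp`, `wbc`,
#'   `platelets`, `neutrophils`, `lymphocytes`.
#' @param cutpoints Optional reference cut points from [infla_cutpoints()];
#'   defaults to sample-internal deciles of `blood` itself.
#' @return Tibble with per-marker scores (`score_crp`, `score_wbc`,
#'   `score_platelets`, `score_nlr`) and the `infla` total; `infla` is `NA`
#'   when any component is missing (count reported via message).
#' @export
compute_infla <- function(blood, cutpoints = NULL) {
  check_columns(blood, c("participant_id", "crp", "wbc", "platelets",
                         "neutrophils", "lymphocytes"), "blood markers")
  if (is.null(cutpoints)) cutpoints <- infla_cutpoints(blood)
  assert_that(all(c("crp", "wbc", "platelets", "nlr") %in% names(cutpoints)),
              "cutpoints must contain crp, wbc, platelets and nlr")
  nlr <- compute_nlr(blood$neutrophils, blood$lymphocytes)
  strip <- function(s) { attributes(s) <- NULL; s }
  out <- tibble::tibble(
    participant_id = blood$participant_id,
    nlr = nlr,
    score_crp = strip(score_marker(blood$crp, cutpoints$crp)),
    score_wbc = strip(score_marker(blood$wbc, cutpoints$wbc)),
    score_platelets = strip(score_marker(blood$platelets, cutpoints$platelets)),
    score_nlr = strip(score_marker(nlr, cutpoints$nlr))
  )
  out$infla <- out$score_crp + out$score_wbc + out$score_platelets + out$score_nlr
  n_missing <- sum(is.na(out$infla))
  if (n_missing > 0) {
    rlang::inform(sprintf("INFLA-score missing for %d participant(s)", n_missing))
  }
  attr(out, "cutpoints") <- cutpoints
  out
}
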