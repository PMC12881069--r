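#' Dietary Inflammatory Index (DII) scoring
#'
#' The DII summarizes the inflammatory potential of a diet. Each dietary
#' parameter (a nutrient, bioactive compound or food) carries a literature-
#' derived inflammatory effect weight (negative = anti-inflammatory, positive
#' = pro-inflammatory) together with a global reference mean and standard
#' deviation of daily intake. A participant's intake is standardized against
#' the global reference, mapped to a centered percentile in (-1, 1) through
#' the standard-normal CDF, multiplied by the weight, and summed over
#' parameters. A diet at the global mean of every parameter scores exactly 0;
#' the score is bounded by the sum of absolute weights.
#'
#' @name dii
NULL

#' Validate a DII reference table
#'
#' @param reference A data frame with columns `parameter` (unique names),
#'   `weight` (signed inflammatory effect score), `global_mean` (> 0) and
#'   `global_sd` (> 0).
#' @return The reference, invisibly, as a tibble.
#' @export
validate_reference <- function(reference) {
  check_columns(reference, c("parameter", "weight", "global_mean", "global_sd"),
                "DII reference")
  assert_that(nrow(reference) >= 1, "DII reference must have at least one row")
  assert_that(!anyDuplicated(reference$parameter),
              "DII reference parameter names must be unique")
  assert_that(all(is.finite(reference$weight)),
              "DII reference weights must be finite")
  if (any(!is.finite(reference$global_sd) | reference$global_sd <= 0)) {
    bad <- reference$parameter[!is.finite(reference$global_sd) |
                                 reference$global_sd <= 0]
    rlang::abort(sprintf("global_sd must be > 0; offending parameter(s): %s",
                         paste(bad, collapse = ", ")))
  }
  assert_that(all(reference$global_mean > 0),
              "global_mean must be > 0 for every parameter")
  invisible(tibble::as_tibble(reference))
}

#' Energy-plausibility filter for dietary assessments
#'
#' Keeps an assessment when its reported energy intake is plausible for the
#' participant's sex: within \[600, 3500\] kcal/day for females and
#' \[800, 4200\] kcal/day for males (bounds inclusive; the exclusion rule is
#' strictly below/above the bounds). A participant is excluded only when none
#' of their assessments is plausible.
#'
#' @param assessments Data frame of dietary assessments with columns
#'   `participant_id`, `energy_kcal` and (typically) one column per dietary
#'   parameter.
#' @param sex Data frame with columns `participant_id` and `sex`
#'   (`"female"`/`"male"`).
#' @return A list with `kept` (the plausible assessments) and `report`
#'   (per-participant tibble: `n_total`, `n_kept`, `excluded`).
#' @export
filter_plausible_assessments <- function(assessments, sex) {
  check_columns(assessments, c("participant_id", "energy_kcal"), "assessments")
  check_columns(sex, c("participant_id", "sex"), "sex table")
  ids <- unique(assessments$participant_id)
  missing_sex <- setdiff(ids, sex$participant_id)
  if (length(missing_sex) > 0) {
    rlang::abort(sprintf("sex unavailable for participant(s): %s",
                         paste(head(missing_sex, 5), collapse = ", ")))
  }
  bad_code <- !sex$sex %in% c("female", "male")
  if (any(bad_code)) {
    rlang::abort(sprintf("unknown sex code for participant(s): %s",
                         paste(head(sex$participant_id[bad_code], 5),
                               collapse = ", ")))
  }

  joined <- dplyr::left_join(assessments,
                             dplyr::distinct(sex, .data$participant_id, .data$sex),
                             by = "participant_id")
  lo <- ifelse(joined$sex == "female", 600, 800)
  hi <- ifelse(joined$sex == "female", 3500, 4200)
  plausible <- !is.na(joined$energy_kcal) &
    joined$energy_kcal >= lo & joined$energy_kcal <= hi

  kept <- assessments[plausible, , drop = FALSE]
  report <- tibble::tibble(participant_id = joined$participant_id,
                           plausible = plausible) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_total = dplyr::n(),
                     n_kept = sum(.data$plausible),
                     .groups = "drop") |>
    dplyr::mutate(excluded = .data$n_kept == 0)
  list(kept = tibble::as_tibble(kept), report = report)
}

#' Average nutrient intakes over a participant's kept assessments
#'
#' Arithmetic mean of every numeric intake column (including energy) over all
#' plausible assessments, one row per participant. Dietary habits reported
#' more than once are better captured by the average than by any single
#' 24-hour recall.
#'
#' @param kept Plausible assessments, e.g. `filter_plausible_assessments()$kept`.
#' @return Tibble with one row per participant, mean intakes, and
#'   `n_assessments_used`.
#' @export
average_intakes <- function(kept) {
  check_columns(kept, "participant_id", "kept assessments")
  assert_that(nrow(kept) >= 1,
              "no kept assessments; zero-assessment participants must be excluded upstream")
  num_cols <- setdiff(names(kept)[vapply(kept, is.numeric, logical(1))],
                      "participant_id")
  g <- as.character(kept$participant_id)
  x <- as.matrix(kept[, num_cols, drop = FALSE])
  sums <- rowsum(x, g)                      # NA propagates, as it must
  counts <- as.vector(rowsum(rep(1, nrow(x)), g))
  means <- sums / counts
  dplyr::bind_cols(
    tibble::tibble(participant_id = rownames(sums)),
    tibble::as_tibble(means),
    tibble::tibble(n_assessments_used = as.integer(counts))
  )
}

#' Compute the Dietary Inflammatory Index
#'
#' For each reference parameter i with intake x, global mean mu and SD sigma:
#' z = (x - mu)/sigma, centered percentile c = 2 * pnorm(z) - 1, contribution
#' c * w. The DII is the sum of contributions. Parameters absent from the
#' intake table are an error unless `allow_missing = TRUE`, in which case the
#' available subset is scored (no re-weighting) and the absent parameters are
#' listed in a warning.
#'
#' @param intakes Per-participant mean intakes (one row per participant), as
#'   from [average_intakes()]; columns named after reference parameters.
#' @param reference DII reference table, see [validate_reference()].
#' @param allow_missing Score on the subset of available parameters.
#' @param contributions If `TRUE`, attach a long per-parameter contribution
#'   table as attribute `"contributions"`.
#' @return Tibble with `participant_id`, `dii`, `dii_group` and, when present
#'   in `intakes`, `n_assessments_used`.
#' @export
compute_dii <- function(intakes, reference, allow_missing = FALSE,
                        contributions = FALSE) {
  reference <- validate_reference(reference)
  check_columns(intakes, "participant_id", "intake table")
  absent <- setdiff(reference$parameter, names(intakes))
  if (length(absent) > 0) {
    if (!allow_missing) {
      rlang::abort(sprintf(
        "intake table lacks reference parameter(s): %s (set allow_missing = TRUE to score the available subset)",
        paste(absent, collapse = ", ")))
    }
    rlang::warn(sprintf("scoring %d of %d reference parameters; absent: %s",
                        nrow(reference) - length(absent), nrow(reference),
                        paste(absent, collapse = ", ")))
    reference <- reference[!reference$parameter %in% absent, , drop = FALSE]
  }

  x <- as.matrix(intakes[, reference$parameter, drop = FALSE])
  z <- sweep(sweep(x, 2, reference$global_mean, "-"), 2, reference$global_sd, "/")
  cp <- 2 * stats::pnorm(z) - 1
  contrib <- sweep(cp, 2, reference$weight, "*")
  dii <- rowSums(contrib)

  out <- tibble::tibble(participant_id = intakes$participant_id,
                        dii = dii,
                        dii_group = assign_dii_group(dii))
  if ("n_assessments_used" %in% names(intakes)) {
    out$n_assessments_used <- intakes$n_assessments_used
  }
  if (contributions) {
    long <- tibble::tibble(
      participant_id = rep(intakes$participant_id, times = nrow(reference)),
      parameter = rep(reference$parameter, each = nrow(intakes)),
      z = as.vector(z),
      centered_percentile = as.vector(cp),
      contribution = as.vector(contrib)
    )
    attr(out, "contributions") <- long
  }
  out
}

#' Assign DII groups
#'
#' Group 1: DII < -2; group 2: -2 <= DII < 0; group 3: 0 <= DII < 2;
#' group 4: DII >= 2. The four groups partition the real line.
#'
#' @param dii Numeric vector of finite DII scores (NA passes through).
#' @return Integer vector of group labels 1-4.
#' @export
assign_dii_group <- function(dii) {
  if (any(!is.na(dii) & !is.finite(dii))) {
    rlang::abort("DII must be finite to be assigned a group")
  }
  g <- rep(NA_integer_, length(dii))
  ok <- !is.na(dii)
  g[ok] <- findInterval(dii[ok], c(-2, 0, 2)) + 1L
  g
}

#' DII stability diagnostics
#'
#' Pearson correlation and Bland-Altman agreement between two paired sets of
#' DII scores (e.g. scores from the earliest assessment versus scores averaged
#' over later assessments). Limits of agreement are mean difference
#' +/- 1.96 * SD of the differences.
#'
#' @param first,later Paired numeric vectors (>= 3 pairs).
#' @return One-row tibble: `n_pairs`, `pearson_r`, `mean_diff`, `sd_diff`,
#'   `loa_lower`, `loa_upper`. `pearson_r` is `NA` (with a message) when
#'   either vector has zero variance.
#' @export
dii_stability <- function(first, later) {
  assert_that(length(first) == length(later), "inputs must be paired")
  keep <- stats::complete.cases(first, later)
  first <- first[keep]; later <- later[keep]
  assert_that(length(first) >= 3, "at least 3 complete pairs required")
  r <- if (stats::sd(first) == 0 || stats::sd(later) == 0) {
    rlang::inform("zero variance in one input; Pearson r undefined")
    NA_real_
  } else {
    stats::cor(first, later)
  }
  d <- first - later
  tibble::tibble(n_pairs = length(d),
                 pearson_r = r,
                 mean_diff = mean(d),
                 sd_diff = stats::sd(d),
                 loa_lower = mean(d) - 1.96 * stats::sd(d),
                 loa_upper = mean(d) + 1.96 * stats::sd(d))
}
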