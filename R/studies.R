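#' Parameter-recovery simulation studies
#'
#' Drivers that repeat the full generate-score-model-estimate pipeline over a
#' set of seeds and collect the estimates of interest, for calibration checks
#' of the synthetic generator and the estimators: does the pipeline recover
#' the effect it was told to plant? Each run builds a fresh cohort, estimates
#' brain age from the IDPs (LASSO grid), merges, and fits the adjusted
#' models. Summaries report the mean estimate and its empirical standard
#' error over seeds.
#'
#' @name recovery-studies
NULL

# One pipeline run returning the merged analysis table.
run_for_seed <- function(seed, n, ref, ...) {
  cfg <- sim_config(n_participants = n, seed = seed, ...)
  run_pipeline(cfg, ref, associations = character(0))
}

#' Continuous-effect recovery study
#'
#' @param seeds Integer vector of generator seeds (one cohort each).
#' @param n Participants per cohort.
#' @param beta_dii_bag True total effect planted, years per DII unit.
#' @param ref DII reference table (default a fixed 31-parameter reference).
#' @param ... Further [sim_config()] overrides.
#' @return Tibble (one row per seed): multivariable-adjusted continuous DII
#'   coefficient with SE, CI, and whether the CI covers the truth.
#' @export
recover_continuous_effect <- function(seeds, n = 20000, beta_dii_bag = 0.07,
                                      ref = generate_reference(31, 101),
                                      ...) {
  purrr::map_dfr(seeds, function(s) {
    run <- run_for_seed(s, n, ref, beta_dii_bag = beta_dii_bag, ...)
    fit <- dii_bag_association(run$analysis, "continuous", "multivariable")
    res <- tidy(fit)
    tibble::tibble(seed = s, estimate = res$estimate, std.error = res$std.error,
                   conf.low = res$conf.low, conf.high = res$conf.high,
                   covers_truth = res$conf.low <= beta_dii_bag &
                     beta_dii_bag <= res$conf.high)
  })
}

#' Group-contrast recovery study
#'
#' Plants pure group-shift effects (no linear DII path) and recovers the
#' group 2-4 versus group 1 contrasts from the multivariable model; also
#' records the pooled DII-group x age-group interaction p-value, which is a
#' null-calibration readout when the planted shifts do not differ by age.
#'
#' @inheritParams recover_continuous_effect
#' @param group_effects Named `c(g2=, g3=, g4=)` true BAG shifts, years.
#' @return Tibble, one row per seed x contrast.
#' @export
recover_group_effects <- function(seeds, n = 20000,
                                  group_effects = c(g2 = 0.13, g3 = 0.26,
                                                    g4 = 0.50),
                                  ref = generate_reference(31, 101), ...) {
  purrr::map_dfr(seeds, function(s) {
    run <- run_for_seed(s, n, ref, beta_dii_bag = 0, prop_mediated_true = 0,
                        group_effects = group_effects, ...)
    fit <- dii_bag_association(run$analysis, "groups", "multivariable")
    res <- tidy(fit)
    st <- stratified_and_interaction(run$analysis, "age_group",
                                     form = "groups",
                                     adjustment = "multivariable")
    truth <- unname(group_effects[c("g2", "g3", "g4")])
    tibble::tibble(seed = s, term = res$term, truth = truth,
                   estimate = res$estimate, std.error = res$std.error,
                   conf.low = res$conf.low, conf.high = res$conf.high,
                   covers_truth = res$conf.low <= truth & truth <= res$conf.high,
                   interaction_p = st$interaction$p.value)
  })
}

#' Age-stratified recovery study
#'
#' Plants age-heterogeneous group shifts (middle-aged versus older strata)
#' and recovers the per-stratum multivariable group contrasts.
#'
#' @inheritParams recover_continuous_effect
#' @param group_effects_middle,group_effects_older True shifts per stratum.
#' @return Tibble, one row per seed x stratum x contrast, with the planted
#'   truth alongside.
#' @export
recover_stratified_effects <- function(seeds, n = 20000,
                                       group_effects_middle =
                                         c(g2 = 0.10, g3 = 0.22, g4 = 0.49),
                                       group_effects_older =
                                         c(g2 = 0.20, g3 = 0.54, g4 = 0.87),
                                       ref = generate_reference(31, 101),
                                       ...) {
  purrr::map_dfr(seeds, function(s) {
    run <- run_for_seed(s, n, ref, beta_dii_bag = 0, prop_mediated_true = 0,
                        group_effects = group_effects_middle,
                        group_effects_older = group_effects_older, ...)
    st <- stratified_and_interaction(run$analysis, "age_group",
                                     form = "groups",
                                     adjustment = "multivariable")
    out <- st$strata[, c("stratum", "term", "estimate", "std.error")]
    truth_map <- list(middle = group_effects_middle,
                      older = group_effects_older)
    out$truth <- purrr::map2_dbl(out$stratum, out$term, function(str, term) {
      truth_map[[str]][[sub("dii_group", "", term)]]
    })
    out$seed <- s
    out$interaction_p <- st$interaction$p.value
    out
  })
}

#' Mediation recovery study
#'
#' Generates baseline-assessment cohorts with a known mediated fraction, runs
#' the full pipeline plus the bootstrap mediation estimator, and collects the
#' effect decomposition per seed.
#'
#' @inheritParams recover_continuous_effect
#' @param prop_mediated_true Planted mediated fraction.
#' @param n_boot Bootstrap replicates per seed.
#' @return Tibble, one row per seed: `acme`, `ade`, `total`, `prop_mediated`
#'   (the per-seed ratio), plus CI bounds for the ACME.
#' @export
recover_mediation <- function(seeds, n = 4439, beta_dii_bag = 0.07,
                              prop_mediated_true = 0.08, n_boot = 1000,
                              ref = generate_reference(31, 101), ...) {
  purrr::map_dfr(seeds, function(s) {
    # the per-cohort weak-identification note is moot here: the study-level
    # summary aggregates over seeds, which is exactly its remedy
    run <- withCallingHandlers(
      run_for_seed(s, n, ref, beta_dii_bag = beta_dii_bag,
                   prop_mediated_true = prop_mediated_true,
                   assessment_scheme = "baseline_only", ...),
      inflammage_weak_mediation = function(w) rlang::cnd_muffle(w))
    med <- bootstrap_mediation(run$analysis, adjustment = "multivariable",
                               n_boot = n_boot, seed = child_seed(s, 17L))
    est <- med$estimates
    tibble::tibble(seed = s,
                   acme = est$estimate[est$effect == "acme"],
                   acme_low = est$conf.low[est$effect == "acme"],
                   acme_high = est$conf.high[est$effect == "acme"],
                   ade = est$estimate[est$effect == "ade"],
                   total = est$estimate[est$effect == "total"],
                   prop_mediated = est$estimate[est$effect == "prop_mediated"],
                   n = med$n)
  })
}

#' Summarize a mediation recovery study
#'
#' The proportion mediated is a ratio whose per-seed estimate is heavy-tailed
#' whenever a cohort's total effect lands near zero, so the study-level
#' summary estimates the proportion as the ratio of the mean ACME to the mean
#' total effect across seeds (a ratio of means, not a mean of ratios), beside
#' plain means of the effect components.
#'
#' @param study Output of [recover_mediation()].
#' @return One-row tibble: mean ACME/ADE/total, `prop_mediated` (ratio of
#'   means), and the mean of per-seed ratios for comparison.
#' @export
summarize_mediation_study <- function(study) {
  tibble::tibble(
    n_seeds = nrow(study),
    mean_acme = mean(study$acme),
    mean_ade = mean(study$ade),
    mean_total = mean(study$total),
    prop_mediated = mean(study$acme) / mean(study$total),
    mean_seed_ratio = mean(study$prop_mediated)
  )
}
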