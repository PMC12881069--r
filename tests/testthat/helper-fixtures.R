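# Small in-code fixtures shared across test files.

tiny_reference <- function() {
  tibble::tibble(
    parameter = c("alpha", "beta", "gamma"),
    weight = c(0.5, -0.3, 0.2),
    global_mean = c(10, 20, 30),
    global_sd = c(2, 4, 6)
  )
}

# Diet table at given z-scores for the tiny reference.
tiny_intakes <- function(z = c(0, 0, 0), id = "A") {
  ref <- tiny_reference()
  tibble::tibble(participant_id = id,
                 alpha = ref$global_mean[1] + z[1] * ref$global_sd[1],
                 beta = ref$global_mean[2] + z[2] * ref$global_sd[2],
                 gamma = ref$global_mean[3] + z[3] * ref$global_sd[3])
}

# Blood marker table whose rows sit in known deciles: marker values are
# 1..n so decile membership is transparent.
graded_blood <- function(n = 100) {
  tibble::tibble(participant_id = sprintf("B%03d", 1:n),
                 crp = as.numeric(1:n),
                 wbc = as.numeric(1:n),
                 platelets = as.numeric(1:n),
                 neutrophils = as.numeric(1:n),
                 lymphocytes = rep(1, n))
}

small_cohort <- function(n = 400, seed = 42, ...) {
  ref <- generate_reference(11, 5)
  cfg <- sim_config(n, seed = seed, n_idps = 24, prop_mediated_true = 0, ...)
  list(ref = ref, cfg = cfg, cohort = generate_cohort(cfg, ref))
}

# Analysis table that bypasses the imaging stage by using the true BAG as
# outcome: fast route for association/mediation tests that do not exercise
# the brain-age estimator.
build_true_bag_analysis <- function(cohort, ref) {
  filt <- filter_plausible_assessments(
    cohort$diet, cohort$covariates[, c("participant_id", "sex")])
  mean_int <- average_intakes(filt$kept)
  dii_tbl <- compute_dii(mean_int, ref)
  infla_tbl <- suppressMessages(compute_infla(cohort$blood))
  derive_covariates(cohort$covariates) |>
    dplyr::inner_join(dii_tbl, by = "participant_id") |>
    dplyr::left_join(mean_int[, c("participant_id", "energy_kcal")],
                     by = "participant_id") |>
    dplyr::left_join(infla_tbl[, c("participant_id", "infla")],
                     by = "participant_id") |>
    dplyr::left_join(cohort$truth[, c("participant_id", "true_bag")],
                     by = "participant_id") |>
    dplyr::mutate(bag = true_bag)
}

# Independent type-7 quantile oracle: h = (n-1)p + 1, linear interpolation
# between order statistics.
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
}
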