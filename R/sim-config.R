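#' Simulation configuration
#'
#' Defines the conditions of a synthetic cohort: its size, the true total
#' effect of diet-driven inflammation on the brain age gap (BAG), the fraction
#' of that effect carried through systemic inflammation, the imaging schema,
#' and nuisance scales. Two runs with an identical configuration (including
#' seed) produce identical tables.
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer seed fixing every draw.
#' @param n_idps Number of imaging-derived phenotypes (default 200; the
#'   full-scale schema has 1,079).
#' @param idp_modality_counts Named integer vector mapping modality to column
#'   count; must sum to `n_idps`. Defaults to [idp_modality_schema()]
#'   proportionally scaled to `n_idps`.
#' @param beta_dii_bag True total (direct + inflammation-mediated) linear
#'   effect on BAG, in years per DII unit.
#' @param group_effects Optional named numeric `c(g2=, g3=, g4=)` of direct
#'   BAG shifts for DII groups 2-4 versus group 1, in years. When supplied
#'   the linear DII path still applies; set `beta_dii_bag = 0` for a purely
#'   group-structured effect.
#' @param group_effects_older Optional override of `group_effects` applied to
#'   the older (>= 60 y) stratum, enabling age-heterogeneous effects.
#' @param prop_mediated_true Fraction of `beta_dii_bag` carried through the
#'   INFLA-score path, in \[0, 1\].
#' @param idp_age_loading_range Range of per-IDP loadings on true brain age.
#' @param idp_noise_sd SD of per-IDP Gaussian noise (years, on the loading
#'   scale).
#' @param bag_noise_sd SD of the BAG residual, years. Default 4, a typical
#'   brain-age residual scale that makes recovery of a 0.07 y effect at
#'   n = 20,000 borderline-significant.
#' @param nutrient_sd_log Within-person (assessment-to-assessment) log-scale
#'   SD of nutrient intakes.
#' @param diet_signal_loading Loading of the shared latent "diet inflammatory
#'   tendency" on each parameter's between-person intake variation; controls
#'   the DII spread (default tuned so DII spans roughly -6..5 with SD ~ 2).
#' @param frac_female Fraction female.
#' @param age_range_baseline Baseline age range, years.
#' @param scan_lag_mean,scan_lag_sd Years from baseline to MRI scan.
#' @param assessment_scheme `"cycles"` (1-5 assessments across a baseline and
#'   four online cycles) or `"baseline_only"` (exactly one baseline
#'   assessment per participant, the mediation-study condition).
#' @param missingness_rates Named list column -> fraction of values set
#'   missing (applied to IDP columns); default none.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_participants,
                       seed = 1L,
                       n_idps = 200L,
                       idp_modality_counts = NULL,
                       beta_dii_bag = 0.07,
                       group_effects = NULL,
                       group_effects_older = NULL,
                       prop_mediated_true = 0.08,
                       idp_age_loading_range = c(0.2, 1.0),
                       idp_noise_sd = 10,
                       bag_noise_sd = 4,
                       nutrient_sd_log = 0.25,
                       diet_signal_loading = 0.3,
                       frac_female = 0.536,
                       age_range_baseline = c(40, 70),
                       scan_lag_mean = 8.7,
                       scan_lag_sd = 1.5,
                       assessment_scheme = c("cycles", "baseline_only"),
                       missingness_rates = NULL) {
  assert_that(n_participants >= 1, "n_participants must be >= 1")
  assert_that(prop_mediated_true >= 0 && prop_mediated_true <= 1,
              "prop_mediated_true must lie in [0, 1]")
  assert_that(length(idp_age_loading_range) == 2 &&
                diff(idp_age_loading_range) >= 0,
              "idp_age_loading_range must be an increasing pair")
  assert_that(idp_noise_sd >= 0 && bag_noise_sd >= 0,
              "noise SDs must be non-negative")
  assert_that(frac_female >= 0 && frac_female <= 1, "frac_female in [0,1]")
  assessment_scheme <- match.arg(assessment_scheme)
  if (is.null(idp_modality_counts)) {
    idp_modality_counts <- scale_modality_counts(n_idps)
  }
  assert_that(sum(idp_modality_counts) == n_idps,
              "idp_modality_counts must sum to n_idps (%d != %d)",
              sum(idp_modality_counts), n_idps)
  if (!is.null(group_effects)) {
    check_group_effects(group_effects)
    if (!is.null(group_effects_older)) check_group_effects(group_effects_older)
  } else {
    assert_that(is.null(group_effects_older),
                "group_effects_older requires group_effects")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    seed = as.integer(seed),
    n_idps = as.integer(n_idps),
    idp_modality_counts = idp_modality_counts,
    beta_dii_bag = beta_dii_bag,
    group_effects = group_effects,
    group_effects_older = group_effects_older,
    prop_mediated_true = prop_mediated_true,
    idp_age_loading_range = idp_age_loading_range,
    idp_noise_sd = idp_noise_sd,
    bag_noise_sd = bag_noise_sd,
    nutrient_sd_log = nutrient_sd_log,
    diet_signal_loading = diet_signal_loading,
    frac_female = frac_female,
    age_range_baseline = age_range_baseline,
    scan_lag_mean = scan_lag_mean,
    scan_lag_sd = scan_lag_sd,
    assessment_scheme = assessment_scheme,
    missingness_rates = missingness_rates
  ), class = "sim_config")
}

check_group_effects <- function(ge) {
  assert_that(all(c("g2", "g3", "g4") %in% names(ge)),
              "group_effects must be named c(g2=, g3=, g4=)")
  assert_that(all(is.finite(unlist(ge[c("g2", "g3", "g4")]))),
              "group_effects must be finite")
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  n = %d, seed = %d, IDPs = %d (%s)\n", x$n_participants,
              x$seed, x$n_idps,
              paste(names(x$idp_modality_counts), x$idp_modality_counts,
                    sep = ":", collapse = ", ")))
  cat(sprintf("  beta_dii_bag = %g y/unit, prop mediated = %g, BAG noise SD = %g y\n",
              x$beta_dii_bag, x$prop_mediated_true, x$bag_noise_sd))
  if (!is.null(x$group_effects)) {
    cat(sprintf("  group effects (y): g2 = %g, g3 = %g, g4 = %g\n",
                x$group_effects[["g2"]], x$group_effects[["g3"]],
                x$group_effects[["g4"]]))
  }
  invisible(x)
}

#' Full-scale IDP modality schema
#'
#' Column counts per imaging modality of the full 1,079-feature schema:
#' T1-weighted (165), T2-FLAIR (1), T2* (14), diffusion MRI (675),
#' resting-state fMRI (210) and task fMRI (14).
#'
#' @return Named integer vector summing to 1,079.
#' @export
idp_modality_schema <- function() {
  c(T1 = 165L, `T2-FLAIR` = 1L, `T2*` = 14L, dMRI = 675L,
    `rs-fMRI` = 210L, `task-fMRI` = 14L)
}

# Scale the full schema proportionally to n_idps (largest-remainder rounding,
# every modality kept with at least one column when n_idps >= 6).
scale_modality_counts <- function(n_idps) {
  full <- idp_modality_schema()
  if (n_idps == sum(full)) return(full)
  raw <- full / sum(full) * n_idps
  base <- floor(raw)
  if (n_idps >= length(full)) base <- pmax(base, 1)
  rem <- n_idps - sum(base)
  if (rem > 0) {
    order_frac <- order(raw - floor(raw), decreasing = TRUE)
    take <- head(order_frac, rem)
    base[take] <- base[take] + 1
  } else if (rem < 0) {
    order_big <- order(base, decreasing = TRUE)
    i <- 1
    while (rem < 0) {
      j <- order_big[(i - 1) %% length(full) + 1]
      if (base[j] > 1) { base[j] <- base[j] - 1; rem <- rem + 1 }
      i <- i + 1
    }
  }
  stats::setNames(as.integer(base), names(full))
}
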