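#' Generate a synthetic DII reference table
#'
#' Draws a reference of dietary parameters with signed inflammatory effect
#' weights (a mixture of pro- and anti-inflammatory parameters whenever
#' `n_params >= 2`), positive global means spanning several orders of
#' magnitude (intake units differ across nutrients) and positive global SDs.
#' The packaged generator produces placeholder weights for testing and
#' simulation; the published effect weights live in an external reference a
#' user can supply as a drop-in table with the same columns.
#'
#' @param n_params Number of dietary parameters (>= 1; 31 mirrors a nutrient
#'   panel, 45 the full index).
#' @param seed Integer seed.
#' @return Tibble: `parameter`, `weight`, `global_mean`, `global_sd`.
#' @export
generate_reference <- function(n_params = 31, seed = 101) {
  assert_that(n_params >= 1, "n_params must be >= 1")
  with_seed(seed, {
    weight <- stats::runif(n_params, -0.7, 0.5)
    if (n_params >= 2 && length(unique(sign(weight))) == 1) {
      weight[which.min(abs(weight))] <- -weight[which.min(abs(weight))]
    }
    global_mean <- exp(stats::rnorm(n_params, mean = 2, sd = 1.5))
    cv <- stats::runif(n_params, 0.3, 0.6)
    tibble::tibble(
      parameter = sprintf("nutrient_%02d", seq_len(n_params)),
      weight = weight,
      global_mean = global_mean,
      global_sd = global_mean * cv
    )
  })
}

# Internal fixed covariate effects on BAG (years); these are the generator's
# confounding structure and are linear in exactly the terms the adjusted
# models contain, so a correctly specified fit recovers beta_dii_bag.
bag_covariate_effects <- function() {
  list(female = -0.2, race_white = -0.2, education_degree = -0.2,
       townsend = 0.04, energy_kcal = -3e-4, bmi = 0.04,
       smoking_former = 0.2, smoking_current = 0.8,
       activity_moderate = -0.2, activity_high = -0.4,
       cvd = 0.8, t2d = 1.2, hypertension = 0.4, prs_ad = 0.15)
}

#' Generate a synthetic cohort
#'
#' Produces dietary assessments (1-5 per participant with kcal energy),
#' baseline blood markers whose latent inflammation depends linearly on the
#' participant's true DII, raw covariates with documented marginal
#' distributions and realistic confounding, and a ground-truth table. The
#' brain age gap is generated as
#' `BAG = c' * DII + b * INFLA + group shifts + covariate effects + noise`,
#' where `b` is calibrated in-sample so that the indirect path accounts for
#' exactly `prop_mediated_true` of `beta_dii_bag`, and `c'` carries the rest.
#' Ground truth is returned separately and must never be fed to estimators.
#'
#' @param config A [sim_config()].
#' @param reference A DII reference table (see [generate_reference()]).
#' @return A `synth_cohort` list: `diet` (per-assessment intakes), `blood`
#'   (four-marker panel plus components), `covariates` (raw fields), `truth`
#'   (per-participant `true_dii`, `true_infla`, `true_bag`,
#'   `true_brain_age`; realized effect parameters as attribute `"params"`).
#' @export
generate_cohort <- function(config, reference) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  reference <- validate_reference(reference)
  n <- config$n_participants

  with_seed(config$seed, {
    id <- sprintf("P%06d", seq_len(n))
    sex <- ifelse(stats::runif(n) < config$frac_female, "female", "male")
    female <- sex == "female"

    # baseline age: normal(55, 7.5) truncated to the design range
    ar <- config$age_range_baseline
    plo <- stats::pnorm((ar[1] - 55) / 7.5); phi <- stats::pnorm((ar[2] - 55) / 7.5)
    age_baseline <- 55 + 7.5 * stats::qnorm(stats::runif(n, plo, phi))
    scan_lag <- pmax(stats::rnorm(n, config$scan_lag_mean, config$scan_lag_sd), 2)
    age_scan <- age_baseline + scan_lag
    zage <- (age_baseline - 55) / 7.5

    # latent diet inflammatory tendency: younger and female lean
    # pro-inflammatory (mild confounding, handled by adjustment)
    D <- -0.12 * zage + 0.12 * (female - mean(female)) / max(stats::sd(female), 1e-9) +
      sqrt(1 - 0.12^2 - 0.12^2) * stats::rnorm(n)

    # --- raw covariates ------------------------------------------------------
    race_white <- stats::runif(n) < stats::plogis(stats::qlogis(0.93) - 0.10 * D)
    education_degree <- stats::runif(n) < stats::plogis(stats::qlogis(0.50) - 0.15 * D)
    townsend <- stats::rnorm(n, -1.9, 2.7) + 0.15 * D
    u <- stats::runif(n)
    p_cur <- stats::plogis(stats::qlogis(0.06) + 0.30 * D)
    smoking <- ifelse(u < p_cur, "current", ifelse(u < p_cur + 0.33, "former", "never"))
    u2 <- stats::runif(n)
    p_low <- stats::plogis(stats::qlogis(0.18) + 0.25 * D)
    p_high <- stats::plogis(stats::qlogis(0.38) - 0.25 * D)
    physical_activity <- ifelse(u2 < p_low, "low",
                                ifelse(u2 < p_low + p_high, "high", "moderate"))
    bmi_latent <- pmin(pmax(27 + 0.8 * D + stats::rnorm(n, 0, 4.3), 15), 55)
    height_m <- stats::rnorm(n, ifelse(female, 1.63, 1.76), 0.07)
    weight_kg <- bmi_latent * height_m^2
    waist_cm <- 78 + 2.1 * (bmi_latent - 27) + 12 * (!female) + stats::rnorm(n, 0, 5)
    sbp <- 135 + 0.35 * (age_baseline - 55) + stats::rnorm(n, 0, 17)
    dbp <- 81 + stats::rnorm(n, 0, 10)
    hypertension_history <- stats::runif(n) <
      stats::plogis(stats::qlogis(0.12) + 0.02 * (age_baseline - 55))
    antihypertensive_meds <- hypertension_history & stats::runif(n) < 0.6
    hba1c_pct <- stats::rnorm(n, 5.5, 0.45) + 0.05 * pmax(bmi_latent - 27, 0)
    glucose_mg_dl <- stats::rnorm(n, 92, 12) + 0.4 * (bmi_latent - 27)
    t2d_history <- stats::runif(n) <
      stats::plogis(stats::qlogis(0.04) + 0.08 * (bmi_latent - 27))
    glucose_meds <- t2d_history & stats::runif(n) < 0.7
    cvd <- stats::runif(n) < stats::plogis(stats::qlogis(0.035) + 0.03 * (age_baseline - 55))
    stroke <- stats::runif(n) < stats::plogis(stats::qlogis(0.05) + 0.04 * (age_baseline - 55))
    longstanding_illness <- stats::runif(n) <
      stats::plogis(stats::qlogis(0.35) + 0.03 * (age_baseline - 55))
    health_latent <- 0.05 * (bmi_latent - 27) + 0.5 * (smoking == "current") +
      0.8 * longstanding_illness + stats::rnorm(n)
    srh_cut <- stats::quantile(health_latent, c(0.35, 0.75, 0.92))
    self_rated_health <- cut(health_latent, c(-Inf, srh_cut, Inf),
                             labels = c("excellent", "good", "fair", "poor"))
    self_rated_health <- as.character(self_rated_health)
    prs_ad <- stats::rnorm(n)
    hap_pool <- c("e2", "e3", "e4")
    hap_freq <- c(0.08, 0.77, 0.15)
    hap1 <- sample(hap_pool, n, TRUE, hap_freq)
    hap2 <- sample(hap_pool, n, TRUE, hap_freq)
    hap_snp <- function(h) {
      # alleles at (rs429358, rs7412): e2 = T/T, e3 = T/C, e4 = C/C
      cbind(ifelse(h == "e4", "C", "T"), ifelse(h == "e2", "T", "C"))
    }
    s1 <- hap_snp(hap1); s2 <- hap_snp(hap2)
    paste_geno <- function(a, b) paste0(pmin(a, b), pmax(a, b))
    rs429358 <- paste_geno(s1[, 1], s2[, 1])
    rs7412 <- paste_geno(s1[, 2], s2[, 2])

    covariates <- tibble::tibble(
      participant_id = id, sex = sex, age_baseline = age_baseline,
      age_scan = age_scan, race_white = race_white,
      education_degree = education_degree, townsend = townsend,
      smoking = smoking, physical_activity = physical_activity,
      height_m = height_m, weight_kg = weight_kg, waist_cm = waist_cm,
      sbp = sbp, dbp = dbp, hypertension_history = hypertension_history,
      antihypertensive_meds = antihypertensive_meds, hba1c_pct = hba1c_pct,
      glucose_mg_dl = glucose_mg_dl, t2d_history = t2d_history,
      glucose_meds = glucose_meds, cvd = cvd, stroke = stroke,
      longstanding_illness = longstanding_illness,
      self_rated_health = self_rated_health, prs_ad = prs_ad,
      rs429358 = rs429358, rs7412 = rs7412
    )

    # --- dietary assessments -------------------------------------------------
    cycles <- c("baseline", "online1", "online2", "online3", "online4")
    if (config$assessment_scheme == "baseline_only") {
      inc <- matrix(FALSE, n, 5); inc[, 1] <- TRUE
    } else {
      probs <- c(0.24, 0.50, 0.45, 0.55, 0.55)
      inc <- matrix(stats::runif(n * 5), n, 5) <
        matrix(probs, n, 5, byrow = TRUE)
      none <- rowSums(inc) == 0
      if (any(none)) {
        inc[cbind(which(none), sample.int(5, sum(none), TRUE))] <- TRUE
      }
    }
    idx_person <- rep(seq_len(n), times = rowSums(inc))
    lin <- which(t(inc))  # row-major order: person by person, cycles ascending
    cycle <- cycles[(lin - 1L) %% 5L + 1L]
    m <- length(idx_person)

    p <- nrow(reference)
    cv <- reference$global_sd / reference$global_mean
    s_tot <- sqrt(log1p(cv^2))
    s_w <- pmin(config$nutrient_sd_log, 0.6 * s_tot)
    s_b <- sqrt(s_tot^2 - s_w^2)
    rho <- config$diet_signal_loading
    sgn <- ifelse(reference$weight >= 0, 1, -1)

    # between-person standardized log deviation, aligned with D through the
    # weight signs so higher D means a more pro-inflammatory diet
    zb <- rho * outer(D, sgn) + sqrt(1 - rho^2) * matrix(stats::rnorm(n * p), n, p)
    logx <- matrix(log(reference$global_mean) - s_tot^2 / 2, m, p, byrow = TRUE) +
      zb[idx_person, , drop = FALSE] %*% diag(s_b, p) +
      matrix(stats::rnorm(m * p), m, p) %*% diag(s_w, p)
    intakes <- exp(logx)
    colnames(intakes) <- reference$parameter

    energy_kcal <- exp(log(2050) - 0.13 * D[idx_person] +
                         0.18 * stats::rnorm(n)[idx_person] +
                         0.10 * stats::rnorm(m))
    diet <- dplyr::bind_cols(
      tibble::tibble(participant_id = id[idx_person], cycle = cycle,
                     energy_kcal = energy_kcal),
      tibble::as_tibble(intakes)
    )

    # --- true DII (scored exactly as the analysis scores it) -----------------
    filt <- filter_plausible_assessments(diet, covariates[, c("participant_id", "sex")])
    mean_int <- average_intakes(filt$kept)
    dii_tbl <- compute_dii(mean_int, reference)
    true_dii <- dii_tbl$dii[match(id, dii_tbl$participant_id)]
    mean_energy <- mean_int$energy_kcal[match(id, mean_int$participant_id)]
    dii_c <- ifelse(is.na(true_dii), 0, true_dii - mean(true_dii, na.rm = TRUE))
    energy_fill <- ifelse(is.na(mean_energy), 2000, mean_energy)

    # --- blood markers through a latent inflammation variable ----------------
    a_L <- if (config$prop_mediated_true == 0) 0 else 0.025
    L <- a_L * dii_c + stats::rnorm(n)
    blood <- tibble::tibble(
      participant_id = id,
      crp = exp(0.25 + 0.75 * L),
      wbc = pmax(6.9 + 1.05 * L + stats::rnorm(n, 0, 1.35), 1),
      platelets = pmax(252 + 20 * L + stats::rnorm(n, 0, 54), 30),
      neutrophils = pmax(4.2 + 0.85 * L + stats::rnorm(n, 0, 1.0), 0.05),
      lymphocytes = pmax(1.95 - 0.15 * L + stats::rnorm(n, 0, 0.55), 0.2)
    )
    S <- suppressMessages(compute_infla(blood))$infla
    S_c <- S - mean(S)

    # --- derived covariates used in the outcome equation ---------------------
    cm <- derive_cardiometabolic(sbp = sbp, dbp = dbp,
                                 hypertension_history = hypertension_history,
                                 antihypertensive_meds = antihypertensive_meds,
                                 hba1c_pct = hba1c_pct,
                                 glucose_mg_dl = glucose_mg_dl,
                                 t2d_history = t2d_history,
                                 glucose_meds = glucose_meds)

    # --- mediated-path calibration ------------------------------------------
    # The implied exposure->mediator slope is a_L * E[dS/dL]; the derivative
    # factor is the projection slope of the INFLA-score on the (approximately
    # normal) latent, which is strongly identified even in small cohorts, so
    # the planted b is stable across seeds while ACME/total equals the
    # configured fraction in expectation.
    acme_target <- config$prop_mediated_true * config$beta_dii_bag
    if (acme_target != 0) {
      slope_SL <- stats::cov(S, L) / stats::var(L)
      a_real <- a_L * slope_SL
      if (!is.finite(a_real) || abs(a_real) < 1e-8) {
        rlang::abort("exposure-mediator slope degenerate; cannot calibrate mediated path")
      }
      # predicted t-statistic of the mediator-model slope under these
      # conditions; below ~2 the per-cohort ACME estimate is noise-dominated
      t_pred <- abs(a_real) * stats::sd(dii_c) * sqrt(n) / stats::sd(S)
      if (t_pred < 2) {
        rlang::warn(sprintf(
          "exposure-mediator path weakly identified under these conditions (predicted |t| = %.1f); per-cohort ACME estimates will be noise-dominated",
          t_pred), class = "inflammage_weak_mediation")
      }
      b <- acme_target / a_real
    } else {
      a_real <- 0; b <- 0
    }
    c_prime <- config$beta_dii_bag - acme_target

    # --- group shifts (optionally age-heterogeneous) -------------------------
    shift <- rep(0, n)
    if (!is.null(config$group_effects)) {
      g <- assign_dii_group(ifelse(is.na(true_dii), 0, true_dii))
      ge <- c(0, config$group_effects[["g2"]], config$group_effects[["g3"]],
              config$group_effects[["g4"]])
      shift <- ge[g]
      if (!is.null(config$group_effects_older)) {
        older <- age_baseline >= 60
        geo <- c(0, config$group_effects_older[["g2"]],
                 config$group_effects_older[["g3"]],
                 config$group_effects_older[["g4"]])
        shift[older] <- geo[g[older]]
      }
    }

    # --- outcome: brain age gap ---------------------------------------------
    ce <- bag_covariate_effects()
    covar_part <-
      ce$female * (female - mean(female)) +
      ce$race_white * (race_white - mean(race_white)) +
      ce$education_degree * (education_degree - mean(education_degree)) +
      ce$townsend * (townsend - mean(townsend)) +
      ce$energy_kcal * (energy_fill - mean(energy_fill)) +
      ce$bmi * (bmi_latent - mean(bmi_latent)) +
      ce$smoking_former * (smoking == "former") +
      ce$smoking_current * (smoking == "current") +
      ce$activity_moderate * (physical_activity == "moderate") +
      ce$activity_high * (physical_activity == "high") +
      ce$cvd * cvd + ce$t2d * cm$t2d + ce$hypertension * cm$hypertension +
      ce$prs_ad * prs_ad

    true_bag <- c_prime * dii_c + b * S_c + shift + covar_part +
      stats::rnorm(n, 0, config$bag_noise_sd)
    true_brain_age <- age_scan + true_bag

    truth <- tibble::tibble(
      participant_id = id, true_dii = true_dii, true_infla = S,
      true_bag = true_bag, true_brain_age = true_brain_age
    )
    attr(truth, "params") <- list(
      a_latent = a_L, a_realized = a_real, b = b, c_prime = c_prime,
      acme = acme_target, total = config$beta_dii_bag,
      prop_mediated = config$prop_mediated_true,
      group_effects = config$group_effects,
      group_effects_older = config$group_effects_older,
      covariate_effects = ce
    )

    structure(list(diet = diet, blood = blood, covariates = covariates,
                   truth = truth, config = config),
              class = "synth_cohort")
  })
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> n = %d, %d dietary assessments, seed = %d\n",
              nrow(x$covariates), nrow(x$diet), x$config$seed))
  invisible(x)
}

#' Generate a synthetic IDP matrix
#'
#' Each imaging-derived phenotype is a linear readout of true brain age:
#' `idp_j = loading_j * true_brain_age + N(0, idp_noise_sd)`, with loadings
#' drawn uniformly from `idp_age_loading_range` and columns labelled by
#' modality per the configured schema. Optional missingness (configured per
#' `missingness_rates$idps`) is injected completely at random.
#'
#' @param truth Truth table from [generate_cohort()] (uses `true_brain_age`).
#' @param config The same [sim_config()] used for the cohort.
#' @return List: `idps` (tibble, `participant_id` + one column per IDP),
#'   `modality_map` (tibble `idp`, `modality`), `loadings` (ground-truth
#'   tibble `idp`, `loading`; for diagnostics only, never a model input).
#' @export
generate_idps <- function(truth, config) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  check_columns(truth, c("participant_id", "true_brain_age"), "truth")
  assert_that(nrow(truth) == config$n_participants,
              "truth and config describe different numbers of participants")
  n <- nrow(truth); p <- config$n_idps
  with_seed(child_seed(config$seed, 7L), {
    loading <- stats::runif(p, config$idp_age_loading_range[1],
                            config$idp_age_loading_range[2])
    mat <- outer(truth$true_brain_age, loading) +
      matrix(stats::rnorm(n * p, 0, config$idp_noise_sd), n, p)
    idp_names <- sprintf("idp_%04d", seq_len(p))
    colnames(mat) <- idp_names
    rate <- config$missingness_rates[["idps"]]
    if (!is.null(rate) && rate > 0) {
      miss <- matrix(stats::runif(n * p) < rate, n, p)
      mat[miss] <- NA_real_
    }
    modality <- rep(names(config$idp_modality_counts),
                    times = config$idp_modality_counts)
    list(
      idps = dplyr::bind_cols(
        tibble::tibble(participant_id = truth$participant_id),
        tibble::as_tibble(mat)),
      modality_map = tibble::tibble(idp = idp_names, modality = modality),
      loadings = tibble::tibble(idp = idp_names, loading = loading)
    )
  })
}
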