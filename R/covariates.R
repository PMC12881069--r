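#' Covariate derivation rules
#'
#' Categorization rules used throughout the analysis: BMI bins, waist-risk
#' cut-offs, hypertension and type-2-diabetes flags from measurements,
#' history and medication, polygenic-risk tertiles, APOE e4 carrier status
#' from the two defining SNPs, and the middle-aged/older age strata.
#'
#' @name covariates
NULL

#' Anthropometric derivation: BMI, BMI category, waist risk
#'
#' BMI = weight / height^2 (kg/m^2), categorized as underweight (< 18.5),
#' normal (18.5 to < 25), overweight (25 to < 30) or obese (>= 30). Waist
#' circumference is high risk at >= 88 cm for females and >= 102 cm for males.
#'
#' @param height_m Height in meters (> 0).
#' @param weight_kg Weight in kg.
#' @param waist_cm Waist circumference in cm.
#' @param sex `"female"`/`"male"`.
#' @return Tibble: `bmi`, `bmi_category` (factor), `waist_risk` (factor
#'   normal/high).
#' @export
derive_anthropometrics <- function(height_m, weight_kg, waist_cm, sex) {
  if (any(!is.na(height_m) & height_m <= 0)) {
    rlang::abort("height must be strictly positive")
  }
  bmi <- weight_kg / height_m^2
  cat_lab <- c("underweight", "normal", "overweight", "obese")
  bmi_category <- factor(cat_lab[findInterval(bmi, c(18.5, 25, 30)) + 1L],
                         levels = cat_lab)
  thr <- ifelse(sex == "female", 88, 102)
  waist_risk <- factor(ifelse(waist_cm >= thr, "high", "normal"),
                       levels = c("normal", "high"))
  tibble::tibble(bmi = bmi, bmi_category = bmi_category, waist_risk = waist_risk)
}

# TRUE if any criterion TRUE; FALSE if all evaluable criteria FALSE; NA if
# none evaluable. `...` are logical vectors of equal length.
any_criterion <- function(...) {
  m <- cbind(...)
  has_true <- rowSums(m, na.rm = TRUE) > 0
  all_na <- rowSums(!is.na(m)) == 0
  out <- has_true
  out[all_na] <- NA
  out
}

#' Cardiometabolic flags: hypertension and type 2 diabetes
#'
#' Hypertension: SBP >= 140 mmHg, DBP >= 90 mmHg, self-reported history, or
#' antihypertensive medication. T2D: medical record / self-reported history,
#' glucose-lowering medication, HbA1c >= 6.5%, or fasting plasma glucose
#' >= 126 mg/dL. A flag is TRUE if any criterion holds, FALSE if all
#' evaluable criteria are false, and NA if none is evaluable.
#'
#' @param sbp,dbp Blood pressures in mmHg.
#' @param hypertension_history,antihypertensive_meds Logical.
#' @param hba1c_pct HbA1c in percent.
#' @param glucose_mg_dl Fasting plasma glucose in mg/dL.
#' @param t2d_history,glucose_meds Logical.
#' @return Tibble: `hypertension`, `t2d` (logical).
#' @export
derive_cardiometabolic <- function(sbp = NA, dbp = NA,
                                   hypertension_history = NA,
                                   antihypertensive_meds = NA,
                                   hba1c_pct = NA, glucose_mg_dl = NA,
                                   t2d_history = NA, glucose_meds = NA) {
  n <- max(lengths(list(sbp, dbp, hypertension_history, antihypertensive_meds,
                        hba1c_pct, glucose_mg_dl, t2d_history, glucose_meds)))
  rec <- function(x) rep_len(x, n)
  hypertension <- any_criterion(rec(sbp) >= 140, rec(dbp) >= 90,
                                as.logical(rec(hypertension_history)),
                                as.logical(rec(antihypertensive_meds)))
  t2d <- any_criterion(as.logical(rec(t2d_history)),
                       as.logical(rec(glucose_meds)),
                       rec(hba1c_pct) >= 6.5, rec(glucose_mg_dl) >= 126)
  tibble::tibble(hypertension = hypertension, t2d = t2d)
}

# Tertile rank (1..3) with the same tie rule as deciles: smallest k with
# v <= cut_k, else 3.
tertile_rank <- function(values, cuts = NULL) {
  if (is.null(cuts)) {
    cuts <- unname(stats::quantile(values[!is.na(values)], c(1, 2) / 3, type = 7))
  }
  k <- rep(NA_integer_, length(values))
  ok <- is.finite(values)
  k[ok] <- 1L + rowSums(outer(values[ok], cuts, ">"))
  attr(k, "cuts") <- cuts
  k
}

# Normalize a genotype string ("CT", "C/T", "tc") to a sorted allele pair.
parse_genotype <- function(g) {
  g <- toupper(gsub("[^ACGTacgt]", "", g))
  a1 <- substr(g, 1, 1); a2 <- substr(g, 2, 2)
  ifelse(nchar(g) == 2, paste0(pmin(a1, a2), pmax(a1, a2)), NA_character_)
}

#' Genetic covariates: PRS tertiles and APOE e4 carrier status
#'
#' PRS tertile bounds are taken from the analytic sample (or supplied).
#' APOE e4 is the haplotype carrying C at rs429358 together with C at rs7412;
#' a participant is a carrier when at least one haplotype is e4. The doubly
#' heterozygous diplotype (C/T at both SNPs) cannot be phased from genotypes
#' alone (e2/e4 versus e1/e3) and is flagged ambiguous, not guessed.
#'
#' @param prs Numeric polygenic risk score.
#' @param rs429358,rs7412 Genotype strings, e.g. `"CT"`, `"T/T"`.
#' @param prs_cuts Optional two tertile cut points (else computed from `prs`).
#' @return Tibble: `prs_tertile` (factor low/moderate/high), `apoe4`
#'   (logical, `NA` when ambiguous or missing), `apoe_ambiguous` (logical).
#'   PRS cut points attached as attribute `"prs_cuts"`.
#' @export
derive_genetic <- function(prs, rs429358, rs7412, prs_cuts = NULL) {
  k <- tertile_rank(prs, prs_cuts)
  prs_tertile <- factor(c("low", "moderate", "high")[k],
                        levels = c("low", "moderate", "high"))
  g1 <- parse_genotype(rs429358)
  g2 <- parse_genotype(rs7412)
  n_c1 <- nchar(gsub("[^C]", "", g1))  # C alleles at rs429358
  n_c2 <- nchar(gsub("[^C]", "", g2))  # C alleles at rs7412
  ambiguous <- !is.na(n_c1) & !is.na(n_c2) & n_c1 == 1 & n_c2 == 1
  carrier <- rep(NA, length(prs))
  known <- !is.na(n_c1) & !is.na(n_c2) & !ambiguous
  # with no double heterozygote, an e4 haplotype exists iff rs429358 carries a
  # C that can pair with a C at rs7412
  carrier[known] <- (n_c1[known] >= 1 & n_c2[known] == 2) |
    (n_c1[known] == 2 & n_c2[known] >= 1)
  out <- tibble::tibble(prs_tertile = prs_tertile,
                        apoe4 = carrier,
                        apoe_ambiguous = ambiguous)
  attr(out, "prs_cuts") <- attr(k, "cuts")
  out
}

#' Age stratum: middle-aged versus older
#'
#' Middle-aged: 40-59 years; older: >= 60 years. Ages below 40 are outside
#' the cohort design: retained with a missing stratum and a warning.
#'
#' @param age Age in years.
#' @return Factor with levels `"middle"`, `"older"`.
#' @export
derive_age_group <- function(age) {
  under <- !is.na(age) & age < 40
  if (any(under)) {
    rlang::warn(sprintf("%d participant(s) younger than 40; age stratum set to NA",
                        sum(under)))
  }
  out <- rep(NA_character_, length(age))
  out[!is.na(age) & age >= 40 & age <= 59] <- "middle"
  out[!is.na(age) & age >= 60] <- "older"
  factor(out, levels = c("middle", "older"))
}

#' Derive all analysis covariates from raw cohort fields
#'
#' One-stop wrapper applying [derive_anthropometrics()],
#' [derive_cardiometabolic()], [derive_genetic()] and [derive_age_group()].
#' Refuses to re-derive a table that already carries derived columns (sample-
#' dependent tertiles must be computed once and reused).
#'
#' @param raw Cohort covariate tibble, e.g. `generate_cohort()$covariates`.
#' @param age_var Age column used for the age stratum (default baseline age).
#' @param prs_cuts Optional externally supplied PRS tertile cut points.
#' @return `raw` plus derived columns (`bmi`, `bmi_category`, `waist_risk`,
#'   `hypertension`, `t2d`, `prs_tertile`, `apoe4`, `apoe_ambiguous`,
#'   `age_group`).
#' @export
derive_covariates <- function(raw, age_var = "age_baseline", prs_cuts = NULL) {
  derived_cols <- c("bmi", "bmi_category", "hypertension", "t2d",
                    "prs_tertile", "apoe4", "age_group")
  already <- intersect(derived_cols, names(raw))
  if (length(already) > 0) {
    rlang::abort(sprintf(
      "input already contains derived column(s): %s; re-derivation would silently re-bin",
      paste(already, collapse = ", ")))
  }
  check_columns(raw, c("participant_id", "sex", age_var, "height_m",
                       "weight_kg", "waist_cm", "sbp", "dbp", "prs_ad",
                       "rs429358", "rs7412"), "raw covariates")
  g <- function(col) if (col %in% names(raw)) raw[[col]] else NA
  anth <- derive_anthropometrics(raw$height_m, raw$weight_kg, raw$waist_cm, raw$sex)
  cm <- derive_cardiometabolic(
    sbp = raw$sbp, dbp = raw$dbp,
    hypertension_history = g("hypertension_history"),
    antihypertensive_meds = g("antihypertensive_meds"),
    hba1c_pct = g("hba1c_pct"), glucose_mg_dl = g("glucose_mg_dl"),
    t2d_history = g("t2d_history"), glucose_meds = g("glucose_meds"))
  gen <- derive_genetic(raw$prs_ad, raw$rs429358, raw$rs7412, prs_cuts = prs_cuts)
  out <- dplyr::bind_cols(tibble::as_tibble(raw), anth, cm, gen)
  out$age_group <- derive_age_group(raw[[age_var]])
  attr(out, "prs_cuts") <- attr(gen, "prs_cuts")
  out
}
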