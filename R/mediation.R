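#' Linear causal mediation of the DII-BAG association by the INFLA-score
#'
#' Classic product-of-coefficients mediation for linear models without an
#' exposure-mediator interaction: with `a` the exposure coefficient in the
#' mediator model, `b` the mediator coefficient in the outcome model and `c'`
#' the exposure coefficient in the outcome model, the average causal
#' mediation effect (indirect effect) is `ACME = a * b`, the average direct
#' effect is `ADE = c'`, and `total = c' + a * b` — an exact algebraic
#' identity on a common row set. Inference is by nonparametric case-resampling
#' bootstrap with percentile intervals; for linear models without interaction
#' this estimand coincides with the quasi-Bayesian one.
#'
#' @name mediation
NULL

# Joint listwise deletion + model matrices for the mediator and outcome fits.
mediation_design <- function(data, exposure, mediator, outcome, covariates) {
  data <- prepare_analysis_data(data)
  vars <- c(exposure, mediator, outcome, covariates)
  check_columns(data, vars, "mediation data")
  used <- stats::complete.cases(data[, vars, drop = FALSE])
  dat <- data[used, , drop = FALSE]
  assert_that(nrow(dat) > length(vars) + 2, "too few complete rows for mediation")
  rhs <- paste(c(exposure, covariates), collapse = " + ")
  Xm <- stats::model.matrix(stats::as.formula(paste("~", rhs)), dat)
  Xy <- cbind(Xm, dat[[mediator]])
  colnames(Xy)[ncol(Xy)] <- mediator
  list(dat = dat, Xm = Xm, Xy = Xy,
       M = dat[[mediator]], Y = dat[[outcome]],
       i_exp = which(colnames(Xm) == exposure),
       i_med = ncol(Xy), n_dropped = sum(!used))
}

# (a, b, c') for one (possibly resampled) row index set.
mediation_coefs <- function(d, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(d$Xm))
  fm <- stats::lm.fit(d$Xm[idx, , drop = FALSE], d$M[idx])
  fy <- stats::lm.fit(d$Xy[idx, , drop = FALSE], d$Y[idx])
  c(a = unname(fm$coefficients[d$i_exp]),
    b = unname(fy$coefficients[d$i_med]),
    c_prime = unname(fy$coefficients[d$i_exp]))
}

#' Mediation point estimates
#'
#' Fits the mediator model (`mediator ~ exposure + covariates`) and the
#' outcome model (`outcome ~ exposure + mediator + covariates`) on one
#' jointly listwise-deleted row set and returns the path coefficients and
#' effect decomposition.
#'
#' @param data Analysis tibble.
#' @param exposure,mediator,outcome Column names (defaults: `dii`, `infla`,
#'   `bag`).
#' @param adjustment `"basic"` or `"multivariable"` (see
#'   [adjustment_covariates()]), or a character vector of covariate names.
#' @param age_var Age covariate.
#' @return One-row tibble: `a`, `b`, `c_prime`, `acme`, `ade`, `total`,
#'   `prop_mediated`, `n`.
#' @export
mediation_point_estimate <- function(data, exposure = "dii",
                                     mediator = "infla", outcome = "bag",
                                     adjustment = "multivariable",
                                     age_var = "age_baseline") {
  covars <- if (length(adjustment) == 1 &&
                adjustment %in% c("basic", "multivariable")) {
    adjustment_covariates(adjustment, age_var)
  } else adjustment
  d <- mediation_design(data, exposure, mediator, outcome, covars)
  co <- mediation_coefs(d)
  acme <- co[["a"]] * co[["b"]]
  total <- co[["c_prime"]] + acme
  tibble::tibble(a = co[["a"]], b = co[["b"]], c_prime = co[["c_prime"]],
                 acme = acme, ade = co[["c_prime"]], total = total,
                 prop_mediated = acme / total, n = nrow(d$dat))
}

#' Bootstrap mediation analysis
#'
#' Nonparametric case-resampling bootstrap (participant-level, with
#' replacement) of the linear mediation decomposition. Point estimates come
#' from the full sample; 95% intervals are percentile intervals over
#' replicates. Replicates whose total effect is degenerate (absolute value
#' below `degenerate_tol`) are excluded from the proportion-mediated interval
#' (the ratio is unstable there) and counted; if more than 10% of replicates
#' are degenerate the proportion's interval is flagged unstable.
#'
#' @inheritParams mediation_point_estimate
#' @param n_boot Number of bootstrap replicates (>= 100; 1,000 typical).
#' @param seed Integer seed (fixed seed gives identical intervals).
#' @param degenerate_tol Threshold for a degenerate replicate total.
#' @return A `mediation_result` with `estimates` (tibble: ACME, ADE, total
#'   effect, proportion mediated with 95% CIs), the replicate draws, and
#'   accounting fields. [tidy()] returns the estimate table.
#' @export
bootstrap_mediation <- function(data, exposure = "dii", mediator = "infla",
                                outcome = "bag",
                                adjustment = "multivariable",
                                age_var = "age_baseline",
                                n_boot = 1000, seed = 1L,
                                degenerate_tol = 1e-8) {
  assert_that(n_boot >= 100, "n_boot must be >= 100")
  covars <- if (length(adjustment) == 1 &&
                adjustment %in% c("basic", "multivariable")) {
    adjustment_covariates(adjustment, age_var)
  } else adjustment
  d <- mediation_design(data, exposure, mediator, outcome, covars)
  n <- nrow(d$dat)

  point <- mediation_coefs(d)
  acme0 <- point[["a"]] * point[["b"]]
  total0 <- point[["c_prime"]] + acme0

  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      co <- mediation_coefs(d, idx)
      acme <- co[["a"]] * co[["b"]]
      c(acme = acme, ade = co[["c_prime"]], total = co[["c_prime"]] + acme)
    }, numeric(3))
  })
  reps <- t(reps)
  degenerate <- abs(reps[, "total"]) < degenerate_tol
  prop_reps <- reps[!degenerate, "acme"] / reps[!degenerate, "total"]
  unstable <- mean(degenerate) > 0.10
  if (unstable) {
    rlang::warn(sprintf(
      "%.1f%% of replicates have a degenerate total effect; proportion-mediated interval is unstable",
      100 * mean(degenerate)))
  }
  pci <- function(x) unname(stats::quantile(x, c(0.025, 0.975), type = 7))
  ci <- rbind(pci(reps[, "acme"]), pci(reps[, "ade"]), pci(reps[, "total"]),
              pci(prop_reps))
  estimates <- tibble::tibble(
    effect = c("acme", "ade", "total", "prop_mediated"),
    estimate = c(acme0, point[["c_prime"]], total0, acme0 / total0),
    conf.low = ci[, 1], conf.high = ci[, 2])

  structure(list(estimates = estimates, replicates = tibble::as_tibble(reps),
                 n = n, n_dropped = d$n_dropped, n_boot = n_boot, seed = seed,
                 n_degenerate = sum(degenerate),
                 prop_ci_unstable = unstable,
                 adjustment = if (length(adjustment) == 1) adjustment else "custom"),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> n = %d, %d bootstrap replicates (seed %d), %s adjustment\n",
              x$n, x$n_boot, x$seed, x$adjustment))
  print(x$estimates)
  if (x$n_degenerate > 0) {
    cat(sprintf("  %d degenerate replicate(s) excluded from the proportion's CI%s\n",
                x$n_degenerate, if (x$prop_ci_unstable) " [UNSTABLE]" else ""))
  }
  invisible(x)
}

#' @rdname bootstrap_mediation
#' @param x A `mediation_result`.
#' @param ... Unused.
#' @export
tidy.mediation_result <- function(x, ...) {
  out <- x$estimates
  out$adjustment <- x$adjustment
  out$n <- x$n
  out
}

#' @rdname bootstrap_mediation
#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(nobs = x$n, n_dropped = x$n_dropped, n_boot = x$n_boot,
                 n_degenerate = x$n_degenerate,
                 prop_ci_unstable = x$prop_ci_unstable, seed = x$seed,
                 adjustment = x$adjustment)
}

#' DII from the baseline assessment only
#'
#' The INFLA-score markers are drawn at the baseline visit, so the mediation
#' analysis scores diet from the same baseline assessment, ignoring later
#' dietary assessments (reverse-causality guard). Participants without a
#' plausible baseline-cycle assessment are excluded.
#'
#' @param assessments Dietary assessment tibble with a `cycle` column.
#' @param reference DII reference table.
#' @param sex Sex table for the plausibility filter.
#' @param baseline_cycle Label of the baseline cycle (default `"baseline"`).
#' @param allow_missing Passed to [compute_dii()].
#' @return Tibble: `participant_id`, `dii`, `dii_group` for participants with
#'   a plausible baseline assessment; exclusion count as attribute
#'   `"n_excluded"`.
#' @export
baseline_only_dii <- function(assessments, reference, sex,
                              baseline_cycle = "baseline",
                              allow_missing = FALSE) {
  check_columns(assessments, c("participant_id", "cycle"), "assessments")
  base <- assessments[assessments$cycle == baseline_cycle, , drop = FALSE]
  filt <- filter_plausible_assessments(base, sex)
  n_all <- length(unique(assessments$participant_id))
  if (nrow(filt$kept) == 0) {
    rlang::abort("no plausible baseline-cycle assessments")
  }
  mean_int <- average_intakes(filt$kept)  # one row each; identity average
  out <- compute_dii(mean_int, reference, allow_missing = allow_missing)
  attr(out, "n_excluded") <- n_all - nrow(out)
  out
}
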