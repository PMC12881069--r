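#' DII-BAG association models
#'
#' Ordinary least squares with the two standard adjustment sets. The basic
#' set adjusts for age, sex, race, education and socioeconomic status
#' (Townsend deprivation index); the multivariable set adds energy intake,
#' BMI, smoking status, physical activity, cardiovascular disease, type 2
#' diabetes, hypertension and the Alzheimer's polygenic risk score.
#' Confidence intervals use t-distribution quantiles (df = n - p).
#'
#' @name assoc
NULL

#' Covariates of an adjustment set
#'
#' Single source of truth for the basic and multivariable adjustment sets,
#' shared by association, stratified and mediation analyses.
#'
#' @param set `"basic"` or `"multivariable"`.
#' @param age_var Age column to adjust for (baseline age by default; scan age
#'   switchable).
#' @param apoe4_instead_of_prs Sensitivity option replacing the polygenic
#'   risk score with APOE e4 carrier status in the multivariable set.
#' @return Character vector of covariate column names.
#' @export
adjustment_covariates <- function(set = c("basic", "multivariable"),
                                  age_var = "age_baseline",
                                  apoe4_instead_of_prs = FALSE) {
  set <- match.arg(set)
  basic <- c(age_var, "sex", "race_white", "education_degree", "townsend")
  if (set == "basic") return(basic)
  extra <- c("energy_kcal", "bmi", "smoking", "physical_activity",
             "cvd", "t2d", "hypertension",
             if (apoe4_instead_of_prs) "apoe4" else "prs_ad")
  c(basic, extra)
}

#' Ordinary least squares with listwise deletion and rank checks
#'
#' @param data Data frame.
#' @param formula Model formula.
#' @return An `ols_fit`: the `lm` object plus a tidy coefficient table
#'   (t-quantile CIs), `n_used` and `n_dropped` (listwise deletion count).
#'   Errors on rank deficiency, naming the collinear columns.
#' @export
fit_linear <- function(data, formula) {
  vars <- all.vars(formula)
  if ("." %in% vars) vars <- union(setdiff(vars, "."), names(data))
  check_columns(data, vars, "model data")
  used <- stats::complete.cases(data[, vars, drop = FALSE])
  dat <- data[used, , drop = FALSE]
  assert_that(nrow(dat) > length(vars),
              "n (%d) must exceed the number of model parameters", nrow(dat))
  fit <- stats::lm(formula, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    rlang::abort(sprintf("rank-deficient design; collinear column(s): %s",
                         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                               collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  df <- fit$df.residual
  ci <- t_ci(sm[, 1], sm[, 2], df)
  result <- tibble::tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                           std.error = unname(sm[, 2]),
                           statistic = unname(sm[, 3]),
                           conf.low = ci$conf.low, conf.high = ci$conf.high,
                           p.value = ci$p.value)
  structure(list(fit = fit, result = result, n_used = nrow(dat),
                 n_dropped = sum(!used), formula = formula),
            class = "ols_fit")
}

# Prepare the analysis frame: factor codings with the reference levels used
# throughout (group 1, never-smoker, low activity, non-carrier, low tertile).
prepare_analysis_data <- function(data) {
  out <- tibble::as_tibble(data)
  if ("dii_group" %in% names(out) && !is.factor(out$dii_group)) {
    out$dii_group <- factor(out$dii_group, levels = 1:4,
                            labels = paste0("g", 1:4))
  }
  if ("smoking" %in% names(out) && !is.factor(out$smoking)) {
    out$smoking <- factor(out$smoking, levels = c("never", "former", "current"))
  }
  if ("physical_activity" %in% names(out) && !is.factor(out$physical_activity)) {
    out$physical_activity <- factor(out$physical_activity,
                                    levels = c("low", "moderate", "high"))
  }
  if ("sex" %in% names(out) && !is.factor(out$sex)) {
    out$sex <- factor(out$sex, levels = c("female", "male"))
  }
  out
}

#' Association of DII with BAG
#'
#' Fits BAG on DII — continuously (one coefficient per DII unit) or as four
#' groups with group 1 (DII < -2) as reference — under the basic or
#' multivariable adjustment set.
#'
#' @param data Analysis tibble containing `bag`, `dii` (and/or `dii_group`)
#'   plus the adjustment covariates.
#' @param form `"continuous"` or `"groups"`.
#' @param adjustment `"basic"` or `"multivariable"`.
#' @param age_var Age covariate (default baseline age).
#' @param apoe4_instead_of_prs See [adjustment_covariates()].
#' @return A `dii_assoc` object; use [tidy()] for the coefficient table
#'   restricted to the DII terms, `tidy(, all = TRUE)` for every term.
#' @export
dii_bag_association <- function(data, form = c("continuous", "groups"),
                                adjustment = c("basic", "multivariable"),
                                age_var = "age_baseline",
                                apoe4_instead_of_prs = FALSE) {
  form <- match.arg(form); adjustment <- match.arg(adjustment)
  data <- prepare_analysis_data(data)
  exposure <- if (form == "continuous") "dii" else "dii_group"
  covars <- adjustment_covariates(adjustment, age_var, apoe4_instead_of_prs)
  check_columns(data, c("bag", exposure, covars), "analysis data")
  if (form == "groups") {
    present <- table(data$dii_group[!is.na(data$bag)])
    empty <- names(present)[present == 0]
    if (length(empty) > 0) {
      rlang::warn(sprintf("empty DII group cell(s): %s; contrast dropped",
                          paste(empty, collapse = ", ")))
      data$dii_group <- droplevels(data$dii_group)
    }
  }
  f <- stats::as.formula(paste("bag ~", paste(c(exposure, covars), collapse = " + ")))
  ols <- fit_linear(data, f)
  structure(list(ols = ols, form = form, adjustment = adjustment,
                 exposure = exposure, age_var = age_var,
                 data_used = ols$fit$model,
                 n_used = ols$n_used, n_dropped = ols$n_dropped),
            class = "dii_assoc")
}

#' @export
print.dii_assoc <- function(x, ...) {
  cat(sprintf("<dii_assoc> %s DII, %s adjustment, n = %d (%d dropped)\n",
              x$form, x$adjustment, x$n_used, x$n_dropped))
  print(tidy(x))
  invisible(x)
}

#' @rdname dii_bag_association
#' @param x A `dii_assoc` object.
#' @param all Return every model term rather than the DII terms only.
#' @param ... Unused.
#' @export
tidy.dii_assoc <- function(x, all = FALSE, ...) {
  res <- x$ols$result
  if (!all) res <- res[grepl("^dii", res$term), , drop = FALSE]
  res$form <- x$form
  res$adjustment <- x$adjustment
  res$n <- x$n_used
  res
}

#' @rdname dii_bag_association
#' @export
glance.dii_assoc <- function(x, ...) {
  sm <- summary(x$ols$fit)
  tibble::tibble(r.squared = sm$r.squared, adj.r.squared = sm$adj.r.squared,
                 sigma = sm$sigma, df.residual = x$ols$fit$df.residual,
                 nobs = x$n_used, n_dropped = x$n_dropped,
                 form = x$form, adjustment = x$adjustment)
}

#' Least-squares (adjusted marginal) means of BAG by DII group
#'
#' Predicted BAG per group, averaging model predictions over the observed
#' covariate distribution of the analysis rows (continuous covariates at
#' their means, categorical covariates at their observed proportions — the
#' two are equivalent for a linear model). Standard errors by the delta
#' method; t-quantile CIs.
#'
#' @param assoc A group-form `dii_assoc`, or an `ols_fit` whose model
#'   contains `group_var` as a factor.
#' @param group_var Grouping factor name (default `"dii_group"`).
#' @return Tibble: `dii_group`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @export
ls_means <- function(assoc, group_var = "dii_group") {
  if (inherits(assoc, "dii_assoc")) {
    assert_that(assoc$form == "groups", "ls_means requires a group-form model")
    fit <- assoc$ols$fit
  } else if (inherits(assoc, "ols_fit")) {
    fit <- assoc$fit
  } else {
    rlang::abort("ls_means requires a dii_assoc or ols_fit")
  }
  dat <- fit$model
  check_columns(dat, group_var, "model frame")
  groups <- levels(dat[[group_var]])
  V <- stats::vcov(fit)
  beta <- stats::coef(fit)
  rows <- purrr::map(groups, function(g) {
    dg <- dat
    dg[[group_var]] <- factor(g, levels = groups)
    X <- stats::model.matrix(stats::delete.response(stats::terms(fit)), dg)
    xbar <- colMeans(X)
    est <- sum(xbar * beta)
    se <- sqrt(drop(t(xbar) %*% V %*% xbar))
    tibble::tibble(dii_group = g, estimate = est, std.error = se)
  })
  out <- dplyr::bind_rows(rows)
  ci <- t_ci(out$estimate, out$std.error, fit$df.residual)
  out$conf.low <- ci$conf.low; out$conf.high <- ci$conf.high
  out
}

# Covariates to drop within strata of a modifier (the variable the modifier
# is derived from; continuous age stays in age strata).
stratum_dropped_covariates <- function(modifier) {
  switch(modifier,
         prs_tertile = "prs_ad",
         sex = "sex",
         bmi_category = "bmi",
         apoe4 = "apoe4",
         character(0))
}

#' Stratified analysis with a pooled interaction test
#'
#' Fits the DII-BAG model separately within strata of an effect modifier
#' (excluding from the covariate list the variable the modifier is derived
#' from) and tests DII x modifier interaction in the pooled model by a joint
#' Wald/F test on the product terms.
#'
#' @param data Analysis tibble (see [dii_bag_association()]).
#' @param modifier Column name of the modifier (e.g. `"age_group"`,
#'   `"prs_tertile"`, `"apoe4"`, `"sex"`, `"bmi_category"`, `"waist_risk"`).
#' @param form,adjustment,age_var As in [dii_bag_association()].
#' @return List: `strata` (long tibble of per-stratum DII coefficients),
#'   `interaction` (one-row tibble: F statistic, df, p-value), `skipped`
#'   (strata skipped for emptiness, with reasons).
#' @export
stratified_and_interaction <- function(data, modifier,
                                       form = c("groups", "continuous"),
                                       adjustment = c("multivariable", "basic"),
                                       age_var = "age_baseline") {
  form <- match.arg(form); adjustment <- match.arg(adjustment)
  data <- prepare_analysis_data(data)
  check_columns(data, modifier, "analysis data")
  mod <- data[[modifier]]
  if (!is.factor(mod)) mod <- factor(mod)
  data$.modifier <- mod
  levs <- levels(mod)
  exposure <- if (form == "continuous") "dii" else "dii_group"
  covars <- setdiff(adjustment_covariates(adjustment, age_var),
                    stratum_dropped_covariates(modifier))

  strata <- list(); skipped <- list()
  for (lv in levs) {
    sub <- data[!is.na(data$.modifier) & data$.modifier == lv, , drop = FALSE]
    n_ok <- sum(stats::complete.cases(sub[, c("bag", exposure, covars)]))
    if (n_ok < length(covars) + 6) {
      rlang::warn(sprintf("stratum '%s' skipped: %d usable rows", lv, n_ok))
      skipped[[lv]] <- sprintf("insufficient rows (%d)", n_ok)
      next
    }
    f <- stats::as.formula(paste("bag ~", paste(c(exposure, covars), collapse = " + ")))
    ols <- fit_linear(sub, f)
    res <- ols$result[grepl("^dii", ols$result$term), , drop = FALSE]
    res$stratum <- lv; res$n <- ols$n_used
    strata[[lv]] <- res
  }
  assert_that(length(strata) >= 2, "fewer than 2 non-empty strata")

  base_f <- paste("bag ~", paste(c(exposure, covars, ".modifier"),
                                 collapse = " + "))
  int_f <- paste(base_f, "+", exposure, ":.modifier")
  pooled0 <- fit_linear(data, stats::as.formula(base_f))
  pooled1 <- fit_linear(data, stats::as.formula(int_f))
  an <- stats::anova(pooled0$fit, pooled1$fit)
  interaction <- tibble::tibble(modifier = modifier, form = form,
                                statistic = an$F[2], df = an$Df[2],
                                df.residual = an$Res.Df[2],
                                p.value = an$`Pr(>F)`[2])
  list(strata = dplyr::bind_rows(strata), interaction = interaction,
       skipped = skipped)
}
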