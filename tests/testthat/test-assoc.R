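test_that("exact linear data is fit exactly", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  fit <- suppressWarnings(fit_linear(d, y ~ x))  # perfect-fit summary note
  expect_equal(fit$result$estimate, c(1, 2), tolerance = 1e-12)
  expect_lt(max(fit$result$std.error), 1e-10)
})

test_that("orthogonal predictors carry their simple-regression slopes", {
  x1 <- rep(c(-1, 1), each = 8)
  x2 <- rep(c(-1, 1), times = 8)
  set.seed(2)
  y <- 3 * x1 - 2 * x2 + rnorm(16)
  fit <- fit_linear(tibble::tibble(x1 = x1, x2 = x2, y = y), y ~ x1 + x2)
  s1 <- coef(lm(y ~ x1))[2]
  s2 <- coef(lm(y ~ x2))[2]
  expect_equal(fit$result$estimate[2], unname(s1), tolerance = 1e-10)
  expect_equal(fit$result$estimate[3], unname(s2), tolerance = 1e-10)
})

test_that("OLS matches the normal-equations oracle on random designs", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 500
    X <- matrix(rnorm(n * 8), n, 8)
    colnames(X) <- paste0("x", 1:8)
    y <- X %*% runif(8, -2, 2) + rnorm(n)
    d <- tibble::as_tibble(as.data.frame(X))
    d$y <- as.vector(y)
    fit <- fit_linear(d, y ~ .)
    Xd <- cbind(1, X)
    oracle <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
    expect_equal(fit$result$estimate, as.vector(oracle), tolerance = 1e-8)
  }
})

test_that("rank deficiency errors name the collinear column; missing rows are counted", {
  d <- tibble::tibble(x = 1:20, x2 = 2 * (1:20), y = rnorm(20))
  expect_error(fit_linear(d, y ~ x + x2), "x2")
  d2 <- tibble::tibble(x = c(1:18, NA, 20), y = rnorm(20))
  fit <- fit_linear(d2, y ~ x)
  expect_equal(fit$n_used, 19)
  expect_equal(fit$n_dropped, 1)
})

test_that("association metadata and group contrasts round-trip into tidy output", {
  sc <- small_cohort(n = 1200, seed = 33)
  analysis <- build_true_bag_analysis(sc$cohort, sc$ref)
  fit_c <- dii_bag_association(analysis, "continuous", "basic")
  res <- tidy(fit_c)
  expect_equal(res$term, "dii")
  expect_equal(res$form, "continuous")
  expect_equal(res$adjustment, "basic")
  fit_g <- dii_bag_association(analysis, "groups", "multivariable")
  res_g <- tidy(fit_g)
  expect_equal(res_g$term, paste0("dii_group", c("g2", "g3", "g4")))
  # group 1 is the reference: no coefficient for it
  expect_false(any(grepl("g1", res_g$term)))
  gl <- glance(fit_g)
  expect_equal(gl$nobs, fit_g$n_used)
  # continuous and group fits use the identical row set
  expect_equal(fit_c$n_used + fit_c$n_dropped, fit_g$n_used + fit_g$n_dropped)
})

test_that("the multivariable model recovers a planted group-4 shift within 3 SE", {
  ref <- generate_reference(11, 5)
  cfg <- sim_config(8000, seed = 35, n_idps = 12, beta_dii_bag = 0,
                    prop_mediated_true = 0,
                    group_effects = c(g2 = 0, g3 = 0.25, g4 = 0.5))
  co <- generate_cohort(cfg, ref)
  analysis <- build_true_bag_analysis(co, ref)
  res <- tidy(dii_bag_association(analysis, "groups", "multivariable"))
  g4 <- res[res$term == "dii_groupg4", ]
  expect_lt(abs(g4$estimate - 0.5), 3 * g4$std.error)
})

test_that("unadjusted LS-means collapse to raw group means", {
  sc <- small_cohort(n = 800, seed = 37)
  analysis <- build_true_bag_analysis(sc$cohort, sc$ref)
  analysis$dii_group <- factor(analysis$dii_group, levels = 1:4,
                               labels = paste0("g", 1:4))
  analysis$dii_group <- droplevels(analysis$dii_group)
  fit <- fit_linear(analysis, bag ~ dii_group)
  lsm <- ls_means(fit)
  raw <- tapply(analysis$bag, analysis$dii_group, mean)
  expect_equal(lsm$estimate, as.vector(raw[lsm$dii_group]), tolerance = 1e-10)
})

test_that("adjusted LS-means match explicit prediction-grid averaging and emmeans", {
  sc <- small_cohort(n = 1500, seed = 39)
  analysis <- build_true_bag_analysis(sc$cohort, sc$ref)
  fit <- dii_bag_association(analysis, "groups", "multivariable")
  lsm <- ls_means(fit)
  # oracle 1: average predict() over the observed rows per counterfactual group
  dat <- fit$ols$fit$model
  for (g in levels(dat$dii_group)) {
    dg <- dat
    dg$dii_group <- factor(g, levels = levels(dat$dii_group))
    expect_equal(lsm$estimate[lsm$dii_group == g],
                 mean(predict(fit$ols$fit, newdata = dg)), tolerance = 1e-10)
  }
  # oracle 2: emmeans with proportional weighting
  skip_if_not_installed("emmeans")
  em <- as.data.frame(emmeans::emmeans(fit$ols$fit, "dii_group",
                                       weights = "proportional"))
  expect_equal(lsm$estimate, em$emmean, tolerance = 1e-8)
})

test_that("stratified fits order planted heterogeneous effects; empty strata are skipped", {
  set.seed(41)
  n <- 4000
  d <- tibble::tibble(
    dii = rnorm(n, 0, 2),
    age_baseline = runif(n, 40, 70),
    sex = sample(c("female", "male"), n, TRUE),
    race_white = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.9, 0.1)),
    education_degree = sample(c(TRUE, FALSE), n, TRUE),
    townsend = rnorm(n)
  )
  d$age_group <- derive_age_group(d$age_baseline)
  older <- d$age_group == "older"
  d$bag <- ifelse(older, 0.5, 0.25) * d$dii + rnorm(n, 0, 2)
  st <- stratified_and_interaction(d, "age_group", form = "continuous",
                                   adjustment = "basic")
  est <- setNames(st$strata$estimate, st$strata$stratum)
  expect_gt(est[["older"]], est[["middle"]])
  expect_lt(st$interaction$p.value, 0.05)
  expect_equal(st$interaction$df, 1)

  d_empty <- d[d$age_group == "middle", ]
  d_empty$age_group <- droplevels(d_empty$age_group)
  levels(d_empty$age_group) <- c("middle", "older")
  expect_error(
    suppressWarnings(stratified_and_interaction(d_empty, "age_group",
                                                form = "continuous",
                                                adjustment = "basic")),
    "fewer than 2")
})

test_that("stratified estimates on homogeneous data average to the pooled estimate", {
  ref <- generate_reference(11, 5)
  cfg <- sim_config(6000, seed = 43, n_idps = 12, beta_dii_bag = 0.3,
                    prop_mediated_true = 0)
  co <- generate_cohort(cfg, ref)
  analysis <- build_true_bag_analysis(co, ref)
  pooled <- tidy(dii_bag_association(analysis, "continuous", "multivariable"))
  st <- stratified_and_interaction(analysis, "age_group", form = "continuous",
                                   adjustment = "multivariable")
  w_mean <- sum(st$strata$estimate * st$strata$n) / sum(st$strata$n)
  expect_lt(abs(w_mean - pooled$estimate), 2 * pooled$std.error)
})
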