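make_mediation_toy <- function(n = 400, a = 0.5, b = 0.8, c_prime = 0.3,
                               seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  m <- a * x + rnorm(n)
  y <- c_prime * x + b * m + rnorm(n)
  tibble::tibble(dii = x, infla = m, bag = y,
                 age_baseline = runif(n, 40, 70),
                 sex = sample(c("female", "male"), n, TRUE),
                 race_white = sample(c(TRUE, FALSE), n, TRUE),
                 education_degree = sample(c(TRUE, FALSE), n, TRUE),
                 townsend = rnorm(n))
}

test_that("an exposure-independent mediator gives ACME zero by construction", {
  d <- make_mediation_toy(a = 0, seed = 2)
  d$infla <- rnorm(nrow(d))  # fully severed path
  d$bag <- 0.3 * d$dii + rnorm(nrow(d))
  est <- mediation_point_estimate(d, adjustment = "basic")
  expect_lt(abs(est$acme), 0.05)
  expect_equal(est$acme, est$a * est$b, tolerance = 1e-12)
})

test_that("a fully mediated chain drives the proportion mediated to one", {
  set.seed(3)
  n <- 4000
  d <- make_mediation_toy(n = n, a = 1, b = 1, c_prime = 0, seed = 3)
  est <- mediation_point_estimate(d, adjustment = "basic")
  expect_lt(abs(est$prop_mediated - 1), 0.15)
})

test_that("ACME + ADE equals the total effect exactly, and equals the marginal model", {
  d <- make_mediation_toy(n = 200, seed = 4)
  covars <- adjustment_covariates("basic")
  est <- mediation_point_estimate(d, adjustment = "basic")
  expect_equal(est$acme + est$ade, est$total, tolerance = 1e-12)
  # model (1): outcome on exposure without the mediator, same rows
  f1 <- fit_linear(d, as.formula(paste("bag ~ dii +",
                                       paste(covars, collapse = " + "))))
  total_marginal <- f1$result$estimate[f1$result$term == "dii"]
  expect_equal(est$total, total_marginal, tolerance = 1e-10)
})

test_that("bootstrap mediation is deterministic under a fixed seed and exact per replicate", {
  d <- make_mediation_toy(n = 300, seed = 5)
  b1 <- bootstrap_mediation(d, adjustment = "basic", n_boot = 200, seed = 9)
  b2 <- bootstrap_mediation(d, adjustment = "basic", n_boot = 200, seed = 9)
  expect_identical(b1$estimates, b2$estimates)
  # the linear-mediation identity holds on every replicate
  expect_lt(max(abs(b1$replicates$acme + b1$replicates$ade -
                      b1$replicates$total)), 1e-10)
  expect_error(bootstrap_mediation(d, n_boot = 50), ">= 100")
})

test_that("a null chain yields an ACME interval covering zero", {
  d <- make_mediation_toy(n = 600, a = 0, b = 0, c_prime = 0, seed = 6)
  b <- bootstrap_mediation(d, adjustment = "basic", n_boot = 300, seed = 11)
  acme <- b$estimates[b$estimates$effect == "acme", ]
  expect_lt(acme$conf.low, 0)
  expect_gt(acme$conf.high, 0)
})

test_that("degenerate replicate totals are excluded and flagged when pervasive", {
  d <- make_mediation_toy(n = 300, seed = 7)
  expect_warning(
    b <- bootstrap_mediation(d, adjustment = "basic", n_boot = 150, seed = 13,
                             degenerate_tol = 10),
    "unstable")
  expect_equal(b$n_degenerate, 150)
  expect_true(b$prop_ci_unstable)
})

test_that("baseline-only DII uses only the baseline cycle and excludes online-only diets", {
  ref <- tiny_reference()
  diet <- tibble::tibble(
    participant_id = c("A", "A", "A", "B", "B"),
    cycle = c("baseline", "online1", "online2", "online1", "online3"),
    energy_kcal = c(2000, 2000, 2000, 2000, 2000),
    alpha = c(12, 30, 40, 10, 11),
    beta = c(20, 25, 10, 20, 21),
    gamma = c(30, 35, 20, 30, 29))
  sex <- tibble::tibble(participant_id = c("A", "B"),
                        sex = c("female", "male"))
  res <- baseline_only_dii(diet, ref, sex)
  expect_equal(res$participant_id, "A")
  expect_equal(attr(res, "n_excluded"), 1)
  # equals scoring the single baseline assessment directly
  direct <- compute_dii(tibble::tibble(participant_id = "A", alpha = 12,
                                       beta = 20, gamma = 30), ref)
  expect_equal(res$dii, direct$dii)
})

test_that("baseline and averaged DII correlate positively but imperfectly over time", {
  sc <- small_cohort(n = 800, seed = 45)
  filt <- filter_plausible_assessments(
    sc$cohort$diet, sc$cohort$covariates[, c("participant_id", "sex")])
  averaged <- compute_dii(average_intakes(filt$kept), sc$ref)
  base <- baseline_only_dii(sc$cohort$diet, sc$ref,
                            sc$cohort$covariates[, c("participant_id", "sex")])
  merged <- dplyr::inner_join(averaged, base, by = "participant_id",
                              suffix = c("_avg", "_base"))
  # restrict to participants with additional non-baseline assessments
  multi <- merged[merged$n_assessments_used_avg > 1, ]
  r <- cor(multi$dii_avg, multi$dii_base)
  expect_gt(r, 0.3)
  expect_lt(r, 0.999)
})

test_that("mediation on a generated cohort recovers the planted decomposition", {
  ref <- generate_reference(31, 5)  # full-width reference: DII spread ~2
  cfg <- sim_config(6000, seed = 47, n_idps = 12, beta_dii_bag = 0.5,
                    prop_mediated_true = 0.3,
                    assessment_scheme = "baseline_only")
  co <- generate_cohort(cfg, ref)
  analysis <- build_true_bag_analysis(co, ref)
  med <- bootstrap_mediation(analysis, adjustment = "multivariable",
                             n_boot = 300, seed = 7)
  params <- attr(co$truth, "params")
  est <- med$estimates
  acme <- est[est$effect == "acme", ]
  total <- est[est$effect == "total", ]
  # the planted decomposition sits inside the bootstrap intervals
  expect_gt(params$acme, acme$conf.low)
  expect_lt(params$acme, acme$conf.high)
  expect_gt(0.5, total$conf.low)
  expect_lt(0.5, total$conf.high)
})
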