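test_that("energy-plausibility filter applies sex-specific inclusive bounds", {
  assessments <- tibble::tibble(
    participant_id = c("F1", "F1", "M1", "F2", "M2"),
    energy_kcal = c(550, 1800, 4300, 600, 4200),
    alpha = 1:5
  )
  sex <- tibble::tibble(participant_id = c("F1", "M1", "F2", "M2"),
                        sex = c("female", "male", "female", "male"))
  res <- filter_plausible_assessments(assessments, sex)

  # female with 550 and 1800 kcal: one kept, participant retained
  f1 <- res$report[res$report$participant_id == "F1", ]
  expect_equal(f1$n_kept, 1)
  expect_false(f1$excluded)
  expect_true("F1" %in% res$kept$participant_id)

  # male with a single 4300 kcal assessment: excluded entirely
  m1 <- res$report[res$report$participant_id == "M1", ]
  expect_equal(m1$n_kept, 0)
  expect_true(m1$excluded)

  # boundary values are kept (exclusion is strictly < 600 / > 4200)
  expect_true("F2" %in% res$kept$participant_id)
  expect_true("M2" %in% res$kept$participant_id)
})

test_that("unknown or missing sex codes fail loudly, naming the participant", {
  assessments <- tibble::tibble(participant_id = "X1", energy_kcal = 2000)
  expect_error(
    filter_plausible_assessments(
      assessments, tibble::tibble(participant_id = "X1", sex = "unknown")),
    "X1")
  expect_error(
    filter_plausible_assessments(
      assessments, tibble::tibble(participant_id = "Y9", sex = "female")),
    "X1")
})

test_that("intake averaging is the arithmetic mean over kept assessments", {
  kept <- tibble::tibble(
    participant_id = c("A", "A", "B", rep("C", 5)),
    energy_kcal = c(2000, 2200, 1500, rep(1800, 5)),
    alpha = c(10, 20, 7, 12.3, 8.1, 15.5, 9.9, 11.0)
  )
  avg <- average_intakes(kept)
  expect_equal(avg$alpha[avg$participant_id == "A"], 15)
  expect_equal(avg$n_assessments_used[avg$participant_id == "A"], 2L)
  # single assessment: identity
  expect_equal(avg$alpha[avg$participant_id == "B"], 7)
  # five assessments: direct sum/5 recomputation
  expect_equal(avg$alpha[avg$participant_id == "C"],
               (12.3 + 8.1 + 15.5 + 9.9 + 11.0) / 5)
})

test_that("a mean-intake diet scores exactly zero", {
  res <- compute_dii(tiny_intakes(c(0, 0, 0)), tiny_reference())
  expect_identical(res$dii, 0)
  expect_equal(res$dii_group, 3L)
})

test_that("DII matches the hand-computed centered-percentile oracle", {
  # z = (1, -1, 0); tabulated Phi(1) = 0.8413447
  res <- compute_dii(tiny_intakes(c(1, -1, 0)), tiny_reference(),
                     contributions = TRUE)
  phi1 <- 0.8413447
  expected <- (2 * phi1 - 1) * 0.5 + (2 * (1 - phi1) - 1) * (-0.3) + 0 * 0.2
  expect_equal(res$dii, expected, tolerance = 1e-6)
  contrib <- attr(res, "contributions")
  expect_equal(sum(contrib$contribution), res$dii)
  expect_equal(contrib$centered_percentile[contrib$parameter == "gamma"], 0)
})

test_that("extreme intakes saturate at the weight and respect the global bound", {
  ref <- tibble::tibble(parameter = "solo", weight = -0.663,
                        global_mean = 5, global_sd = 1)
  huge <- tibble::tibble(participant_id = "A", solo = 5 + 1000)
  res <- compute_dii(huge, ref)
  expect_equal(res$dii, -0.663, tolerance = 1e-8)
  expect_lte(abs(res$dii), sum(abs(ref$weight)))
})

test_that("DII is monotone in each parameter in the direction of its weight", {
  ref <- tiny_reference()
  base <- compute_dii(tiny_intakes(c(0.2, -0.1, 0.5)), ref)$dii
  up_pos <- compute_dii(tiny_intakes(c(1.2, -0.1, 0.5)), ref)$dii  # w > 0
  up_neg <- compute_dii(tiny_intakes(c(0.2, 0.9, 0.5)), ref)$dii   # w < 0
  expect_gte(up_pos, base)
  expect_lte(up_neg, base)
})

test_that("DII is invariant to affine rescaling of a parameter's units", {
  ref <- tiny_reference()
  intake <- tiny_intakes(c(0.7, -1.3, 0.4))
  a <- 2.5; b <- 7
  ref2 <- ref
  ref2$global_mean[1] <- a * ref$global_mean[1] + b
  ref2$global_sd[1] <- a * ref$global_sd[1]
  intake2 <- intake
  intake2$alpha <- a * intake$alpha + b
  expect_equal(compute_dii(intake2, ref2)$dii, compute_dii(intake, ref)$dii)
})

test_that("subset scoring requires the allow-missing flag and warns", {
  intake <- tiny_intakes(c(1, 0, 0))[, c("participant_id", "alpha", "beta")]
  expect_error(compute_dii(intake, tiny_reference()), "gamma")
  expect_warning(res <- compute_dii(intake, tiny_reference(),
                                    allow_missing = TRUE),
                 "gamma")
  expect_equal(res$dii, (2 * pnorm(1) - 1) * 0.5, tolerance = 1e-10)
})

test_that("reference validation rejects malformed tables", {
  ref <- tiny_reference()
  bad_sd <- ref; bad_sd$global_sd[2] <- 0
  expect_error(compute_dii(tiny_intakes(), bad_sd), "beta")
  dup <- ref; dup$parameter[2] <- "alpha"
  expect_error(validate_reference(dup), "unique")
})

test_that("the four DII groups partition the line with the stated boundaries", {
  expect_equal(assign_dii_group(c(-2, 0, 2)), c(2L, 3L, 4L))
  expect_equal(assign_dii_group(c(-2.0001, -0.0001, 1.9999, 5)),
               c(1L, 2L, 3L, 4L))
  expect_error(assign_dii_group(Inf), "finite")
  # every finite value lands in exactly one group
  x <- seq(-12, 12, length.out = 201)
  g <- assign_dii_group(x)
  expect_true(all(g %in% 1:4))
})

test_that("stability diagnostics match the textbook Pearson and Bland-Altman formulas", {
  x <- c(1.2, -0.4, 2.2, 0.3, -1.8, 0.9, 1.5, -0.2, 0.0, 2.8)
  y <- c(0.8, 0.1, 1.9, -0.5, -1.2, 1.4, 1.1, 0.4, -0.3, 2.1)
  res <- dii_stability(x, y)
  # direct sum-based formulas, independent of cor()/sd()
  n <- length(x)
  r_manual <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  d <- x - y
  sd_manual <- sqrt(sum((d - mean(d))^2) / (n - 1))
  expect_equal(res$pearson_r, r_manual, tolerance = 1e-12)
  expect_equal(res$mean_diff, mean(d))
  expect_equal(res$loa_upper, mean(d) + 1.96 * sd_manual, tolerance = 1e-12)

  ident <- dii_stability(x, x)
  expect_equal(ident$pearson_r, 1)
  expect_equal(ident$mean_diff, 0)
  anti <- dii_stability(x, -x)
  expect_equal(anti$pearson_r, -1)

  expect_message(flat <- dii_stability(rep(1, 5), c(1, 2, 3, 4, 5)),
                 "zero variance")
  expect_true(is.na(flat$pearson_r))
})
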