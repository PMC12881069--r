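test_that("the healthy subset excludes any flagged or unflagged-missing participant", {
  covars <- tibble::tibble(
    participant_id = c("A", "B", "C", "D", "E"),
    stroke = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    t2d = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    longstanding_illness = c(FALSE, FALSE, FALSE, FALSE, NA),
    self_rated_health = c("good", "excellent", "good", "fair", "good"))
  ids <- select_healthy_subset(covars)
  expect_equal(as.character(ids), "A")
  counts <- attr(ids, "counts")
  expect_equal(unname(counts["missing_flags"]), 1)
})

test_that("healthy-subset size matches a direct boolean-mask count on synthetic draws", {
  sc <- small_cohort(n = 500)
  covars <- derive_covariates(sc$cohort$covariates)
  ids <- select_healthy_subset(covars)
  mask <- !covars$stroke & !covars$t2d & !covars$longstanding_illness &
    !covars$self_rated_health %in% c("fair", "poor") &
    !is.na(covars$t2d)
  expect_equal(length(ids), sum(mask, na.rm = TRUE))
})

test_that("the 4:1 split reproduces the printed sizes and is a seeded partition", {
  ids <- sprintf("H%04d", 1:4355)
  sp <- split_train_validation(ids, seed = 3)
  expect_length(sp$train, 3484)
  expect_length(sp$validation, 871)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), ids)
  sp2 <- split_train_validation(ids, seed = 3)
  expect_identical(sp, sp2)
  tiny <- split_train_validation(letters[1:5], seed = 1)
  expect_length(tiny$train, 4)
  expect_error(split_train_validation(letters[1:4]), "at least 5")
})

test_that("standardization constants come from training rows only", {
  idps <- tibble::tibble(participant_id = sprintf("P%02d", 1:20),
                         f1 = rnorm(20, 50, 5), f2 = rnorm(20, -3, 2))
  train <- idps$participant_id[1:12]
  std <- standardize_idps(idps, train)
  tr <- std$standardized$participant_id %in% train
  expect_lt(max(abs(colMeans(std$standardized[tr, c("f1", "f2")]))), 1e-10)
  expect_lt(max(abs(apply(std$standardized[tr, c("f1", "f2")], 2, sd) - 1)),
            1e-10)
  # held-out rows: independent two-pass recomputation
  mu <- mean(idps$f1[1:12]); s <- sd(idps$f1[1:12])
  expect_equal(std$standardized$f1[13:20], (idps$f1[13:20] - mu) / s,
               tolerance = 1e-12)
  # a row at the training mean maps to zero
  probe <- tibble::tibble(participant_id = "Q", f1 = mu,
                          f2 = mean(idps$f2[1:12]))
  std2 <- standardize_idps(dplyr::bind_rows(idps, probe), train)
  expect_equal(unlist(std2$standardized[21, c("f1", "f2")]),
               c(f1 = 0, f2 = 0), tolerance = 1e-12)
})

test_that("zero-variance IDPs are dropped with a warning, not imputed", {
  idps <- tibble::tibble(participant_id = sprintf("P%02d", 1:10),
                         f1 = rnorm(10), flat = rep(2, 10))
  expect_warning(std <- standardize_idps(idps, idps$participant_id[1:6]),
                 "flat")
  expect_equal(std$dropped, "flat")
  expect_false("flat" %in% names(std$standardized))
})

test_that("a pure age signal is learned to near-zero MAE; the grid selects by MAE", {
  set.seed(1)
  n <- 300; p <- 15
  age <- runif(n, 45, 80)
  x <- outer(age, runif(p, 0.3, 1)) + matrix(rnorm(n * p, 0, 1e-6), n, p)
  colnames(x) <- paste0("f", 1:p)
  x <- scale(x)
  m <- train_and_select(x[1:240, ], age[1:240], x[241:300, ], age[241:300],
                        grid = "lasso", seed = 2)
  expect_s3_class(m, "brainage_model")
  expect_equal(m$kind, "lasso")  # singleton grid returns that model
  expect_lt(m$validation_mae, 0.1)
  expect_equal(m$validation_mae, min(m$mae_table$validation_mae))
})

test_that("the full model grid runs and the selected cell attains the minimum MAE", {
  skip_if_not_installed("xgboost")
  skip_if_not_installed("e1071")
  set.seed(4)
  n <- 120; p <- 12
  age <- runif(n, 45, 80)
  x <- outer(age, runif(p, 0.3, 1)) + matrix(rnorm(n * p, 0, 3), n, p)
  colnames(x) <- paste0("f", 1:p)
  x <- scale(x)
  m <- train_and_select(x[1:90, ], age[1:90], x[91:120, ], age[91:120],
                        grid = "full", seed = 2, search_budget = 3)
  expect_equal(nrow(m$mae_table), 6)  # 3 predictors x 2 selection modes
  expect_equal(m$validation_mae, min(m$mae_table$validation_mae))
})

test_that("bias-correction coefficients match closed-form least squares", {
  age <- c(50, 55, 60, 65, 70)
  bc <- fit_bias_correction(age, age)
  expect_equal(bc$alpha, 1)
  expect_equal(bc$beta, 0)
  bc2 <- fit_bias_correction(0.5 * age + 30, age)
  expect_equal(bc2$alpha, 0.5)
  expect_equal(bc2$beta, 30)
  set.seed(9)
  pred <- 0.7 * age + 18 + rnorm(5, 0, 0.5)
  bc3 <- fit_bias_correction(pred, age)
  # normal-equations oracle
  X <- cbind(1, age)
  beta_hat <- solve(t(X) %*% X, t(X) %*% pred)
  expect_equal(bc3$beta, beta_hat[1], tolerance = 1e-10)
  expect_equal(bc3$alpha, beta_hat[2], tolerance = 1e-10)
  expect_error(fit_bias_correction(rep(3, 5), age), "slope is zero")
})

test_that("the correction inverts the training regression: slope 1, intercept 0", {
  expect_equal(apply_bias_correction(65, 1, 0), 65)
  expect_equal(apply_bias_correction(65, 0.5, 30), 70)
  set.seed(11)
  age <- runif(200, 45, 80)
  pred <- 0.72 * age + 17 + rnorm(200, 0, 2)
  bc <- fit_bias_correction(pred, age)
  corrected <- apply_bias_correction(pred, bc$alpha, bc$beta)
  refit <- coef(lm(corrected ~ age))
  expect_equal(unname(refit[2]), 1, tolerance = 1e-8)
  expect_equal(unname(refit[1]), 0, tolerance = 1e-6)
  expect_error(apply_bias_correction(65, 0, 3), "nonzero")
})

test_that("BAG is corrected brain age minus scan age with the stated sign", {
  bag <- compute_bag(c(66, 64), c(64, 64), c("A", "B"))
  expect_equal(bag$bag, c(2, 0))
  expect_error(compute_bag(60, -1), "positive")
})

test_that("deleting test rows changes neither constants, model, nor correction", {
  sc <- small_cohort(n = 500, seed = 15)
  covars <- derive_covariates(sc$cohort$covariates)
  idp <- generate_idps(sc$cohort$truth, sc$cfg)
  fit_full <- estimate_brain_age(idp$idps, covars, seed = 5)
  test_ids <- fit_full$bag$participant_id[fit_full$bag$subset == "test"]
  drop_ids <- head(test_ids, 40)
  idp_sub <- idp$idps[!idp$idps$participant_id %in% drop_ids, ]
  fit_sub <- estimate_brain_age(idp_sub, covars, seed = 5)
  expect_identical(fit_sub$constants, fit_full$constants)
  expect_identical(fit_sub$alpha, fit_full$alpha)
  expect_identical(fit_sub$beta, fit_full$beta)
  kept <- fit_full$bag$participant_id %in% fit_sub$bag$participant_id
  expect_equal(fit_sub$bag$bag, fit_full$bag$bag[kept], tolerance = 1e-12)
})

test_that("rows with missing IDPs are excluded and counted before modeling", {
  sc <- small_cohort(n = 300, seed = 19)
  covars <- derive_covariates(sc$cohort$covariates)
  idp <- generate_idps(sc$cohort$truth, sc$cfg)
  idp$idps[3, 5] <- NA
  idp$idps[9, 2] <- NA
  expect_message(fit <- estimate_brain_age(idp$idps, covars, seed = 5),
                 "2 participant")
  expect_equal(fit$exclusions$missing_idps, 2)
  expect_equal(nrow(fit$bag), 298)
})

test_that("estimated BAG tracks true BAG with near-unit slope at default noise", {
  ref <- generate_reference(11, 5)
  cfg <- sim_config(6000, seed = 23, prop_mediated_true = 0)  # default 200 IDPs
  co <- generate_cohort(cfg, ref)
  covars <- derive_covariates(co$covariates)
  idp <- generate_idps(co$truth, cfg)
  fit <- estimate_brain_age(idp$idps, covars, seed = 5)
  merged <- dplyr::inner_join(fit$bag[, c("participant_id", "bag")],
                              co$truth, by = "participant_id")
  slope <- coef(lm(bag ~ true_bag, merged))[2]
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.1)
})
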