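#' Brain age estimation and the brain age gap
#'
#' Brain age is predicted from imaging-derived phenotypes (IDPs) by a model
#' trained on a healthy subset (in whom brain age should match chronological
#' age), selected by validation mean absolute error (MAE), bias-corrected for
#' the regression-to-the-mean of age predictions, and applied to the whole
#' cohort. The brain age gap (BAG) is corrected brain age minus chronological
#' age at scan; BAG > 0 denotes an older-looking brain.
#'
#' @name brainage
NULL

#' Select the healthy model-building subset
#'
#' Retains participants free of stroke, type 2 diabetes, long-term illness/
#' disability/frailty, and fair-or-poor self-rated health. A participant with
#' any of these flags missing is conservatively excluded (and counted).
#'
#' @param covars Derived covariate tibble with columns `stroke`, `t2d`,
#'   `longstanding_illness`, `self_rated_health`.
#' @return Character vector of participant ids, with attribute `"counts"`
#'   (per-criterion exclusion counts, overlapping).
#' @export
select_healthy_subset <- function(covars) {
  check_columns(covars, c("participant_id", "stroke", "t2d",
                          "longstanding_illness", "self_rated_health"),
                "covariates")
  fair_poor <- covars$self_rated_health %in% c("fair", "poor")
  fair_poor[is.na(covars$self_rated_health)] <- NA
  flags <- cbind(stroke = covars$stroke, t2d = covars$t2d,
                 longstanding = covars$longstanding_illness,
                 fair_poor_health = fair_poor)
  any_missing <- rowSums(is.na(flags)) > 0
  healthy <- !any_missing & rowSums(flags, na.rm = TRUE) == 0
  ids <- covars$participant_id[healthy]
  attr(ids, "counts") <- c(colSums(flags, na.rm = TRUE),
                           missing_flags = sum(any_missing))
  ids
}

#' Random 4:1 train/validation split
#'
#' `round(0.8 * n)` ids (round-half-away-from-zero) go to training after a
#' seeded shuffle; the rest to validation. Disjoint and exhaustive.
#'
#' @param ids Vector of at least 5 ids.
#' @param ratio Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return List `train`, `validation`.
#' @export
split_train_validation <- function(ids, ratio = 0.8, seed = 1L) {
  n <- length(ids)
  assert_that(n >= 5, "at least 5 ids required for a 4:1 split (got %d)", n)
  n_train <- floor(ratio * n + 0.5)  # round half away from zero (positive n)
  with_seed(seed, {
    shuffled <- sample(ids, n)
    list(train = shuffled[seq_len(n_train)],
         validation = shuffled[(n_train + 1):n])
  })
}

#' Leakage-free IDP standardization
#'
#' Means and SDs are computed exclusively from training rows and applied to
#' all rows. Columns with zero training SD are dropped with a warning, never
#' silently imputed.
#'
#' @param idps IDP tibble (`participant_id` + numeric columns).
#' @param train_ids Ids of training rows.
#' @return List: `standardized` (tibble, all rows), `constants` (tibble
#'   `idp`, `mean`, `sd`), `dropped` (character).
#' @export
standardize_idps <- function(idps, train_ids) {
  check_columns(idps, "participant_id", "IDP matrix")
  feat <- setdiff(names(idps), "participant_id")
  train_rows <- idps$participant_id %in% train_ids
  assert_that(sum(train_rows) >= 2, "need at least 2 training rows")
  x_train <- as.matrix(idps[train_rows, feat, drop = FALSE])
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2, stats::sd)
  dropped <- feat[!is.finite(sdv) | sdv == 0]
  if (length(dropped) > 0) {
    rlang::warn(sprintf("dropping %d IDP(s) with zero training SD: %s",
                        length(dropped),
                        paste(head(dropped, 5), collapse = ", ")))
    feat <- setdiff(feat, dropped)
    mu <- mu[feat]; sdv <- sdv[feat]
  }
  x_all <- as.matrix(idps[, feat, drop = FALSE])
  z <- sweep(sweep(x_all, 2, mu, "-"), 2, sdv, "/")
  std <- dplyr::bind_cols(tibble::tibble(participant_id = idps$participant_id),
                          tibble::as_tibble(z))
  list(standardized = std,
       constants = tibble::tibble(idp = feat, mean = unname(mu), sd = unname(sdv)),
       dropped = dropped)
}

# ---- model zoo ---------------------------------------------------------------

fit_predictor <- function(kind, x, y, seed, search_budget = 8) {
  switch(kind,
    lasso = {
      # disable early path termination so a near-noiseless signal can reach
      # an effectively unpenalized fit
      old_ctl <- glmnet::glmnet.control()
      glmnet::glmnet.control(fdev = 0, devmax = 1)
      on.exit(do.call(glmnet::glmnet.control, old_ctl[c("fdev", "devmax")]),
              add = TRUE)
      cvfit <- with_seed(seed, glmnet::cv.glmnet(x, y, alpha = 1, nfolds = 5,
                                                 lambda.min.ratio = 1e-6,
                                                 nlambda = 120))
      list(kind = "lasso", fit = cvfit,
           n_nonzero = sum(as.vector(stats::coef(cvfit, s = "lambda.min"))[-1] != 0),
           predict = function(newx) {
             as.vector(stats::predict(cvfit, newx = newx, s = "lambda.min"))
           })
    },
    gbt = {
      if (!requireNamespace("xgboost", quietly = TRUE)) {
        rlang::abort("the gradient-boosted-trees grid cell requires the xgboost package")
      }
      grid <- with_seed(seed, tibble::tibble(
        eta = stats::runif(search_budget, 0.05, 0.3),
        max_depth = sample(2:6, search_budget, TRUE),
        nrounds = sample(80:300, search_budget, TRUE),
        subsample = stats::runif(search_budget, 0.7, 1)))
      folds <- with_seed(seed + 1L, sample(rep(1:3, length.out = nrow(x))))
      cv_mae <- vapply(seq_len(search_budget), function(i) {
        errs <- vapply(1:3, function(f) {
          tr <- folds != f
          bst <- xgboost::xgboost(x[tr, , drop = FALSE], y[tr],
                                  learning_rate = grid$eta[i],
                                  max_depth = grid$max_depth[i],
                                  nrounds = grid$nrounds[i],
                                  subsample = grid$subsample[i],
                                  objective = "reg:squarederror",
                                  nthreads = 1, verbosity = 0)
          mean(abs(stats::predict(bst, x[!tr, , drop = FALSE]) - y[!tr]))
        }, numeric(1))
        mean(errs)
      }, numeric(1))
      best <- which.min(cv_mae)
      bst <- xgboost::xgboost(x, y, learning_rate = grid$eta[best],
                              max_depth = grid$max_depth[best],
                              nrounds = grid$nrounds[best],
                              subsample = grid$subsample[best],
                              objective = "reg:squarederror",
                              nthreads = 1, verbosity = 0)
      list(kind = "gbt", fit = bst, hyper = grid[best, ], n_nonzero = NA_integer_,
           predict = function(newx) as.vector(stats::predict(bst, newx)))
    },
    svr = {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        rlang::abort("the support-vector-regression grid cell requires the e1071 package")
      }
      grid <- with_seed(seed, tibble::tibble(
        cost = 2^stats::runif(search_budget, -2, 6),
        gamma = 2^stats::runif(search_budget, -8, -2),
        epsilon = stats::runif(search_budget, 0.05, 0.5)))
      folds <- with_seed(seed + 1L, sample(rep(1:3, length.out = nrow(x))))
      cv_mae <- vapply(seq_len(search_budget), function(i) {
        errs <- vapply(1:3, function(f) {
          tr <- folds != f
          m <- e1071::svm(x[tr, , drop = FALSE], y[tr], type = "eps-regression",
                          cost = grid$cost[i], gamma = grid$gamma[i],
                          epsilon = grid$epsilon[i], scale = FALSE)
          mean(abs(stats::predict(m, x[!tr, , drop = FALSE]) - y[!tr]))
        }, numeric(1))
        mean(errs)
      }, numeric(1))
      best <- which.min(cv_mae)
      m <- e1071::svm(x, y, type = "eps-regression", cost = grid$cost[best],
                      gamma = grid$gamma[best], epsilon = grid$epsilon[best],
                      scale = FALSE)
      list(kind = "svr", fit = m, hyper = grid[best, ], n_nonzero = NA_integer_,
           predict = function(newx) as.vector(stats::predict(m, newx)))
    },
    rlang::abort(sprintf("unknown predictor kind '%s'", kind))
  )
}

# Recursive feature elimination with cross-validation: repeatedly halve the
# feature set by ranked importance (absolute LASSO coefficient, refit each
# round), choosing the subset size with lowest 3-fold CV MAE.
rfe_cv_select <- function(x, y, seed, min_size = 8) {
  p <- ncol(x)
  sizes <- c(); s <- p
  while (s >= min_size) { sizes <- c(sizes, s); s <- floor(s / 2) }
  if (length(sizes) == 0) sizes <- p
  folds <- with_seed(seed + 2L, sample(rep(1:3, length.out = nrow(x))))
  current <- colnames(x)
  results <- list()
  for (s in sizes) {
    if (length(current) > s) {
      cvfit <- with_seed(seed, glmnet::cv.glmnet(
        x[, current, drop = FALSE], y, alpha = 1, nfolds = 5))
      imp <- abs(as.vector(stats::coef(cvfit, s = "lambda.min"))[-1])
      current <- current[order(imp, decreasing = TRUE)][seq_len(s)]
    }
    cv_mae <- mean(vapply(1:3, function(f) {
      tr <- folds != f
      fit <- with_seed(seed, glmnet::cv.glmnet(
        x[tr, current, drop = FALSE], y[tr], alpha = 1, nfolds = 5))
      mean(abs(as.vector(stats::predict(fit, x[!tr, current, drop = FALSE],
                                        s = "lambda.min")) - y[!tr]))
    }, numeric(1)))
    results[[as.character(s)]] <- list(features = current, cv_mae = cv_mae)
  }
  maes <- vapply(results, `[[`, numeric(1), "cv_mae")
  results[[which.min(maes)]]$features
}

#' Train the model zoo and select by validation MAE
#'
#' Fits every cell of a (predictor x feature-selection) grid on the
#' standardized training data — hyperparameters tuned by a bounded, seeded
#' random search with training-internal cross-validation — and returns the
#' cell with the lowest mean absolute error on the validation set (computed
#' on raw, uncorrected predictions).
#'
#' @param x_train,x_val Standardized IDP matrices (rows = participants).
#' @param age_train,age_val Chronological ages at scan (the labels).
#' @param grid `"lasso"` (L1-penalized linear only, the default),
#'   `"full"` (lasso/gradient-boosted trees/SVR x none/RFE-CV), or a tibble
#'   with columns `model`, `selection`.
#' @param seed Integer seed for every stochastic step.
#' @param search_budget Random-search draws per tuned cell.
#' @return A `brainage_model`: the fitted predictor, selected features,
#'   `mae_table` over all grid cells, validation MAE, and (for linear models)
#'   the nonzero-coefficient count.
#' @export
train_and_select <- function(x_train, age_train, x_val, age_val,
                             grid = "lasso", seed = 1L, search_budget = 8) {
  assert_that(stats::sd(age_train) > 0, "degenerate label variance in training ages")
  if (is.character(grid)) {
    grid <- switch(match.arg(grid, c("lasso", "full")),
      lasso = tibble::tibble(model = "lasso", selection = "none"),
      full = tidyr::expand_grid(model = c("lasso", "gbt", "svr"),
                                selection = c("none", "rfecv")))
  }
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)

  cells <- purrr::pmap(grid, function(model, selection) {
    feats <- colnames(x_train)
    if (selection == "rfecv") feats <- rfe_cv_select(x_train, age_train, seed)
    fit <- fit_predictor(model, x_train[, feats, drop = FALSE], age_train,
                         seed = seed, search_budget = search_budget)
    val_pred <- fit$predict(x_val[, feats, drop = FALSE])
    list(model = model, selection = selection, fit = fit, features = feats,
         val_mae = mean(abs(val_pred - age_val)))
  })
  mae_table <- tibble::tibble(
    model = grid$model, selection = grid$selection,
    n_features = vapply(cells, function(c) length(c$features), integer(1)),
    validation_mae = vapply(cells, `[[`, numeric(1), "val_mae"))
  best <- cells[[which.min(mae_table$validation_mae)]]
  structure(list(
    kind = best$model, selection = best$selection,
    predictor = best$fit, features = best$features,
    validation_mae = best$val_mae, mae_table = mae_table,
    n_nonzero = best$fit$n_nonzero, seed = seed
  ), class = "brainage_model")
}

#' @export
print.brainage_model <- function(x, ...) {
  cat(sprintf("<brainage_model> %s (feature selection: %s), validation MAE = %.3f y\n",
              x$kind, x$selection, x$validation_mae))
  if (!is.na(x$n_nonzero)) {
    cat(sprintf("  nonzero coefficients: %d of %d features\n",
                x$n_nonzero, length(x$features)))
  }
  invisible(x)
}

#' Predict raw brain age from a fitted model
#'
#' @param object A `brainage_model`.
#' @param newdata Standardized IDP tibble or matrix containing the model's
#'   feature columns.
#' @param ... Unused.
#' @return Numeric vector of raw (uncorrected) brain-age predictions.
#' @export
predict.brainage_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, object$features, drop = FALSE])
  } else {
    newdata <- newdata[, object$features, drop = FALSE]
  }
  object$predictor$predict(newdata)
}

#' Fit the age-bias correction
#'
#' Age predictions regress toward the training mean: young ages are over- and
#' old ages under-predicted. The correction regresses raw predicted brain age
#' on chronological age in the training set, `prediction = alpha * age +
#' beta`, and later inverts that line.
#'
#' @param predictions Raw predictions on training rows.
#' @param ages Chronological ages of the same rows.
#' @return List `alpha` (slope), `beta` (intercept).
#' @export
fit_bias_correction <- function(predictions, ages) {
  assert_that(length(predictions) == length(ages) && length(ages) >= 3,
              "need >= 3 paired training points")
  assert_that(stats::var(ages) > 0, "zero variance in training ages")
  fit <- stats::lm(predictions ~ ages)
  alpha <- unname(stats::coef(fit)[2]); beta <- unname(stats::coef(fit)[1])
  if (abs(alpha) < 1e-8) {
    rlang::abort("bias-correction slope is zero; correction refused")
  }
  list(alpha = alpha, beta = beta)
}

#' Apply the age-bias correction
#'
#' `corrected = (raw - beta) / alpha`: subtract the training intercept, then
#' divide by the training slope, so that corrected predictions regressed on
#' chronological age in the training set have slope 1 and intercept 0.
#'
#' @param raw Raw predicted brain ages.
#' @param alpha,beta Coefficients from [fit_bias_correction()].
#' @return Corrected brain ages.
#' @export
apply_bias_correction <- function(raw, alpha, beta) {
  assert_that(is.finite(alpha) && alpha != 0, "alpha must be nonzero")
  (raw - beta) / alpha
}

#' Compute the brain age gap
#'
#' @param corrected Corrected brain age, years.
#' @param age_at_scan Chronological age at MRI, years (> 0).
#' @param participant_id Optional ids.
#' @return Tibble: `participant_id`, `corrected_brain_age`, `age_at_scan`,
#'   `bag` (= corrected - age at scan; positive means accelerated aging).
#' @export
compute_bag <- function(corrected, age_at_scan, participant_id = NULL) {
  assert_that(all(age_at_scan > 0, na.rm = TRUE), "ages must be positive")
  tibble::tibble(
    participant_id = participant_id %||% seq_along(corrected),
    corrected_brain_age = corrected,
    age_at_scan = age_at_scan,
    bag = corrected - age_at_scan
  )
}

#' End-to-end brain age estimation
#'
#' Complete-case filtering on the IDPs, healthy-subset selection, seeded 4:1
#' train/validation split, leakage-free standardization, model training and
#' selection by validation MAE, bias correction fitted on the training set,
#' and BAG computation for every complete-case participant.
#'
#' @param idps IDP tibble (`participant_id` + features).
#' @param covars Derived covariate tibble (needs `age_scan` and the healthy-
#'   subset flags; see [select_healthy_subset()]).
#' @param grid,seed,search_budget Passed to [train_and_select()].
#' @return A `brainage_fit`: `model`, `constants`, `alpha`, `beta`,
#'   `bag` (tibble with raw/corrected predictions and BAG), `mae_table`,
#'   `exclusions` (complete-case and healthy-subset accounting).
#' @export
estimate_brain_age <- function(idps, covars, grid = "lasso", seed = 1L,
                               search_budget = 8) {
  check_columns(covars, c("participant_id", "age_scan"), "covariates")
  feat <- setdiff(names(idps), "participant_id")
  complete <- stats::complete.cases(idps[, feat, drop = FALSE])
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    rlang::inform(sprintf("%d participant(s) dropped for missing IDPs", n_dropped))
  }
  idps <- idps[complete, , drop = FALSE]

  healthy <- select_healthy_subset(covars)
  healthy_counts <- attr(healthy, "counts")
  healthy <- intersect(healthy, idps$participant_id)
  split <- split_train_validation(healthy, seed = child_seed(seed, 11L))
  std <- standardize_idps(idps, split$train)

  age <- covars$age_scan[match(idps$participant_id, covars$participant_id)]
  feat <- std$constants$idp
  zmat <- as.matrix(std$standardized[, feat, drop = FALSE])
  rownames(zmat) <- std$standardized$participant_id
  tr <- std$standardized$participant_id %in% split$train
  va <- std$standardized$participant_id %in% split$validation

  model <- train_and_select(zmat[tr, , drop = FALSE], age[tr],
                            zmat[va, , drop = FALSE], age[va],
                            grid = grid, seed = child_seed(seed, 13L),
                            search_budget = search_budget)

  raw_all <- predict(model, zmat)
  bc <- fit_bias_correction(raw_all[tr], age[tr])
  corrected <- apply_bias_correction(raw_all, bc$alpha, bc$beta)
  bag <- compute_bag(corrected, age, std$standardized$participant_id)
  bag$raw_brain_age <- raw_all
  bag$subset <- ifelse(tr, "train", ifelse(va, "validation", "test"))

  structure(list(
    model = model, constants = std$constants, dropped_idps = std$dropped,
    alpha = bc$alpha, beta = bc$beta, bag = bag,
    mae_table = model$mae_table,
    exclusions = list(missing_idps = n_dropped,
                      healthy_counts = healthy_counts,
                      n_healthy = length(healthy),
                      n_train = sum(tr), n_validation = sum(va),
                      n_test = sum(!tr & !va))
  ), class = "brainage_fit")
}

#' @export
print.brainage_fit <- function(x, ...) {
  cat(sprintf("<brainage_fit> %s model, validation MAE = %.3f y, alpha = %.3f, beta = %.2f\n",
              x$model$kind, x$model$validation_mae, x$alpha, x$beta))
  cat(sprintf("  train/validation/test: %d/%d/%d\n",
              x$exclusions$n_train, x$exclusions$n_validation, x$exclusions$n_test))
  invisible(x)
}
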