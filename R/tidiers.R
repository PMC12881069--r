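#' Tidiers for brain-age fits
#'
#' `tidy()` returns the BAG table (one row per participant); `glance()` a
#' one-row model summary (selected model, validation MAE, bias-correction
#' coefficients, split sizes).
#'
#' @param x A `brainage_fit` from [estimate_brain_age()].
#' @param ... Unused.
#' @export
tidy.brainage_fit <- function(x, ...) {
  x$bag
}

#' @rdname tidy.brainage_fit
#' @export
glance.brainage_fit <- function(x, ...) {
  tibble::tibble(model = x$model$kind, selection = x$model$selection,
                 validation_mae = x$model$validation_mae,
                 alpha = x$alpha, beta = x$beta,
                 n_features = length(x$model$features),
                 n_nonzero = x$model$n_nonzero,
                 n_train = x$exclusions$n_train,
                 n_validation = x$exclusions$n_validation,
                 n_test = x$exclusions$n_test,
                 n_missing_idps = x$exclusions$missing_idps)
}

#' @rdname tidy.brainage_fit
#' @export
tidy.ols_fit <- function(x, ...) {
  x$result
}
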