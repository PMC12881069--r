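#' Forest plot of DII-BAG coefficients
#'
#' @param results Tidy coefficient tibble (`term`, `estimate`, `conf.low`,
#'   `conf.high`, optionally `stratum` or `adjustment` for faceting/colour),
#'   e.g. `tidy(dii_bag_association(...))` or the `strata` table from
#'   [stratified_and_interaction()].
#' @param colour Optional column name mapped to colour.
#' @return A ggplot.
#' @export
plot_forest <- function(results, colour = NULL) {
  check_columns(results, c("term", "estimate", "conf.low", "conf.high"),
                "results")
  aes <- if (!is.null(colour)) {
    ggplot2::aes(x = .data$estimate, y = .data$term,
                 colour = .data[[colour]])
  } else {
    ggplot2::aes(x = .data$estimate, y = .data$term)
  }
  ggplot2::ggplot(results, aes) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "BAG difference (years)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Least-squares means plot of BAG by DII group
#'
#' @param lsm Tibble from [ls_means()].
#' @return A ggplot.
#' @export
plot_ls_means <- function(lsm) {
  check_columns(lsm, c("dii_group", "estimate", "conf.low", "conf.high"),
                "ls_means table")
  ggplot2::ggplot(lsm, ggplot2::aes(x = .data$dii_group, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::labs(x = "DII group", y = "Adjusted mean BAG (years)") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of two DII score sets
#'
#' Plots per-participant mean against difference, with the mean difference
#' and 95% limits of agreement from [dii_stability()].
#'
#' @param first,later Paired numeric score vectors.
#' @return A ggplot.
#' @export
plot_bland_altman <- function(first, later) {
  stab <- dii_stability(first, later)
  df <- tibble::tibble(mean = (first + later) / 2, diff = first - later)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = stab$mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(stab$loa_lower, stab$loa_upper),
                        linetype = 2, colour = "steelblue") +
    ggplot2::labs(x = "Mean of paired DII scores",
                  y = "Difference (first - later)") +
    ggplot2::theme_minimal()
}

#' @rdname bootstrap_mediation
#' @param object A `mediation_result`.
#' @export
autoplot.mediation_result <- function(object, ...) {
  est <- object$estimates
  est$effect <- factor(est$effect,
                       levels = rev(c("acme", "ade", "total", "prop_mediated")),
                       labels = rev(c("ACME", "ADE", "Total effect",
                                      "Prop. mediated")))
  ggplot2::ggplot(est, ggplot2::aes(x = .data$estimate, y = .data$effect)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "Estimate (95% percentile CI)", y = NULL) +
    ggplot2::theme_minimal()
}
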