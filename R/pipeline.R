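#' Exclusion cascade accounting
#'
#' Cohort analyses remove participants in ordered stages (no dietary data,
#' implausible energy intake, neurological disorders, ...). The cascade
#' records, per stage, how many participants enter, are removed and remain,
#' and validates the arithmetic: `remaining = entering - removed` at every
#' stage and `entering[k+1] = remaining[k]`.
#'
#' @param n_start Number of participants entering the first stage.
#' @param removals Named numeric vector: stage label -> number removed.
#' @return An `exclusion_cascade` tibble: `stage`, `n_entering`, `n_removed`,
#'   `n_remaining`.
#' @export
exclusion_cascade <- function(n_start, removals) {
  assert_that(n_start >= 0, "n_start must be non-negative")
  if (length(removals) == 0) {
    return(structure(tibble::tibble(stage = character(), n_entering = integer(),
                                    n_removed = integer(), n_remaining = integer()),
                     class = c("exclusion_cascade", "tbl_df", "tbl", "data.frame")))
  }
  assert_that(!is.null(names(removals)) && all(nzchar(names(removals))),
              "removals must be a named vector")
  entering <- n_start
  rows <- purrr::imap(as.list(removals), function(rm, label) {
    row <- tibble::tibble(stage = label, n_entering = entering,
                          n_removed = rm, n_remaining = entering - rm)
    entering <<- entering - rm
    row
  })
  out <- dplyr::bind_rows(rows)
  validate_cascade(out)
  structure(out, class = c("exclusion_cascade", class(tibble::tibble())))
}

#' Validate an exclusion cascade
#'
#' @param cascade A cascade tibble (`stage`, `n_entering`, `n_removed`,
#'   `n_remaining`).
#' @return The cascade, invisibly; errors pinpoint the inconsistent stage.
#' @export
validate_cascade <- function(cascade) {
  check_columns(cascade, c("stage", "n_entering", "n_removed", "n_remaining"),
                "cascade")
  bad <- which(cascade$n_remaining != cascade$n_entering - cascade$n_removed)
  if (length(bad) > 0) {
    rlang::abort(sprintf("cascade inconsistent at stage '%s': %d - %d != %d",
                         cascade$stage[bad[1]], cascade$n_entering[bad[1]],
                         cascade$n_removed[bad[1]], cascade$n_remaining[bad[1]]))
  }
  if (nrow(cascade) > 1) {
    chain <- which(cascade$n_entering[-1] != cascade$n_remaining[-nrow(cascade)])
    if (length(chain) > 0) {
      rlang::abort(sprintf(
        "cascade broken between stages '%s' and '%s': %d remaining but %d entering",
        cascade$stage[chain[1]], cascade$stage[chain[1] + 1],
        cascade$n_remaining[chain[1]], cascade$n_entering[chain[1] + 1]))
    }
  }
  if (any(cascade$n_removed < 0) || any(cascade$n_remaining < 0)) {
    rlang::abort("cascade counts must be non-negative")
  }
  invisible(cascade)
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates generation and analysis end to end: simulate a cohort, score
#' DII (plausibility filter, averaging) and INFLA, derive covariates,
#' estimate brain age from IDPs (healthy subset, 4:1 split, leakage-free
#' standardization, validation-MAE model selection, bias correction), merge
#' into one analysis table, and fit the association models. Deterministic
#' under a fixed configuration.
#'
#' @param config A [sim_config()].
#' @param reference DII reference; default `generate_reference(31, seed)`
#'   derived from the config seed.
#' @param grid Model grid for [train_and_select()] (default `"lasso"`).
#' @param associations Character subset of
#'   `c("continuous", "groups")` to fit (both adjustment sets each); empty to
#'   skip.
#' @param mediation_boot Bootstrap replicates for the mediation stage
#'   (0 = skip mediation).
#' @param out_dir Optional directory: writes the analysis table, BAG table,
#'   MAE table and cascade as CSV.
#' @return An `inflammage_run` list: `analysis` (merged per-participant
#'   tibble), `brainage`, `assoc` (list of `dii_assoc`), `mediation`,
#'   `cascade`, `truth`, `config`.
#' @export
run_pipeline <- function(config, reference = NULL, grid = "lasso",
                         associations = c("continuous", "groups"),
                         mediation_boot = 0, out_dir = NULL) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  if (is.null(reference)) reference <- generate_reference(31, child_seed(config$seed, 3L))

  cohort <- generate_cohort(config, reference)
  n0 <- nrow(cohort$covariates)

  filt <- filter_plausible_assessments(
    cohort$diet, cohort$covariates[, c("participant_id", "sex")])
  n_nodiet <- n0 - length(unique(cohort$diet$participant_id))
  n_implausible <- sum(filt$report$excluded)
  mean_int <- average_intakes(filt$kept)
  dii_tbl <- compute_dii(mean_int, reference)

  infla_tbl <- suppressMessages(compute_infla(cohort$blood))
  covars <- derive_covariates(cohort$covariates)

  idp <- generate_idps(cohort$truth, config)
  ba <- suppressMessages(
    estimate_brain_age(idp$idps, covars, grid = grid,
                       seed = child_seed(config$seed, 29L)))

  analysis <- covars |>
    dplyr::left_join(dii_tbl, by = "participant_id") |>
    dplyr::left_join(mean_int[, c("participant_id", "energy_kcal")],
                     by = "participant_id") |>
    dplyr::left_join(infla_tbl[, c("participant_id", "infla")],
                     by = "participant_id") |>
    dplyr::left_join(ba$bag[, c("participant_id", "bag", "corrected_brain_age",
                                "subset")],
                     by = "participant_id")
  analysis_final <- analysis[!is.na(analysis$dii) & !is.na(analysis$bag), ,
                             drop = FALSE]
  n_after_diet <- n0 - n_nodiet - n_implausible
  cascade <- exclusion_cascade(n0, c(
    "no dietary data" = n_nodiet,
    "implausible energy in all assessments" = n_implausible,
    "missing IDPs / no brain age" = n_after_diet - nrow(analysis_final)))

  assoc <- list()
  for (f in associations) {
    for (adj in c("basic", "multivariable")) {
      assoc[[paste(f, adj, sep = "_")]] <-
        dii_bag_association(analysis_final, form = f, adjustment = adj)
    }
  }

  mediation <- NULL
  if (mediation_boot > 0) {
    base_dii <- baseline_only_dii(cohort$diet, reference,
                                  cohort$covariates[, c("participant_id", "sex")])
    med_data <- analysis_final |>
      dplyr::select(-dplyr::any_of(c("dii", "dii_group"))) |>
      dplyr::inner_join(base_dii[, c("participant_id", "dii")],
                        by = "participant_id")
    mediation <- lapply(stats::setNames(c("basic", "multivariable"),
                                        c("basic", "multivariable")),
                        function(adj) {
      bootstrap_mediation(med_data, adjustment = adj, n_boot = mediation_boot,
                          seed = child_seed(config$seed, 31L))
    })
  }

  run <- structure(list(analysis = analysis_final, brainage = ba,
                        assoc = assoc, mediation = mediation,
                        cascade = cascade, truth = cohort$truth,
                        reference = reference, config = config),
                   class = "inflammage_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(run$analysis, file.path(out_dir, "analysis.csv"),
                     row.names = FALSE)
    utils::write.csv(ba$bag, file.path(out_dir, "bag.csv"), row.names = FALSE)
    utils::write.csv(ba$mae_table, file.path(out_dir, "mae_table.csv"),
                     row.names = FALSE)
    utils::write.csv(run$cascade, file.path(out_dir, "cascade.csv"),
                     row.names = FALSE)
  }
  run
}

#' @export
print.inflammage_run <- function(x, ...) {
  cat(sprintf("<inflammage_run> %d analytic participants (of %d simulated)\n",
              nrow(x$analysis), x$config$n_participants))
  print(x$cascade)
  if (length(x$assoc) > 0) {
    cat("\nDII-BAG associations:\n")
    print(dplyr::bind_rows(lapply(x$assoc, tidy)))
  }
  invisible(x)
}
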