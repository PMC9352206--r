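#' @title End-to-end analysis pipeline
#'
#' @description
#' `run_pipeline()` chains the package's stages at desk scale: simulate a
#' synthetic cohort, fit the winning model of each task to every
#' participant, compute behavioural statistics, and run permutation
#' Spearman correlations between paranoia and the recovered parameters of
#' interest. All outputs are written as CSV plus a JSON manifest, and the
#' run is deterministic under the config seed.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param n_participants Cohort size (default 50 for a fast desk run).
#' @param seed Integer seed for the whole run.
#' @param prl_model,social_model Model ids fitted to each task.
#' @param B_perm Permutations for the correlation tests.
#' @param fit Optimiser settings, see [fit_config()].
#' @export
pipeline_config <- function(n_participants = 50L, seed = 1L,
                            prl_model = "ph_reset_phi",
                            social_model = "bb_free_1eta",
                            B_perm = 1000L, fit = fit_config()) {
  get_model_spec(prl_model)     # fail early on unknown ids
  get_model_spec(social_model)
  list(n_participants = as.integer(n_participants), seed = as.integer(seed),
       prl_model = prl_model, social_model = social_model,
       B_perm = as.integer(B_perm), fit = fit)
}

#' Run the full pipeline
#'
#' @param out_dir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `cohort`, `fits` (combined tibble),
#'   `stats`, `correlations` (tibble of permutation results) and the paths
#'   written.
#' @export
run_pipeline <- function(out_dir = NULL, config = pipeline_config()) {
  cohort <- generate_cohort(cohort_config(
    n_participants = config$n_participants, seed = config$seed))

  prl_fits <- compare_models(cohort$prl_trials,
                             get_model_spec(config$prl_model),
                             config = config$fit, seed = config$seed)
  dg_fits <- compare_models(cohort$dg_trials,
                            get_model_spec(config$social_model),
                            config = config$fit, seed = config$seed + 1L)
  fits <- dplyr::bind_rows(
    dplyr::mutate(prl_fits, task = "prl"),
    dplyr::mutate(dg_fits, task = "dg"))

  stats_tbl <- switch_stats(cohort$prl_trials,
                            scope = c("all_trials", "pre_reversal",
                                      "post_reversal"))

  est <- dplyr::left_join(
    dplyr::select(dplyr::filter(fits, .data$task == "prl"),
                  "participant_id", est_tau = "est_tau"),
    dplyr::select(dplyr::filter(fits, .data$task == "dg"),
                  "participant_id", est_pHI0 = "est_pHI0",
                  est_u_pi = "est_u_pi", est_wSI = "est_wSI"),
    by = "participant_id")
  est <- dplyr::left_join(cohort$covariates, est, by = "participant_id")

  targets <- c("est_tau", "est_pHI0", "est_u_pi", "est_wSI")
  correlations <- purrr::map_dfr(seq_along(targets), function(i) {
    pr <- permutation_spearman(est$paranoia, est[[targets[i]]],
                               B = config$B_perm, seed = config$seed + i)
    tibble::tibble(x = "paranoia", y = targets[i], rho = pr$statistic,
                   p_permuted = pr$p_permuted, n = pr$n,
                   B = pr$n_permutations)
  })

  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      covariates = file.path(out_dir, "covariates.csv"),
      true_params = file.path(out_dir, "true_params.csv"),
      prl_trials = file.path(out_dir, "prl_trials.csv"),
      dg_trials = file.path(out_dir, "dg_trials.csv"),
      fits = file.path(out_dir, "fits.csv"),
      stats = file.path(out_dir, "stats.csv"),
      permcorr = file.path(out_dir, "permcorr.csv"))
    utils::write.csv(cohort$covariates, paths["covariates"], row.names = FALSE)
    utils::write.csv(cohort$true_params, paths["true_params"],
                     row.names = FALSE)
    write_prl_trials(cohort$prl_trials, paths["prl_trials"])
    write_dg_trials(cohort$dg_trials, paths["dg_trials"])
    write_fits(fits, paths["fits"])
    utils::write.csv(stats_tbl, paths["stats"], row.names = FALSE)
    utils::write.csv(correlations, paths["permcorr"], row.names = FALSE)
    write_run_manifest(file.path(out_dir, "manifest.json"), config,
                       config$seed, unname(paths))
    paths <- c(paths, manifest = file.path(out_dir, "manifest.json"))
  }

  invisible(list(cohort = cohort, fits = fits, stats = stats_tbl,
                 correlations = correlations, paths = paths))
}
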