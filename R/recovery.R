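#' @title Parameter and model recovery
#'
#' @description
#' Recovery analyses validate the fitting machinery on data whose ground
#' truth is known: `parameter_recovery()` draws generating parameters over
#' broad, plausible ranges, simulates one agent per draw, refits the same
#' model and correlates true with recovered values; `model_recovery()`
#' simulates from one model and asks how often model comparison picks it
#' (or its family) against a rival set.
#'
#' @name recovery
NULL

#' Default generating ranges for recovery analyses
#'
#' Recovery sweeps draw generating parameters uniformly (log-uniformly for
#' scale parameters) over the region in which each mechanism is
#' behaviourally expressed: decision temperatures beyond ~8 points make
#' choices indistinguishable from random in a 15-point value range, policy
#' uncertainties beyond ~3 flatten the emission grid to near-uniform, and
#' policy sensitivities below ~0.08 leave beliefs static, so parameters
#' outside these ranges are trivially unrecoverable and would only dilute
#' the sweep.
#'
#' @return Tibble `name`, `lower`, `upper`, `scale` (`"linear"`/`"log"`).
#' @export
recovery_ranges <- function() {
  tibble::tribble(
    ~name, ~lower, ~upper, ~scale,
    "tau", 0.5, 8, "log",
    "lambda1", 0.05, 0.9, "linear",
    "lambda2", 0.05, 0.9, "linear",
    "S", 0.1, 0.9, "linear",
    "phi", 0.3, 0.98, "linear",
    "eta_pr", 0.05, 0.95, "linear",
    "zeta", 0.01, 0.2, "linear",
    "pHI0", 0.05, 0.95, "linear",
    "pSI0", 0.05, 0.95, "linear",
    "uHI0", 0.4, 4, "log",
    "uSI0", 0.4, 4, "log",
    "u_pi", 0.4, 3, "log",
    "w0", -2.5, 0.5, "linear",
    "wHI", 0.08, 1.2, "log",
    "wSI", 0.08, 1.2, "log",
    "eta_dg", 0.05, 0.95, "linear",
    "eta_hi", 0.05, 0.95, "linear",
    "eta_si", 0.05, 0.95, "linear",
    "eta", 0.05, 0.95, "linear",
    "esv0", 0.05, 0.45, "linear",
    "alpha", 0.05, 0.95, "linear",
    "sigma", 0.05, 0.4, "log",
    "a_wHI0", -2, 2, "linear",
    "a_wSI0", -2, 2, "linear",
    "a_wHI", -8, 8, "linear",
    "a_wSI", -8, 8, "linear",
    "a_w0", -2, 2, "linear",
    "a_w", -8, 8, "linear"
  )
}

# Draw n generating parameter sets for a spec, uniform over the default
# recovery ranges.
draw_recovery_params <- function(spec, n, priors = default_priors()) {
  free <- spec$free_params[[1]]
  rr <- recovery_ranges()
  idx <- match(free, rr$name)
  if (anyNA(idx)) {
    stop("no recovery range defined for: ",
         paste(free[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  draws <- lapply(idx, function(j) {
    if (rr$scale[j] == "log") {
      exp(stats::runif(n, log(rr$lower[j]), log(rr$upper[j])))
    } else {
      stats::runif(n, rr$lower[j], rr$upper[j])
    }
  })
  names(draws) <- free
  tibble::as_tibble(draws)
}

simulate_for_spec <- function(spec, values, env = NULL, seed = NULL,
                              participant_id = "sim") {
  task <- spec_task(spec)
  p <- params_from_spec(spec, unlist(values))
  switch(task,
         prl = simulate_prl_agent(env %||% prl_environment(), p, seed,
                                  participant_id),
         social_belief = {
           p2 <- p
           if (!is.null(p2$eta_hi)) {
             p2$eta_dg <- c(p2$eta_hi, p2$eta_si)
             p2$eta_hi <- NULL; p2$eta_si <- NULL
           }
           simulate_social_agent(env %||% dg_environment(), p2, seed,
                                 participant_id)
         },
         social_assoc = simulate_assoc_agent(env %||% dg_environment(), p,
                                             seed, participant_id))
}

#' Parameter recovery for one model
#'
#' @param model Model id or one-row spec tibble.
#' @param n_agents Number of simulated participants.
#' @param seed Integer seed governing draws, simulation and fitting.
#' @param priors,config Passed to [fit_map()].
#' @param env Task environment (defaults to the canonical task).
#' @param sampler Optional function `n -> tibble` of generating parameter
#'   draws; defaults to broad uniform draws on the prior table's init range.
#' @return List of class `revattr_recovery` with `results` (tibble of
#'   `true_*` and `est_*` columns per agent) and `correlations` (tibble
#'   `parameter`, `pearson_r`, `spearman_rho`).
#' @export
parameter_recovery <- function(model, n_agents = 50L, seed = 1L,
                               priors = default_priors(),
                               config = fit_config(), env = NULL,
                               sampler = NULL) {
  spec <- if (is.character(model)) get_model_spec(model) else model
  free <- spec$free_params[[1]]
  set.seed(seed)
  truth <- if (is.null(sampler)) draw_recovery_params(spec, n_agents, priors)
           else sampler(n_agents)
  sim_seeds <- sample.int(2^30, n_agents)
  fit_seeds <- sample.int(2^30, n_agents)
  res <- purrr::map(seq_len(n_agents), function(i) {
    d <- simulate_for_spec(spec, truth[i, ], env, sim_seeds[i],
                           participant_id = sprintf("agent%03d", i))
    f <- fit_map(d, spec, priors, config, seed = fit_seeds[i])
    est <- tibble::as_tibble(as.list(f$estimates))
    names(est) <- paste0("est_", names(est))
    dplyr::bind_cols(tibble::tibble(participant_id = f$participant_id,
                                    converged = f$converged,
                                    loglik = f$loglik),
                     est)
  })
  results <- dplyr::bind_cols(
    stats::setNames(truth, paste0("true_", names(truth))),
    dplyr::bind_rows(res))
  rows <- prior_rows(free, priors)
  correlations <- purrr::map_dfr(seq_along(free), function(i) {
    nm <- free[i]
    x <- results[[paste0("true_", nm)]]
    y <- results[[paste0("est_", nm)]]
    tr <- rows$transform[i]
    # degenerate (constant) truths have no defined correlation
    suppressWarnings(tibble::tibble(
      parameter = nm,
      pearson_r = stats::cor(x, y, use = "complete.obs"),
      pearson_r_link = stats::cor(to_transformed(x, tr),
                                  to_transformed(y, tr),
                                  use = "complete.obs"),
      spearman_rho = stats::cor(x, y, method = "spearman",
                                use = "complete.obs")))
  })
  structure(list(model_id = spec$model_id, results = results,
                 correlations = correlations, seed = seed),
            class = "revattr_recovery")
}

#' @export
print.revattr_recovery <- function(x, ...) {
  cat("<revattr_recovery> model ", x$model_id, ", ",
      nrow(x$results), " agents\n", sep = "")
  print(dplyr::mutate(x$correlations,
                      dplyr::across(dplyr::where(is.numeric),
                                    function(v) round(v, 3))))
  invisible(x)
}

#' Model recovery: is the generating model re-selected?
#'
#' Simulates `n_agents` datasets from `gen_model` (parameters drawn as in
#' [parameter_recovery()]) and fits every spec in `fit_specs`, recording
#' the best model by BIC per agent.
#'
#' @param gen_model Generating model id or spec row.
#' @param fit_specs Spec tibble of candidate models (should include the
#'   generating model or a relative).
#' @param n_agents Number of simulated agents.
#' @param seed,priors,config,env,sampler As in [parameter_recovery()].
#' @return List of class `revattr_model_recovery` with `winners` (tibble
#'   per agent: `best_model`, `best_family`) and `counts`.
#' @export
model_recovery <- function(gen_model, fit_specs, n_agents = 50L, seed = 1L,
                           priors = default_priors(), config = fit_config(),
                           env = NULL, sampler = NULL) {
  gen <- if (is.character(gen_model)) get_model_spec(gen_model) else gen_model
  set.seed(seed)
  truth <- if (is.null(sampler)) draw_recovery_params(gen, n_agents, priors)
           else sampler(n_agents)
  sim_seeds <- sample.int(2^30, n_agents)
  winners <- purrr::map_dfr(seq_len(n_agents), function(i) {
    d <- simulate_for_spec(gen, truth[i, ], env, sim_seeds[i],
                           participant_id = sprintf("agent%03d", i))
    cmp <- compare_models(d, fit_specs, priors, config, seed = seed + i)
    b <- cmp[cmp$best, ]
    tibble::tibble(participant_id = b$participant_id[1],
                   best_model = b$model_id[1],
                   best_family = get_model_spec(b$model_id[1],
                                                fit_specs)$family[[1]])
  })
  counts <- dplyr::count(winners, .data$best_model, name = "n_best")
  structure(list(gen_model = gen$model_id, winners = winners,
                 counts = dplyr::arrange(counts, dplyr::desc(.data$n_best)),
                 seed = seed),
            class = "revattr_model_recovery")
}

#' @export
print.revattr_model_recovery <- function(x, ...) {
  cat("<revattr_model_recovery> generated from ", x$gen_model, "\n", sep = "")
  print(x$counts)
  invisible(x)
}
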