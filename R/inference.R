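#' @title MAP fitting and model comparison
#'
#' @description
#' Every model variant is fitted per participant by maximum a posteriori
#' estimation: the trial-sequence log-likelihood is penalised by weak,
#' range-restricting priors (Beta(1.2, 1.2) on unit-interval parameters,
#' Gamma(shape 2, scale 3) on positive parameters, Normal(0, 5) on real
#' weights, half-Normal(0, 5) on the non-negative policy sensitivities).
#' Optimisation runs in an unconstrained transformed space (logit / log /
#' identity links) through three stages: a Latin-hypercube / factorial grid
#' scan, short simulated-annealing chains started from the best grid
#' points, and a Nelder-Mead plus BFGS polish. The whole pipeline is
#' deterministic under a fixed seed.
#'
#' @name inference
NULL

# ---- parameter metadata -----------------------------------------------------

#' Prior and transform specification for every model parameter
#'
#' One row per parameter name appearing in any model registry: the link
#' used for unconstrained optimisation, the legal range (outside which the
#' posterior is -Inf), the weak regularising prior, and the range over
#' which grid/annealing starting points are spread.
#'
#' @return Tibble with columns `name`, `transform`, `lower`, `upper`,
#'   `prior`, `h1`, `h2`, `init_lower`, `init_upper`.
#' @export
default_priors <- function() {
  row <- function(name, transform, lower, upper, prior, h1, h2, il, iu) {
    tibble::tibble(name = name, transform = transform, lower = lower,
                   upper = upper, prior = prior, h1 = h1, h2 = h2,
                   init_lower = il, init_upper = iu)
  }
  unit <- function(name) row(name, "logit", 0, 1, "beta", 1.2, 1.2, 0.03, 0.97)
  pos <- function(name, iu = 8) row(name, "log", 1e-3, 100, "gamma", 2, 3, 0.25, iu)
  real <- function(name) row(name, "identity", -30, 30, "normal", 0, 5, -4, 4)
  dplyr::bind_rows(
    pos("tau", iu = 15),
    unit("lambda1"), unit("lambda2"), unit("S"), unit("phi"),
    unit("eta_pr"), unit("zeta"),
    unit("pHI0"), unit("pSI0"),
    pos("uHI0"), pos("uSI0"), pos("u_pi"),
    real("w0"),
    row("wHI", "log", 1e-6, 30, "halfnormal", 0, 5, 0.02, 2),
    row("wSI", "log", 1e-6, 30, "halfnormal", 0, 5, 0.02, 2),
    unit("eta_dg"), unit("eta_hi"), unit("eta_si"), unit("eta"),
    row("esv0", "logit05", 0, 0.5, "beta05", 1.2, 1.2, 0.03, 0.47),
    unit("alpha"),
    real("a_wHI0"), real("a_wHI"), real("a_wSI0"), real("a_wSI"),
    real("a_w0"), real("a_w"),
    row("sigma", "log", 1e-3, 10, "gamma", 2, 3, 0.03, 0.8)
  )
}

prior_rows <- function(free, priors) {
  idx <- match(free, priors$name)
  if (anyNA(idx)) {
    stop("no prior/transform defined for parameter(s): ",
         paste(free[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  priors[idx, ]
}

to_transformed <- function(x, transform) {
  switch(transform,
         logit = stats::qlogis(x),
         log = log(x),
         logit05 = stats::qlogis(x / 0.5),
         identity = x,
         stop("unknown transform ", transform))
}

from_transformed <- function(z, transform) {
  switch(transform,
         logit = stats::plogis(z),
         log = exp(z),
         logit05 = 0.5 * stats::plogis(z),
         identity = z,
         stop("unknown transform ", transform))
}

log_prior_one <- function(x, prior, h1, h2) {
  switch(prior,
         beta = stats::dbeta(x, h1, h2, log = TRUE),
         beta05 = stats::dbeta(x / 0.5, h1, h2, log = TRUE),
         gamma = stats::dgamma(x, shape = h1, scale = h2, log = TRUE),
         normal = stats::dnorm(x, h1, h2, log = TRUE),
         halfnormal = stats::dnorm(x, h1, h2, log = TRUE) + log(2),
         flat = 0,
         stop("unknown prior ", prior))
}

log_prior <- function(values, rows) {
  sum(vapply(seq_along(values), function(i) {
    log_prior_one(values[i], rows$prior[i], rows$h1[i], rows$h2[i])
  }, numeric(1)))
}

# ---- spec -> params assembly ------------------------------------------------

spec_task <- function(spec) {
  switch(spec$family[[1]],
         WS = , RW = , PH = "prl",
         BB = "social_belief",
         AS = "social_assoc",
         stop("unknown model family ", spec$family[[1]]))
}

# Build the full parameter list a likelihood needs from a spec row and a
# named vector of free-parameter values.
params_from_spec <- function(spec, values) {
  p <- as.list(spec$fixed_params[[1]])
  if (length(values)) p[names(values)] <- as.list(unname(values))
  task <- spec_task(spec)
  if (task == "social_assoc") {
    if (!is.null(p$a_w0)) {
      p$a_wHI0 <- p$a_w0; p$a_wSI0 <- p$a_w0; p$a_w0 <- NULL
    }
    if (!is.null(p$a_w)) {
      p$a_wHI <- p$a_w; p$a_wSI <- p$a_w; p$a_w <- NULL
    }
    if (!is.null(p$eta_hi)) {
      p$eta <- c(p$eta_hi, p$eta_si); p$eta_hi <- NULL; p$eta_si <- NULL
    }
  }
  if (task == "social_belief" && is.null(p$xi)) p$xi <- XI_LAPSE
  p
}

spec_loglik <- function(data, spec, values, reversal_trial = NULL) {
  task <- spec_task(spec)
  p <- params_from_spec(spec, values)
  switch(task,
         prl = prl_loglik(data, p, reversal_trial %||% 30L),
         social_belief = social_loglik(data, p, reversal_trial %||% 10L),
         social_assoc = assoc_loglik(data, p, reversal_trial %||% 10L))
}

#' Negative log-posterior objective
#'
#' `-(loglik + sum log prior)` at a named vector of free-parameter values on
#' their natural scale; `+Inf` outside the legal range (so optimisers can
#' probe freely) and on numerical failure.
#'
#' @param values Named numeric vector of free-parameter values.
#' @param data Trial table for the spec's task.
#' @param spec One-row spec tibble (see [get_model_spec()]).
#' @param priors Prior table from [default_priors()].
#' @param reversal_trial Optional override of the task's reversal trial.
#' @return Scalar objective value (to be minimised).
#' @export
map_objective <- function(values, data, spec, priors = default_priors(),
                          reversal_trial = NULL) {
  rows <- prior_rows(names(values), priors)
  if (any(values < rows$lower | values > rows$upper) || anyNA(values)) {
    return(Inf)
  }
  ll <- tryCatch(spec_loglik(data, spec, values, reversal_trial),
                 error = function(e) -Inf)
  lp <- log_prior(values, rows)
  out <- -(ll + lp)
  if (!is.finite(out)) Inf else out
}

# ---- fitting ----------------------------------------------------------------

# Fast objective closure used by the optimiser: validates the data once,
# precomputes the kernel inputs and per-parameter prior evaluators, and
# skips per-call revalidation. Agrees with map_objective() everywhere
# inside the legal range (tested).
make_objective <- function(data, spec, priors, reversal_trial = NULL) {
  free <- spec$free_params[[1]]
  rows <- prior_rows(free, priors)
  task <- spec_task(spec)
  lower <- rows$lower
  upper <- rows$upper
  k <- length(free)
  prior_fns <- lapply(seq_len(k), function(i) {
    h1 <- rows$h1[i]; h2 <- rows$h2[i]
    switch(rows$prior[i],
           beta = function(x) stats::dbeta(x, h1, h2, log = TRUE),
           beta05 = function(x) stats::dbeta(x / 0.5, h1, h2, log = TRUE),
           gamma = function(x) stats::dgamma(x, shape = h1, scale = h2,
                                             log = TRUE),
           normal = function(x) stats::dnorm(x, h1, h2, log = TRUE),
           halfnormal = function(x) stats::dnorm(x, h1, h2, log = TRUE) +
             log(2),
           flat = function(x) 0)
  })
  lp_fn <- function(values) {
    s <- 0
    for (i in seq_len(k)) s <- s + prior_fns[[i]](values[i])
    s
  }
  fixed <- spec$fixed_params[[1]]
  # positional accessor: free value if fitted, fixed value otherwise
  getter <- function(nm, default = NA_real_) {
    i <- match(nm, free)
    if (!is.na(i)) {
      force(i)
      function(values) values[i]
    } else {
      v <- fixed[[nm]] %||% default
      function(values) v
    }
  }
  if (task == "social_belief") {
    assert_dg_trials(data)
    assert_contiguous_trials(data)
    unfair <- as.integer(data$partner_return == "unfair")
    hi_bin <- as.integer(rating_to_bin(data$hi_rating))
    si_bin <- as.integer(rating_to_bin(data$si_rating))
    rt <- as.integer(reversal_trial %||% 10L)
    g <- lapply(c("pHI0", "uHI0", "pSI0", "uSI0", "u_pi", "w0", "wHI",
                  "wSI"), getter)
    n_eta <- if ("eta_hi" %in% free) 2L else if ("eta_dg" %in% free) 1L
             else 0L
    g_ehi <- getter(if (n_eta == 2L) "eta_hi" else "eta_dg", 1)
    g_esi <- getter(if (n_eta == 2L) "eta_si" else "eta_dg", 1)
    xi <- fixed$xi %||% XI_LAPSE
    ll_fn <- function(values) {
      social_loglik_full_cpp(unfair, hi_bin, si_bin,
                             g[[1]](values), g[[2]](values), g[[3]](values),
                             g[[4]](values), g[[5]](values), g[[6]](values),
                             g[[7]](values), g[[8]](values), n_eta,
                             g_ehi(values), g_esi(values), rt, xi)
    }
  } else if (task == "social_assoc") {
    assert_dg_trials(data)
    assert_contiguous_trials(data)
    unfair <- as.integer(data$partner_return == "unfair")
    hi01 <- data$hi_rating / 100
    si01 <- data$si_rating / 100
    rt <- as.integer(reversal_trial %||% 10L)
    shared <- "a_w0" %in% free || !is.null(fixed$a_w0)
    g_esv0 <- getter("esv0"); g_alpha <- getter("alpha", 0)
    g_sigma <- getter("sigma")
    if (shared) {
      g_hi0 <- getter("a_w0"); g_hi <- getter("a_w")
      g_si0 <- g_hi0; g_si <- g_hi
    } else {
      g_hi0 <- getter("a_wHI0"); g_hi <- getter("a_wHI")
      g_si0 <- getter("a_wSI0"); g_si <- getter("a_wSI")
    }
    n_eta <- if ("eta_hi" %in% free) 2L else if ("eta" %in% free) 1L else 0L
    g_ehi <- getter(if (n_eta == 2L) "eta_hi" else "eta", 1)
    g_esi <- getter(if (n_eta == 2L) "eta_si" else "eta", 1)
    ll_fn <- function(values) {
      assoc_loglik_cpp(unfair, hi01, si01, g_esv0(values), g_alpha(values),
                       g_hi0(values), g_hi(values), g_si0(values),
                       g_si(values), g_sigma(values), n_eta,
                       g_ehi(values), g_esi(values), rt)
    }
  } else {
    assert_prl_trials(data)
    assert_contiguous_trials(data)
    choice <- as.integer(data$choice)
    reward <- as.numeric(data$reward)
    rt <- as.integer(reversal_trial %||% 30L)
    g_tau <- getter("tau"); g_l1 <- getter("lambda1")
    g_l2 <- getter("lambda2"); g_S <- getter("S")
    g_phi <- getter("phi"); g_eta <- getter("eta_pr")
    g_zeta <- getter("zeta")
    ll_fn <- function(values) {
      prl_loglik_cpp(choice, reward, g_tau(values), g_l1(values),
                     g_l2(values), g_S(values), g_phi(values),
                     g_eta(values), g_zeta(values), rt)
    }
  }
  function(values) {
    if (anyNA(values) || any(values < lower | values > upper)) return(Inf)
    ll <- ll_fn(values)
    out <- -(ll + lp_fn(values))
    if (!is.finite(out)) Inf else out
  }
}

#' Optimiser configuration for [fit_map()]
#'
#' @param grid_points_per_dim Factorial grid resolution for models with up
#'   to 4 free parameters.
#' @param grid_cap Number of Latin-hypercube points used above 4 parameters
#'   (and the cap on the factorial grid).
#' @param n_chains Annealing chains, started from the best grid points.
#' @param anneal_steps Proposals per chain.
#' @param t0,t1 Geometric temperature schedule endpoints.
#' @param proposal_sd Gaussian proposal sd in transformed space.
#' @param nm_maxit,bfgs_maxit Iteration caps for the polish stages.
#' @export
fit_config <- function(grid_points_per_dim = 5L, grid_cap = 800L,
                       n_chains = 4L, anneal_steps = 100L,
                       t0 = 1, t1 = 0.01, proposal_sd = 0.4,
                       nm_maxit = 300L, bfgs_maxit = 100L) {
  list(grid_points_per_dim = grid_points_per_dim, grid_cap = grid_cap,
       n_chains = n_chains, anneal_steps = anneal_steps, t0 = t0, t1 = t1,
       proposal_sd = proposal_sd, nm_maxit = nm_maxit,
       bfgs_maxit = bfgs_maxit)
}

#' Fit one model to one participant by MAP
#'
#' Runs the grid-scan / simulated-annealing / polish pipeline on the
#' negative log posterior. The returned object carries the MAP estimates,
#' the log-likelihood at the MAP, and BIC/AIC computed with `k` = number of
#' free parameters and `n_obs` = number of trials.
#'
#' @param data Trial table (single participant) for the model's task.
#' @param model Model id string or one-row spec tibble.
#' @param priors Prior table, see [default_priors()].
#' @param config See [fit_config()].
#' @param seed Integer seed; refits with the same seed are bitwise
#'   reproducible.
#' @param n_obs Override for the BIC sample size (default: number of
#'   trials; pass `2 * nrow(data)` to count each rating pair as two
#'   observations for the social models).
#' @param reversal_trial Optional override of the task's reversal trial.
#' @return Object of class `revattr_fit`.
#' @export
fit_map <- function(data, model, priors = default_priors(),
                    config = fit_config(), seed = 1L, n_obs = NULL,
                    reversal_trial = NULL) {
  spec <- if (is.character(model)) get_model_spec(model) else model
  free <- spec$free_params[[1]]
  k <- length(free)
  n_obs <- n_obs %||% nrow(data)
  pid <- if ("participant_id" %in% names(data)) {
    as.character(data$participant_id[[1]])
  } else NA_character_

  if (k == 0L) {  # fully pinned model (e.g. win-stay/lose-shift)
    ll <- spec_loglik(data, spec, numeric(0), reversal_trial)
    return(new_fit(spec$model_id, pid, stats::setNames(numeric(0), free),
                   ll, ll, k, n_obs, TRUE, 0L, seed))
  }

  rows <- prior_rows(free, priors)
  obj <- make_objective(data, spec, priors, reversal_trial)
  tr <- rows$transform
  fn_t <- function(z) {
    x <- numeric(k)
    for (i in seq_len(k)) x[i] <- from_transformed(z[i], tr[i])
    obj(x)
  }

  set.seed(seed)
  lo <- vapply(seq_len(k), function(i)
    to_transformed(rows$init_lower[i], rows$transform[i]), numeric(1))
  hi <- vapply(seq_len(k), function(i)
    to_transformed(rows$init_upper[i], rows$transform[i]), numeric(1))

  # stage 1: grid scan (factorial for small k, Latin hypercube otherwise)
  ppd <- config$grid_points_per_dim
  if (ppd^k <= config$grid_cap) {
    marks <- lapply(seq_len(k), function(i) seq(lo[i], hi[i], length.out = ppd))
    grid <- as.matrix(expand.grid(marks))
  } else {
    u <- lhs::randomLHS(config$grid_cap, k)
    grid <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  }
  fgrid <- apply(grid, 1, fn_t)
  ord <- order(fgrid)

  # stage 2: simulated annealing from the best grid points
  n_chains <- min(config$n_chains, nrow(grid))
  best_z <- grid[ord[1], ]
  best_f <- fgrid[ord[1]]
  steps <- config$anneal_steps
  for (ch in seq_len(n_chains)) {
    z <- grid[ord[ch], ]
    f <- fgrid[ord[ch]]
    for (s in seq_len(steps)) {
      temp <- config$t0 * (config$t1 / config$t0)^((s - 1) / max(1, steps - 1))
      zp <- z + stats::rnorm(k, 0, config$proposal_sd)
      fp <- fn_t(zp)
      if (is.finite(fp) &&
          (fp < f || stats::runif(1) < exp((f - fp) / temp))) {
        z <- zp; f <- fp
      }
      if (f < best_f) { best_f <- f; best_z <- z }
    }
  }

  # stage 3: derivative-free then quasi-Newton polish (Brent in 1-d)
  converged <- FALSE
  nm <- tryCatch(
    if (k == 1L) {
      stats::optim(best_z, fn_t, method = "Brent",
                   lower = lo - 10, upper = hi + 10)
    } else {
      stats::optim(best_z, fn_t, method = "Nelder-Mead",
                   control = list(maxit = config$nm_maxit))
    },
    error = function(e) NULL)
  if (!is.null(nm) && is.finite(nm$value) && nm$value < best_f) {
    best_f <- nm$value; best_z <- nm$par
  }
  bf <- tryCatch(
    stats::optim(best_z, fn_t, method = "BFGS",
                 control = list(maxit = config$bfgs_maxit)),
    error = function(e) NULL)
  if (!is.null(bf) && is.finite(bf$value)) {
    if (bf$value < best_f) { best_f <- bf$value; best_z <- bf$par }
    converged <- bf$convergence == 0
  } else if (!is.null(nm)) {
    converged <- nm$convergence == 0
  }

  if (!is.finite(best_f)) {
    return(new_fit(spec$model_id, pid,
                   stats::setNames(rep(NA_real_, k), free),
                   NA_real_, NA_real_, k, n_obs, FALSE, n_chains, seed))
  }

  est <- stats::setNames(
    vapply(seq_len(k), function(i)
      from_transformed(best_z[i], rows$transform[i]), numeric(1)), free)
  ll <- spec_loglik(data, spec, est, reversal_trial)
  new_fit(spec$model_id, pid, est, ll, -best_f, k, n_obs, converged,
          n_chains, seed)
}

new_fit <- function(model_id, participant_id, estimates, loglik, logpost,
                    k, n_obs, converged, n_restarts, seed) {
  structure(
    list(model_id = model_id, participant_id = participant_id,
         estimates = estimates, loglik = loglik, logpost = logpost,
         bic = -2 * loglik + k * log(n_obs),
         aic = -2 * loglik + 2 * k,
         n_free = k, n_obs = n_obs, converged = converged,
         n_restarts = n_restarts, seed = seed),
    class = "revattr_fit")
}

#' @export
print.revattr_fit <- function(x, ...) {
  cat("<revattr_fit> model ", x$model_id,
      if (!is.na(x$participant_id)) paste0(", participant ", x$participant_id),
      "\n", sep = "")
  cat("  loglik ", format(x$loglik, digits = 6), ", BIC ",
      format(x$bic, digits = 6), ", AIC ", format(x$aic, digits = 6),
      ", k = ", x$n_free, ", n = ", x$n_obs, "\n", sep = "")
  if (x$n_free > 0) {
    cat("  estimates:\n")
    print(round(x$estimates, 4))
  }
  invisible(x)
}

# ---- model comparison -------------------------------------------------------

#' Fit a set of models to every participant and rank them
#'
#' Fits each spec to each participant's trials, ranks models per
#' participant by BIC (ties broken by fewer free parameters, then by model
#' id), and tallies how often each model wins.
#'
#' @details
#' The belief-based models score each trial's rating pair as a probability
#' mass on the 9 x 9 attribution grid, while the associative models score
#' the two ratings as continuous Gaussian densities on the unit interval.
#' When a comparison set mixes the two conventions, ranking raw BIC values
#' would privilege densities (which are not bounded by 1). With
#' `equate_scales = TRUE` (default) the belief-family log-likelihoods are
#' converted to densities on the unit rating square before ranking — each
#' trial's cell mass is divided by the cell area `1/81`, i.e.
#' `2 * log(9)` is added per trial — which makes the two conventions
#' commensurable. The stored per-fit `bic`/`aic`/`loglik` fields are never
#' altered; only the ranking column `bic_cmp` is adjusted, and only when
#' families of both conventions are present.
#'
#' @param data Trial table with a `participant_id` column.
#' @param specs Spec tibble (rows from the model registries); all rows must
#'   belong to task families sharing the same trial-table format.
#' @param priors,config,seed As in [fit_map()].
#' @param n_obs Optional BIC sample-size override passed to [fit_map()].
#' @param equate_scales Convert bin-mass log-likelihoods to rating-square
#'   densities when ranking across measurement conventions (see Details).
#' @return A tibble of class `revattr_comparison`: one row per participant
#'   x model with the flattened fit fields, `bic_cmp`, `rank_bic`, and
#'   `best` flag.
#' @export
compare_models <- function(data, specs, priors = default_priors(),
                           config = fit_config(), seed = 1L, n_obs = NULL,
                           equate_scales = TRUE) {
  stopifnot("participant_id" %in% names(data), nrow(specs) >= 1)
  split_data <- split(data, data$participant_id)
  fam <- stats::setNames(specs$family, specs$model_id)
  rows <- purrr::imap(split_data, function(d, pid) {
    purrr::map(seq_len(nrow(specs)), function(j) {
      f <- tryCatch(
        fit_map(d, specs[j, ], priors, config,
                seed = seed + j, n_obs = n_obs),
        error = function(e) {
          warning("fit failed for participant ", pid, ", model ",
                  specs$model_id[j], ": ", conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(f)) NULL else fit_to_row(f)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  out$family <- unname(fam[out$model_id])
  mixed <- equate_scales && all(c("BB", "AS") %in% out$family)
  n_trials <- vapply(split_data, nrow, integer(1))
  out$bic_cmp <- out$bic
  if (mixed) {
    idx <- out$family == "BB"
    out$bic_cmp[idx] <- out$bic[idx] -
      2 * n_trials[out$participant_id[idx]] * log(81)
  }
  out <- dplyr::group_by(out, .data$participant_id)
  out <- dplyr::mutate(
    out,
    rank_bic = order(order(.data$bic_cmp, .data$n_free, .data$model_id)),
    best = .data$rank_bic == 1L)
  out <- dplyr::ungroup(out)
  class(out) <- c("revattr_comparison", class(out))
  out
}

fit_to_row <- function(f) {
  row <- tibble::tibble(participant_id = f$participant_id,
                        model_id = f$model_id,
                        loglik = f$loglik, logpost = f$logpost, bic = f$bic,
                        aic = f$aic, n_free = f$n_free, n_obs = f$n_obs,
                        converged = f$converged, seed = f$seed)
  if (length(f$estimates)) {
    est <- tibble::as_tibble(as.list(f$estimates))
    names(est) <- paste0("est_", names(est))
    row <- dplyr::bind_cols(row, est)
  }
  row
}

#' Tally of best-by-BIC models across participants
#'
#' @param comparison Output of [compare_models()].
#' @return Tibble `model_id`, `n_best`, `prop_best`.
#' @export
best_model_counts <- function(comparison) {
  best <- dplyr::filter(comparison, .data$best)
  tally <- dplyr::count(best, .data$model_id, name = "n_best")
  tally$prop_best <- tally$n_best / sum(tally$n_best)
  dplyr::arrange(tally, dplyr::desc(.data$n_best))
}
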