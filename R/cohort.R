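#' @title Synthetic cohort generation
#'
#' @description
#' Builds cohorts with the covariate and parameter structure of the study
#' population: a zero-heavy, right-tailed paranoia score (negative binomial
#' moment-matched to mean 3.88, sd 6.18, clipped at the observed maximum of
#' 33), a truncated-normal fluid-intelligence (ICAR) score (mean 4.96,
#' sd 2.42 on \[0, 11\]), and per-participant generating parameters for the
#' winning reversal-learning and social-attribution models drawn on link
#' scales with standardised slopes coupling z-paranoia to decision
#' temperature, prior strength over harmful intent, policy uncertainty and
#' self-interest sensitivity. Both tasks are then simulated forward for
#' every participant.
#'
#' @name synthetic_cohort
NULL

#' Population means/sds of the generating parameters on their link scales
#'
#' Link-scale locations echo the fitted group means reported for the tasks
#' (e.g. policy-map intercept near -1, sensitivities near 0.1) and prior
#' studies' typical reversal-learning estimates.
#'
#' @return Tibble `task`, `param`, `link`, `mean_link`, `sd_link`.
#' @export
cohort_base_params <- function() {
  tibble::tribble(
    ~task, ~param, ~link, ~mean_link, ~sd_link,
    "prl", "tau", "log", log(3), 0.6,
    "prl", "lambda1", "logit", stats::qlogis(0.35), 0.8,
    "prl", "S", "logit", 0, 0.8,
    "prl", "eta_pr", "logit", 0, 1.0,
    "prl", "phi", "logit", stats::qlogis(0.8), 0.8,
    "social", "pHI0", "logit", stats::qlogis(0.4), 0.9,
    "social", "uHI0", "log", log(1.5), 0.5,
    "social", "pSI0", "logit", stats::qlogis(0.6), 0.9,
    "social", "uSI0", "log", log(1.5), 0.5,
    "social", "u_pi", "log", log(1.5), 0.5,
    "social", "w0", "identity", -1, 0.8,
    "social", "wHI", "log", log(0.12), 0.7,
    "social", "wSI", "log", log(0.14), 0.8,
    "social", "eta_dg", "logit", 0, 1.2
  )
}

#' Cohort configuration
#'
#' @param n_participants Cohort size (default 200; the study itself had
#'   693, reachable by config).
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the config.
#' @param paranoia_mean,paranoia_sd,paranoia_max Target moments and cap of
#'   the paranoia (R-GPTS persecutory) score.
#' @param icar_mean,icar_sd,icar_range Target moments and support of the
#'   ICAR score.
#' @param effect_map Named numeric: standardised link-scale slopes from
#'   z-paranoia to parameters. Defaults couple paranoia to `tau` (0.13),
#'   `pHI0` (0.16), `u_pi` (0.17) and `wSI` (0.15).
#' @param base_params See [cohort_base_params()].
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 200L, seed = 1L,
                          paranoia_mean = 3.88, paranoia_sd = 6.18,
                          paranoia_max = 33,
                          icar_mean = 4.96, icar_sd = 2.42,
                          icar_range = c(0, 11),
                          effect_map = c(tau = 0.13, pHI0 = 0.16,
                                         u_pi = 0.17, wSI = 0.15),
                          base_params = cohort_base_params()) {
  if (paranoia_sd > 0 && paranoia_sd^2 <= paranoia_mean) {
    stop("paranoia_sd^2 must exceed paranoia_mean for a negative-binomial ",
         "draw (overdispersion).", call. = FALSE)
  }
  if (any(abs(effect_map) >= 1)) {
    stop("effect_map slopes are standardised and must lie in (-1, 1).",
         call. = FALSE)
  }
  structure(
    list(n_participants = as.integer(n_participants), seed = as.integer(seed),
         paranoia_mean = paranoia_mean, paranoia_sd = paranoia_sd,
         paranoia_max = paranoia_max, icar_mean = icar_mean,
         icar_sd = icar_sd, icar_range = icar_range,
         effect_map = effect_map, base_params = base_params),
    class = "cohort_config")
}

# Mean and sd of a negative binomial clipped at cap.
clipped_nb_moments <- function(mu, size, cap) {
  k <- 0:(cap - 1)
  pk <- stats::dnbinom(k, size = size, mu = mu)
  ptail <- max(0, 1 - sum(pk))
  m <- sum(k * pk) + cap * ptail
  v <- sum(k^2 * pk) + cap^2 * ptail - m^2
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Solve for negative-binomial parent parameters whose clipped moments hit
# the configured mean/sd targets.
calibrate_paranoia_parent <- function(mean_target, sd_target, cap) {
  size0 <- mean_target^2 / (sd_target^2 - mean_target)
  obj <- function(par) {
    mo <- clipped_nb_moments(exp(par[1]), exp(par[2]), cap)
    (mo["mean"] - mean_target)^2 + (mo["sd"] - sd_target)^2
  }
  fit <- stats::optim(c(log(mean_target), log(size0)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  list(mu = exp(fit$par[1]), size = exp(fit$par[2]))
}

# Mean of a normal truncated to [a, b].
truncnorm_mean <- function(m, s, a, b) {
  al <- (a - m) / s; be <- (b - m) / s
  z <- stats::pnorm(be) - stats::pnorm(al)
  m + s * (stats::dnorm(al) - stats::dnorm(be)) / z
}

#' Draw cohort covariates
#'
#' Paranoia: negative binomial with moment-matched size/mu, clipped at the
#' observed maximum. ICAR: truncated normal whose parent mean is solved so
#' the truncated mean hits the target.
#'
#' @param n Number of participants.
#' @param config A [cohort_config()]. Uses the current RNG state.
#' @return Tibble `paranoia`, `icar`.
#' @export
draw_covariates <- function(n, config = cohort_config()) {
  if (config$paranoia_sd == 0) {
    paranoia <- rep(config$paranoia_mean, n)
  } else {
    parent <- calibrate_paranoia_parent(config$paranoia_mean,
                                        config$paranoia_sd,
                                        config$paranoia_max)
    paranoia <- pmin(stats::rnbinom(n, size = parent$size, mu = parent$mu),
                     config$paranoia_max)
  }
  a <- config$icar_range[1]; b <- config$icar_range[2]
  if (config$icar_sd == 0) {
    icar <- rep(config$icar_mean, n)
  } else {
    m <- stats::uniroot(function(m) {
      truncnorm_mean(m, config$icar_sd, a, b) - config$icar_mean
    }, interval = c(a - 3 * config$icar_sd, b + 3 * config$icar_sd))$root
    u <- stats::runif(n, stats::pnorm(a, m, config$icar_sd),
                      stats::pnorm(b, m, config$icar_sd))
    icar <- stats::qnorm(u, m, config$icar_sd)
  }
  tibble::tibble(paranoia = paranoia, icar = icar)
}

#' Draw per-participant generating parameters
#'
#' On each parameter's link scale:
#' `theta_link = mean_link + sd_link * (beta * z_paranoia +
#' sqrt(1 - beta^2) * noise)`, so that `beta` is the link-scale correlation
#' between paranoia and the parameter. Values are then back-transformed to
#' their natural ranges.
#'
#' @param paranoia Numeric vector of paranoia scores.
#' @param icar Numeric vector (carried along; no default effects).
#' @param config A [cohort_config()]. Uses the current RNG state.
#' @return Tibble, one row per participant: all PRL and social parameters
#'   plus their `*_link` values.
#' @export
draw_participant_params <- function(paranoia, icar,
                                    config = cohort_config()) {
  n <- length(paranoia)
  z <- (paranoia - config$paranoia_mean) / config$paranoia_sd
  bp <- config$base_params
  out <- tibble::tibble(.rows = n)
  for (i in seq_len(nrow(bp))) {
    beta <- unname(config$effect_map[bp$param[i]])
    if (is.na(beta) || length(beta) == 0) beta <- 0
    link_val <- bp$mean_link[i] + bp$sd_link[i] *
      (beta * z + sqrt(1 - beta^2) * stats::rnorm(n))
    nat <- switch(bp$link[i],
                  log = exp(link_val),
                  logit = stats::plogis(link_val),
                  identity = link_val)
    out[[bp$param[i]]] <- nat
    out[[paste0(bp$param[i], "_link")]] <- link_val
  }
  out
}

#' Generate a full synthetic cohort
#'
#' Draws covariates and generating parameters, assigns Dictator-game
#' conditions 50/50 (alternating), and simulates both tasks forward for
#' every participant. Deterministic under the config's seed.
#'
#' @param config A [cohort_config()].
#' @return List of class `revattr_cohort`: `covariates` (participant_id,
#'   paranoia, icar, condition), `true_params` (wide tibble incl. link
#'   values), `prl_trials`, `dg_trials`, and the `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  n <- config$n_participants
  ids <- sprintf("p%04d", seq_len(n))
  cov <- draw_covariates(n, config)
  pars <- draw_participant_params(cov$paranoia, cov$icar, config)
  condition <- rep(c("initially_unfair", "initially_fair"), length.out = n)
  sim_seeds <- matrix(sample.int(2^30, 2 * n), ncol = 2)

  prl_env <- prl_environment()
  prl <- purrr::map_dfr(seq_len(n), function(i) {
    p <- prl_params(tau = pars$tau[i], lambda1 = pars$lambda1[i],
                    S = pars$S[i], phi = pars$phi[i],
                    eta_pr = pars$eta_pr[i])
    simulate_prl_agent(prl_env, p, seed = sim_seeds[i, 1],
                       participant_id = ids[i])
  })
  dg <- purrr::map_dfr(seq_len(n), function(i) {
    p <- social_params(pHI0 = pars$pHI0[i], uHI0 = pars$uHI0[i],
                       pSI0 = pars$pSI0[i], uSI0 = pars$uSI0[i],
                       u_pi = pars$u_pi[i], w0 = pars$w0[i],
                       wHI = pars$wHI[i], wSI = pars$wSI[i],
                       eta_dg = pars$eta_dg[i])
    simulate_social_agent(dg_environment(condition = condition[i]), p,
                          seed = sim_seeds[i, 2], participant_id = ids[i])
  })

  structure(
    list(covariates = dplyr::bind_cols(
           tibble::tibble(participant_id = ids), cov,
           tibble::tibble(condition = condition)),
         true_params = dplyr::bind_cols(
           tibble::tibble(participant_id = ids), pars),
         prl_trials = prl, dg_trials = dg, config = config),
    class = "revattr_cohort")
}

#' @export
print.revattr_cohort <- function(x, ...) {
  cat("<revattr_cohort> ", nrow(x$covariates), " participants\n", sep = "")
  cat("  paranoia mean/sd: ",
      round(mean(x$covariates$paranoia), 2), "/",
      round(stats::sd(x$covariates$paranoia), 2),
      "; icar mean/sd: ", round(mean(x$covariates$icar), 2), "/",
      round(stats::sd(x$covariates$icar), 2), "\n", sep = "")
  invisible(x)
}
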