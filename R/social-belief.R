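#' @title Bayesian belief-grid model of intention attribution
#'
#' @description
#' The belief-based social model represents a participant's beliefs about
#' their Dictator-game partner as a discrete joint distribution over two
#' latent attributes, harmful intent (HI) and self-interest (SI), each
#' discretised into `Nb = 9` Likert-like bins (bin 1 = totally altruistic,
#' bin 9 = totally antisocial). Priors along each dimension are
#' binomial-power distributions with a central tendency `p` and an
#' uncertainty exponent `u` (u > 1 sharpens, u < 1 blunts). A logistic
#' policy map links attribute pairs to the probability of an unfair return;
#' beliefs are updated by exact Bayes on the 81-cell grid after every
#' return, blunted by a policy-uncertainty exponent `u_pi` (plus a small
#' fixed lapse) to form the emission distribution from which the trial's
#' rating pair is drawn, and partially reset toward the initial prior at
#' the covert policy reversal via `eta_dg`.
#'
#' @name social_belief_model
NULL

NB_BINS <- 9L
#' Fixed emission lapse, 0.02 / Nb^2
#' @export
XI_LAPSE <- 0.02 / 81

#' Parameters of the belief-based social model
#'
#' @param pHI0,pSI0 Prior central tendencies over harmful intent /
#'   self-interest, in \[0, 1\].
#' @param uHI0,uSI0 Prior uncertainty exponents (> 0; values above 1 sharpen
#'   the prior, below 1 blunt it).
#' @param u_pi Policy uncertainty exponent (> 0) blunting the emission
#'   distribution.
#' @param w0 Policy-map intercept (real; negative values make fair returns
#'   the default).
#' @param wHI,wSI Policy-map sensitivities to HI / SI (>= 0).
#' @param eta_dg Reset-at-reversal mixing weight in \[0, 1\] (0 = full reset
#'   to the initial prior, 1 = full carry-over). May be length 2
#'   (`c(hi, si)`) for the two-eta variants, or `NULL` for no reset.
#' @param xi Emission lapse; fixed at `0.02/81` and never fitted.
#' @return Named list of class `social_params`.
#' @export
social_params <- function(pHI0 = 0.5, uHI0 = 1, pSI0 = 0.5, uSI0 = 1,
                          u_pi = 1, w0 = -1, wHI = 0.1, wSI = 0.1,
                          eta_dg = NULL, xi = XI_LAPSE) {
  p <- list(pHI0 = pHI0, uHI0 = uHI0, pSI0 = pSI0, uSI0 = uSI0,
            u_pi = u_pi, w0 = w0, wHI = wHI, wSI = wSI, xi = xi)
  if (!is.null(eta_dg)) p$eta_dg <- eta_dg
  validate_social_params(p)
  structure(p, class = "social_params")
}

validate_social_params <- function(p) {
  stopifnot(p$pHI0 >= 0, p$pHI0 <= 1, p$pSI0 >= 0, p$pSI0 <= 1,
            p$uHI0 >= 0, p$uSI0 >= 0, p$u_pi > 0,
            is.finite(p$w0), p$wHI >= 0, p$wSI >= 0)
  if (!is.null(p$eta_dg)) {
    stopifnot(all(p$eta_dg >= 0), all(p$eta_dg <= 1),
              length(p$eta_dg) %in% 1:2)
  }
  invisible(p)
}

#' Binomial-power prior over discrete bins
#'
#' `P_k propto Binomial(k; Nb - 1, p)^u` for `k = 0..Nb-1`, mapped onto bins
#' `1..Nb` and renormalised. `u = 1` gives the plain binomial, `u = 0` the
#' uniform distribution; larger `u` sharpens around the binomial mode.
#'
#' @param p Central tendency in \[0, 1\].
#' @param u Uncertainty exponent (>= 0).
#' @param nb Number of bins (default 9).
#' @return Probability vector of length `nb`.
#' @export
binomial_power_prior <- function(p, u, nb = NB_BINS) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1].", call. = FALSE)
  if (u < 0) stop("u must be >= 0.", call. = FALSE)
  if (nb < 2) stop("nb must be >= 2.", call. = FALSE)
  if (u == 0) return(rep(1 / nb, nb))
  # work in logs: u * log Binomial pmf, then softmax-normalise
  lw <- u * stats::dbinom(0:(nb - 1), size = nb - 1, prob = p, log = TRUE)
  if (all(!is.finite(lw))) {          # p in {0,1} with u > 0: point mass
    out <- numeric(nb)
    out[if (p < 0.5) 1 else nb] <- 1
    return(out)
  }
  lw[!is.finite(lw)] <- -Inf
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Initial joint belief grid
#'
#' Outer product of the HI and SI binomial-power priors: rows index HI bins,
#' columns index SI bins.
#'
#' @param params A [social_params()] object.
#' @param nb Grid size per dimension (default 9).
#' @return `nb x nb` matrix summing to 1.
#' @export
initial_joint_belief <- function(params, nb = NB_BINS) {
  hi <- binomial_power_prior(params$pHI0, params$uHI0, nb)
  si <- binomial_power_prior(params$pSI0, params$uSI0, nb)
  outer(hi, si)
}

#' Logistic policy map from attributes to behaviour
#'
#' `P(unfair | HI, SI) = logistic(w0 + wHI * (HI - (Nb+1)/2) +
#' wSI * (SI - (Nb+1)/2))`, with bins centred on the middle bin so the
#' intercept is the log-odds of an unfair return from a neutral partner.
#'
#' @inheritParams initial_joint_belief
#' @return `nb x nb` matrix of unfair-return probabilities in (0, 1); the
#'   fair-return map is its elementwise complement.
#' @export
build_policy_map <- function(params, nb = NB_BINS) {
  centre <- (nb + 1) / 2
  hi <- seq_len(nb) - centre
  si <- seq_len(nb) - centre
  stats::plogis(params$w0 + outer(params$wHI * hi, params$wSI * si, `+`))
}

#' One exact Bayesian belief update on the grid
#'
#' Multiplies the prior cellwise by the likelihood of the observed return
#' under the policy map and renormalises.
#'
#' @param prior `nb x nb` belief grid (normalised).
#' @param observed `"fair"` or `"unfair"`.
#' @param pmap Policy map from [build_policy_map()] (unfair-return
#'   probabilities).
#' @return Posterior belief grid.
#' @export
belief_update <- function(prior, observed, pmap) {
  lik <- if (identical(observed, "unfair")) pmap else 1 - pmap
  post <- lik * prior
  z <- sum(post)
  if (!is.finite(z) || z <= 0) {
    stop("belief update produced zero/non-finite total mass.", call. = FALSE)
  }
  post / z
}

#' Blunt a belief grid into an emission distribution
#'
#' `p_hat propto p^(1/u_pi) + xi`: large policy uncertainty flattens the
#' emitted attribution distribution; the small fixed lapse `xi` keeps every
#' cell reachable.
#'
#' @param belief Normalised belief grid.
#' @param u_pi Policy uncertainty (> 0).
#' @param xi Lapse (default `0.02/81`).
#' @return Normalised emission grid.
#' @export
blunt_for_emission <- function(belief, u_pi, xi = XI_LAPSE) {
  if (u_pi <= 0) stop("u_pi must be > 0.", call. = FALSE)
  p <- belief^(1 / u_pi) + xi
  p / sum(p)
}

#' Mix the initial prior back in at the policy reversal
#'
#' `p_bar = (1 - eta_dg) * p0 + eta_dg * p_t10`; a convex mixture, so the
#' result is a distribution by construction.
#'
#' @param prior0 Initial joint prior.
#' @param posterior Posterior after the last pre-reversal trial.
#' @param eta_dg Mixing weight in \[0, 1\].
#' @export
reset_beliefs_dg <- function(prior0, posterior, eta_dg) {
  stopifnot(eta_dg >= 0, eta_dg <= 1)
  (1 - eta_dg) * prior0 + eta_dg * posterior
}

# Two-eta variant: mix the HI and SI marginals separately, then rebuild the
# joint as the product of mixed marginals (documented reconstruction).
reset_beliefs_dg_2eta <- function(prior0, posterior, eta_hi, eta_si) {
  hi <- (1 - eta_hi) * rowSums(prior0) + eta_hi * rowSums(posterior)
  si <- (1 - eta_si) * colSums(prior0) + eta_si * colSums(posterior)
  outer(hi / sum(hi), si / sum(si))
}

#' Map a 0-100 rating to its belief bin and back
#'
#' `rating_to_bin` assigns `bin = min(9, floor(rating * 9 / 100) + 1)`;
#' `bin_to_rating` returns the bin centre `(bin - 0.5) * 100 / 9`.
#'
#' @param rating Numeric rating(s) in \[0, 100\].
#' @param bin Integer bin(s) in 1..9.
#' @param nb Number of bins.
#' @export
rating_to_bin <- function(rating, nb = NB_BINS) {
  if (any(rating < 0 | rating > 100)) {
    stop("ratings must lie in [0, 100].", call. = FALSE)
  }
  pmin(nb, floor(rating * nb / 100) + 1L)
}

#' @rdname rating_to_bin
#' @export
bin_to_rating <- function(bin, nb = NB_BINS) {
  stopifnot(all(bin >= 1), all(bin <= nb))
  (bin - 0.5) * 100 / nb
}

#' The social model registry (belief-based family)
#'
#' Six specs: policy map fixed at documented defaults (`bb_fixed_*`) or
#' individually fitted (`bb_free_*`), crossed with no, one or two
#' reset-at-reversal parameters. The winning model is `bb_free_1eta`.
#'
#' @param fixed_map Named list giving the policy-map constants used by the
#'   `bb_fixed_*` variants.
#' @return Spec tibble (same shape as [prl_model_space()]).
#' @export
social_model_space <- function(fixed_map = list(w0 = -1, wHI = 0.1, wSI = 0.1)) {
  base_free <- c("pHI0", "uHI0", "pSI0", "uSI0", "u_pi")
  map_free <- c("w0", "wHI", "wSI")
  spec <- function(model_id, free, fixed, n_eta) {
    tibble::tibble(model_id = model_id, family = "BB",
                   free_params = list(free), fixed_params = list(fixed),
                   n_free = length(free), n_eta = n_eta)
  }
  dplyr::bind_rows(
    spec("bb_fixed_0eta", base_free, fixed_map, 0L),
    spec("bb_fixed_1eta", c(base_free, "eta_dg"), fixed_map, 1L),
    spec("bb_fixed_2eta", c(base_free, "eta_hi", "eta_si"), fixed_map, 2L),
    spec("bb_free_0eta", c(base_free, map_free), list(), 0L),
    spec("bb_free_1eta", c(base_free, map_free, "eta_dg"), list(), 1L),
    spec("bb_free_2eta", c(base_free, map_free, "eta_hi", "eta_si"),
         list(), 2L)
  )
}

# Normalise eta arguments for the C++ kernel.
social_eta <- function(params) {
  if (is.null(params$eta_dg) && is.null(params$eta_hi)) {
    list(n_eta = 0L, eta_hi = 1, eta_si = 1)
  } else if (!is.null(params$eta_hi) || length(params$eta_dg) == 2L) {
    eh <- params$eta_hi %||% params$eta_dg[1]
    es <- params$eta_si %||% params$eta_dg[2]
    list(n_eta = 2L, eta_hi = eh, eta_si = es)
  } else {
    list(n_eta = 1L, eta_hi = params$eta_dg, eta_si = params$eta_dg)
  }
}

#' Trial-sequence log-likelihood for the belief-based social model
#'
#' Per trial: Bayes-update the belief grid on the observed partner return,
#' blunt it into the emission distribution, and score the observed rating
#' pair's joint bin; the unblunted posterior is carried forward, and the
#' reset mixture is applied between the last pre-reversal and first
#' post-reversal trial. Set `propagate_blunted = TRUE` to carry the blunted
#' distribution forward instead (a documented alternative reading).
#'
#' @param data Tibble with columns `trial`, `partner_return`, `hi_rating`,
#'   `si_rating`.
#' @param params A [social_params()] object; `eta_dg` may be absent
#'   (no reset), scalar, or length 2.
#' @param reversal_trial Last trial of block 1 (default 10).
#' @param propagate_blunted Carry the blunted emission distribution forward
#'   as the next prior (default `FALSE`).
#' @param engine `"cpp"` (default) or `"r"`.
#' @return Log-likelihood (scalar).
#' @export
social_loglik <- function(data, params, reversal_trial = 10L,
                          propagate_blunted = FALSE,
                          engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  assert_dg_trials(data)
  assert_contiguous_trials(data)
  validate_social_params(params)
  eta <- social_eta(params)
  prior0 <- initial_joint_belief(params)
  pmap <- build_policy_map(params)
  hi_bin <- rating_to_bin(data$hi_rating)
  si_bin <- rating_to_bin(data$si_rating)
  unfair <- as.integer(data$partner_return == "unfair")
  if (engine == "cpp") {
    ll <- social_loglik_cpp(unfair, as.integer(hi_bin), as.integer(si_bin),
                            prior0, pmap, params$u_pi, params$xi %||% XI_LAPSE,
                            eta$n_eta, eta$eta_hi, eta$eta_si,
                            as.integer(reversal_trial), propagate_blunted)
  } else {
    ll <- social_loglik_r(data, params, reversal_trial, propagate_blunted)
  }
  if (!is.finite(ll)) {
    stop("non-finite social log-likelihood.", call. = FALSE)
  }
  ll
}

# Reference recursion composed from the exported grid operations.
social_loglik_r <- function(data, params, reversal_trial = 10L,
                            propagate_blunted = FALSE) {
  eta <- social_eta(params)
  xi <- params$xi %||% XI_LAPSE
  prior0 <- initial_joint_belief(params)
  pmap <- build_policy_map(params)
  belief <- prior0
  ll <- 0
  for (i in seq_len(nrow(data))) {
    post <- belief_update(belief, data$partner_return[i], pmap)
    emit <- blunt_for_emission(post, params$u_pi, xi)
    ll <- ll + log(emit[rating_to_bin(data$hi_rating[i]),
                        rating_to_bin(data$si_rating[i])])
    belief <- if (propagate_blunted) emit else post
    if (data$trial[i] == reversal_trial && eta$n_eta > 0L) {
      belief <- if (eta$n_eta == 2L) {
        reset_beliefs_dg_2eta(prior0, belief, eta$eta_hi, eta$eta_si)
      } else {
        reset_beliefs_dg(prior0, belief, eta$eta_hi)
      }
    }
  }
  ll
}

#' Simulate an agent on the Dictator game
#'
#' Partner returns are sampled from the environment; each trial's rating
#' pair is drawn from the blunted emission grid and reported as bin centres.
#'
#' @param env A [dg_environment()].
#' @param params A [social_params()] object.
#' @param seed Optional integer seed.
#' @param participant_id Identifier written into the output table.
#' @param propagate_blunted See [social_loglik()].
#' @return Tibble with columns `participant_id`, `trial`, `partner_return`,
#'   `hi_rating`, `si_rating`, `condition`.
#' @export
simulate_social_agent <- function(env, params, seed = NULL,
                                  participant_id = "sim",
                                  propagate_blunted = FALSE) {
  validate_social_params(params)
  if (!is.null(seed)) set.seed(seed)
  eta <- social_eta(params)
  xi <- params$xi %||% XI_LAPSE
  prior0 <- initial_joint_belief(params)
  pmap <- build_policy_map(params)
  belief <- prior0
  nb <- nrow(prior0)
  n <- env$n_trials
  ret <- character(n); hi <- numeric(n); si <- numeric(n)
  for (t in seq_len(n)) {
    ret[t] <- sample_dg_return(env, t)
    post <- belief_update(belief, ret[t], pmap)
    emit <- blunt_for_emission(post, params$u_pi, xi)
    cell <- sample.int(nb * nb, 1L, prob = as.vector(emit))
    hi_bin <- (cell - 1L) %% nb + 1L          # row index (HI)
    si_bin <- (cell - 1L) %/% nb + 1L         # column index (SI)
    hi[t] <- bin_to_rating(hi_bin, nb)
    si[t] <- bin_to_rating(si_bin, nb)
    belief <- if (propagate_blunted) emit else post
    if (t == env$reversal_trial && eta$n_eta > 0L) {
      belief <- if (eta$n_eta == 2L) {
        reset_beliefs_dg_2eta(prior0, belief, eta$eta_hi, eta$eta_si)
      } else {
        reset_beliefs_dg(prior0, belief, eta$eta_hi)
      }
    }
  }
  tibble::tibble(participant_id = participant_id, trial = seq_len(n),
                 partner_return = ret, hi_rating = hi, si_rating = si,
                 condition = env$condition)
}

#' Belief trajectory in long format
#'
#' Runs the belief recursion over a participant's trials and returns every
#' grid cell's probability per trial, for plotting or export.
#'
#' @inheritParams social_loglik
#' @param blunted Return the blunted emission grids instead of the Bayes
#'   posteriors.
#' @return Tibble `participant_id`, `trial`, `hi_bin`, `si_bin`, `prob`
#'   (long format, ready for CSV export or [plot_belief_trajectory()]).
#' @export
belief_trajectory <- function(data, params, reversal_trial = 10L,
                              blunted = FALSE) {
  assert_dg_trials(data)
  validate_social_params(params)
  eta <- social_eta(params)
  xi <- params$xi %||% XI_LAPSE
  prior0 <- initial_joint_belief(params)
  pmap <- build_policy_map(params)
  belief <- prior0
  nb <- nrow(prior0)
  pid <- if ("participant_id" %in% names(data)) {
    as.character(data$participant_id[[1]])
  } else "p1"
  out <- vector("list", nrow(data))
  for (i in seq_len(nrow(data))) {
    post <- belief_update(belief, data$partner_return[i], pmap)
    grid <- if (blunted) blunt_for_emission(post, params$u_pi, xi) else post
    out[[i]] <- tibble::tibble(participant_id = pid,
                               trial = data$trial[i],
                               hi_bin = rep(seq_len(nb), times = nb),
                               si_bin = rep(seq_len(nb), each = nb),
                               prob = as.vector(grid))
    belief <- post
    if (data$trial[i] == reversal_trial && eta$n_eta > 0L) {
      belief <- if (eta$n_eta == 2L) {
        reset_beliefs_dg_2eta(prior0, belief, eta$eta_hi, eta$eta_si)
      } else {
        reset_beliefs_dg(prior0, belief, eta$eta_hi)
      }
    }
  }
  dplyr::bind_rows(out)
}
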