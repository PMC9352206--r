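#' @title Q-learning model family for the reversal-learning task
#'
#' @description
#' The non-social model family consists of variants of a three-option
#' Q-learning model with a softmax response rule. All variants share the
#' decision temperature `tau` and a learning rate `lambda1`; the richer
#' variants add a Pearce-Hall salience weight `S` (prediction-error-scaled
#' learning rate), a memory-decay parameter `phi` pulling unchosen option
#' values back to the prior mean, a reset-at-reversal parameter `eta_pr`
#' shifting all values toward the prior mean between the two task blocks,
#' a lapse rate `zeta`, and a post-reversal learning rate `lambda2`.
#'
#' Q values live on the raw points scale and are initialised at 2.5, the
#' expected value of a symbol paying +10 or -5 with even odds. Within a trial
#' the operator order is: choose (softmax over current Q), observe the
#' outcome, update salience on the absolute prediction error, update the
#' chosen option's value, decay unchosen values; the reset is applied once,
#' after the trial-30 update and before trial 31.
#'
#' @name rl_models
NULL

Q_INIT <- 2.5
# Largest attainable |prediction error|: Q and r are both confined to
# [-5, +10], so |r - Q| <= 15. Salience is kept in [0, 1] by this scaling.
PE_SCALE <- 15

#' Construct a parameter set for the reversal-learning models
#'
#' Unused parameters are left `NULL`; their presence/absence selects the
#' model variant in [prl_loglik()] and friends.
#'
#' @param tau Decision temperature (> 0), on the points scale.
#' @param lambda1 Learning rate in \[0, 1\].
#' @param lambda2 Optional post-reversal learning rate, replacing `lambda1`
#'   from trial `reversal_trial + 1` onward.
#' @param S Optional Pearce-Hall salience weight in \[0, 1\].
#' @param phi Optional memory-retention parameter in \[0, 1\] (1 = no decay).
#' @param eta_pr Optional reset-at-reversal weight in \[0, 1\].
#' @param zeta Optional lapse rate in \[0, 1\].
#' @return A named list of class `prl_params`.
#' @export
prl_params <- function(tau, lambda1, lambda2 = NULL, S = NULL, phi = NULL,
                       eta_pr = NULL, zeta = NULL) {
  p <- list(tau = tau, lambda1 = lambda1, lambda2 = lambda2, S = S,
            phi = phi, eta_pr = eta_pr, zeta = zeta)
  p <- p[!vapply(p, is.null, logical(1))]
  validate_prl_params(p)
  structure(p, class = "prl_params")
}

validate_prl_params <- function(p) {
  if (is.null(p$tau) || p$tau <= 0) stop("tau must be > 0.", call. = FALSE)
  for (nm in intersect(names(p), c("lambda1", "lambda2", "S", "phi",
                                   "eta_pr", "zeta"))) {
    v <- p[[nm]]
    if (v < 0 || v > 1) stop(nm, " must lie in [0, 1].", call. = FALSE)
  }
  invisible(p)
}

#' Initial Q state
#'
#' @return List with `q` (value triple, all 2.5) and `salience` (1).
#' @export
q_state_init <- function() list(q = rep(Q_INIT, 3), salience = 1)

#' Rescorla-Wagner value update for the chosen option
#'
#' `Q <- Q + lambda * (r - Q)` for the chosen option only.
#'
#' @param state List with elements `q` and `salience` (see [q_state_init()]).
#' @param choice Chosen option in 1..3.
#' @param reward Observed outcome (+10 or -5 in the task).
#' @param lambda Learning rate in \[0, 1\].
#' @export
q_update <- function(state, choice, reward, lambda) {
  state$q[choice] <- state$q[choice] + lambda * (reward - state$q[choice])
  state
}

#' Pearce-Hall salience-weighted update
#'
#' The salience trace is a running average of scaled absolute prediction
#' error, `salience <- S * |PE|/15 + (1 - S) * salience`, and the effective
#' learning rate is `salience * lambda`. With `S = 0` and the trace at its
#' initial value of 1, this reduces exactly to [q_update()].
#'
#' @inheritParams q_update
#' @param S Salience weight in \[0, 1\].
#' @export
pearce_hall_step <- function(state, choice, reward, lambda, S) {
  pe <- reward - state$q[choice]
  state$salience <- S * abs(pe) / PE_SCALE + (1 - S) * state$salience
  state$q[choice] <- state$q[choice] + state$salience * lambda * pe
  state
}

#' Decay unchosen option values toward the prior mean
#'
#' Every option other than `choice` moves to `2.5 - phi * (2.5 - Q)`;
#' `phi = 1` retains values perfectly, `phi = 0` forgets them entirely.
#'
#' @inheritParams q_update
#' @param phi Memory retention in \[0, 1\].
#' @export
memory_decay <- function(state, choice, phi) {
  idx <- setdiff(1:3, choice)
  state$q[idx] <- Q_INIT - phi * (Q_INIT - state$q[idx])
  state
}

#' Reset all option values toward the prior mean at the reversal
#'
#' Applied exactly once, between the last pre-reversal trial and the first
#' post-reversal trial: `Q <- Q + eta_pr * (2.5 - Q)`.
#'
#' @inheritParams q_update
#' @param eta_pr Reset weight in \[0, 1\].
#' @export
reset_at_reversal <- function(state, eta_pr) {
  state$q <- state$q + eta_pr * (Q_INIT - state$q)
  state
}

#' Softmax choice probabilities with optional lapse
#'
#' `p(c) propto exp(Q_c / tau)`, computed with the log-sum-exp trick; with a
#' lapse rate the emitted policy is `zeta/3 + (1 - zeta) * p`.
#'
#' @param q Value triple.
#' @param tau Decision temperature > 0.
#' @param zeta Lapse rate in \[0, 1\] (default 0).
#' @return Probability triple summing to 1.
#' @export
choice_probs <- function(q, tau, zeta = 0) {
  if (tau <= 0) stop("tau must be > 0.", call. = FALSE)
  z <- q / tau
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  zeta / 3 + (1 - zeta) * p
}

#' Trial-sequence log-likelihood for a reversal-learning model variant
#'
#' Sums `log pi_t(choice_t)` over the supplied trials, running the model
#' recursion selected by which parameters are present in `params` (see
#' [prl_params()]). Uses a compiled kernel by default; `engine = "r"` runs
#' the same recursion composed from the exported per-step operations.
#'
#' @param data Tibble/data frame with columns `trial`, `choice`, `reward`
#'   (a contiguous prefix of the task's trials, 1-based).
#' @param params A [prl_params()] object or named list.
#' @param reversal_trial Last trial of block 1 (default 30).
#' @param engine `"cpp"` (default) or `"r"`.
#' @return Log-likelihood (scalar).
#' @export
prl_loglik <- function(data, params, reversal_trial = 30L,
                       engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  assert_prl_trials(data)
  assert_contiguous_trials(data)
  validate_prl_params(params)
  if (engine == "cpp") {
    ll <- prl_loglik_cpp(
      as.integer(data$choice), as.numeric(data$reward),
      params$tau, params$lambda1,
      params$lambda2 %||% NA_real_, params$S %||% NA_real_,
      params$phi %||% NA_real_, params$eta_pr %||% NA_real_,
      params$zeta %||% NA_real_, as.integer(reversal_trial))
  } else {
    ll <- prl_loglik_r(data, params, reversal_trial)
  }
  if (!is.finite(ll)) {
    stop("non-finite log-likelihood for the supplied parameters.", call. = FALSE)
  }
  ll
}

# Reference recursion composed from the exported step operations.
prl_loglik_r <- function(data, params, reversal_trial = 30L) {
  st <- q_state_init()
  zeta <- params$zeta %||% 0
  ll <- 0
  for (i in seq_len(nrow(data))) {
    t <- data$trial[i]; c <- data$choice[i]; r <- data$reward[i]
    # log softmax computed directly (finite even at extreme temperatures)
    z <- st$q / params$tau
    z <- z - max(z)
    lp <- z[c] - log(sum(exp(z)))
    ll <- ll + if (zeta > 0) log(zeta / 3 + (1 - zeta) * exp(lp)) else lp
    lam <- if (!is.null(params$lambda2) && t > reversal_trial)
      params$lambda2 else params$lambda1
    if (!is.null(params$S)) {
      st <- pearce_hall_step(st, c, r, lam, params$S)
    } else {
      st <- q_update(st, c, r, lam)
    }
    if (!is.null(params$phi)) st <- memory_decay(st, c, params$phi)
    if (!is.null(params$eta_pr) && t == reversal_trial) {
      st <- reset_at_reversal(st, params$eta_pr)
    }
  }
  ll
}

#' Simulate an agent on the reversal-learning task
#'
#' Samples choices from the model's softmax (plus lapse) policy and outcomes
#' from the environment, trial by trial.
#'
#' @param env A [prl_environment()].
#' @param params A [prl_params()] object.
#' @param seed Optional integer seed (uses the global RNG if `NULL`).
#' @param participant_id Identifier written into the output table.
#' @return Tibble with columns `participant_id`, `trial`, `choice`, `reward`.
#' @export
simulate_prl_agent <- function(env, params, seed = NULL,
                               participant_id = "sim") {
  validate_prl_params(params)
  if (!is.null(seed)) set.seed(seed)
  st <- q_state_init()
  zeta <- params$zeta %||% 0
  choice <- integer(env$n_trials)
  reward <- numeric(env$n_trials)
  for (t in seq_len(env$n_trials)) {
    p <- choice_probs(st$q, params$tau, zeta)
    c <- sample.int(3L, 1L, prob = p)
    r <- sample_prl_outcome(env, t, c)
    choice[t] <- c; reward[t] <- r
    lam <- if (!is.null(params$lambda2) && t > env$reversal_trial)
      params$lambda2 else params$lambda1
    st <- if (!is.null(params$S)) pearce_hall_step(st, c, r, lam, params$S)
          else q_update(st, c, r, lam)
    if (!is.null(params$phi)) st <- memory_decay(st, c, params$phi)
    if (!is.null(params$eta_pr) && t == env$reversal_trial) {
      st <- reset_at_reversal(st, params$eta_pr)
    }
  }
  tibble::tibble(participant_id = participant_id,
                 trial = seq_len(env$n_trials),
                 choice = choice, reward = reward)
}

#' The reversal-learning model registry
#'
#' Eight model variants spanning 0 to 6 free parameters, from a pure
#' win-stay/lose-shift agent (`wsls`, a Rescorla-Wagner model pinned at
#' `tau = 0.01`, `lambda = 0.99`) through Rescorla-Wagner and Pearce-Hall
#' variants to the winning Pearce-Hall + reset + memory-decay model
#' (`ph_reset_phi`). The exact membership beyond the named families is a
#' documented reconstruction; the registry is data, so alternative spaces
#' can be assembled by subsetting or by building spec rows directly.
#'
#' @return Tibble with columns `model_id`, `family`, `free_params`
#'   (list-column of names), `fixed_params` (list-column of named lists),
#'   `n_free`.
#' @export
prl_model_space <- function() {
  spec <- function(model_id, family, free, fixed = list()) {
    tibble::tibble(model_id = model_id, family = family,
                   free_params = list(free), fixed_params = list(fixed),
                   n_free = length(free))
  }
  dplyr::bind_rows(
    spec("wsls", "WS", character(0), list(tau = 0.01, lambda1 = 0.99)),
    spec("rw2", "RW", c("tau", "lambda1")),
    spec("rw_l2", "RW", c("tau", "lambda1", "lambda2")),
    spec("rw_phi", "RW", c("tau", "lambda1", "phi")),
    spec("ph3", "PH", c("tau", "lambda1", "S")),
    spec("ph_reset", "PH", c("tau", "lambda1", "S", "eta_pr")),
    spec("ph_reset_phi", "PH", c("tau", "lambda1", "S", "eta_pr", "phi")),
    spec("ph_reset_phi_zeta", "PH",
         c("tau", "lambda1", "S", "eta_pr", "phi", "zeta"))
  )
}

#' Look up one model spec by id
#'
#' @param model_id Stable string id (e.g. `"ph_reset_phi"`).
#' @param space Registry tibble, by default the matching built-in registry.
#' @return One-row spec tibble.
#' @export
get_model_spec <- function(model_id, space = NULL) {
  if (is.null(space)) {
    space <- dplyr::bind_rows(prl_model_space(), social_model_space(),
                              assoc_model_space())
  }
  row <- space[space$model_id == model_id, ]
  if (nrow(row) != 1L) {
    stop("unknown model_id '", model_id, "'; valid ids: ",
         paste(space$model_id, collapse = ", "), call. = FALSE)
  }
  row
}

`%||%` <- function(a, b) if (is.null(a)) b else a
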