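#' Probabilistic reversal-learning task environment
#'
#' Defines the three-option reversal-learning paradigm: 60 trials, one option
#' rewarding (+10 points, otherwise -5) with high (80%), even (50%) and low
#' (20%) probability respectively. After `reversal_trial` the contingencies
#' rotate covertly: the low-probability option becomes the high one, the high
#' becomes the even one, and the even becomes the low one.
#'
#' @param n_trials Number of trials (default 60).
#' @param reversal_trial 1-based index of the last pre-reversal trial
#'   (default 30); the rotated contingencies apply from `reversal_trial + 1`.
#' @param reward_probs Probability that each of the three options pays the win
#'   outcome in block 1. Must be a permutation of `c(0.8, 0.5, 0.2)` unless
#'   `strict = FALSE` (degenerate probabilities are convenient in tests).
#' @param reward_win,reward_loss Points for a win / loss outcome.
#' @param strict Enforce the canonical 80/50/20 contingency set.
#' @return An object of class `prl_env`.
#' @examples
#' env <- prl_environment()
#' prl_reward_probs(env, trial = 31)
#' @export
prl_environment <- function(n_trials = 60L, reversal_trial = 30L,
                            reward_probs = c(0.8, 0.5, 0.2),
                            reward_win = 10, reward_loss = -5,
                            strict = TRUE) {
  stopifnot(n_trials >= 1, reversal_trial >= 1, length(reward_probs) == 3)
  if (strict && !setequal(reward_probs, c(0.8, 0.5, 0.2))) {
    stop("reward_probs must be a permutation of c(0.8, 0.5, 0.2); ",
         "use strict = FALSE for degenerate test environments.", call. = FALSE)
  }
  if (any(reward_probs < 0 | reward_probs > 1)) {
    stop("reward_probs must lie in [0, 1].", call. = FALSE)
  }
  structure(
    list(n_trials = as.integer(n_trials),
         reversal_trial = as.integer(reversal_trial),
         reward_probs_block1 = as.numeric(reward_probs),
         reward_win = reward_win, reward_loss = reward_loss,
         # explicit best-symbol probes (metadata only; no model term uses them)
         probe_trials = as.integer(c(reversal_trial, n_trials))),
    class = "prl_env")
}

#' @export
print.prl_env <- function(x, ...) {
  cat("<prl_env> ", x$n_trials, " trials, reversal after trial ",
      x$reversal_trial, "\n", sep = "")
  cat("  block 1 P(win):", paste(x$reward_probs_block1, collapse = "/"), "\n")
  cat("  block 2 P(win):", paste(rotate_reward_probs(x$reward_probs_block1),
                                 collapse = "/"), "\n")
  invisible(x)
}

# Block-2 contingencies: lowest -> high, highest -> even, even -> low.
# Implemented by rank so it works for any distinct probability triple.
rotate_reward_probs <- function(p) {
  rk <- rank(p, ties.method = "first")      # 1 = lowest, 3 = highest
  sorted <- sort(p)                          # low, even, high
  out <- numeric(3)
  out[rk == 1] <- sorted[3]                  # low -> high
  out[rk == 3] <- sorted[2]                  # high -> even
  out[rk == 2] <- sorted[1]                  # even -> low
  out
}

#' Per-trial reward probabilities
#'
#' @param env A [prl_environment()].
#' @param trial 1-based trial index.
#' @return Numeric triple: P(win) for options 1-3 on that trial.
#' @export
prl_reward_probs <- function(env, trial) {
  check_trial(env, trial)
  if (trial <= env$reversal_trial) env$reward_probs_block1
  else rotate_reward_probs(env$reward_probs_block1)
}

check_trial <- function(env, trial) {
  if (!is.numeric(trial) || length(trial) != 1L || is.na(trial) ||
      trial < 1 || trial > env$n_trials) {
    stop("trial must be a single index in [1, ", env$n_trials, "].",
         call. = FALSE)
  }
  invisible(trial)
}

#' Sample one reversal-task outcome
#'
#' Draws the reward for choosing `choice` on `trial` under the block-appropriate
#' contingency. Draws are conditional on the chosen option (no pre-generated
#' reward schedule) and use R's global RNG stream.
#'
#' @inheritParams prl_reward_probs
#' @param choice Option index in 1..3.
#' @return `reward_win` or `reward_loss` (scalar).
#' @export
sample_prl_outcome <- function(env, trial, choice) {
  check_trial(env, trial)
  if (!choice %in% 1:3) stop("choice must be in {1, 2, 3}.", call. = FALSE)
  p <- prl_reward_probs(env, trial)[choice]
  if (stats::runif(1) < p) env$reward_win else env$reward_loss
}

#' Dictator-game environment
#'
#' The repeated-reversal Dictator game: the partner receives 10 points per
#' trial and either splits them (fair, return r = 0.5) or keeps them (unfair,
#' r = 0). The partner follows an 80/20 stochastic policy that reverses after
#' `reversal_trial`: an initially-unfair partner (P(unfair) = 0.8) becomes
#' mostly fair, and vice versa.
#'
#' @param n_trials Number of trials (default 20).
#' @param reversal_trial Last trial of block 1 (default 10).
#' @param condition `"initially_unfair"` or `"initially_fair"`.
#' @param p_unfair_block1 Block-1 probability of an unfair return; defaults to
#'   0.8 / 0.2 according to `condition`.
#' @return An object of class `dg_env`.
#' @export
dg_environment <- function(n_trials = 20L, reversal_trial = 10L,
                           condition = c("initially_unfair", "initially_fair"),
                           p_unfair_block1 = NULL) {
  condition <- match.arg(condition)
  if (is.null(p_unfair_block1)) {
    p_unfair_block1 <- if (condition == "initially_unfair") 0.8 else 0.2
  }
  stopifnot(p_unfair_block1 >= 0, p_unfair_block1 <= 1, n_trials >= 1)
  structure(
    list(n_trials = as.integer(n_trials),
         reversal_trial = as.integer(reversal_trial),
         condition = condition,
         p_unfair_block1 = p_unfair_block1),
    class = "dg_env")
}

#' @export
print.dg_env <- function(x, ...) {
  cat("<dg_env> ", x$n_trials, " trials, ", x$condition,
      ", P(unfair) = ", x$p_unfair_block1, " -> ", 1 - x$p_unfair_block1,
      " after trial ", x$reversal_trial, "\n", sep = "")
  invisible(x)
}

#' Block-appropriate probability of an unfair return
#' @inheritParams sample_dg_return
#' @export
dg_p_unfair <- function(env, trial) {
  check_trial(env, trial)
  if (trial <= env$reversal_trial) env$p_unfair_block1
  else 1 - env$p_unfair_block1
}

#' Sample one partner return
#'
#' @param env A [dg_environment()].
#' @param trial 1-based trial index.
#' @return `"unfair"` or `"fair"`.
#' @export
sample_dg_return <- function(env, trial) {
  p <- dg_p_unfair(env, trial)
  if (stats::runif(1) < p) "unfair" else "fair"
}

# ---- trial-record validation ------------------------------------------------

assert_prl_trials <- function(data, env = NULL) {
  need <- c("trial", "choice", "reward")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("PRL trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(data$trial, strictly = TRUE)) {
    stop("trial indices must be strictly increasing.", call. = FALSE)
  }
  if (!all(data$choice %in% 1:3)) stop("choice must be in {1, 2, 3}.", call. = FALSE)
  win <- if (is.null(env)) 10 else env$reward_win
  loss <- if (is.null(env)) -5 else env$reward_loss
  if (!all(data$reward %in% c(win, loss))) {
    stop("reward must be in {", win, ", ", loss, "}.", call. = FALSE)
  }
  invisible(data)
}

assert_contiguous_trials <- function(data) {
  if (!identical(as.integer(data$trial), seq_len(nrow(data)))) {
    stop("likelihoods require a contiguous 1-based trial prefix (1, 2, ...).",
         call. = FALSE)
  }
  invisible(data)
}

assert_dg_trials <- function(data) {
  need <- c("trial", "partner_return", "hi_rating", "si_rating")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("DG trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(data$trial, strictly = TRUE)) {
    stop("trial indices must be strictly increasing.", call. = FALSE)
  }
  if (!all(data$partner_return %in% c("fair", "unfair"))) {
    stop("partner_return must be 'fair' or 'unfair'.", call. = FALSE)
  }
  if (any(data$hi_rating < 0 | data$hi_rating > 100 |
          data$si_rating < 0 | data$si_rating > 100)) {
    stop("ratings must lie in [0, 100].", call. = FALSE)
  }
  invisible(data)
}
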