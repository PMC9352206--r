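#' @title Model-agnostic behavioural statistics
#'
#' @description
#' Win-switch rate: of the trials on which a participant was rewarded (and
#' a next trial exists), the proportion followed by a switch to a different
#' option. Lose-stay rate: of the trials with a loss, the proportion
#' followed by repeating the same option. Rates can be computed over all
#' trials or split at the reversal; the trial-30 to trial-31 transition is
#' attributed to the pre-reversal scope, since the feedback driving that
#' switch was delivered pre-reversal.
#'
#' @name behavioral_stats
NULL

scope_index <- function(trials, scope, reversal_trial) {
  last <- max(trials)
  switch(scope,
         all_trials = trials < last,
         pre_reversal = trials <= reversal_trial & trials < last,
         post_reversal = trials > reversal_trial & trials < last,
         stop("scope must be one of all_trials, pre_reversal, post_reversal",
              call. = FALSE))
}

switch_stats_one <- function(d, scope, reversal_trial, reward_win) {
  d <- d[order(d$trial), ]
  n <- nrow(d)
  idx <- which(scope_index(d$trial, scope, reversal_trial))
  idx <- idx[idx < n]
  won <- d$reward[idx] == reward_win
  switched <- d$choice[idx + 1L] != d$choice[idx]
  n_wins <- sum(won); n_losses <- sum(!won)
  tibble::tibble(
    scope = scope,
    win_switch_rate = if (n_wins > 0) sum(won & switched) / n_wins else NA_real_,
    lose_stay_rate = if (n_losses > 0) sum(!won & !switched) / n_losses
                     else NA_real_,
    n_wins = n_wins, n_losses = n_losses)
}

#' Win-switch and lose-stay rates
#'
#' @param data PRL trial table (`trial`, `choice`, `reward`, optionally
#'   `participant_id`).
#' @param scope One or more of `"all_trials"`, `"pre_reversal"`,
#'   `"post_reversal"`.
#' @param reversal_trial Last trial of block 1 (default 30).
#' @param reward_win Points value identifying a win (default +10).
#' @return Tibble, one row per participant x scope, with
#'   `win_switch_rate`, `lose_stay_rate`, `n_wins`, `n_losses`. Zero
#'   denominators yield `NA`, never 0.
#' @export
switch_stats <- function(data, scope = "all_trials", reversal_trial = 30L,
                         reward_win = 10) {
  if (!"participant_id" %in% names(data)) data$participant_id <- "p1"
  purrr::map_dfr(split(data, data$participant_id), function(d) {
    assert_prl_trials(d[order(d$trial), ])
    purrr::map_dfr(scope, function(sc) {
      dplyr::bind_cols(tibble::tibble(participant_id = d$participant_id[1]),
                       switch_stats_one(d, sc, reversal_trial, reward_win))
    })
  })
}

#' @rdname switch_stats
#' @export
win_switch_rate <- function(data, scope = "all_trials",
                            reversal_trial = 30L, reward_win = 10) {
  dplyr::select(switch_stats(data, scope, reversal_trial, reward_win),
                "participant_id", "scope", "win_switch_rate", "n_wins")
}

#' @rdname switch_stats
#' @export
lose_stay_rate <- function(data, scope = "all_trials",
                           reversal_trial = 30L, reward_win = 10) {
  dplyr::select(switch_stats(data, scope, reversal_trial, reward_win),
                "participant_id", "scope", "lose_stay_rate", "n_losses")
}

#' Per-block proportions of best / even / worst option choices
#'
#' Classifies each choice by the chosen option's reward probability in the
#' block where the choice was made (so the block-1 best option counts as
#' the even option after the rotation).
#'
#' @param data PRL trial table.
#' @param env A [prl_environment()] defining the contingencies.
#' @return Tibble per participant x block with `p_best`, `p_even`,
#'   `p_worst` (rows sum to 1).
#' @export
choice_proportions <- function(data, env = prl_environment()) {
  assert_prl_trials(data, env)
  if (!"participant_id" %in% names(data)) data$participant_id <- "p1"
  block <- ifelse(data$trial <= env$reversal_trial, 1L, 2L)
  role <- vapply(seq_len(nrow(data)), function(i) {
    p <- prl_reward_probs(env, data$trial[i])
    rk <- rank(p, ties.method = "first")[data$choice[i]]
    c("worst", "even", "best")[rk]
  }, character(1))
  d <- tibble::tibble(participant_id = data$participant_id, block = block,
                      role = factor(role, c("best", "even", "worst")))
  out <- dplyr::count(d, .data$participant_id, .data$block, .data$role,
                      .drop = FALSE)
  out <- dplyr::group_by(out, .data$participant_id, .data$block)
  out <- dplyr::mutate(out, prop = .data$n / sum(.data$n))
  out <- dplyr::ungroup(out)
  tidyr::pivot_wider(dplyr::select(out, -"n"),
                     names_from = "role", values_from = "prop",
                     names_prefix = "p_")
}

#' Permutation test for a Spearman correlation
#'
#' Computes the observed Spearman rho and a null distribution from `B`
#' random permutations of `y`; the two-sided p-value uses the add-one
#' correction `p = (1 + #{|rho_null| >= |rho_obs|}) / (B + 1)`, so the
#' smallest attainable p is `1/(B + 1)`.
#'
#' @param x,y Numeric vectors of equal length (>= 10).
#' @param B Number of permutations (>= 100).
#' @param seed Integer seed for the permutation draws.
#' @return Object of class `revattr_perm` with `statistic` (rho),
#'   `p_permuted`, `null_draws`, `n`, `n_permutations`, `seed`.
#' @export
permutation_spearman <- function(x, y, B = 1000L, seed = 1L) {
  if (length(x) != length(y)) stop("x and y must have equal length.",
                                   call. = FALSE)
  if (length(x) < 10) stop("need at least 10 paired observations.",
                           call. = FALSE)
  if (B < 100) stop("B must be >= 100.", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman rho is undefined.", call. = FALSE)
    return(structure(list(statistic = NA_real_, p_permuted = NA_real_,
                          null_draws = rep(NA_real_, B), n = length(x),
                          n_permutations = B, seed = seed),
                     class = "revattr_perm"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  set.seed(seed)
  perm <- replicate(B, sample(ry))
  null_draws <- as.vector(stats::cor(rx, perm))
  p <- (1 + sum(abs(null_draws) >= abs(rho))) / (B + 1)
  structure(list(statistic = rho, p_permuted = p, null_draws = null_draws,
                 n = length(x), n_permutations = B, seed = seed),
            class = "revattr_perm")
}

#' @export
print.revattr_perm <- function(x, ...) {
  cat("<revattr_perm> Spearman rho = ", format(x$statistic, digits = 4),
      ", p_permuted = ", format(x$p_permuted, digits = 4),
      " (n = ", x$n, ", B = ", x$n_permutations, ")\n", sep = "")
  invisible(x)
}
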