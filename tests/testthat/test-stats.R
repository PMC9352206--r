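test_that("win-switch and lose-stay rates match hand counts", {
  # handcrafted 8-trial sequence: wins on trials 1, 4, 6; switches follow
  # trials 1 and 6 but not 4; losses on 2, 3, 5, 7; stays follow all but 5
  d <- tibble::tibble(
    trial = 1:8,
    choice = c(1, 2, 2, 2, 2, 3, 1, 1),
    reward = c(10, -5, -5, 10, -5, 10, -5, 10))
  st <- switch_stats(d)
  expect_equal(st$win_switch_rate, 2 / 3)
  expect_equal(st$lose_stay_rate, 3 / 4)
  expect_equal(st$n_wins, 3)
  expect_equal(st$n_losses, 4)
  # always-repeat agent: no win switches, always lose-stays
  rep_d <- tibble::tibble(trial = 1:6, choice = rep(2L, 6),
                          reward = c(10, -5, 10, -5, -5, 10))
  expect_equal(switch_stats(rep_d)$win_switch_rate, 0)
  expect_equal(switch_stats(rep_d)$lose_stay_rate, 1)
  # alternating winner switches after every win
  alt <- tibble::tibble(trial = 1:6, choice = rep(c(1L, 2L), 3),
                        reward = rep(10, 6))
  expect_equal(switch_stats(alt)$win_switch_rate, 1)
  expect_true(is.na(switch_stats(alt)$lose_stay_rate))  # no losses: NA, not 0
})

test_that("scope counts add up across the reversal split", {
  d <- random_prl_data(60, seed = 71)
  all_s <- switch_stats(d, "all_trials")
  pre <- switch_stats(d, "pre_reversal")
  post <- switch_stats(d, "post_reversal")
  expect_equal(pre$n_wins + post$n_wins, all_s$n_wins)
  expect_equal(pre$n_losses + post$n_losses, all_s$n_losses)
  num_all <- all_s$win_switch_rate * all_s$n_wins
  num_split <- pre$win_switch_rate * pre$n_wins +
    post$win_switch_rate * post$n_wins
  expect_equal(num_all, num_split)
})

test_that("choice proportions classify options by their block role", {
  env <- prl_environment()
  # an agent glued to the block-1 best option: best in block 1, the
  # rotation makes that same option the even one in block 2
  d <- tibble::tibble(trial = 1:60, choice = rep(1L, 60),
                      reward = rep(10, 60))
  cp <- choice_proportions(d, env)
  expect_equal(cp$p_best[cp$block == 1], 1)
  expect_equal(cp$p_even[cp$block == 2], 1)
  expect_equal(cp$p_best[cp$block == 2], 0)
  # toy record with a hand-counted split (all six trials pre-reversal)
  d2 <- tibble::tibble(trial = 1:6, choice = c(1L, 2L, 3L, 1L, 1L, 2L),
                       reward = rep(10, 6))
  cp2 <- choice_proportions(d2, env)
  expect_equal(cp2$p_best, 3 / 6)   # option 1 chosen three times
  expect_equal(cp2$p_even, 2 / 6)
  expect_equal(cp2$p_worst, 1 / 6)
  # proportions always sum to one within a block
  d3 <- random_prl_data(60, seed = 72)
  cp3 <- choice_proportions(d3, env)
  expect_equal(cp3$p_best + cp3$p_even + cp3$p_worst, c(1, 1))
})

test_that("permutation Spearman behaves at its edges", {
  x <- 1:50
  pr <- permutation_spearman(x, x, B = 500, seed = 1)
  expect_equal(pr$statistic, 1)
  expect_equal(pr$p_permuted, 1 / 501)
  expect_length(pr$null_draws, 500)
  # invariant to monotone transforms of either input
  set.seed(2)
  a <- rnorm(40); b <- rnorm(40) + 0.5 * a
  p1 <- permutation_spearman(a, b, B = 300, seed = 3)
  p2 <- permutation_spearman(exp(a), b, B = 300, seed = 3)
  p3 <- permutation_spearman(a, rank(b), B = 300, seed = 3)
  expect_equal(p1$statistic, p2$statistic)
  expect_equal(p1$p_permuted, p2$p_permuted)
  expect_equal(p1$p_permuted, p3$p_permuted)
  # constant input is flagged, not silently zero
  expect_warning(pc <- permutation_spearman(rep(1, 20), rnorm(20), B = 100),
                 "constant")
  expect_true(is.na(pc$statistic))
  expect_error(permutation_spearman(1:5, 1:5, B = 100), "at least 10")
  expect_error(permutation_spearman(1:20, 1:20, B = 10), "B must")
  # tidy() exposes the estimate and p-value
  td <- tidy(p1)
  expect_equal(td$estimate, p1$statistic)
  expect_equal(td$p.value, p1$p_permuted)
})
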