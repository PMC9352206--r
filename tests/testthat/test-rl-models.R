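test_that("value update arithmetic matches the delta rule", {
  st <- q_state_init()
  expect_equal(st$q, rep(2.5, 3))
  expect_equal(q_update(st, 1, 10, 0.5)$q[1], 6.25)
  expect_equal(q_update(st, 2, 10, 0)$q, st$q)      # zero learning
  expect_equal(q_update(st, 3, 10, 1)$q[3], 10)     # full update
  expect_equal(q_update(st, 1, -5, 0.2)$q[1], 2.5 + 0.2 * (-7.5))
})

test_that("Pearce-Hall salience scales the learning rate and nests the base rule", {
  st <- q_state_init()
  # S = 0 with salience at 1 reduces exactly to the plain update
  expect_equal(pearce_hall_step(st, 1, 10, 0.5, 0)$q,
               q_update(st, 1, 10, 0.5)$q)
  # S = 1: salience equals the scaled |PE|
  out <- pearce_hall_step(st, 1, 10, 0.5, 1)
  expect_equal(out$salience, 7.5 / 15)
  # three-step trajectory against a hand-rolled recursion
  q <- c(2.5, 2.5, 2.5); sal <- 1
  st2 <- q_state_init()
  for (tr in list(c(1, 10), c(1, -5), c(2, 10))) {
    pe <- tr[2] - q[tr[1]]
    sal <- 0.4 * abs(pe) / 15 + 0.6 * sal
    q[tr[1]] <- q[tr[1]] + sal * 0.7 * pe
    st2 <- pearce_hall_step(st2, tr[1], tr[2], 0.7, 0.4)
  }
  expect_equal(st2$q, q)
  expect_equal(st2$salience, sal)
})

test_that("memory decay pulls unchosen values to the prior mean", {
  st <- q_state_init()
  st$q <- c(10, 10, 10)
  expect_equal(memory_decay(st, 1, 1)$q, c(10, 10, 10))       # full memory
  expect_equal(memory_decay(st, 1, 0)$q, c(10, 2.5, 2.5))     # full decay
  expect_equal(memory_decay(st, 1, 0.5)$q, c(10, 6.25, 6.25))
})

test_that("reset-at-reversal shifts all values toward 2.5", {
  st <- q_state_init()
  st$q <- c(10, 2.5, -5)
  expect_equal(reset_at_reversal(st, 1)$q, rep(2.5, 3))
  expect_equal(reset_at_reversal(st, 0)$q, c(10, 2.5, -5))
  expect_equal(reset_at_reversal(st, 0.4)$q, c(7.0, 2.5, -2.0))
})

test_that("softmax choice probabilities are valid and hit their limits", {
  expect_equal(choice_probs(c(5, 5, 5), 3), rep(1 / 3, 3))
  expect_equal(choice_probs(c(10, -5, 2.5), 7, zeta = 1), rep(1 / 3, 3))
  p <- choice_probs(c(10, -5, 2.5), 5)
  expect_equal(p, oracle_softmax3(c(10, -5, 2.5), 5), tolerance = 1e-12)
  expect_error(choice_probs(c(1, 2, 3), 0), "tau")
  # probability vector for a spread of temperatures and values
  set.seed(1)
  for (i in 1:50) {
    q <- runif(3, -5, 10)
    tau <- exp(runif(1, log(1e-3), log(1e3)))
    pp <- choice_probs(q, tau)
    expect_true(all(pp >= 0))
    expect_lt(abs(sum(pp) - 1), 1e-12)
  }
  # greedy limit concentrates on the argmax
  pg <- choice_probs(c(3.5, 2.5, 2.5), 1e-3)
  expect_gt(pg[1], 1 - 1e-6)
})

test_that("trial-sequence log-likelihood has its closed forms and matches the oracle", {
  d <- random_prl_data(60, seed = 5)
  expect_equal(prl_loglik(d, prl_params(tau = 1, lambda1 = 0.5, zeta = 1)),
               60 * log(1 / 3))
  d1 <- tibble::tibble(trial = 1L, choice = 2L, reward = 10)
  expect_equal(prl_loglik(d1, prl_params(tau = 2, lambda1 = 0.3)),
               log(1 / 3))
  # oracle equivalence across 20 random (data, params) instances, both engines
  set.seed(6)
  for (i in 1:20) {
    d <- random_prl_data(60, seed = 100 + i)
    pars <- list(tau = exp(runif(1, log(0.3), log(10))),
                 lambda1 = runif(1), lambda2 = runif(1), S = runif(1),
                 phi = runif(1), eta_pr = runif(1), zeta = runif(1, 0, 0.5))
    keep <- c("tau", "lambda1",
              sample(c("lambda2", "S", "phi", "eta_pr", "zeta"),
                     sample(0:5, 1)))
    pars <- pars[unique(keep)]
    ll_or <- do.call(oracle_prl_loglik,
                     c(list(choice = d$choice, reward = d$reward), pars))
    expect_equal(prl_loglik(d, pars), ll_or, tolerance = 1e-8)
    expect_equal(prl_loglik(d, pars, engine = "r"), ll_or, tolerance = 1e-8)
  }
})

test_that("richer variants collapse exactly onto their nested models", {
  d <- random_prl_data(60, seed = 7)
  base <- prl_loglik(d, prl_params(tau = 2.5, lambda1 = 0.45))
  expect_equal(prl_loglik(d, prl_params(tau = 2.5, lambda1 = 0.45, S = 0)),
               base, tolerance = 1e-10)
  expect_equal(prl_loglik(d, prl_params(tau = 2.5, lambda1 = 0.45, phi = 1)),
               base, tolerance = 1e-10)
  expect_equal(prl_loglik(d, prl_params(tau = 2.5, lambda1 = 0.45,
                                        eta_pr = 0)),
               base, tolerance = 1e-10)
  expect_equal(prl_loglik(d, prl_params(tau = 2.5, lambda1 = 0.45,
                                        zeta = 0)),
               base, tolerance = 1e-10)
  expect_equal(prl_loglik(d, prl_params(tau = 2.5, lambda1 = 0.45,
                                        lambda2 = 0.45)),
               base, tolerance = 1e-10)
})

test_that("the model registry has the expected structure", {
  space <- prl_model_space()
  expect_equal(nrow(space), 8)
  expect_setequal(get_model_spec("ph_reset_phi", space)$free_params[[1]],
                  c("tau", "lambda1", "S", "eta_pr", "phi"))
  expect_equal(get_model_spec("wsls", space)$fixed_params[[1]],
               list(tau = 0.01, lambda1 = 0.99))
  expect_equal(get_model_spec("wsls", space)$n_free, 0)
  expect_error(get_model_spec("nope"), "unknown model_id")
})

test_that("simulated agents express their parameters", {
  # win-stay/lose-shift configuration repeats after a win
  env <- prl_environment()
  d <- simulate_prl_agent(env, prl_params(tau = 0.01, lambda1 = 0.99),
                          seed = 8)
  wins <- which(d$reward == 10 & d$trial < 60)
  expect_gt(mean(d$choice[wins + 1] == d$choice[wins]), 0.99)
  # greedy agent converges onto the winning option in a deterministic env
  env1 <- prl_environment(reward_probs = c(1, 0, 0), strict = FALSE)
  dg <- simulate_prl_agent(env1, prl_params(tau = 0.01, lambda1 = 0.5),
                           seed = 9)
  expect_true(all(dg$choice[20:30] == 1))
  # full lapse yields near-uniform choice frequencies
  env_long <- prl_environment(n_trials = 6000, reversal_trial = 3000)
  dl <- simulate_prl_agent(env_long,
                           prl_params(tau = 1, lambda1 = 0.5, zeta = 1),
                           seed = 10)
  freqs <- table(factor(dl$choice, 1:3)) / 6000
  expect_true(all(abs(freqs - 1 / 3) < 3 * sqrt(2 / 9 / 6000) + 0.01))
})
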