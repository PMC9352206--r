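test_that("binomial-power priors hit their closed forms", {
  expect_equal(binomial_power_prior(0.5, 1),
               c(1, 8, 28, 56, 70, 56, 28, 8, 1) / 256)
  expect_equal(binomial_power_prior(0.3, 0), rep(1 / 9, 9))
  expect_equal(binomial_power_prior(0.7, 2), oracle_binom_power(0.7, 2),
               tolerance = 1e-12)
  # sharpening keeps the mode, u < 1 blunts toward uniform
  b1 <- binomial_power_prior(0.7, 1)
  b3 <- binomial_power_prior(0.7, 3)
  expect_equal(which.max(b1), which.max(b3))
  expect_gt(max(b3), max(b1))
  expect_error(binomial_power_prior(1.2, 1), "p must")
})

test_that("the initial joint belief is the product of its marginals", {
  p <- social_params(pHI0 = 0.5, uHI0 = 2, pSI0 = 0.5, uSI0 = 2)
  g <- initial_joint_belief(p)
  expect_equal(sum(g), 1, tolerance = 1e-12)
  b <- oracle_binom_power(0.5, 2)
  expect_equal(g, outer(b, b), tolerance = 1e-12)
  expect_equal(rowSums(g), binomial_power_prior(0.5, 2), tolerance = 1e-12)
  # flat exponents give the uniform 1/81 grid
  pf <- social_params(uHI0 = 0, uSI0 = 0)
  expect_equal(initial_joint_belief(pf), matrix(1 / 81, 9, 9))
})

test_that("the policy map is the elementwise logistic of the linear score", {
  p0 <- social_params(w0 = 0, wHI = 0, wSI = 0)
  expect_equal(build_policy_map(p0), matrix(0.5, 9, 9))
  p1 <- social_params(w0 = -1, wHI = 0.1, wSI = 0.1)
  expect_equal(build_policy_map(p1)[5, 5], plogis(-1))
  p2 <- social_params(w0 = -1, wHI = 0.1, wSI = 0.3)
  expect_equal(build_policy_map(p2), oracle_policy_map(-1, 0.1, 0.3),
               tolerance = 1e-12)
})

test_that("grid updates are exact Bayes", {
  # uninformative likelihood leaves the prior untouched
  g <- random_belief_grid(1)
  expect_equal(belief_update(g, "unfair", matrix(0.5, 9, 9)), g)
  # an unfair return raises the harmful-intent marginal mean when wHI > 0
  p <- social_params(w0 = -1, wHI = 0.4, wSI = 0.1)
  prior <- initial_joint_belief(p)
  post <- belief_update(prior, "unfair", build_policy_map(p))
  expect_gt(sum(rowSums(post) * 1:9), sum(rowSums(prior) * 1:9))
  # five-observation sequence equals the brute-force enumeration
  pm <- build_policy_map(social_params(w0 = 0.5, wHI = 0.2, wSI = 0.15))
  obs <- c("unfair", "fair", "unfair", "unfair", "fair")
  b1 <- random_belief_grid(2); b2 <- b1
  for (o in obs) {
    b1 <- belief_update(b1, o, pm)
    b2 <- oracle_bayes_step(b2, o == "unfair", pm)
  }
  expect_equal(b1, b2, tolerance = 1e-12)
})

test_that("blunting flattens the emission distribution as intended", {
  g <- random_belief_grid(3)
  expect_equal(blunt_for_emission(g, 1, xi = 0), g)
  expect_true(all(abs(blunt_for_emission(g, 1e6, xi = 0) - 1 / 81) < 1e-4))
  # fixed lapse bounds every cell away from zero
  pm <- matrix(1e-12, 9, 9); pm[1, 1] <- 1 - 80e-12
  em <- blunt_for_emission(pm / sum(pm), 1)
  xi <- 0.02 / 81
  expect_gte(min(em), xi / (1 + 81 * xi) - 1e-15)
})

test_that("the reversal reset is a convex mixture", {
  p0 <- initial_joint_belief(social_params(pHI0 = 0.3, uHI0 = 2))
  pt <- random_belief_grid(4)
  expect_equal(reset_beliefs_dg(p0, pt, 0), p0)
  expect_equal(reset_beliefs_dg(p0, pt, 1), pt)
  expect_equal(reset_beliefs_dg(p0, pt, 0.5), (p0 + pt) / 2)
  for (e in c(0.2, 0.7)) {
    expect_equal(sum(reset_beliefs_dg(p0, pt, e)), 1, tolerance = 1e-12)
  }
})

test_that("ratings map onto bins and back consistently", {
  expect_equal(rating_to_bin(0), 1)
  expect_equal(rating_to_bin(100), 9)
  expect_equal(rating_to_bin(50), 5)
  expect_equal(bin_to_rating(5), 50)
  for (r in seq(0, 100, by = 2.5)) {
    expect_equal(rating_to_bin(bin_to_rating(rating_to_bin(r))),
                 rating_to_bin(r))
  }
  expect_error(rating_to_bin(101), "ratings")
})

test_that("the social log-likelihood matches closed forms and the oracle", {
  d <- random_dg_data(20, seed = 21)
  flat <- social_params(pHI0 = 0.5, uHI0 = 0, pSI0 = 0.5, uSI0 = 0,
                        u_pi = 1, w0 = 0, wHI = 0, wSI = 0, xi = 0)
  expect_equal(social_loglik(d, flat), 20 * log(1 / 81))
  # one-trial dataset equals a single oracle-computed cell
  d1 <- d[1, ]
  p <- social_params(pHI0 = 0.5, uHI0 = 2, pSI0 = 0.5, uSI0 = 2, u_pi = 2,
                     w0 = -1, wHI = 0.1, wSI = 0.1, eta_dg = 0.5)
  expect_equal(social_loglik(d1, p),
               oracle_social_loglik(d1$partner_return, d1$hi_rating,
                                    d1$si_rating, 0.5, 2, 0.5, 2, 2, -1,
                                    0.1, 0.1, eta_dg = 0.5),
               tolerance = 1e-12)
  # 20-trial recursion at the S11 base configuration, both engines
  ll_or <- oracle_social_loglik(d$partner_return, d$hi_rating, d$si_rating,
                                0.5, 2, 0.5, 2, 2, -1, 0.1, 0.1,
                                eta_dg = 0.5)
  expect_equal(social_loglik(d, p), ll_or, tolerance = 1e-8)
  expect_equal(social_loglik(d, p, engine = "r"), ll_or, tolerance = 1e-8)
  # random instances, both engines, including the no-eta variant
  for (i in 1:10) {
    d2 <- random_dg_data(20, seed = 300 + i)
    set.seed(400 + i)
    pp <- social_params(pHI0 = runif(1), uHI0 = runif(1, 0.2, 4),
                        pSI0 = runif(1), uSI0 = runif(1, 0.2, 4),
                        u_pi = runif(1, 0.3, 3), w0 = runif(1, -2, 2),
                        wHI = runif(1, 0, 1), wSI = runif(1, 0, 1),
                        eta_dg = if (i %% 2) runif(1) else NULL)
    ll_or <- oracle_social_loglik(d2$partner_return, d2$hi_rating,
                                  d2$si_rating, pp$pHI0, pp$uHI0, pp$pSI0,
                                  pp$uSI0, pp$u_pi, pp$w0, pp$wHI, pp$wSI,
                                  eta_dg = pp$eta_dg)
    expect_equal(social_loglik(d2, pp), ll_or, tolerance = 1e-8)
    expect_equal(social_loglik(d2, pp, engine = "r"), ll_or,
                 tolerance = 1e-8)
  }
})

test_that("with no blunting and full carry-over the recursion is batch Bayes", {
  d <- random_dg_data(20, seed = 22)
  p <- social_params(pHI0 = 0.4, uHI0 = 1.5, pSI0 = 0.6, uSI0 = 2,
                     u_pi = 1, w0 = -0.5, wHI = 0.3, wSI = 0.2,
                     eta_dg = 1, xi = 0)
  traj <- belief_trajectory(d, p)
  final <- matrix(0, 9, 9)
  last <- traj[traj$trial == 20, ]
  final[cbind(last$hi_bin, last$si_bin)] <- last$prob
  # batch: multiply all 20 likelihood factors into the prior at once
  pm <- build_policy_map(p)
  lik <- matrix(1, 9, 9)
  for (t in 1:20) {
    lik <- lik * (if (d$partner_return[t] == "unfair") pm else 1 - pm)
  }
  batch <- lik * initial_joint_belief(p)
  batch <- batch / sum(batch)
  expect_equal(final, batch, tolerance = 1e-10)
})

test_that("every produced grid is a normalised distribution", {
  set.seed(23)
  for (i in 1:100) {
    g <- random_belief_grid(600 + i)
    pm <- oracle_policy_map(runif(1, -3, 3), runif(1, 0, 1), runif(1, 0, 1))
    post <- belief_update(g, sample(c("fair", "unfair"), 1), pm)
    expect_true(all(post >= 0))
    expect_lt(abs(sum(post) - 1), 1e-10)
    em <- blunt_for_emission(post, runif(1, 0.3, 5))
    expect_lt(abs(sum(em) - 1), 1e-10)
  }
})

test_that("simulated social agents express their parameters", {
  # symmetric parameters give mean ratings near the scale midpoint
  p <- social_params(pHI0 = 0.5, uHI0 = 1, pSI0 = 0.5, uSI0 = 1,
                     u_pi = 1, w0 = 0, wHI = 0, wSI = 0)
  sims <- purrr::map_dfr(1:300, function(i) {
    simulate_social_agent(dg_environment(), p, seed = 700 + i)
  })
  expect_lt(abs(mean(sims$hi_rating) - 50), 2)
  # near-point-mass priors with no blunting emit the prior mode
  pm <- social_params(pHI0 = 0.9, uHI0 = 50, pSI0 = 0.1, uSI0 = 50,
                      u_pi = 1, w0 = 0, wHI = 0, wSI = 0, xi = 0)
  dpm <- simulate_social_agent(dg_environment(), pm, seed = 24)
  mode_hi <- which.max(binomial_power_prior(0.9, 50))
  mode_si <- which.max(binomial_power_prior(0.1, 50))
  expect_true(all(dpm$hi_rating == bin_to_rating(mode_hi)))
  expect_true(all(dpm$si_rating == bin_to_rating(mode_si)))
})

test_that("the social registry spans the published model space", {
  space <- social_model_space()
  expect_equal(nrow(space), 6)
  win <- get_model_spec("bb_free_1eta", space)
  expect_setequal(win$free_params[[1]],
                  c("pHI0", "uHI0", "pSI0", "uSI0", "u_pi", "w0", "wHI",
                    "wSI", "eta_dg"))
  expect_equal(get_model_spec("bb_fixed_2eta", space)$n_eta, 2L)
  # two-eta reset mixes the marginals separately and recombines
  p0 <- initial_joint_belief(social_params(pHI0 = 0.3, uHI0 = 2,
                                           pSI0 = 0.7, uSI0 = 2))
  pt <- random_belief_grid(25)
  mixed <- revattr:::reset_beliefs_dg_2eta(p0, pt, 0.2, 0.9)
  hi <- (1 - 0.2) * rowSums(p0) + 0.2 * rowSums(pt)
  si <- (1 - 0.9) * colSums(p0) + 0.9 * colSums(pt)
  expect_equal(mixed, outer(hi / sum(hi), si / sum(si)), tolerance = 1e-12)
  expect_equal(sum(mixed), 1, tolerance = 1e-12)
})
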