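test_that("the MAP objective is the negative penalised log-likelihood", {
  d <- random_prl_data(60, seed = 41)
  spec <- get_model_spec("rw2")
  priors <- default_priors()
  set.seed(42)
  for (i in 1:10) {
    v <- c(tau = exp(runif(1, log(0.3), log(10))), lambda1 = runif(1))
    ll <- prl_loglik(d, as.list(v))
    lp <- dgamma(v[["tau"]], 2, scale = 3, log = TRUE) +
      dbeta(v[["lambda1"]], 1.2, 1.2, log = TRUE)
    expect_equal(map_objective(v, d, spec, priors), -(ll + lp),
                 tolerance = 1e-10)
  }
  # flat priors reduce the objective to the negative log-likelihood
  flat <- priors
  flat$prior <- "flat"
  v <- c(tau = 2, lambda1 = 0.4)
  expect_equal(map_objective(v, d, spec, flat), -prl_loglik(d, as.list(v)))
  # out-of-range values yield +Inf, not errors
  expect_identical(map_objective(c(tau = -1, lambda1 = 0.4), d, spec,
                                 priors), Inf)
  expect_identical(map_objective(c(tau = 2, lambda1 = 1.4), d, spec,
                                 priors), Inf)
})

test_that("the optimiser's fast objective agrees with the validated one", {
  specs <- list(get_model_spec("ph_reset_phi_zeta"),
                get_model_spec("bb_free_1eta"),
                get_model_spec("as_shared_2eta"))
  datas <- list(random_prl_data(60, seed = 43),
                random_dg_data(20, seed = 44),
                random_dg_data(20, seed = 45))
  priors <- default_priors()
  for (j in 1:3) {
    spec <- specs[[j]]
    obj <- revattr:::make_objective(datas[[j]], spec, priors)
    free <- spec$free_params[[1]]
    set.seed(46 + j)
    for (i in 1:10) {
      truth <- revattr:::draw_recovery_params(spec, 1)
      v <- stats::setNames(as.numeric(truth[1, ]), free)
      expect_equal(obj(unname(v)), map_objective(v, datas[[j]], spec, priors),
                   tolerance = 1e-10)
    }
  }
})

test_that("one-parameter MAP matches an exhaustive 1-d search", {
  # constant-prediction associative model: only the HI intercept is free
  spec <- tibble::tibble(
    model_id = "toy", family = "AS",
    free_params = list("a_wHI0"),
    fixed_params = list(list(esv0 = 0.25, alpha = 0, a_wHI = 0,
                             a_wSI0 = 0, a_wSI = 0, sigma = 0.1)),
    n_free = 1)
  d <- random_dg_data(20, seed = 47)
  f <- fit_map(d, spec, seed = 1)
  dense <- optimize(function(w) map_objective(c(a_wHI0 = w), d, spec),
                    c(-5, 5), tol = 1e-10)
  expect_equal(unname(f$estimates["a_wHI0"]), dense$minimum,
               tolerance = 1e-4)
  expect_lte(-f$logpost, dense$objective + 1e-6)
})

test_that("fits are reproducible and dominate the grid scan", {
  d <- simulate_prl_agent(prl_environment(),
                          prl_params(tau = 2, lambda1 = 0.3), seed = 48)
  f1 <- fit_map(d, "rw2", seed = 7)
  f2 <- fit_map(d, "rw2", seed = 7)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$logpost, f2$logpost)
  # MAP beats a fresh coarse grid everywhere
  spec <- get_model_spec("rw2")
  grid <- expand.grid(tau = exp(seq(log(0.2), log(15), length.out = 12)),
                      lambda1 = seq(0.05, 0.95, length.out = 12))
  objs <- apply(grid, 1, function(g)
    map_objective(c(tau = unname(g[1]), lambda1 = unname(g[2])), d, spec))
  expect_lte(-f1$logpost, min(objs) + 1e-6)
  # BIC/AIC identities
  expect_equal(f1$bic, -2 * f1$loglik + 2 * log(60))
  expect_equal(f1$aic, -2 * f1$loglik + 4)
  # pinned model has zero free parameters and needs no optimisation
  fw <- fit_map(d, "wsls", seed = 1)
  expect_equal(fw$n_free, 0)
  expect_equal(fw$bic, -2 * fw$loglik)
})

test_that("nested models never beat their extensions by likelihood", {
  d <- simulate_prl_agent(prl_environment(),
                          prl_params(tau = 2, lambda1 = 0.35, S = 0.6,
                                     eta_pr = 0.5, phi = 0.9), seed = 49)
  ll_rw <- fit_map(d, "rw2", seed = 2)$loglik
  ll_ph <- fit_map(d, "ph3", seed = 2)$loglik
  ll_win <- fit_map(d, "ph_reset_phi", seed = 2)$loglik
  expect_gte(ll_ph, ll_rw - 1e-3)
  expect_gte(ll_win, ll_ph - 1e-3)
})

test_that("model comparison ranks by BIC with deterministic tie-breaking", {
  d <- dplyr::bind_rows(
    simulate_prl_agent(prl_environment(),
                       prl_params(tau = 1.5, lambda1 = 0.4),
                       seed = 50, participant_id = "a"),
    simulate_prl_agent(prl_environment(),
                       prl_params(tau = 3, lambda1 = 0.2),
                       seed = 51, participant_id = "b"))
  cmp <- compare_models(d, prl_model_space()[c(1, 2, 5), ], seed = 3)
  expect_equal(nrow(cmp), 6)
  expect_equal(sum(cmp$best), 2)
  per <- dplyr::count(cmp[cmp$best, ], participant_id)
  expect_true(all(per$n == 1))
  # a single spec is trivially ranked first
  cmp1 <- compare_models(d, prl_model_space()[2, ], seed = 3)
  expect_true(all(cmp1$best))
  # glance/tidy methods expose the fit fields
  f <- fit_map(d[d$participant_id == "a", ], "rw2", seed = 1)
  expect_named(tidy(f), c("term", "estimate"))
  expect_equal(glance(f)$bic, f$bic)
})
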