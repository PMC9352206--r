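test_that("expected-social-value updates follow the delta rule and stay bounded", {
  expect_equal(esv_update(0.25, 0.5, 0), 0.25)
  expect_equal(esv_update(0.25, 0.5, 1), 0.5)
  expect_equal(esv_update(0.25, 0.5, 0.4), 0.35)
  expect_equal(esv_update(0.2, "fair", 0.5), 0.35)
  expect_equal(esv_update(0.2, "unfair", 0.5), 0.1)
  # trajectory is a convex combination of esv0 and returns
  set.seed(1)
  for (i in 1:20) {
    v <- runif(1, 0, 0.5)
    a <- runif(1)
    for (t in 1:30) {
      v <- esv_update(v, sample(c(0, 0.5), 1), a)
      expect_gte(v, 0); expect_lte(v, 0.5)
    }
  }
})

test_that("attribution predictions are logistic in the centred latent", {
  p0 <- assoc_params(a_wHI0 = 0, a_wHI = 0, a_wSI0 = 0, a_wSI = 0)
  expect_equal(unname(predict_attributions(0.1, p0)), c(0.5, 0.5))
  p <- assoc_params(a_wHI0 = 0, a_wHI = -4)
  expect_equal(predict_attributions(0.5, p)[["hi"]], plogis(-1))
  # negative slope makes harmful intent decrease in expected social value
  preds <- sapply(seq(0, 0.5, 0.05), function(v)
    predict_attributions(v, p)[["hi"]])
  expect_true(all(diff(preds) < 0))
})

test_that("the associative likelihood has its closed form and matches the oracle", {
  p <- assoc_params(esv0 = 0.25, alpha = 0.3, a_wHI0 = 0, a_wHI = -4,
                    a_wSI0 = 0.5, a_wSI = -2, sigma = 0.12)
  # place observations exactly at the model's predictions
  env <- dg_environment()
  ret <- c(rep("unfair", 10), rep("fair", 10))
  vh <- p$esv0
  hi <- si <- numeric(20)
  for (t in 1:20) {
    vh <- esv_update(vh, ret[t], p$alpha)
    pr <- predict_attributions(vh, p)
    hi[t] <- pr[["hi"]] * 100
    si[t] <- pr[["si"]] * 100
  }
  d <- tibble::tibble(trial = 1:20, partner_return = ret,
                      hi_rating = hi, si_rating = si)
  expect_equal(assoc_loglik(d, p), 40 * log(1 / (p$sigma * sqrt(2 * pi))),
               tolerance = 1e-10)
  # full reset between blocks returns the latent to its starting value
  pe <- assoc_params(alpha = 1, eta = 0)
  d2 <- random_dg_data(20, seed = 31)
  ll_or <- oracle_assoc_loglik(d2$partner_return, d2$hi_rating,
                               d2$si_rating, pe$esv0, 1, pe$a_wHI0,
                               pe$a_wHI, pe$a_wSI0, pe$a_wSI, pe$sigma,
                               eta = 0)
  expect_equal(assoc_loglik(d2, pe), ll_or, tolerance = 1e-10)
  # random instances, both engines, one- and two-eta variants
  for (i in 1:10) {
    set.seed(500 + i)
    pp <- assoc_params(esv0 = runif(1, 0, 0.5), alpha = runif(1),
                       a_wHI0 = runif(1, -2, 2), a_wHI = runif(1, -8, 8),
                       a_wSI0 = runif(1, -2, 2), a_wSI = runif(1, -8, 8),
                       sigma = runif(1, 0.05, 0.4),
                       eta = switch(i %% 3 + 1, NULL, runif(1), runif(2)))
    d3 <- random_dg_data(20, seed = 600 + i)
    ll_or <- oracle_assoc_loglik(d3$partner_return, d3$hi_rating,
                                 d3$si_rating, pp$esv0, pp$alpha,
                                 pp$a_wHI0, pp$a_wHI, pp$a_wSI0, pp$a_wSI,
                                 pp$sigma, eta = pp$eta)
    expect_equal(assoc_loglik(d3, pp), ll_or, tolerance = 1e-10)
    expect_equal(assoc_loglik(d3, pp, engine = "r"), ll_or,
                 tolerance = 1e-10)
  }
  expect_error(assoc_params(sigma = 0), "sigma")
})

test_that("the associative registry has 7 specs with finite likelihoods", {
  space <- assoc_model_space()
  expect_equal(nrow(space), 7)
  expect_setequal(get_model_spec("as_2eta", space)$free_params[[1]],
                  c("esv0", "alpha", "a_wHI0", "a_wHI", "a_wSI0", "a_wSI",
                    "sigma", "eta_hi", "eta_si"))
  d <- random_dg_data(20, seed = 32)
  for (j in seq_len(nrow(space))) {
    spec <- space[j, ]
    set.seed(700 + j)
    vals <- runif(spec$n_free, 0.1, 0.4)
    names(vals) <- spec$free_params[[1]]
    obj <- map_objective(vals, d, spec)
    expect_true(is.finite(obj))
  }
})
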