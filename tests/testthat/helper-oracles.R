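# Independent straight-line oracles. These deliberately re-derive every
# quantity from first principles (plain loops, no package step functions)
# so that agreement with the package is a genuine dual-route check.

oracle_softmax3 <- function(q, tau, zeta = 0) {
  e <- exp(q / tau)
  p <- e / sum(e)
  zeta / 3 + (1 - zeta) * p
}

# Full PRL model recursion, written independently.
oracle_prl_loglik <- function(choice, reward, tau, lambda1, lambda2 = NULL,
                              S = NULL, phi = NULL, eta_pr = NULL,
                              zeta = NULL, reversal_trial = 30) {
  q <- c(2.5, 2.5, 2.5)
  sal <- 1
  z <- if (is.null(zeta)) 0 else zeta
  ll <- 0
  for (t in seq_along(choice)) {
    c <- choice[t]
    p <- oracle_softmax3(q, tau, z)
    ll <- ll + log(p[c])
    lam <- if (!is.null(lambda2) && t > reversal_trial) lambda2 else lambda1
    pe <- reward[t] - q[c]
    if (!is.null(S)) {
      sal <- S * abs(pe) / 15 + (1 - S) * sal
      q[c] <- q[c] + sal * lam * pe
    } else {
      q[c] <- q[c] + lam * pe
    }
    if (!is.null(phi)) {
      for (k in 1:3) if (k != c) q[k] <- 2.5 - phi * (2.5 - q[k])
    }
    if (!is.null(eta_pr) && t == reversal_trial) {
      q <- q + eta_pr * (2.5 - q)
    }
  }
  ll
}

# Binomial-power prior by direct term-by-term enumeration.
oracle_binom_power <- function(p, u, nb = 9) {
  if (u == 0) return(rep(1 / nb, nb))
  w <- sapply(0:(nb - 1), function(k) {
    (choose(nb - 1, k) * p^k * (1 - p)^(nb - 1 - k))^u
  })
  w / sum(w)
}

oracle_policy_map <- function(w0, wHI, wSI, nb = 9) {
  m <- matrix(0, nb, nb)
  for (i in 1:nb) for (j in 1:nb) {
    m[i, j] <- 1 / (1 + exp(-(w0 + wHI * (i - (nb + 1) / 2) +
                                wSI * (j - (nb + 1) / 2))))
  }
  m
}

# Cell-by-cell Bayes update over all 81 grid cells.
oracle_bayes_step <- function(prior, unfair, pmap) {
  nb <- nrow(prior)
  post <- matrix(0, nb, nb)
  for (i in 1:nb) for (j in 1:nb) {
    lik <- if (unfair) pmap[i, j] else 1 - pmap[i, j]
    post[i, j] <- lik * prior[i, j]
  }
  post / sum(post)
}

oracle_rating_bin <- function(r, nb = 9) min(nb, floor(r * nb / 100) + 1)

# Full belief-model recursion, written independently.
oracle_social_loglik <- function(partner_return, hi_rating, si_rating,
                                 pHI0, uHI0, pSI0, uSI0, u_pi, w0, wHI, wSI,
                                 eta_dg = NULL, reversal_trial = 10,
                                 xi = 0.02 / 81) {
  nb <- 9
  prior0 <- outer(oracle_binom_power(pHI0, uHI0, nb),
                  oracle_binom_power(pSI0, uSI0, nb))
  pmap <- oracle_policy_map(w0, wHI, wSI, nb)
  belief <- prior0
  ll <- 0
  for (t in seq_along(partner_return)) {
    post <- oracle_bayes_step(belief, partner_return[t] == "unfair", pmap)
    emit <- post^(1 / u_pi) + xi
    emit <- emit / sum(emit)
    ll <- ll + log(emit[oracle_rating_bin(hi_rating[t]),
                        oracle_rating_bin(si_rating[t])])
    belief <- post
    if (!is.null(eta_dg) && t == reversal_trial) {
      belief <- (1 - eta_dg) * prior0 + eta_dg * belief
    }
  }
  ll
}

# Full associative-model recursion, written independently.
oracle_assoc_loglik <- function(partner_return, hi_rating, si_rating,
                                esv0, alpha, a_wHI0, a_wHI, a_wSI0, a_wSI,
                                sigma, eta = NULL, reversal_trial = 10) {
  eh <- if (is.null(eta)) 1 else eta[1]
  es <- if (is.null(eta)) 1 else eta[length(eta)]
  vh <- esv0; vs <- esv0
  ll <- 0
  for (t in seq_along(partner_return)) {
    r <- if (partner_return[t] == "fair") 0.5 else 0
    vh <- vh + alpha * (r - vh)
    vs <- vs + alpha * (r - vs)
    mh <- 1 / (1 + exp(-(a_wHI0 + a_wHI * (vh - 0.25))))
    ms <- 1 / (1 + exp(-(a_wSI0 + a_wSI * (vs - 0.25))))
    ll <- ll + dnorm(hi_rating[t] / 100, mh, sigma, log = TRUE) +
      dnorm(si_rating[t] / 100, ms, sigma, log = TRUE)
    if (!is.null(eta) && t == reversal_trial) {
      vh <- (1 - eh) * esv0 + eh * vh
      vs <- (1 - es) * esv0 + es * vs
    }
  }
  ll
}

# ---- fixture builders -------------------------------------------------------

random_prl_data <- function(n = 60, seed = 1) {
  set.seed(seed)
  tibble::tibble(trial = seq_len(n),
                 choice = sample.int(3, n, replace = TRUE),
                 reward = sample(c(10, -5), n, replace = TRUE))
}

random_dg_data <- function(n = 20, seed = 1) {
  set.seed(seed)
  tibble::tibble(trial = seq_len(n),
                 partner_return = sample(c("fair", "unfair"), n,
                                         replace = TRUE),
                 hi_rating = round(runif(n, 0, 100)),
                 si_rating = round(runif(n, 0, 100)))
}

random_belief_grid <- function(seed = 1) {
  set.seed(seed)
  g <- matrix(rexp(81), 9, 9)
  g / sum(g)
}
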