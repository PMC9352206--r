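#' @title Associative comparator models of intention attribution
#'
#' @description
#' The associative family explains Dictator-game attributions without
#' belief distributions: a single scalar latent, the expected social value
#' (ESV, on the return scale \[0, 0.5\]), is updated by a delta rule on each
#' observed return, and harmful-intent / self-interest attributions are
#' logistic functions of the centred latent, observed with Gaussian noise
#' on the 0-1 rating scale. Variants add zero, one or two reset weights at
#' the reversal and may share one logistic mapping across both attributions.
#' The family is a documented reconstruction of its published description
#' and exists to exercise the model-comparison machinery.
#'
#' @name social_associative_model
NULL

ESV_CENTRE <- 0.25

#' Parameters of the associative social models
#'
#' @param esv0 Initial expected social value in \[0, 0.5\].
#' @param alpha Learning rate in \[0, 1\].
#' @param a_wHI0,a_wSI0 Attribution intercepts (real).
#' @param a_wHI,a_wSI Attribution slopes (real; sign unconstrained).
#' @param sigma Rating noise sd on the 0-1 scale (> 0).
#' @param eta Optional reset weight(s) in \[0, 1\]: scalar (shared) or
#'   `c(hi, si)`.
#' @return Named list of class `assoc_params`.
#' @export
assoc_params <- function(esv0 = 0.25, alpha = 0.3, a_wHI0 = 0, a_wHI = -4,
                         a_wSI0 = 0, a_wSI = -4, sigma = 0.1, eta = NULL) {
  p <- list(esv0 = esv0, alpha = alpha, a_wHI0 = a_wHI0, a_wHI = a_wHI,
            a_wSI0 = a_wSI0, a_wSI = a_wSI, sigma = sigma)
  if (!is.null(eta)) p$eta <- eta
  validate_assoc_params(p)
  structure(p, class = "assoc_params")
}

validate_assoc_params <- function(p) {
  stopifnot(p$esv0 >= 0, p$esv0 <= 0.5, p$alpha >= 0, p$alpha <= 1)
  if (p$sigma <= 0) stop("sigma must be > 0.", call. = FALSE)
  if (!is.null(p$eta)) stopifnot(all(p$eta >= 0), all(p$eta <= 1))
  invisible(p)
}

#' Delta-rule update of the expected social value
#'
#' `esv <- esv + alpha * (r - esv)` with returns `r` in {0, 0.5}; the latent
#' is a convex combination of its initial value and observed returns, so it
#' stays in \[0, 0.5\].
#'
#' @param esv Current latent value.
#' @param observed_return Numeric return (0 = unfair, 0.5 = fair) or the
#'   strings `"fair"`/`"unfair"`.
#' @param alpha Learning rate.
#' @export
esv_update <- function(esv, observed_return, alpha) {
  r <- if (is.character(observed_return)) {
    ifelse(observed_return == "fair", 0.5, 0)
  } else observed_return
  esv + alpha * (r - esv)
}

#' Logistic attribution predictions from the latent
#'
#' `hi_pred = logistic(a_wHI0 + a_wHI * (esv - 0.25))` and likewise for SI:
#' negative slopes make low expected social value (an ungenerous partner)
#' predict high attributions.
#'
#' @param esv Latent value in \[0, 0.5\].
#' @param params An [assoc_params()] object.
#' @return Named numeric `c(hi, si)` in (0, 1).
#' @export
predict_attributions <- function(esv, params) {
  x <- esv - ESV_CENTRE
  c(hi = stats::plogis(params$a_wHI0 + params$a_wHI * x),
    si = stats::plogis(params$a_wSI0 + params$a_wSI * x))
}

#' Trial-sequence log-likelihood for an associative social model
#'
#' Per trial the latent is updated on the observed return and both observed
#' ratings (divided by 100) are scored under Gaussian densities centred on
#' the logistic predictions, sd `sigma`. With a reset weight the latent is
#' pulled back toward `esv0` between the two blocks
#' (`esv <- (1 - eta) * esv0 + eta * esv`); the two-eta variants keep
#' separate latents for the HI and SI mappings that differ only in their
#' reset weight.
#'
#' @inheritParams social_loglik
#' @param params An [assoc_params()] object.
#' @return Log-likelihood (scalar; sum over 2 x n trials densities).
#' @export
assoc_loglik <- function(data, params, reversal_trial = 10L,
                         engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  assert_dg_trials(data)
  assert_contiguous_trials(data)
  validate_assoc_params(params)
  eta <- params$eta
  n_eta <- if (is.null(eta)) 0L else length(eta)
  eta_hi <- if (n_eta >= 1L) eta[1] else 1
  eta_si <- if (n_eta == 2L) eta[2] else eta_hi
  unfair <- as.integer(data$partner_return == "unfair")
  if (engine == "cpp") {
    ll <- assoc_loglik_cpp(unfair, data$hi_rating / 100, data$si_rating / 100,
                           params$esv0, params$alpha,
                           params$a_wHI0, params$a_wHI,
                           params$a_wSI0, params$a_wSI, params$sigma,
                           n_eta, eta_hi, eta_si, as.integer(reversal_trial))
  } else {
    ll <- assoc_loglik_r(data, params, reversal_trial)
  }
  if (!is.finite(ll)) stop("non-finite associative log-likelihood.", call. = FALSE)
  ll
}

assoc_loglik_r <- function(data, params, reversal_trial = 10L) {
  eta <- params$eta
  n_eta <- if (is.null(eta)) 0L else length(eta)
  eta_hi <- if (n_eta >= 1L) eta[1] else 1
  eta_si <- if (n_eta == 2L) eta[2] else eta_hi
  esv_hi <- params$esv0
  esv_si <- params$esv0
  ll <- 0
  for (i in seq_len(nrow(data))) {
    r <- if (data$partner_return[i] == "fair") 0.5 else 0
    esv_hi <- esv_update(esv_hi, r, params$alpha)
    esv_si <- esv_update(esv_si, r, params$alpha)
    pred_hi <- predict_attributions(esv_hi, params)[["hi"]]
    pred_si <- predict_attributions(esv_si, params)[["si"]]
    ll <- ll +
      stats::dnorm(data$hi_rating[i] / 100, pred_hi, params$sigma, log = TRUE) +
      stats::dnorm(data$si_rating[i] / 100, pred_si, params$sigma, log = TRUE)
    if (data$trial[i] == reversal_trial && n_eta > 0L) {
      esv_hi <- (1 - eta_hi) * params$esv0 + eta_hi * esv_hi
      esv_si <- (1 - eta_si) * params$esv0 + eta_si * esv_si
    }
  }
  ll
}

#' Simulate an agent from an associative social model
#'
#' @inheritParams simulate_social_agent
#' @param params An [assoc_params()] object.
#' @return Tibble in the DG trial-table format (ratings truncated to
#'   \[0, 100\]).
#' @export
simulate_assoc_agent <- function(env, params, seed = NULL,
                                 participant_id = "sim") {
  validate_assoc_params(params)
  if (!is.null(seed)) set.seed(seed)
  eta <- params$eta
  n_eta <- if (is.null(eta)) 0L else length(eta)
  eta_hi <- if (n_eta >= 1L) eta[1] else 1
  eta_si <- if (n_eta == 2L) eta[2] else eta_hi
  esv_hi <- params$esv0; esv_si <- params$esv0
  n <- env$n_trials
  ret <- character(n); hi <- numeric(n); si <- numeric(n)
  for (t in seq_len(n)) {
    ret[t] <- sample_dg_return(env, t)
    r <- if (ret[t] == "fair") 0.5 else 0
    esv_hi <- esv_update(esv_hi, r, params$alpha)
    esv_si <- esv_update(esv_si, r, params$alpha)
    hi[t] <- clamp01(stats::rnorm(1, predict_attributions(esv_hi, params)[["hi"]],
                                  params$sigma)) * 100
    si[t] <- clamp01(stats::rnorm(1, predict_attributions(esv_si, params)[["si"]],
                                  params$sigma)) * 100
    if (t == env$reversal_trial && n_eta > 0L) {
      esv_hi <- (1 - eta_hi) * params$esv0 + eta_hi * esv_hi
      esv_si <- (1 - eta_si) * params$esv0 + eta_si * esv_si
    }
  }
  tibble::tibble(participant_id = participant_id, trial = seq_len(n),
                 partner_return = ret, hi_rating = hi, si_rating = si,
                 condition = env$condition)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' The associative social model registry
#'
#' Seven specs: separate HI/SI logistic mappings with no, one or two reset
#' weights (`as_base`, `as_1eta`, `as_2eta`), a shared mapping crossed with
#' the same reset options (`as_shared*`), and a no-learning static baseline
#' (`as_static`, `alpha = 0` fixed).
#'
#' @return Spec tibble (same shape as [prl_model_space()]).
#' @export
assoc_model_space <- function() {
  sep <- c("esv0", "alpha", "a_wHI0", "a_wHI", "a_wSI0", "a_wSI", "sigma")
  shared <- c("esv0", "alpha", "a_w0", "a_w", "sigma")
  spec <- function(model_id, free, fixed = list()) {
    tibble::tibble(model_id = model_id, family = "AS",
                   free_params = list(free), fixed_params = list(fixed),
                   n_free = length(free))
  }
  dplyr::bind_rows(
    spec("as_base", sep),
    spec("as_1eta", c(sep, "eta")),
    spec("as_2eta", c(sep, "eta_hi", "eta_si")),
    spec("as_shared", shared),
    spec("as_shared_1eta", c(shared, "eta")),
    spec("as_shared_2eta", c(shared, "eta_hi", "eta_si")),
    spec("as_static", setdiff(sep, "alpha"), list(alpha = 0))
  )
}
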