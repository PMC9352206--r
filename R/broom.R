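#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a MAP fit
#'
#' @param x A `revattr_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`.
#' @export
tidy.revattr_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unname(x$estimates))
}

#' One-row fit summary
#'
#' @inheritParams tidy.revattr_fit
#' @export
glance.revattr_fit <- function(x, ...) {
  tibble::tibble(model_id = x$model_id, participant_id = x$participant_id,
                 loglik = x$loglik, logpost = x$logpost, bic = x$bic,
                 aic = x$aic, n_free = x$n_free, n_obs = x$n_obs,
                 converged = x$converged)
}

#' Tidy a permutation correlation result
#'
#' @param x A `revattr_perm`.
#' @param ... Unused.
#' @export
tidy.revattr_perm <- function(x, ...) {
  tibble::tibble(estimate = x$statistic, p.value = x$p_permuted,
                 n = x$n, n_permutations = x$n_permutations)
}

#' Recovery correlations in tidy form
#'
#' @param x A `revattr_recovery`.
#' @param ... Unused.
#' @export
tidy.revattr_recovery <- function(x, ...) x$correlations
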