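#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Null distribution of a permutation correlation
#'
#' Histogram of the permuted Spearman correlations with the observed rho
#' marked; red if the observed value is permutation-significant at 0.05.
#'
#' @param object A `revattr_perm`.
#' @param ... Unused.
#' @export
autoplot.revattr_perm <- function(object, ...) {
  df <- tibble::tibble(rho = object$null_draws)
  sig <- is.finite(object$p_permuted) && object$p_permuted < 0.05
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$statistic,
                        colour = if (sig) "red" else "black",
                        linewidth = 1) +
    ggplot2::labs(
      x = "Spearman rho (permuted)", y = "count",
      title = sprintf("rho = %.3f, p_permuted = %.4f",
                      object$statistic, object$p_permuted)) +
    ggplot2::theme_minimal()
}

#' True-versus-recovered parameter scatter
#'
#' @param object A `revattr_recovery`.
#' @param ... Unused.
#' @export
autoplot.revattr_recovery <- function(object, ...) {
  free <- object$correlations$parameter
  long <- purrr::map_dfr(free, function(nm) {
    tibble::tibble(parameter = nm,
                   true = object$results[[paste0("true_", nm)]],
                   recovered = object$results[[paste0("est_", nm)]])
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$true, y = .data$recovered)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "generating value", y = "recovered value",
                  title = paste("Parameter recovery:", object$model_id)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a belief trajectory
#'
#' @param trajectory Output of [belief_trajectory()].
#' @param trials Optional subset of trials to facet.
#' @export
plot_belief_trajectory <- function(trajectory, trials = NULL) {
  if (!is.null(trials)) {
    trajectory <- trajectory[trajectory$trial %in% trials, ]
  }
  ggplot2::ggplot(trajectory,
                  ggplot2::aes(x = .data$si_bin, y = .data$hi_bin,
                               fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~trial) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "self-interest bin", y = "harmful-intent bin",
                  fill = "probability") +
    ggplot2::theme_minimal()
}

#' Cohort covariate overview
#'
#' @param object A `revattr_cohort`.
#' @param ... Unused.
#' @export
autoplot.revattr_cohort <- function(object, ...) {
  long <- tidyr::pivot_longer(object$covariates, c("paranoia", "icar"),
                              names_to = "score", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~score, scales = "free") +
    ggplot2::theme_minimal()
}
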