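#' Coefficient interval plot for a fitted model
#'
#' Posterior medians and credible intervals of the treatment main effect and
#' treatment-by-covariate interactions for the primary outcome — the
#' coefficients that constitute the treatment benefit index.
#'
#' @param object A `tbi_fit`.
#' @param conf.level Credible level.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tbi_fit <- function(object, conf.level = 0.95, ...) {
  td <- tidy(object, conf.level = conf.level)
  keep <- c("beta0[1]", paste0("beta[1,", seq_len(object$p), "]"))
  td <- td[td$term %in% keep, ]
  td$term <- factor(td$term, levels = rev(keep))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(
      x = "posterior median and credible interval (log OR scale)",
      y = NULL,
      title = paste(object$model_tag, "model: TBI coefficients")
    )
}

#' Benchmark boxplots
#'
#' PCD and AUC distributions over replications by training size and model,
#' the standard comparative display for the multivariate-versus-univariate
#' study.
#'
#' @param object A `tbi_benchmark` from [run_benchmark()].
#' @param metric `"pcd"`, `"auc"` or `"both"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tbi_benchmark <- function(object, metric = c("both", "pcd", "auc"),
                                   ...) {
  metric <- match.arg(metric)
  df <- dplyr::filter(object, .data$status == "ok")
  long <- tidyr::pivot_longer(df, cols = c("pcd", "auc"),
                              names_to = "metric", values_to = "value")
  if (metric != "both") long <- long[long$metric == metric, ]
  ggplot2::ggplot(long,
                  ggplot2::aes(x = factor(.data$n), y = .data$value,
                               fill = .data$model)) +
    ggplot2::geom_boxplot(outlier.shape = 4, position = "dodge") +
    ggplot2::facet_grid(metric ~ sigma,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "training set size", y = NULL, fill = NULL)
}

#' Odds ratio versus TBI scatter
#'
#' Posterior-mean odds ratio of each outcome against the treatment benefit
#' index, one point per subject; the OR of the primary outcome decreases
#' monotonically in the TBI.  No smoothing is applied.
#'
#' @param object A `tbi_table` from [tbi_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tbi_table <- function(object, ...) {
  d <- attr(object, "d")
  long <- tidyr::pivot_longer(
    object,
    cols = dplyr::all_of(paste0("or_mean_", seq_len(d))),
    names_to = "outcome", values_to = "or", names_prefix = "or_mean_"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tbi, y = .data$or,
                                     colour = .data$outcome)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "treatment benefit index",
                  y = "posterior mean odds ratio", colour = "outcome")
}

#' Posterior predictive discrepancy plot
#'
#' Replicated-versus-observed discrepancy values; points above the diagonal
#' pull the Bayesian p-value towards 1.  Requires
#' `posterior_predictive_check(..., keep_samples = TRUE)`.
#'
#' @param object A `tbi_ppc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tbi_ppc <- function(object, ...) {
  s <- attr(object, "samples")
  if (is.null(s)) {
    stop("rerun posterior_predictive_check() with keep_samples = TRUE")
  }
  ggplot2::ggplot(s, ggplot2::aes(x = .data$observed, y = .data$replicated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(
      title = sprintf("%s: Bayesian p = %.3f", object$statistic[1],
                      object$bayesian_p[1]),
      x = "observed discrepancy", y = "replicated discrepancy"
    )
}
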