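#' Decision configuration
#'
#' @param threshold TBI threshold `delta` in (0, 1) above which the
#'   experimental treatment is recommended (strict inequality); default 0.5.
#' @param level Credible level for odds-ratio intervals; default 0.95.
#' @return A list of class `decision_config`.
#' @export
decision_config <- function(threshold = 0.5, level = 0.95) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  structure(list(threshold = threshold, level = level),
            class = "decision_config")
}

new_data_matrix <- function(fit, new_data) {
  if (is.matrix(new_data)) {
    X <- new_data
  } else if (is.data.frame(new_data)) {
    X <- as.matrix(new_data[fit$schema$covariates])
  } else {
    X <- matrix(as.numeric(new_data), nrow = 1)
  }
  if (ncol(X) != fit$p) {
    stop("new_data must supply p = ", fit$p, " covariates, got ", ncol(X))
  }
  X
}

#' Treatment benefit index
#'
#' `TBI(x) = Pr(beta0^(1) + x' beta^(1) < 0 | data)`: the posterior
#' probability that the treatment-control log odds ratio on the primary
#' outcome is negative, i.e. that the experimental treatment is beneficial
#' for a subject with covariates `x`.  Computed as the exact fraction of
#' retained draws with strictly negative contrast (draws at exactly 0 count
#' as not beneficial).
#'
#' @param fit A `tbi_fit`.
#' @param new_data Data frame with the model's covariate columns, a numeric
#'   covariate matrix, or a single covariate vector.
#' @return Numeric vector of TBI values in `[0, 1]`, one per subject.
#' @export
tbi <- function(fit, new_data) {
  stopifnot(inherits(fit, "tbi_fit"))
  X <- new_data_matrix(fit, new_data)
  cd <- contrast_draws(fit)
  contrasts <- cd[, 1] + cd[, -1, drop = FALSE] %*% t(X)  # S x n
  as.numeric(colMeans(contrasts < 0))
}

#' Treatment recommendation from a TBI value
#'
#' `1` (recommend the experimental treatment) iff `tbi_value > threshold`,
#' strictly; ties at the threshold map to control.
#'
#' @param tbi_value Numeric TBI value(s) in `[0, 1]`.
#' @param config A [decision_config()].
#' @return Integer vector of 0/1 recommendations.
#' @export
recommend <- function(tbi_value, config = decision_config()) {
  if (any(tbi_value < 0 | tbi_value > 1)) stop("tbi values must be in [0, 1]")
  as.integer(tbi_value > config$threshold)
}

#' Posterior odds-ratio summary for one covariate profile
#'
#' Exponentiates the per-draw treatment-control contrast for outcome `k` and
#' returns the posterior median and equal-tailed credible interval of the
#' odds ratio.
#'
#' @param fit A `tbi_fit`.
#' @param x Covariate vector of length `p`.
#' @param k Outcome index.
#' @param level Credible level.
#' @return A tibble with columns `outcome`, `or_median`, `or_lo`, `or_hi`.
#' @export
or_summary <- function(fit, x, k = 1, level = 0.95) {
  stopifnot(inherits(fit, "tbi_fit"))
  x <- check_x(x, fit$p)
  k <- check_k(k, fit$d)
  cols <- c(paste0("beta0[", k, "]"), paste0("beta[", k, ",", seq_len(fit$p), "]"))
  contrast <- fit$draws[, cols[1]] +
    fit$draws[, cols[-1], drop = FALSE] %*% x
  a <- (1 - level) / 2
  orq <- exp(quantile(contrast, c(0.5, a, 1 - a)))
  tibble::tibble(outcome = k, or_median = orq[[1]], or_lo = orq[[2]],
                 or_hi = orq[[3]])
}

#' Per-subject TBI, odds ratios and recommendations
#'
#' One row per subject of `new_data`: the TBI, the posterior mean and median
#' odds ratio of the treatment contrast for every outcome, and the 0/1
#' recommendation at the configured threshold.  This is the tabular content
#' behind OR-versus-TBI displays; no smoothing is applied.
#'
#' @inheritParams tbi
#' @param config A [decision_config()].
#' @return A tibble of class `tbi_table` with columns `subject_id`, `tbi`,
#'   `or_mean_k` / `or_median_k` / `or_lo_k` / `or_hi_k` for each outcome
#'   `k`, and `recommend`.
#' @export
tbi_table <- function(fit, new_data, config = decision_config()) {
  stopifnot(inherits(fit, "tbi_fit"))
  X <- new_data_matrix(fit, new_data)
  n <- nrow(X)
  out <- tibble::tibble(subject_id = seq_len(n),
                        tbi = if (n) tbi(fit, X) else numeric())
  a <- (1 - config$level) / 2
  for (k in seq_len(fit$d)) {
    cols <- c(paste0("beta0[", k, "]"),
              paste0("beta[", k, ",", seq_len(fit$p), "]"))
    contrasts <- fit$draws[, cols[1]] +
      fit$draws[, cols[-1], drop = FALSE] %*% t(X)  # S x n
    ors <- exp(contrasts)
    out[[paste0("or_mean_", k)]] <- if (n) colMeans(ors) else numeric()
    qs <- if (n) apply(ors, 2, quantile, probs = c(0.5, a, 1 - a)) else
      matrix(numeric(), 3, 0)
    out[[paste0("or_median_", k)]] <- qs[1, ]
    out[[paste0("or_lo_", k)]] <- qs[2, ]
    out[[paste0("or_hi_", k)]] <- qs[3, ]
  }
  out$recommend <- recommend(out$tbi, config)
  class(out) <- c("tbi_table", class(out))
  attr(out, "d") <- fit$d
  attr(out, "model_tag") <- fit$model_tag
  out
}
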