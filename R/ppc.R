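# Posterior predictive checking with Bayesian p-values.
#
# For each (thinned) retained draw, a replicated outcome table is simulated
# from the fitted likelihood at that draw; a discrepancy statistic is
# evaluated on replicated and observed data, and the Bayesian p-value is the
# fraction of draws with replicated >= observed (ties counted 1/2, so a
# degenerate statistic yields exactly 0.5).  Values near 0.5 indicate that
# the model can generate data resembling what was observed.

# per-subject ordinal category probabilities (n x L) at one draw
draw_ordinal_probs <- function(fit, X, trt, s) {
  p <- fit$p; L <- fit$L
  dr <- fit$draws[s, ]
  tau <- dr[paste0("tau1[", seq_len(L - 1), "]")]
  theta <- as.numeric(
    X %*% dr[paste0("m[1,", seq_len(p), "]")] +
      trt * (dr["beta0[1]"] + X %*% dr[paste0("beta[1,", seq_len(p), "]")])
  )
  exceed <- cbind(1, plogis(outer(theta, tau, `+`)), 0)
  -t(apply(exceed, 1, diff))
}

draw_binary_probs <- function(fit, X, trt, s) {
  p <- fit$p; d <- fit$d
  if (d < 2) return(NULL)
  dr <- fit$draws[s, ]
  vapply(2:d, function(k) {
    theta <- as.numeric(
      X %*% dr[paste0("m[", k, ",", seq_len(p), "]")] +
        trt * (dr[paste0("beta0[", k, "]")] +
                 X %*% dr[paste0("beta[", k, ",", seq_len(p), "]")])
    )
    plogis(dr[paste0("tau[", k, "]")] + theta)
  }, numeric(nrow(X)))
}

# Built-in parameter-dependent discrepancies.  Each receives the outcome
# table and the per-subject probabilities at the current draw and returns a
# scalar; chi-square-type distances between observed/replicated counts and
# their expectations under the draw.
ppc_builtin_stats <- function() {
  list(
    ordinal_chisq = function(yord, ybin, probs_ord, probs_bin) {
      L <- ncol(probs_ord)
      obs <- tabulate(yord + 1L, nbins = L)
      expd <- colSums(probs_ord)
      sum((obs - expd)^2 / pmax(expd, 1e-8))
    },
    binary_freq = function(yord, ybin, probs_ord, probs_bin) {
      if (is.null(probs_bin) || ncol(ybin) == 0) {
        stop("binary_freq discrepancy needs binary outcomes in the fit")
      }
      obs <- colSums(ybin)
      expd <- colSums(probs_bin)
      sum((obs - expd)^2 / pmax(expd, 1e-8))
    }
  )
}

#' Posterior predictive check
#'
#' @param fit A `tbi_fit` fitted to `data`.
#' @param data The observed dataset the model was fitted to.
#' @param statistic Name of a built-in discrepancy (`"ordinal_chisq"`:
#'   chi-square distance of ordinal category counts from their expected
#'   counts at each draw; `"binary_freq"`: same for binary event counts), or
#'   a function `f(yord, ybin, X, trt)` returning a scalar computed from an
#'   outcome table (applied to observed and replicated outcomes alike, e.g.
#'   a subgroup contrast on a covariate the model does not use).
#' @param n_draws Number of (evenly thinned) posterior draws to use.
#' @param keep_samples Keep the per-draw observed/replicated discrepancies.
#' @return A tibble of class `tbi_ppc` with one row: `statistic`,
#'   `bayesian_p`, `observed_mean`, `replicated_mean`, `n_draws`; when
#'   `keep_samples = TRUE` the per-draw values are in attribute `samples`.
#' @export
#' @examples
#' \donttest{
#' trial <- sim_trial(scenario_base(n_train = 200), seed = 1)
#' fit <- fit_multivariate(trial, mcmc = mcmc_config(200, 200, chains = 2))
#' posterior_predictive_check(fit, trial)
#' }
posterior_predictive_check <- function(fit, data,
                                       statistic = "ordinal_chisq",
                                       n_draws = 500, keep_samples = FALSE) {
  stopifnot(inherits(fit, "tbi_fit"))
  arr <- trial_arrays(data, L = fit$L, schema = fit$schema)
  X <- arr$X; trt <- arr$trt
  n <- nrow(X)

  param_dependent <- is.character(statistic)
  if (param_dependent) {
    reg <- ppc_builtin_stats()
    if (!statistic %in% names(reg)) {
      stop("unknown statistic '", statistic, "'; built-ins: ",
           paste(names(reg), collapse = ", "),
           " (or pass a function f(yord, ybin, X, trt))")
    }
    stat_fun <- reg[[statistic]]
    stat_name <- statistic
  } else {
    stat_fun <- statistic
    stat_name <- "custom"
  }

  S <- nrow(fit$draws)
  idx <- unique(round(seq(1, S, length.out = min(n_draws, S))))
  d_obs <- d_rep <- numeric(length(idx))
  for (ii in seq_along(idx)) {
    s <- idx[ii]
    probs_ord <- draw_ordinal_probs(fit, X, trt, s)
    probs_bin <- draw_binary_probs(fit, X, trt, s)
    # replicate outcomes from the likelihood at this draw
    u <- runif(n)
    cum <- t(apply(probs_ord, 1, cumsum))
    yord_rep <- as.integer(rowSums(u > cum))  # category index 0..L-1
    ybin_rep <- if (!is.null(probs_bin)) {
      matrix(rbinom(length(probs_bin), 1, probs_bin), nrow = n)
    } else {
      matrix(integer(), n, 0)
    }
    if (param_dependent) {
      d_obs[ii] <- stat_fun(arr$yord, arr$Ybin, probs_ord, probs_bin)
      d_rep[ii] <- stat_fun(yord_rep, ybin_rep, probs_ord, probs_bin)
    } else {
      d_obs[ii] <- stat_fun(arr$yord, arr$Ybin, X, trt)
      d_rep[ii] <- stat_fun(yord_rep, ybin_rep, X, trt)
    }
  }
  bp <- mean(d_rep > d_obs) + 0.5 * mean(d_rep == d_obs)
  out <- tibble::tibble(
    statistic = stat_name,
    bayesian_p = bp,
    observed_mean = mean(d_obs),
    replicated_mean = mean(d_rep),
    n_draws = length(idx)
  )
  class(out) <- c("tbi_ppc", class(out))
  if (keep_samples) {
    attr(out, "samples") <- tibble::tibble(draw = idx, observed = d_obs,
                                           replicated = d_rep)
  }
  out
}
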