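# Split-chain potential scale reduction factor and effective sample size.
# Classic formulations (chain-mean / within-chain variance decomposition for
# R-hat; Geyer initial-monotone-sequence truncation of the autocorrelation
# sum for ESS), computed per parameter on the constrained draws.

split_chains <- function(x, chain_id) {
  chains <- split(x, chain_id)
  out <- list()
  for (ch in chains) {
    h <- length(ch) %/% 2
    if (h < 2) return(chains)
    out <- c(out, list(ch[seq_len(h)], ch[(h + 1):(2 * h)]))
  }
  out
}

rhat_split <- function(x, chain_id) {
  sc <- split_chains(x, chain_id)
  m <- length(sc)
  n <- length(sc[[1]])
  if (m < 2 || n < 2) return(NA_real_)
  means <- vapply(sc, mean, 0)
  vars <- vapply(sc, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_geyer <- function(x, chain_id) {
  sc <- split_chains(x, chain_id)
  m <- length(sc)
  n <- length(sc[[1]])
  if (n < 4) return(NA_real_)
  W <- mean(vapply(sc, var, 0))
  B <- n * var(vapply(sc, mean, 0))
  var_plus <- (n - 1) / n * W + B / n
  if (!is.finite(var_plus) || var_plus == 0) return(NA_real_)
  # mean autocovariance across split chains
  max_lag <- min(n - 1, 2000)
  acov <- rowMeans(vapply(sc, function(ch) {
    a <- stats::acf(ch, lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    length(a) <- max_lag + 1
    a[is.na(a)] <- 0
    a
  }, numeric(max_lag + 1)))
  rho <- 1 - (W - acov) / var_plus
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  s <- 0
  prev <- Inf
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    prev <- pair
    s <- s + pair
    t <- t + 2
  }
  tau <- max(-1 + 2 * s, 1 / (m * n))  # rho[1] term: -1 + 2*sum of pairs
  max(1, m * n / tau)
}

#' MCMC diagnostics report
#'
#' Per-parameter split-R-hat and effective sample size plus per-chain
#' divergence counts.  Parameters with split-R-hat above 1.01 are flagged.
#' With a single chain R-hat is omitted with a warning.
#'
#' @param fit A `tbi_fit`.
#' @param rhat_threshold Flagging threshold (default 1.01).
#' @return A tibble with one row per parameter: `term`, `rhat`, `ess`,
#'   `flagged`; attributes `divergences` (total) and `sampler` (per-chain
#'   table).
#' @export
mcmc_diagnostics <- function(fit, rhat_threshold = 1.01) {
  stopifnot(inherits(fit, "tbi_fit"))
  single <- fit$mcmc$chains < 2
  if (single) {
    warning("only one chain: split R-hat between chains is omitted")
  }
  terms <- colnames(fit$draws)
  rhat <- vapply(terms, function(tm) {
    rhat_split(fit$draws[, tm], fit$chain_id)
  }, 0)
  ess <- vapply(terms, function(tm) {
    ess_geyer(fit$draws[, tm], fit$chain_id)
  }, 0)
  out <- tibble::tibble(
    term = terms,
    rhat = if (single) NA_real_ else unname(rhat),
    ess = unname(ess),
    flagged = !single & (is.na(rhat) | rhat > rhat_threshold)
  )
  attr(out, "divergences") <- sum(fit$divergent)
  attr(out, "sampler") <- fit$sampler
  out
}

#' @describeIn mcmc_diagnostics Tidy posterior summaries: one row per
#'   parameter with posterior median, equal-tailed credible interval,
#'   R-hat and ESS.
#' @param x A `tbi_fit`.
#' @param conf.level Credible level for the equal-tailed interval.
#' @param ... Unused.
#' @export
tidy.tbi_fit <- function(x, conf.level = 0.95, ...) {
  a <- (1 - conf.level) / 2
  qs <- apply(x$draws, 2, quantile, probs = c(a, 0.5, 1 - a))
  tibble::tibble(
    term = colnames(x$draws),
    estimate = qs[2, ],
    conf.low = qs[1, ],
    conf.high = qs[3, ],
    std.error = apply(x$draws, 2, sd)
  )
}

#' @describeIn mcmc_diagnostics One-row model summary (sample sizes,
#'   divergences, worst R-hat, smallest ESS).
#' @export
glance.tbi_fit <- function(x, ...) {
  dg <- suppressWarnings(mcmc_diagnostics(x))
  tibble::tibble(
    model = x$model_tag,
    n = x$n, p = x$p, d = x$d, L = x$L,
    chains = x$mcmc$chains,
    draws = nrow(x$draws),
    divergences = sum(x$divergent),
    max_rhat = if (all(is.na(dg$rhat))) NA_real_ else
      max(dg$rhat, na.rm = TRUE),
    min_ess = min(dg$ess, na.rm = TRUE)
  )
}
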