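#' Simulate trial covariates
#'
#' The first `binary_count` columns are i.i.d. Bernoulli(0.5), the remaining
#' `p - binary_count` columns i.i.d. standard normal.
#'
#' @param n Number of subjects (0 allowed).
#' @param p Number of covariates.
#' @param binary_count Number of leading binary covariates (default 3).
#' @param seed Optional integer seed (set locally, restoring the RNG state).
#' @return An `n x p` numeric matrix with column names `x1..xp`.
#' @export
sim_covariates <- function(n, p, binary_count = 3, seed = NULL) {
  if (p < binary_count) {
    stop("p = ", p, " is smaller than the number of binary covariates (",
         binary_count, ")")
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  X <- matrix(0, nrow = n, ncol = p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  if (n > 0) {
    if (binary_count > 0) {
      X[, seq_len(binary_count)] <- rbinom(n * binary_count, 1, 0.5)
    }
    if (p > binary_count) {
      X[, (binary_count + 1):p] <- rnorm(n * (p - binary_count))
    }
  }
  X
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Simulate a synthetic trial dataset
#'
#' Draws treatment `A ~ Bernoulli(treatment_prob)`, covariates per
#' [sim_covariates()], optional subject-level random effects `gamma_i0` and
#' `Gamma_i` (i.i.d. Normal(0, sigma^2), shared across outcomes), then
#' samples the primary ordinal outcome from the cumulative proportional-odds
#' model and each binary outcome from its logistic model at the scenario's
#' true coefficients.  With `random_effect_sd = 0` this is exactly the
#' fixed-effect generator; with `sigma > 0` the linear predictor becomes
#' `theta_i^(k) = x_i' m^(k) + a_i (beta_0^(k) + gamma_i0) +
#' a_i x_i' (beta^(k) + Gamma_i)`.
#'
#' @param scenario A [trial_scenario].
#' @param split `"train"` or `"test"`; selects `n_train` or `n_test`.
#' @param seed Integer seed; the split contributes a fixed offset so train
#'   and test draws are independent under one master seed.
#' @param n Optional explicit sample size overriding the split size.
#' @return A tibble with columns `x1..xp`, `trt`, `y1` (ordinal, `0..L-1`),
#'   `y2..yd` (binary), carrying attributes `truth` (the generating
#'   [coef_set]), `scenario`, `random_effects` (n x (p+1) matrix, columns
#'   `gamma0`, `Gamma1..Gammap`) and `L`.
#' @export
#' @examples
#' trial <- sim_trial(scenario_base(n_train = 100), seed = 1)
#' table(trial$y1)
sim_trial <- function(scenario, split = c("train", "test"), seed = 1,
                      n = NULL) {
  stopifnot(inherits(scenario, "trial_scenario"))
  split <- match.arg(split)
  if (is.null(n)) {
    n <- if (split == "train") scenario$n_train else scenario$n_test
  }
  truth <- scenario$truth
  p <- truth$p
  d <- truth$d
  L <- truth$L

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  # fixed split offset keeps train/test independent under one master seed
  set.seed((abs(seed) + if (split == "test") 499979L else 0L) %%
             .Machine$integer.max)

  X <- sim_covariates(n, p, scenario$binary_covariate_count)
  trt <- rbinom(n, 1, scenario$treatment_prob)

  sigma <- scenario$random_effect_sd
  re <- matrix(0, n, p + 1,
               dimnames = list(NULL, c("gamma0", paste0("Gamma", seq_len(p)))))
  if (sigma > 0 && n > 0) re[] <- rnorm(n * (p + 1), 0, sigma)

  Y <- matrix(0L, n, d, dimnames = list(NULL, paste0("y", seq_len(d))))
  for (k in seq_len(d)) {
    theta <- as.numeric(
      X %*% truth$cov_main[, k] +
        trt * (truth$trt_main[k] + re[, 1]) +
        trt * (X %*% truth$interaction[, k])
    )
    if (sigma > 0 && n > 0) {
      theta <- theta + trt * rowSums(X * re[, -1, drop = FALSE])
    }
    if (k == 1) {
      # P(Y >= y) = G(tau_y + theta) are nested events; one uniform draw
      # gives Y = number of exceedance thresholds passed
      exceed <- plogis(outer(theta, truth$ordinal_intercepts, `+`))
      u <- runif(n)
      Y[, 1] <- as.integer(rowSums(u <= exceed))
    } else {
      pr <- plogis(truth$binary_intercepts[k - 1] + theta)
      Y[, k] <- rbinom(n, 1, pr)
    }
  }

  out <- tibble::as_tibble(as.data.frame(cbind(X, trt = trt, Y)))
  attr(out, "truth") <- truth
  attr(out, "scenario") <- scenario
  attr(out, "random_effects") <- re
  attr(out, "L") <- L
  attr(out, "seed") <- seed
  attr(out, "split") <- split
  out
}

#' Per-replication seed derivation
#'
#' Counter-based scheme so replication `r` of a benchmark run is reproducible
#' in isolation from the master seed alone.
#'
#' @param master Master integer seed.
#' @param r Replication counter (1-based).
#' @return Integer seed below 2^31.
#' @export
replication_seed <- function(master, r) {
  as.integer((abs(as.numeric(master)) %% 1000003 + 100003 * as.numeric(r)) %%
               2147483647)
}
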