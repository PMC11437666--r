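#' Default ordinal intercepts: uniform reference categories
#'
#' The simulation truths in the literature this package mirrors print every
#' regression coefficient but not the intercepts.  The package default places
#' the control-arm reference subject (`x = 0`) at uniform category
#' probabilities: `tau_y = logit(1 - y/L)` for `y = 1..L-1`, which is strictly
#' decreasing in `y`.
#'
#' @param L Number of ordinal levels (>= 2).
#' @return Numeric vector of length `L - 1`.
#' @export
uniform_ordinal_intercepts <- function(L) {
  stopifnot(L >= 2)
  y <- seq_len(L - 1)
  qlogis(1 - y / L)
}

#' Generative scenario for a synthetic trial
#'
#' Describes every parameter of the data-generating process: sample sizes,
#' covariate scheme (3 Bernoulli(0.5) covariates plus `p - 3` standard
#' normals by default), the true coefficient set, the element-wise standard
#' deviation `sigma` of the subject-level random effects on the treatment
#' main effect and interactions, and an optional null mask zeroing the
#' treatment effects of selected outcomes.
#'
#' @param truth A [coef_set] holding the true coefficients.
#' @param n_train,n_test Training and test sample sizes.
#' @param random_effect_sd `sigma >= 0`: SD of the subject-level random
#'   effects `gamma_i0` (treatment main effect) and the `p` components of
#'   `Gamma_i` (interactions), i.i.d. Normal(0, sigma^2), shared across
#'   outcomes.  `sigma = 0` gives the fixed-effect generator.
#' @param treatment_prob Probability of assignment to the experimental arm.
#' @param binary_covariate_count Number of leading Bernoulli(0.5) covariates.
#' @param null_mask Integer vector of outcome indices whose treatment main
#'   effect and interactions are zeroed (see [apply_null_mask()]).
#' @param label Free-text scenario name carried into metadata.
#' @return An object of class `trial_scenario`.
#' @seealso [scenario_base()], [scenario_sensitivity()], [scenario_null()]
#' @export
trial_scenario <- function(truth, n_train = 500, n_test = 2000,
                           random_effect_sd = 0, treatment_prob = 0.5,
                           binary_covariate_count = 3, null_mask = integer(),
                           label = "custom") {
  stopifnot(inherits(truth, "coef_set"))
  if (random_effect_sd < 0) stop("random_effect_sd must be >= 0")
  if (treatment_prob <= 0 || treatment_prob >= 1) {
    stop("treatment_prob must be in (0, 1)")
  }
  if (binary_covariate_count > truth$p) {
    stop("binary_covariate_count cannot exceed p = ", truth$p)
  }
  sc <- structure(
    list(
      truth = truth, n_train = n_train, n_test = n_test,
      random_effect_sd = random_effect_sd, treatment_prob = treatment_prob,
      binary_covariate_count = binary_covariate_count,
      null_mask = as.integer(null_mask), label = label
    ),
    class = "trial_scenario"
  )
  if (length(null_mask)) sc <- apply_null_mask(sc, null_mask) else sc
}

#' @export
print.trial_scenario <- function(x, ...) {
  cat("<trial_scenario>", x$label, "\n")
  cat("  p =", x$truth$p, ", d =", x$truth$d, ", L =", x$truth$L,
      ", sigma =", x$random_effect_sd, "\n")
  cat("  n_train =", x$n_train, ", n_test =", x$n_test, "\n")
  if (length(x$null_mask)) cat("  null mask on outcomes:", x$null_mask, "\n")
  invisible(x)
}

# True coefficient values of the comparative simulation study: p = 5
# covariates, d = 4 outcomes (11-level ordinal + 3 binary).
base_truth <- function(L = 11) {
  cov_main <- cbind(
    c(0.35, -0.40, 0.15, 0.20, -0.21),
    c(0.40, -0.38, 0.13, 0.19, -0.22),
    c(0.38, -0.39, 0.14, 0.18, -0.20),
    c(0.42, -0.41, 0.16, 0.21, -0.19)
  )
  interaction <- cbind(
    c(0.20, -0.10, 0.10, 0.05, -0.06),
    c(0.19, -0.11, 0.09, 0.04, -0.07),
    c(0.18, -0.12, 0.11, 0.06, -0.05),
    c(0.21, -0.09, 0.12, 0.07, -0.04)
  )
  coef_set(
    ordinal_intercepts = uniform_ordinal_intercepts(L),
    binary_intercepts = c(0, 0, 0),
    cov_main = cov_main,
    trt_main = c(-0.05, -0.06, -0.03, -0.04),
    interaction = interaction
  )
}

#' Scenario presets
#'
#' `scenario_base()` is the comparative-study setting: `p = 5` covariates
#' (3 binary, 2 continuous), `d = 4` outcomes (one 11-level ordinal, three
#' binary), true treatment main effects `(-0.05, -0.06, -0.03, -0.04)` and
#' positively correlated interaction vectors of similar magnitude across
#' outcomes, no random effects.  `scenario_sensitivity(sigma)` adds
#' subject-level random effects with element-wise SD `sigma` (grid used in
#' sensitivity analyses: 0.1, 0.2, 0.3).  `scenario_null(mask)` zeroes the
#' treatment main effect and interactions of the masked outcomes (default:
#' outcome 4), the misspecified-null setting.
#'
#' @param n_train,n_test Sample sizes (defaults 500 train, 2000 test).
#' @param sigma Element-wise random-effect SD.
#' @param mask Outcome indices to null.
#' @return A [trial_scenario].
#' @export
scenario_base <- function(n_train = 500, n_test = 2000) {
  trial_scenario(base_truth(), n_train = n_train, n_test = n_test,
                 label = "base")
}

#' @rdname scenario_base
#' @export
scenario_sensitivity <- function(sigma = 0.1, n_train = 500, n_test = 2000) {
  stopifnot(sigma >= 0)
  trial_scenario(base_truth(), n_train = n_train, n_test = n_test,
                 random_effect_sd = sigma,
                 label = paste0("sensitivity-sigma-", sigma))
}

#' @rdname scenario_base
#' @export
scenario_null <- function(mask = 4L, n_train = 500, n_test = 2000) {
  trial_scenario(base_truth(), n_train = n_train, n_test = n_test,
                 null_mask = mask, label = "null-effects")
}

#' Zero out treatment effects for selected outcomes
#'
#' Returns a scenario whose masked outcomes have `beta_0^(k) = 0` and
#' `beta^(k) = 0`; all other coefficients are untouched.  Masking the primary
#' outcome (k = 1) changes the true optimal treatment rule to the degenerate
#' all-control rule and is flagged with a warning.
#'
#' @param scenario A [trial_scenario].
#' @param mask Integer outcome indices in `1..d`.
#' @return The modified [trial_scenario].
#' @export
apply_null_mask <- function(scenario, mask = scenario$null_mask) {
  stopifnot(inherits(scenario, "trial_scenario"))
  mask <- as.integer(mask)
  if (!length(mask)) return(scenario)
  d <- scenario$truth$d
  if (any(mask < 1 | mask > d)) stop("mask indices must be in 1..", d)
  if (1L %in% mask) {
    warning("null mask includes the primary outcome (k = 1): the true ",
            "treatment contrast is identically 0 and the true optimal ITR ",
            "is degenerate")
  }
  tr <- scenario$truth
  tr$trt_main[mask] <- 0
  tr$interaction[, mask] <- 0
  scenario$truth <- coef_set(tr$ordinal_intercepts, tr$binary_intercepts,
                             tr$cov_main, tr$trt_main, tr$interaction)
  scenario$null_mask <- sort(unique(c(scenario$null_mask, mask)))
  scenario
}
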