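#' Coefficient set for the joint ordinal/binary outcome model
#'
#' Bundles every regression coefficient of the joint model: the level-specific
#' intercepts of the cumulative proportional-odds model for the primary
#' ordinal outcome (exceedance parameterization, `logit P(Y >= y) = tau_y +
#' theta`), intercepts for the binary outcomes, covariate main effects,
#' treatment main effects and treatment-by-covariate interactions for each of
#' the `d` outcomes.
#'
#' The exceedance (`>=`) parameterization is kept exactly as in the model
#' definition: a *larger* linear predictor pushes mass towards *higher*
#' (worse) ordinal categories, so a *negative* treatment contrast means the
#' experimental arm is beneficial.  Most ordinal-regression software uses the
#' complementary `<=` convention; coefficients are not interchangeable
#' between the two.
#'
#' @param ordinal_intercepts Numeric vector `tau_y`, `y = 1..L-1`, strictly
#'   decreasing (so exceedance probabilities are non-increasing in `y`).
#' @param binary_intercepts Numeric vector of length `d - 1`, intercepts of
#'   the logistic models for outcomes `k = 2..d`.  May be length 0 (`d = 1`).
#' @param cov_main `p x d` matrix of covariate main effects `m^(k)` (columns
#'   index outcomes).
#' @param trt_main Length-`d` vector of treatment main effects `beta_0^(k)`.
#' @param interaction `p x d` matrix of treatment-by-covariate interaction
#'   effects `beta^(k)`.
#'
#' @return An object of class `coef_set` with elements as supplied plus
#'   dimensions `p`, `d`, `L`.
#' @export
#' @examples
#' cs <- coef_set(
#'   ordinal_intercepts = c(1, -1),
#'   binary_intercepts = 0,
#'   cov_main = matrix(0, 2, 2),
#'   trt_main = c(-0.2, -0.1),
#'   interaction = matrix(0, 2, 2)
#' )
#' ordinal_probs(cs, theta = 0)
coef_set <- function(ordinal_intercepts, binary_intercepts = numeric(),
                     cov_main, trt_main, interaction) {
  cov_main <- as.matrix(cov_main)
  interaction <- as.matrix(interaction)
  p <- nrow(cov_main)
  d <- ncol(cov_main)
  L <- length(ordinal_intercepts) + 1L
  if (L < 2) stop("need at least one ordinal intercept (L >= 2)")
  if (any(diff(ordinal_intercepts) >= 0)) {
    stop("ordinal_intercepts must be strictly decreasing (exceedance ",
         "parameterization); got: ",
         paste(signif(ordinal_intercepts, 4), collapse = ", "))
  }
  if (length(binary_intercepts) != d - 1L) {
    stop("binary_intercepts must have length d - 1 = ", d - 1L,
         ", got ", length(binary_intercepts))
  }
  if (!identical(dim(interaction), dim(cov_main))) {
    stop("interaction must be a ", p, " x ", d, " matrix like cov_main")
  }
  if (length(trt_main) != d) {
    stop("trt_main must have length d = ", d, ", got ", length(trt_main))
  }
  structure(
    list(
      ordinal_intercepts = as.numeric(ordinal_intercepts),
      binary_intercepts = as.numeric(binary_intercepts),
      cov_main = cov_main,
      trt_main = as.numeric(trt_main),
      interaction = interaction,
      p = p, d = d, L = L
    ),
    class = "coef_set"
  )
}

#' @export
print.coef_set <- function(x, ...) {
  cat("<coef_set> p =", x$p, ", d =", x$d, ", L =", x$L, "\n")
  cat("  trt_main (beta_0):", signif(x$trt_main, 3), "\n")
  invisible(x)
}

check_x <- function(x, p, what = "x") {
  x <- as.numeric(x)
  if (length(x) != p) {
    stop(what, " must have length p = ", p, ", got ", length(x))
  }
  x
}

check_k <- function(k, d) {
  if (length(k) != 1 || k < 1 || k > d) {
    stop("outcome index k must be in 1..", d)
  }
  as.integer(k)
}

#' Linear predictor of the joint model
#'
#' Computes `theta^(k) = x' m^(k) + a * beta_0^(k) + a * x' beta^(k)` for one
#' covariate profile, treatment arm and outcome.
#'
#' @param coeffs A [coef_set].
#' @param x Covariate vector of length `p`.
#' @param a Treatment indicator, 0 or 1.
#' @param k Outcome index in `1..d`.
#' @return A single numeric value.
#' @export
#' @examples
#' cs <- coef_set(c(1, -1), 0, matrix(1, 1, 2), c(-0.5, 0), matrix(2, 1, 2))
#' linear_predictor(cs, x = 1, a = 1, k = 1)  # 1 - 0.5 + 2
linear_predictor <- function(coeffs, x, a, k) {
  stopifnot(inherits(coeffs, "coef_set"))
  x <- check_x(x, coeffs$p)
  k <- check_k(k, coeffs$d)
  if (!a %in% c(0, 1)) stop("treatment indicator a must be 0 or 1")
  sum(x * coeffs$cov_main[, k]) + a * coeffs$trt_main[k] +
    a * sum(x * coeffs$interaction[, k])
}

#' Ordinal category probabilities
#'
#' Maps a linear predictor to the `L` category probabilities of the primary
#' ordinal outcome under the cumulative proportional-odds model with
#' exceedance parameterization: `P(Y = y) = G(tau_y + theta) - G(tau_{y+1} +
#' theta)` with `G` the logistic function, `tau_0 = +Inf`, `tau_L = -Inf`.
#'
#' @inheritParams linear_predictor
#' @param theta Linear predictor value (finite scalar).
#' @return Numeric probability vector of length `L` (categories `0..L-1`);
#'   non-negative, sums to 1.
#' @export
ordinal_probs <- function(coeffs, theta) {
  stopifnot(inherits(coeffs, "coef_set"))
  if (!is.finite(theta)) stop("theta must be finite")
  exceed <- c(1, plogis(coeffs$ordinal_intercepts + theta), 0)
  -diff(exceed)
}

#' Treatment-control contrast (log odds ratio)
#'
#' The treatment-control effect contrast on the link scale for outcome `k`:
#' `beta_0^(k) + x' beta^(k)`.  For the logit link used here this is the log
#' odds ratio; it does not involve the covariate main effects `m^(k)` or any
#' intercept.  A negative contrast (OR < 1) means the experimental treatment
#' lowers the odds of a worse outcome.
#'
#' @inheritParams linear_predictor
#' @return A single numeric value (log OR).
#' @export
treatment_contrast <- function(coeffs, x, k = 1) {
  stopifnot(inherits(coeffs, "coef_set"))
  x <- check_x(x, coeffs$p)
  k <- check_k(k, coeffs$d)
  coeffs$trt_main[k] + sum(x * coeffs$interaction[, k])
}
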