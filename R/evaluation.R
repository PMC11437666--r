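#' True optimal individualized treatment rule
#'
#' `a_opt(x) = I(OR(x) < 1)` with `OR(x) = exp(beta0^(1) + x' beta^(1))`
#' evaluated at the *generating* coefficients: recommend the experimental
#' treatment exactly when the true log odds ratio is negative.  A boundary
#' contrast of exactly 0 maps to 0 (strict inequality); if every contrast is
#' 0 (fully nulled truth) the rule is degenerate and a warning is emitted.
#'
#' @param truth A [coef_set] holding the generating coefficients.
#' @param x Covariate matrix (`n x p`), data frame, or single vector.
#' @return Integer 0/1 vector.
#' @export
true_optimal_itr <- function(truth, x) {
  stopifnot(inherits(truth, "coef_set"))
  if (is.data.frame(x)) {
    x <- as.matrix(x[paste0("x", seq_len(truth$p))])
  }
  if (!is.matrix(x)) x <- matrix(as.numeric(x), nrow = 1)
  if (ncol(x) != truth$p) stop("x must have p = ", truth$p, " columns")
  contrast <- truth$trt_main[1] + as.numeric(x %*% truth$interaction[, 1])
  if (all(contrast == 0) && nrow(x) > 0) {
    warning("true treatment contrast is identically 0: the optimal rule ",
            "is degenerate (all control)")
  }
  as.integer(contrast < 0)
}

#' Proportion of correct decisions
#'
#' Mean agreement between estimated and true optimal treatment assignments.
#'
#' @param recommendations,truths Equal-length 0/1 vectors.
#' @return Value in `[0, 1]`.
#' @export
pcd <- function(recommendations, truths) {
  if (length(recommendations) != length(truths)) {
    stop("recommendations and truths must have equal length")
  }
  if (!length(recommendations)) stop("empty input")
  mean(recommendations == truths)
}

#' Area under the ROC curve of TBI scores
#'
#' AUC of the ROC built by thresholding the TBI at every unique value, with
#' the true optimal treatment (1 = benefit) as the positive class.  Equals
#' the pairwise concordance probability with ties counted 1/2, computed here
#' through the rank (Mann-Whitney) identity.
#'
#' @param scores Numeric scores (TBI values).
#' @param labels 0/1 true class labels; both classes must be present.
#' @return Value in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC is undefined: labels contain a single class")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Credible-interval metrics for the primary treatment main effect
#'
#' Equal-tailed interval length, truth-coverage indicator and squared error
#' of the posterior median of `beta0^(1)` against the generating value.
#' Averaging `sq_error` over replications gives the MSE of the treatment
#' effect estimate.
#'
#' @param fit A `tbi_fit`.
#' @param truth_beta0 Generating value of `beta0^(1)`.
#' @param level Credible level (default 0.95).
#' @return A tibble with columns `ci_length`, `covered`, `sq_error`.
#' @export
interval_metrics <- function(fit, truth_beta0, level = 0.95) {
  stopifnot(inherits(fit, "tbi_fit"))
  draws <- fit$draws[, "beta0[1]"]
  a <- (1 - level) / 2
  q <- quantile(draws, c(a, 0.5, 1 - a))
  tibble::tibble(
    ci_length = q[[3]] - q[[1]],
    covered = as.integer(truth_beta0 >= q[[1]] && truth_beta0 <= q[[3]]),
    sq_error = (q[[2]] - truth_beta0)^2
  )
}

#' Benchmark grid
#'
#' Configuration of a replication study comparing the multivariate and
#' univariate models: training sizes, random-effect SDs, replication count,
#' test size and MCMC settings.  The full-scale study uses `n` in
#' `{250, 500, 1000, 2000}`, 2000 test subjects and 1000 replications;
#' scaled-down runs are explicit configuration, never silent.
#'
#' @param n Vector of training sample sizes.
#' @param sigma Vector of random-effect SDs (0 = fixed-effect generator).
#' @param reps Replications per condition.
#' @param n_test Test-set size.
#' @param scenario Scenario preset factory: a function `(n_train, n_test)`
#'   returning a [trial_scenario] (default [scenario_base]); random-effect
#'   SDs from `sigma` are applied on top.
#' @param mcmc An [mcmc_config()] (its seed is ignored; per-replication
#'   seeds derive from `seed`).
#' @param models Which models to run.
#' @param seed Master seed; replication `r` uses [replication_seed()].
#' @return A list of class `benchmark_grid`.
#' @export
benchmark_grid <- function(n = c(250, 500, 1000, 2000), sigma = 0, reps = 10,
                           n_test = 2000, scenario = scenario_base,
                           mcmc = mcmc_config(chains = 2),
                           models = c("multivariate", "univariate"),
                           seed = 1) {
  stopifnot(all(n > 0), all(sigma >= 0), reps >= 1, n_test > 0)
  models <- match.arg(models, several.ok = TRUE)
  structure(
    list(n = n, sigma = sigma, reps = as.integer(reps),
         n_test = as.integer(n_test), scenario = scenario, mcmc = mcmc,
         models = models, seed = as.integer(seed)),
    class = "benchmark_grid"
  )
}

run_one_replication <- function(sc, n_test, mcmc, models, rep_seed,
                                decision = decision_config()) {
  train <- sim_trial(sc, "train", seed = rep_seed)
  test <- sim_trial(sc, "test", seed = rep_seed, n = n_test)
  truth <- sc$truth
  Xtest <- as.matrix(test[paste0("x", seq_len(truth$p))])
  a_true <- suppressWarnings(true_optimal_itr(truth, Xtest))
  degenerate <- length(unique(a_true)) < 2

  purrr::map_dfr(models, function(mod) {
    mc <- mcmc
    mc$seed <- rep_seed
    fit <- if (mod == "multivariate") {
      fit_multivariate(train, mcmc = mc)
    } else {
      fit_univariate(train, mcmc = mc)
    }
    scores <- tbi(fit, Xtest)
    im <- interval_metrics(fit, truth$trt_main[1])
    tibble::tibble(
      model = mod,
      pcd = pcd(recommend(scores, decision), a_true),
      auc = if (degenerate) NA_real_ else roc_auc(scores, a_true),
      ci_length = im$ci_length,
      covered = im$covered,
      sq_error = im$sq_error,
      divergences = sum(fit$divergent)
    )
  })
}

#' Run a replication benchmark
#'
#' For every combination of training size, random-effect SD and replication:
#' generate a train/test pair, fit the requested models, compute the TBI of
#' every test subject, and score the induced treatment rule against the true
#' optimal rule (PCD, AUC) together with credible-interval metrics for the
#' primary treatment main effect.  Replications that error (e.g. sampler
#' failure) are recorded with `status = "error"` rather than dropped.
#'
#' @param grid A [benchmark_grid()].
#' @param progress Print one line per condition.
#' @return A tibble of class `tbi_benchmark`: one row per
#'   replication x model with columns `n`, `sigma`, `rep`, `seed`, `model`,
#'   `pcd`, `auc`, `ci_length`, `covered`, `sq_error`, `divergences`,
#'   `status`.
#' @seealso [summarize_benchmark()], [autoplot.tbi_benchmark()]
#' @export
run_benchmark <- function(grid, progress = FALSE) {
  stopifnot(inherits(grid, "benchmark_grid"))
  conditions <- tidyr::expand_grid(n = grid$n, sigma = grid$sigma)
  out <- purrr::pmap_dfr(conditions, function(n, sigma) {
    if (progress) message("benchmark: n = ", n, ", sigma = ", sigma)
    purrr::map_dfr(seq_len(grid$reps), function(r) {
      rep_seed <- replication_seed(grid$seed, r + 10000L * which(
        grid$n == n) + 1000000L * which(grid$sigma == sigma))
      sc <- grid$scenario(n, grid$n_test)
      sc$random_effect_sd <- sigma
      res <- tryCatch(
        run_one_replication(sc, grid$n_test, grid$mcmc, grid$models,
                            rep_seed),
        error = function(e) {
          tibble::tibble(model = grid$models, pcd = NA_real_,
                         auc = NA_real_, ci_length = NA_real_,
                         covered = NA_integer_, sq_error = NA_real_,
                         divergences = NA_integer_,
                         status = paste("error:", conditionMessage(e)))
        })
      if (!"status" %in% names(res)) res$status <- "ok"
      tibble::tibble(n = n, sigma = sigma, rep = r, seed = rep_seed, res)
    })
  })
  class(out) <- c("tbi_benchmark", class(out))
  out
}

#' Aggregate benchmark replications
#'
#' Per-condition, per-model summaries (mean, median, quartiles of PCD and
#' AUC; mean interval length, coverage rate, MSE) mirroring the content of
#' the comparative boxplots.
#'
#' @param results A `tbi_benchmark` tibble from [run_benchmark()].
#' @return A tibble with one row per `(n, sigma, model)`.
#' @export
summarize_benchmark <- function(results) {
  results |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::group_by(.data$n, .data$sigma, .data$model) |>
    dplyr::summarise(
      reps = dplyr::n(),
      pcd_mean = mean(.data$pcd),
      pcd_q1 = quantile(.data$pcd, 0.25),
      pcd_median = median(.data$pcd),
      pcd_q3 = quantile(.data$pcd, 0.75),
      auc_mean = mean(.data$auc),
      auc_median = median(.data$auc),
      ci_length_mean = mean(.data$ci_length),
      coverage = mean(.data$covered),
      mse = mean(.data$sq_error),
      .groups = "drop"
    )
}
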