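#' Column schema of a trial dataset file
#'
#' Names the covariate, treatment, ordinal-outcome and binary-outcome
#' columns and the number of ordinal levels `L`, for reading external
#' delimited files.
#'
#' @param covariates Character vector of covariate column names.
#' @param treatment Name of the 0/1 treatment column.
#' @param ordinal Name of the ordinal outcome column (values `0..L-1`).
#' @param binary Character vector of binary outcome column names (may be
#'   empty).
#' @param L Number of ordinal levels (>= 3 for real datasets; inferred from
#'   the data when `NULL`).
#' @return A list of class `trial_schema`.
#' @export
trial_schema <- function(covariates, treatment = "trt", ordinal = "y1",
                         binary = character(), L = NULL) {
  structure(
    list(covariates = covariates, treatment = treatment, ordinal = ordinal,
         binary = binary, L = if (is.null(L)) NULL else as.integer(L)),
    class = "trial_schema"
  )
}

#' Read a trial dataset from delimited text
#'
#' Reads a comma-separated file with a header row, validates it against the
#' schema, and drops rows with any missing value (complete-case analysis),
#' reporting the dropped count via a warning.
#'
#' @param path File path.
#' @param schema A [trial_schema()].
#' @return A validated tibble with attribute `L`.
#' @export
read_trial_data <- function(path, schema) {
  stopifnot(inherits(schema, "trial_schema"))
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  if (nrow(raw) == 0) stop("empty dataset: ", path)
  needed <- c(schema$covariates, schema$treatment, schema$ordinal,
              schema$binary)
  miss <- setdiff(needed, names(raw))
  if (length(miss)) stop("missing columns in ", path, ": ",
                         paste(miss, collapse = ", "))
  raw <- raw[needed]
  cc <- stats::complete.cases(raw)
  if (any(!cc)) {
    warning(sum(!cc), " row(s) with missing values dropped (complete-case)")
    raw <- raw[cc, , drop = FALSE]
  }
  L <- if (is.null(schema$L)) max(raw[[schema$ordinal]]) + 1L else schema$L
  yord <- raw[[schema$ordinal]]
  if (any(yord < 0 | yord > L - 1 | yord != floor(yord))) {
    stop("ordinal outcome '", schema$ordinal, "' has values outside 0..",
         L - 1)
  }
  if (!all(raw[[schema$treatment]] %in% c(0, 1))) {
    stop("treatment column '", schema$treatment, "' is not coded 0/1")
  }
  for (bn in schema$binary) {
    if (!all(raw[[bn]] %in% c(0, 1))) {
      stop("binary outcome '", bn, "' is not coded 0/1")
    }
  }
  out <- tibble::as_tibble(raw)
  attr(out, "L") <- as.integer(L)
  out
}

#' Write a trial dataset (and scenario metadata) to text
#'
#' Writes the dataset as comma-separated text with a header row; when the
#' dataset came from [sim_trial()], a JSON sidecar `<path>.meta.json`
#' recording the full generative scenario (truth coefficients, random-effect
#' SD, seed, split) is written alongside, so the file can be re-created
#' exactly.
#'
#' @param data A trial tibble (typically from [sim_trial()]).
#' @param path Output file path.
#' @param sidecar Write the JSON metadata sidecar when scenario metadata is
#'   present.
#' @return `path`, invisibly.
#' @export
write_trial_data <- function(data, path, sidecar = TRUE) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  sc <- attr(data, "scenario")
  if (sidecar && !is.null(sc)) {
    truth <- sc$truth
    meta <- list(
      label = sc$label,
      seed = attr(data, "seed"),
      split = attr(data, "split"),
      n = nrow(data),
      L = truth$L, p = truth$p, d = truth$d,
      random_effect_sd = sc$random_effect_sd,
      treatment_prob = sc$treatment_prob,
      binary_covariate_count = sc$binary_covariate_count,
      null_mask = sc$null_mask,
      truth = list(
        ordinal_intercepts = truth$ordinal_intercepts,
        binary_intercepts = truth$binary_intercepts,
        cov_main = truth$cov_main,
        trt_main = truth$trt_main,
        interaction = truth$interaction
      )
    )
    jsonlite::write_json(meta, paste0(path, ".meta.json"), digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Re-create a scenario from a metadata sidecar
#'
#' @param path Path to a `.meta.json` sidecar written by
#'   [write_trial_data()].
#' @return A [trial_scenario].
#' @export
read_scenario_meta <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- coef_set(
    ordinal_intercepts = meta$truth$ordinal_intercepts,
    binary_intercepts = meta$truth$binary_intercepts,
    cov_main = matrix(unlist(meta$truth$cov_main), meta$p, meta$d),
    trt_main = meta$truth$trt_main,
    interaction = matrix(unlist(meta$truth$interaction), meta$p, meta$d)
  )
  trial_scenario(truth,
                 random_effect_sd = as.numeric(meta$random_effect_sd),
                 treatment_prob = as.numeric(meta$treatment_prob),
                 binary_covariate_count = meta$binary_covariate_count,
                 label = meta$label)
}

#' Persist posterior draws as delimited text
#'
#' Writes the labeled draw matrix (one column per parameter, names
#' `tau1[y]`, `tau[k]`, `m[k,j]`, `beta0[k]`, `beta[k,j]`, `beta_star[j]`,
#' `sigma_beta[j]`) plus `.chain` and `.divergent` columns as CSV, and a
#' JSON sidecar `<path>.meta.json` describing the model (tag, dimensions,
#' priors, MCMC settings), making the container self-describing.
#'
#' @param fit A `tbi_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_draws()]
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "tbi_fit"))
  df <- as.data.frame(fit$draws, check.names = FALSE)
  df$.chain <- fit$chain_id
  df$.divergent <- fit$divergent
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(model_tag = fit$model_tag, n = fit$n, p = fit$p, d = fit$d,
               L = fit$L, priors = unclass(fit$priors),
               mcmc = unclass(fit$mcmc), prior_only = fit$prior_only,
               covariates = fit$schema$covariates)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Reload persisted posterior draws
#'
#' Reconstructs a `tbi_fit` (draws, chain ids, divergence flags, model
#' metadata) from the files written by [write_draws()].  Downstream
#' consumers ([tbi()], [tbi_table()], [tidy()], [mcmc_diagnostics()],
#' [interval_metrics()]) work on the reloaded object.
#'
#' @param path CSV path previously given to [write_draws()].
#' @return A `tbi_fit`.
#' @export
read_draws <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  chain <- df$.chain
  divergent <- df$.divergent
  draws <- as.matrix(df[setdiff(names(df), c(".chain", ".divergent"))])
  structure(
    list(model_tag = meta$model_tag, draws = draws,
         chain_id = as.integer(chain), divergent = as.integer(divergent),
         sampler = NULL,
         p = as.integer(meta$p), d = as.integer(meta$d),
         L = as.integer(meta$L), n = as.integer(meta$n),
         schema = trial_schema(covariates = meta$covariates),
         priors = do.call(prior_config, as.list(meta$priors)),
         mcmc = do.call(mcmc_config, as.list(meta$mcmc)),
         prior_only = isTRUE(meta$prior_only)),
    class = "tbi_fit"
  )
}

#' Published application coefficient table
#'
#' Posterior medians and 95 percent credible intervals of the treatment
#' benefit index coefficients from the published COMPILE COVID-19
#' convalescent-plasma analysis (univariate model and multivariate model,
#' all four outcomes), shipped as a plain-text fixture.  These numbers are
#' the published fit -- the trial data are not public and this package does
#' not recompute them; the table serves as input for odds-ratio transforms
#' and display examples.
#'
#' @return A tibble with columns `term`, `model`, `outcome`, `median`,
#'   `lo`, `hi`.
#' @export
compile_coefficients <- function() {
  path <- system.file("extdata", "compile_tbi_coefficients.csv",
                      package = "tbijoint")
  tibble::as_tibble(utils::read.csv(path))
}
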