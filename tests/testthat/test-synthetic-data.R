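test_that("covariate generator matches the stated scheme", {
  expect_error(sim_covariates(10, 2), "binary covariates")

  empty <- sim_covariates(0, 5)
  expect_identical(dim(empty), c(0L, 5L))

  X <- sim_covariates(1e5, 5, seed = 7)
  for (j in 1:3) {
    expect_true(all(X[, j] %in% c(0, 1)))
    expect_lt(abs(mean(X[, j]) - 0.5), 3 * sqrt(0.25 / 1e5))
  }
  for (j in 4:5) {
    expect_lt(abs(mean(X[, j])), 3 / sqrt(1e5))
    expect_lt(abs(sd(X[, j]) - 1), 3 / sqrt(2 * 1e5))
  }
  expect_identical(X, sim_covariates(1e5, 5, seed = 7))
})

test_that("base preset generates the stated outcome structure, reproducibly", {
  sc <- scenario_base(n_train = 250)
  trial <- sim_trial(sc, seed = 5)
  expect_identical(nrow(trial), 250L)
  expect_named(trial, c(paste0("x", 1:5), "trt", paste0("y", 1:4)))
  expect_true(all(trial$y1 %in% 0:10))
  expect_true(all(as.matrix(trial[paste0("y", 2:4)]) %in% 0:1))
  expect_true(all(trial$trt %in% 0:1))
  expect_identical(trial, sim_trial(sc, seed = 5))
  expect_false(identical(trial$y1, sim_trial(sc, seed = 6)$y1))
  # train and test splits are independent draws under one master seed
  expect_false(identical(trial$y1[1:10],
                         sim_trial(sc, "test", seed = 5, n = 250)$y1[1:10]))
})

test_that("all-zero truth with uniform intercepts gives uniform categories", {
  flat <- coef_set(uniform_ordinal_intercepts(11), rep(0, 3),
                   matrix(0, 5, 4), rep(0, 4), matrix(0, 5, 4))
  sc <- trial_scenario(flat, n_train = 2e4, label = "flat")
  trial <- sim_trial(sc, seed = 31)
  freq <- tabulate(trial$y1 + 1L, nbins = 11) / 2e4
  se <- sqrt((1 / 11) * (10 / 11) / 2e4)
  expect_true(all(abs(freq - 1 / 11) < 3 * se))
})

test_that("a maximum-likelihood logistic fit recovers binary-outcome truth", {
  sc <- scenario_base(n_train = 5e4)
  trial <- sim_trial(sc, seed = 13)
  X <- as.matrix(trial[paste0("x", 1:5)])
  fit <- glm(trial$y2 ~ X + trial$trt + X:trial$trt,
             family = binomial())
  truth <- sc$truth
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  expected <- c(truth$binary_intercepts[1], truth$cov_main[, 2],
                truth$trt_main[2], truth$interaction[, 2])
  expect_true(all(abs(est - expected) < 3 * se))
})

test_that("empirical exceedance curves converge to the model curves", {
  sc <- scenario_base(n_train = 1e5)
  trial <- sim_trial(sc, seed = 17)
  truth <- sc$truth
  X <- as.matrix(trial[paste0("x", 1:5)])
  theta <- as.numeric(X %*% truth$cov_main[, 1] +
    trial$trt * (truth$trt_main[1] + X %*% truth$interaction[, 1]))
  model_exceed <- colMeans(plogis(outer(theta, truth$ordinal_intercepts, `+`)))
  emp_exceed <- vapply(1:10, function(y) mean(trial$y1 >= y), 0)
  expect_lt(max(abs(emp_exceed - model_exceed)), 0.01)
})

test_that("random effects have the configured spread and enter the sampler", {
  sc <- scenario_sensitivity(sigma = 0.2, n_train = 1e4)
  trial <- sim_trial(sc, seed = 23)
  re <- attr(trial, "random_effects")
  expect_identical(dim(re), c(10000L, 6L))
  se_sd <- 0.2 / sqrt(2 * 1e4)
  for (j in 1:6) expect_lt(abs(sd(re[, j]) - 0.2), 3 * se_sd)
  # sigma = 0 stores zeros and reproduces the fixed-effect generator
  re0 <- attr(sim_trial(scenario_base(n_train = 50), seed = 3),
              "random_effects")
  expect_true(all(re0 == 0))
})

test_that("null masks zero exactly the flagged outcomes", {
  sc <- scenario_base()
  masked <- apply_null_mask(sc, 4L)
  expect_identical(masked$truth$trt_main[4], 0)
  expect_identical(unname(masked$truth$interaction[, 4]), rep(0, 5))
  expect_identical(masked$truth$trt_main[1:3], sc$truth$trt_main[1:3])
  expect_identical(masked$truth$interaction[, 1:3], sc$truth$interaction[, 1:3])
  expect_identical(masked$truth$cov_main, sc$truth$cov_main)

  expect_identical(apply_null_mask(sc, integer())$truth, sc$truth)

  expect_warning(all_null <- apply_null_mask(sc, 1:4), "primary outcome")
  X <- sim_covariates(20, 5, seed = 1)
  expect_warning(itr <- true_optimal_itr(all_null$truth, X), "degenerate")
  expect_identical(itr, rep(0L, 20))
})

test_that("replication seeds are deterministic and within integer range", {
  s1 <- replication_seed(1, 1:5)
  expect_identical(s1, replication_seed(1, 1:5))
  expect_true(all(s1 > 0 & s1 < 2^31))
  expect_identical(length(unique(s1)), 5L)
  expect_true(replication_seed(7, 2e6) < 2^31)
})
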