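base <- tbijoint:::base_truth()

test_that("the true optimal rule thresholds the generating odds ratio at 1", {
  expect_identical(true_optimal_itr(base, rep(0, 5)), 1L)  # -0.05 < 0
  expect_identical(true_optimal_itr(base, c(1, 0, 0, 0, 0)), 0L)  # 0.15
  X <- rbind(rep(0, 5), c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0))
  expect_identical(true_optimal_itr(base, X), c(1L, 0L, 1L))
  expect_error(true_optimal_itr(base, matrix(0, 2, 3)), "p = 5")
})

test_that("PCD is mean agreement", {
  expect_identical(pcd(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_identical(pcd(c(1, 0, 1, 1), c(1, 1, 1, 0)), 0.5)
  expect_identical(pcd(c(1, 1), c(0, 0)), 0)
  expect_error(pcd(1, c(1, 0)), "equal length")
  expect_error(pcd(integer(), integer()), "empty")
})

test_that("AUC equals pairwise concordance with half-weight ties", {
  expect_identical(roc_auc(c(0.9, 0.7, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_identical(roc_auc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_identical(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "single class")

  pairwise_auc <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    gr <- outer(pos, neg, `>`); eq <- outer(pos, neg, `==`)
    mean(gr + 0.5 * eq)
  }
  set.seed(90)
  for (rep in 1:20) {
    n <- 40
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    s <- round(runif(n), 2)  # induces ties
    a <- roc_auc(s, l)
    expect_equal(a, pairwise_auc(s, l), tolerance = 1e-12)
    # independent rank-based (Mann-Whitney) computation
    w <- wilcox.test(s[l == 1], s[l == 0], exact = FALSE)$statistic
    expect_equal(a, unname(w) / (sum(l == 1) * sum(l == 0)),
                 tolerance = 1e-12)
    # invariant to subject ordering
    o <- sample(n)
    expect_identical(a, roc_auc(s[o], l[o]))
    expect_identical(pcd(round(s), l), pcd(round(s)[o], l[o]))
  }
})

test_that("interval metrics are quantile arithmetic", {
  # evenly spread draws on [0, 1]: 95% equal-tailed interval has length 0.95
  fit <- fake_fit(cbind(seq(0, 1, length.out = 2001), 0))
  m <- interval_metrics(fit, truth_beta0 = 0.5)
  expect_equal(m$ci_length, 0.95, tolerance = 1e-3)
  expect_identical(m$covered, 1L)
  expect_equal(m$sq_error, 0, tolerance = 1e-6)

  m2 <- interval_metrics(fit, truth_beta0 = 0.99)
  expect_identical(m2$covered, 0L)

  degen <- fake_fit(cbind(rep(-0.05, 100), 0))
  m3 <- interval_metrics(degen, truth_beta0 = -0.05)
  expect_identical(m3$ci_length, 0)
  expect_identical(m3$covered, 1L)
  expect_identical(m3$sq_error, 0)
})

test_that("the benchmark engine produces complete bookkeeping", {
  g <- benchmark_grid(n = 250, sigma = 0, reps = 2, n_test = 300,
                      mcmc = mcmc_config(200, 150, chains = 1,
                                         target_accept = 0.8),
                      seed = 3)
  res <- run_benchmark(g)
  expect_identical(nrow(res), 4L)
  expect_setequal(unique(res$model), c("multivariate", "univariate"))
  expect_true(all(res$status == "ok"))
  expect_true(all(res$pcd >= 0 & res$pcd <= 1))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  expect_true(all(res$ci_length > 0))
  expect_true(all(res$covered %in% 0:1))
  expect_true(all(res$seed > 0))
  # per-model row for each replication, reproducible seeds
  expect_identical(res$seed[res$model == "multivariate"],
                   res$seed[res$model == "univariate"])

  summ <- summarize_benchmark(res)
  expect_identical(nrow(summ), 2L)
  expect_named(summ, c("n", "sigma", "model", "reps", "pcd_mean", "pcd_q1",
                       "pcd_median", "pcd_q3", "auc_mean", "auc_median",
                       "ci_length_mean", "coverage", "mse"))
})
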