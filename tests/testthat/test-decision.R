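test_that("TBI equals brute-force counting over contrast draws", {
  # x = 0: the contrast is beta0[1] itself
  fit <- fake_fit(cbind(c(-1, 1, -2, 3), 0))
  expect_identical(tbi(fit, 0), 0.5)

  all_neg <- fake_fit(cbind(rep(-0.3, 50), 0))
  expect_identical(tbi(all_neg, 0), 1)

  set.seed(77)
  for (rep in 1:10) {
    S <- 200; p <- 3
    draws <- matrix(rnorm(S * (p + 1), 0, 0.7), S)
    fit <- fake_fit(draws, extra_noise_seed = rep)
    x <- rnorm(p)
    brute <- mean(vapply(seq_len(S), function(s) {
      (draws[s, 1] + sum(draws[s, -1] * x)) < 0
    }, NA))
    expect_equal(tbi(fit, x), brute)
  }
})

test_that("TBI ignores nuisance parameters and respects the sign-flip identity", {
  set.seed(78)
  draws <- matrix(rnorm(300 * 3), 300)
  f1 <- fake_fit(draws, extra_noise_seed = 1)
  f2 <- fake_fit(draws, extra_noise_seed = 2)  # different nuisance draws
  x <- c(0.4, -1)
  expect_identical(tbi(f1, x), tbi(f2, x))

  flipped <- fake_fit(-draws)
  expect_equal(tbi(f1, x) + tbi(flipped, x), 1)
})

test_that("recommendation thresholds are strict", {
  cfg <- decision_config()
  expect_identical(recommend(0.51, cfg), 1L)
  expect_identical(recommend(0.5, cfg), 0L)
  expect_identical(recommend(0, cfg), 0L)
  expect_identical(recommend(c(0.2, 0.9)), c(0L, 1L))
  expect_error(recommend(1.2), "\\[0, 1\\]")
  expect_error(decision_config(threshold = 0), "\\(0, 1\\)")

  # median/quantile duality at delta = 0.5 for continuous draws
  set.seed(79)
  for (rep in 1:10) {
    draws <- matrix(rnorm(201, rnorm(1, 0, 0.5)), ncol = 1)
    fit <- fake_fit(cbind(draws, 0))
    expect_identical(recommend(tbi(fit, 0)),
                     as.integer(median(draws) < 0))
  }
})

test_that("odds-ratio summaries are exponentiated contrast quantiles", {
  const <- fake_fit(cbind(rep(-0.25, 40), 0))
  s <- or_summary(const, 0, 1)
  expect_equal(s$or_median, exp(-0.25))
  expect_equal(s$or_lo, exp(-0.25))
  expect_equal(s$or_hi, exp(-0.25))

  # the published headline transform: coefficient -0.39 is OR 0.68
  expect_identical(round(exp(-0.39), 2), 0.68)

  set.seed(80)
  draws <- matrix(rnorm(500 * 2), 500)
  fit <- fake_fit(draws)
  x <- 1.3
  contr <- draws[, 1] + draws[, 2] * x
  s <- or_summary(fit, x, 1, level = 0.9)
  expect_equal(unname(s$or_median), unname(exp(quantile(contr, 0.5))))
  expect_equal(unname(s$or_lo), unname(exp(quantile(contr, 0.05))))
  expect_equal(unname(s$or_hi), unname(exp(quantile(contr, 0.95))))
})

test_that("tbi_table has one row per subject and d OR blocks", {
  set.seed(81)
  fit <- fake_fit(matrix(rnorm(400 * 3, -0.2, 0.6), 400), d = 4)
  X <- matrix(rnorm(2 * 30), 30)
  tab <- tbi_table(fit, X)
  expect_identical(nrow(tab), 30L)
  expect_identical(sum(grepl("^or_median_", names(tab))), 4L)
  expect_true(all(tab$tbi >= 0 & tab$tbi <= 1))
  expect_identical(tab$recommend, as.integer(tab$tbi > 0.5))

  one <- tbi_table(fit, matrix(0, 1, 2))
  expect_identical(nrow(one), 1L)

  empty <- tbi_table(fit, matrix(0, 0, 2))
  expect_identical(nrow(empty), 0L)

  # posterior-mean OR of the primary outcome decreases in TBI
  expect_lt(cor(tab$tbi, tab$or_mean_1, method = "spearman"), 0)
})
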