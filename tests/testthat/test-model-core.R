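base <- tbijoint:::base_truth()

test_that("linear predictor combines main, treatment and interaction terms", {
  zero <- coef_set(c(1, -1), numeric(), matrix(0, 3, 1), 0, matrix(0, 3, 1))
  expect_identical(linear_predictor(zero, c(1, -2, 0.5), 1, 1), 0)
  expect_identical(linear_predictor(zero, c(0, 0, 0), 0, 1), 0)

  # reference simulation truth: x = 0 isolates the treatment main effect
  expect_equal(linear_predictor(base, rep(0, 5), 1, 1), -0.05)
  # x = e1: m1 + beta0 + beta1 = 0.35 - 0.05 + 0.20
  expect_equal(linear_predictor(base, c(1, 0, 0, 0, 0), 1, 1), 0.50)
  # control arm never sees treatment terms
  expect_equal(linear_predictor(base, c(1, 0, 0, 0, 0), 0, 2), 0.40)

  expect_error(linear_predictor(base, rep(0, 4), 1, 1), "length p")
  expect_error(linear_predictor(base, rep(0, 5), 1, 9), "outcome index")
})

test_that("ordinal category probabilities are logistic exceedance increments", {
  two <- coef_set(0, numeric(), matrix(0, 1, 1), 0, matrix(0, 1, 1))
  expect_equal(ordinal_probs(two, 0), c(0.5, 0.5))

  three <- coef_set(c(1, -1), numeric(), matrix(0, 1, 1), 0,
                    matrix(0, 1, 1))
  expect_equal(ordinal_probs(three, 0),
               c(1 - plogis(1), plogis(1) - plogis(-1), plogis(-1)),
               tolerance = 1e-12)
  expect_equal(round(ordinal_probs(three, 0), 4), c(0.2689, 0.4621, 0.2689))

  expect_error(
    coef_set(c(-1, 1), numeric(), matrix(0, 1, 1), 0, matrix(0, 1, 1)),
    "strictly decreasing"
  )
  expect_error(ordinal_probs(three, Inf), "finite")
})

test_that("probability vectors normalize and exceedance curves are monotone", {
  set.seed(11)
  for (rep in 1:25) {
    L <- sample(3:12, 1)
    cs <- coef_set(sort(rnorm(L - 1, 0, 2), decreasing = TRUE), numeric(),
                   matrix(0, 2, 1), 0, matrix(0, 2, 1))
    theta <- rnorm(1, 0, 3)
    pr <- ordinal_probs(cs, theta)
    expect_length(pr, L)
    expect_true(all(pr >= 0))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    exceed <- rev(cumsum(rev(pr)))  # P(Y >= y), y = 0..L-1
    expect_true(all(diff(exceed) <= 1e-12))
  }
})

test_that("treatment contrast is the log OR and ignores main effects", {
  expect_equal(treatment_contrast(base, rep(0, 5), 1), -0.05)
  expect_equal(treatment_contrast(base, c(1, 0, 0, 0, 0), 1), 0.15)

  shifted <- base
  shifted$cov_main <- base$cov_main + 5
  shifted <- coef_set(base$ordinal_intercepts, base$binary_intercepts,
                      shifted$cov_main, base$trt_main, base$interaction)
  expect_equal(treatment_contrast(shifted, c(1, 1, 1, 1, 1), 2),
               treatment_contrast(base, c(1, 1, 1, 1, 1), 2))

  # identity: contrast equals the arm difference of linear predictors
  set.seed(21)
  for (rep in 1:20) {
    x <- rnorm(5)
    k <- sample(1:4, 1)
    expect_equal(treatment_contrast(base, x, k),
                 linear_predictor(base, x, 1, k) -
                   linear_predictor(base, x, 0, k),
                 tolerance = 1e-12)
  }
  expect_error(treatment_contrast(base, 1:3, 1), "length p")
})
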