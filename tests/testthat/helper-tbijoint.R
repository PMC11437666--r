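# Shared fixtures and independent oracles, built in code at test time.

# tiny joint instance: n = 40, p = 1, d = 2, L = 3
tiny_truth <- function() {
  coef_set(
    ordinal_intercepts = uniform_ordinal_intercepts(3),
    binary_intercepts = 0,
    cov_main = matrix(c(0.35, 0.40), 1, 2),
    trt_main = c(-0.05, -0.06),
    interaction = matrix(c(0.20, 0.19), 1, 2)
  )
}

tiny_trial <- function(n = 40, seed = 202) {
  sc <- trial_scenario(tiny_truth(), n_train = n, binary_covariate_count = 1,
                       label = "tiny")
  sim_trial(sc, seed = seed)
}

quick_mcmc <- function(warmup = 300, iter = 300, chains = 2, seed = 1,
                       target_accept = 0.8) {
  mcmc_config(warmup, iter, chains = chains, seed = seed,
              target_accept = target_accept)
}

# minimal tbi_fit-shaped object with prescribed contrast draws, for testing
# the decision layer against brute-force counting
fake_fit <- function(contrast, p = NULL, d = 1, extra_noise_seed = NULL) {
  contrast <- as.matrix(contrast)  # S x (p+1): beta0[1], beta[1,j]
  p <- ncol(contrast) - 1L
  S <- nrow(contrast)
  draws <- contrast
  colnames(draws) <- c("beta0[1]", if (p > 0) paste0("beta[1,", 1:p, "]"))
  # nuisance columns the TBI must ignore
  if (!is.null(extra_noise_seed)) {
    set.seed(extra_noise_seed)
    nuis <- matrix(rnorm(S * (2 + p)), S)
    colnames(nuis) <- c("tau1[1]", "tau1[2]", paste0("m[1,", seq_len(p), "]"))
    draws <- cbind(draws, nuis)
  }
  if (d > 1) {
    for (k in 2:d) {
      blk <- matrix(rnorm(S * (p + 1), 0, 0.5), S)
      colnames(blk) <- c(paste0("beta0[", k, "]"),
                         paste0("beta[", k, ",", seq_len(p), "]"))
      draws <- cbind(draws, blk)
    }
  }
  structure(
    list(model_tag = "fake", draws = draws,
         chain_id = rep(1L, S), divergent = rep(0L, S),
         p = p, d = d, L = 3L,
         schema = trial_schema(covariates = if (p > 0) paste0("x", 1:p)
                               else character()),
         mcmc = mcmc_config(chains = 1),
         prior_only = FALSE),
    class = "tbi_fit"
  )
}

# ---- independent posterior oracle for the tiny instance ----------------
# Pure-R unnormalized log posterior (vectorized over columns of Q) plus a
# self-normalized importance sampler with a Laplace-centered multivariate-t
# proposal.  Entirely independent of the compiled sampler path.

tiny_logpost_mat <- function(Q, x, a, y1, y2, hier = TRUE,
                             prior_only = FALSE) {
  lt <- function(v) dt(v / 8, 3, log = TRUE) - log(8)
  if (hier) {
    tau1 <- Q[1, ]; tau2 <- tau1 - exp(Q[2, ])
    taub <- Q[3, ]; m1 <- Q[4, ]; m2 <- Q[5, ]
    sg0 <- exp(Q[12, ]); sg1 <- exp(Q[13, ])
    b01 <- Q[10, ] + sg0 * Q[6, ]; b11 <- Q[11, ] + sg1 * Q[7, ]
    b02 <- Q[10, ] + sg0 * Q[8, ]; b12 <- Q[11, ] + sg1 * Q[9, ]
  } else {
    tau1 <- Q[1, ]; tau2 <- tau1 - exp(Q[2, ])
    m1 <- Q[3, ]; b01 <- Q[4, ]; b11 <- Q[5, ]
  }
  lp <- lt(tau1) + lt(tau2) + Q[2, ] + dnorm(m1, 0, 2.5, log = TRUE)
  if (!prior_only) {
    th1 <- outer(m1, x) + outer(b01, a) + outer(b11, x * a)
    q1 <- plogis(tau1 + th1); q2 <- plogis(tau2 + th1)
    lp <- lp + rowSums(log(cbind((1 - q1)[, y1 == 0, drop = FALSE],
                                 (q1 - q2)[, y1 == 1, drop = FALSE],
                                 q2[, y1 == 2, drop = FALSE]) + 1e-300))
  }
  if (hier) {
    if (!prior_only) {
      eta <- taub + outer(m2, x) + outer(b02, a) + outer(b12, x * a)
      lp <- lp + rowSums(sweep(eta, 2, y2, `*`) - log1p(exp(eta)))
    }
    lp <- lp + lt(taub) + dnorm(m2, 0, 2.5, log = TRUE) +
      colSums(dnorm(Q[6:9, , drop = FALSE], log = TRUE)) +
      colSums(dnorm(Q[10:11, , drop = FALSE], 0, 2.5, log = TRUE)) +
      dexp(sg0, 1, log = TRUE) + dexp(sg1, 1, log = TRUE) +
      Q[12, ] + Q[13, ]
  } else {
    lp <- lp + dnorm(b01, 0, 2.5, log = TRUE) + dnorm(b11, 0, 2.5, log = TRUE)
  }
  lp
}

tiny_is_oracle <- function(trial, hier = TRUE, S = 5e5, seed = 5, df = 4,
                           inflate = 1.6) {
  x <- trial$x1; a <- trial$trt; y1 <- trial$y1; y2 <- trial$y2
  f <- function(q) tiny_logpost_mat(matrix(q, ncol = 1), x, a, y1, y2, hier)
  npar <- if (hier) 13L else 5L
  set.seed(seed)
  opt <- optim(rep(0, npar), function(q) -f(q), method = "BFGS",
               hessian = TRUE, control = list(maxit = 500))
  Sig <- solve(opt$hessian)
  Sig <- (Sig + t(Sig)) / 2 * inflate^2
  Lc <- t(chol(Sig))
  Z <- matrix(rnorm(S * npar), npar, S)
  chi <- sqrt(rchisq(S, df) / df)
  Q <- opt$par + (Lc %*% Z) / rep(chi, each = npar)
  sol <- forwardsolve(Lc, Q - opt$par)
  lq <- -0.5 * (df + npar) * log1p(colSums(sol^2) / df)
  lp <- tiny_logpost_mat(Q, x, a, y1, y2, hier)
  lw <- lp - lq
  lw <- lw - max(lw[is.finite(lw)])
  w <- exp(lw); w[!is.finite(w)] <- 0
  if (hier) {
    b01 <- Q[10, ] + exp(Q[12, ]) * Q[6, ]
    b11 <- Q[11, ] + exp(Q[13, ]) * Q[7, ]
  } else {
    b01 <- Q[4, ]; b11 <- Q[5, ]
  }
  list(beta0 = sum(w * b01) / sum(w), beta1 = sum(w * b11) / sum(w),
       ess = sum(w)^2 / sum(w^2))
}
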