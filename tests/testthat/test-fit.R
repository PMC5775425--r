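test_that("the weight is recovered at grid resolution in the noiseless limit", {
  d <- standard_design("exp3")
  for (w_true in c(1, 0.5)) {
    tr <- sim_subject_filtered(d, w = w_true, sigma = 1e-6, seed = 31)
    f <- fit_weighting(tr, "visual", block = 1)
    expect_lt(abs(f$w_hat - w_true), 0.011)
    expect_lt(abs(f$w_mean - w_true), 0.011)
    # round trip recovers the generating response parameters too
    expect_equal(f$params$zeta1_valid, 2.2, tolerance = 1e-3)
    expect_equal(f$params$zeta2_valid, 0.5, tolerance = 1e-2)
  }
})

test_that("the grid profile agrees with an independent likelihood evaluation", {
  # oracle: recompute the profiled likelihood at a few w values using lm()
  d <- standard_design("exp3")
  tr <- sim_subject_filtered(d, w = 0.8, sigma = 0.1, seed = 13)
  f <- fit_weighting(tr, "visual", block = 2)
  u <- f$data
  for (w in c(0.2, 0.5, 0.9)) {
    p_int <- w * u$p_own + (1 - w) * u$p_other
    x <- ifelse(u$validity == "valid", p_int, 1 - p_int)
    sse <- 0
    for (cond in c("valid", "invalid")) {
      i <- u$validity == cond
      sse <- sse + sum(resid(lm(u$rs[i] ~ x[i]))^2)
    }
    n <- nrow(u)
    ll_oracle <- -n / 2 * (log(2 * pi * sse / n) + 1)
    expect_equal(f$profile$log_likelihood[f$profile$w == w], ll_oracle,
                 tolerance = 1e-8)
  }
})

test_that("constant response speeds leave the weight unidentified but flagged", {
  tr <- rs_trials(validity = rep(c("valid", "invalid"), each = 10),
                  rs = rep(2.1, 20))
  tr$modality <- rep(c("visual", "tactile"), 10)
  f <- fit_weighting(tr, "visual")
  expect_true("w_unidentified" %in% f$flags)
  expect_true(is.na(f$w_hat))
})

test_that("units with too few kept trials return a flagged record, not an error", {
  tr <- rs_trials(validity = rep("valid", 4), rs = rnorm(4, 2, 0.1))
  f <- fit_weighting(tr, "visual")
  expect_s3_class(f, "weight_fit")
  expect_true("too_few_trials" %in% f$flags)
  expect_true(is.na(f$log_evidence))
})

test_that("the likelihood profile in w is invariant to shifting all RS", {
  d <- standard_design("exp3")
  tr <- sim_subject_filtered(d, w = 0.7, sigma = 0.15, seed = 5)
  f1 <- fit_weighting(tr, "tactile", block = 1)
  tr$rs[!is.na(tr$rs)] <- tr$rs[!is.na(tr$rs)] + 0.7
  f2 <- fit_weighting(tr, "tactile", block = 1)
  expect_equal(f1$profile$log_likelihood, f2$profile$log_likelihood,
               tolerance = 1e-8)
  expect_equal(f1$w_hat, f2$w_hat, tolerance = 1e-6)
})

test_that("concatenated fitting reduces to the single-block fit and ignores block order", {
  d <- standard_design("exp3")
  tr <- sim_subject_filtered(d, w = 0.9, sigma = 0.1, seed = 8)
  one <- tr[tr$block == 2, ]
  expect_equal(fit_bayesian_concatenated(one, "visual")$w_hat,
               fit_weighting(one, "visual", block = 2)$w_hat,
               tolerance = 1e-9)
  # permuting whole blocks (within-block order intact) changes nothing
  perm <- tr[order(match(tr$block, c(3, 1, 4, 2)), tr$trial_index), ]
  expect_equal(fit_bayesian_concatenated(perm, "visual")$w_hat,
               fit_bayesian_concatenated(tr, "visual")$w_hat,
               tolerance = 1e-9)
})

test_that("concatenated weights are recovered across a noisy mini-cohort", {
  # bound verified by simulation at sigma = 0.2 (the profile has a
  # w-slope ridge in complementary designs, so recovery is noisy)
  d <- standard_design("exp3")
  errs <- c()
  for (s in 1:6) {
    w_true <- c(0.5, 0.7, 0.9)[(s - 1) %% 3 + 1]
    tr <- sim_subject_filtered(d, w = w_true, sigma = 0.2, seed = 100 + s)
    for (m in c("visual", "tactile"))
      errs <- c(errs, abs(fit_bayesian_concatenated(tr, m)$w_hat - w_true))
  }
  expect_lte(median(errs), 0.2)
})

test_that("the constant model is exact on saturated noiseless data", {
  tr <- rs_trials(validity = rep(c("valid", "invalid"), each = 10),
                  rs = rep(c(2.4, 2.1), each = 10))
  f <- fit_constant_model(tr, "visual")
  expect_lt(max(abs(f$residuals)), 1e-10)
  expect_equal(unname(fitted(f)[1]), 2.4)
})

test_that("fitted block constants sit at the optimum of a grid oracle", {
  d <- standard_design("exp1")
  tr <- sim_subject_filtered(d, w = 0.6, sigma = 0.15, seed = 17)
  f <- fit_constant_model(tr, "visual")
  u <- f$data
  z <- f$params
  blocks <- sort(unique(u$block))
  for (b in blocks) {
    i <- u$block == b
    sse_at <- function(p) {
      x <- ifelse(u$validity[i] == "valid", p, 1 - p)
      sum((u$rs[i] - xmcue:::predict_from_zetas(x, u$validity[i], z))^2)
    }
    grid <- seq(0, 1, 0.001)
    best <- grid[which.min(vapply(grid, sse_at, numeric(1)))]
    expect_lt(abs(f$p_const[paste0("block", b)] - best), 0.0015)
  }
})

test_that("model-object methods are coherent", {
  d <- standard_design("exp3")
  tr <- sim_subject_filtered(d, w = 0.8, sigma = 0.1, seed = 23)
  f <- fit_weighting(tr, "visual", block = 1)
  expect_named(coef(f)[1], "w")
  expect_equal(unname(coef(f)["sigma"]), f$params$sigma)
  ll <- logLik(f)
  expect_equal(attr(ll, "df"), f$k_params)
  expect_equal(length(residuals(f)), f$n_trials_used)
  expect_equal(fitted(f) + residuals(f), f$data$rs)
  expect_equal(predict(f), fitted(f))
  nd <- data.frame(p_own = 0.9, p_other = 0.2, validity = "valid")
  expect_equal(predict(f, nd),
               f$params$zeta1_valid + f$params$zeta2_valid *
                 (f$w_hat * 0.9 + (1 - f$w_hat) * 0.2))
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(f$n_trials_used, 3))
  expect_identical(sims, simulate(f, nsim = 3, seed = 1))
  expect_output(print(f), "w = ")
  expect_output(print(summary(f)), "residual RMSE")
  # evidence is penalized likelihood
  expect_lt(f$log_evidence, f$log_likelihood)
})

test_that("laplace evidence is finite and below the likelihood for interior optima", {
  d <- standard_design("exp3")
  tr <- sim_subject_filtered(d, w = 0.7, sigma = 0.2, seed = 41)
  f <- suppressWarnings(
    fit_bayesian_concatenated(tr, "visual", evidence_method = "laplace"))
  expect_true(is.finite(f$log_evidence))
  expect_lt(f$log_evidence, f$log_likelihood)
})
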