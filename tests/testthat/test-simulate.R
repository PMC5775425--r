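test_that("simulation is deterministic in the seed and reproducible", {
  d <- standard_design("exp3")
  truth <- list(w = 0.8, params = default_truth_params())
  t1 <- simulate_subject(d, truth, seed = 9)
  t2 <- simulate_subject(d, truth, seed = 9)
  expect_identical(t1, t2)
  expect_false(identical(t1$rt_ms, simulate_subject(d, truth, seed = 10)$rt_ms))
  expect_equal(nrow(t1), 320)
  expect_true(all(t1$correct))
  expect_true(all(t1$rt_ms > 0 & t1$rt_ms <= 5000))
})

test_that("zero slopes make the validity effect independent of predictability", {
  d <- standard_design("exp3")
  params <- default_truth_params(zeta2_valid = 0, zeta2_invalid = 0,
                                 sigma = 1e-6)
  tr <- simulate_subject(d, list(w = 1, params = params), seed = 4)
  rs <- 1000 / tr$rt_ms
  for (b in unique(tr$block)) {
    i <- tr$block == b
    expect_equal(mean(rs[i & tr$validity == "valid"]), 2.2, tolerance = 1e-4)
    expect_equal(mean(rs[i & tr$validity == "invalid"]), 2.0, tolerance = 1e-4)
  }
})

test_that("simulated validity effects grow with cue predictability at w = 1", {
  d <- standard_design("exp3")
  tr <- simulate_subject(d, list(w = 1, params = default_truth_params(sigma = 1e-6)),
                         seed = 12)
  rs <- 1000 / tr$rt_ms
  for (m in c("visual", "tactile")) {
    p_block <- if (m == "visual") d$blocks$p_valid_visual
               else d$blocks$p_valid_tactile
    effect <- vapply(d$blocks$block, function(b) {
      i <- tr$block == b & tr$modality == m
      mean(rs[i & tr$validity == "valid"]) -
        mean(rs[i & tr$validity == "invalid"])
    }, numeric(1))
    expect_equal(cor(effect, p_block, method = "spearman"), 1)
  }
})

test_that("cohorts carry ground truth and honor the truth sampler", {
  d <- standard_design("exp1")
  coh <- simulate_cohort(d, n_subjects = 3, seed = 2)
  expect_equal(length(unique(coh$trials$subject_id)), 3)
  expect_equal(nrow(coh$trials), 3 * 480)
  expect_equal(length(coh$truth), 3)
  expect_true(all(vapply(coh$truth, function(t) t$w >= 0.5 && t$w <= 1,
                         logical(1))))
  point <- function(i) list(w = 0.75, params = default_truth_params())
  coh2 <- simulate_cohort(d, 3, point, seed = 2)
  expect_equal(unique(vapply(coh2$truth, `[[`, numeric(1), "w")), 0.75)
  expect_identical(simulate_cohort(d, 3, seed = 2)$trials, coh$trials)
})

test_that("error injection feeds the exclusion rules", {
  d <- standard_design("exp3")
  tr <- simulate_subject(d, list(w = 0.8, params = default_truth_params()),
                         seed = 6, error_rate = 0.2)
  expect_gt(mean(!tr$correct), 0.1)
  expect_lt(mean(!tr$correct), 0.3)
  f <- filter_trials(tr)
  expect_equal(sum(f$exclusion_reason == "incorrect"), sum(!tr$correct))
})

test_that("noiseless round trip recovers the generating truth", {
  d <- standard_design("exp3")
  tr <- sim_subject_filtered(d, w = 0.9, sigma = 1e-6, seed = 3)
  f <- fit_bayesian_concatenated(tr, "tactile")
  expect_lt(abs(f$w_hat - 0.9), 0.011)
  expect_equal(f$params$zeta1_invalid, 2.0, tolerance = 1e-3)
})

test_that("recovery reports tabulate every unit exactly once", {
  d <- standard_design("exp3")
  rep <- recovery_experiment(d, w_values = c(0.6, 0.9), n_subjects = 4,
                             sigma = 0.05, seed = 5, model_recovery = FALSE)
  expect_equal(nrow(rep$units), 4 * 4 * 2)
  expect_equal(nrow(unique(rep$units[, c("subject", "block", "modality")])),
               nrow(rep$units))
  expect_equal(nrow(rep$concatenated), 4 * 2)
  expect_true(all(c("block_argmax", "concat_postmean") %in%
                    names(rep$summary)))
  # at low noise the pipeline tracks the truth closely
  expect_lt(rep$summary$concat_argmax$median_abs_error, 0.1)
  expect_output(print(rep), "median")
})
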