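make_records <- function(rt, response = "proximal", correct = TRUE) {
  n <- length(rt)
  data.frame(rt_ms = rt, response = rep(response, length.out = n),
             correct = rep(correct, length.out = n),
             stringsAsFactors = FALSE)
}

test_that("two-stage exclusion matches direct arithmetic on a mixed fixture", {
  rts7 <- c(400, 410, 390, 405, 395, 402, 1200)
  rec <- rbind(
    make_records(350, correct = FALSE),          # incorrect
    make_records(NA, response = "none"),         # miss
    make_records(90),                            # anticipation
    make_records(rts7)                           # correct responses
  )
  out <- filter_trials(rec)
  expect_equal(out$exclusion_reason[1:3], c("incorrect", "miss", "anticipation"))
  # stage-2 oracle: mean/SD over the 7 stage-1 survivors
  bound <- 2 * stats::sd(rts7)
  is_out <- abs(rts7 - mean(rts7)) > bound
  expect_true(is_out[7])  # the 1200 ms response deviates > 2 SD
  expect_equal(out$exclusion_reason[4:10],
               ifelse(is_out, "outlier", "kept"))
  expect_equal(sum(out$exclusion_reason == "kept"), 6)
  # RS in 1/s for kept rows only
  kept <- out$exclusion_reason == "kept"
  expect_equal(out$rs[kept], 1000 / out$rt_ms[kept])
  expect_true(all(is.na(out$rs[!kept])))
})

test_that("boundary and zero-variance cases follow the stated rules", {
  # exactly 100 ms is not an anticipation (rule is strictly < 100 ms)
  out <- filter_trials(make_records(c(100, 400, 400, 400)))
  expect_equal(out$exclusion_reason[1], "kept")
  expect_warning(just_under <- filter_trials(make_records(99.9)),
                 "all trials excluded")
  expect_equal(just_under$exclusion_reason, "anticipation")
  # identical RTs: SD = 0, nothing deviates more than 2 SD
  all_same <- filter_trials(make_records(rep(400, 8)))
  expect_true(all(all_same$exclusion_reason == "kept"))
})

test_that("exclusion labels always partition the input", {
  set.seed(42)
  for (i in 1:5) {
    n <- 50
    rec <- make_records(
      rt = ifelse(runif(n) < 0.05, NA, rlnorm(n, log(420), 0.25)),
      correct = runif(n) > 0.08)
    rec$response[is.na(rec$rt_ms)] <- "none"
    out <- filter_trials(rec)
    tab <- table(factor(out$exclusion_reason,
                        c("kept", "incorrect", "miss", "anticipation",
                          "outlier")))
    expect_equal(sum(tab), n)
    kept <- out[out$exclusion_reason == "kept", ]
    expect_true(all(kept$rs > 0 & is.finite(kept$rs)))
  }
})

test_that("filtering is idempotent when survivors stay inside the new bounds", {
  rec <- make_records(c(400, 410, 390, 405, 395, 402, 1200))
  out <- filter_trials(rec)
  kept <- out[out$exclusion_reason == "kept", c("rt_ms", "response", "correct")]
  # survivors sit within 2 SD of their own mean, so a second pass keeps all
  expect_true(all(abs(kept$rt_ms - mean(kept$rt_ms)) <=
                    2 * stats::sd(kept$rt_ms)))
  again <- filter_trials(kept)
  expect_true(all(again$exclusion_reason == "kept"))
})

test_that("degenerate inputs are handled without error", {
  expect_equal(nrow(filter_trials(make_records(numeric(0)))), 0)
  expect_warning(filter_trials(make_records(c(NA, NA), response = "none")),
                 "all trials excluded")
  expect_error(
    filter_trials(cbind(make_records(c(400, 410)),
                        subject_id = c("a", "b"))),
    "single subject")
})

test_that("accuracy summary counts every exclusion as an error", {
  rts7 <- c(400, 410, 390, 405, 395, 402, 1200)
  rec <- rbind(make_records(350, correct = FALSE),
               make_records(NA, response = "none"),
               make_records(90),
               make_records(rts7))
  s <- accuracy_summary(rec)
  expect_equal(s$pct_correct, 60)  # 6 kept of 10
  expect_equal(s$mean_rt_ms, mean(rts7[-7]))
  miss_all <- suppressWarnings(
    accuracy_summary(make_records(c(NA, NA), response = "none")))
  expect_equal(miss_all$pct_correct, 0)
  expect_true(miss_all$degenerate)
  expect_true(is.na(miss_all$mean_rt_ms))
})
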