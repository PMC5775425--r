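#' Simulate one subject's session with known ground truth
#'
#' Generates a full behavioral session by composing the forward model: the
#' seeded trial sequence of the design, the ideal observer's trial-wise
#' validity estimates, the weighted integration of the two modality-specific
#' estimates, and the linear response model with Gaussian RS noise. Under
#' the alternative generating model (`model = "constant"`), the per-trial
#' mean RS uses a fixed per-block predictability instead of the learner's
#' trajectory. Simulated RS is floored at 0.2 1/s (RT of at most 5 s), a
#' generator-only convention that keeps Gaussian tails from producing
#' non-positive speeds. All trials are marked correct unless `error_rate`
#' is set, in which case a seeded fraction of trials is marked incorrect to
#' exercise the exclusion rules.
#'
#' @param design an `experiment_design`.
#' @param truth list describing the generating process: `w` (scalar, or a
#'   named vector `c(visual = , tactile = )`), `params` (list with the four
#'   zeta values and `sigma`), optional `model` (`"bayesian"`, the default,
#'   or `"constant"`), and for the constant model `p_const`, a vector of
#'   per-block predictabilities (recycled across modalities or a
#'   blocks-by-2 matrix with columns visual/tactile).
#' @param seed integer seed controlling both the trial sequence and the
#'   noise draws.
#' @param subject_id identifier stored in the output.
#' @param error_rate fraction of trials marked incorrect (default 0).
#' @return A trial table (data frame) in the standard schema: design
#'   columns plus `subject_id`, `experiment`, `rt_ms`, `response`,
#'   `correct`, with attribute `"truth"` carrying the generating values.
#' @examples
#' tr <- simulate_subject(standard_design("exp3"),
#'                        truth = list(w = 1, params = default_truth_params()),
#'                        seed = 1)
#' nrow(tr)  # 320
#' @export
simulate_subject <- function(design, truth, seed, subject_id = "s1",
                             error_rate = 0) {
  validate_design(design)
  stopifnot(is.list(truth), !is.null(truth$w) || !is.null(truth$p_const))
  model <- if (is.null(truth$model)) "bayesian" else truth$model
  params <- truth$params
  stopifnot(params$sigma > 0)
  trials <- randomize_trials(design, seed = seed)
  traj <- observer_trajectories(trials)
  w <- truth$w
  if (model == "bayesian") {
    if (length(w) == 1) w <- c(visual = unname(w), tactile = unname(w))
    if (any(w < 0 | w > 1)) stop("true w must lie in [0, 1]")
    oo <- own_other(traj)
    wt <- unname(w[traj$modality])
    p_int <- wt * oo$p_own + (1 - wt) * oo$p_other
  } else {
    pc <- truth$p_const
    blocks <- design$blocks$block
    if (is.null(dim(pc))) pc <- cbind(visual = pc, tactile = pc)
    bi <- match(traj$block, blocks)
    p_int <- ifelse(traj$modality == "visual", pc[bi, "visual"],
                    pc[bi, "tactile"])
  }
  mu <- predicted_rs(p_int, traj$validity, params)
  if (any(mu <= 0))
    stop("pathological response parameters: non-positive predicted mean RS")
  out <- with_seed(as.integer(seed) + 1L, {
    rs <- stats::rnorm(length(mu), mu, params$sigma)
    bad <- rs < 0.2
    if (any(bad)) rs[bad] <- pmax(stats::rnorm(sum(bad), mu[bad],
                                               params$sigma), 0.2)
    correct <- rep(TRUE, length(rs))
    if (error_rate > 0)
      correct[stats::runif(length(rs)) < error_rate] <- FALSE
    list(rs = rs, correct = correct)
  })
  trials$subject_id <- subject_id
  trials$experiment <- design$experiment_id
  trials$rt_ms <- 1000 / out$rs
  trials$response <- trials$elevation
  trials$response[!out$correct] <-
    ifelse(trials$elevation[!out$correct] == "proximal", "distal", "proximal")
  trials$correct <- out$correct
  cols <- c("subject_id", "experiment", "block", "trial_index", "modality",
            "cue_side", "target_side", "validity", "elevation", "rt_ms",
            "response", "correct")
  trials <- trials[, cols]
  attr(trials, "truth") <- c(truth, list(model = model))
  trials
}

#' Default response-model ground-truth parameters
#'
#' Intercepts of 2.2 (valid) and 2.0 (invalid) 1/s, slopes of 0.5 1/s per
#' unit probability and a noise SD of 0.2 1/s put the simulated mean RT in
#' the low-400 ms range typical of speeded multisensory detection, with a
#' validity effect that grows with the learned cue predictability.
#'
#' @param zeta1_valid,zeta1_invalid condition intercepts (1/s).
#' @param zeta2_valid,zeta2_invalid condition slopes (1/s per unit
#'   probability).
#' @param sigma RS noise SD (1/s).
#' @return A named list usable as the `params` element of a simulation
#'   truth.
#' @export
default_truth_params <- function(zeta1_valid = 2.2, zeta2_valid = 0.5,
                                 zeta1_invalid = 2.0, zeta2_invalid = 0.5,
                                 sigma = 0.2) {
  list(zeta1_valid = zeta1_valid, zeta2_valid = zeta2_valid,
       zeta1_invalid = zeta1_invalid, zeta2_invalid = zeta2_invalid,
       sigma = sigma)
}

#' Simulate a cohort with stored ground truth
#'
#' Independent per-subject seeds are derived from the master seed, so the
#' whole dataset is reproducible from `(design, truth_sampler, seed)` alone.
#'
#' @param design an `experiment_design`.
#' @param n_subjects cohort size (default 21).
#' @param truth_sampler function `(subject_index)` returning a truth list
#'   as accepted by [simulate_subject()]; the default draws `w` uniformly
#'   on \[0.5, 1\] with [default_truth_params()].
#' @param seed master integer seed.
#' @param error_rate passed to [simulate_subject()].
#' @return A list with `trials` (row-bound trial tables of all subjects)
#'   and `truth` (per-subject list of generating values).
#' @export
simulate_cohort <- function(design, n_subjects = 21,
                            truth_sampler = NULL, seed = 1,
                            error_rate = 0) {
  if (is.null(truth_sampler)) {
    truth_sampler <- function(i)
      list(w = stats::runif(1, 0.5, 1), params = default_truth_params())
  }
  seed <- as.integer(seed)
  subject_seeds <- with_seed(seed, sample.int(2^30, n_subjects))
  truths <- with_seed(seed + 1L, lapply(seq_len(n_subjects), truth_sampler))
  tables <- lapply(seq_len(n_subjects), function(i) {
    simulate_subject(design, truths[[i]], seed = subject_seeds[i],
                     subject_id = sprintf("s%02d", i),
                     error_rate = error_rate)
  })
  names(truths) <- sprintf("s%02d", seq_len(n_subjects))
  list(trials = do.call(rbind, tables), truth = truths)
}

#' Parameter- and model-recovery study
#'
#' The package's stand-in for unavailable raw data: simulate a cohort with
#' known ground truth, push it through the exclusion rules and the fitting
#' pipeline, and tabulate how well the generating values are recovered.
#' With `w_values` given, subjects cycle through the listed true weights
#' and every (block, modality) unit is fitted separately; the report
#' summarizes the absolute estimation error and the truth-estimate
#' correlation. With `model_recovery = TRUE` the function additionally fits
#' both candidate models to each subject's concatenated session and runs
#' random-effects BMS, reporting the protected exceedance probability of
#' the generating model.
#'
#' @param design an `experiment_design`.
#' @param w_values true weighting factors cycled over subjects.
#' @param n_subjects cohort size (default 21).
#' @param sigma RS noise SD of the generator (1/s).
#' @param seed master seed.
#' @param params response ground truth (default [default_truth_params()]
#'   with `sigma` substituted).
#' @param generating_model `"bayesian"` or `"constant"`.
#' @param p_const per-block constant predictabilities when generating from
#'   the constant model. The default samples each block's and modality's
#'   level uniformly on \[0, 1\] per subject — the parameter's own prior —
#'   so that the recovery study probes the alternative model's full
#'   generative range rather than the special case where its predictions
#'   coincide with the learner's asymptote.
#' @param model_recovery run the BMS model-recovery arm (default TRUE).
#' @param grid_step passed to [fit_weighting()].
#' @return An object of class `recovery_report`: list with `units` (one
#'   row per fitted subject x block x modality: true w, the
#'   maximum-likelihood `w_hat` and the grid posterior mean `w_mean`,
#'   flags), `concatenated` (the same per subject x modality from the
#'   concatenated fits), `median_abs_error` and `correlation` (per-block
#'   `w_hat` versus truth), `summary` (the same two numbers for all four
#'   estimator/level combinations), and when requested `bms` (per-modality
#'   `bms_result`s) and `pxp_generating` (named vector, protected
#'   exceedance probability of the generating model per modality).
#' @export
recovery_experiment <- function(design, w_values = c(0.5, 0.7, 0.9),
                                n_subjects = 21, sigma = 0.2, seed = 1,
                                params = NULL,
                                generating_model = c("bayesian", "constant"),
                                p_const = NULL,
                                model_recovery = TRUE,
                                grid_step = 0.01) {
  generating_model <- match.arg(generating_model)
  if (is.null(params)) params <- default_truth_params(sigma = sigma)
  params$sigma <- sigma
  sampler <- function(i) {
    tr <- list(params = params, model = generating_model,
               w = w_values[(i - 1) %% length(w_values) + 1])
    if (generating_model == "constant") {
      nb <- nrow(design$blocks)
      tr$p_const <- if (is.null(p_const))
        cbind(visual = stats::runif(nb), tactile = stats::runif(nb))
      else p_const
    }
    tr
  }
  cohort <- simulate_cohort(design, n_subjects, sampler, seed = seed)
  trials <- filter_trials_by_subject(cohort$trials)
  units <- list()
  concat <- list()
  for (s in unique(trials$subject_id)) {
    d <- trials[trials$subject_id == s, , drop = FALSE]
    true_w <- cohort$truth[[s]]$w
    for (m in c("visual", "tactile")) {
      fcat <- fit_bayesian_concatenated(d, m, grid_step = grid_step)
      concat[[length(concat) + 1]] <- data.frame(
        subject = s, modality = m, w_true = true_w,
        w_hat = fcat$w_hat, w_mean = fcat$w_mean,
        flags = paste(fcat$flags, collapse = ";"))
      for (b in unique(d$block)) {
        f <- fit_weighting(d, m, block = b, grid_step = grid_step)
        units[[length(units) + 1]] <- data.frame(
          subject = s, block = b, modality = m,
          w_true = true_w, w_hat = f$w_hat, w_mean = f$w_mean,
          flags = paste(f$flags, collapse = ";")
        )
      }
    }
  }
  units <- do.call(rbind, units)
  concat <- do.call(rbind, concat)
  recov_summary <- function(tab, col) {
    ok <- !is.na(tab[[col]])
    list(
      median_abs_error = stats::median(abs(tab[[col]][ok] - tab$w_true[ok])),
      correlation = if (sum(ok) > 2 && stats::sd(tab$w_true[ok]) > 0 &&
                        stats::sd(tab[[col]][ok]) > 0)
        stats::cor(tab$w_true[ok], tab[[col]][ok]) else NA_real_
    )
  }
  s_block <- recov_summary(units, "w_hat")
  out <- list(units = units, concatenated = concat,
              median_abs_error = s_block$median_abs_error,
              correlation = s_block$correlation,
              summary = list(
                block_argmax = s_block,
                block_postmean = recov_summary(units, "w_mean"),
                concat_argmax = recov_summary(concat, "w_hat"),
                concat_postmean = recov_summary(concat, "w_mean")
              ),
              n_flagged = sum(is.na(units$w_hat)),
              generating_model = generating_model)
  if (model_recovery) {
    cmp <- compare_learning_models(trials, seed = seed, n_samples = 1e5)
    out$bms <- lapply(cmp, `[[`, "bms")
    out$pxp_generating <- vapply(
      cmp, function(x) unname(x$bms$pxp[generating_model]), numeric(1))
  }
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "Recovery study (%s generator): %d fitted units, %d flagged\n",
    x$generating_model, nrow(x$units), x$n_flagged))
  cat(sprintf("  median |w_hat - w_true| = %.3f, correlation = %.3f\n",
              x$median_abs_error, x$correlation))
  if (!is.null(x$pxp_generating)) {
    cat("  protected exceedance probability of the generating model:\n")
    for (m in names(x$pxp_generating))
      cat(sprintf("    %s: %.3f\n", m, x$pxp_generating[m]))
  }
  invisible(x)
}

# filter_trials() applied per subject, keeping the cohort in one table.
filter_trials_by_subject <- function(trials) {
  pieces <- lapply(split(trials, trials$subject_id), filter_trials)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$subject_id, out$block, out$trial_index), ]
}
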