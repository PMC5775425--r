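#' Fit the weighting factor w and response parameters for one unit
#'
#' Estimates, by profiled maximum likelihood, how a subject combined the
#' two modality-specific cue predictabilities when responding to targets of
#' one modality. The ideal-observer trajectories are computed from the full
#' presented trial sequence (both modalities, all blocks, excluded trials
#' included — the cue-target contingency is observed regardless of the
#' response); the likelihood uses only the kept trials of the requested
#' modality (and block, when fitting per block).
#'
#' For each candidate weight `w` on a grid over \[0, 1\] (default step 0.01,
#' followed by golden-section refinement around the best grid point), the
#' integrated expectation per trial follows from
#' [integrate_expectancy()], the four response intercepts/slopes are
#' profiled per validity condition by closed-form least squares, and the
#' noise SD by the maximum-likelihood residual variance. A validity
#' condition with fewer than `min_condition_n` kept trials (or a constant
#' predictor) gets an intercept only, with its slope fixed at 0. Log model
#' evidence is BIC by default (`log_lik - k/2 * log(n)`), or a Laplace
#' approximation using a numerical Hessian.
#'
#' When the likelihood is flat in `w` (e.g. both slopes fixed at 0, so `w`
#' enters the model nowhere), the fit is flagged `"w_unidentified"` and
#' `w_hat` is `NA`. Units with fewer than 6 kept trials return a flagged
#' failure record (`"too_few_trials"`) rather than an error, so cohort runs
#' survive sparse subjects.
#'
#' @param trials full trial table of one subject: columns `block`,
#'   `trial_index`, `modality`, `validity`, plus either `rs` (1/s, with an
#'   optional `exclusion_reason` column) or `rt_ms`/`response`/`correct`, in
#'   which case [filter_trials()] is applied first.
#' @param modality `"visual"` or `"tactile"`: the fitting unit's target
#'   modality.
#' @param block block number(s) to fit; `NULL` (default) concatenates all
#'   blocks with one shared parameter set (belief trajectories still reset
#'   at every block boundary).
#' @param grid_step grid resolution for the w search (default 0.01).
#' @param w_range interval searched for w, default `c(0, 1)`.
#' @param evidence_method `"bic"` or `"laplace"`.
#' @param min_condition_n minimum kept trials per validity condition for a
#'   free slope (default 3).
#' @param refine logical: golden-section refinement after the grid search.
#' @return An object of class `c("weight_fit", "cue_fit")` with components
#'   `w_hat` (the maximum-likelihood weight), `w_mean` (the posterior mean
#'   of w over the grid under a uniform prior with profiled nuisance
#'   parameters — a shrinkage summary that stays interior when the profile
#'   is nearly flat, as in designs with complementary predictability
#'   levels), `params` (`zeta1_valid`, `zeta2_valid`, `zeta1_invalid`,
#'   `zeta2_invalid`, `sigma`), `log_likelihood`, `log_evidence`,
#'   `k_params`, `n_trials_used`, `fitting_unit`, `profile` (the gridded
#'   log-likelihood over w), `flags`, and the per-trial `data`, `fitted`
#'   and `residuals`. Methods: `print`, `summary`, `coef`, `logLik`,
#'   `predict`, `residuals`, `simulate`, `plot`.
#' @seealso [fit_constant_model()] for the no-learning alternative model,
#'   [rfx_bms()] for group-level model comparison.
#' @export
fit_weighting <- function(trials, modality = c("visual", "tactile"),
                          block = NULL, grid_step = 0.01,
                          w_range = c(0, 1),
                          evidence_method = c("bic", "laplace"),
                          min_condition_n = 3, refine = TRUE) {
  modality <- match.arg(modality)
  evidence_method <- match.arg(evidence_method)
  unit <- prepare_unit(trials, modality, block)
  fit <- structure(
    list(call = match.call(), model = "bayesian",
         fitting_unit = unit$fitting_unit, flags = character()),
    class = c("weight_fit", "cue_fit")
  )
  if (nrow(unit$kept) < 6) {
    return(failed_fit(fit, "too_few_trials", n = nrow(unit$kept)))
  }
  d <- unit$kept
  ll_at <- function(w) {
    p_int <- w * d$p_own + (1 - w) * d$p_other
    x <- ifelse(d$validity == "valid", p_int, 1 - p_int)
    prof <- profile_zetas(d$rs, x, d$validity, min_condition_n)
    loglik_from_sse(prof$sse, nrow(d))
  }
  ws <- seq(w_range[1], w_range[2], by = grid_step)
  lls <- vapply(ws, ll_at, numeric(1))
  if (diff(range(lls)) < 1e-8) {
    fit$flags <- c(fit$flags, "w_unidentified")
    w_hat <- NA_real_
    best_ll <- lls[1]
  } else {
    i <- which.max(lls)
    w_hat <- ws[i]
    best_ll <- lls[i]
    if (refine) {
      lo <- max(w_range[1], w_hat - grid_step)
      hi <- min(w_range[2], w_hat + grid_step)
      opt <- stats::optimize(ll_at, c(lo, hi), maximum = TRUE,
                             tol = .Machine$double.eps^0.5)
      if (opt$objective > best_ll) {
        w_hat <- opt$maximum
        best_ll <- opt$objective
      }
    }
  }
  w_eval <- if (is.na(w_hat)) 0.5 else w_hat
  p_int <- w_eval * d$p_own + (1 - w_eval) * d$p_other
  x <- ifelse(d$validity == "valid", p_int, 1 - p_int)
  prof <- profile_zetas(d$rs, x, d$validity, min_condition_n)
  n <- nrow(d)
  sigma <- sqrt(max(prof$sse / n, .Machine$double.xmin))
  k <- 1 + prof$k_zeta + 1
  d$p_int <- p_int
  fit$w_hat <- w_hat
  # grid posterior mean of w under a uniform prior (profiled nuisances):
  # a shrinkage summary that stays interior when the profile is ridge-flat
  wgt <- exp(lls - max(lls))
  fit$w_mean <- sum(ws * wgt) / sum(wgt)
  fit$params <- c(prof$zetas, list(sigma = sigma))
  fit$log_likelihood <- best_ll
  fit$k_params <- k
  fit$n_trials_used <- n
  fit$evidence_method <- evidence_method
  fit$profile <- data.frame(w = ws, log_likelihood = lls)
  fit$data <- d
  fit$fitted <- prof$fitted
  fit$residuals <- d$rs - prof$fitted
  fit$flags <- c(fit$flags, prof$flags)
  hess <- NULL
  if (evidence_method == "laplace" && !("w_unidentified" %in% fit$flags))
    hess <- fit_neg_hessian(fit)
  fit$log_evidence <- log_evidence(best_ll, k, n, evidence_method, hess)
  fit
}

#' Fit the weighting model over all blocks of a session
#'
#' Convenience wrapper around [fit_weighting()] with `block = NULL`: one
#' shared `(w, zeta, sigma)` set across all blocks of one subject and
#' modality (6 free parameters), with the observer's beliefs still reset to
#' the uniform prior at every block boundary. This concatenated fit is the
#' one entered into group-level Bayesian model selection against the
#' block-constant alternative.
#'
#' @inheritParams fit_weighting
#' @param ... passed on to [fit_weighting()].
#' @return A `weight_fit` object; see [fit_weighting()].
#' @export
fit_bayesian_concatenated <- function(trials, modality = c("visual", "tactile"),
                                      ...) {
  fit_weighting(trials, modality = match.arg(modality), block = NULL, ...)
}

#' Fit the block-constant predictability model
#'
#' The no-learning alternative: response speed in each block depends on a
#' single constant level of cue predictability `p_const` (one free value
#' per block, estimated from the data) through the same linear response
#' model, with the four intercept/slope parameters and the noise SD shared
#' across blocks. Predicted RS is therefore constant within each block and
#' validity condition. Parameters are estimated by alternating closed-form
#' least squares: given the block constants, the response parameters are a
#' per-condition linear regression; given the response parameters, each
#' block's optimal constant has a closed form (clipped to \[0, 1\]). The
#' free-parameter count is `n_blocks + n_free_zeta + 1`.
#'
#' @inheritParams fit_weighting
#' @param max_iter,tol alternating least-squares iteration cap and
#'   convergence tolerance on the residual sum of squares.
#' @return An object of class `c("constant_fit", "cue_fit")` with
#'   `p_const` (named by block) in place of `w_hat`; remaining components
#'   and methods as for [fit_weighting()].
#' @export
fit_constant_model <- function(trials, modality = c("visual", "tactile"),
                               block = NULL,
                               evidence_method = c("bic", "laplace"),
                               min_condition_n = 3,
                               max_iter = 500, tol = 1e-12) {
  modality <- match.arg(modality)
  evidence_method <- match.arg(evidence_method)
  unit <- prepare_unit(trials, modality, block)
  fit <- structure(
    list(call = match.call(), model = "constant",
         fitting_unit = unit$fitting_unit, flags = character()),
    class = c("constant_fit", "cue_fit")
  )
  if (nrow(unit$kept) < 6) {
    return(failed_fit(fit, "too_few_trials", n = nrow(unit$kept)))
  }
  d <- unit$kept
  blocks <- sort(unique(d$block))
  bi <- match(d$block, blocks)
  # init: empirical valid fraction per block, kept interior for identifiability
  p <- vapply(split(d$validity == "valid", bi), mean, numeric(1))
  p <- pmin(pmax(p, 0.05), 0.95)
  valid <- d$validity == "valid"
  sse_prev <- Inf
  prof <- NULL
  for (it in seq_len(max_iter)) {
    x <- ifelse(valid, p[bi], 1 - p[bi])
    prof <- profile_zetas(d$rs, x, d$validity, min_condition_n)
    z <- prof$zetas
    # closed-form per-block optimum of the constant predictability
    num <- den <- numeric(length(blocks))
    for (b in seq_along(blocks)) {
      iv <- valid & bi == b
      ii <- !valid & bi == b
      num[b] <- z$zeta2_valid * sum(d$rs[iv] - z$zeta1_valid) -
        z$zeta2_invalid * sum(d$rs[ii] - z$zeta1_invalid - z$zeta2_invalid)
      den[b] <- sum(iv) * z$zeta2_valid^2 + sum(ii) * z$zeta2_invalid^2
    }
    p_new <- ifelse(den > 1e-12, pmin(pmax(num / pmax(den, 1e-12), 0), 1), p)
    x_new <- ifelse(valid, p_new[bi], 1 - p_new[bi])
    pred <- predict_from_zetas(x_new, d$validity, z)
    sse <- sum((d$rs - pred)^2)
    p <- p_new
    if (abs(sse_prev - sse) < tol * max(1, sse_prev)) break
    sse_prev <- sse
  }
  x <- ifelse(valid, p[bi], 1 - p[bi])
  prof <- profile_zetas(d$rs, x, d$validity, min_condition_n)
  if (all(c(prof$zetas$zeta2_valid, prof$zetas$zeta2_invalid) == 0))
    fit$flags <- c(fit$flags, "p_const_unidentified")
  n <- nrow(d)
  sigma <- sqrt(max(prof$sse / n, .Machine$double.xmin))
  ll <- loglik_from_sse(prof$sse, n)
  k <- length(blocks) + prof$k_zeta + 1
  fit$p_const <- stats::setNames(p, paste0("block", blocks))
  fit$params <- c(prof$zetas, list(sigma = sigma))
  fit$log_likelihood <- ll
  fit$k_params <- k
  fit$n_trials_used <- n
  fit$evidence_method <- evidence_method
  fit$data <- d
  fit$fitted <- prof$fitted
  fit$residuals <- d$rs - prof$fitted
  fit$flags <- c(fit$flags, prof$flags)
  hess <- if (evidence_method == "laplace") fit_neg_hessian(fit) else NULL
  fit$log_evidence <- log_evidence(ll, k, n, evidence_method, hess)
  fit
}

# ---- shared internals -------------------------------------------------

# Select one subject/modality(/block) unit; attach observer trajectories
# computed from the full presented sequence.
prepare_unit <- function(trials, modality, block) {
  trials <- as.data.frame(trials)
  if (!is.null(trials$subject_id) && length(unique(trials$subject_id)) > 1)
    stop("fit one subject at a time; got multiple subject_id values")
  for (col in c("block", "modality", "validity"))
    if (is.null(trials[[col]])) stop("trials lack required column '", col, "'")
  if (is.null(trials$rs) && is.null(trials$exclusion_reason)) {
    if (is.null(trials$rt_ms))
      stop("trials need either an 'rs' or an 'rt_ms' column")
    trials <- filter_trials(trials)
  }
  if (is.null(trials$exclusion_reason))
    trials$exclusion_reason <- ifelse(is.na(trials$rs), "miss", "kept")
  if (!is.null(trials$trial_index))
    trials <- trials[order(trials$block, trials$trial_index), ]
  traj <- observer_trajectories(trials)
  oo <- own_other(traj)
  traj$p_own <- oo$p_own
  traj$p_other <- oo$p_other
  keep <- traj$exclusion_reason == "kept" & !is.na(traj$rs) &
    traj$modality == modality
  if (!is.null(block)) keep <- keep & traj$block %in% block
  kept <- traj[keep, , drop = FALSE]
  subject <- if (!is.null(trials$subject_id)) trials$subject_id[1] else NA
  list(
    kept = kept,
    fitting_unit = list(
      subject = subject, modality = modality,
      blocks = if (is.null(block)) sort(unique(traj$block)) else block
    )
  )
}

# Closed-form per-condition least squares of rs on the condition predictor
# x (p_int for valid trials, 1 - p_int for invalid ones). Conditions with
# fewer than min_n trials or a constant predictor get slope 0.
profile_zetas <- function(rs, x, validity, min_n) {
  zet <- list(zeta1_valid = NA_real_, zeta2_valid = 0,
              zeta1_invalid = NA_real_, zeta2_invalid = 0)
  fitted <- numeric(length(rs))
  sse <- 0
  k <- 0
  flags <- character()
  for (cond in c("valid", "invalid")) {
    idx <- validity == cond
    nc <- sum(idx)
    if (nc == 0) next
    xc <- x[idx]; yc <- rs[idx]
    vx <- sum((xc - mean(xc))^2)
    if (nc < min_n || vx < 1e-12) {
      slope <- 0
      intercept <- mean(yc)
      k <- k + 1
      if (nc >= min_n) flags <- c(flags, paste0("constant_predictor_", cond))
      else flags <- c(flags, paste0("slope_fixed_", cond))
    } else {
      slope <- sum((xc - mean(xc)) * (yc - mean(yc))) / vx
      intercept <- mean(yc) - slope * mean(xc)
      k <- k + 2
    }
    zet[[paste0("zeta1_", cond)]] <- intercept
    zet[[paste0("zeta2_", cond)]] <- slope
    f <- intercept + slope * xc
    fitted[idx] <- f
    sse <- sse + sum((yc - f)^2)
  }
  list(zetas = zet, sse = sse, k_zeta = k, fitted = fitted, flags = flags)
}

predict_from_zetas <- function(x, validity, z) {
  ifelse(validity == "valid",
         z$zeta1_valid + z$zeta2_valid * x,
         z$zeta1_invalid + z$zeta2_invalid * x)
}

# Gaussian log-likelihood at the profiled (ML) noise variance.
loglik_from_sse <- function(sse, n) {
  sigma2 <- max(sse / n, .Machine$double.xmin)
  -n / 2 * (log(2 * pi * sigma2) + 1)
}

failed_fit <- function(fit, flag, n) {
  fit$flags <- c(fit$flags, flag)
  fit$w_hat <- NA_real_
  fit$w_mean <- NA_real_
  fit$params <- list(zeta1_valid = NA_real_, zeta2_valid = NA_real_,
                     zeta1_invalid = NA_real_, zeta2_invalid = NA_real_,
                     sigma = NA_real_)
  fit$log_likelihood <- NA_real_
  fit$log_evidence <- NA_real_
  fit$k_params <- NA_integer_
  fit$n_trials_used <- n
  fit
}

# Negative Hessian of the full (unprofiled) log-likelihood at the optimum,
# over the free parameters, for the Laplace evidence.
fit_neg_hessian <- function(fit) {
  d <- fit$data
  z <- fit$params
  free_z <- c("zeta1_valid", "zeta1_invalid")
  if (!any(grepl("_fixed_valid|predictor_valid", fit$flags)))
    free_z <- c(free_z, "zeta2_valid")
  if (!any(grepl("_fixed_invalid|predictor_invalid", fit$flags)))
    free_z <- c(free_z, "zeta2_invalid")
  free_z <- free_z[!is.na(unlist(z[free_z]))]
  is_w <- inherits(fit, "weight_fit")
  theta0 <- c(if (is_w) fit$w_hat else unname(fit$p_const),
              unlist(z[free_z]), z$sigma)
  nb <- if (is_w) 1 else length(fit$p_const)
  nll <- function(theta) {
    zz <- z
    zz[free_z] <- as.list(theta[nb + seq_along(free_z)])
    sigma <- theta[length(theta)]
    if (sigma <= 0) return(Inf)
    if (is_w) {
      w <- theta[1]
      p_int <- w * d$p_own + (1 - w) * d$p_other
      x <- ifelse(d$validity == "valid", p_int, 1 - p_int)
    } else {
      blocks <- sort(unique(d$block))
      p <- theta[seq_len(nb)]
      pb <- p[match(d$block, blocks)]
      x <- ifelse(d$validity == "valid", pb, 1 - pb)
    }
    pred <- predict_from_zetas(x, d$validity, zz)
    -sum(stats::dnorm(d$rs, pred, sigma, log = TRUE))
  }
  h <- try(pracma::hessian(nll, theta0), silent = TRUE)
  if (inherits(h, "try-error")) return(NULL)
  h
}
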