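#' @export
print.cue_fit <- function(x, digits = 4, ...) {
  unit <- x$fitting_unit
  cat(sprintf(
    "%s response-speed model fit (subject %s, %s targets, block%s %s)\n",
    if (x$model == "bayesian") "Bayesian-learner" else "Block-constant",
    as.character(unit$subject), unit$modality,
    if (length(unit$blocks) > 1) "s" else "",
    paste(unit$blocks, collapse = ",")
  ))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  if ("too_few_trials" %in% x$flags) {
    cat(sprintf("not fitted: only %d kept trials\n", x$n_trials_used))
    return(invisible(x))
  }
  if (inherits(x, "weight_fit")) {
    cat(sprintf("  w = %s\n",
                if (is.na(x$w_hat)) "unidentified" else
                  format(x$w_hat, digits = digits)))
  } else {
    cat("  p_const:", paste(format(x$p_const, digits = digits),
                            collapse = " "), "\n")
  }
  cat("  coefficients:\n")
  print(round(unlist(x$params), digits))
  cat(sprintf("  log-likelihood %s, log evidence (%s) %s on %d trials\n",
              format(x$log_likelihood, digits = digits), x$evidence_method,
              format(x$log_evidence, digits = digits), x$n_trials_used))
  invisible(x)
}

#' @export
summary.cue_fit <- function(object, ...) {
  out <- list(
    fit = object,
    kept = object$n_trials_used,
    rmse = if (is.null(object$residuals)) NA_real_ else
      sqrt(mean(object$residuals^2)),
    by_condition = if (!is.null(object$data)) {
      do.call(rbind, lapply(split(object$data, object$data$validity),
        function(d) data.frame(validity = d$validity[1], n = nrow(d),
                               mean_rs = mean(d$rs))))
    } else NULL
  )
  class(out) <- "summary.cue_fit"
  out
}

#' @export
print.summary.cue_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$by_condition)) {
    cat("  mean observed RS by condition (1/s):\n")
    print(x$by_condition, row.names = FALSE)
    cat(sprintf("  residual RMSE %.4f 1/s\n", x$rmse))
  }
  invisible(x)
}

#' @export
coef.cue_fit <- function(object, ...) {
  base <- unlist(object$params)
  if (inherits(object, "weight_fit")) c(w = object$w_hat, base)
  else c(object$p_const, base)
}

#' @export
logLik.cue_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$k_params,
            nobs = object$n_trials_used, class = "logLik")
}

#' @export
residuals.cue_fit <- function(object, ...) object$residuals

#' @export
fitted.cue_fit <- function(object, ...) object$fitted

#' Predict mean response speed from a fitted model
#'
#' @param object a `weight_fit` or `constant_fit`.
#' @param newdata optional data frame. For a `weight_fit`: either a column
#'   `p_int`, or `p_own`/`p_other` to be integrated with the fitted weight;
#'   plus `validity`. For a `constant_fit`: columns `block` and `validity`.
#'   With `newdata = NULL` the fitted values are returned.
#' @param ... unused.
#' @return Predicted mean RS in 1/s.
#' @export
predict.cue_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  newdata <- as.data.frame(newdata)
  if (inherits(object, "weight_fit")) {
    p_int <- if (!is.null(newdata$p_int)) newdata$p_int
    else integrate_expectancy(newdata$p_own, newdata$p_other, object$w_hat)
    predicted_rs(p_int, newdata$validity, object$params)
  } else {
    p <- object$p_const[paste0("block", newdata$block)]
    predicted_rs(unname(p), newdata$validity, object$params)
  }
}

#' Simulate response speeds from a fitted model
#'
#' Draws Gaussian RS replicates around the fitted per-trial means with the
#' fitted noise SD, in the convention of [stats::simulate()].
#'
#' @param object a fitted `cue_fit`.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param ... unused.
#' @return A data frame with `nsim` columns of simulated RS (1/s), one row
#'   per kept trial of the fit.
#' @export
simulate.cue_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- object$fitted
  sigma <- object$params$sigma
  draw <- function() stats::rnorm(length(mu), mu, sigma)
  sims <- if (is.null(seed)) replicate(nsim, draw())
  else with_seed(as.integer(seed), replicate(nsim, draw()))
  out <- as.data.frame(matrix(sims, ncol = nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Diagnostic plot for a weighting-model fit
#'
#' Left: the profiled log-likelihood over the weight grid with the estimate
#' marked. Right: observed response speeds over trials with the model's
#' fitted means, split by cue validity.
#'
#' @param x a `weight_fit`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.weight_fit <- function(x, ...) {
  if ("too_few_trials" %in% x$flags) {
    warning("nothing to plot for an unfitted unit")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$profile$w, x$profile$log_likelihood, type = "l",
                 xlab = "weighting factor w", ylab = "profile log-likelihood",
                 main = "w profile", ...)
  if (!is.na(x$w_hat)) graphics::abline(v = x$w_hat, lty = 2)
  d <- x$data
  col <- ifelse(d$validity == "valid", "#1b7837", "#b2182b")
  graphics::plot(seq_len(nrow(d)), d$rs, col = col, pch = 16,
                 xlab = "kept trial", ylab = "RS (1/s)",
                 main = "observed vs fitted")
  graphics::lines(seq_len(nrow(d)), x$fitted)
  graphics::legend("topleft", legend = c("valid", "invalid"),
                   col = c("#1b7837", "#b2182b"), pch = 16, bty = "n")
  invisible(x)
}
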