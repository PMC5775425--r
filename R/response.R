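#' Predicted response speed under the linear response model
#'
#' The response model maps the integrated cue-validity expectation carried
#' into a trial onto mean response speed. For validly cued trials
#' `RS = zeta1_valid + zeta2_valid * p`; for invalidly cued trials
#' `RS = zeta1_invalid + zeta2_invalid * (1 - p)`, where `p` is the
#' pre-outcome integrated probability of a valid cue. The intercepts set the
#' overall speed level per condition; the slopes quantify how strongly
#' speed rises with the expected (in)validity.
#'
#' @param p_int integrated probability estimate(s) in \[0, 1\].
#' @param validity character vector, `"valid"` or `"invalid"`.
#' @param params list with `zeta1_valid`, `zeta2_valid`, `zeta1_invalid`,
#'   `zeta2_invalid` (1/s and 1/s per unit probability).
#' @return Predicted mean response speed in 1/s.
#' @examples
#' p <- list(zeta1_valid = 2, zeta2_valid = 0.5,
#'           zeta1_invalid = 2, zeta2_invalid = 0.5)
#' predicted_rs(0.8, "valid", p)    # 2.4
#' predicted_rs(0.8, "invalid", p)  # 2.1
#' @export
predicted_rs <- function(p_int, validity, params) {
  stopifnot(all(p_int >= 0 & p_int <= 1, na.rm = TRUE),
            all(validity %in% c("valid", "invalid")))
  ifelse(validity == "valid",
         params$zeta1_valid + params$zeta2_valid * p_int,
         params$zeta1_invalid + params$zeta2_invalid * (1 - p_int))
}

#' Gaussian log-likelihood of observed response speeds
#'
#' Independent homoscedastic normal observation noise on RS.
#'
#' @param rs_observed,rs_predicted numeric vectors of equal length (1/s).
#' @param sigma noise standard deviation (1/s), > 0.
#' @return The summed log-density in nats.
#' @export
gaussian_loglik <- function(rs_observed, rs_predicted, sigma) {
  if (length(rs_observed) != length(rs_predicted))
    stop("observed and predicted vectors must have equal length")
  if (sigma <= 0) stop("sigma must be positive")
  sum(stats::dnorm(rs_observed, rs_predicted, sigma, log = TRUE))
}

#' Penalized log model evidence
#'
#' Approximates the log marginal likelihood of a fitted model. The `"bic"`
#' method applies the Bayesian information criterion penalty,
#' `log_lik - (k/2) * log(n)`. The `"laplace"` method adds the Gaussian
#' curvature correction `(k/2) * log(2*pi) - log(det(H)) / 2`, where `H` is
#' the negative Hessian of the log-likelihood at the optimum; it requires
#' `hessian` and falls back to BIC with a warning when the Hessian is
#' singular or not positive definite (as at a boundary optimum).
#'
#' @param log_lik maximized log-likelihood in nats.
#' @param k_params number of free parameters.
#' @param n_obs number of observations.
#' @param method `"bic"` or `"laplace"`.
#' @param hessian negative Hessian matrix of the log-likelihood at the
#'   optimum (only used by `"laplace"`).
#' @return Log evidence in nats (never above `log_lik` for `k_params` > 0
#'   under BIC).
#' @examples
#' log_evidence(-10, k_params = 6, n_obs = 40)  # -10 - 3 * log(40)
#' @export
log_evidence <- function(log_lik, k_params, n_obs,
                         method = c("bic", "laplace"), hessian = NULL) {
  method <- match.arg(method)
  stopifnot(n_obs >= 1, k_params >= 0)
  bic_ev <- log_lik - k_params / 2 * log(n_obs)
  if (method == "bic" || k_params == 0) return(bic_ev)
  if (is.null(hessian)) {
    warning("laplace evidence requires a Hessian; falling back to BIC")
    return(bic_ev)
  }
  det_h <- suppressWarnings(determinant(hessian, logarithm = TRUE))
  ok <- is.finite(det_h$modulus) && det_h$sign > 0 &&
    all(diag(as.matrix(hessian)) > 0)
  if (!ok) {
    warning("singular or indefinite Hessian; falling back to BIC")
    return(bic_ev)
  }
  log_lik + k_params / 2 * log(2 * pi) - 0.5 * as.numeric(det_h$modulus)
}
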