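#' Random-effects Bayesian model selection
#'
#' Group-level comparison of competing models from per-subject log model
#' evidences, treating the model identity as a random effect: each subject
#' "uses" one model, drawn from population frequencies `r` with a Dirichlet
#' prior. The variational scheme iterates the posterior model assignment of
#' every subject (a softmax of the subject's log evidence plus the digamma
#' of the current Dirichlet pseudo-counts) against the Dirichlet update
#' until the pseudo-counts stabilize.
#'
#' Exceedance probabilities (the posterior probability that one model is
#' the most frequent in the population) are computed by seeded Monte Carlo
#' sampling of the posterior Dirichlet. The Bayesian omnibus risk — the
#' posterior probability that all models are equally frequent — is derived
#' from the variational free energy of the random-effects model against the
#' null of equal frequencies, and protects the exceedance probabilities:
#' `pxp = xp * (1 - bor) + bor / K`.
#'
#' @param evidence numeric matrix of log model evidences in nats, one row
#'   per subject, one column per model (at least 2 of each); column names
#'   label the models. Adding a constant to a subject's row leaves every
#'   result unchanged.
#' @param alpha0 Dirichlet prior pseudo-count per model (default 1).
#' @param n_samples Monte Carlo draws for the exceedance probabilities
#'   (default 1e6).
#' @param seed integer seed for the Monte Carlo step (RNG state restored).
#' @param tol,max_iter convergence tolerance on the pseudo-counts and
#'   iteration cap for the variational loop.
#' @return An object of class `bms_result`: list with `alpha` (posterior
#'   Dirichlet pseudo-counts), `expected_freq`, `xp`, `bor`, `pxp`,
#'   `assignments` (per-subject posterior model probabilities),
#'   `free_energy` (random-effects vs equal-frequency null), `converged`
#'   and `n_subjects`.
#' @examples
#' ev <- cbind(bayesian = rep(0, 8), constant = rep(-3, 8))
#' rfx_bms(ev, seed = 1, n_samples = 1e4)
#' @export
rfx_bms <- function(evidence, alpha0 = 1, n_samples = 1e6, seed = 1,
                    tol = 1e-6, max_iter = 10000) {
  evidence <- as.matrix(evidence)
  if (nrow(evidence) < 2) stop("group inference needs at least 2 subjects")
  if (ncol(evidence) < 2) stop("need at least 2 models to compare")
  if (!all(is.finite(evidence))) stop("log evidences must be finite")
  n <- nrow(evidence)
  K <- ncol(evidence)
  models <- colnames(evidence)
  if (is.null(models)) models <- paste0("model", seq_len(K))
  lev <- evidence - apply(evidence, 1, max)  # row shift: invariant
  alpha <- rep(alpha0, K)
  g <- matrix(1 / K, n, K)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    logu <- sweep(lev, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    logu <- logu - apply(logu, 1, max)
    g <- exp(logu) / rowSums(exp(logu))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  ef <- alpha / sum(alpha)
  xp <- dirichlet_exceedance(alpha, n_samples, seed)
  # free energies: random-effects model vs fixed equal frequencies
  lnC <- function(a) lgamma(sum(a)) - sum(lgamma(a))
  g_safe <- pmax(g, 1e-300)
  f_rfx <- sum(g * lev) + lnC(rep(alpha0, K)) - lnC(alpha) -
    sum(g * log(g_safe))
  f_null <- sum(apply(lev, 1, function(r) log(mean(exp(r - max(r)))) + max(r)))
  bor <- 1 / (1 + exp(f_rfx - f_null))
  pxp <- xp * (1 - bor) + bor / K
  structure(
    list(alpha = stats::setNames(alpha, models),
         expected_freq = stats::setNames(ef, models),
         xp = stats::setNames(xp, models),
         bor = bor,
         pxp = stats::setNames(pxp, models),
         assignments = g,
         free_energy = c(rfx = f_rfx, null = f_null),
         converged = converged,
         n_subjects = n),
    class = "bms_result"
  )
}

# P(r_k > r_j for all j != k) under Dirichlet(alpha), by seeded Monte Carlo.
dirichlet_exceedance <- function(alpha, n_samples, seed) {
  K <- length(alpha)
  with_seed(as.integer(seed), {
    counts <- integer(K)
    chunk <- 250000L
    left <- as.integer(n_samples)
    while (left > 0) {
      m <- min(chunk, left)
      draws <- matrix(stats::rgamma(m * K, shape = rep(alpha, each = m)),
                      nrow = m)
      win <- max.col(draws, ties.method = "random")
      counts <- counts + tabulate(win, K)
      left <- left - m
    }
    counts / as.integer(n_samples)
  })
}

# Exact two-model exceedance via the Beta CDF; used as an independent
# cross-check of the Monte Carlo routine.
beta_exceedance <- function(alpha) {
  stopifnot(length(alpha) == 2)
  x1 <- 1 - stats::pbeta(0.5, alpha[1], alpha[2])
  c(x1, 1 - x1)
}

#' @export
print.bms_result <- function(x, digits = 3, ...) {
  cat(sprintf("Random-effects BMS over %d subjects, %d models\n",
              x$n_subjects, length(x$alpha)))
  tab <- rbind(`expected freq` = x$expected_freq,
               `exceedance p` = x$xp,
               `protected xp` = x$pxp)
  print(round(tab, digits))
  cat(sprintf("Bayesian omnibus risk: %.4g%s\n", x$bor,
              if (!x$converged) " (variational loop not converged)" else ""))
  invisible(x)
}

#' Compare the Bayesian-learner and block-constant models across a cohort
#'
#' Fits both models to every subject's concatenated session, separately per
#' target modality, and runs random-effects BMS on the resulting log
#' evidences — the group-level test of whether behavior reflects
#' trial-by-trial learning of cue predictability or block-constant
#' expectations.
#'
#' @param cohort data frame of trials for several subjects (column
#'   `subject_id` distinguishes them) in the schema accepted by
#'   [fit_weighting()].
#' @param modalities which target modalities to analyze.
#' @param evidence_method,min_condition_n passed to the fitting functions.
#' @param seed,n_samples passed to [rfx_bms()].
#' @return A list per modality, each with elements `bms` (a `bms_result`
#'   with models `bayesian` and `constant`), `evidence` (the subject-by-
#'   model log-evidence matrix) and `fits` (per-subject fit pairs). Subjects
#'   whose fits are flagged unusable in either model are dropped with a
#'   warning (both models are always fitted on identical kept-trial sets).
#' @export
compare_learning_models <- function(cohort,
                                    modalities = c("visual", "tactile"),
                                    evidence_method = c("bic", "laplace"),
                                    min_condition_n = 3,
                                    seed = 1, n_samples = 1e6) {
  evidence_method <- match.arg(evidence_method)
  cohort <- as.data.frame(cohort)
  if (is.null(cohort$subject_id)) stop("cohort needs a subject_id column")
  out <- list()
  for (m in modalities) {
    subjects <- unique(cohort$subject_id)
    fits <- lapply(subjects, function(s) {
      d <- cohort[cohort$subject_id == s, , drop = FALSE]
      list(
        bayesian = fit_bayesian_concatenated(
          d, m, evidence_method = evidence_method,
          min_condition_n = min_condition_n),
        constant = fit_constant_model(
          d, m, evidence_method = evidence_method,
          min_condition_n = min_condition_n)
      )
    })
    names(fits) <- as.character(subjects)
    ev <- t(vapply(fits, function(f)
      c(bayesian = f$bayesian$log_evidence,
        constant = f$constant$log_evidence), numeric(2)))
    usable <- apply(is.finite(ev), 1, all)
    if (!all(usable))
      warning(sum(!usable), " subject(s) dropped from BMS (", m,
              "): unusable fits")
    if (sum(usable) < 2)
      stop("fewer than 2 usable subjects for BMS (", m, ")")
    out[[m]] <- list(
      bms = rfx_bms(ev[usable, , drop = FALSE], seed = seed,
                    n_samples = n_samples),
      evidence = ev,
      fits = fits
    )
  }
  out
}
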