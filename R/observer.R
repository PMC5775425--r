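#' Beta-Bernoulli belief over cue validity
#'
#' The ideal observer tracks, separately for each target modality, a Beta
#' posterior over the probability that the spatial cue is valid. With a
#' uniform Beta(1, 1) prior and counts of valid (`n_valid`) and invalid
#' (`n_invalid`) outcomes, the posterior is Beta(1 + n_valid, 1 + n_invalid)
#' and its mean — the observer's current estimate of cue validity — is
#' (n_valid + 1) / (n_valid + n_invalid + 2).
#'
#' @param n_valid,n_invalid observed counts of valid and invalid trials of
#'   the belief's modality (non-negative).
#' @return The posterior mean probability of a valid cue.
#' @examples
#' posterior_mean(0, 0)    # 0.5 (uniform prior)
#' posterior_mean(36, 4)   # 37/42, after a full 90% block of 40 trials
#' @export
posterior_mean <- function(n_valid, n_invalid) {
  stopifnot(all(n_valid >= 0), all(n_invalid >= 0))
  (n_valid + 1) / (n_valid + n_invalid + 2)
}

#' Run the ideal observer over one block of trials
#'
#' Both modality-specific beliefs start from the uniform prior at the
#' beginning of the block. For each trial the function records the two
#' posterior means *before* observing that trial's outcome (the prediction
#' carried into the trial comes from trials 1..t-1); afterwards the belief
#' of the trial's own modality is updated with its validity. The other
#' modality's belief is untouched, so the two trajectories depend only on
#' the trial sequence, never on the weighting or response parameters. All
#' presented trials update the beliefs, including trials later excluded
#' from the behavioral analysis: the cue-target contingency is observed
#' regardless of response quality.
#'
#' @param trials data frame of one block's trials in presentation order,
#'   with columns `modality` ("visual"/"tactile") and `validity`
#'   ("valid"/"invalid").
#' @return The input data frame with columns `p_vis_prior` and `p_tac_prior`
#'   appended: the observer's pre-outcome validity estimates for visual and
#'   tactile targets at each trial.
#' @examples
#' tr <- data.frame(modality = "visual",
#'                  validity = c("valid", "valid", "invalid"))
#' run_observer(tr)$p_vis_prior  # 0.5, 2/3, 3/4
#' @export
run_observer <- function(trials) {
  trials <- as.data.frame(trials)
  n <- nrow(trials)
  p_vis <- p_tac <- numeric(n)
  if (n == 0) {
    trials$p_vis_prior <- numeric(0)
    trials$p_tac_prior <- numeric(0)
    return(trials)
  }
  stopifnot(all(trials$modality %in% c("visual", "tactile")),
            all(trials$validity %in% c("valid", "invalid")))
  cnt <- c(vis_valid = 0, vis_invalid = 0, tac_valid = 0, tac_invalid = 0)
  for (t in seq_len(n)) {
    p_vis[t] <- posterior_mean(cnt["vis_valid"], cnt["vis_invalid"])
    p_tac[t] <- posterior_mean(cnt["tac_valid"], cnt["tac_invalid"])
    key <- paste0(substr(trials$modality[t], 1, 3), "_", trials$validity[t])
    cnt[key] <- cnt[key] + 1
  }
  trials$p_vis_prior <- p_vis
  trials$p_tac_prior <- p_tac
  trials
}

#' Ideal-observer trajectories for a full session
#'
#' Applies [run_observer()] block by block (beliefs reset to the uniform
#' prior at every block boundary) while preserving the original row order.
#'
#' @param trials data frame with columns `block`, `modality`, `validity`,
#'   ordered by presentation within each block.
#' @return `trials` with `p_vis_prior` and `p_tac_prior` columns appended.
#' @export
observer_trajectories <- function(trials) {
  trials <- as.data.frame(trials)
  if (nrow(trials) == 0) return(run_observer(trials))
  stopifnot(!is.null(trials$block))
  pieces <- lapply(split(seq_len(nrow(trials)), trials$block), function(idx) {
    out <- run_observer(trials[idx, , drop = FALSE])
    out$.row <- idx
    out
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$.row), ]
  out$.row <- NULL
  rownames(out) <- NULL
  out
}

#' Weighted integration of the two modality-specific predictabilities
#'
#' The combined expectation for the current trial is a linear mixture of
#' the validity estimate of the target's own modality (`p_own`) and that of
#' the other modality (`p_other`): `w * p_own + (1 - w) * p_other`. A weight
#' of 0.5 is full averaging of the two probabilistic contexts (supramodal
#' processing); a weight of 1 is fully separate, modality-specific
#' processing; weights below 0.5 weigh the other modality more.
#'
#' @param p_own,p_other probabilities in \[0, 1\].
#' @param w weighting factor in \[0, 1\].
#' @return The integrated probability `w * p_own + (1 - w) * p_other`.
#' @examples
#' integrate_expectancy(0.9, 0.3, w = 0.5)  # 0.6, averaging
#' integrate_expectancy(0.9, 0.3, w = 1)    # 0.9, separate processing
#' @export
integrate_expectancy <- function(p_own, p_other, w) {
  if (any(w < 0 | w > 1)) stop("w must lie in [0, 1]")
  stopifnot(all(p_own >= 0 & p_own <= 1), all(p_other >= 0 & p_other <= 1))
  w * p_own + (1 - w) * p_other
}

# Per-trial (p_own, p_other) for the trial's own modality, from trajectory
# columns p_vis_prior/p_tac_prior.
own_other <- function(traj) {
  vis <- traj$modality == "visual"
  list(
    p_own = ifelse(vis, traj$p_vis_prior, traj$p_tac_prior),
    p_other = ifelse(vis, traj$p_tac_prior, traj$p_vis_prior)
  )
}
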