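#' Apply trial-exclusion rules and convert RT to response speed
#'
#' Two-stage screening of one subject's trials. Stage 1 drops incorrect
#' responses, misses (no response / missing RT) and anticipations
#' (RT < 100 ms; an RT of exactly 100 ms survives). Stage 2 computes the
#' mean and standard deviation of RT over the stage-1 survivors — per
#' subject, across the whole session — and drops trials deviating more than
#' 2 SD from that mean, in a single pass without re-trimming. Kept trials
#' get response speed RS = 1/RT in 1/s (RT converted to seconds first, so
#' typical values are around 2-2.5 1/s).
#'
#' @param records data frame of one subject's trials with columns `rt_ms`
#'   (NA for misses), `response` (`"proximal"`, `"distal"` or `"none"`) and
#'   `correct` (logical; ignored for misses).
#' @param sd_criterion multiple of the SD beyond which a trial is an
#'   outlier (default 2).
#' @return The input with two columns appended: `exclusion_reason`, one of
#'   `"kept"`, `"incorrect"`, `"miss"`, `"anticipation"`, `"outlier"`; and
#'   `rs` (1/s), present only for kept rows (NA otherwise).
#' @examples
#' d <- data.frame(rt_ms = c(400, 90, NA), response = c("distal", "distal", "none"),
#'                 correct = c(TRUE, TRUE, NA))
#' filter_trials(d)$exclusion_reason
#' @export
filter_trials <- function(records, sd_criterion = 2) {
  records <- as.data.frame(records)
  n <- nrow(records)
  if (n == 0) {
    records$exclusion_reason <- character(0)
    records$rs <- numeric(0)
    return(records)
  }
  if (!is.null(records$subject_id) &&
      length(unique(records$subject_id)) > 1)
    stop("filter_trials() expects trials of a single subject")
  miss <- is.na(records$rt_ms) | records$response == "none"
  incorrect <- !miss & !as.logical(records$correct)
  anticipation <- !miss & !incorrect & records$rt_ms < 100
  reason <- rep("kept", n)
  reason[incorrect] <- "incorrect"
  reason[anticipation] <- "anticipation"
  reason[miss] <- "miss"
  surv <- reason == "kept"
  if (any(surv)) {
    m <- mean(records$rt_ms[surv])
    s <- stats::sd(records$rt_ms[surv])
    if (is.na(s)) s <- 0  # single survivor
    outlier <- surv & abs(records$rt_ms - m) > sd_criterion * s
    reason[outlier] <- "outlier"
  }
  records$exclusion_reason <- reason
  records$rs <- ifelse(reason == "kept", 1000 / records$rt_ms, NA_real_)
  if (!any(reason == "kept"))
    warning("all trials excluded for this subject")
  records
}

#' Behavioral descriptives for one subject
#'
#' Percentage of correct responses — counting misses, anticipations and
#' RT outliers as errors, in line with the exclusion rules — and the mean
#' RT over kept trials, overall and split by target modality.
#'
#' @param records data frame as accepted by [filter_trials()]; the
#'   exclusion labels are recomputed internally.
#' @return A list with `pct_correct`, `mean_rt_ms` (NA with a `degenerate`
#'   flag when no trial is kept) and `per_modality`, a data frame with the
#'   same two summaries per modality.
#' @export
accuracy_summary <- function(records) {
  f <- filter_trials(records)
  summarize <- function(d) {
    kept <- d$exclusion_reason == "kept"
    list(pct_correct = 100 * mean(kept),
         mean_rt_ms = if (any(kept)) mean(d$rt_ms[kept]) else NA_real_)
  }
  overall <- summarize(f)
  per_mod <- NULL
  if (!is.null(f$modality)) {
    per_mod <- do.call(rbind, lapply(split(f, f$modality), function(d) {
      s <- summarize(d)
      data.frame(modality = d$modality[1], pct_correct = s$pct_correct,
                 mean_rt_ms = s$mean_rt_ms)
    }))
    rownames(per_mod) <- NULL
  }
  list(pct_correct = overall$pct_correct,
       mean_rt_ms = overall$mean_rt_ms,
       degenerate = !any(f$exclusion_reason == "kept"),
       per_modality = per_mod)
}
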