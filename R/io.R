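trial_schema_mandatory <- c("subject_id", "block", "trial_index", "modality",
                            "validity", "rt_ms", "response", "correct")

#' Read a trial table from CSV
#'
#' Reads the standard behavioral trial schema. Extra columns are tolerated
#' and carried through; rows with out-of-vocabulary `modality`/`validity`
#' or a negative RT are collected into a rejects report (attribute
#' `"rejects"`) rather than silently dropped. An empty `rt_ms` together
#' with `response == "none"` is a miss.
#'
#' @param path CSV file; header must include `subject_id`, `block`,
#'   `trial_index`, `modality`, `validity`, `rt_ms`, `response`, `correct`.
#' @return A data frame of typed trial records, attribute `"rejects"`
#'   holding the malformed rows (with a `reject_reason` column).
#' @export
read_trials_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_schema_mandatory, names(raw))
  if (length(missing))
    stop("trial CSV is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  raw$rt_ms <- suppressWarnings(as.numeric(raw$rt_ms))
  raw$correct <- as.logical(raw$correct)
  bad_modality <- !raw$modality %in% c("visual", "tactile")
  bad_validity <- !raw$validity %in% c("valid", "invalid")
  bad_rt <- !is.na(raw$rt_ms) & raw$rt_ms < 0
  bad <- bad_modality | bad_validity | bad_rt
  rejects <- raw[bad, , drop = FALSE]
  if (nrow(rejects)) {
    rejects$reject_reason <- ifelse(bad_modality[bad], "modality",
                                    ifelse(bad_validity[bad], "validity",
                                           "negative_rt"))
  }
  out <- raw[!bad, , drop = FALSE]
  miss <- is.na(out$rt_ms)
  out$response[miss] <- "none"
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

#' Write a trial table to CSV
#'
#' @param trials data frame of trial records.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Tidy table of weighting estimates with block-level factors
#'
#' Assembles the per-(subject, block, modality) weighting estimates into
#' the flat table used as the dependent variable in external group models
#' (e.g. linear mixed models on w): one row per unit with the estimate and
#' the block covariates from [block_factors()], all recomputed from the
#' design rather than hand-entered. Units without a usable fit get an NA
#' estimate and a warning.
#'
#' @param fits either a list of `weight_fit` objects from per-block
#'   [fit_weighting()] calls, or a data frame with columns `subject`,
#'   `block`, `modality`, `w_hat` (e.g. the `units` element of a
#'   [recovery_experiment()] report).
#' @param design the `experiment_design` the fits refer to.
#' @return A data frame with columns `subject`, `experiment`, `block`,
#'   `modality`, `w_hat`, `predictability_distance`, `signed_divergence`,
#'   `abs_divergence`.
#' @export
export_w_table <- function(fits, design) {
  validate_design(design)
  if (is.data.frame(fits)) {
    tab <- fits[, c("subject", "block", "modality", "w_hat")]
  } else {
    tab <- do.call(rbind, lapply(fits, function(f) {
      u <- f$fitting_unit
      data.frame(subject = as.character(u$subject),
                 block = u$blocks[1], modality = u$modality,
                 w_hat = if (is.null(f$w_hat)) NA_real_ else f$w_hat)
    }))
  }
  subjects <- unique(tab$subject)
  grid <- expand.grid(subject = subjects, block = design$blocks$block,
                      modality = c("visual", "tactile"),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out <- merge(grid, tab, by = c("subject", "block", "modality"),
               all.x = TRUE, sort = FALSE)
  if (anyNA(out$w_hat))
    warning(sum(is.na(out$w_hat)), " unit(s) lack a usable w estimate")
  bf <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
    b <- design$blocks[design$blocks$block == out$block[i], ]
    as.data.frame(block_factors(b, out$modality[i]))
  }))
  out <- cbind(experiment = design$experiment_id, out, bf)
  out <- out[order(out$subject, out$block, out$modality),
             c("subject", "experiment", "block", "modality", "w_hat",
               "predictability_distance", "signed_divergence",
               "abs_divergence")]
  rownames(out) <- NULL
  out
}

#' Serialize fit results as JSON
#'
#' @param fits list of `cue_fit` objects.
#' @param path file to write; `NULL` returns the JSON string.
#' @return The path (or JSON string), invisibly.
#' @export
fits_to_json <- function(fits, path = NULL) {
  x <- lapply(fits, function(f) {
    list(fitting_unit = f$fitting_unit,
         model = f$model,
         w_hat = f$w_hat,
         p_const = as.list(f$p_const),
         params = f$params,
         log_likelihood = f$log_likelihood,
         log_evidence = f$log_evidence,
         n_trials_used = f$n_trials_used,
         flags = as.list(f$flags))
  })
  if (is.null(path)) return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
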