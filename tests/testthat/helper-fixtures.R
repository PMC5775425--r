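# Small builders shared across test files; everything generated in code.

# One-modality trial list in presentation order from a validity string
# like "vvi" (valid, valid, invalid).
vseq <- function(code, modality = "visual", block = 1) {
  ch <- strsplit(code, "")[[1]]
  v <- ifelse(ch == "v", "valid", "invalid")
  data.frame(block = rep(block, length(v)), trial_index = seq_along(v),
             modality = rep(modality, length(v)), validity = v)
}

# A clean single-subject trial table with RS already attached (no
# exclusions), for direct fitting tests.
rs_trials <- function(validity, rs, modality = "visual", block = 1) {
  data.frame(block = block, trial_index = seq_along(validity),
             modality = modality, validity = validity, rs = rs,
             exclusion_reason = "kept")
}

# Simulated, filtered single subject under the Bayesian generator.
sim_subject_filtered <- function(design, w, sigma, seed,
                                 params = default_truth_params()) {
  params$sigma <- sigma
  filter_trials(simulate_subject(design, list(w = w, params = params),
                                 seed = seed))
}
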