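# Small fixture cohorts built in code.

# The two-patient hand-checkable cohort: one recovering patient whose
# anchors imply a positive slope, one perfectly flat patient.
hand_cohort <- function() {
  mmse_cohort(data.frame(
    patient_id = rep(c("A", "B"), each = 4),
    day_since_onset = c(5, 12, 19, 26, 6, 13, 20, 27),
    mmse = c(20, 24, 26, 27, 15, 15, 15, 15)))
}

# Zero-noise logarithmic cohort at the default parameter distributions.
zero_noise_cohort <- function(n = 43, seed = 101, decline_fraction = 0.1) {
  generate_cohort(cohort_config(n_patients = n, noise_sd = 0,
                                decline_fraction = decline_fraction,
                                seed = seed))
}
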