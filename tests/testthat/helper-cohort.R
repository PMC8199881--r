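# shared fixtures, all built in code

# a minimal cohort-shaped object carrying only truth labels, for survival
# simulation tests that do not need observations
fake_truth_cohort <- function(subpop) {
  structure(list(truth = tibble::tibble(
    patient_id = sprintf("pt%03d", seq_along(subpop)),
    subpop = subpop)), class = "qsp_cohort")
}

# neutral covariates (no ASCT, ratio 1) for n patients
neutral_covariates <- function(n, baseline_mtv = 100) {
  tibble::tibble(patient_id = sprintf("pt%03d", seq_len(n)),
                 ASCT = 0, cd4cd8_day7 = 1, baseline_mtv = baseline_mtv)
}

# noise-free single-subpopulation parameter set (mixture degenerate at
# reference) used in round-trip tests
novar <- function() qsp_variability(omega2_Vmax1 = 0, omega2_Vmax5_2 = 0,
                                    sigma2 = c(TN = 0, TCM = 0, TEM = 0,
                                               TEFF = 0, CD19 = 0))
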