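# hand-built 4-patient cohort exercising the exclusion rules:
#   A: baseline-only; B: ordinary; C: first + second line; D: baseline CD4 520
tiny_cohort <- function() {
  visits <- data.frame(
    patient_id = c("A",
                   "B", "B", "B",
                   "C", "C", "C", "C", "C",
                   "D", "D", "D"),
    time_on_art = c(0,
                    0, 0.5, 1,
                    0, 0.5, 1, 1.5, 2,
                    0, 0.5, 1),
    cd4 = c(80,
            120, 180, NA,
            90, 140, 200, 230, 260,
            520, 540, 600),
    viral_load = c(1e5,
                   8e4, NA, 500,
                   1.2e5, 300, 4000, 200, 100,
                   5e4, 100, 100),
    first_line = c(TRUE,
                   TRUE, TRUE, TRUE,
                   TRUE, TRUE, TRUE, FALSE, FALSE,
                   TRUE, TRUE, TRUE))
  baselines <- data.frame(
    patient_id = c("A", "B", "C", "D"),
    sex = c(1, 0, 1, NA),
    age = c(35, 42, 29, 51),
    baseline_cd4 = c(80, 120, 90, 520),
    baseline_log_vl = c(5, 4.9, 5.1, 4.7),
    in_care = c(0, 1, 1, 1))
  cohort_table(visits, baselines)
}

# small complete-data synthetic cohort, ready for fitting
quick_cohort <- function(n = 40, seed = 1, ...) {
  sim <- simulate_cohort(synthetic_config(n_patients = n, ...), seed = seed)
  standardize_covariates(apply_exclusions(sim$cohort, "slope"))
}

quick_control <- function(seed = 1, ...) {
  mcmc_control(adapt = 200, burn_in = 300, n_iter = 500, seed = seed, ...)
}
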