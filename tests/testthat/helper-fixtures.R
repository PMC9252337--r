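# Small cohorts and observation sets built in code for the unit tests.

tiny_cohort <- function(n_subjects = 40, seed = 7, ...) {
  simulate_cohort(cohort_config(n_subjects = n_subjects, seed = seed, ...))
}

# standardized observations from a small simulated cohort (no missingness)
tiny_observations <- function(n_subjects = 40, seed = 7, standardize = TRUE, ...) {
  cohort <- tiny_cohort(n_subjects, seed, ...)
  obs <- build_observations(cohort)
  if (!standardize) return(obs)
  # small fixtures can have constant SNP columns; the warning is expected
  std <- suppressWarnings(fit_standardizer(obs))
  apply_standardizer(obs, std)
}

# hand-built two-subject cohort with controllable scale sequences
manual_cohort <- function(anxiety1 = c(5, NA, NA, 7), anxiety2 = c(NA, 3, NA)) {
  n1 <- length(anxiety1); n2 <- length(anxiety2)
  visits <- tibble::tibble(
    subject_id = rep(1:2, c(n1, n2)),
    visit = c(seq_len(n1), seq_len(n2)),
    time_years = c(seq_len(n1) - 1, seq_len(n2) - 1),
    anxiety = c(anxiety1, anxiety2),
    depression = 5, rem = 4, updrs3 = 20,
    icd = rep(c(0L, 1L), c(n1, n2)),
    on_levodopa = 0L, on_dopamine_agonist = 0L, on_other = 0L,
    da_daily_dose = 0
  )
  static <- tibble::tibble(subject_id = 1:2, age = c(60, 55), sex = c(1L, 0L),
                           snp_1 = c(0L, 2L))
  medication <- tibble::tibble(subject_id = integer(), drug_class = character(),
                               start_years = numeric(), end_years = numeric(),
                               daily_dose_ledd = numeric())
  icdnext:::new_icd_cohort(visits, static, medication)
}
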