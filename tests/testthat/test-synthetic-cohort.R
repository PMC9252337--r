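test_that("identical config and seed give identical cohorts", {
  cfg <- cohort_config(n_subjects = 30, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$visits, b$visits)
  expect_identical(a$static, b$static)
  expect_identical(a$medication, b$medication)
  expect_identical(a$ground_truth$probabilities, b$ground_truth$probabilities)
})

test_that("cohorts satisfy the structural invariants", {
  cohort <- tiny_cohort(50, seed = 3)
  by_subj <- split(cohort$visits, cohort$visits$subject_id)
  expect_true(all(vapply(by_subj, nrow, integer(1)) >= 2L))
  expect_true(all(vapply(by_subj, function(v) v$time_years[1] == 0, logical(1))))
  expect_true(all(vapply(by_subj, function(v) all(diff(v$time_years) > 0), logical(1))))
  # dose implies the flag
  expect_true(all(cohort$visits$on_dopamine_agonist[cohort$visits$da_daily_dose > 0] == 1L))
  # ground truth probabilities live in [0, 1] and coefficients echo the config
  expect_true(all(dplyr::between(cohort$ground_truth$probabilities$p_true, 0, 1)))
  expect_identical(cohort$ground_truth$coefficients,
                   cohort$meta$config$effect_sizes)
})

test_that("drug-naive dialect has zero medication exposure at baseline", {
  cohort <- tiny_cohort(60, seed = 11)
  base <- dplyr::filter(cohort$visits, visit == 1L)
  expect_true(all(base$on_levodopa == 0L))
  expect_true(all(base$on_dopamine_agonist == 0L))
  expect_true(all(base$da_daily_dose == 0))
  for (sid in cohort$static$subject_id[1:5]) {
    med <- dplyr::filter(cohort$medication, subject_id == sid)
    expect_equal(unname(derive_da_features(med, 0)), c(0, 0, 0, 0))
  }
})

test_that("with only an intercept the observation-level prevalence matches the closed form", {
  # Monte-Carlo check of the Bernoulli hazard over > 50,000 observations
  fx <- default_effect_sizes(intercept = qlogis(0.14), prev = 0, da_duration = 0,
                             da_dose = 0, age = 0, sex = 0, depression = 0,
                             rem = 0, anxiety = 0, motor = 0, snp = 0)
  cohort <- simulate_cohort(cohort_config(n_subjects = 8500, seed = 13,
                                          effect_sizes = fx))
  obs_icd <- dplyr::filter(cohort$visits, visit > 1L)$icd
  expect_gt(length(obs_icd), 50000)
  se <- sqrt(0.14 * 0.86 / length(obs_icd))
  expect_lt(abs(mean(obs_icd) - 0.14), 4 * se)
  expect_true(all(dplyr::near(cohort$ground_truth$probabilities$p_true, 0.14)))
})

test_that("a dominant persistence effect makes ICD status absorbing", {
  fx <- default_effect_sizes(intercept = -8, prev = 20, da_duration = 0,
                             da_dose = 0, age = 0, sex = 0, depression = 0,
                             rem = 0, anxiety = 0, motor = 0, snp = 0)
  cohort <- simulate_cohort(cohort_config(n_subjects = 300, seed = 5,
                                          effect_sizes = fx))
  recovered <- cohort$visits |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(drop = any(diff(icd) < 0), .groups = "drop")
  expect_false(any(recovered$drop))
})

test_that("genotype dosages follow Binomial(2, MAF)", {
  g1 <- simulate_genotypes(20000, 5, c(0.5, 0.5), seed = 2)
  expect_true(all(g1 %in% 0:2))
  expect_true(all(abs(colMeans(g1) - 1) < 0.03))
  g2 <- simulate_genotypes(200000, 1, c(0.05, 0.05), seed = 3)
  expect_lt(abs(mean(g2 == 2) - 0.0025), 5e-4)
  g3 <- simulate_genotypes(10, 31, c(0.05, 0.5), seed = 4)
  expect_equal(ncol(g3), 31)
  expect_identical(g3, simulate_genotypes(10, 31, c(0.05, 0.5), seed = 4))
})

test_that("missingness injection respects rates and exclusions", {
  cohort <- tiny_cohort(40, seed = 9)
  same <- inject_missingness(cohort, missing_rate = c(anxiety = 0), seed = 1)
  expect_identical(same$visits, cohort$visits)

  big <- tiny_cohort(300, seed = 10)
  out <- inject_missingness(big, missing_rate = c(anxiety = 0.1), seed = 2)
  n_cells <- nrow(big$visits)
  n_missing <- sum(is.na(out$visits$anxiety))
  sigma <- sqrt(n_cells * 0.1 * 0.9)
  expect_lt(abs(n_missing - 0.1 * n_cells), 3 * sigma)
  # ICD and treatment columns are never masked
  expect_false(anyNA(out$visits$icd))
  expect_false(anyNA(out$visits$on_dopamine_agonist))
  # at least one baseline value retained per masked scale
  expect_gt(sum(!is.na(dplyr::filter(out$visits, visit == 1L)$anxiety)), 0)
  expect_identical(out$visits,
                   inject_missingness(big, c(anxiety = 0.1), seed = 2)$visits)
})

test_that("malformed configurations are rejected", {
  expect_error(cohort_config(n_subjects = 0), class = "icdnext_config_error")
  expect_error(cohort_config(maf_range = c(0, 0.5)), class = "icdnext_config_error")
  expect_error(cohort_config(maf_range = c(0.2, 0.7)), class = "icdnext_config_error")
  expect_error(cohort_config(missing_rate = c(anxiety = 1)), class = "icdnext_config_error")
  expect_error(simulate_genotypes(10, 3, c(0.6, 0.7)), class = "icdnext_config_error")
  cohort <- tiny_cohort(10)
  expect_error(inject_missingness(cohort, c(anxiety = 1.2)),
               class = "icdnext_config_error")
})
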