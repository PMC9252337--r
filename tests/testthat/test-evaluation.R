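test_that("the outer split follows the 80/20 floor convention at subject level", {
  cohort <- tiny_cohort(95, seed = 121)
  plan <- make_cv_plan(cohort, seed = 1)
  expect_length(plan$outer_train, 76)   # floor(0.8 * 95)
  expect_length(plan$outer_test, 19)
  expect_length(intersect(plan$outer_train, plan$outer_test), 0)
  # inner folds partition the outer-training subjects
  all_inner <- sort(unlist(plan$inner_folds))
  expect_equal(all_inner, sort(plan$outer_train))
  expect_equal(anyDuplicated(all_inner), 0L)
  # determinism
  plan2 <- make_cv_plan(cohort, seed = 1)
  expect_identical(plan, plan2)
})

test_that("a 380-subject cohort splits 304/76", {
  cohort <- tiny_cohort(380, seed = 122)
  plan <- make_cv_plan(cohort, seed = 3)
  expect_length(plan$outer_train, 304)
  expect_length(plan$outer_test, 76)
})

test_that("too few subjects for the inner loop is a planning error", {
  cohort <- tiny_cohort(8, seed = 123)
  expect_error(make_cv_plan(cohort), class = "icdnext_config_error")
})

test_that("preprocessing statistics never touch test subjects", {
  cohort <- inject_missingness(tiny_cohort(60, seed = 131), seed = 4)
  plan <- make_cv_plan(cohort, seed = 2)
  prep <- preprocess_cohorts(cohort, plan)
  expect_setequal(attr(prep$baseline_means, "fingerprint"), plan$outer_train)
  expect_setequal(prep$standardizer$fingerprint, plan$outer_train)
  expect_length(intersect(prep$standardizer$fingerprint, plan$outer_test), 0)
  # pipeline totality: every schema feature is populated
  expect_false(anyNA(do.call(rbind, prep$outer_test$history)))
  expect_false(anyNA(icdnext:::static_matrix(prep$outer_test)))
})

test_that("the experiment report keeps the books straight", {
  tr <- tiny_cohort(60, seed = 141)
  rp <- simulate_cohort(cohort_config(n_subjects = 50, seed = 142,
                                      dialect = "treated_baseline"))
  res <- run_experiment(
    tr, rp,
    specs = list(spec_trivial(),
                 spec_logistic(reduction_scheme("last_only"),
                               penalty = "l2", lambda = c(0.01, 1))),
    seed = 7
  )
  # one row per model per cohort
  expect_equal(nrow(res$metrics), 2 * 2)
  expect_setequal(unique(res$metrics$cohort), c("train_test", "replication"))
  expect_true("trivial" %in% res$metrics$model)
  # trivial identity holds in every reported cohort
  triv <- dplyr::filter(res$metrics, model == "trivial")
  expect_equal(triv$roc_auc, triv$balanced_accuracy)
  # comparisons: every non-trivial model against the baseline, both cohorts
  expect_equal(nrow(res$comparisons), 2)
  expect_equal(res$comparisons$p_adjusted,
               pmin(1, nrow(res$comparisons) * res$comparisons$p_value))
  # tidy/glance/autoplot surfaces
  expect_identical(tidy(res), res$metrics)
  expect_equal(glance(res)$n_models, 2)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(res, "pr"), "ggplot")
  expect_s3_class(plot_auc_comparison(res), "ggplot")
})

test_that("experiments are reproducible from their seed", {
  tr <- tiny_cohort(50, seed = 151)
  specs <- list(spec_trivial(),
                spec_logistic(reduction_scheme("uniform"), penalty = "l2",
                              lambda = 0.01))
  r1 <- run_experiment(tr, NULL, specs, seed = 5)
  r2 <- run_experiment(tr, NULL, specs, seed = 5)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$comparisons, r2$comparisons)
})

test_that("clinical-only ablation drops the genetic features", {
  tr <- tiny_cohort(50, seed = 161)
  res <- run_experiment(tr, NULL,
                        specs = list(spec_trivial(),
                                     spec_logistic(reduction_scheme("last_only"),
                                                   penalty = "l2", lambda = 0.01)),
                        seed = 3, feature_set = "clinical_only")
  fit <- res$models[["logistic_last_only"]]
  expect_false(any(grepl("^snp_", names(fit$coefficients))))
})

test_that("repeating the outer split stacks one metric table per repeat", {
  tr <- tiny_cohort(45, seed = 171)
  out <- repeat_experiment(tr, NULL,
                           specs = list(spec_trivial(),
                                        spec_logistic(reduction_scheme("last_only"),
                                                      penalty = "l2", lambda = 0.01)),
                           seed = 1, R = 2)
  expect_equal(nrow(out), 2 * 2)
  expect_setequal(unique(out$repeat_id), 1:2)
})

test_that("cohorts and reports round-trip through CSV", {
  dir <- withr::local_tempdir()
  cohort <- tiny_cohort(12, seed = 181)
  write_cohort(cohort, file.path(dir, "cohort"))
  back <- read_cohort(file.path(dir, "cohort"))
  expect_equal(as.data.frame(back$visits), as.data.frame(cohort$visits))
  expect_equal(as.data.frame(back$static), as.data.frame(cohort$static))
  expect_equal(back$ground_truth$coefficients$prev,
               cohort$ground_truth$coefficients$prev)
  # simulate twice with the same seed: identical files on disk
  write_cohort(simulate_cohort(cohort_config(n_subjects = 12, seed = 181)),
               file.path(dir, "again"))
  expect_identical(readLines(file.path(dir, "cohort", "visits.csv")),
                   readLines(file.path(dir, "again", "visits.csv")))

  bigger <- tiny_cohort(40, seed = 182)
  res <- run_experiment(bigger, NULL,
                        specs = list(spec_trivial(),
                                     spec_logistic(reduction_scheme("last_only"),
                                                   penalty = "l2", lambda = 0.01)),
                        seed = 2)
  write_report(res, file.path(dir, "report"))
  for (f in c("metrics.csv", "comparisons.csv", "curves.csv", "run_manifest.json")) {
    expect_true(file.exists(file.path(dir, "report", f)))
  }
})
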