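#' Model specifications for the comparison harness
#'
#' A model spec names a model family and its hyperparameter grid. The inner
#' cross-validation loop of [run_experiment()] selects the grid point with
#' the best mean inner-fold ROC AUC; ties are broken toward the stronger
#' penalty (larger lambda), then grid order.
#'
#' @param label Display label for report rows.
#' @param reduction An [reduction_scheme()] (logistic only).
#' @param penalty Character vector of penalties to search over.
#' @param lambda Numeric vector of penalty strengths to search over.
#' @param config A [gru_config()] (GRU only).
#' @return An object of class `icd_model_spec`.
#' @name model_specs
NULL

#' @rdname model_specs
#' @export
spec_trivial <- function(label = "trivial") {
  structure(list(kind = "trivial", label = label), class = "icd_model_spec")
}

#' @rdname model_specs
#' @export
spec_logistic <- function(reduction = reduction_scheme("last_only"),
                          penalty = c("l2", "l1"), lambda = lambda_grid(),
                          label = NULL) {
  label <- label %||% paste0("logistic_", reduction$name)
  structure(list(kind = "logistic", label = label, reduction = reduction,
                 grid = expand.grid(penalty = penalty, lambda = lambda,
                                    stringsAsFactors = FALSE)),
            class = "icd_model_spec")
}

#' @rdname model_specs
#' @export
spec_gru <- function(config = gru_config(), label = "gru") {
  structure(list(kind = "gru", label = label, config = config),
            class = "icd_model_spec")
}

#' Preprocess train/test/replication cohorts with training statistics only
#'
#' Applies the full preprocessing pipeline while guaranteeing that every
#' statistic used to transform any cohort derives from the outer-training
#' subjects of the training cohort alone: forward fill per cohort, baseline
#' means from outer-train subjects, baseline-mean imputation everywhere,
#' observation building, and standardization fitted on outer-train
#' observations. The replication cohort is mapped onto the same feature
#' schema and transformed with the training parameters (cross-cohort
#' harmonization).
#'
#' When the two cohorts measure the clinical scales with different
#' instruments (different dialects), the replication cohort's scales are
#' first mapped onto the training instruments with
#' [harmonize_scales()] - a fixed affine map built from the instruments'
#' population parameters, not from any sample statistic - and only then
#' transformed with the training standardizer.
#'
#' @param train_cohort The training cohort (`icd_cohort`).
#' @param plan An [make_cv_plan()] for `train_cohort`.
#' @param replication_cohort Optional second cohort evaluated as a whole.
#' @param feature_set `"all"` or `"clinical_only"`.
#' @param harmonize Map the replication cohort's scale instruments onto the
#'   training cohort's before standardizing (default `TRUE`; requires both
#'   cohorts to carry their generating config).
#' @return List with standardized `icd_observations` for `outer_train`,
#'   `outer_test`, `replication` (or NULL), plus the fitted `standardizer`
#'   and the baseline means (both fingerprinted).
#' @export
preprocess_cohorts <- function(train_cohort, plan, replication_cohort = NULL,
                               feature_set = c("all", "clinical_only"),
                               harmonize = TRUE) {
  feature_set <- match.arg(feature_set)
  stopifnot(inherits(plan, "icd_cv_plan"))
  tr_ff <- impute_forward_fill(train_cohort)
  means <- baseline_means(tr_ff, subject_ids = plan$outer_train)
  tr_imp <- impute_baseline_mean(tr_ff, means)

  obs_all <- build_observations(tr_imp, feature_set)
  obs_train <- subset_obs(obs_all, obs_all$subject_id %in% plan$outer_train)
  obs_test <- subset_obs(obs_all, obs_all$subject_id %in% plan$outer_test)
  standardizer <- fit_standardizer(obs_train)
  out <- list(
    outer_train = apply_standardizer(obs_train, standardizer),
    outer_test = apply_standardizer(obs_test, standardizer),
    replication = NULL,
    standardizer = standardizer, baseline_means = means
  )
  if (!is.null(replication_cohort)) {
    if (isTRUE(harmonize)) {
      replication_cohort <- harmonize_scales(
        replication_cohort,
        to_specs = train_cohort$meta$config$scale_specs
      )
    }
    rep_imp <- impute_baseline_mean(impute_forward_fill(replication_cohort), means)
    rep_obs <- build_observations(rep_imp, feature_set)
    out$replication <- apply_standardizer(rep_obs, standardizer)
  }
  out
}

# inner-CV grid search + refit for one model spec on the outer-training set
fit_model_spec <- function(spec, obs_train, plan) {
  switch(spec$kind,
    trivial = fit_trivial(obs_train),
    logistic = {
      grid <- spec$grid
      if (nrow(grid) > 1L) {
        mean_auc <- vapply(seq_len(nrow(grid)), function(gi) {
          aucs <- vapply(plan$inner_folds, function(fold) {
            fit_idx <- !(obs_train$subject_id %in% fold)
            fit <- fit_logistic(subset_obs(obs_train, fit_idx), spec$reduction,
                                grid$penalty[gi], grid$lambda[gi])
            hold <- subset_obs(obs_train, !fit_idx)
            if (length(unique(hold$y)) < 2L) return(NA_real_)
            roc_auc(hold$y, predict(fit, hold))
          }, numeric(1))
          mean(aucs, na.rm = TRUE)
        }, numeric(1))
        best <- order(-round(mean_auc, 10), -grid$lambda)[1]
      } else {
        best <- 1L
      }
      fit_logistic(obs_train, spec$reduction, grid$penalty[best], grid$lambda[best])
    },
    gru = {
      # first inner fold held out for early stopping / checkpoint selection
      val_ids <- plan$inner_folds[[1]]
      fit_idx <- !(obs_train$subject_id %in% val_ids)
      train_gru(subset_obs(obs_train, fit_idx), subset_obs(obs_train, !fit_idx),
                spec$config)
    },
    abort_config(sprintf("unknown model kind '%s'.", spec$kind))
  )
}

#' Run the full model-comparison experiment
#'
#' The evaluation protocol of the package: subject-level 80/20 outer split
#' of the training cohort; per model, inner 5-fold subject-level grid search
#' on the outer-training subjects, refit on the full outer-training set,
#' evaluation on the outer-test set and on the entire replication cohort;
#' pairwise DeLong tests of every model against the trivial persistence
#' baseline with Bonferroni adjustment over all comparisons.
#'
#' @param train_cohort,replication_cohort `icd_cohort` objects (the
#'   replication cohort may be `NULL`).
#' @param specs List of model specs (see [model_specs]); a trivial spec is
#'   added automatically if absent.
#' @param seed Integer seed driving the CV plan and model training.
#' @param feature_set `"all"` or `"clinical_only"` (drops the SNP dosages).
#' @param threshold Decision threshold for the confusion metrics.
#' @param plan Optional pre-built [make_cv_plan()].
#' @return An object of class `icd_comparison`: tibbles `metrics` (one row
#'   per model per cohort), `comparisons` (DeLong vs trivial with adjusted
#'   p-values), `curves` (ROC and precision-recall points), the fitted
#'   `models`, `plan` and `scores`.
#' @export
run_experiment <- function(train_cohort, replication_cohort = NULL,
                           specs = list(spec_trivial(),
                                        spec_logistic(reduction_scheme("last_only")),
                                        spec_gru()),
                           seed = 1L, feature_set = "all", threshold = 0.5,
                           plan = NULL) {
  stopifnot(inherits(train_cohort, "icd_cohort"))
  labels <- vapply(specs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) abort_config("model spec labels must be unique.")
  if (!any(vapply(specs, `[[`, character(1), "kind") == "trivial")) {
    specs <- c(list(spec_trivial()), specs)
    labels <- c("trivial", labels)
  }
  plan <- plan %||% make_cv_plan(train_cohort, seed = seed)
  prep <- preprocess_cohorts(train_cohort, plan, replication_cohort, feature_set)

  eval_sets <- list(train_test = prep$outer_test)
  if (!is.null(prep$replication)) eval_sets$replication <- prep$replication

  models <- list()
  scores <- list()
  metrics <- list()
  curves <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    set.seed(seed + si)
    fit <- fit_model_spec(spec, prep$outer_train, plan)
    models[[spec$label]] <- fit
    for (cn in names(eval_sets)) {
      es <- eval_sets[[cn]]
      sc <- predict(fit, es)
      scores[[cn]][[spec$label]] <- sc
      metrics[[length(metrics) + 1L]] <- metric_report(es$y, sc, threshold) |>
        dplyr::mutate(model = spec$label, cohort = cn, .before = 1)
      curves[[length(curves) + 1L]] <- dplyr::bind_rows(
        roc_curve(es$y, sc) |>
          dplyr::mutate(curve = "roc", x = .data$fpr, yv = .data$tpr) |>
          dplyr::select("threshold", "curve", "x", "yv"),
        pr_curve(es$y, sc) |>
          dplyr::mutate(curve = "pr", x = .data$recall, yv = .data$precision) |>
          dplyr::select("threshold", "curve", "x", "yv")
      ) |> dplyr::mutate(model = spec$label, cohort = cn, .before = 1)
    }
  }

  non_trivial <- setdiff(names(models), "trivial")
  trivial_label <- labels[vapply(specs, `[[`, character(1), "kind") == "trivial"][1]
  non_trivial <- setdiff(names(models), trivial_label)
  comp <- list()
  for (cn in names(eval_sets)) {
    y <- eval_sets[[cn]]$y
    for (ml in non_trivial) {
      dl <- delong_test(y, scores[[cn]][[ml]], scores[[cn]][[trivial_label]])
      comp[[length(comp) + 1L]] <- dplyr::mutate(tibble::as_tibble(dl),
                                                 model = ml, baseline = trivial_label,
                                                 cohort = cn, .before = 1)
    }
  }
  comparisons <- dplyr::bind_rows(comp)
  if (nrow(comparisons)) {
    m_comp <- nrow(comparisons)
    comparisons$p_adjusted <- bonferroni(comparisons$p_value, m_comp)
    comparisons$significant <- comparisons$p_adjusted <= 0.05
    comparisons$stars <- cut(comparisons$p_adjusted,
                             breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                             labels = c("***", "**", "*", ""))
  }

  structure(list(metrics = dplyr::bind_rows(metrics),
                 comparisons = comparisons,
                 curves = dplyr::bind_rows(curves),
                 models = models, scores = scores, plan = plan,
                 feature_set = feature_set, seed = seed),
            class = "icd_comparison")
}

#' @export
print.icd_comparison <- function(x, ...) {
  cat("<icd_comparison>\n")
  m <- x$metrics |>
    dplyr::select("model", "cohort", "roc_auc", "average_precision",
                  "balanced_accuracy")
  print(as.data.frame(m), digits = 3, row.names = FALSE)
  if (nrow(x$comparisons)) {
    cat("\nDeLong vs trivial (Bonferroni-adjusted):\n")
    print(as.data.frame(x$comparisons[, c("model", "cohort", "diff", "p_adjusted", "stars")]),
          digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Tidy a model-comparison report
#'
#' @param x An `icd_comparison` object.
#' @param ... Unused.
#' @return `tidy()`: the per-model per-cohort metric tibble. `glance()`: a
#'   one-row summary (number of models, cohorts, significant comparisons).
#' @export
tidy.icd_comparison <- function(x, ...) x$metrics

#' @rdname tidy.icd_comparison
#' @export
glance.icd_comparison <- function(x, ...) {
  tibble::tibble(n_models = length(x$models),
                 n_cohorts = length(unique(x$metrics$cohort)),
                 n_comparisons = nrow(x$comparisons),
                 n_significant = sum(x$comparisons$significant %||% logical(0)),
                 seed = x$seed)
}

#' Repeat the outer split of an experiment
#'
#' Re-runs [run_experiment()] with `R` different outer splits (seeds
#' `seed, seed+1, ...`) and stacks the metric tibbles, to assess the
#' sensitivity of the reported performance to the split.
#'
#' @inheritParams run_experiment
#' @param R Number of repetitions.
#' @return Tibble of metrics with a `repeat_id` column.
#' @export
repeat_experiment <- function(train_cohort, replication_cohort = NULL,
                              specs = list(spec_trivial(),
                                           spec_logistic(reduction_scheme("last_only"))),
                              seed = 1L, R = 3, feature_set = "all") {
  purrr::map_dfr(seq_len(R), function(r) {
    rep <- run_experiment(train_cohort, replication_cohort, specs,
                          seed = seed + r - 1L, feature_set = feature_set)
    dplyr::mutate(rep$metrics, repeat_id = r, .before = 1)
  })
}
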