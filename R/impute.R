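SCALE_COLS <- c("anxiety", "depression", "rem", "updrs3")

#' Map a cohort's clinical-scale instruments onto another instrument set
#'
#' Different cohorts may assess the same construct with different
#' instruments (e.g. two anxiety scales with very different ranges). Before
#' a model trained on one cohort can score another, the scales must live on
#' a common schema. This applies, per scale, the affine map
#' `(x - mean_from) / sd_from * sd_to + mean_to` built from the instruments'
#' population parameters (the generating configs' scale specifications) -
#' fixed instrument metadata, not statistics estimated from any sample, so
#' no information leaks from the cohort being mapped.
#'
#' @param cohort An `icd_cohort` whose config records its scale parameters.
#' @param to_specs Target scale specification list (per-scale `mean`, `sd`),
#'   e.g. the training cohort's `meta$config$scale_specs`.
#' @param from_specs Source specification; defaults to the cohort's own.
#' @return The cohort with mapped scale columns (identity when source and
#'   target parameters already agree or either config is absent).
#' @export
harmonize_scales <- function(cohort, to_specs, from_specs = NULL) {
  stopifnot(inherits(cohort, "icd_cohort"))
  from_specs <- from_specs %||% cohort$meta$config$scale_specs
  if (is.null(from_specs) || is.null(to_specs)) return(cohort)
  for (s in intersect(names(from_specs), intersect(names(to_specs), SCALE_COLS))) {
    f <- from_specs[[s]]; t <- to_specs[[s]]
    if (isTRUE(all.equal(c(f$mean, f$sd), c(t$mean, t$sd)))) next
    cohort$visits[[s]] <- (cohort$visits[[s]] - f$mean) / f$sd * t$sd + t$mean
  }
  cohort$meta$config$scale_specs[names(to_specs)] <- to_specs
  cohort
}

#' Forward-fill missing clinical values within each subject
#'
#' Every missing clinical value that has an earlier non-missing value for the
#' same subject and feature is replaced by the most recent such value.
#' Baseline missing values (no earlier value) remain missing and are handled
#' by [impute_baseline_mean()]. The operation is idempotent.
#'
#' @param cohort An `icd_cohort`.
#' @return The cohort with forward-filled visit scales.
#' @seealso [impute_baseline_mean()]
#' @export
impute_forward_fill <- function(cohort) {
  stopifnot(inherits(cohort, "icd_cohort"))
  cohort$visits <- cohort$visits |>
    dplyr::arrange(.data$subject_id, .data$visit) |>
    dplyr::group_by(.data$subject_id) |>
    tidyr::fill(dplyr::all_of(SCALE_COLS), .direction = "down") |>
    dplyr::ungroup()
  cohort
}

#' Per-feature mean of training subjects' baseline visits
#'
#' @param cohort An `icd_cohort` (the training cohort or its training split).
#' @param subject_ids Optional subject subset to compute the means from;
#'   defaults to all subjects in `cohort`. Use this to restrict the means to
#'   outer-training subjects so that no test-subject value leaks into them.
#' @return Named numeric vector of baseline means, with attribute
#'   `fingerprint` recording which subjects the means were computed from.
#' @export
baseline_means <- function(cohort, subject_ids = NULL) {
  stopifnot(inherits(cohort, "icd_cohort"))
  base <- dplyr::filter(cohort$visits, .data$visit == 1L)
  if (!is.null(subject_ids)) base <- dplyr::filter(base, .data$subject_id %in% subject_ids)
  means <- vapply(SCALE_COLS, function(s) mean(base[[s]], na.rm = TRUE), numeric(1))
  bad <- names(means)[is.nan(means)]
  if (length(bad)) {
    abort_impute(paste0("feature(s) missing at every training baseline: ",
                        paste(bad, collapse = ", ")))
  }
  attr(means, "fingerprint") <- sort(unique(base$subject_id))
  means
}

#' Impute remaining baseline missing values with training baseline means
#'
#' After [impute_forward_fill()], the only possible missing clinical values
#' are at (or propagated from) a subject's first visits before any
#' observation of that feature. These are replaced by the mean baseline value
#' computed on the training set via [baseline_means()], so a test cohort
#' never influences its own imputation statistics.
#'
#' @param cohort An `icd_cohort`.
#' @param train_baseline_means Named vector from [baseline_means()].
#' @return The cohort with no missing clinical values remaining (given a
#'   prior forward fill).
#' @export
impute_baseline_mean <- function(cohort, train_baseline_means) {
  stopifnot(inherits(cohort, "icd_cohort"))
  visits <- cohort$visits
  for (s in SCALE_COLS) {
    miss <- is.na(visits[[s]])
    if (any(miss)) visits[[s]][miss] <- train_baseline_means[[s]]
  }
  cohort$visits <- visits
  cohort$meta$impute_fingerprint <- attr(train_baseline_means, "fingerprint")
  cohort
}
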