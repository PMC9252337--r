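#' Write a cohort to plain-text files
#'
#' Writes the long-format visit table, the wide-format static table
#' (age, sex, SNP dosages), the medication intervals, and - when present -
#' the ground truth (per-visit true probabilities as CSV, coefficients as
#' JSON) into a directory.
#'
#' @param cohort An `icd_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "icd_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$visits, file.path(dir, "visits.csv"))
  readr::write_csv(cohort$static, file.path(dir, "static.csv"))
  readr::write_csv(cohort$medication, file.path(dir, "medication.csv"))
  if (!is.null(cohort$ground_truth)) {
    readr::write_csv(cohort$ground_truth$probabilities,
                     file.path(dir, "ground_truth_probabilities.csv"))
    jsonlite::write_json(
      list(coefficients = cohort$ground_truth$coefficients,
           maf = cohort$ground_truth$maf),
      file.path(dir, "ground_truth_coefficients.json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' Also accepts externally produced tables with the same layout, e.g. a
#' dosage matrix exported from an additive genotype recoding as
#' `snp_*` columns of `static.csv`.
#'
#' @param dir Directory containing `visits.csv`, `static.csv` and
#'   `medication.csv`.
#' @return An `icd_cohort` (without ground truth unless present on disk).
#' @export
read_cohort <- function(dir) {
  visits <- readr::read_csv(file.path(dir, "visits.csv"), show_col_types = FALSE)
  static <- readr::read_csv(file.path(dir, "static.csv"), show_col_types = FALSE)
  medication <- readr::read_csv(file.path(dir, "medication.csv"), show_col_types = FALSE)
  gt <- NULL
  gp <- file.path(dir, "ground_truth_probabilities.csv")
  gc <- file.path(dir, "ground_truth_coefficients.json")
  if (file.exists(gp) && file.exists(gc)) {
    cj <- jsonlite::read_json(gc, simplifyVector = TRUE)
    gt <- list(probabilities = readr::read_csv(gp, show_col_types = FALSE),
               coefficients = as.list(cj$coefficients), maf = cj$maf)
  }
  new_icd_cohort(visits, static, medication, ground_truth = gt)
}

#' Write a comparison report as CSV tables
#'
#' Writes the per-model metric table, the pairwise DeLong comparison table
#' with adjusted p-values, and ROC / precision-recall curve points (as
#' threshold-indexed coordinates, never images).
#'
#' @param report An `icd_comparison`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "icd_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$metrics, file.path(dir, "metrics.csv"))
  readr::write_csv(report$comparisons, file.path(dir, "comparisons.csv"))
  readr::write_csv(report$curves, file.path(dir, "curves.csv"))
  jsonlite::write_json(
    list(seed = report$seed, feature_set = report$feature_set,
         outer_train = report$plan$outer_train,
         outer_test = report$plan$outer_test),
    file.path(dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
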