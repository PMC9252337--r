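#' Nested subject-level cross-validation plan
#'
#' Splits the training cohort's subjects 80/20 into outer-train and
#' outer-test (stratified by whether the subject ever has an ICD, so
#' prevalence stays comparable across splits), and partitions the
#' outer-train subjects into 5 subject-level inner folds for hyperparameter
#' selection. No subject crosses any boundary. Deterministic under `seed`.
#'
#' @param cohort An `icd_cohort`.
#' @param seed Integer seed.
#' @param train_prop Outer training proportion (default 0.8; the outer-train
#'   size is `floor(train_prop * n)`).
#' @param k Number of inner folds (default 5).
#' @return An object of class `icd_cv_plan`: `outer_train`, `outer_test`,
#'   `inner_folds` (list of k subject-id vectors partitioning outer-train),
#'   `seed`.
#' @export
make_cv_plan <- function(cohort, seed = 1L, train_prop = 0.8, k = 5L) {
  stopifnot(inherits(cohort, "icd_cohort"))
  subjects <- sort(unique(cohort$static$subject_id))
  n <- length(subjects)
  if (n < 2 * k) abort_config(sprintf("too few subjects (%d) for a %d-fold inner loop.", n, k))
  set.seed(seed)

  ever_icd <- cohort$visits |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(ever = as.integer(any(.data$icd == 1L)), .groups = "drop")
  strata <- ever_icd$ever[match(subjects, ever_icd$subject_id)]

  n_train <- floor(train_prop * n)
  # proportional allocation per stratum, largest remainder for the leftover
  train_ids <- integer(0)
  sizes <- table(strata)
  quota <- train_prop * as.numeric(sizes)
  base_q <- floor(quota)
  left <- n_train - sum(base_q)
  if (left > 0) {
    extra <- order(quota - base_q, decreasing = TRUE)[seq_len(left)]
    base_q[extra] <- base_q[extra] + 1
  }
  for (si in seq_along(sizes)) {
    ids <- subjects[strata == as.integer(names(sizes)[si])]
    train_ids <- c(train_ids, sample(ids, base_q[si]))
  }
  train_ids <- sort(train_ids)
  test_ids <- setdiff(subjects, train_ids)

  # stratified round-robin assignment to inner folds
  fold_of <- integer(length(train_ids))
  names(fold_of) <- train_ids
  tr_strata <- strata[match(train_ids, subjects)]
  for (s in unique(tr_strata)) {
    ids <- sample(train_ids[tr_strata == s])
    fold_of[as.character(ids)] <- rep_len(seq_len(k), length(ids))
  }
  inner_folds <- lapply(seq_len(k), function(f) sort(as.numeric(names(fold_of)[fold_of == f])))

  structure(list(outer_train = train_ids, outer_test = test_ids,
                 inner_folds = inner_folds, k = k, seed = seed),
            class = "icd_cv_plan")
}

#' @export
print.icd_cv_plan <- function(x, ...) {
  cat(sprintf("<icd_cv_plan> %d outer-train / %d outer-test subjects, %d inner folds (seed %d)\n",
              length(x$outer_train), length(x$outer_test), x$k, x$seed))
  invisible(x)
}
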