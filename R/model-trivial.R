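#' The trivial persistence baseline
#'
#' Predicts the ICD status at the next visit with the ICD status at the most
#' recent visit, verbatim, as both probability and class. Stateless: fitting
#' records nothing.
#'
#' On any labeled set its ROC AUC equals its balanced accuracy, because a
#' binary score's AUC is `(sensitivity + specificity) / 2`.
#'
#' @param train Ignored (kept for a uniform fitting interface).
#' @return An object of class `icd_trivial`.
#' @export
fit_trivial <- function(train = NULL) {
  structure(list(), class = "icd_trivial")
}

#' @describeIn fit_trivial Predict with the persistence baseline: returns
#'   the raw current ICD status in \{0, 1\} for each observation.
#' @param object An `icd_trivial` model.
#' @param obs An `icd_observations` tibble.
#' @param ... Unused.
#' @export
predict.icd_trivial <- function(object, obs, ...) {
  stopifnot(inherits(obs, "icd_observations"))
  as.numeric(obs$icd_current)
}
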