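#' Fit a feature standardizer on a training observation set
#'
#' Estimates per-feature means and standard deviations: sequential features
#' are pooled over every history row of the training observations, static
#' features over the training observations themselves. Every feature is
#' standardized, binary indicators included. A zero-variance feature keeps a
#' scale of 1 (centering only), with a warning naming it.
#'
#' The fitted object records a fingerprint of the subjects it was computed
#' from, so downstream leakage audits can verify that no test subject
#' contributed.
#'
#' @param train An `icd_observations` tibble (training observations only).
#' @return An object of class `icd_standardizer`.
#' @seealso [apply_standardizer()]
#' @export
fit_standardizer <- function(train) {
  stopifnot(inherits(train, "icd_observations"))
  if (!nrow(train)) abort_arg("training observation set is empty.")
  schema <- observation_schema(train)
  pooled <- do.call(rbind, train$history)
  if (anyNA(pooled)) abort_validation("non-finite sequential features; impute before standardizing.")
  # population (divide-by-n) standard deviations, the machine learning
  # scaler convention, so a length-3 column (1,2,3) maps to +/-1.2247
  pop_sd <- function(m) sqrt(colMeans(sweep(m, 2, colMeans(m), "-")^2))
  seq_mean <- colMeans(pooled)
  seq_sd <- pop_sd(pooled)
  stat_mat <- static_matrix(train)
  stat_mean <- colMeans(stat_mat)
  stat_sd <- pop_sd(stat_mat)
  fix_sd <- function(sds) {
    zero <- !is.finite(sds) | sds < 1e-12
    if (any(zero)) {
      rlang::warn(paste0("zero-variance feature(s) scaled by 1: ",
                         paste(names(sds)[zero], collapse = ", ")))
      sds[zero] <- 1
    }
    sds
  }
  structure(
    list(sequential = list(mean = seq_mean, sd = fix_sd(seq_sd)),
         static = list(mean = stat_mean, sd = fix_sd(stat_sd)),
         schema = schema,
         fingerprint = sort(unique(train$subject_id))),
    class = "icd_standardizer"
  )
}

#' Apply a fitted standardizer to an observation set
#'
#' Transforms every sequential and static feature with the training means
#' and standard deviations. The raw persistence columns (`icd_current`, `y`)
#' are left untouched.
#'
#' @param obs An `icd_observations` tibble.
#' @param standardizer From [fit_standardizer()].
#' @return The standardized observation set; `attr(x, "standardized")`
#'   carries the fingerprint of the subjects the statistics came from.
#' @export
apply_standardizer <- function(obs, standardizer) {
  stopifnot(inherits(obs, "icd_observations"),
            inherits(standardizer, "icd_standardizer"))
  schema <- observation_schema(obs)
  if (!identical(schema$sequential, standardizer$schema$sequential) ||
      !identical(schema$static, standardizer$schema$static)) {
    abort_validation("observation schema does not match the standardizer's fit-time schema.")
  }
  sq <- standardizer$sequential
  obs$history <- lapply(obs$history, function(h) {
    sweep(sweep(h, 2, sq$mean[colnames(h)], "-"), 2, sq$sd[colnames(h)], "/")
  })
  st <- standardizer$static
  for (col in schema$static) {
    obs[[col]] <- (obs[[col]] - st$mean[[col]]) / st$sd[[col]]
  }
  out <- new_icd_observations(obs, schema)
  attr(out, "standardized") <- standardizer$fingerprint
  out
}

#' Invert a standardizer on a standardized observation set
#'
#' @param obs A standardized `icd_observations` tibble.
#' @param standardizer The `icd_standardizer` used to transform it.
#' @return The observation set on the original scale.
#' @export
invert_standardizer <- function(obs, standardizer) {
  stopifnot(inherits(obs, "icd_observations"))
  schema <- observation_schema(obs)
  sq <- standardizer$sequential
  obs$history <- lapply(obs$history, function(h) {
    sweep(sweep(h, 2, sq$sd[colnames(h)], "*"), 2, sq$mean[colnames(h)], "+")
  })
  st <- standardizer$static
  for (col in schema$static) {
    obs[[col]] <- obs[[col]] * st$sd[[col]] + st$mean[[col]]
  }
  new_icd_observations(obs, schema)
}
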