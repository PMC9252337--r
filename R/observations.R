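#' Derived dopamine-agonist exposure features at a time point
#'
#' Summarizes a subject's dopamine-agonist treatment intervals up to time
#' `t`: cumulative duration in years, total dose as the integral of the
#' daily levodopa-equivalent dose over the exposed time (LEDD-years),
#' maximum daily dose attained, and mean daily dose (total dose divided by
#' cumulative duration, 0 when unexposed). All but the mean are monotonically
#' non-decreasing in `t`.
#'
#' @param medication Tibble of treatment intervals with columns `drug_class`,
#'   `start_years`, `end_years`, `daily_dose_ledd` (one subject's rows, e.g.
#'   filtered from `cohort$medication`).
#' @param t Non-negative time in years.
#' @return Named numeric vector `(mean_daily, max_daily, total_dose,
#'   cum_duration)`.
#' @examples
#' iv <- tibble::tibble(drug_class = "dopamine_agonist",
#'                      start_years = 0, end_years = 2, daily_dose_ledd = 100)
#' derive_da_features(iv, 2)
#' @export
derive_da_features <- function(medication, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    abort_arg("`t` must be a single non-negative time in years.")
  }
  da <- medication[medication$drug_class == "dopamine_agonist", , drop = FALSE]
  out <- da_exposure_at(da, t)
  names(out) <- c("mean_daily", "max_daily", "total_dose", "cum_duration")
  out
}

SEQ_FEATURES <- c("anxiety", "depression", "rem", "updrs3", "icd",
                  "on_levodopa", "on_dopamine_agonist", "on_other",
                  "da_mean_daily", "da_max_daily", "da_total_dose",
                  "da_cum_duration", "follow_up_years", "time_to_next")

#' Build the supervised next-visit observation set
#'
#' Turns a fully imputed cohort into one supervised instance per
#' (subject, visit t) pair with t before the last visit: the label is the ICD
#' status at visit t+1, and the clinical history contains the visits up to
#' and including t only (no future leakage). Each history row carries the
#' clinical scales, the ICD indicator at that visit, treatment-class flags,
#' the four derived dopamine-agonist exposure features at that visit's time,
#' the follow-up length (time since baseline) and the time to the following
#' visit; the final row's time-to-next is the prediction horizon. Static
#' features are age, sex and, unless `feature_set = "clinical_only"`, the
#' SNP dosages. The observation count is the total number of visits minus
#' the number of subjects.
#'
#' @param cohort An imputed `icd_cohort`.
#' @param feature_set `"all"` (clinical + genetic) or `"clinical_only"`.
#' @return A tibble of class `icd_observations` with columns `subject_id`,
#'   `t` (index of the most recent history visit), `time_t`, `time_to_next`,
#'   `icd_current` (raw status at visit t, the persistence baseline's
#'   prediction), `y` (ICD at visit t+1), a list-column `history` of
#'   t x d feature matrices, and the static feature columns. The feature
#'   schema is stored in `attr(x, "schema")`.
#' @export
build_observations <- function(cohort, feature_set = c("all", "clinical_only")) {
  stopifnot(inherits(cohort, "icd_cohort"))
  feature_set <- match.arg(feature_set)
  visits <- dplyr::arrange(cohort$visits, .data$subject_id, .data$visit)
  if (anyNA(visits[SCALE_COLS])) {
    abort_validation("cohort has missing clinical values; impute before building observations.")
  }
  counts <- table(visits$subject_id)
  if (any(counts < 2L)) {
    abort_validation("every subject needs at least 2 visits (baseline plus one follow-up).")
  }

  static_cols <- c("age", "sex",
                   if (feature_set == "all") {
                     grep("^snp_", names(cohort$static), value = TRUE)
                   })
  schema <- list(sequential = SEQ_FEATURES, static = static_cols,
                 feature_set = feature_set)

  by_subj <- split(visits, visits$subject_id)
  med <- cohort$medication
  obs_list <- lapply(by_subj, function(sv) {
    Ti <- nrow(sv)
    sid <- sv$subject_id[1]
    da <- med[med$subject_id == sid & med$drug_class == "dopamine_agonist", , drop = FALSE]
    expo <- t(vapply(sv$time_years, function(tt) da_exposure_at(da, tt), numeric(4)))
    colnames(expo) <- c("da_mean_daily", "da_max_daily", "da_total_dose", "da_cum_duration")
    tt_next <- c(diff(sv$time_years), NA_real_)
    hist_full <- cbind(
      as.matrix(sv[, c(SCALE_COLS, "icd", "on_levodopa", "on_dopamine_agonist", "on_other")]),
      expo,
      follow_up_years = sv$time_years,
      time_to_next = tt_next
    )[, SEQ_FEATURES, drop = FALSE]
    lapply(seq_len(Ti - 1L), function(tv) {
      list(subject_id = sid, t = tv, time_t = sv$time_years[tv],
           time_to_next = tt_next[tv],
           icd_current = sv$icd[tv], y = sv$icd[tv + 1L],
           history = hist_full[seq_len(tv), , drop = FALSE])
    })
  })
  flat <- unlist(obs_list, recursive = FALSE, use.names = FALSE)
  num_field <- function(name) vapply(flat, function(o) as.numeric(o[[name]]), numeric(1))
  obs <- tibble::tibble(
    subject_id = num_field("subject_id"),
    t = as.integer(num_field("t")),
    time_t = num_field("time_t"),
    time_to_next = num_field("time_to_next"),
    icd_current = num_field("icd_current"),
    y = num_field("y"),
    history = lapply(flat, `[[`, "history")
  )
  obs <- dplyr::bind_cols(
    obs,
    dplyr::left_join(obs["subject_id"], cohort$static[, c("subject_id", static_cols)],
                     by = "subject_id")[, static_cols, drop = FALSE]
  )
  new_icd_observations(obs, schema)
}

new_icd_observations <- function(x, schema) {
  tibble::new_tibble(as.data.frame(x), schema = schema, nrow = nrow(x),
                     class = "icd_observations")
}

# row subset that preserves the schema attribute
subset_obs <- function(obs, idx) {
  schema <- observation_schema(obs)
  new_icd_observations(as.data.frame(obs)[idx, , drop = FALSE], schema)
}

#' Feature schema of an observation set
#' @param obs An `icd_observations` tibble.
#' @return List with `sequential` and `static` feature names.
#' @export
observation_schema <- function(obs) {
  attr(obs, "schema")
}

# static design matrix (n_obs x d_static)
static_matrix <- function(obs) {
  schema <- observation_schema(obs)
  as.matrix(as.data.frame(obs)[, schema$static, drop = FALSE])
}
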