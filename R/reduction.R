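#' Convex-combination history reduction schemes
#'
#' A reduction scheme collapses a variable-length visit history into a single
#' "summary" visit by a convex combination: non-negative per-visit weights
#' that sum to one. Named schemes:
#'
#' * `baseline_only` — weight 1 on the first visit (the summary is the
#'   baseline visit);
#' * `last_only` — weight 1 on the most recent visit;
#' * `uniform` — each visit contributes equally (the mean over past visits,
#'   the current visit included);
#' * `exponential_recency` — weights proportional to `decay^(t - i)` for
#'   visit i of t, normalized: recent visits weigh more, all visits weigh
#'   something.
#'
#' @param name Scheme name.
#' @param decay Decay factor in (0, 1); `exponential_recency` only.
#' @return An object of class `icd_reduction`.
#' @export
reduction_scheme <- function(name = c("baseline_only", "last_only", "uniform",
                                      "exponential_recency"),
                             decay = 0.5) {
  name <- match.arg(name)
  if (name == "exponential_recency" &&
      (!is.numeric(decay) || length(decay) != 1L || decay <= 0 || decay >= 1)) {
    abort_config("`decay` must lie strictly inside (0, 1).")
  }
  structure(list(name = name, decay = if (name == "exponential_recency") decay else NULL),
            class = "icd_reduction")
}

#' Convex weights of a reduction scheme for a history of length t
#'
#' @param scheme An [reduction_scheme()] object.
#' @param t History length (>= 1).
#' @return Length-`t` numeric vector: non-negative, summing to one.
#' @examples
#' reduction_weights(reduction_scheme("uniform"), 4)
#' reduction_weights(reduction_scheme("exponential_recency", 0.5), 3)
#' @export
reduction_weights <- function(scheme, t) {
  stopifnot(inherits(scheme, "icd_reduction"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 1 || t != floor(t)) {
    abort_arg("history length `t` must be a single integer >= 1.")
  }
  t <- as.integer(t)
  w <- switch(scheme$name,
    baseline_only = c(1, rep(0, t - 1L)),
    last_only = c(rep(0, t - 1L), 1),
    uniform = rep(1 / t, t),
    exponential_recency = {
      raw <- scheme$decay^((t - 1L):0)
      raw / sum(raw)
    }
  )
  w
}

#' Summarize a visit history by a convex combination
#'
#' Returns the weighted sum of the history rows. The result lies in the
#' convex hull of the rows: `baseline_only` reproduces the first row
#' exactly, `last_only` the most recent.
#'
#' @param history Numeric matrix, one row per visit (t x d).
#' @param weights Length-t convex weight vector (non-negative, summing to 1).
#' @return Length-d named numeric vector.
#' @export
summarize_history <- function(history, weights) {
  if (!is.matrix(history)) abort_arg("`history` must be a matrix (visits x features).")
  if (length(weights) != nrow(history)) {
    abort_arg("`weights` length must equal the number of history rows.")
  }
  if (any(weights < -1e-12) || abs(sum(weights) - 1) > 1e-8) {
    abort_validation("`weights` must be non-negative and sum to one.")
  }
  drop(crossprod(history, weights))
}

#' Reduce an observation set to a fixed-length design
#'
#' Applies [summarize_history()] with the scheme's weights to every
#' observation's history and binds the summary to the static features,
#' producing the fixed-width design matrix that fixed-input learners expect.
#'
#' @param obs An `icd_observations` tibble.
#' @param scheme An [reduction_scheme()].
#' @return List with `x` (design matrix: summarized sequential features then
#'   static features), `y` (labels), and `feature_names`.
#' @export
reduce_observations <- function(obs, scheme) {
  stopifnot(inherits(obs, "icd_observations"))
  schema <- observation_schema(obs)
  summ <- t(vapply(obs$history, function(h) {
    summarize_history(h, reduction_weights(scheme, nrow(h)))
  }, numeric(length(schema$sequential))))
  colnames(summ) <- schema$sequential
  x <- cbind(summ, static_matrix(obs))
  list(x = x, y = obs$y, feature_names = colnames(x))
}
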