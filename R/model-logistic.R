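#' Penalized logistic regression on a reduced visit history
#'
#' Collapses each observation's history with a convex-combination reduction
#' scheme, binds the static features, and fits an l1- or l2-penalized
#' logistic regression (via glmnet) at penalty strength `lambda`. The
#' intercept is unpenalized. Features are expected standardized and fully
#' imputed; glmnet's internal re-standardization is disabled so the
#' coefficients stay on the feature scale.
#'
#' @param train An `icd_observations` tibble (standardized, imputed).
#' @param scheme An [reduction_scheme()].
#' @param penalty `"l1"` or `"l2"`.
#' @param lambda Positive regularization strength.
#' @return An object of class `icd_logistic` with the coefficient vector,
#'   intercept, scheme and penalty settings.
#' @export
fit_logistic <- function(train, scheme = reduction_scheme("last_only"),
                         penalty = c("l2", "l1"), lambda = 0.01) {
  stopifnot(inherits(train, "icd_observations"))
  penalty <- match.arg(penalty)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    abort_config("`lambda` must be a single positive value.")
  }
  d <- reduce_observations(train, scheme)
  if (!all(is.finite(d$x))) abort_validation("non-finite features in the design matrix.")
  fit <- glmnet::glmnet(d$x, d$y, family = "binomial",
                        alpha = if (penalty == "l1") 1 else 0,
                        lambda = lambda, standardize = FALSE)
  beta <- as.numeric(fit$beta)
  names(beta) <- rownames(fit$beta)
  structure(
    list(coefficients = beta, intercept = as.numeric(fit$a0),
         scheme = scheme, penalty = penalty, lambda = lambda,
         feature_names = d$feature_names,
         schema = observation_schema(train)),
    class = "icd_logistic"
  )
}

#' @describeIn fit_logistic Predicted next-visit ICD probabilities in (0, 1).
#'   The observation schema must match the fit-time schema; the first
#'   discrepant column is named otherwise.
#' @param object An `icd_logistic` model.
#' @param obs An `icd_observations` tibble.
#' @param ... Unused.
#' @export
predict.icd_logistic <- function(object, obs, ...) {
  stopifnot(inherits(obs, "icd_observations"))
  d <- reduce_observations(obs, object$scheme)
  if (!identical(d$feature_names, object$feature_names)) {
    bad <- which(is.na(match(object$feature_names, d$feature_names)) |
                   d$feature_names[seq_along(object$feature_names)] != object$feature_names)[1]
    abort_validation(sprintf("feature schema mismatch at column '%s'.",
                             object$feature_names[bad]))
  }
  as.numeric(sigmoid(object$intercept + d$x %*% object$coefficients))
}

#' Logarithmic penalty-strength grid
#'
#' @param from,to Grid end points.
#' @param length Number of grid points.
#' @return Numeric vector, increasing.
#' @export
lambda_grid <- function(from = 1e-3, to = 1e3, length = 13) {
  exp(seq(log(from), log(to), length.out = length))
}

#' @export
print.icd_logistic <- function(x, ...) {
  cat(sprintf("<icd_logistic> %s penalty, lambda = %.4g, reduction '%s'\n",
              x$penalty, x$lambda, x$scheme$name))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the coefficients of a fitted logistic model
#'
#' @param x An `icd_logistic` model.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` and the feature branch
#'   (sequential summary vs static).
#' @export
tidy.icd_logistic <- function(x, ...) {
  schema <- x$schema
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients)),
    branch = c("intercept",
               ifelse(names(x$coefficients) %in% schema$sequential,
                      "history_summary", "static"))
  )
}

#' @rdname tidy.icd_logistic
#' @export
glance.icd_logistic <- function(x, ...) {
  tibble::tibble(penalty = x$penalty, lambda = x$lambda,
                 reduction = x$scheme$name,
                 n_features = length(x$coefficients),
                 n_nonzero = sum(x$coefficients != 0))
}
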