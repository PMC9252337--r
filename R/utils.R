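#' @importFrom stats rbinom rnorm runif plogis qlogis pnorm qnorm sd predict
#' @importFrom rlang .data abort warn `%||%`
#' @importFrom utils head tail
NULL

sigmoid <- function(x) plogis(x)

logit <- function(p) qlogis(p)

# stop with a classed condition so callers/tests can distinguish error families
abort_config <- function(msg) rlang::abort(msg, class = "icdnext_config_error")
abort_arg <- function(msg) rlang::abort(msg, class = "icdnext_argument_error")
abort_validation <- function(msg) rlang::abort(msg, class = "icdnext_validation_error")
abort_leakage <- function(msg) rlang::abort(msg, class = "icdnext_leakage_error")
abort_metric <- function(msg) rlang::abort(msg, class = "icdnext_metric_error")
abort_impute <- function(msg) rlang::abort(msg, class = "icdnext_impute_error")

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort_config(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_binary_labels <- function(labels) {
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    abort_arg("`labels` must be binary (0/1) with no missing values.")
  }
  as.integer(labels)
}
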