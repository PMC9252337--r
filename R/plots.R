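#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_point
#'   geom_errorbar facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot ROC or precision-recall curves from a comparison report
#'
#' @param object An `icd_comparison` object.
#' @param curve `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot object: one panel per cohort, one line per model.
#' @export
autoplot.icd_comparison <- function(object, curve = c("roc", "pr"), ...) {
  curve <- match.arg(curve)
  dat <- dplyr::filter(object$curves, .data$curve == !!curve)
  p <- ggplot(dat, aes(x = .data$x, y = .data$yv, colour = .data$model)) +
    geom_line() +
    facet_wrap(~cohort) +
    theme_minimal()
  if (curve == "roc") {
    p <- p + geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
      labs(x = "False positive rate", y = "True positive rate",
           title = "ROC curves")
  } else {
    p <- p + labs(x = "Recall", y = "Precision", title = "Precision-recall curves")
  }
  p
}

#' Forest-style plot of per-model ROC AUCs with 95% confidence intervals
#'
#' Confidence intervals come from the asymptotic normal distribution of each
#' AUC (DeLong variance); models whose DeLong comparison against the trivial
#' baseline stays significant after Bonferroni adjustment are starred.
#'
#' @param report An `icd_comparison` object.
#' @return A ggplot object.
#' @export
plot_auc_comparison <- function(report) {
  stopifnot(inherits(report, "icd_comparison"))
  cis <- purrr::map_dfr(names(report$scores), function(cn) {
    y_set <- report$scores[[cn]]
    purrr::map_dfr(names(y_set), function(ml) {
      # labels reconstructed from the stored per-cohort scores and metrics
      met <- dplyr::filter(report$metrics, .data$model == ml, .data$cohort == cn)
      tibble::tibble(model = ml, cohort = cn, auc = met$roc_auc[1])
    })
  })
  comp <- report$comparisons
  ci_tab <- dplyr::bind_rows(
    dplyr::transmute(comp, model = .data$model, cohort = .data$cohort,
                     lower = .data$ci_a_lower, upper = .data$ci_a_upper),
    dplyr::distinct(dplyr::transmute(comp, model = .data$baseline, cohort = .data$cohort,
                                     lower = .data$ci_b_lower, upper = .data$ci_b_upper))
  )
  dat <- dplyr::left_join(cis, ci_tab, by = c("model", "cohort")) |>
    dplyr::left_join(dplyr::select(comp, "model", "cohort", "stars"),
                     by = c("model", "cohort"))
  ggplot(dat, aes(x = .data$model, y = .data$auc)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$lower, ymax = .data$upper), width = 0.2) +
    ggplot2::geom_text(aes(label = dplyr::coalesce(as.character(.data$stars), ""),
                           y = .data$upper + 0.02)) +
    facet_wrap(~cohort) +
    labs(x = NULL, y = "ROC AUC",
         title = "ROC AUC with 95% asymptotic-normal confidence intervals") +
    theme_minimal()
}
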