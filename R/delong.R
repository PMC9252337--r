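#' DeLong test for two correlated ROC AUCs
#'
#' Nonparametric comparison of the ROC AUCs of two scoring rules evaluated on
#' the same labeled observations (paired design), using the
#' structural-component (placement-value) estimator of the covariance matrix
#' of the two AUCs. For each model, the placement value of a positive is the
#' fraction of negatives it outscores (ties half credit), and symmetrically
#' for negatives; the empirical covariances of these placements across
#' models give the variance of the AUC difference. The test statistic
#' `z = (AUC_A - AUC_B) / sqrt(var)` is referred to the standard normal,
#' two-sided. Per-model 95% confidence intervals use the asymptotic normal
#' distribution of each AUC (`AUC +/- 1.96 SE`).
#'
#' When the variance of the difference is numerically zero (e.g. identical
#' scores), the result is flagged degenerate with difference as computed and
#' p = 1.
#'
#' @param labels Binary 0/1 vector.
#' @param scores_a,scores_b Paired score vectors on the same observations.
#' @return A one-row tibble of class `icd_delong`: `auc_a`, `auc_b`, `diff`,
#'   `var_diff`, `z`, `p_value`, per-model CI bounds, and `degenerate`.
#' @references DeLong, E.R., DeLong, D.M., Clarke-Pearson, D.L. (1988),
#'   Biometrics 44(3), 837-845.
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  labels <- check_binary_labels(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    abort_arg("score vectors must be paired with `labels` (same length).")
  }
  pos <- labels == 1L
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L) abort_metric("DeLong test needs both classes present.")

  pl <- function(scores) placements(scores, pos)
  pa <- pl(scores_a); pb <- pl(scores_b)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)

  s10 <- stats::cov(cbind(pa$v10, pb$v10))        # across positives
  s01 <- stats::cov(cbind(pa$v01, pb$v01))        # across negatives
  var_a <- s10[1, 1] / m + s01[1, 1] / n
  var_b <- s10[2, 2] / m + s01[2, 2] / n
  var_diff <- var_a + var_b - 2 * (s10[1, 2] / m + s01[1, 2] / n)

  d <- auc_a - auc_b
  degenerate <- !is.finite(var_diff) || var_diff <= .Machine$double.eps * 100
  if (degenerate) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  ci <- function(auc, v) auc + c(-1, 1) * stats::qnorm(0.975) * sqrt(max(v, 0))
  cia <- ci(auc_a, var_a); cib <- ci(auc_b, var_b)
  out <- tibble::tibble(
    auc_a = auc_a, auc_b = auc_b, diff = d, var_diff = max(var_diff, 0),
    z = z, p_value = p,
    ci_a_lower = cia[1], ci_a_upper = cia[2],
    ci_b_lower = cib[1], ci_b_upper = cib[2],
    degenerate = degenerate
  )
  class(out) <- c("icd_delong", class(out))
  out
}

# midrank placement values: v10 (per positive) and v01 (per negative)
placements <- function(scores, pos) {
  m <- sum(pos); n <- sum(!pos)
  r_all <- rank(scores, ties.method = "average")
  r_pos <- rank(scores[pos], ties.method = "average")
  r_neg <- rank(scores[!pos], ties.method = "average")
  v10 <- (r_all[pos] - r_pos) / n           # fraction of negatives outscored
  v01 <- 1 - (r_all[!pos] - r_neg) / m      # fraction of positives outscoring
  list(v10 = v10, v01 = v01)
}

#' Asymptotic-normal confidence interval for one ROC AUC
#'
#' Uses the DeLong placement-value variance of a single AUC.
#'
#' @inheritParams roc_auc
#' @param level Confidence level (default 0.95).
#' @return Named vector `(auc, lower, upper, se)`.
#' @export
auc_ci <- function(labels, scores, level = 0.95) {
  labels <- check_binary_labels(labels)
  pos <- labels == 1L
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L) abort_metric("AUC CI needs both classes present.")
  p <- placements(scores, pos)
  auc <- mean(p$v10)
  v <- stats::var(p$v10) / m + stats::var(p$v01) / n
  zq <- stats::qnorm(1 - (1 - level) / 2)
  c(auc = auc, lower = auc - zq * sqrt(v), upper = auc + zq * sqrt(v),
    se = sqrt(v))
}

#' Subject-level cluster bootstrap of an AUC difference
#'
#' Sensitivity analysis for the paired DeLong test when observations are
#' nested within subjects: resamples subjects with replacement and
#' recomputes the AUC difference, returning a percentile interval and a
#' bootstrap p-value (fraction of resamples crossing zero, doubled).
#'
#' @param labels,scores_a,scores_b As in [delong_test()].
#' @param subject_id Cluster identifier per observation.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return One-row tibble with the observed difference, percentile CI and
#'   bootstrap p-value.
#' @export
cluster_bootstrap_auc_diff <- function(labels, scores_a, scores_b, subject_id,
                                       n_boot = 2000, seed = 1L) {
  labels <- check_binary_labels(labels)
  set.seed(seed)
  subjects <- unique(subject_id)
  idx_by_subj <- split(seq_along(labels), subject_id)
  diffs <- vapply(seq_len(n_boot), function(b) {
    take <- sample(subjects, length(subjects), replace = TRUE)
    idx <- unlist(idx_by_subj[as.character(take)], use.names = FALSE)
    lb <- labels[idx]
    if (length(unique(lb)) < 2L) return(NA_real_)
    roc_auc(lb, scores_a[idx]) - roc_auc(lb, scores_b[idx])
  }, numeric(1))
  diffs <- diffs[!is.na(diffs)]
  obs <- roc_auc(labels, scores_a) - roc_auc(labels, scores_b)
  p_boot <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  tibble::tibble(diff = obs,
                 ci_lower = stats::quantile(diffs, 0.025, names = FALSE),
                 ci_upper = stats::quantile(diffs, 0.975, names = FALSE),
                 p_value = min(1, p_boot), n_boot = length(diffs))
}
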