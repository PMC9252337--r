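# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the package implementations they check.

# AUC by exhaustive positive-negative pair counting, ties half credit
auc_pair_counting <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) total <- total + 1
      else if (p == q) total <- total + 0.5
    }
  }
  total / (length(pos) * length(neg))
}

# average precision by explicit enumeration over distinct thresholds
ap_enumeration <- function(labels, scores) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  ap <- 0
  recall_prev <- 0
  for (th in thresholds) {
    sel <- scores >= th
    tp <- sum(labels == 1 & sel)
    precision <- tp / sum(sel)
    recall <- tp / npos
    ap <- ap + (recall - recall_prev) * precision
    recall_prev <- recall
  }
  ap
}

# stratified bootstrap variance of an AUC difference (paired scores)
bootstrap_var_auc_diff <- function(labels, scores_a, scores_b, n_boot) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  diffs <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
    roc_auc(labels[idx], scores_a[idx]) - roc_auc(labels[idx], scores_b[idx])
  }, numeric(1))
  stats::var(diffs)
}
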