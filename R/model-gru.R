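#' Training configuration for the GRU-static fusion network
#'
#' Defaults: hidden size 16, Adam with learning rate 1e-2, at most 200
#' epochs with early stopping after 20 epochs without improvement of the
#' validation ROC AUC, minibatches of 64. `pos_weight` optionally reweights
#' the positive class in the cross-entropy (1 = unweighted, the default).
#' The learning rate is chosen so that convergence (typically within 10-40
#' epochs at these problem sizes) fits inside the early-stopping patience
#' window; a slower rate risks stopping on a noisy validation-AUC fluke
#' long before convergence.
#'
#' @param hidden Hidden state size H.
#' @param lr Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience, in epochs.
#' @param batch_size Minibatch size.
#' @param pos_weight Positive-class weight in the loss.
#' @param seed Integer seed for initialization and shuffling.
#' @return A list of class `icd_gru_config`.
#' @export
gru_config <- function(hidden = 16, lr = 1e-2, epochs = 200, patience = 20,
                       batch_size = 64, pos_weight = 1, seed = 1L) {
  structure(list(hidden = check_count(hidden, "hidden"), lr = lr,
                 epochs = check_count(epochs, "epochs"),
                 patience = check_count(patience, "patience"),
                 batch_size = check_count(batch_size, "batch_size"),
                 pos_weight = pos_weight, seed = check_count(seed, "seed", 0L)),
            class = "icd_gru_config")
}

# parameter initialization, uniform in +/- 1/sqrt(H) (standard GRU init)
gru_init <- function(d_clin, d_stat, hidden) {
  s <- 1 / sqrt(hidden)
  u <- function(nr, nc) matrix(runif(nr * nc, -s, s), nr, nc)
  list(Wxr = u(d_clin, hidden), Wxz = u(d_clin, hidden), Wxn = u(d_clin, hidden),
       Whr = u(hidden, hidden), Whz = u(hidden, hidden), Whn = u(hidden, hidden),
       br = u(1, hidden), bz = u(1, hidden), bxn = u(1, hidden), bhn = u(1, hidden),
       Wfc = u(hidden + d_stat, 1), bfc = matrix(0, 1, 1))
}

# pack an observation set into front-padded step matrices + mask
gru_pack <- function(obs) {
  schema <- observation_schema(obs)
  d <- length(schema$sequential)
  n <- nrow(obs)
  lens <- vapply(obs$history, nrow, integer(1))
  Tmax <- max(lens)
  X <- lapply(seq_len(Tmax), function(k) matrix(0, n, d))
  mask <- matrix(0, n, Tmax)
  for (i in seq_len(n)) {
    ti <- lens[i]
    rows <- (Tmax - ti + 1L):Tmax           # front padding
    mask[i, rows] <- 1
    for (j in seq_along(rows)) X[[rows[j]]][i, ] <- obs$history[[i]][j, ]
  }
  list(X = X, mask = mask, S = static_matrix(obs), y = obs$y)
}

# batched forward pass; returns scores and (optionally) the BPTT cache
gru_forward_batch <- function(params, X, mask, S, keep_cache = FALSE) {
  n <- nrow(S)
  H <- ncol(params$Whr)
  h <- matrix(0, n, H)
  Tmax <- length(X)
  cache <- if (keep_cache) vector("list", Tmax)
  for (k in seq_len(Tmax)) {
    x <- X[[k]]
    m <- mask[, k]
    r <- sigmoid(x %*% params$Wxr + h %*% params$Whr +
                   matrix(params$br, n, H, byrow = TRUE))
    z <- sigmoid(x %*% params$Wxz + h %*% params$Whz +
                   matrix(params$bz, n, H, byrow = TRUE))
    q <- h %*% params$Whn + matrix(params$bhn, n, H, byrow = TRUE)
    g <- tanh(x %*% params$Wxn + matrix(params$bxn, n, H, byrow = TRUE) + r * q)
    h_new <- (1 - z) * g + z * h
    if (keep_cache) cache[[k]] <- list(x = x, m = m, h_prev = h, r = r, z = z,
                                       q = q, g = g)
    h <- m * h_new + (1 - m) * h
  }
  u <- cbind(h, S)
  logit <- drop(u %*% params$Wfc) + params$bfc[1, 1]
  list(score = sigmoid(logit), logit = logit, h = h, u = u, cache = cache)
}

# full BPTT gradient of the (optionally weighted) mean binary cross-entropy
gru_backward <- function(params, fwd, y, pos_weight = 1) {
  n <- length(y)
  H <- ncol(params$Whr)
  w <- ifelse(y == 1, pos_weight, 1)
  dlogit <- matrix(w * (fwd$score - y) / sum(w), n, 1)
  grads <- lapply(params, function(p) array(0, dim(p)))
  grads$Wfc <- crossprod(fwd$u, dlogit)
  grads$bfc <- matrix(sum(dlogit), 1, 1)
  dh <- dlogit %*% t(params$Wfc[seq_len(H), , drop = FALSE])
  for (k in rev(seq_along(fwd$cache))) {
    cc <- fwd$cache[[k]]
    dh_new <- cc$m * dh
    dcarry <- (1 - cc$m) * dh
    dz <- dh_new * (cc$h_prev - cc$g)
    dg <- dh_new * (1 - cc$z)
    dh_prev <- dh_new * cc$z
    da_g <- dg * (1 - cc$g^2)
    dr <- da_g * cc$q
    dq <- da_g * cc$r
    grads$Wxn <- grads$Wxn + crossprod(cc$x, da_g)
    grads$bxn <- grads$bxn + colSums(da_g)
    grads$Whn <- grads$Whn + crossprod(cc$h_prev, dq)
    grads$bhn <- grads$bhn + colSums(dq)
    dh_prev <- dh_prev + dq %*% t(params$Whn)
    da_z <- dz * cc$z * (1 - cc$z)
    grads$Wxz <- grads$Wxz + crossprod(cc$x, da_z)
    grads$bz <- grads$bz + colSums(da_z)
    grads$Whz <- grads$Whz + crossprod(cc$h_prev, da_z)
    dh_prev <- dh_prev + da_z %*% t(params$Whz)
    da_r <- dr * cc$r * (1 - cc$r)
    grads$Wxr <- grads$Wxr + crossprod(cc$x, da_r)
    grads$br <- grads$br + colSums(da_r)
    grads$Whr <- grads$Whr + crossprod(cc$h_prev, da_r)
    dh_prev <- dh_prev + da_r %*% t(params$Whr)
    dh <- dh_prev + dcarry
  }
  grads
}

#' Train the GRU-static fusion network
#'
#' Fits the recurrent model of the package end-to-end: a gated recurrent
#' unit reads the clinical history `x(1..t)` into a hidden vector `h(t)`
#' (which exists only inside the forward pass - there is no separate
#' estimation of it), the hidden vector is concatenated with the static
#' socio-demographic and genetic vector `s`, and a fully connected layer
#' with a sigmoid emits the probability of an ICD at the next visit.
#' Training minimizes binary cross-entropy with Adam on minibatches;
#' variable-length histories are front-padded and masked, which is exactly
#' equivalent to per-sequence evaluation. The returned model is the
#' checkpoint with the best validation ROC AUC. Deterministic under a fixed
#' seed and single-threaded execution.
#'
#' @param train,val Disjoint-subject `icd_observations` tibbles; `val` is
#'   used for early stopping / checkpoint selection only.
#' @param config A [gru_config()].
#' @return An object of class `icd_gru` with the learned parameters, the
#'   config, the validation AUC trace and the best epoch.
#' @export
train_gru <- function(train, val, config = gru_config()) {
  stopifnot(inherits(train, "icd_observations"), inherits(val, "icd_observations"))
  if (length(intersect(unique(train$subject_id), unique(val$subject_id)))) {
    abort_leakage("training and validation sets share subjects.")
  }
  schema <- observation_schema(train)
  set.seed(config$seed)
  params <- gru_init(length(schema$sequential), length(schema$static), config$hidden)
  packed <- gru_pack(train)
  packed_val <- gru_pack(val)

  adam_m <- lapply(params, function(p) array(0, dim(p)))
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L

  n <- nrow(packed$S)
  best <- list(auc = -Inf, params = params, epoch = 0L)
  trace <- numeric(0)
  stale <- 0L
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s0 in starts) {
      idx <- perm[s0:min(s0 + config$batch_size - 1L, n)]
      Xb <- lapply(packed$X, function(xk) xk[idx, , drop = FALSE])
      fwd <- gru_forward_batch(params, Xb, packed$mask[idx, , drop = FALSE],
                               packed$S[idx, , drop = FALSE], keep_cache = TRUE)
      grads <- gru_backward(params, fwd, packed$y[idx], config$pos_weight)
      step <- step + 1L
      for (nm in names(params)) {
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * grads[[nm]]
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * grads[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - b1^step)
        vhat <- adam_v[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - config$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    val_scores <- gru_forward_batch(params, packed_val$X, packed_val$mask,
                                    packed_val$S)$score
    auc <- roc_auc(packed_val$y, val_scores)
    trace <- c(trace, auc)
    if (auc > best$auc + 1e-6) {
      best <- list(auc = auc, params = params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  structure(list(params = best$params, config = config, schema = schema,
                 val_auc = best$auc, best_epoch = best$epoch,
                 val_trace = trace),
            class = "icd_gru")
}

#' Forward pass of the GRU-static fusion network for one history
#'
#' Computes `h(t)` by the standard gated-recurrent-unit recursion (update
#' and reset gates, candidate state) over the clinical history from
#' `h(0) = 0`, then `sigmoid(FC(h(t) || s))`. Any history length t >= 1 is
#' handled without retraining.
#'
#' @param model An `icd_gru` model.
#' @param x_seq Numeric matrix (t x d_clinical) of sequential features.
#' @param s Numeric static feature vector.
#' @return Predicted probability in (0, 1).
#' @export
gru_forward <- function(model, x_seq, s) {
  stopifnot(inherits(model, "icd_gru"))
  if (!is.matrix(x_seq) || nrow(x_seq) < 1L) {
    abort_arg("`x_seq` must be a matrix with at least one visit row.")
  }
  d <- nrow(model$params$Wxr)
  ds <- nrow(model$params$Wfc) - ncol(model$params$Whr)
  if (ncol(x_seq) != d) abort_validation(sprintf("expected %d sequential features.", d))
  if (length(s) != ds) abort_validation(sprintf("expected %d static features.", ds))
  X <- lapply(seq_len(nrow(x_seq)), function(k) matrix(x_seq[k, ], 1, d))
  fwd <- gru_forward_batch(model$params, X, matrix(1, 1, nrow(x_seq)),
                           matrix(s, 1, ds))
  as.numeric(fwd$score)
}

#' @describeIn train_gru Predicted next-visit ICD probabilities in (0, 1)
#'   for an observation set.
#' @param object An `icd_gru` model.
#' @param obs An `icd_observations` tibble.
#' @param ... Unused.
#' @export
predict.icd_gru <- function(object, obs, ...) {
  stopifnot(inherits(obs, "icd_observations"))
  schema <- observation_schema(obs)
  if (!identical(schema$sequential, object$schema$sequential) ||
      !identical(schema$static, object$schema$static)) {
    abort_validation("observation schema does not match the model's fit-time schema.")
  }
  packed <- gru_pack(obs)
  as.numeric(gru_forward_batch(object$params, packed$X, packed$mask, packed$S)$score)
}

#' @export
print.icd_gru <- function(x, ...) {
  cat(sprintf("<icd_gru> H = %d, best epoch %d, validation ROC AUC %.3f\n",
              x$config$hidden, x$best_epoch, x$val_auc))
  invisible(x)
}

#' @rdname tidy.icd_logistic
#' @export
glance.icd_gru <- function(x, ...) {
  tibble::tibble(hidden = x$config$hidden, lr = x$config$lr,
                 best_epoch = x$best_epoch, epochs_run = length(x$val_trace),
                 val_roc_auc = x$val_auc)
}
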