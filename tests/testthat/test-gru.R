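test_that("backpropagation matches numerical gradients", {
  set.seed(101)
  d <- 3; ds <- 2; H = 4; n <- 5
  params <- icdnext:::gru_init(d, ds, H)
  X <- lapply(1:3, function(k) matrix(rnorm(n * d), n, d))
  mask <- rbind(c(0, 1, 1), c(1, 1, 1), c(0, 0, 1), c(1, 1, 1), c(0, 1, 1))
  S <- matrix(rnorm(n * ds), n, ds)
  y <- c(1, 0, 1, 1, 0)

  loss_at <- function(p) {
    fwd <- icdnext:::gru_forward_batch(p, X, mask, S)
    -mean(y * log(fwd$score) + (1 - y) * log(1 - fwd$score))
  }
  fwd <- icdnext:::gru_forward_batch(params, X, mask, S, keep_cache = TRUE)
  grads <- icdnext:::gru_backward(params, fwd, y)

  eps <- 1e-6
  for (nm in names(params)) {
    # probe a few entries of every parameter tensor
    idx <- seq_len(min(3, length(params[[nm]])))
    for (i in idx) {
      p_plus <- params; p_plus[[nm]][i] <- p_plus[[nm]][i] + eps
      p_minus <- params; p_minus[[nm]][i] <- p_minus[[nm]][i] - eps
      num <- (loss_at(p_plus) - loss_at(p_minus)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("degenerate parameterizations behave as the architecture dictates", {
  set.seed(103)
  params <- icdnext:::gru_init(3, 2, 4)
  model <- structure(list(params = params,
                          config = gru_config(), schema = NULL),
                     class = "icd_gru")
  # zero FC layer: probability 1/2 whatever the input
  m0 <- model
  m0$params$Wfc[] <- 0; m0$params$bfc[] <- 0
  expect_equal(gru_forward(m0, matrix(rnorm(9), 3, 3), rnorm(2)), 0.5)
  # zero recurrent and input weights: the score depends only on s
  m1 <- model
  for (nm in c("Wxr", "Wxz", "Wxn", "Whr", "Whz", "Whn",
               "br", "bz", "bxn", "bhn")) m1$params[[nm]][] <- 0
  s <- rnorm(2)
  p1 <- gru_forward(m1, matrix(rnorm(6), 2, 3), s)
  p2 <- gru_forward(m1, matrix(rnorm(15), 5, 3), s)
  expect_equal(p1, p2)
})

test_that("front padding under masking is exact", {
  set.seed(107)
  params <- icdnext:::gru_init(4, 2, 5)
  model <- structure(list(params = params, config = gru_config(), schema = NULL),
                     class = "icd_gru")
  x <- matrix(rnorm(12), 3, 4)
  s <- rnorm(2)
  unpadded <- gru_forward(model, x, s)
  # same sequence fed with two leading all-zero padded steps, mask 0
  X <- c(lapply(1:2, function(k) matrix(0, 1, 4)),
         lapply(1:3, function(k) matrix(x[k, ], 1, 4)))
  padded <- icdnext:::gru_forward_batch(params, X, matrix(c(0, 0, 1, 1, 1), 1, 5),
                                        matrix(s, 1, 2))$score
  expect_equal(as.numeric(padded), unpadded, tolerance = 1e-12)
})

test_that("training is deterministic and improves on the persistence-free signal", {
  cohort <- simulate_cohort(scenario_config("exposure_driven", n_subjects = 120,
                                            seed = 109))
  obs <- build_observations(cohort)
  std <- fit_standardizer(obs)
  obs <- apply_standardizer(obs, std)
  subjects <- unique(obs$subject_id)
  val_ids <- subjects[1:30]
  train <- icdnext:::subset_obs(obs, !(obs$subject_id %in% val_ids))
  val <- icdnext:::subset_obs(obs, obs$subject_id %in% val_ids)
  cfg <- gru_config(epochs = 30, patience = 30, seed = 5)
  m1 <- train_gru(train, val, cfg)
  m2 <- train_gru(train, val, cfg)
  expect_identical(m1$val_trace, m2$val_trace)
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, val), predict(m2, val))
  expect_true(all(predict(m1, val) > 0 & predict(m1, val) < 1))
  # learned model beats chance on held-out subjects
  expect_gt(roc_auc(val$y, predict(m1, val)), 0.6)
})

test_that("shared subjects between train and validation are refused", {
  obs <- tiny_observations(20, seed = 113)
  expect_error(train_gru(obs, obs, gru_config(epochs = 1)),
               class = "icdnext_leakage_error")
})

test_that("forward pass validates its inputs", {
  params <- icdnext:::gru_init(3, 2, 4)
  model <- structure(list(params = params, config = gru_config(), schema = NULL),
                     class = "icd_gru")
  expect_error(gru_forward(model, matrix(numeric(0), 0, 3), rnorm(2)),
               class = "icdnext_argument_error")
  expect_error(gru_forward(model, matrix(rnorm(8), 2, 4), rnorm(2)),
               class = "icdnext_validation_error")
  expect_error(gru_forward(model, matrix(rnorm(6), 2, 3), rnorm(5)),
               class = "icdnext_validation_error")
})
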