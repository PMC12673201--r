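test_that("weighted cross-entropy matches closed forms and the scalar oracle", {
  # perfect prediction: log(1) = 0 regardless of weights
  y <- rbind(c(1, 0), c(0, 1))
  t <- rbind(c(1, 0), c(0, 1))
  expect_equal(wcee_loss(y, t, c(3, 0.5)), 0)

  # the symmetric single example
  expect_equal(wcee_loss(rbind(c(0.5, 0.5)), rbind(c(1, 0)), 1),
               -log(0.5), tolerance = 1e-12)

  withr::with_seed(17, {
    for (i in 1:5) {
      n <- 7
      p <- runif(n, 0.01, 0.99)
      y <- cbind(p, 1 - p)
      lab <- rbinom(n, 1, 0.5)
      t <- cbind(1 - lab, lab)
      w <- runif(n, 0.2, 4)
      expect_equal(wcee_loss(y, t, w), oracle_wcee(y, t, w),
                   tolerance = 1e-10)
    }
  })
})

test_that("unit weights reduce the loss to plain mean cross-entropy", {
  withr::with_seed(21, {
    p <- runif(10, 0.05, 0.95)
    y <- cbind(p, 1 - p)
    lab <- rbinom(10, 1, 0.4)
    plain <- -mean(log(ifelse(lab == 1, 1 - p, p)))
    expect_equal(wcee_loss(y, lab, 1), plain, tolerance = 1e-12)
    # per-class weights broadcast to each example's true class
    w <- c(0.6, 5)
    expect_equal(wcee_loss(y, lab, w), wcee_loss(y, lab, w[lab + 1]),
                 tolerance = 1e-12)
  })
})

test_that("zero probability at the true class is clamped with a warning", {
  y <- rbind(c(0, 1))
  t <- rbind(c(1, 0))
  expect_warning(l <- wcee_loss(y, t, 1), "clamped")
  expect_true(is.finite(l) && l > 0)
})

test_that("auto class weights are inverse-frequency and average to one", {
  expect_equal(unname(auto_class_weights(c(0, 0, 1, 1))), c(1, 1))
  w <- auto_class_weights(c(rep(0, 90), rep(1, 10)))
  expect_equal(unname(w), c(100 / 180, 100 / 20), tolerance = 1e-12)
  withr::with_seed(5, {
    for (i in 1:5) {
      lab <- c(0, 1, rbinom(30, 1, runif(1, 0.2, 0.8)))
      w <- auto_class_weights(lab)
      # the expected weight of a random example is one
      expect_equal(mean(w[lab + 1]), 1, tolerance = 1e-12)
    }
  })
  expect_error(auto_class_weights(rep(1, 5)), "both classes")
})

test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- network_config(channels_block1 = 2, channels_block2 = 3, init_seed = 7)
  params <- init_network_params(cfg)
  withr::with_seed(1, x <- array(rnorm(21^3 * 4), c(21, 21, 21, 4, 1)))
  t <- stenonet:::onehot(c(0, 1, 1, 0))
  wts <- c(1.2, 3.0, 3.0, 1.2)
  loss_at <- function(pp) {
    f <- stenonet:::net_forward_batch(x, pp, cfg, training = TRUE)
    wcee_loss(f$probs, t, wts)
  }
  fwd <- stenonet:::net_forward_batch(x, params, cfg, training = TRUE,
                                      keep_cache = TRUE)
  grads <- stenonet:::net_backward_batch(fwd, t, wts, params)
  eps <- 1e-6
  withr::with_seed(2, {
    for (path in list(c("fc", "W"), c("fc", "b"), c("conv2", "W"),
                      c("conv1", "W"), c("bn1", "gamma"), c("bn1", "beta"),
                      c("bn2", "gamma"), c("bn2", "beta"))) {
      pv <- params[[path[1]]][[path[2]]]
      for (i in sample(length(pv), min(3, length(pv)))) {
        p2 <- params
        p2[[path[1]]][[path[2]]][i] <- pv[i] + eps
        l_hi <- loss_at(p2)
        p2[[path[1]]][[path[2]]][i] <- pv[i] - eps
        l_lo <- loss_at(p2)
        num <- (l_hi - l_lo) / (2 * eps)
        ana <- grads[[path[1]]][[path[2]]][i]
        expect_equal(ana, num, tolerance = 1e-4,
                     label = paste("gradient of", paste(path, collapse = ".")))
      }
    }
  })
  # conv biases are absorbed by batch normalization: their gradient is zero
  expect_lt(max(abs(grads$conv1$b), abs(grads$conv2$b)), 1e-10)
})

small_net <- function(seed = 3) {
  network_config(channels_block1 = 2, channels_block2 = 4, init_seed = seed)
}

test_that("training reduces the loss on separable data and respects the epoch cap", {
  tr <- make_toy_vois(6, 14, seed = 41)
  va <- make_toy_vois(3, 7, seed = 42, patient_prefix = "V")
  tcfg <- train_config(batch_size = 4, max_epochs = 3, learning_rate = 1e-3,
                       patience = 5, seed = 9)
  fit <- suppressMessages(train_one_split(tr, va, small_net(), tcfg))
  expect_lte(nrow(fit$history), tcfg$max_epochs)
  expect_lt(fit$history$train_loss[nrow(fit$history)], fit$history$train_loss[1])
  expect_gte(fit$best_epoch, 1L)
  # returned parameters reproduce the best recorded validation loss
  val_again <- stenonet:::batched_eval_loss(
    stenonet:::stack_vois(va$values), va$label, fit$params, small_net(),
    fit$class_weights)
  expect_equal(val_again, min(fit$history$val_loss), tolerance = 1e-12)
})

test_that("single-class training sets are rejected", {
  tr <- make_toy_vois(0, 8, seed = 1)
  va <- make_toy_vois(2, 2, seed = 2, patient_prefix = "V")
  expect_error(
    suppressMessages(train_one_split(tr, va, small_net(),
                                     train_config(max_epochs = 1))),
    "both classes")
})

test_that("identical seeds give bit-identical fits", {
  tr <- make_toy_vois(4, 8, seed = 11)
  va <- make_toy_vois(2, 4, seed = 12, patient_prefix = "V")
  tcfg <- train_config(batch_size = 4, max_epochs = 2, learning_rate = 1e-3,
                       seed = 77)
  f1 <- suppressMessages(train_one_split(tr, va, small_net(), tcfg))
  f2 <- suppressMessages(train_one_split(tr, va, small_net(), tcfg))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("augmented positives inherit their parent's patient identity", {
  tr <- make_toy_vois(3, 0, seed = 13)
  aug <- augment_positives(tr)
  expect_identical(sort(unique(aug$patient_id)), sort(tr$patient_id))
  expect_equal(nrow(aug), 12L)
})
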