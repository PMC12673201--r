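#' Training configuration
#'
#' Defaults follow the study protocol: batch size 4, at most 50 epochs,
#' learning rate 1e-4, SGD with momentum 0.9, early stopping on validation
#' loss with patience 5, and inverse-frequency ("auto") class weights for the
#' weighted cross-entropy objective.
#'
#' @param batch_size Training batch size.
#' @param max_epochs Maximum number of epochs.
#' @param learning_rate Positive SGD learning rate.
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param class_weights `"auto"` (inverse class frequency on the training
#'   set, normalized to average 1) or a length-2 positive numeric
#'   `c(w_negative, w_positive)`.
#' @param patience Early stopping: epochs without validation improvement
#'   tolerated before training halts.
#' @param seed Seed controlling epoch shuffling.
#' @return A validated `train_config` object.
#' @export
train_config <- function(batch_size = 4L,
                         max_epochs = 50L,
                         learning_rate = 1e-4,
                         momentum = 0.9,
                         class_weights = "auto",
                         patience = 5L,
                         seed = 1L) {
  cfg <- list(
    batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    learning_rate = learning_rate,
    momentum = momentum,
    class_weights = class_weights,
    patience = as.integer(patience),
    seed = as.integer(seed)
  )
  stopifnot_msg(cfg$batch_size >= 1, "batch_size must be >= 1")
  stopifnot_msg(cfg$max_epochs >= 1, "max_epochs must be >= 1")
  stopifnot_msg(is.numeric(cfg$learning_rate) && cfg$learning_rate > 0,
                "learning_rate must be > 0")
  stopifnot_msg(is.numeric(cfg$momentum) && cfg$momentum >= 0 && cfg$momentum < 1,
                "momentum must be in [0, 1)")
  if (!identical(cfg$class_weights, "auto")) {
    stopifnot_msg(is.numeric(cfg$class_weights) &&
                    length(cfg$class_weights) == 2 &&
                    all(cfg$class_weights > 0),
                  "class_weights must be \"auto\" or two positive numbers")
  }
  structure(cfg, class = "train_config")
}

#' Weighted cross-entropy error
#'
#' `-(1/n) * sum_i w_i * <t_i, log(y_i)>`, where `t_i` is the one-hot true
#' class vector, `y_i` the predicted probability vector and `w_i` the weight
#' of example i's true class. With all weights 1 this reduces to the ordinary
#' mean cross-entropy. Predicted probabilities of exactly zero at the true
#' class are clamped to `eps` (with a warning) so the loss stays finite.
#'
#' @param y n x 2 matrix of predicted probabilities (rows on the simplex).
#' @param t n x 2 one-hot matrix, or a binary label vector of length n.
#' @param w Per-example weights (length n), a length-2 per-class weight
#'   `c(w_negative, w_positive)` broadcast by true class, or a scalar.
#' @param eps Clamping floor for log arguments.
#' @return Non-negative scalar loss.
#' @export
wcee_loss <- function(y, t, w = 1, eps = 1e-12) {
  y <- as.matrix(y)
  if (is.null(dim(t))) t <- onehot(t, ncol(y))
  n <- nrow(y)
  stopifnot_msg(nrow(t) == n && ncol(t) == ncol(y), "y and t shapes differ")
  if (length(w) == ncol(y) && ncol(y) == 2 && n != 2) {
    w <- w[max.col(t)]
  } else if (length(w) == 1) {
    w <- rep(w, n)
  }
  stopifnot_msg(length(w) == n && all(w > 0), "w must be positive, one per example")
  p_true <- rowSums(y * t)
  if (any(p_true < eps)) {
    warn("predicted probability at the true class clamped to eps to keep the loss finite")
    p_true <- pmax(p_true, eps)
  }
  -mean(w * log(p_true))
}

onehot <- function(labels, k = 2L) {
  labels <- as.integer(labels)
  m <- matrix(0, length(labels), k)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}

#' Inverse-frequency class weights
#'
#' `w_k = n_total / (2 * n_k)` for the two classes, so the weights average
#' to 1 and the minority class is up-weighted in proportion to its rarity.
#'
#' @param labels Binary label vector; both classes must be present.
#' @return Named numeric: `c(w_negative, w_positive)`.
#' @export
auto_class_weights <- function(labels) {
  n0 <- sum(labels == 0)
  n1 <- sum(labels == 1)
  if (n0 == 0 || n1 == 0) {
    abort("both classes must be present to compute class weights")
  }
  n <- n0 + n1
  c(w_negative = n / (2 * n0), w_positive = n / (2 * n1))
}

learnable_paths <- list(
  c("conv1", "W"), c("conv1", "b"),
  c("bn1", "gamma"), c("bn1", "beta"),
  c("conv2", "W"), c("conv2", "b"),
  c("bn2", "gamma"), c("bn2", "beta"),
  c("fc", "W"), c("fc", "b")
)

sgd_momentum_step <- function(params, grads, velocity, lr, mom) {
  for (p in learnable_paths) {
    v <- mom * velocity[[p[1]]][[p[2]]] - lr * grads[[p[1]]][[p[2]]]
    velocity[[p[1]]][[p[2]]] <- v
    params[[p[1]]][[p[2]]] <- params[[p[1]]][[p[2]]] + v
  }
  list(params = params, velocity = velocity)
}

zero_like_grads <- function(params) {
  out <- list()
  for (p in learnable_paths) {
    out[[p[1]]][[p[2]]] <- params[[p[1]]][[p[2]]] * 0
  }
  out
}

batched_eval_loss <- function(x_all, labels, params, net_config, cw,
                              batch_size = 64L) {
  n <- length(labels)
  p_true <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out <- net_forward_batch(
      x_all[, , , idx, , drop = FALSE], params, net_config, training = FALSE)
    p_true[idx] <- out$probs[cbind(seq_along(idx), labels[idx] + 1L)]
  }
  -mean(cw[labels + 1L] * log(pmax(p_true, 1e-12)))
}

#' Train on one cross-validation split
#'
#' Minimizes the weighted cross-entropy error with SGD-momentum over seeded
#' per-epoch shuffles of the training VOIs (short final batches are kept),
#' evaluating the validation loss in eval mode after every epoch. Training
#' stops when the validation loss has not improved for `patience` epochs, and
#' the parameters from the best-validation epoch are returned. Positives in
#' the training table are expected to be pre-augmented; validation VOIs are
#' never augmented.
#'
#' @param train_vois,val_vois VOI tibbles (see [build_voi_table()]); the
#'   training table must contain both classes.
#' @param net_config A [network_config()].
#' @param train_config A [train_config()].
#' @return A `stenonet_fit` list: `params` (best-epoch weights), `history`
#'   (tibble epoch / train_loss / val_loss), `best_epoch`, `class_weights`.
#' @export
train_one_split <- function(train_vois, val_vois, net_config, train_config) {
  labels <- train_vois$label
  if (length(unique(labels)) < 2) {
    abort("training set must contain both classes")
  }
  cw <- if (identical(train_config$class_weights, "auto")) {
    auto_class_weights(labels)
  } else {
    as.numeric(train_config$class_weights)
  }

  x_train <- stack_vois(train_vois$values)
  x_val <- stack_vois(val_vois$values)
  val_labels <- val_vois$label

  params <- init_network_params(net_config)
  velocity <- zero_like_grads(params)
  n <- length(labels)
  t_all <- onehot(labels)
  w_all <- cw[labels + 1L]

  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  stall <- 0L
  hist_epoch <- integer(0)
  hist_train <- numeric(0)
  hist_val <- numeric(0)

  with_local_seed(train_config$seed, {
    for (epoch in seq_len(train_config$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = train_config$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + train_config$batch_size - 1L, n)]
        xb <- x_train[, , , idx, , drop = FALSE]
        tb <- t_all[idx, , drop = FALSE]
        wb <- w_all[idx]
        fwd <- net_forward_batch(xb, params, net_config, training = TRUE,
                                 keep_cache = TRUE)
        p_true <- rowSums(fwd$probs * tb)
        epoch_loss <- epoch_loss + sum(-wb * log(pmax(p_true, 1e-12)))
        grads <- net_backward_batch(fwd, tb, wb, params)
        upd <- sgd_momentum_step(params, grads, velocity,
                                 train_config$learning_rate,
                                 train_config$momentum)
        params <- upd$params
        velocity <- upd$velocity
        params$bn1$run_mean <- fwd$run_stats$bn1$run_mean
        params$bn1$run_var <- fwd$run_stats$bn1$run_var
        params$bn2$run_mean <- fwd$run_stats$bn2$run_mean
        params$bn2$run_var <- fwd$run_stats$bn2$run_var
      }
      train_loss <- epoch_loss / n
      val_loss <- batched_eval_loss(x_val, val_labels, params, net_config, cw)
      hist_epoch <- c(hist_epoch, epoch)
      hist_train <- c(hist_train, train_loss)
      hist_val <- c(hist_val, val_loss)
      inform(sprintf("epoch %d: train WCEE %.4f, val WCEE %.4f",
                     epoch, train_loss, val_loss))
      if (val_loss < best_val - 1e-9) {
        best_val <- val_loss
        best_params <- params
        best_epoch <- epoch
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= train_config$patience) break
      }
    }
  })

  structure(list(
    params = best_params,
    history = tibble(epoch = hist_epoch, train_loss = hist_train,
                     val_loss = hist_val),
    best_epoch = best_epoch,
    class_weights = cw
  ), class = "stenonet_fit")
}

#' Four-fold patient-level cross-validation
#'
#' Assigns patients to stenosis-balanced folds, then for each of the four
#' rotations trains on two folds (with four-fold rotation augmentation of
#' training positives only), early-stops on the validation fold, and scores
#' the held-out test fold in eval mode. Every retained segment receives
#' exactly one out-of-fold probability score.
#'
#' @param records Segment records (`patient_id`, `segment_id`, `x`, `y`, `z`,
#'   `label`, optionally `has_stent` / `visible_on_cmra`, which are filtered
#'   through [apply_inclusion_filter()] first).
#' @param volumes Named list of patient volumes.
#' @param net_config A [network_config()].
#' @param train_config A [train_config()].
#' @param seed Seed driving fold assignment and per-fold training seeds.
#' @return A `stenonet_cv` list: `scores` (tibble patient_id / segment_id /
#'   label / score / fold), `assignment`, `fits` (per-rotation histories).
#' @export
run_cross_validation <- function(records, volumes, net_config, train_config,
                                 seed = 1L) {
  if (all(c("has_stent", "visible_on_cmra") %in% names(records))) {
    records <- apply_inclusion_filter(records)
  }
  vois <- build_voi_table(records, volumes)
  assignment <- assign_folds(records, n_folds = 4L, seed = seed)
  splits <- make_cv_splits(assignment)

  score_list <- vector("list", 4)
  fit_list <- vector("list", 4)
  for (r in seq_len(4)) {
    tr_pat <- splits$train[[r]]
    va_pat <- splits$validation[[r]]
    te_pat <- splits$test[[r]]
    tr <- dplyr::filter(vois, .data$patient_id %in% tr_pat)
    tr_aug <- dplyr::bind_rows(
      dplyr::filter(tr, .data$label == 0L),
      augment_positives(dplyr::filter(tr, .data$label == 1L))
    )
    va <- dplyr::filter(vois, .data$patient_id %in% va_pat)
    te <- dplyr::filter(vois, .data$patient_id %in% te_pat)

    ncfg <- net_config
    ncfg$init_seed <- net_config$init_seed + 1000L * r
    tcfg <- train_config
    tcfg$seed <- train_config$seed + 1000L * r + as.integer(seed)

    inform(sprintf("CV rotation %d: %d train VOIs (%d augmented), %d val, %d test",
                   r - 1L, nrow(tr_aug), nrow(tr_aug) - nrow(tr), nrow(va),
                   nrow(te)))
    fit <- train_one_split(tr_aug, va, ncfg, tcfg)
    sc <- score_vois(te, fit$params, ncfg)
    sc$fold <- r - 1L
    score_list[[r]] <- dplyr::select(sc, "patient_id", "segment_id", "label",
                                     "score", "fold")
    fit_list[[r]] <- fit[c("history", "best_epoch", "class_weights")]
  }

  structure(list(
    scores = dplyr::bind_rows(score_list),
    assignment = assignment,
    fits = fit_list
  ), class = "stenonet_cv")
}
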