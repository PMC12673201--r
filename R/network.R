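#' Architecture configuration for the two-block weighted 3D CNN
#'
#' The classifier consists of two feature-extracting blocks (3D convolution,
#' batch normalization, ReLU, ceil-mode 2x2x2 max pooling) joined by a fixed
#' Gaussian center-weighting layer, followed by a fully connected layer and a
#' softmax over the two classes. The spatial contract is 21 -> 11 after
#' block 1 and 11 -> 6 after block 2, which forces ceil-mode pooling with
#' window 2 and stride 2; configurations that break the contract are
#' rejected.
#'
#' @param conv_kernel Odd convolution kernel side (same padding), default 3.
#' @param channels_block1,channels_block2 Feature channels per block.
#' @param pool_size,pool_stride Max-pooling window and stride; must both be 2
#'   to satisfy the 21 -> 11 -> 6 shape contract.
#' @param gaussian_sd Standard deviation of the center-weighting Gaussian, in
#'   voxel units on the 11^3 feature map (default 0.75).
#' @param gaussian_peak Peak value of the weight at the map center.
#' @param n_classes Number of output classes (2).
#' @param init_seed Seed for parameter initialization.
#' @return A validated `network_config` object.
#' @export
network_config <- function(conv_kernel = 3L,
                           channels_block1 = 16L,
                           channels_block2 = 32L,
                           pool_size = 2L,
                           pool_stride = 2L,
                           gaussian_sd = 0.75,
                           gaussian_peak = 1.0,
                           n_classes = 2L,
                           init_seed = 1L) {
  cfg <- list(
    conv_kernel = as.integer(conv_kernel),
    channels_block1 = as.integer(channels_block1),
    channels_block2 = as.integer(channels_block2),
    pool_size = as.integer(pool_size),
    pool_stride = as.integer(pool_stride),
    gaussian_sd = gaussian_sd,
    gaussian_peak = gaussian_peak,
    n_classes = as.integer(n_classes),
    init_seed = as.integer(init_seed)
  )
  if (cfg$conv_kernel %% 2L != 1L || cfg$conv_kernel < 1L) {
    abort("conv_kernel must be a positive odd integer (same padding)")
  }
  if (cfg$channels_block1 < 1L || cfg$channels_block2 < 1L) {
    abort("channel counts must be >= 1")
  }
  if (cfg$pool_size != 2L || cfg$pool_stride != 2L) {
    abort(paste0("shape contract violated: ceil-mode pooling with size 2 and ",
                 "stride 2 is required so that 21 -> 11 -> 6; got size ",
                 cfg$pool_size, ", stride ", cfg$pool_stride))
  }
  if (cfg$gaussian_sd <= 0) abort("gaussian_sd must be > 0")
  if (cfg$n_classes != 2L) abort("the classifier is binary (n_classes = 2)")
  stopifnot(ceiling(21 / 2) == 11, ceiling(11 / 2) == 6)
  structure(cfg, class = "network_config")
}

#' Gaussian center weight for the Hadamard weighting layer
#'
#' Builds the fixed (non-learned) weight array applied elementwise to every
#' channel of the block-1 feature maps: `w[v] = peak * exp(-||v - c||^2 /
#' (2 sd^2))` where `c` is the center voxel. The array peaks at `peak` at the
#' center and is symmetric under axis reflections about it.
#'
#' @param map_side Odd side length of the cubic feature map (11 for the
#'   standard architecture; even sides are rejected since the center voxel
#'   would be ambiguous).
#' @param sd Positive standard deviation in voxel units.
#' @param peak Positive peak value at the center.
#' @return A `map_side^3` numeric array.
#' @export
build_gaussian_weight <- function(map_side, sd = 0.75, peak = 1.0) {
  map_side <- as.integer(map_side)
  if (map_side %% 2L != 1L) {
    abort("map_side must be odd: an even map has no center voxel")
  }
  if (!is.numeric(sd) || sd <= 0) abort("sd must be > 0")
  c0 <- (map_side + 1L) / 2
  g1 <- (seq_len(map_side) - c0)^2
  d2 <- outer(outer(g1, g1, "+"), g1, "+")
  array(peak * exp(-d2 / (2 * sd^2)), rep(map_side, 3))
}

#' Initialize network parameters
#'
#' He-uniform initialization for convolution and fully connected weights
#' (limit `sqrt(6 / fan_in)`), zero biases, unit batch-norm scale and zero
#' shift, zero running mean and unit running variance. Seeded by
#' `config$init_seed`.
#'
#' @param config A [network_config()].
#' @return A `network_params` list with components `conv1`, `bn1`, `conv2`,
#'   `bn2`, `fc`.
#' @export
init_network_params <- function(config) {
  k3 <- config$conv_kernel^3
  c1 <- config$channels_block1
  c2 <- config$channels_block2
  he <- function(fan_in, nr, nc) {
    lim <- sqrt(6 / fan_in)
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  params <- with_local_seed(config$init_seed, list(
    conv1 = list(W = he(k3, k3, c1), b = numeric(c1)),
    bn1 = list(gamma = rep(1, c1), beta = numeric(c1),
               run_mean = numeric(c1), run_var = rep(1, c1)),
    conv2 = list(W = he(k3 * c1, k3 * c1, c2), b = numeric(c2)),
    bn2 = list(gamma = rep(1, c2), beta = numeric(c2),
               run_mean = numeric(c2), run_var = rep(1, c2)),
    fc = list(W = he(6^3 * c2, 6^3 * c2, config$n_classes),
              b = numeric(config$n_classes))
  ))
  structure(params, class = "network_params")
}

#' Number of learnable parameters
#'
#' Pure function of the architecture configuration: convolution kernels and
#' biases, batch-norm scale/shift, and the fully connected layer (running
#' statistics are state, not parameters).
#'
#' @param config A [network_config()].
#' @return Integer parameter count.
#' @export
count_params <- function(config) {
  k3 <- config$conv_kernel^3
  c1 <- config$channels_block1
  c2 <- config$channels_block2
  as.integer(k3 * c1 + c1 + 2 * c1 +
               k3 * c1 * c2 + c2 + 2 * c2 +
               6^3 * c2 * config$n_classes + config$n_classes)
}

#' Run one feature-extracting block
#'
#' Applies convolution (same padding), batch normalization (running
#' statistics), ReLU, and ceil-mode 2x2x2 max pooling. Block 1 takes a
#' single-channel 21^3 input and emits 11^3 maps; block 2 takes 11^3
#' multi-channel input and emits 6^3 maps.
#'
#' @param input For block 1 a 21^3 array; for block 2 an 11^3 x channels
#'   array (4D, channels last).
#' @param params A `network_params` object.
#' @param config A [network_config()].
#' @param block_index 1 or 2.
#' @return Feature array with spatial side 11 (block 1) or 6 (block 2) and a
#'   trailing channel dimension.
#' @export
forward_block <- function(input, params, config, block_index) {
  d <- dim(input)
  if (block_index == 1) {
    if (length(d) != 3 || !all(d == 21)) {
      abort(paste0("block 1 expects a 21x21x21 input; got ",
                   paste(d, collapse = "x")))
    }
    x <- array(input, c(d, 1L, 1L))
    cp <- params$conv1; bn <- params$bn1
  } else if (block_index == 2) {
    if (length(d) != 4 || !all(d[1:3] == 11) || d[4] != config$channels_block1) {
      abort(paste0("block 2 expects an 11x11x11x", config$channels_block1,
                   " input; got ", paste(d, collapse = "x")))
    }
    x <- aperm(array(input, c(d[1:3], d[4], 1L)), c(1, 2, 3, 5, 4))
    cp <- params$conv2; bn <- params$bn2
  } else {
    abort("block_index must be 1 or 2")
  }
  cv <- conv3_forward(x, cp$W, cp$b, config$conv_kernel)
  b <- bn_forward(cv$y, bn, training = FALSE)
  y <- maxpool2_forward(pmax(b$y, 0))$y
  dy <- dim(y)
  aperm(y, c(1, 2, 3, 5, 4))[, , , , 1, drop = TRUE] |>
    array(c(dy[1:3], dy[5]))
}

#' Forward pass: VOI to class probabilities
#'
#' Runs a normalized 21^3 patch through block 1, the Gaussian center
#' weighting, block 2, the fully connected layer and softmax, returning the
#' two-class probability vector. Eval mode uses batch-norm running statistics
#' and is fully deterministic.
#'
#' @param voi A 21^3 numeric array (all values finite).
#' @param params A `network_params` object.
#' @param config A [network_config()].
#' @param mode `"eval"` (default, deterministic) or `"train"` (batch
#'   statistics).
#' @return Named numeric vector `c(p_no_stenosis, p_stenosis)` summing to 1.
#' @export
net_forward <- function(voi, params, config, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  d <- dim(voi)
  if (is.null(d) || length(d) != 3 || !all(d == 21)) {
    abort("voi must be a 21x21x21 array")
  }
  if (!all(is.finite(voi))) abort("voi contains non-finite values")
  x <- array(voi, c(21L, 21L, 21L, 1L, 1L))
  out <- net_forward_batch(x, params, config, training = (mode == "train"))
  setNames(as.numeric(out$probs[1, ]), c("p_no_stenosis", "p_stenosis"))
}

#' Score a table of VOIs
#'
#' Deterministic eval-mode forward over a VOI tibble, in batches.
#'
#' @param vois VOI tibble (see [build_voi_table()]).
#' @param params,config Network parameters and configuration.
#' @param batch_size Scoring batch size.
#' @return The input tibble (minus `values`) with a `score` column: the
#'   predicted probability of significant stenosis.
#' @export
score_vois <- function(vois, params, config, batch_size = 32L) {
  n <- nrow(vois)
  score <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- stack_vois(vois$values[idx])
    out <- net_forward_batch(x, params, config, training = FALSE)
    score[idx] <- out$probs[, 2]
  }
  out <- dplyr::select(vois, -"values")
  out$score <- score
  out
}
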