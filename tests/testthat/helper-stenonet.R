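# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (loops, exhaustive scans) and share no code with the
# implementation they check.

# A scored-segment tibble in the shape the evaluation functions expect.
scored <- function(score, label) tibble::tibble(
  segment_id = sprintf("S%03d", seq_along(score)), label = label, score = score)

# Pairwise Mann-Whitney AUC: mean over all positive x negative pairs of
# win = 1, tie = 1/2, loss = 0.
oracle_auc_pairwise <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Exhaustive Youden scan under the rule "score > threshold => positive",
# ties broken toward the lowest threshold.
oracle_youden_scan <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  best <- NULL
  for (t in sort(unique(score))) {
    sens <- mean(pos > t)
    spec <- mean(neg <= t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(threshold = t, sens = sens, spec = spec, j = j)
    }
  }
  best
}

# Elementwise weighted cross-entropy, scalar loops only.
oracle_wcee <- function(y, t, w) {
  n <- nrow(y)
  total <- 0
  for (i in seq_len(n)) {
    s <- 0
    for (k in seq_len(ncol(y))) {
      s <- s + t[i, k] * log(y[i, k])
    }
    total <- total + w[i] * s
  }
  unname(-total / n)
}

# Diameter of a tube on a binary lumen mask: voxel count of the chord
# through the known centerline position, scanned along the tube axis.
oracle_tube_diameters <- function(mask, y0, z0) {
  vapply(seq_len(dim(mask)[1]), function(x) {
    max(sum(mask[x, , z0]), sum(mask[x, y0, ]))
  }, numeric(1))
}

# A minimal VOI tibble of random patches whose class means differ, for fast
# training tests; patches are positive-valued like normalized CMRA patches.
make_toy_vois <- function(n_pos, n_neg, shift = 1.5, seed = 1,
                          patient_prefix = "T") {
  withr::with_seed(seed, {
    n <- n_pos + n_neg
    label <- c(rep(1L, n_pos), rep(0L, n_neg))
    values <- lapply(seq_len(n), function(i) {
      array(abs(rnorm(21^3, mean = 1 + shift * label[i], sd = 0.3)),
            c(21, 21, 21))
    })
    tibble::tibble(
      patient_id = sprintf("%s%02d", patient_prefix, seq_len(n)),
      segment_id = sprintf("%s%02d_S01", patient_prefix, seq_len(n)),
      label = label,
      augmentation_tag = "original",
      values = values
    )
  })
}

# Straight noiseless single-tube phantom used by geometry tests.
straight_tube_config <- function(...) {
  phantom_config(
    n_patients = 1L, segments_per_patient = 1L,
    blur_sigma = 0, noise_sigma = 0, curvature_max = 0,
    patient_scale_sd = 0, mild_narrowing_prob = 0,
    volume_shape = c(64L, 64L, 64L), ...
  )
}
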