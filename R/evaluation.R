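#' ROC curve, AUC and Youden operating point for scored segments
#'
#' The classification rule is `score > threshold => positive`; ties at the
#' threshold count as negative. Candidate thresholds are the sorted unique
#' scores. The AUC is the Mann-Whitney pairwise-comparison estimator (ties
#' counted 1/2), which equals the trapezoidal area under the empirical ROC
#' curve.
#'
#' @param scores A data frame with a numeric `score` column and a binary
#'   `label` column (both classes must be present). Extra columns are kept in
#'   the object for provenance.
#' @return A `roc_result`: `curve` (tibble threshold / sensitivity /
#'   specificity / fpr), `auc`, `n_pos`, `n_neg`, and the Youden operating
#'   point (`youden_threshold`, `sensitivity`, `specificity`, `accuracy`).
#' @export
roc_curve <- function(scores) {
  s <- scores$score
  lab <- as.integer(scores$label)
  if (any(!lab %in% c(0L, 1L)) || anyNA(s)) {
    abort("scores must have binary labels and non-missing scores")
  }
  n_pos <- sum(lab == 1L)
  n_neg <- sum(lab == 0L)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC requires at least one positive and one negative")
  }
  pos <- s[lab == 1L]
  neg <- s[lab == 0L]
  thr <- sort(unique(s))
  sens <- vapply(thr, function(t) mean(pos > t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg <= t), numeric(1))

  r <- rank(s)  # midranks: ties counted 1/2 in the pairwise estimator
  auc <- (sum(r[lab == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]  # ties broken toward lowest threshold
  acc <- (sens[best] * n_pos + spec[best] * n_neg) / (n_pos + n_neg)

  structure(list(
    curve = tibble(threshold = thr, sensitivity = sens, specificity = spec,
                   fpr = 1 - spec),
    auc = auc,
    n_pos = n_pos,
    n_neg = n_neg,
    youden_threshold = thr[best],
    sensitivity = sens[best],
    specificity = spec[best],
    accuracy = acc
  ), class = "roc_result")
}

#' Operating point maximizing the Youden index
#'
#' Returns the threshold maximizing `J = sensitivity + specificity - 1` over
#' the candidate thresholds of a [roc_curve()] result, with ties broken
#' toward the lowest threshold (favoring sensitivity, the screening-relevant
#' choice), and the sensitivity, specificity and accuracy at that threshold.
#'
#' @param roc A `roc_result`.
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `accuracy`, `youden_j`.
#' @export
youden_operating_point <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  tibble(
    threshold = roc$youden_threshold,
    sensitivity = roc$sensitivity,
    specificity = roc$specificity,
    accuracy = roc$accuracy,
    youden_j = roc$sensitivity + roc$specificity - 1
  )
}

# Placement values: V10[i] = mean_j psi(x_i, y_j), V01[j] = mean_i psi(.),
# with psi = 1 / 0.5 / 0 for win / tie / loss of the positive score.
delong_placements <- function(pos, neg) {
  cmp <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two score sets over the same segments,
#' using placement-value covariances. The variance of the AUC difference
#' accounts for the correlation induced by scoring the same cases; the test
#' statistic is `z = (auc_a - auc_b) / sd(diff)` referred to the standard
#' normal (two-sided).
#'
#' @param scores_a,scores_b Data frames with `segment_id`, `label`, `score`;
#'   the (segment, label) support must be identical.
#' @return A `delong_result` tibble row: `auc_a`, `auc_b`, `var_a`, `var_b`,
#'   `cov_ab`, `z`, `p_value`. If the difference has zero variance, `z = 0`
#'   and `p = 1` with a warning.
#' @export
delong_test <- function(scores_a, scores_b) {
  a <- dplyr::arrange(tibble(segment_id = scores_a$segment_id,
                             label = as.integer(scores_a$label),
                             score = scores_a$score), .data$segment_id)
  b <- dplyr::arrange(tibble(segment_id = scores_b$segment_id,
                             label = as.integer(scores_b$label),
                             score = scores_b$score), .data$segment_id)
  if (!identical(a$segment_id, b$segment_id) || !identical(a$label, b$label)) {
    abort("the two score sets must cover the same segments with the same labels")
  }
  pos_idx <- a$label == 1L
  m <- sum(pos_idx)
  n <- sum(!pos_idx)
  if (m == 0 || n == 0) abort("both classes must be present")

  pa <- delong_placements(a$score[pos_idx], a$score[!pos_idx])
  pb <- delong_placements(b$score[pos_idx], b$score[!pos_idx])

  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (var_diff <= .Machine$double.eps) {
    warn("zero variance of the AUC difference; returning z = 0, p = 1")
    z <- 0
    p <- 1
  } else {
    z <- (pa$auc - pb$auc) / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  structure(
    tibble(auc_a = pa$auc, auc_b = pb$auc,
           var_a = S[1, 1], var_b = S[2, 2], cov_ab = S[1, 2],
           z = z, p_value = p),
    class = c("delong_result", "tbl_df", "tbl", "data.frame")
  )
}

#' DeLong variance of a single AUC
#'
#' @param scores Data frame with `label` and `score`.
#' @return Scalar variance estimate of the AUC.
#' @export
delong_variance <- function(scores) {
  lab <- as.integer(scores$label)
  p <- delong_placements(scores$score[lab == 1L], scores$score[lab == 0L])
  var(p$v10) / sum(lab == 1L) + var(p$v01) / sum(lab == 0L)
}

stratify_deciles <- function(x) {
  qs <- unique(quantile(x, probs = seq(0, 1, by = 0.1), type = 7))
  if (length(qs) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = qs, include.lowest = TRUE))
}

# Largest-remainder proportional allocation of n draws over strata of the
# given sizes, capped at stratum size with spillover to spare capacity.
allocate_strata <- function(sizes, n) {
  raw <- n * sizes / sum(sizes)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  over <- pmax(base - sizes, 0)
  base <- pmin(base, sizes)
  spare <- sum(over)
  while (spare > 0) {
    cap <- which(base < sizes)
    take <- cap[order(sizes[cap] - base[cap], decreasing = TRUE)[1]]
    base[take] <- base[take] + 1
    spare <- spare - 1
  }
  as.integer(base)
}

#' Select observer-study cases by stratified random sampling
#'
#' Draws exactly `n_pos` positive and `n_neg` negative segments, stratified
#' over score deciles within each class, redrawing (seeded, up to
#' `max_draws`) until the AUC of the selected subset is within `tolerance`
#' of the full-set AUC; if the cap is reached the best-matching draw is
#' returned.
#'
#' @param pooled_scores Data frame with `segment_id`, `label`, `score`.
#' @param n_pos,n_neg Segments to select per class.
#' @param tolerance Maximum allowed `|AUC(selected) - AUC(all)|`.
#' @param seed Integer seed.
#' @param max_draws Cap on the accept/reject search.
#' @return An `observer_selection`: `selected` (tibble of chosen rows),
#'   `segment_ids`, `auc_subset`, `auc_full`, `auc_diff`, `n_draws`,
#'   `converged`.
#' @export
select_observer_cases <- function(pooled_scores, n_pos = 40L, n_neg = 40L,
                                  tolerance = 0.02, seed = 1L,
                                  max_draws = 10000L) {
  lab <- as.integer(pooled_scores$label)
  if (sum(lab == 1L) < n_pos || sum(lab == 0L) < n_neg) {
    abort("not enough segments in one of the classes for the requested draw")
  }
  auc_full <- roc_curve(pooled_scores)$auc
  pos <- pooled_scores[lab == 1L, , drop = FALSE]
  neg <- pooled_scores[lab == 0L, , drop = FALSE]
  pos_strat <- stratify_deciles(pos$score)
  neg_strat <- stratify_deciles(neg$score)

  draw_class <- function(df, strat, n_want) {
    sizes <- tabulate(strat)
    alloc <- allocate_strata(sizes, n_want)
    idx <- unlist(lapply(seq_along(alloc), function(s) {
      pool <- which(strat == s)
      if (alloc[s] == 0) integer(0) else pool[sample.int(length(pool), alloc[s])]
    }))
    df[idx, , drop = FALSE]
  }

  with_local_seed(seed, {
    best <- NULL
    best_diff <- Inf
    n_draws <- 0L
    converged <- FALSE
    while (n_draws < max_draws) {
      n_draws <- n_draws + 1L
      sel <- dplyr::bind_rows(draw_class(pos, pos_strat, n_pos),
                              draw_class(neg, neg_strat, n_neg))
      d <- abs(roc_curve(sel)$auc - auc_full)
      if (d < best_diff) {
        best <- sel
        best_diff <- d
      }
      if (d <= tolerance) {
        converged <- TRUE
        break
      }
    }
    structure(list(
      selected = as_tibble(best),
      segment_ids = best$segment_id,
      auc_subset = roc_curve(best)$auc,
      auc_full = auc_full,
      auc_diff = best_diff,
      n_draws = n_draws,
      converged = converged
    ), class = "observer_selection")
  })
}

#' Reader-group averaged ROC
#'
#' Computes each reader's ROC and AUC on a common case set, the arithmetic
#' mean AUC, and a vertically averaged curve (mean sensitivity at each
#' false-positive rate over a common grid, linear interpolation between
#' curve vertices).
#'
#' @param ratings Long data frame with `reader_id`, `segment_id`, `label`,
#'   `score`; every reader must rate the same (segment, label) set.
#' @return A `group_roc`: `mean_auc`, `reader_aucs` (named), `curve`
#'   (tibble fpr / mean_tpr / min_tpr / max_tpr), `n_readers`.
#' @export
group_average_roc <- function(ratings) {
  readers <- split(
    tibble(segment_id = ratings$segment_id, label = as.integer(ratings$label),
           score = ratings$score),
    ratings$reader_id
  )
  if (length(readers) < 1) abort("at least one reader required")
  support <- lapply(readers, function(r) {
    r <- dplyr::arrange(r, .data$segment_id)
    paste(r$segment_id, r$label)
  })
  if (length(unique(support)) != 1) {
    abort("all readers must rate the same segments with the same labels")
  }
  rocs <- lapply(readers, roc_curve)
  aucs <- vapply(rocs, function(r) r$auc, numeric(1))

  grid <- sort(unique(c(0, 1, unlist(lapply(rocs, function(r) r$curve$fpr)))))
  tprs <- vapply(rocs, function(r) {
    xy <- dplyr::arrange(
      dplyr::bind_rows(tibble(fpr = c(0, 1), sensitivity = c(0, 1)),
                       r$curve[, c("fpr", "sensitivity")]),
      .data$fpr, .data$sensitivity)
    approx(xy$fpr, xy$sensitivity, xout = grid, ties = max)$y
  }, numeric(length(grid)))
  tprs <- matrix(tprs, nrow = length(grid))

  structure(list(
    mean_auc = mean(aucs),
    reader_aucs = aucs,
    curve = tibble(fpr = grid,
                   mean_tpr = rowMeans(tprs),
                   min_tpr = apply(tprs, 1, min),
                   max_tpr = apply(tprs, 1, max)),
    n_readers = length(readers)
  ), class = "group_roc")
}
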