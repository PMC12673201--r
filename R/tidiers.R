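#' @describeIn roc_curve `tidy()` returns the ROC curve as a tibble, one row
#'   per threshold.
#' @param x A `roc_result`.
#' @param ... Unused.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @describeIn roc_curve `glance()` returns a one-row summary with the AUC
#'   and the Youden operating point.
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
         youden_threshold = x$youden_threshold,
         sensitivity = x$sensitivity, specificity = x$specificity,
         accuracy = x$accuracy)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC over %d positives / %d negatives\n  AUC %.3f\n  Youden threshold %.3f: sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%\n",
    x$n_pos, x$n_neg, x$auc, x$youden_threshold,
    100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy))
  invisible(x)
}

#' @describeIn roc_curve `autoplot()` draws the ROC curve with the Youden
#'   operating point marked.
#' @param object A `roc_result`.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  crv <- dplyr::arrange(object$curve, .data$fpr, .data$sensitivity)
  ggplot2::ggplot(crv, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::annotate("point", x = 1 - object$specificity,
                      y = object$sensitivity, shape = 4, size = 3) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC = %.3f", object$auc),
      subtitle = "x marks the Youden operating point"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @describeIn train_one_split `tidy()` returns the per-epoch loss history.
#' @param x A `stenonet_fit`.
#' @param ... Unused.
#' @method tidy stenonet_fit
#' @export
tidy.stenonet_fit <- function(x, ...) x$history

#' @describeIn train_one_split `glance()` summarises the fit: epochs run,
#'   best epoch and its validation loss.
#' @method glance stenonet_fit
#' @export
glance.stenonet_fit <- function(x, ...) {
  tibble(n_epochs = nrow(x$history),
         best_epoch = x$best_epoch,
         best_val_loss = min(x$history$val_loss),
         final_train_loss = x$history$train_loss[nrow(x$history)])
}

#' @describeIn train_one_split `autoplot()` draws training and validation
#'   loss curves with the best epoch marked.
#' @param object A `stenonet_fit`.
#' @method autoplot stenonet_fit
#' @export
autoplot.stenonet_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                              names_to = "set", values_to = "wcee")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$wcee,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "Epoch", y = "Weighted cross-entropy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn run_cross_validation `tidy()` returns the pooled out-of-fold
#'   score table.
#' @param x A `stenonet_cv`.
#' @param ... Unused.
#' @method tidy stenonet_cv
#' @export
tidy.stenonet_cv <- function(x, ...) x$scores

#' @describeIn run_cross_validation `glance()` returns pooled out-of-fold
#'   performance: AUC and the Youden operating point over all folds.
#' @method glance stenonet_cv
#' @export
glance.stenonet_cv <- function(x, ...) {
  g <- glance(roc_curve(x$scores))
  dplyr::bind_cols(
    tibble(n_segments = nrow(x$scores),
           n_patients = length(unique(x$scores$patient_id))),
    g
  )
}

#' @export
print.stenonet_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Four-fold patient-level CV: %d segments, %d patients\n  pooled out-of-fold AUC %.3f (sens %.1f%%, spec %.1f%%, acc %.1f%% at Youden threshold %.3f)\n",
    g$n_segments, g$n_patients, g$auc, 100 * g$sensitivity,
    100 * g$specificity, 100 * g$accuracy, g$youden_threshold))
  invisible(x)
}

#' @export
print.observer_selection <- function(x, ...) {
  cat(sprintf(
    "Observer-study selection: %d segments (%d positive / %d negative)\n  subset AUC %.3f vs full-set AUC %.3f (|diff| %.4f, %d draw%s%s)\n",
    nrow(x$selected), sum(x$selected$label == 1), sum(x$selected$label == 0),
    x$auc_subset, x$auc_full, x$auc_diff, x$n_draws,
    if (x$n_draws == 1) "" else "s",
    if (x$converged) "" else "; tolerance not met, best draw returned"))
  invisible(x)
}

#' @describeIn group_average_roc `autoplot()` draws the vertically averaged
#'   curve with the per-reader min/max band.
#' @param object A `group_roc`.
#' @param ... Unused.
#' @method autoplot group_roc
#' @export
autoplot.group_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min_tpr,
                                      ymax = .data$max_tpr), alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "Mean sensitivity",
                  title = sprintf("Group mean AUC = %.3f (%d readers)",
                                  object$mean_auc, object$n_readers)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
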