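# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for evaluation and training objects
#'
#' `tidy()` returns the long, per-unit view (per-class metrics, confusion
#' cells, ROC points, per-epoch log rows); `glance()` returns a one-row
#' summary.
#'
#' @param x a `wfpn_metrics`, `wfpn_confusion`, `wfpn_roc`, `wfpn_report`,
#'   `wfpn_eval` or `wfpn_fit` object.
#' @param ... unused.
#' @return A tibble.
#' @name wfpn-tidiers
NULL

#' @rdname wfpn-tidiers
#' @method tidy wfpn_metrics
#' @export
tidy.wfpn_metrics <- function(x, ...) x$per_class

#' @rdname wfpn-tidiers
#' @method glance wfpn_metrics
#' @export
glance.wfpn_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall,
                 macro_f1 = x$macro_f1, n = x$n)
}

#' @rdname wfpn-tidiers
#' @param normalize return row-normalized proportions instead of counts.
#' @method tidy wfpn_confusion
#' @export
tidy.wfpn_confusion <- function(x, normalize = FALSE, ...) {
  m <- if (normalize) normalize_confusion(x) else unclass(x)
  out <- as.data.frame.table(m, responseName = "n")
  tibble::as_tibble(out)
}

#' @rdname wfpn-tidiers
#' @method tidy wfpn_roc
#' @export
tidy.wfpn_roc <- function(x, ...) x$points

#' @rdname wfpn-tidiers
#' @method glance wfpn_roc
#' @export
glance.wfpn_roc <- function(x, ...) {
  tibble::tibble(macro_auc = x$macro_auc)
}

#' @rdname wfpn-tidiers
#' @method tidy wfpn_report
#' @export
tidy.wfpn_report <- function(x, ...) {
  dplyr::left_join(x$metrics$per_class,
                   dplyr::select(x$roc$auc, "class", "auc"),
                   by = "class")
}

#' @rdname wfpn-tidiers
#' @method glance wfpn_report
#' @export
glance.wfpn_report <- function(x, ...) {
  dplyr::bind_cols(glance(x$metrics),
                   tibble::tibble(macro_auc = x$roc$macro_auc))
}

#' @rdname wfpn-tidiers
#' @method tidy wfpn_eval
#' @export
tidy.wfpn_eval <- function(x, ...) tidy(x$report)

#' @rdname wfpn-tidiers
#' @method glance wfpn_eval
#' @export
glance.wfpn_eval <- function(x, ...) glance(x$report)

#' @rdname wfpn-tidiers
#' @method tidy wfpn_fit
#' @export
tidy.wfpn_fit <- function(x, ...) x$log

#' @rdname wfpn-tidiers
#' @method glance wfpn_fit
#' @export
glance.wfpn_fit <- function(x, ...) {
  last <- utils::tail(x$log, 1)
  tibble::tibble(epochs = nrow(x$log), final_loss = last$loss,
                 final_train_acc = last$train_acc,
                 final_val_acc = last$val_acc,
                 best_epoch = x$best$epoch, best_acc = x$best$metric)
}

#' Plot methods for evaluation and training objects
#'
#' `autoplot()` draws one-vs-rest ROC curves (`wfpn_roc`), a confusion
#' heat map (`wfpn_confusion`), or learning curves (`wfpn_fit`).
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @name wfpn-autoplot
NULL

#' @rdname wfpn-autoplot
#' @method autoplot wfpn_roc
#' @export
autoplot.wfpn_roc <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL,
                  title = sprintf("One-vs-rest ROC (macro AUC %.3f)",
                                  object$macro_auc)) +
    ggplot2::theme_minimal()
}

#' @rdname wfpn-autoplot
#' @param normalize plot row-normalized proportions instead of counts.
#' @method autoplot wfpn_confusion
#' @export
autoplot.wfpn_confusion <- function(object, normalize = TRUE, ...) {
  df <- tidy(object, normalize = normalize)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$n, 3)),
                       colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::labs(x = "Predicted", y = "True",
                  fill = if (normalize) "rate" else "count") +
    ggplot2::theme_minimal()
}

#' @rdname wfpn-autoplot
#' @method autoplot wfpn_fit
#' @export
autoplot.wfpn_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log,
                            cols = c("loss", "train_acc", "val_acc"),
                            names_to = "series", values_to = "value")
  df <- dplyr::filter(df, !is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "Epoch", y = NULL) +
    ggplot2::theme_minimal()
}
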