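#' Confusion matrix from prediction records
#'
#' Tabulates true class against predicted class.  `counts[i, j]` is the
#' number of records with true class `i` predicted as class `j`; the total
#' equals the number of records.
#'
#' @param data a data frame of prediction records.
#' @param truth,estimate columns of `data` holding true and predicted class
#'   indices in `1..k` (tidy-eval; bare column names).
#' @param k number of classes. Defaults to the largest label seen.
#' @param labels optional class names (length `k`).
#' @return A `wfpn_confusion` object: an integer `k x k` matrix with class
#'   labels as dimnames.
#' @examples
#' recs <- tibble::tibble(truth = c(1, 1, 2), pred = c(1, 2, 2))
#' confusion_matrix(recs, truth, pred, k = 2)
#' @export
confusion_matrix <- function(data, truth, estimate, k = NULL, labels = NULL) {
  tr <- dplyr::pull(data, {{ truth }})
  pr <- dplyr::pull(data, {{ estimate }})
  if (length(tr) == 0L) stop("no prediction records")
  tr <- as.integer(tr); pr <- as.integer(pr)
  k <- as.integer(k %||% max(tr, pr))
  if (any(tr < 1L | tr > k) || any(pr < 1L | pr > k)) {
    stop("class labels must lie in 1..", k)
  }
  labels <- labels %||% paste0("stage", seq_len(k))
  stopifnot(length(labels) == k)
  cm <- matrix(0L, k, k, dimnames = list(truth = labels, predicted = labels))
  for (i in seq_along(tr)) cm[tr[i], pr[i]] <- cm[tr[i], pr[i]] + 1L
  structure(cm, class = c("wfpn_confusion", "matrix", "array"))
}

#' @export
print.wfpn_confusion <- function(x, ...) {
  cat("Confusion matrix (rows: truth, cols: predicted)\n")
  print(unclass(x))
  invisible(x)
}

# row-normalized by true-class counts; empty rows stay 0
normalize_confusion <- function(cm) {
  rs <- rowSums(cm)
  rs[rs == 0] <- 1
  sweep(unclass(cm), 1L, rs, "/")
}

#' Precision, recall, F1 and accuracy from a confusion matrix
#'
#' One-vs-rest per class: `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2 p r / (p + r)`; overall `accuracy = trace/total` and macro-F1 is
#' the unweighted mean of the per-class F1 values.  Cells with a zero
#' denominator are reported as 0 (with a message), the common convention
#' when a class receives no predictions.
#'
#' @param cm a [confusion_matrix()].
#' @return A `wfpn_metrics` object: list with `per_class` (tibble of class,
#'   tp/fp/fn/tn, precision, recall, f1, support), `accuracy`, `macro_f1`,
#'   and macro precision/recall.
#' @export
prf_accuracy <- function(cm) {
  stopifnot(inherits(cm, "wfpn_confusion"))
  m <- unclass(cm)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  k <- nrow(m)
  tp <- unname(diag(m))
  fp <- unname(colSums(m)) - tp
  fn <- unname(rowSums(m)) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(num, den, what) {
    out <- ifelse(den == 0, 0, num / den)
    if (any(den == 0)) {
      message("0/0 in ", what, " for class(es) ",
              paste(rownames(m)[den == 0], collapse = ", "),
              "; reported as 0")
    }
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  per_class <- tibble::tibble(
    class = rownames(m), tp = tp, fp = fp, fn = fn, tn = tn,
    precision = precision, recall = recall, f1 = f1,
    support = unname(rowSums(m))
  )
  structure(list(per_class = per_class,
                 accuracy = sum(tp) / total,
                 macro_precision = mean(precision),
                 macro_recall = mean(recall),
                 macro_f1 = mean(f1),
                 n = total),
            class = "wfpn_metrics")
}

#' @export
print.wfpn_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro-P %.4f | macro-R %.4f | macro-F1 %.4f (n = %d)\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1, x$n))
  print(x$per_class)
  invisible(x)
}

#' One-vs-rest ROC curves and AUC
#'
#' For every class, treats that class as positive, ranks records by its
#' score column and accumulates the ROC as (FPR, TPR) points at each
#' distinct threshold; the AUC is the trapezoidal area (ties in scores form
#' diagonal segments, matching the rank-statistic definition).  Macro AUC
#' is the unweighted mean of the per-class AUCs; a class absent from the
#' truth has undefined AUC and is dropped from the macro mean with a
#' warning.
#'
#' @param data data frame of prediction records with a truth column and one
#'   numeric score column per class.
#' @param truth column holding true class indices in `1..k` (tidy-eval).
#' @param score_cols names of the per-class score columns, in class order.
#'   Defaults to all columns matching `"^score_"`.
#' @return A `wfpn_roc` object: list with `points` (tibble: class, fpr,
#'   tpr, threshold), `auc` (tibble: class, auc, n_pos), `macro_auc`.
#' @export
roc_auc <- function(data, truth, score_cols = NULL) {
  tr <- as.integer(dplyr::pull(data, {{ truth }}))
  score_cols <- score_cols %||% grep("^score_", names(data), value = TRUE)
  k <- length(score_cols)
  stopifnot(k >= 2L, all(tr >= 1L), all(tr <= k))
  pts <- vector("list", k)
  aucs <- rep(NA_real_, k)
  for (cls in seq_len(k)) {
    pos <- tr == cls
    n1 <- sum(pos); n0 <- sum(!pos)
    s <- data[[score_cols[cls]]]
    if (n1 == 0L || n0 == 0L) {
      warning("class ", cls, " absent from truth (or its complement); ",
              "AUC undefined, excluded from macro mean")
      next
    }
    ord <- order(s, decreasing = TRUE)
    sp <- s[ord]; pp <- pos[ord]
    # collapse ties: cumulative counts at each distinct threshold
    last <- c(diff(sp) != 0, TRUE)
    tps <- cumsum(pp)[last]
    fps <- cumsum(!pp)[last]
    tpr <- c(0, tps / n1)
    fpr <- c(0, fps / n0)
    aucs[cls] <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    pts[[cls]] <- tibble::tibble(class = paste0("stage", cls),
                                 fpr = fpr, tpr = tpr,
                                 threshold = c(Inf, sp[last]))
  }
  structure(list(points = dplyr::bind_rows(pts),
                 auc = tibble::tibble(class = paste0("stage", seq_len(k)),
                                      auc = aucs,
                                      n_pos = vapply(seq_len(k),
                                                     function(cl) sum(tr == cl),
                                                     numeric(1))),
                 macro_auc = mean(aucs, na.rm = TRUE)),
            class = "wfpn_roc")
}

#' @export
print.wfpn_roc <- function(x, ...) {
  cat(sprintf("macro AUC %.4f\n", x$macro_auc))
  print(x$auc)
  invisible(x)
}

#' Full metric report for a set of prediction records
#'
#' Convenience wrapper building the confusion matrix, precision / recall /
#' F1 / accuracy / macro-F1 and the one-vs-rest ROC/AUC in one call.
#'
#' @inheritParams roc_auc
#' @param estimate column of predicted class indices.
#' @param k number of classes.
#' @return A `wfpn_report`: list with `confusion`, `metrics`, `roc`.
#' @export
metric_report <- function(data, truth, estimate, score_cols = NULL, k = NULL) {
  score_cols <- score_cols %||% grep("^score_", names(data), value = TRUE)
  k <- k %||% length(score_cols)
  cm <- confusion_matrix(data, {{ truth }}, {{ estimate }}, k = k)
  structure(list(confusion = cm,
                 metrics = prf_accuracy(cm),
                 roc = roc_auc(data, {{ truth }}, score_cols)),
            class = "wfpn_report")
}

#' @export
print.wfpn_report <- function(x, ...) {
  print(x$metrics)
  cat(sprintf("macro AUC %.4f\n", x$roc$macro_auc))
  invisible(x)
}

#' Write a metric report to disk as plain-text artifacts
#'
#' Writes `confusion.csv`, `confusion_normalized.csv` (row-normalized by
#' true-class counts), `metrics.json`, and one `roc_<class>.csv` per class.
#'
#' @param report a [metric_report()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_metrics <- function(report, dir) {
  stopifnot(inherits(report, "wfpn_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cm <- report$confusion
  utils::write.csv(unclass(cm), file.path(dir, "confusion.csv"))
  utils::write.csv(normalize_confusion(cm),
                   file.path(dir, "confusion_normalized.csv"))
  met <- report$metrics
  jsonlite::write_json(
    list(accuracy = met$accuracy,
         macro_precision = met$macro_precision,
         macro_recall = met$macro_recall,
         macro_f1 = met$macro_f1,
         macro_auc = report$roc$macro_auc,
         n = met$n,
         per_class = met$per_class,
         auc = report$roc$auc),
    file.path(dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  for (cls in unique(report$roc$points$class)) {
    readr::write_csv(
      dplyr::filter(report$roc$points, .data$class == cls),
      file.path(dir, paste0("roc_", cls, ".csv")),
      progress = FALSE
    )
  }
  invisible(dir)
}
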