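# Multi-class evaluation: confusion-matrix metrics, one-vs-rest ROC and
# precision-recall curves, macro averages.

#' One-vs-rest ROC curve and AUC
#'
#' Threshold sweep over the scores; AUC by trapezoidal integration (the
#' Mann-Whitney statistic for distinct scores).
#'
#' @param scores numeric scores (higher = more positive).
#' @param positive logical vector of true positives.
#' @return list with `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc_curve <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  pos <- sum(positive); neg <- sum(!positive)
  if (pos == 0 || neg == 0)
    return(list(fpr = c(0, 1), tpr = c(0, 1), thresholds = c(Inf, -Inf),
                auc = NA_real_))
  ord <- order(scores, decreasing = TRUE)
  lab <- positive[ord]
  sc <- scores[ord]
  tp <- cumsum(lab); fp <- cumsum(!lab)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)   # one point per threshold
  tpr <- c(0, tp[keep] / pos)
  fpr <- c(0, fp[keep] / neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, sc[keep]), auc = auc)
}

#' One-vs-rest precision-recall curve
#' @inheritParams roc_curve
#' @return list with `recall`, `precision`, `thresholds`.
#' @export
pr_curve <- function(scores, positive) {
  pos <- sum(positive)
  if (pos == 0)
    return(list(recall = c(0, 1), precision = c(1, 0), thresholds = c(Inf, -Inf)))
  ord <- order(scores, decreasing = TRUE)
  lab <- positive[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(tp)
  rec <- tp / pos
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  list(recall = c(0, rec[keep]), precision = c(1, prec[keep]),
       thresholds = c(Inf, sc[keep]))
}

softmax_cols <- function(lg) {
  e <- exp(sweep(lg, 2, apply(lg, 2, max)))
  sweep(e, 2, colSums(e), "/")
}

#' Evaluate a classifier on a split
#'
#' Confusion-matrix-derived per-class precision/recall/F1 (one-vs-rest),
#' unweighted macro averages, overall accuracy, and one-vs-rest ROC / PR
#' curves from the softmax scores with macro AUC.  A class absent from the
#' ground truth yields an undefined recall, reported as 0 with a warning.
#'
#' @param model a model (evaluated in eval mode), or `NULL` if `scores` are
#'   supplied directly.
#' @param split list with `x` images and `y` integer labels.
#' @param class_order class names (defaults to [dfu_classes]).
#' @param batch_size forward batch size.
#' @param scores optional pre-computed `(K, N)` score matrix (bypasses the
#'   model).
#' @return object of class `class_metrics`: list with `accuracy`, `per_class`
#'   (data.frame), `macro` (precision/recall/f1/auc), `confusion`, `roc`,
#'   `pr`.
#' @export
evaluate <- function(model, split, class_order = dfu_classes,
                     batch_size = 16L, scores = NULL) {
  y <- split$y
  if (length(y) == 0) stop("evaluate: empty split")
  K <- length(class_order)
  if (is.null(scores)) {
    was_training <- model$training
    set_train(model, FALSE)
    on.exit(set_train(model, was_training))
    n <- length(y)
    scores <- matrix(0, K, n)
    for (ix in batch_slices(n, batch_size)) {
      lg <- dt_no_grad(forward(model, split$x[, , , ix, drop = FALSE]))
      scores[, ix] <- dt_value(lg)
    }
  }
  prob <- softmax_cols(scores)
  pred <- apply(scores, 2, which.max)
  conf <- matrix(0L, K, K, dimnames = list(truth = class_order,
                                           pred = class_order))
  for (i in seq_along(y)) conf[y[i], pred[i]] <- conf[y[i], pred[i]] + 1L
  per <- data.frame(class = class_order, precision = NA_real_,
                    recall = NA_real_, f1 = NA_real_, auc = NA_real_,
                    support = as.integer(table(factor(y, levels = seq_len(K)))))
  roc <- list(); pr <- list()
  for (k in seq_len(K)) {
    tp <- conf[k, k]
    fp <- sum(conf[-k, k])
    fn <- sum(conf[k, -k])
    if (per$support[k] == 0)
      warning("evaluate: class '", class_order[k],
              "' absent from ground truth; recall reported as 0")
    per$precision[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    per$recall[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    per$f1[k] <- if (per$precision[k] + per$recall[k] > 0)
      2 * per$precision[k] * per$recall[k] / (per$precision[k] + per$recall[k])
    else 0
    roc[[class_order[k]]] <- roc_curve(prob[k, ], y == k)
    pr[[class_order[k]]] <- pr_curve(prob[k, ], y == k)
    per$auc[k] <- roc[[class_order[k]]]$auc
  }
  structure(list(accuracy = mean(pred == y),
                 per_class = per,
                 macro = list(precision = mean(per$precision),
                              recall = mean(per$recall),
                              f1 = mean(per$f1),
                              auc = mean(per$auc, na.rm = TRUE)),
                 confusion = conf, roc = roc, pr = pr),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("accuracy: %.4f  macro F1: %.4f  macro AUC: %s\n",
              x$accuracy, x$macro$f1,
              ifelse(is.na(x$macro$auc), "-", sprintf("%.4f", x$macro$auc))))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Write ROC / PR curves as PNG plots
#' @param metrics a `class_metrics` object.
#' @param roc_file,pr_file output paths (NULL to skip one).
#' @export
plot_curves_png <- function(metrics, roc_file = NULL, pr_file = NULL) {
  if (!is.null(roc_file)) {
    grDevices::png(roc_file, width = 600, height = 600)
    plot(0:1, 0:1, type = "l", lty = 2, col = "grey",
         xlab = "False positive rate", ylab = "True positive rate",
         main = "One-vs-rest ROC")
    i <- 1
    for (nm in names(metrics$roc)) {
      lines(metrics$roc[[nm]]$fpr, metrics$roc[[nm]]$tpr, col = i + 1)
      i <- i + 1
    }
    legend("bottomright", legend = names(metrics$roc), col = seq_along(metrics$roc) + 1,
           lty = 1, bty = "n")
    grDevices::dev.off()
  }
  if (!is.null(pr_file)) {
    grDevices::png(pr_file, width = 600, height = 600)
    plot(NULL, xlim = 0:1, ylim = 0:1, xlab = "Recall", ylab = "Precision",
         main = "One-vs-rest precision-recall")
    i <- 1
    for (nm in names(metrics$pr)) {
      lines(metrics$pr[[nm]]$recall, metrics$pr[[nm]]$precision, col = i + 1)
      i <- i + 1
    }
    legend("bottomleft", legend = names(metrics$pr), col = seq_along(metrics$pr) + 1,
           lty = 1, bty = "n")
    grDevices::dev.off()
  }
  invisible(metrics)
}
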