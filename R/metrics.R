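#' Confusion matrix over checklist decisions
#'
#' Compares predicted checklists against gold annotations. Every (post, item)
#' pair contributes exactly one cell: yes/yes is a true positive, no/no a
#' true negative, yes/no a false positive and no/yes a false negative.
#'
#' @param predicted List of `phq_checklist` objects, or of named "yes"/"no"
#'   vectors over S1..S9.
#' @param gold List of named "yes"/"no" annotation vectors over S1..S9.
#' @return Object of class `phq_confusion`: integers `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(predicted, gold) {
  if (length(predicted) != length(gold)) {
    validation_error("predicted and gold must have the same length")
  }
  items <- phq9_items()
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(predicted)) {
    p <- predicted[[i]]
    if (inherits(p, "phq_checklist")) p <- p$answers
    g <- gold[[i]]
    if (is.list(g)) g <- unlist(g)
    if (!all(items %in% names(p)) || !all(items %in% names(g))) {
      validation_error(sprintf("entry %d is missing S1..S9 keys", i))
    }
    py <- p[items] == "yes"
    gy <- g[items] == "yes"
    tp <- tp + sum(py & gy)
    tn <- tn + sum(!py & !gy)
    fp <- fp + sum(py & !gy)
    fn <- fn + sum(!py & gy)
  }
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn), class = "phq_confusion")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall and F1:
#' accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = 2*precision*recall/(precision+recall).
#' Zero-division conventions: precision is 0 when TP+FP = 0, recall is 0
#' when TP+FN = 0, and F1 is 0 when precision+recall = 0 — never NaN.
#'
#' @param cm A `phq_confusion` (or list with TP/TN/FP/FN).
#' @return List of class `phq_metrics` with `accuracy`, `precision`,
#'   `recall`, `f1` and the confusion cells.
#' @export
#' @examples
#' metrics(structure(list(TP = 8, TN = 5, FP = 2, FN = 1), class = "phq_confusion"))
metrics <- function(cm) {
  tp <- cm$TP; tn <- cm$TN; fp <- cm$FP; fn <- cm$FN
  n <- tp + tn + fp + fn
  if (n == 0) validation_error("empty confusion matrix")
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(accuracy = (tp + tn) / n, precision = precision,
                 recall = recall, f1 = f1,
                 confusion = list(TP = tp, TN = tn, FP = fp, FN = fn)),
            class = "phq_metrics")
}

#' Evaluate checklists against gold annotations
#'
#' Convenience wrapper reporting micro (all 9N decisions pooled into one
#' confusion matrix), macro (metrics averaged over the nine items) and
#' per-item views of the same comparison.
#'
#' @inheritParams confusion
#' @param mode `"micro"`, `"macro"`, `"per_item"` or `"all"`.
#' @return For `"micro"` a `phq_metrics`; for `"macro"` a list of averaged
#'   metrics; for `"per_item"` a named list of `phq_metrics`; for `"all"` a
#'   list with all three.
#' @export
evaluate_checklists <- function(predicted, gold, mode = c("micro", "macro", "per_item", "all")) {
  mode <- match.arg(mode)
  items <- phq9_items()
  micro <- metrics(confusion(predicted, gold))
  if (mode == "micro") return(micro)
  pv <- vapply(predicted, function(p) {
    a <- if (inherits(p, "phq_checklist")) p$answers else p
    a[items] == "yes"
  }, logical(9L))
  gv <- vapply(gold, function(g) {
    g <- if (is.list(g)) unlist(g) else g
    g[items] == "yes"
  }, logical(9L))
  per_item <- lapply(seq_along(items), function(k) {
    py <- pv[k, ]; gy <- gv[k, ]
    metrics(structure(list(TP = sum(py & gy), TN = sum(!py & !gy),
                           FP = sum(py & !gy), FN = sum(!py & gy)),
                      class = "phq_confusion"))
  })
  names(per_item) <- items
  if (mode == "per_item") return(per_item)
  macro <- list(
    accuracy = mean(vapply(per_item, `[[`, numeric(1), "accuracy")),
    precision = mean(vapply(per_item, `[[`, numeric(1), "precision")),
    recall = mean(vapply(per_item, `[[`, numeric(1), "recall")),
    f1 = mean(vapply(per_item, `[[`, numeric(1), "f1")))
  if (mode == "macro") return(macro)
  list(micro = micro, macro = macro, per_item = per_item)
}
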