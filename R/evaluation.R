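# Classification performance metrics; the positive class is ASD.

#' Confusion counts for two-class predictions
#'
#' @param predicted,actual label vectors of equal length (values `ASD` /
#'   `control`, case-insensitive).
#' @param positive the positive class (default `"ASD"`).
#' @return an object of class `confusion_counts`: list with `tp`, `fp`,
#'   `tn`, `fn`, `positive`.
#' @export
confusion_counts <- function(predicted, actual, positive = "ASD") {
  if (length(predicted) != length(actual))
    ff_stop("validation", "predicted (%d) and actual (%d) lengths differ",
            length(predicted), length(actual))
  if (length(actual) < 1) ff_stop("validation", "no subjects to evaluate")
  p <- normalize_labels(predicted)
  a <- normalize_labels(actual)
  pos <- normalize_labels(positive)
  structure(list(tp = sum(p == pos & a == pos),
                 fp = sum(p == pos & a != pos),
                 tn = sum(p != pos & a != pos),
                 fn = sum(p != pos & a == pos),
                 positive = pos),
            class = "confusion_counts")
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Standard formulas: accuracy `(tp+tn)/total`, precision `tp/(tp+fp)`,
#' recall `tp/(tp+fn)`, F1 the harmonic mean of precision and recall.
#' A metric whose denominator is zero is reported as 0 with a warning.
#'
#' @param counts a [confusion_counts()].
#' @return list with `accuracy`, `precision`, `recall`, `f1`.
#' @export
compute_metrics <- function(counts) {
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  if (total == 0) ff_stop("validation", "no subjects in confusion counts")
  ratio0 <- function(num, den, what) {
    if (den == 0) {
      ff_warn("%s undefined (zero denominator); reporting 0", what)
      return(0)
    }
    num / den
  }
  precision <- ratio0(counts$tp, counts$tp + counts$fp, "precision")
  recall <- ratio0(counts$tp, counts$tp + counts$fn, "recall")
  list(accuracy = (counts$tp + counts$tn) / total,
       precision = precision,
       recall = recall,
       f1 = f1_score(precision, recall))
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2pr/(p+r)`; 0 when both are 0.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return the F1 score.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Evaluate a trained network on labelled subjects
#'
#' @param net a network (`multimodal`, `resnet3d`, or `mlp`).
#' @param fingerprints `(C, H, W, D, B)` array (or `NULL` for an MLP).
#' @param vectors `(B x P)` matrix (or `NULL` for a ResNet).
#' @param labels true labels (length `B`).
#' @return list with the four metrics plus `counts`.
#' @export
evaluate_network <- function(net, fingerprints = NULL, vectors = NULL, labels) {
  pred <- predict_labels(net, fingerprints, vectors)
  counts <- confusion_counts(pred, labels)
  c(compute_metrics(counts), list(counts = counts))
}

#' Write a metrics report as JSON
#' @param metrics a metrics list (possibly nested).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
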