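#' Build a confusion matrix from predicted and true labels
#'
#' Rows are truth, columns are predictions. Missing predictions (`NA` or
#' empty strings) are mapped to an explicit `"none"` class so that
#' detector-only conditions, which may predict nothing, remain scorable.
#'
#' @param pred,truth Character vectors of equal length.
#' @param classes Optional fixed class order; defaults to the sorted union
#'   of both vectors with `"none"` last.
#' @return An integer matrix of class `confusion_matrix` with `dimnames`
#'   `truth` x `predicted`.
#' @export
build_confusion <- function(pred, truth, classes = NULL) {
  if (length(pred) != length(truth))
    stop("argument error: pred and truth must have equal length")
  pred <- as.character(pred); truth <- as.character(truth)
  pred[is.na(pred) | pred == ""] <- "none"
  if (is.null(classes)) {
    classes <- sort(unique(c(truth, pred)))
    if ("none" %in% classes) classes <- c(setdiff(classes, "none"), "none")
  }
  cm <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Metrics from a confusion matrix
#'
#' Accuracy is `trace / total`. Per class, precision is the diagonal over
#' the column sum, recall the diagonal over the row sum, F1 their harmonic
#' mean; a class never predicted (empty column) gets precision 0 under the
#' default `zero_division = "zero"`, or is excluded from the macro/weighted
#' precision means under `"exclude"`. Macro averages are unweighted means
#' over classes with positive support; weighted averages weight the same
#' classes by support. For single-label data the weighted recall equals the
#' accuracy identically (both are `trace / total`).
#'
#' @param cm A [build_confusion()] matrix with positive total.
#' @param zero_division `"zero"` or `"exclude"`.
#' @return A list of class `metrics_report`: `accuracy`, `per_class` (data
#'   frame with `class`, `precision`, `recall`, `f1`, `support`),
#'   `macro` and `weighted` (named vectors `precision`, `recall`, `f1`),
#'   `total`.
#' @export
compute_metrics <- function(cm, zero_division = c("zero", "exclude")) {
  zero_division <- match.arg(zero_division)
  total <- sum(cm)
  if (total == 0) stop("argument error: empty confusion matrix")
  d <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  precision <- ifelse(predicted > 0, d / predicted, 0)
  recall <- ifelse(support > 0, d / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  keep <- support > 0
  pkeep <- if (zero_division == "exclude") keep & predicted > 0 else keep
  wmean <- function(v, k) sum(v[k] * support[k]) / sum(support[k])
  report <- list(
    accuracy = sum(d) / total,
    per_class = data.frame(class = rownames(cm), precision = precision,
                           recall = recall, f1 = f1,
                           support = as.integer(support),
                           row.names = NULL, stringsAsFactors = FALSE),
    macro = c(precision = mean(precision[pkeep]), recall = mean(recall[keep]),
              f1 = mean(f1[keep])),
    weighted = c(precision = wmean(precision, pkeep),
                 recall = wmean(recall, keep), f1 = wmean(f1, keep)),
    total = as.integer(total)
  )
  structure(report, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d, accuracy = %.3f\n", x$total, x$accuracy))
  cat(sprintf("  macro:    P %.3f  R %.3f  F1 %.3f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  cat(sprintf("  weighted: P %.3f  R %.3f  F1 %.3f\n",
              x$weighted["precision"], x$weighted["recall"], x$weighted["f1"]))
  invisible(x)
}

#' Row-normalize a confusion matrix
#'
#' Each row with positive support is divided by its sum (so it becomes the
#' conditional distribution of predictions given the true class); zero rows
#' stay zero.
#'
#' @param cm A [build_confusion()] matrix.
#' @return A numeric matrix of class `confusion_matrix_norm`.
#' @export
normalize_confusion <- function(cm) {
  rs <- rowSums(cm)
  out <- sweep(unclass(cm), 1, ifelse(rs > 0, rs, 1), "/")
  structure(out, class = c("confusion_matrix_norm", "matrix", "array"))
}

#' Plot a normalized confusion matrix
#'
#' Heatmap with rows = truth, columns = predictions; cells with value zero
#' are left blank.
#'
#' @param cmn A [normalize_confusion()] matrix (a raw count matrix is
#'   normalized first).
#' @param digits Decimals printed in the non-blank cells.
#' @return A ggplot object.
#' @export
plot_confusion <- function(cmn, digits = 2) {
  if (inherits(cmn, "confusion_matrix")) cmn <- normalize_confusion(cmn)
  df <- expand.grid(truth = rownames(cmn), predicted = colnames(cmn),
                    stringsAsFactors = FALSE)
  df$value <- as.vector(unclass(cmn))
  df$shown <- ifelse(df$value > 0, df$value, NA_real_)
  df$label <- ifelse(is.na(df$shown), "", formatC(df$shown, format = "f",
                                                  digits = digits))
  df$truth <- factor(df$truth, levels = rev(rownames(cmn)))
  df$predicted <- factor(df$predicted, levels = colnames(cmn))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$shown)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient(low = "#f7fbff", high = "#08519c",
                                 na.value = "white", limits = c(0, 1),
                                 name = "rate") +
    ggplot2::labs(x = "predicted", y = "truth") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Evaluate annotations against manual ground truth
#'
#' Joins predicted annotations to a manual-label table by `frame_index`,
#' optionally merges both sides through a merge map, and reports the
#' confusion matrix and metrics.
#'
#' @param pred Data frame with `frame_index` and a prediction column
#'   (`resolved_label` by default), or a CSV path.
#' @param truth Data frame with `frame_index` and `label`, or a CSV path
#'   (the output format of a manual annotation tool).
#' @param merge_map Optional merge map applied to both sides; `NULL`
#'   evaluates raw labels.
#' @param pred_col Name of the prediction column in `pred`.
#' @param zero_division Passed to [compute_metrics()].
#' @return A list of class `evaluation_report`: `confusion`, `normalized`,
#'   `metrics`, `n`.
#' @export
evaluate_annotations <- function(pred, truth, merge_map = NULL,
                                 pred_col = "resolved_label",
                                 zero_division = c("zero", "exclude")) {
  if (is.character(pred)) pred <- utils::read.csv(pred, stringsAsFactors = FALSE)
  if (is.character(truth)) truth <- utils::read.csv(truth, stringsAsFactors = FALSE)
  stopifnot("frame_index" %in% names(pred), "frame_index" %in% names(truth),
            pred_col %in% names(pred), "label" %in% names(truth))
  joined <- merge(pred[, c("frame_index", pred_col)],
                  truth[, c("frame_index", "label")], by = "frame_index")
  if (!nrow(joined)) stop("no frames in common between predictions and truth")
  p <- merge_label(joined[[pred_col]], merge_map)
  t <- merge_label(joined$label, merge_map)
  cm <- build_confusion(p, t)
  structure(list(confusion = cm, normalized = normalize_confusion(cm),
                 metrics = compute_metrics(cm, zero_division = zero_division),
                 n = nrow(joined)),
            class = "evaluation_report")
}
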