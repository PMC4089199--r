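#' Build a confusion matrix from actual and predicted labels
#'
#' Rows are actual classes, columns predicted classes, so row sums are the
#' actual class counts and column sums the predicted counts.
#'
#' @param actual Vector of true class labels.
#' @param predicted Vector of predicted class labels, same length.
#' @param classes Ordered class labels; defaults to the levels (or
#'   first-appearance order) of `actual`.
#' @return An integer matrix of class `confusion_matrix` with `dimnames`
#'   `list(actual = classes, predicted = classes)`.
#' @examples
#' confusion_matrix(c("x", "x", "y"), c("x", "y", "y"))
#' @export
confusion_matrix <- function(actual, predicted, classes = NULL) {
  if (length(actual) != length(predicted)) {
    abort("`actual` and `predicted` must have the same length")
  }
  if (length(actual) == 0) abort("empty prediction vectors")
  classes <- classes %||% class_levels(actual)
  bad <- setdiff(unique(c(as.character(actual), as.character(predicted))),
                 classes)
  if (length(bad) > 0) {
    abort(paste0("labels not in `classes`: ", paste(bad, collapse = ", ")))
  }
  cm <- table(factor(actual, levels = classes),
              factor(predicted, levels = classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(actual = classes, predicted = classes))
  structure(cm, class = c("confusion_matrix", class(cm)))
}

new_confusion <- function(counts, classes) {
  m <- matrix(as.integer(counts), nrow = length(classes),
              dimnames = list(actual = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Read / write a confusion matrix TSV
#'
#' The dialect mirrors the usual printed layout: a header row of predicted
#' labels, one row per actual class with its label in the first column,
#' and integer cells.
#'
#' @param path TSV path.
#' @return For the reader, a `confusion_matrix`; the writer invisibly
#'   returns `path`.
#' @export
read_confusion_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  classes <- names(df)[-1]
  counts <- as.matrix(df[, -1])
  suppressWarnings(storage.mode(counts) <- "integer")
  if (anyNA(counts)) abort(paste0("non-integer cells in ", path))
  if (!identical(unname(df[[1]]), classes)) {
    abort("row labels must match column labels, in order")
  }
  new_confusion(counts, classes)
}

#' @rdname read_confusion_tsv
#' @param cm A `confusion_matrix`.
#' @export
write_confusion_tsv <- function(cm, path) {
  classes <- rownames(cm)
  df <- as_tibble(as.data.frame.matrix(cm))
  readr::write_tsv(cbind(tibble(class = classes), df), path)
  invisible(path)
}

#' Per-class and aggregate classification metrics
#'
#' Reduces a multiclass confusion matrix one-vs-rest: for class c,
#' TP = cell (c, c), FN = rest of row c, FP = rest of column c,
#' TN = everything else.  Per class it reports TPR (= sensitivity =
#' recall), FPR, specificity, precision, F-measure and MCC; any 0/0 is
#' defined as 0 and flagged rather than raised, so degenerate runs (a
#' class never predicted) still aggregate.  Macro values are unweighted
#' means over classes; weighted values weight by actual class counts.
#' Accuracy is trace over total.
#'
#' @param cm A `confusion_matrix` (or plain square matrix with dimnames).
#' @return An object of class `evaluation_report`: a list with `per_class`
#'   (tibble), `macro` and `weighted` (named numeric vectors), `accuracy`,
#'   `total` and the matrix itself.  Supports [tidy()] and [glance()].
#' @examples
#' cm <- confusion_matrix(rep(c("a", "b"), c(4, 4)),
#'                        c("a", "a", "a", "b", "b", "b", "b", "a"))
#' evaluation_report(cm)$accuracy
#' @export
evaluation_report <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) abort("confusion matrix must be square")
  total <- sum(cm)
  if (total < 1) abort("confusion matrix must contain at least one count")
  classes <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  per <- purrr::map(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    precision <- safe_div(tp, tp + fp)
    recall <- safe_div(tp, tp + fn)
    mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    tibble(class = classes[i],
           n_actual = tp + fn,
           tp = tp, fp = fp, fn = fn, tn = tn,
           tpr = recall,
           fpr = safe_div(fp, fp + tn),
           sensitivity = recall,
           specificity = safe_div(tn, tn + fp),
           precision = precision,
           recall = recall,
           f_measure = safe_div(2 * precision * recall,
                                precision + recall),
           mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den,
           flagged = (tp + fp) == 0 || (tp + fn) == 0 || mcc_den == 0)
  })
  per_class <- bind_rows(per)
  metric_cols <- c("tpr", "fpr", "sensitivity", "specificity",
                   "precision", "recall", "f_measure", "mcc")
  macro <- purrr::map_dbl(per_class[metric_cols], mean)
  weighted <- purrr::map_dbl(per_class[metric_cols],
                             ~ sum(.x * per_class$n_actual) / total)
  structure(
    list(per_class = per_class, macro = macro, weighted = weighted,
         accuracy = sum(diag(cm)) / total, total = total,
         confusion = new_confusion(cm, classes)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> accuracy =", round(x$accuracy, 4),
      "over", x$total, "sequences\n")
  print(x$per_class[, c("class", "n_actual", "sensitivity", "specificity",
                        "precision", "f_measure", "mcc")])
  invisible(x)
}

#' @describeIn evaluation_report Per-class metric rows as a tibble.
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.evaluation_report <- function(x, ...) x$per_class

#' @describeIn evaluation_report One row with accuracy and the
#'   macro-averaged panel.
#' @exportS3Method generics::glance
glance.evaluation_report <- function(x, ...) {
  as_tibble(c(list(accuracy = x$accuracy, total = x$total),
              as.list(setNames(x$macro, paste0("macro_", names(x$macro))))))
}

#' @describeIn evaluation_report Heatmap of the confusion matrix.
#' @param object An `evaluation_report`.
#' @exportS3Method ggplot2::autoplot
autoplot.evaluation_report <- function(object, ...) {
  cm <- object$confusion
  d <- as_tibble(as.data.frame(as.table(cm), stringsAsFactors = FALSE))
  names(d) <- c("actual", "predicted", "count")
  d$actual <- factor(d$actual, levels = rev(rownames(cm)))
  d$predicted <- factor(d$predicted, levels = colnames(cm))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::theme_minimal()
}
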