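#' Build a confusion matrix
#'
#' Rows are true classes, columns predicted classes.
#'
#' @param truth,estimate equal-length label vectors (factor, character, or
#'   integer indices into `class_names`).
#' @param class_names class labels fixing the matrix order; defaults to the
#'   sorted union of the observed labels (or factor levels).
#' @return a `confusion_matrix`: integer `K x K` matrix with dimnames
#'   `truth` x `estimate`.
#' @examples
#' build_confusion(c("a", "b", "b"), c("a", "b", "a"))
#' @export
build_confusion <- function(truth, estimate, class_names = NULL) {
  if (length(truth) != length(estimate))
    stopf("truth and estimate must have equal length")
  if (is.null(class_names)) {
    class_names <- if (is.factor(truth)) levels(truth)
                   else sort(unique(c(as.character(truth),
                                      as.character(estimate))))
  }
  to_idx <- function(v) {
    if (is.numeric(v) && !is.factor(v)) {
      v <- as.integer(v)
      if (any(v < 1 | v > length(class_names)))
        stopf("label index out of range 1..%d", length(class_names))
      v
    } else {
      i <- match(as.character(v), class_names)
      if (anyNA(i)) stopf("label not among class_names")
      i
    }
  }
  t_i <- to_idx(truth); e_i <- to_idx(estimate)
  K <- length(class_names)
  cm <- matrix(0L, K, K, dimnames = list(truth = class_names,
                                         estimate = class_names))
  for (s in seq_along(t_i)) cm[t_i[s], e_i[s]] <- cm[t_i[s], e_i[s]] + 1L
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

#' Per-class and macro classification metrics
#'
#' One-vs-rest metrics per class, reported as percentages at full internal
#' precision: accuracy `(TP+TN)/N` (the per-class convention under which a
#' class's accuracy can exceed its recall), precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, F-score `2PR/(P+R)`, and G-mean
#' `sqrt(recall * specificity)` — the geometric mean of sensitivity and
#' specificity, robust to class imbalance. Macro values are unweighted
#' means over classes. Ratios with zero numerator and zero denominator are
#' reported as 0 (a zero-support class additionally warns).
#'
#' @param cm a [build_confusion()] matrix (any square count matrix with
#'   dimnames works).
#' @return a `metrics_report` with tibbles `per_class` (columns `class`,
#'   `support`, `accuracy`, `precision`, `recall`, `specificity`,
#'   `f_score`, `g_mean`) and `macro` (one row of the same metrics plus
#'   `micro_accuracy`, the trace over N). Use [round_half_up()] (or the
#'   print method) for 2-decimal report formatting.
#' @export
compute_metrics <- function(cm) {
  cm <- unclass(cm)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) stopf("cm must be square")
  N <- sum(cm)
  if (N == 0) stopf("empty confusion matrix")
  K <- nrow(cm)
  classes <- rownames(cm) %||% as.character(seq_len(K))
  ratio0 <- function(num, den) ifelse(den == 0, 0, num / den)
  tp <- unname(diag(cm))
  fn <- unname(rowSums(cm)) - tp
  fp <- unname(colSums(cm)) - tp
  tn <- N - tp - fn - fp
  if (any(tp + fn == 0))
    warning("zero-support class; its metrics are reported as 0",
            call. = FALSE)
  acc <- (tp + tn) / N
  prec <- ratio0(tp, tp + fp)
  rec <- ratio0(tp, tp + fn)
  spec <- ratio0(tn, tn + fp)
  f1 <- ratio0(2 * prec * rec, prec + rec)
  gm <- sqrt(rec * spec)
  per_class <- tibble::tibble(
    class = classes, support = as.integer(tp + fn),
    accuracy = 100 * acc, precision = 100 * prec, recall = 100 * rec,
    specificity = 100 * spec, f_score = 100 * f1, g_mean = 100 * gm)
  macro <- tibble::tibble(
    accuracy = mean(per_class$accuracy),
    precision = mean(per_class$precision),
    recall = mean(per_class$recall),
    specificity = mean(per_class$specificity),
    f_score = mean(per_class$f_score),
    g_mean = mean(per_class$g_mean),
    micro_accuracy = 100 * sum(tp) / N)
  structure(list(per_class = per_class, macro = macro,
                 confusion = cm, n = N),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  cat(sprintf("<metrics_report: %d samples, %d classes>\n",
              x$n, nrow(x$per_class)))
  pc <- x$per_class
  pc[, -(1:2)] <- lapply(pc[, -(1:2)], round_half_up, digits)
  print(as.data.frame(pc), row.names = FALSE)
  cat("macro:\n")
  print(as.data.frame(lapply(x$macro, round_half_up, digits)),
        row.names = FALSE)
  invisible(x)
}

#' Collapse subclass labels to their superclass
#'
#' Aggregates a subclass confusion matrix into the binary
#' benign-vs-malignant (or any superclass) form by summing the rows and
#' columns that share a superclass.
#'
#' @param cm a [build_confusion()] matrix over subclasses.
#' @param superclass_map named character vector mapping each subclass to
#'   its superclass, e.g. `c(A = "benign", ..., DC = "malignant", ...)`.
#' @return a `confusion_matrix` over the superclasses.
#' @export
collapse_confusion <- function(cm, superclass_map) {
  cm <- unclass(cm)
  classes <- rownames(cm)
  if (is.null(classes) || !all(classes %in% names(superclass_map)))
    stopf("superclass_map must cover every class in cm")
  sup <- superclass_map[classes]
  sup_levels <- unique(unname(superclass_map))
  K <- length(sup_levels)
  out <- matrix(0L, K, K, dimnames = list(truth = sup_levels,
                                          estimate = sup_levels))
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    out[sup[i], sup[j]] <- out[sup[i], sup[j]] + cm[i, j]
  }
  structure(out, class = c("confusion_matrix", "matrix", "array"))
}

#' Evaluate predictions into a metrics report
#'
#' Data-frame-first convenience: builds the confusion matrix from a
#' predictions table and computes all metrics.
#'
#' @param data tibble with a truth column and an estimate column.
#' @param truth,estimate column names (default `"label"`,
#'   `".pred_class"`).
#' @param class_names optional class ordering.
#' @return a `metrics_report`.
#' @export
evaluate_predictions <- function(data, truth = "label",
                                 estimate = ".pred_class",
                                 class_names = NULL) {
  compute_metrics(build_confusion(data[[truth]], data[[estimate]],
                                  class_names))
}
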