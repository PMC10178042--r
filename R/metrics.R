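#' Multiclass confusion matrix
#'
#' Counts matrix with rows = true class, columns = predicted class.
#'
#' @param y_true,y_pred equal-length vectors of integer labels in `0..K-1`.
#' @param k number of classes (default 5).
#' @param class_names names for the label levels.
#' @return A `K x K` integer matrix of class `confusion_matrix` with the
#'   class names as dimnames.
#' @export
confusion <- function(y_true, y_pred, k = 5L,
                      class_names = pesticide_classes[seq_len(k)]) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (length(y_true) && (any(!(y_true %in% 0:(k - 1))) ||
                         any(!(y_pred %in% 0:(k - 1)))))
    stop(sprintf("labels must lie in 0..%d", k - 1))
  counts <- table(factor(y_true, levels = 0:(k - 1)),
                  factor(y_pred, levels = 0:(k - 1)))
  m <- matrix(as.integer(counts), k, k,
              dimnames = list(true = class_names, predicted = class_names))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Per-class one-vs-rest classification metrics
#'
#' For each class `k`: `TP = cm[k, k]`, `FP` = rest of column `k`,
#' `FN` = rest of row `k`, `TN` = everything else; then
#' `precision = TP / (TP + FP)`, `sensitivity = TP / (TP + FN)`,
#' `F1 = 2 P S / (P + S)`. The reported per-class *accuracy* equals the
#' sensitivity (the convention used in per-class result tables for balanced
#' designs); the strict one-vs-rest accuracy `(TP + TN) / total` is exposed
#' separately as `ovr_accuracy`. Zero denominators yield 0 with a warning.
#'
#' @param cm a [confusion()] matrix.
#' @return A `metrics_report`: list with `per_class` (data frame, percentages
#'   at full precision, F1 on 0--1), `overall` (macro row, see
#'   [macro_overall()]), `overall_accuracy_global` and the confusion matrix.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  k <- nrow(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  safe_div <- function(num, den, what, cls) {
    if (den == 0) {
      warning(sprintf("%s undefined for class '%s' (zero denominator); using 0",
                      what, cls))
      return(0)
    }
    num / den
  }
  rows <- lapply(seq_len(k), function(i) {
    cls <- rownames(cm)[i]
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    tn <- total - tp - fp - fn
    prec <- safe_div(tp, tp + fp, "precision", cls)
    sens <- safe_div(tp, tp + fn, "sensitivity", cls)
    f1 <- if (prec + sens == 0) {
      warning(sprintf("F1 undefined for class '%s'; using 0", cls))
      0
    } else 2 * prec * sens / (prec + sens)
    data.frame(class = cls,
               accuracy = 100 * sens,
               precision = 100 * prec,
               sensitivity = 100 * sens,
               f1 = f1,
               ovr_accuracy = 100 * (tp + tn) / total,
               stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  global_acc <- 100 * sum(diag(cm)) / total
  overall <- macro_overall(per_class, accuracy_global = global_acc)
  structure(list(per_class = per_class, overall = overall,
                 overall_accuracy_global = global_acc, confusion = cm),
            class = "metrics_report")
}

#' Macro-averaged overall metrics row
#'
#' Overall precision, sensitivity and F1 are the unweighted means of the
#' per-class values; overall accuracy is the global `correct / total` when
#' available (it equals the macro sensitivity for balanced classes), else the
#' mean per-class accuracy.
#'
#' @param report a `metrics_report` or its `per_class` data frame.
#' @param accuracy_global optional global accuracy percentage.
#' @return One-row data frame with `accuracy`, `precision`, `sensitivity`,
#'   `f1`.
#' @export
macro_overall <- function(report, accuracy_global = NULL) {
  per_class <- if (inherits(report, "metrics_report")) {
    if (is.null(accuracy_global))
      accuracy_global <- report$overall_accuracy_global
    report$per_class
  } else report
  data.frame(
    accuracy = if (is.null(accuracy_global)) mean(per_class$accuracy)
               else accuracy_global,
    precision = mean(per_class$precision),
    sensitivity = mean(per_class$sensitivity),
    f1 = mean(per_class$f1))
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(df) {
    df$accuracy <- sprintf("%.2f", df$accuracy)
    df$precision <- sprintf("%.2f", df$precision)
    df$sensitivity <- sprintf("%.2f", df$sensitivity)
    df$f1 <- sprintf("%.4f", df$f1)
    df
  }
  all_row <- cbind(class = "All", fmt(x$overall))
  body <- fmt(x$per_class[, c("class", "accuracy", "precision",
                              "sensitivity", "f1")])
  print(rbind(all_row, body), row.names = FALSE)
  invisible(x)
}

#' Write metrics reports as a results-table CSV
#'
#' One block per model with an `All` (macro) row followed by the per-class
#' rows; columns `Model,Class,Accuracy,Precision,Sensitivity,F1`, percentages
#' rounded to 2 decimals and F1 to 4, matching the usual presentation of
#' multiclass spectral-classification results.
#'
#' @param reports named list of `metrics_report` objects (names = model
#'   labels), or a single report.
#' @param path output CSV path.
#' @export
write_metrics_csv <- function(reports, path) {
  if (inherits(reports, "metrics_report")) reports <- list(model = reports)
  blocks <- lapply(names(reports), function(nm) {
    rep_ <- reports[[nm]]
    all_row <- data.frame(Model = nm, Class = "All",
                          Accuracy = round(rep_$overall$accuracy, 2),
                          Precision = round(rep_$overall$precision, 2),
                          Sensitivity = round(rep_$overall$sensitivity, 2),
                          F1 = round(rep_$overall$f1, 4))
    pc <- rep_$per_class
    rbind(all_row,
          data.frame(Model = nm, Class = pc$class,
                     Accuracy = round(pc$accuracy, 2),
                     Precision = round(pc$precision, 2),
                     Sensitivity = round(pc$sensitivity, 2),
                     F1 = round(pc$f1, 4)))
  })
  utils::write.csv(do.call(rbind, blocks), path, row.names = FALSE)
  invisible(path)
}

#' Write a confusion matrix as CSV
#'
#' @param cm a [confusion()] matrix.
#' @param path output CSV path.
#' @export
write_confusion_csv <- function(cm, path) {
  stopifnot(inherits(cm, "confusion_matrix"))
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}

#' Published reference metric tables
#'
#' Loads the per-class classification metrics reported for the SWIR melon
#' pesticide-residue models (three classical classifiers, three
#' preprocessing treatments, three metaheuristic-optimised ELMs) that ship
#' with the package as a plain-text fixture. Used to validate the
#' macro-averaging and F1 arithmetic against independently published
#' numbers.
#'
#' @return Data frame with columns `table`, `model`, `class`, `accuracy`,
#'   `precision`, `sensitivity`, `f1`.
#' @export
reference_tables <- function() {
  path <- system.file("extdata", "reference_tables.csv", package = "badgerlm")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
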