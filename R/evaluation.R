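#' Confusion matrix for single-finger classification
#'
#' Builds the 6 x 5 count matrix of predictions (five fingers plus `none`)
#' against actual folded fingers. Column sums equal the trials per actual
#' class. A `none` prediction counts as a false negative for the actual
#' finger and never as a false positive for any finger class.
#'
#' @param predictions character vector over the six prediction classes.
#' @param truths character vector over the five finger classes, same
#'   length.
#' @return Integer matrix of class `finger_confusion`, rows = predictions
#'   (`thumb`, `index`, `middle`, `ring`, `little`, `none`), columns =
#'   actual fingers.
#' @examples
#' cm <- confusion(c("thumb", "thumb", "none"),
#'                 c("thumb", "index", "index"))
#' @export
confusion <- function(predictions, truths) {
  pred_levels <- c(finger_names(), "none")
  if (length(predictions) != length(truths)) {
    stop("predictions and truths must have equal length", call. = FALSE)
  }
  if (length(predictions) > 0) {
    if (!all(predictions %in% pred_levels)) {
      stop("unknown prediction label", call. = FALSE)
    }
    if (!all(truths %in% finger_names())) {
      stop("unknown truth label (must be a finger)", call. = FALSE)
    }
  }
  counts <- table(factor(predictions, levels = pred_levels),
                  factor(truths, levels = finger_names()))
  m <- matrix(as.integer(counts), nrow = 6,
              dimnames = list(prediction = pred_levels,
                              actual = finger_names()))
  structure(m, class = c("finger_confusion", "matrix", "array"))
}

#' @rdname confusion
#' @param counts a 6 x 5 (or 5 x 5, `none` row absent) integer matrix of
#'   counts, rows in prediction order thumb, index, middle, ring, little(,
#'   none).
#' @export
as_confusion <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 5L) counts <- rbind(counts, 0L)
  if (!all(dim(counts) == c(6L, 5L))) {
    stop("counts must be 6 x 5 (predictions x actual)", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  m <- matrix(as.integer(counts), nrow = 6,
              dimnames = list(prediction = c(finger_names(), "none"),
                              actual = finger_names()))
  structure(m, class = c("finger_confusion", "matrix", "array"))
}

#' Per-class metrics from a confusion matrix
#'
#' For a finger class: `TP` is its diagonal cell, `FP` its prediction-row
#' sum minus `TP`, `FN` its actual-column sum minus `TP`, and
#' `TN = total - TP - FP - FN`. Metrics follow the standard definitions
#' `Accuracy = (TP + TN) / (TP + FN + TN + FP)`,
#' `Precision = TP / (TP + FP)`, `Recall = TP / (TP + FN)`,
#' `F1 = 2 * Precision * Recall / (Precision + Recall)` (0 when precision
#' and recall are both 0). Full precision is retained; display rounding is
#' half-away-from-zero at 3 decimals via `metrics_table()`.
#'
#' @param matrix a [confusion()] matrix.
#' @param class one of the five finger labels.
#' @return List with `tp`, `fp`, `fn`, `tn`, `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
class_metrics <- function(matrix, class) {
  stopifnot(inherits(matrix, "finger_confusion"))
  if (!(class %in% finger_names())) stop("unknown class", call. = FALSE)
  total <- sum(matrix)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  if (sum(matrix[, class]) == 0) {
    stop(sprintf("class '%s' never occurs; recall undefined", class),
         call. = FALSE)
  }
  tp <- matrix[class, class]
  fp <- sum(matrix[class, ]) - tp
  fn <- sum(matrix[, class]) - tp
  tn <- total - tp - fp - fn
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = (tp + tn) / total, precision = precision,
       recall = recall, f1 = f1)
}

#' @rdname class_metrics
#' @return `macro_metrics()`: list with `accuracy` and `f1`, the unweighted
#'   means over the five finger classes.
#' @export
macro_metrics <- function(matrix) {
  per <- lapply(finger_names(), function(cl) class_metrics(matrix, cl))
  list(accuracy = mean(vapply(per, `[[`, numeric(1), "accuracy")),
       f1 = mean(vapply(per, `[[`, numeric(1), "f1")))
}

#' @rdname class_metrics
#' @param digits display rounding (half away from zero).
#' @return `metrics_table()`: data frame, one row per finger plus a macro
#'   row, with accuracy, precision, recall and F1.
#' @export
metrics_table <- function(matrix, digits = 3) {
  rows <- lapply(finger_names(), function(cl) {
    m <- class_metrics(matrix, cl)
    data.frame(class = cl,
               accuracy = round_half_up(m$accuracy, digits),
               precision = round_half_up(m$precision, digits),
               recall = round_half_up(m$recall, digits),
               f1 = round_half_up(m$f1, digits))
  })
  mac <- macro_metrics(matrix)
  out <- rbind(do.call(rbind, rows),
               data.frame(class = "macro",
                          accuracy = round_half_up(mac$accuracy, digits),
                          precision = NA_real_, recall = NA_real_,
                          f1 = round_half_up(mac$f1, digits)))
  rownames(out) <- NULL
  out
}
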