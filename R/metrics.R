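#' Confusion matrix with one-vs-rest counts
#'
#' @param true,predicted integer class labels in `1..K`, equal length.
#' @param K number of classes.
#' @return An object of class `confusion_matrix`: `counts` is the `K x K`
#'   matrix (rows = true, columns = predicted), `n` the total, `n_c` the
#'   per-class (true) totals, and `TP`, `FP`, `FN`, `TN` the one-vs-rest
#'   counts per class.
#' @export
confusion <- function(true, predicted, K) {
  if (length(true) != length(predicted))
    stop("label vectors differ in length", call. = FALSE)
  if (anyNA(true) || anyNA(predicted) ||
      !all(c(true, predicted) %in% seq_len(K)))
    stop("labels must be integers in 1..", K, call. = FALSE)
  counts <- matrix(0L, K, K, dimnames = list(true = seq_len(K),
                                             predicted = seq_len(K)))
  for (i in seq_along(true))
    counts[true[i], predicted[i]] <- counts[true[i], predicted[i]] + 1L
  n <- length(true)
  TP <- diag(counts)
  FP <- colSums(counts) - TP
  FN <- rowSums(counts) - TP
  structure(
    list(counts = counts, n = n, n_c = rowSums(counts),
         TP = TP, FP = FP, FN = FN, TN = n - TP - FP - FN),
    class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> n = %d, %d classes\n", x$n,
              nrow(x$counts)))
  print(x$counts)
  invisible(x)
}

.safe_ratio <- function(num, den, what) {
  out <- ifelse(den == 0, 0, num / ifelse(den == 0, 1, den))
  if (any(den == 0))
    warning(what, " undefined (0/0) for class(es) ",
            paste(which(den == 0), collapse = ", "), "; reported as 0",
            call. = FALSE)
  out
}

#' Class-wise and weighted classification metrics
#'
#' Per class: precision `TP / (TP + FP)`, recall `TP / (TP + FN)`,
#' specificity `TN / (TN + FP)`, and F1 as the harmonic mean of precision
#' and recall. The overall accuracy is the recall weighted by the class
#' distribution `n_c / n` — i.e. the fraction of correctly classified
#' samples. Undefined (0/0) ratios are reported as 0 with a warning.
#'
#' @param cm a [confusion()] result.
#' @return An object of class `metrics_report`: `per_class` data.frame with
#'   columns `class`, `n`, `PRC`, `REC`, `SPC`, `F1`; `weighted` named vector
#'   of class-distribution-weighted means; `ACC` overall accuracy.
#' @export
class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$n == 0) stop("empty confusion matrix", call. = FALSE)
  PRC <- .safe_ratio(cm$TP, cm$TP + cm$FP, "precision")
  REC <- .safe_ratio(cm$TP, cm$TP + cm$FN, "recall")
  SPC <- .safe_ratio(cm$TN, cm$TN + cm$FP, "specificity")
  F1 <- .safe_ratio(2 * PRC * REC, PRC + REC, "F1")
  w <- cm$n_c / cm$n
  per_class <- data.frame(class = seq_along(cm$TP), n = cm$n_c,
                          PRC = PRC, REC = REC, SPC = SPC, F1 = F1,
                          row.names = NULL)
  structure(
    list(per_class = per_class,
         weighted = c(PRC = sum(w * PRC), REC = sum(w * REC),
                      SPC = sum(w * SPC), F1 = sum(w * F1)),
         ACC = sum(cm$TP) / cm$n),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> ACC = %.4f\n", x$ACC))
  print(cbind(round(x$per_class[, c("PRC", "REC", "SPC", "F1")], 4),
              n = x$per_class$n))
  cat("weighted means:\n"); print(round(x$weighted, 4))
  invisible(x)
}

#' One-vs-rest precision-recall curves with average-precision AUC
#'
#' For each class, samples are ranked by their score for that class
#' (descending) and precision/recall pairs are computed at every distinct
#' threshold; the AUC is the step-wise average precision
#' `sum_k (R_k - R_{k-1}) P_k`. Classes absent from the truth yield a
#' missing (`NULL`) curve.
#'
#' @param scores `n x K` matrix of per-class scores (one-vs-rest).
#' @param true integer true labels in `1..K`.
#' @return A list of length `K`; element `c` is `NULL` or a list with
#'   `curve` (data.frame `threshold`, `recall`, `precision`) and `auc`.
#' @export
pr_curve <- function(scores, true) {
  stopifnot(is.matrix(scores), nrow(scores) == length(true),
            all(is.finite(scores)))
  K <- ncol(scores)
  lapply(seq_len(K), function(cl) {
    pos <- true == cl
    if (!any(pos)) return(NULL)
    s <- scores[, cl]
    ord <- order(s, decreasing = TRUE)
    s <- s[ord]; pos <- pos[ord]
    tp <- cumsum(pos); fp <- cumsum(!pos)
    last <- !duplicated(s, fromLast = TRUE)   # one point per distinct threshold
    tp <- tp[last]; fp <- fp[last]
    recall <- tp / sum(pos)
    precision <- tp / (tp + fp)
    auc <- sum(diff(c(0, recall)) * precision)
    list(curve = data.frame(threshold = s[last], recall = recall,
                            precision = precision),
         auc = auc)
  })
}
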