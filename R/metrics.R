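# Evaluation statistics: accuracy, Cohen's kappa, Wilcoxon signed-rank.

#' Confusion matrix
#'
#' @param y_true,y_pred Integer class labels in `1..n_classes`.
#' @param n_classes Number of classes.
#' @return `n_classes` x `n_classes` count matrix; rows are true classes,
#'   columns predictions.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = max(y_true, y_pred)) {
  stopifnot(length(y_true) == length(y_pred))
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  cm
}

#' Classification accuracy in percent
#'
#' Fraction of correct predictions (the trace of the confusion matrix over
#' its total), reported in percent.
#'
#' @param y_true,y_pred Label vectors, or pass a confusion matrix as the
#'   single argument.
#' @return Accuracy in `[0, 100]`.
#' @export
accuracy_pct <- function(y_true, y_pred = NULL) {
  if (is.matrix(y_true) && is.null(y_pred)) {
    cm <- y_true
    return(100 * sum(diag(cm)) / sum(cm))
  }
  100 * mean(y_true == y_pred)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(P0 - Pe) / (1 - Pe)` with observed accuracy
#' `P0 = trace(CM)/N` and chance agreement `Pe = sum_k row_k * col_k / N^2`.
#' A degenerate matrix with `Pe = 1` (all mass in one cell) returns 0 with
#' a warning.
#'
#' @param cm Square count matrix (rows true, columns predicted).
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  n <- sum(cm)
  p0 <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("degenerate confusion matrix (Pe = 1); kappa defined as 0")
    return(0)
  }
  (p0 - pe) / (1 - pe)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired scores, dropping zero differences
#' first (Wilcoxon convention) and using the exact null distribution for
#' n <= 25 remaining pairs (normal approximation beyond, or under ties).
#' If every difference is zero the p-value is defined as 1 with a warning.
#'
#' @param a,b Paired score vectors (e.g. per-subject accuracies of two
#'   models).
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  keep <- d != 0
  if (!any(keep)) {
    warning("all paired differences are zero; p-value defined as 1")
    return(1)
  }
  a <- a[keep]; b <- b[keep]
  d <- a - b
  n <- length(d)
  if (n <= 25) {
    # exact sign-flip null distribution of the rank sum, valid under tied
    # ranks (midranks doubled to integers; generating-function convolution)
    r2 <- as.integer(round(2 * rank(abs(d))))
    w_obs <- sum(r2[d > 0])
    counts <- c(1, numeric(sum(r2)))     # counts[s + 1] = #patterns with sum s
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    mu <- sum(r2) / 2
    s <- seq_along(counts) - 1
    p <- sum(counts[abs(s - mu) >= abs(w_obs - mu) - 1e-9]) / 2^n
    return(min(1, p))
  }
  res <- suppressWarnings(
    wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE)
  )
  unname(res$p.value)
}
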