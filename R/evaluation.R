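#' Confusion counts for binary predictions
#'
#' TP counts true self-interacting proteins predicted as interacting, FP
#' non-interacting proteins judged interacting, TN non-interacting
#' predicted correctly, FN interacting proteins judged non-interacting.
#'
#' @param labels true labels, 0/1 (or logical).
#' @param predictions predicted labels, same coding and length.
#' @return Named integer vector \code{c(TP, FP, TN, FN)}.
#' @export
confusionCounts <- function(labels, predictions) {
  labels <- as.integer(as.logical(as.numeric(labels)))
  predictions <- as.integer(as.logical(as.numeric(predictions)))
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  if (length(labels) == 0L) stop("empty input")
  c(TP = sum(labels == 1L & predictions == 1L),
    FP = sum(labels == 0L & predictions == 1L),
    TN = sum(labels == 0L & predictions == 0L),
    FN = sum(labels == 1L & predictions == 0L))
}

#' Scalar metrics from confusion counts
#'
#' Computes
#' \deqn{ACC = \frac{TN + TP}{TN + FN + TP + FP},\quad
#'       TPR = \frac{TP}{FN + TP},\quad
#'       PPV = \frac{TP}{TP + FP},\quad
#'       SPC = \frac{TN}{TN + FP},}
#' and the Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FN)(TP+FP)(TN+FN)(TN+FP)}},}
#' the phi coefficient of the 2x2 table (bounded in [-1, 1] and robust to
#' class skew). A metric whose denominator is zero is reported as
#' \code{NaN} and named in the report's \code{flags} rather than raising,
#' so batch evaluation over degenerate folds keeps going.
#'
#' @param counts named vector with TP, FP, TN, FN (as from
#'   \code{\link{confusionCounts}}).
#' @param auc optional AUC to embed in the report.
#' @return A \code{\linkS4class{MetricsReport}}.
#' @export
computeMetrics <- function(counts, auc = NA_real_) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero")
  sdiv <- function(num, den) if (den == 0) NaN else num / den
  acc <- (tn + tp) / total
  tpr <- sdiv(tp, fn + tp)
  ppv <- sdiv(tp, tp + fp)
  spc <- sdiv(tn, tn + fp)
  mccDen <- sqrt((tp + fn) * (tp + fp) * (tn + fn) * (tn + fp))
  mcc <- if (mccDen == 0) NaN else (tp * tn - fp * fn) / mccDen
  metrics <- c(ACC = acc, TPR = tpr, SPC = spc, PPV = ppv, MCC = mcc)
  flags <- names(metrics)[is.nan(metrics)]
  if (length(flags))
    warning("undefined metrics (zero denominator): ",
            paste(flags, collapse = ", "))
  new("MetricsReport",
      counts = c(TP = as.integer(tp), FP = as.integer(fp),
                 TN = as.integer(tn), FN = as.integer(fn)),
      metrics = metrics, auc = auc, flags = flags)
}

#' ROC curve and AUC
#'
#' The AUC is computed from the tie-corrected rank statistic (equivalent to
#' the Wilcoxon-Mann-Whitney probability that a random positive outranks a
#' random negative, ties counting one half). ROC points come from the
#' score-sorted threshold sweep with tied scores collapsed.
#'
#' @param labels true labels, 0/1.
#' @param scores real-valued classifier scores, higher = more positive.
#' @return list with \code{auc} and a data.frame \code{roc} of
#'   (\code{fpr}, \code{tpr}, \code{threshold}) points.
#' @export
rocAuc <- function(labels, scores) {
  labels <- as.integer(as.logical(as.numeric(labels)))
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L)
    stop("both classes must be present to compute a ROC curve")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - P * (P + 1) / 2) / (P * N)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- c(diff(s) != 0, TRUE)   # last index of each tied block
  tpr <- cumsum(l == 1L)[keep] / P
  fpr <- cumsum(l == 0L)[keep] / N
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, s[keep]))
  list(auc = auc, roc = roc)
}

#' Full evaluation of scored predictions
#'
#' Convenience wrapper: thresholds the scores at 0.5, assembles the
#' confusion counts, the five scalar metrics and the AUC into one report.
#'
#' @param labels true labels, 0/1.
#' @param scores positive-class probabilities.
#' @return A \code{\linkS4class{MetricsReport}} including AUC.
#' @export
evaluateScores <- function(labels, scores) {
  counts <- confusionCounts(labels, as.integer(scores >= 0.5))
  computeMetrics(counts, auc = rocAuc(labels, scores)$auc)
}

#' Write a metrics report
#'
#' @param report a \code{\linkS4class{MetricsReport}}.
#' @param file output path for the JSON report.
#' @param rocFile optional path for the ROC points as two-column TSV.
#' @param roc optional ROC data.frame (from \code{\link{rocAuc}}).
#' @return \code{file}, invisibly.
#' @export
writeMetricsReport <- function(report, file, rocFile = NULL, roc = NULL) {
  out <- list(counts = as.list(report@counts),
              metrics = as.list(report@metrics),
              auc = report@auc, undefined = report@flags)
  jsonlite::write_json(out, file, digits = NA, auto_unbox = TRUE)
  if (!is.null(rocFile) && !is.null(roc))
    utils::write.table(roc, rocFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(file)
}
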