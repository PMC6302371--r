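#' Accessors for package classes
#'
#' \code{profileMatrix} returns the Y x 20 score matrix of a
#' \code{\linkS4class{PSWM}}; \code{momentValues} the complex moment vector
#' of a \code{\linkS4class{ZernikeMomentSet}} (with names "n,m");
#' \code{momentIndices} the index table; \code{nMax} the order cap;
#' \code{isTrained} and \code{trainingLog} the state of an
#' \code{\linkS4class{SLSTMModel}}; \code{metricValues} the named metric
#' vector of a \code{\linkS4class{MetricsReport}}.
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("profileMatrix", function(object) standardGeneric("profileMatrix"))

#' @rdname accessors
#' @export
setMethod("profileMatrix", "PSWM", function(object) object@profile)

#' @rdname accessors
#' @export
setGeneric("momentValues", function(object) standardGeneric("momentValues"))

#' @rdname accessors
#' @export
setMethod("momentValues", "ZernikeMomentSet", function(object) {
  v <- object@values
  names(v) <- paste(object@n, object@m, sep = ",")
  v
})

#' @rdname accessors
#' @export
setGeneric("momentIndices", function(object) standardGeneric("momentIndices"))

#' @rdname accessors
#' @export
setMethod("momentIndices", "ZernikeMomentSet", function(object) {
  data.frame(n = object@n, m = object@m)
})

#' @rdname accessors
#' @export
setGeneric("nMax", function(object) standardGeneric("nMax"))

#' @rdname accessors
#' @export
setMethod("nMax", "ZernikeMomentSet", function(object) object@nMax)

#' @rdname accessors
#' @export
setGeneric("isTrained", function(object) standardGeneric("isTrained"))

#' @rdname accessors
#' @export
setMethod("isTrained", "SLSTMModel", function(object) object@trained)

#' @rdname accessors
#' @export
setGeneric("trainingLog", function(object) standardGeneric("trainingLog"))

#' @rdname accessors
#' @export
setMethod("trainingLog", "SLSTMModel", function(object) object@log)

#' @rdname accessors
#' @export
setGeneric("metricValues", function(object) standardGeneric("metricValues"))

#' @rdname accessors
#' @export
setMethod("metricValues", "MetricsReport", function(object) {
  c(object@metrics, AUC = object@auc)
})

#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(object) standardGeneric("confusionMatrix"))

#' @rdname accessors
#' @export
setMethod("confusionMatrix", "MetricsReport", function(object) object@counts)

setMethod("show", "PSWM", function(object) {
  cat(sprintf("PSWM: %d positions x 20 amino acids\n", nrow(object@profile)))
  cat(sprintf("  score range: [%.3g, %.3g]\n",
              min(object@profile), max(object@profile)))
  if (length(object@residues))
    cat(sprintf("  sequence: %s%s\n",
                paste(utils::head(object@residues, 25), collapse = ""),
                if (length(object@residues) > 25) "..." else ""))
  invisible(object)
})

setMethod("show", "ZernikeMomentSet", function(object) {
  cat(sprintf(
    "ZernikeMomentSet: %d moments, order cap n_max = %d, image %d x %d\n",
    length(object@values), object@nMax, object@imageDim[1],
    object@imageDim[2]))
  invisible(object)
})

setMethod("show", "SLSTMModel", function(object) {
  cat(sprintf("SLSTMModel: %d-%s-%d (%s)\n", object@inputDim,
              paste(object@hidden, collapse = "-"), object@nClasses,
              if (object@trained) "trained" else "untrained"))
  cat(sprintf("  dropout p = %.2f; softmax output head\n", object@dropout))
  if (nrow(object@log))
    cat(sprintf("  trained %d epochs; best validation loss %.4g\n",
                nrow(object@log), min(object@log$valLoss)))
  invisible(object)
})

setMethod("show", "MetricsReport", function(object) {
  ct <- object@counts
  cat(sprintf("MetricsReport (TP=%d FP=%d TN=%d FN=%d)\n",
              ct["TP"], ct["FP"], ct["TN"], ct["FN"]))
  m <- object@metrics
  cat(sprintf("  ACC %.4f  TPR %.4f  SPC %.4f  PPV %.4f  MCC %.4f\n",
              m["ACC"], m["TPR"], m["SPC"], m["PPV"], m["MCC"]))
  if (!is.na(object@auc)) cat(sprintf("  AUC %.4f\n", object@auc))
  if (length(object@flags))
    cat("  undefined (zero denominator):",
        paste(object@flags, collapse = ", "), "\n")
  invisible(object)
})
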