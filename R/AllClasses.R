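#' @import methods
NULL

#' PSI-BLAST amino-acid column order
#'
#' The fixed 20-letter alphabet order used for the columns of every profile
#' matrix in this package. It is the column order of the PSI-BLAST ASCII
#' PSSM log-odds block.
#'
#' @return Character vector of 20 single-letter amino-acid codes.
#' @export
pssmAlphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Position-specific weight matrix for one protein
#'
#' A \code{PSWM} holds the Y x 20 matrix of per-position amino-acid scores
#' for a single protein: one row per sequence position, one column per
#' amino acid in the fixed alphabet order of \code{\link{pssmAlphabet}}.
#' Entries are typically PSI-BLAST log-odds scores; high values mark
#' evolutionarily conserved positions.
#'
#' @slot profile numeric matrix, Y x 20, all entries finite.
#' @slot residues character vector of residue letters per position (may be
#'   empty when the profile was built from a frequency matrix).
#' @slot alphabet character(20), the column order.
#'
#' @seealso \code{\link{parsePsiblastPssm}}, \code{\link{buildPSWM}}
#' @export
setClass("PSWM",
  representation(profile = "matrix", residues = "character",
                 alphabet = "character"),
  prototype(residues = character(0), alphabet = character(0))
)

setValidity("PSWM", function(object) {
  p <- object@profile
  if (!is.numeric(p)) return("profile must be a numeric matrix")
  if (ncol(p) != 20L) return("profile must have exactly 20 columns")
  if (nrow(p) < 1L) return("profile must have at least one row (Y >= 1)")
  if (!all(is.finite(p))) return("profile entries must all be finite")
  if (length(object@alphabet) != 20L)
    return("alphabet must contain 20 amino-acid letters")
  if (length(object@residues) > 0L &&
      length(object@residues) != nrow(p))
    return("residues, when present, must have one letter per profile row")
  TRUE
})

#' Construct a PSWM
#'
#' @param profile numeric matrix with 20 columns (positions x amino acids).
#' @param residues optional character vector of residue letters, one per row.
#' @param alphabet column order; defaults to the PSI-BLAST order.
#' @return A \code{\linkS4class{PSWM}} object.
#' @examples
#' m <- matrix(rnorm(60), nrow = 3, ncol = 20)
#' PSWM(m)
#' @export
PSWM <- function(profile, residues = character(0),
                 alphabet = pssmAlphabet()) {
  profile <- as.matrix(profile)
  storage.mode(profile) <- "double"
  new("PSWM", profile = profile, residues = as.character(residues),
      alphabet = alphabet)
}

#' Set of complex Zernike moments of one profile image
#'
#' Stores the complex moments \eqn{A_{nm}} of a disk-mapped profile for all
#' valid index pairs with \eqn{0 \le n \le n_{max}}, \eqn{m \ge 0},
#' \eqn{n - m} even. Negative repetitions are never stored: they follow
#' from the conjugate symmetry \eqn{A_{n,-m} = \overline{A_{nm}}} and are
#' available through \code{\link{momentAt}}.
#'
#' @slot values complex vector of moments, aligned with \code{n} and \code{m}.
#' @slot n integer vector of orders.
#' @slot m integer vector of (non-negative) repetitions.
#' @slot nMax integer, the order cap the set was computed to.
#' @slot imageDim integer(2), the row/column dimensions of the source matrix.
#' @export
setClass("ZernikeMomentSet",
  representation(values = "complex", n = "integer", m = "integer",
                 nMax = "integer", imageDim = "integer")
)

setValidity("ZernikeMomentSet", function(object) {
  k <- length(object@values)
  if (length(object@n) != k || length(object@m) != k)
    return("values, n and m must have equal length")
  if (any(object@m < 0L)) return("stored repetitions must satisfy m >= 0")
  if (any(object@m > object@n)) return("indices must satisfy m <= n")
  if (any((object@n - object@m) %% 2L != 0L))
    return("indices must satisfy n - m even")
  if (length(object@nMax) != 1L || object@nMax < 0L)
    return("nMax must be a single non-negative integer")
  TRUE
})

#' Stacked peephole-LSTM classifier
#'
#' Holds the parameters of a stacked long short-term memory network: an
#' ordered list of hidden layers of peephole memory blocks, a softmax output
#' head, and the dropout configuration. Created untrained by
#' \code{\link{newSLSTMModel}} and fitted by \code{\link{trainSLSTM}}.
#'
#' @slot inputDim integer, dimension of the input feature vectors.
#' @slot hidden integer vector, memory blocks per hidden layer.
#' @slot nClasses integer, output classes (2 for SIP prediction).
#' @slot layers list of per-layer parameter lists (Wi, Wf, Wo, Wc, bi, bf,
#'   bo, bc).
#' @slot head list with softmax weights \code{Ws} and bias \code{bs}.
#' @slot dropout numeric in [0, 1), probability of discarding a hidden unit
#'   during training.
#' @slot eq12AsPrinted logical; keep \code{FALSE} for the standard block
#'   output \eqn{h_t = \tanh(C_t) * o_t} (see the methods vignette).
#' @slot trained logical flag.
#' @slot log data.frame of per-epoch training/validation losses.
#' @slot seed integer seed used at initialisation.
#' @export
setClass("SLSTMModel",
  representation(inputDim = "integer", hidden = "integer",
                 nClasses = "integer", layers = "list", head = "list",
                 dropout = "numeric", eq12AsPrinted = "logical",
                 chunks = "integer", trained = "logical",
                 log = "data.frame", seed = "integer")
)

setValidity("SLSTMModel", function(object) {
  if (length(object@dropout) != 1L || object@dropout < 0 ||
      object@dropout >= 1)
    return("dropout probability must lie in [0, 1)")
  if (length(object@layers) != length(object@hidden))
    return("one parameter set per hidden layer is required")
  if (object@inputDim < 1L) return("inputDim must be positive")
  for (l in seq_along(object@layers)) {
    par <- object@layers[[l]]
    if (!all(c("Wi", "Wf", "Wo", "Wc", "bi", "bf", "bo", "bc") %in%
             names(par)))
      return(sprintf("layer %d is missing gate parameters", l))
    if (!all(vapply(par, function(w) all(is.finite(w)), logical(1))))
      return(sprintf("layer %d contains non-finite parameters", l))
  }
  TRUE
})

#' Binary-classifier evaluation report
#'
#' Confusion counts together with the five scalar metrics (ACC, TPR, SPC,
#' PPV, MCC) and, when scores are available, the area under the ROC curve.
#' Metrics whose denominator vanishes are reported as \code{NaN} and listed
#' in \code{flags} instead of raising an error, so batch reports survive
#' degenerate folds.
#'
#' @slot counts named integer(4): TP, FP, TN, FN.
#' @slot metrics named numeric: ACC, TPR, SPC, PPV, MCC.
#' @slot auc numeric(1), NA when not computed.
#' @slot flags character vector naming metrics that were undefined.
#' @export
setClass("MetricsReport",
  representation(counts = "integer", metrics = "numeric", auc = "numeric",
                 flags = "character")
)

setValidity("MetricsReport", function(object) {
  if (!all(c("TP", "FP", "TN", "FN") %in% names(object@counts)))
    return("counts must be named TP, FP, TN, FN")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  ok <- object@metrics[c("ACC", "TPR", "SPC", "PPV")]
  ok <- ok[is.finite(ok)]
  if (any(ok < 0 | ok > 1)) return("rate metrics must lie in [0, 1]")
  mcc <- object@metrics[["MCC"]]
  if (is.finite(mcc) && (mcc < -1 - 1e-12 || mcc > 1 + 1e-12))
    return("MCC must lie in [-1, 1]")
  TRUE
})
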