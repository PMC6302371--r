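## Synthetic profile generator with a planted, extractor-recoverable class
## signal. The positive-class pattern lives in the span of a few low-order
## Zernike basis functions, so the magnitude features at those indices
## separate the classes by construction; everything downstream (disk
## mapping, moments, PCA, classifier) can therefore be validated end to
## end without any external database.

## Indices carrying the planted signal. Low orders survive both the
## logistic squashing and integer rounding of the ASCII round trip.
.plantedIndices <- function() {
  data.frame(n = c(2L, 3L, 4L, 5L), m = c(2L, 1L, 4L, 3L))
}

## Unit-RMS spatial pattern on the Y x 20 grid (zero outside the disk).
.plantedPattern <- function(nr, nc = 20L) {
  g <- .diskGrid(nr, nc)
  idx <- .plantedIndices()
  v <- rep(0, length(g$rho))
  for (j in seq_len(nrow(idx)))
    v <- v + Re(zernikeBasis(idx$n[j], idx$m[j], g$rho, g$theta)) +
             Im(zernikeBasis(idx$n[j], idx$m[j], g$rho, g$theta))
  v <- v / sqrt(mean(v^2))
  out <- matrix(0, nr, nc)
  out[g$inside] <- v
  out
}

#' Generate one synthetic profile matrix
#'
#' Produces a Y x 20 PSWM-shaped matrix: a smooth low-order spatial
#' pattern (a fixed combination of Zernike basis functions) scaled by
#' \code{classSignal}, plus i.i.d. Gaussian noise. With
#' \code{classSignal = 0} the matrix is pure noise; with a strong signal
#' the planted moment magnitudes dominate, so the class structure is
#' recoverable by the Zernike feature extractor by construction.
#'
#' @param length number of sequence positions Y (rows).
#' @param classSignal amplitude of the planted pattern (0 for the null
#'   class).
#' @param noiseScale standard deviation of the additive noise.
#' @param seed optional integer seed for this single profile.
#' @return A \code{\linkS4class{PSWM}} with random residue letters.
#' @export
generatePSWM <- function(length, classSignal = 0, noiseScale = 1,
                         seed = NULL) {
  if (length < 1) stop("invalid length")
  if (!is.null(seed)) set.seed(seed)
  mat <- classSignal * .plantedPattern(length) +
    matrix(stats::rnorm(length * 20L, sd = noiseScale), length, 20L)
  PSWM(mat, residues = sample(pssmAlphabet(), length, replace = TRUE))
}

#' Synthetic dataset configuration
#'
#' Defaults mirror the class skew of the yeast SIP benchmark (710 positives
#' to 5511 negatives, about 1:7.7) at a desk-scale total of 800 proteins,
#' with residue counts in the curated 50--5000 range.
#'
#' @param nPositive,nNegative class sizes.
#' @param lengthRange integer range of sequence lengths (residues).
#' @param signalStrength planted-pattern amplitude for the positive class.
#' @param noiseScale noise standard deviation.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return list of class \code{synthConfig}.
#' @export
synthConfig <- function(nPositive = 92L, nNegative = 708L,
                        lengthRange = c(50L, 300L), signalStrength = 3,
                        noiseScale = 1, seed = 1L) {
  stopifnot(nPositive >= 0, nNegative >= 0, lengthRange[1] >= 1,
            lengthRange[2] >= lengthRange[1], noiseScale > 0,
            signalStrength >= 0)
  structure(list(nPositive = as.integer(nPositive),
                 nNegative = as.integer(nNegative),
                 lengthRange = as.integer(lengthRange),
                 signalStrength = signalStrength, noiseScale = noiseScale,
                 seed = as.integer(seed)),
            class = "synthConfig")
}

## Stratified 40/30/30 split of n items (returns character vector).
.splitClass <- function(n) {
  nTrain <- round(0.4 * n); nVal <- round(0.3 * n)
  parts <- c(rep("train", nTrain), rep("val", nVal),
             rep("test", n - nTrain - nVal))
  parts[sample.int(n)]
}

#' Generate a labeled synthetic dataset with a 40/30/30 split
#'
#' Draws positive profiles (planted signal) and negative profiles (pure
#' noise) and assigns every record to the training (40\%), validation
#' (30\%) or test (30\%) partition by stratified random sampling, so each
#' partition preserves the class ratio to within one sample.
#'
#' @param config a \code{\link{synthConfig}}.
#' @return list with \code{records} (data.frame: id, label, split, length)
#'   and \code{pswms} (named list of \code{\linkS4class{PSWM}}).
#' @export
generateDataset <- function(config = synthConfig()) {
  set.seed(config$seed)
  nP <- config$nPositive; nN <- config$nNegative
  n <- nP + nN
  if (n < 1L) stop("dataset must contain at least one record")
  if ((nP > 0L && nP < 3L) || (nN > 0L && nN < 3L))
    stop("class counts too small to stratify a 40/30/30 split")
  label <- c(rep(1L, nP), rep(0L, nN))
  len <- sample(seq.int(config$lengthRange[1], config$lengthRange[2]),
                n, replace = TRUE)
  split <- character(n)
  split[label == 1L] <- .splitClass(nP)
  split[label == 0L] <- .splitClass(nN)
  pswms <- vector("list", n)
  for (i in seq_len(n)) {
    amp <- if (label[i] == 1L) config$signalStrength else 0
    pswms[[i]] <- generatePSWM(len[i], classSignal = amp,
                               noiseScale = config$noiseScale)
  }
  ids <- sprintf("SYN%05d", seq_len(n))
  names(pswms) <- ids
  list(records = data.frame(id = ids, label = label, split = split,
                            length = len, stringsAsFactors = FALSE),
       pswms = pswms)
}

#' Write a synthetic dataset to disk
#'
#' Profiles are written in the same ASCII PSSM dialect the parser reads
#' (scores rounded to integers, as PSI-BLAST prints them), together with a
#' TSV manifest of id, label, split and length.
#'
#' @param dataset result of \code{\link{generateDataset}}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(dataset$pswms))
    writePssmFile(dataset$pswms[[id]],
                  file.path(dir, paste0(id, ".pssm")), id = id)
  utils::write.table(dataset$records, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
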