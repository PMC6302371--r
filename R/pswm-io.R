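#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the standard layout written by \code{psiblast -out_ascii_pssm}:
#' header lines, then one row per residue carrying the position index, the
#' residue letter, 20 integer log-odds scores and (optionally) 20 weighted
#' percentage columns plus information-content fields. Only the log-odds
#' block is kept; the percentage block, when present, is ignored.
#'
#' @param file path to an ASCII PSSM file, or \code{NULL} when \code{text}
#'   is given.
#' @param text character scalar (or vector of lines) with the file content.
#' @return A \code{\linkS4class{PSWM}} whose rows are the residue positions
#'   and whose residue letters are kept for diagnostics.
#' @examples
#' txt <- c("", "Last position-specific scoring matrix computed",
#'   paste(" ", paste(pssmAlphabet(), collapse = "  ")),
#'   paste("    1 M ", paste(1:20, collapse = " ")))
#' parsePsiblastPssm(text = txt)
#' @export
parsePsiblastPssm <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply either 'file' or 'text'")
    text <- readLines(file, warn = FALSE)
  }
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(text) == 0L || all(!nzchar(trimws(text))))
    stop("empty PSSM input: no content to parse")

  rowPattern <- "^\\s*([0-9]+)\\s+([A-Za-z*])\\s+(.*)$"
  isRow <- grepl(rowPattern, text)
  if (!any(isRow))
    stop("no residue rows found: input does not look like an ASCII PSSM")

  idx <- which(isRow)
  pos <- integer(0); res <- character(0); rows <- list()
  for (i in idx) {
    ln <- text[i]
    p <- as.integer(sub(rowPattern, "\\1", ln))
    r <- sub(rowPattern, "\\2", ln)
    rest <- strsplit(trimws(sub(rowPattern, "\\3", ln)), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(rest))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 20L)
      stop(sprintf(
        "line %d: expected 20 score fields, found %d", i, length(vals)))
    pos <- c(pos, p); res <- c(res, r)
    rows[[length(rows) + 1L]] <- vals[1:20]
  }
  if (!all(pos == seq_along(pos)))
    stop(sprintf(
      "non-contiguous position indices at line %d (position %d after %d rows)",
      idx[which(pos != seq_along(pos))[1]],
      pos[which(pos != seq_along(pos))[1]],
      which(pos != seq_along(pos))[1] - 1L))

  mat <- do.call(rbind, rows)
  colnames(mat) <- pssmAlphabet()
  PSWM(mat, residues = res)
}

#' Write a PSWM in the PSI-BLAST ASCII dialect
#'
#' Writes a profile in the same layout \code{\link{parsePsiblastPssm}}
#' reads, with scores rounded to integers as PSI-BLAST prints them. The
#' round trip through write/parse therefore preserves integer-valued
#' profiles exactly.
#'
#' @param pswm a \code{\linkS4class{PSWM}}.
#' @param file output path.
#' @param id optional identifier echoed into the header.
#' @return The path, invisibly.
#' @export
writePssmFile <- function(pswm, file, id = "protein") {
  stopifnot(is(pswm, "PSWM"))
  m <- round(profileMatrix(pswm))
  res <- pswm@residues
  if (length(res) == 0L) res <- rep("X", nrow(m))
  header <- c(
    "",
    sprintf("Last position-specific scoring matrix computed for %s", id),
    paste("           ", paste(sprintf("%3s", pssmAlphabet()),
                               collapse = " ")))
  body <- vapply(seq_len(nrow(m)), function(u) {
    sprintf("%5d %s %s", u, res[u],
            paste(sprintf("%3d", as.integer(m[u, ])), collapse = " "))
  }, character(1))
  writeLines(c(header, body), file)
  invisible(file)
}

#' Build a PSWM from a frequency matrix and a substitution matrix
#'
#' Each profile entry is the inner product of the position's amino-acid
#' frequencies with the substitution-matrix row of the target amino acid:
#' \deqn{M_{uj} = \sum_{k=1}^{20} p(u,k)\, w(j,k),}
#' i.e. the matrix product \code{freq \%*\% t(subst)}. This is the standard
#' construction of a position-specific weight matrix from observed residue
#' frequencies and a mutation (substitution) matrix.
#'
#' @param freq numeric matrix, Y x 20, non-negative position frequencies
#'   \eqn{p(u,k)}.
#' @param subst numeric 20 x 20 substitution matrix \eqn{w(v,k)} in the
#'   same alphabet order.
#' @return A \code{\linkS4class{PSWM}}.
#' @export
buildPSWM <- function(freq, subst) {
  freq <- as.matrix(freq); subst <- as.matrix(subst)
  if (ncol(freq) != 20L)
    stop("frequency matrix must have 20 columns")
  if (!all(dim(subst) == c(20L, 20L)))
    stop("substitution matrix must be 20 x 20")
  if (any(freq < 0))
    stop("frequency matrix entries must be non-negative")
  PSWM(freq %*% t(subst))
}

#' Curate a protein record table into positive and negative SIP sets
#'
#' Applies the dataset-curation rules for self-interacting protein (SIP)
#' benchmarks. Records are first filtered on length: sequences shorter than
#' 50 or longer than 5000 residues are removed. Among the survivors, a
#' record enters the \emph{positive} set when its self-interaction evidence
#' meets at least one of:
#' \itemize{
#'   \item (a) at least two large-scale (mass) experiments, or one
#'     small-scale experiment;
#'   \item (b) an explicit homooligomer annotation;
#'   \item (c) self-interaction reported by more than one publication.
#' }
#' Records with no self-interaction evidence of any kind form the
#' \emph{negative} set. Records with some evidence that meets none of the
#' criteria are quarantined as \emph{ambiguous} rather than silently treated
#' as negatives, to avoid label contamination.
#'
#' @param records data.frame with columns \code{id}, \code{length},
#'   \code{largeScale} (count of large-scale experiments),
#'   \code{smallScale} (count of small-scale experiments),
#'   \code{homooligomer} (logical annotation flag) and
#'   \code{publications} (count of publications reporting the
#'   self-interaction). Missing evidence columns default to zero/FALSE.
#' @return A list of data.frames \code{positives}, \code{negatives},
#'   \code{ambiguous}, \code{removed}; the four parts partition the input.
#' @examples
#' recs <- data.frame(id = c("P1", "P2", "P3"),
#'   length = c(30, 300, 300), largeScale = c(0, 2, 0),
#'   smallScale = 0, homooligomer = FALSE, publications = 0)
#' curateRecords(recs)
#' @export
curateRecords <- function(records) {
  records <- as.data.frame(records)
  if (!all(c("id", "length") %in% names(records)))
    stop("records must have 'id' and 'length' columns")
  if (any(is.na(records$length)))
    stop("every record must have a length")
  n <- nrow(records)
  ls <- if ("largeScale" %in% names(records)) records$largeScale else rep(0, n)
  ss <- if ("smallScale" %in% names(records)) records$smallScale else rep(0, n)
  ho <- if ("homooligomer" %in% names(records)) records$homooligomer
        else rep(FALSE, n)
  pub <- if ("publications" %in% names(records)) records$publications
         else rep(0, n)
  ls[is.na(ls)] <- 0; ss[is.na(ss)] <- 0; pub[is.na(pub)] <- 0
  ho[is.na(ho)] <- FALSE

  removed <- records$length < 50 | records$length > 5000
  meetsA <- ls >= 2 | ss >= 1
  meetsB <- as.logical(ho)
  meetsC <- pub >= 2
  positive <- !removed & (meetsA | meetsB | meetsC)
  noEvidence <- ls == 0 & ss == 0 & !meetsB & pub == 0
  negative <- !removed & noEvidence
  ambiguous <- !removed & !positive & !negative

  list(positives = records[positive, , drop = FALSE],
       negatives = records[negative, , drop = FALSE],
       ambiguous = records[ambiguous, , drop = FALSE],
       removed = records[removed, , drop = FALSE])
}

#' Write curated accession lists
#'
#' @param curated result of \code{\link{curateRecords}}.
#' @param dir output directory; \code{positives.txt} and
#'   \code{negatives.txt} are written with one accession per line.
#' @return The directory, invisibly.
#' @export
writeCuratedLists <- function(curated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(as.character(curated$positives$id),
             file.path(dir, "positives.txt"))
  writeLines(as.character(curated$negatives$id),
             file.path(dir, "negatives.txt"))
  invisible(dir)
}
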