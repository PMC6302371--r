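# Fixture builders. All fixtures are constructed in code at test time.

## ASCII PSSM text in the PSI-BLAST -out_ascii_pssm layout, built
## independently of writePssmFile.
makePssmText <- function(scores, residues = NULL) {
  scores <- as.matrix(scores)
  if (is.null(residues))
    residues <- rep(LETTERS[seq_len(min(nrow(scores), 26))],
                    length.out = nrow(scores))
  c("",
    "Last position-specific scoring matrix computed, weighted observed percentages",
    paste("   ", paste(pssmAlphabet(), collapse = "   ")),
    vapply(seq_len(nrow(scores)), function(u)
      paste(c(sprintf("%4d", u), residues[u],
              sprintf("%4d", as.integer(scores[u, ]))), collapse = " "),
      character(1)))
}

randomRecords <- function(n) {
  data.frame(
    id = sprintf("P%04d", seq_len(n)),
    length = sample(c(10:60, 200:400, 4900:5100), n, replace = TRUE),
    largeScale = rpois(n, 0.8),
    smallScale = rpois(n, 0.3),
    homooligomer = runif(n) < 0.2,
    publications = rpois(n, 0.7))
}

## 90-degree counter-clockwise rotation of a matrix.
rotate90 <- function(M) t(M)[ncol(M):1, , drop = FALSE]
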