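## Pipeline stage runners. Each stage reads the previous stage's artifacts
## from disk, writes its own plus a resolved-config snapshot, and returns
## its main result invisibly. The command-line script in
## inst/scripts/zernsip.R is a thin flag-parsing shim over these functions.

.writeSnapshot <- function(dir, stage, config) {
  jsonlite::write_json(config, file.path(dir, paste0(stage, "-config.json")),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
}

.needFile <- function(path, what) {
  if (!file.exists(path))
    stop(sprintf("missing %s: '%s' does not exist (run the previous stage first)",
                 what, path))
  path
}

#' Pipeline stage: simulate a synthetic dataset
#'
#' Writes ASCII PSSM files, the manifest (id, label, split, length) and a
#' resolved-config snapshot into \code{dir}.
#'
#' @param dir output directory.
#' @param config a \code{\link{synthConfig}}.
#' @return The dataset, invisibly.
#' @export
runSimulate <- function(dir, config = synthConfig()) {
  ds <- generateDataset(config)
  writeSyntheticDataset(ds, dir)
  .writeSnapshot(dir, "simulate", unclass(config))
  message(sprintf("simulate: wrote %d profiles to %s", nrow(ds$records), dir))
  invisible(ds)
}

#' Pipeline stage: extract Zernike magnitude features
#'
#' Parses every \code{*.pssm} file in \code{pssmDir}; files that fail to
#' parse are logged and skipped with a summary count. Features are written
#' as a TSV (one row per protein) with a JSON sidecar recording the order
#' cap, squashing switch and feature index order.
#'
#' @param pssmDir directory of ASCII PSSM files.
#' @param outDir output directory.
#' @param nMax Zernike order cap (default 30).
#' @param squash logistic squashing switch (default TRUE).
#' @return The feature matrix, invisibly.
#' @export
runExtract <- function(pssmDir, outDir, nMax = 30L, squash = TRUE) {
  files <- list.files(pssmDir, pattern = "\\.pssm$", full.names = TRUE)
  if (length(files) == 0L)
    stop(sprintf("no PSSM files found in '%s'", pssmDir))
  pswms <- list(); skipped <- 0L
  for (f in files) {
    p <- tryCatch(parsePsiblastPssm(f), error = function(e) {
      message(sprintf("extract: skipping %s (%s)", basename(f),
                      conditionMessage(e)))
      NULL
    })
    if (is.null(p)) skipped <- skipped + 1L
    else pswms[[sub("\\.pssm$", "", basename(f))]] <- p
  }
  if (length(pswms) == 0L)
    stop("no parsable PSSM files: every input failed to parse")
  feats <- extractFeatures(pswms, nMax = nMax, squash = squash)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(id = rownames(feats), feats, check.names = FALSE),
    file.path(outDir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(nMax = nMax, squash = squash, nFeatures = ncol(feats),
         indexOrder = colnames(feats), nProteins = nrow(feats),
         skipped = skipped),
    file.path(outDir, "features-meta.json"), auto_unbox = TRUE)
  message(sprintf("extract: %d proteins, %d features (%d skipped)",
                  nrow(feats), ncol(feats), skipped))
  invisible(feats)
}

.readFeatures <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}

.readManifest <- function(file) {
  utils::read.delim(.needFile(file, "manifest"))
}

#' Pipeline stage: PCA reduction fitted on the training split
#'
#' The projection is fitted on training-split features only and applied to
#' every protein; reduced coordinates plus the projection itself are
#' written so the transform is portable to new data.
#'
#' @param featuresFile TSV written by \code{\link{runExtract}}.
#' @param manifestFile TSV with id, label, split columns.
#' @param outDir output directory.
#' @param nComponents number of components to keep (default 150).
#' @return The reduced feature matrix, invisibly.
#' @export
runReduce <- function(featuresFile, manifestFile, outDir,
                      nComponents = 150L) {
  feats <- .readFeatures(.needFile(featuresFile, "feature matrix"))
  man <- .readManifest(manifestFile)
  trainIds <- man$id[man$split == "train"]
  xTrain <- feats[rownames(feats) %in% trainIds, , drop = FALSE]
  if (nrow(xTrain) == 0L) stop("no training-split rows found in features")
  pca <- fitFeaturePCA(xTrain, nComponents = nComponents)
  red <- applyFeaturePCA(pca, feats)
  rownames(red) <- rownames(feats)
  colnames(red) <- paste0("PC", seq_len(ncol(red)))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(id = rownames(red), red, check.names = FALSE),
    file.path(outDir, "reduced.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(center = pca$center, rotation = pca$rotation, sdev = pca$sdev,
         nComponents = pca$nComponents),
    file.path(outDir, "pca.json"), digits = NA)
  .writeSnapshot(outDir, "reduce", list(nComponents = nComponents))
  message(sprintf("reduce: %d -> %d dimensions (fit on %d training rows)",
                  ncol(feats), ncol(red), nrow(xTrain)))
  invisible(red)
}

#' Pipeline stage: train the stacked-LSTM classifier
#'
#' Trains on the training split with the validation split driving early
#' stopping, then writes the JSON checkpoint and the per-epoch training
#' log as CSV.
#'
#' @param reducedFile TSV written by \code{\link{runReduce}}.
#' @param manifestFile manifest TSV.
#' @param outDir output directory.
#' @param hidden memory blocks per hidden layer.
#' @param dropout dropout probability.
#' @param chunks timesteps the feature vector is split into.
#' @param config a \code{\link{trainConfig}}.
#' @return The trained model, invisibly.
#' @export
runTrain <- function(reducedFile, manifestFile, outDir,
                     hidden = c(16L, 16L, 16L), dropout = 0.5,
                     chunks = 1L, config = trainConfig()) {
  red <- .readFeatures(.needFile(reducedFile, "reduced feature matrix"))
  man <- .readManifest(manifestFile)
  man <- man[match(rownames(red), man$id), ]
  tr <- man$split == "train"; va <- man$split == "val"
  if (!any(tr) || !any(va)) stop("manifest must provide train and val splits")
  model <- newSLSTMModel(ncol(red) %/% chunks, hidden = hidden,
                         dropout = dropout, chunks = chunks,
                         seed = config$seed)
  model <- trainSLSTM(model, red[tr, , drop = FALSE], man$label[tr],
                      red[va, , drop = FALSE], man$label[va],
                      config = config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeSLSTMModel(model, file.path(outDir, "model.json"))
  utils::write.csv(trainingLog(model), file.path(outDir, "trainlog.csv"),
                   row.names = FALSE)
  .writeSnapshot(outDir, "train",
                 c(unclass(config), list(hidden = hidden, dropout = dropout,
                                         chunks = chunks)))
  message(sprintf("train: %d epochs, best validation loss %.4g",
                  nrow(trainingLog(model)), min(trainingLog(model)$valLoss)))
  invisible(model)
}

#' Pipeline stage: evaluate on the held-out test split
#'
#' Scores the test split with the trained model and writes the metrics
#' report (JSON) and the ROC points (TSV).
#'
#' @param modelFile checkpoint written by \code{\link{runTrain}}.
#' @param reducedFile reduced feature TSV.
#' @param manifestFile manifest TSV.
#' @param outDir output directory.
#' @return The \code{\linkS4class{MetricsReport}}, invisibly.
#' @export
runEvaluate <- function(modelFile, reducedFile, manifestFile, outDir) {
  model <- readSLSTMModel(.needFile(modelFile, "model checkpoint"))
  red <- .readFeatures(.needFile(reducedFile, "reduced feature matrix"))
  man <- .readManifest(manifestFile)
  man <- man[match(rownames(red), man$id), ]
  te <- man$split == "test"
  if (!any(te)) stop("manifest contains no test split")
  pred <- predictSLSTM(model, red[te, , drop = FALSE])
  rr <- rocAuc(man$label[te], pred$score)
  report <- computeMetrics(confusionCounts(man$label[te], pred$label),
                           auc = rr$auc)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeMetricsReport(report, file.path(outDir, "metrics.json"),
                     rocFile = file.path(outDir, "roc.tsv"), roc = rr$roc)
  message(sprintf("evaluate: ACC %.4f, MCC %.4f, AUC %.4f on %d test samples",
                  report@metrics["ACC"], report@metrics["MCC"], rr$auc,
                  sum(te)))
  invisible(report)
}

#' Run the full pipeline on synthetic data
#'
#' simulate -> extract -> reduce -> train -> evaluate, all under one
#' working directory. Every stage's artifacts are left on disk.
#'
#' @param dir working directory.
#' @param synth a \code{\link{synthConfig}}.
#' @param nMax,squash feature extraction settings.
#' @param nComponents PCA dimension.
#' @param hidden,dropout,chunks classifier architecture.
#' @param train a \code{\link{trainConfig}}.
#' @return The final \code{\linkS4class{MetricsReport}}, invisibly.
#' @export
runPipeline <- function(dir, synth = synthConfig(), nMax = 30L,
                        squash = TRUE, nComponents = 150L,
                        hidden = c(16L, 16L, 16L), dropout = 0.5,
                        chunks = 1L, train = trainConfig()) {
  pssmDir <- file.path(dir, "pssm")
  runSimulate(pssmDir, synth)
  runExtract(pssmDir, dir, nMax = nMax, squash = squash)
  manifest <- file.path(pssmDir, "manifest.tsv")
  runReduce(file.path(dir, "features.tsv"), manifest, dir,
            nComponents = nComponents)
  runTrain(file.path(dir, "reduced.tsv"), manifest, dir, hidden = hidden,
           dropout = dropout, chunks = chunks, config = train)
  runEvaluate(file.path(dir, "model.json"), file.path(dir, "reduced.tsv"),
              manifest, dir)
}
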