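## Stacked peephole-LSTM classifier.
##
## Each hidden layer is a bank of memory blocks sharing one parameter set.
## Gate equations (element-wise products written *):
##   i_t = sigm(W_i . [C_{t-1}, x_t, h_{t-1}] + b_i)
##   f_t = sigm(W_f . [C_{t-1}, x_t, h_{t-1}] + b_f)
##   C~_t = tanh(W_C . [x_t, h_{t-1}] + b_C)
##   C_t = C_{t-1} * f_t + C~_t * i_t
##   o_t = sigm(W_o . [C_t, x_t, h_{t-1}] + b_o)    (peephole on current cell)
##   h_t = tanh(C_t) * o_t
## The input/forget peepholes read the previous cell state, the output
## peephole the current one. An optional literal variant adds C~_t * i_t to
## h_t (eq12AsPrinted); it is off by default.

.initMatrix <- function(nr, nc) {
  s <- 1 / sqrt(nc)
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

#' Create an untrained stacked-LSTM model
#'
#' Builds the parameter set for a stacked peephole-LSTM with a softmax
#' output head. The default architecture uses three hidden layers of 16
#' memory blocks and two output classes. Weights are drawn uniformly with
#' fan-in scaling; forget-gate biases start at 1 so early training does not
#' erase the cell state.
#'
#' @param inputDim dimension of the per-timestep input (the reduced feature
#'   dimension when \code{chunks = 1}).
#' @param hidden integer vector of memory blocks per hidden layer.
#' @param nClasses number of output classes.
#' @param dropout probability of discarding a hidden unit during training;
#'   test-time outputs are scaled by the retention probability instead.
#' @param chunks number of timesteps the feature vector is split into
#'   (1 = the whole vector is a single-step sequence).
#' @param eq12AsPrinted logical; use the non-standard block output that
#'   adds the candidate term to \eqn{h_t} (kept only for comparison).
#' @param seed integer seed for weight initialisation.
#' @return An untrained \code{\linkS4class{SLSTMModel}}.
#' @export
newSLSTMModel <- function(inputDim, hidden = c(16L, 16L, 16L),
                          nClasses = 2L, dropout = 0.5, chunks = 1L,
                          eq12AsPrinted = FALSE, seed = 1L) {
  set.seed(seed)
  inputDim <- as.integer(inputDim)
  hidden <- as.integer(hidden)
  layers <- vector("list", length(hidden))
  d <- inputDim
  for (l in seq_along(hidden)) {
    u <- hidden[l]
    layers[[l]] <- list(
      Wi = .initMatrix(u, u + d + u), bi = numeric(u),
      Wf = .initMatrix(u, u + d + u), bf = rep(1, u),
      Wo = .initMatrix(u, u + d + u), bo = numeric(u),
      Wc = .initMatrix(u, d + u), bc = numeric(u))
    d <- u
  }
  head <- list(Ws = .initMatrix(nClasses, d), bs = numeric(nClasses))
  new("SLSTMModel", inputDim = inputDim, hidden = hidden,
      nClasses = as.integer(nClasses), layers = layers, head = head,
      dropout = dropout, eq12AsPrinted = eq12AsPrinted,
      chunks = as.integer(chunks), trained = FALSE,
      log = data.frame(), seed = as.integer(seed))
}

## One layer, one timestep, batched: X (B x D), C/H (B x U). Returns the
## new state plus everything the backward pass needs.
.layerStep <- function(par, X, C, H, eq12 = FALSE) {
  B <- nrow(X); U <- length(par$bi)
  A <- cbind(C, X, H)
  i <- stats::plogis(tcrossprod(A, par$Wi) +
                     matrix(par$bi, B, U, byrow = TRUE))
  f <- stats::plogis(tcrossprod(A, par$Wf) +
                     matrix(par$bf, B, U, byrow = TRUE))
  XH <- cbind(X, H)
  g <- tanh(tcrossprod(XH, par$Wc) + matrix(par$bc, B, U, byrow = TRUE))
  Cnew <- C * f + g * i
  Ao <- cbind(Cnew, X, H)
  o <- stats::plogis(tcrossprod(Ao, par$Wo) +
                     matrix(par$bo, B, U, byrow = TRUE))
  tc <- tanh(Cnew)
  h <- tc * o
  if (eq12) h <- h + g * i
  list(C = Cnew, h = h, i = i, f = f, o = o, g = g, tc = tc,
       A = A, Ao = Ao, XH = XH, Cprev = C, X = X, Hprev = H)
}

#' Single memory-block step
#'
#' Advances one bank of peephole memory blocks by one timestep. Gate
#' activations are returned alongside the new state so the information flow
#' can be inspected. With all weights and biases zero and previous cell
#' \eqn{c}, the gates sit at 0.5 and the step returns \eqn{C_t = 0.5 c},
#' \eqn{h_t = 0.5 \tanh(0.5 c)}.
#'
#' @param params list with weight matrices \code{Wi}, \code{Wf}, \code{Wo}
#'   (units x (units + inputDim + units), column blocks cell/input/output),
#'   \code{Wc} (units x (inputDim + units)) and bias vectors \code{bi},
#'   \code{bf}, \code{bo}, \code{bc}.
#' @param x input vector for this timestep.
#' @param prev list with previous state \code{C} and \code{h}; defaults to
#'   zeros.
#' @param eq12AsPrinted logical, use the non-standard output variant.
#' @return list with \code{C}, \code{h} and gate activations \code{i},
#'   \code{f}, \code{o} and candidate \code{g}.
#' @export
memoryBlockStep <- function(params, x, prev = NULL, eq12AsPrinted = FALSE) {
  u <- length(params$bi)
  if (is.null(prev)) prev <- list(C = numeric(u), h = numeric(u))
  if (length(prev$C) != u || length(prev$h) != u)
    stop("state dimension does not match the block count")
  if (!all(vapply(params[c("Wi", "Wf", "Wo", "Wc")],
                  function(w) all(is.finite(w)), logical(1))))
    stop("non-finite parameters")
  st <- .layerStep(params, matrix(x, nrow = 1),
                   matrix(prev$C, nrow = 1), matrix(prev$h, nrow = 1),
                   eq12 = eq12AsPrinted)
  list(C = drop(st$C), h = drop(st$h), i = drop(st$i), f = drop(st$f),
       o = drop(st$o), g = drop(st$g))
}

#' Dropout as used in training and testing
#'
#' In \code{train} mode each unit is independently zeroed with probability
#' \code{p} (no rescaling). In \code{test} mode nothing is zeroed; the
#' output is scaled by the retention probability \eqn{1-p}, merging the
#' ensemble of thinned networks into a single network with reduced weights.
#'
#' @param x numeric vector or matrix of layer outputs.
#' @param p dropout probability in [0, 1).
#' @param mode "train" or "test".
#' @return Object of the same shape as \code{x}.
#' @export
applyDropout <- function(x, p, mode = c("train", "test")) {
  mode <- match.arg(mode)
  if (length(p) != 1L || is.na(p) || p < 0 || p >= 1)
    stop("dropout probability must lie in [0, 1)")
  if (p == 0) return(x)
  if (mode == "test") return(x * (1 - p))
  mask <- stats::runif(length(x)) >= p
  x * array(as.numeric(mask), dim = if (is.null(dim(x))) length(x)
                                    else dim(x))
}

## Split a feature matrix (B x D) into a list of `chunks` timestep inputs.
.toSequence <- function(x, chunks) {
  x <- as.matrix(x)
  D <- ncol(x)
  if (D %% chunks != 0)
    stop("feature dimension is not divisible by the chunk count")
  step <- D %/% chunks
  lapply(seq_len(chunks), function(t)
    x[, ((t - 1) * step + 1):(t * step), drop = FALSE])
}

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## Full forward pass. Xseq: list over timesteps of B x D matrices.
## masks: NULL (test mode, scale by 1-p) or list[layer][t] of B x U 0/1
## matrices (train mode). Returns probs, logits and per-layer caches.
.forwardPass <- function(model, Xseq, masks = NULL) {
  p <- model@dropout
  Tn <- length(Xseq)
  B <- nrow(Xseq[[1]])
  caches <- vector("list", length(model@layers))
  inSeq <- Xseq
  for (l in seq_along(model@layers)) {
    par <- model@layers[[l]]
    U <- length(par$bi)
    C <- matrix(0, B, U); H <- matrix(0, B, U)
    steps <- vector("list", Tn)
    out <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      st <- .layerStep(par, inSeq[[t]], C, H, eq12 = model@eq12AsPrinted)
      C <- st$C; H <- st$h
      steps[[t]] <- st
      ht <- st$h
      if (p > 0) {
        ht <- if (is.null(masks)) ht * (1 - p) else ht * masks[[l]][[t]]
      }
      out[[t]] <- ht
    }
    caches[[l]] <- list(steps = steps, out = out)
    inSeq <- out
  }
  hHead <- inSeq[[Tn]]
  logits <- tcrossprod(hHead, model@head$Ws) +
    matrix(model@head$bs, B, model@nClasses, byrow = TRUE)
  list(probs = .softmax(logits), logits = logits, hHead = hHead,
       caches = caches, Xseq = Xseq)
}

#' Forward pass: class probabilities
#'
#' Runs input feature vectors through the stacked network. Layer
#' \eqn{l} consumes the output sequence of layer \eqn{l-1}; the last
#' timestep of the top layer feeds the softmax head. With nonzero dropout
#' the hidden outputs are scaled by the retention probability (test-time
#' weight scaling).
#'
#' @param model an \code{\linkS4class{SLSTMModel}}.
#' @param x single feature vector, or a matrix with one sample per row.
#' @return Probability matrix (rows sum to 1), columns
#'   \code{c("negative", "positive")} for two-class models; a named vector
#'   for a single sample.
#' @export
slstmForward <- function(model, x) {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, nrow = 1)
  if (ncol(x) != model@inputDim * model@chunks)
    stop(sprintf("input dimension %d does not match the model (%d)",
                 ncol(x), model@inputDim * model@chunks))
  fp <- .forwardPass(model, .toSequence(x, model@chunks))
  pr <- fp$probs
  if (model@nClasses == 2L) colnames(pr) <- c("negative", "positive")
  if (single) drop(pr) else pr
}

## Backward pass matching .forwardPass. dlogits: B x nClasses. Returns
## gradients with the same nesting as the parameters.
.backwardPass <- function(model, fp, dlogits, masks = NULL) {
  p <- model@dropout
  Tn <- length(fp$Xseq)
  B <- nrow(dlogits)
  nL <- length(model@layers)
  grads <- list(layers = vector("list", nL), head = NULL)

  gWs <- crossprod(dlogits, fp$hHead)
  gbs <- colSums(dlogits)
  dhHead <- dlogits %*% model@head$Ws
  grads$head <- list(Ws = gWs, bs = gbs)

  ## dOut[[t]]: gradient w.r.t. the (dropped) output of the current layer.
  dOut <- vector("list", Tn)
  for (t in seq_len(Tn)) dOut[[t]] <- matrix(0, B, ncol(dhHead))
  dOut[[Tn]] <- dhHead

  for (l in rev(seq_len(nL))) {
    par <- model@layers[[l]]
    cache <- fp$caches[[l]]
    U <- length(par$bi)
    D <- ncol(cache$steps[[1]]$X)
    g <- list(Wi = 0 * par$Wi, bi = 0 * par$bi, Wf = 0 * par$Wf,
              bf = 0 * par$bf, Wo = 0 * par$Wo, bo = 0 * par$bo,
              Wc = 0 * par$Wc, bc = 0 * par$bc)
    dXout <- vector("list", Tn)
    dCc <- matrix(0, B, U); dHc <- matrix(0, B, U)
    for (t in rev(seq_len(Tn))) {
      st <- cache$steps[[t]]
      dH <- dOut[[t]]
      if (p > 0) {  # undo dropout on this layer's output
        dH <- if (is.null(masks)) dH * (1 - p) else dH * masks[[l]][[t]]
      }
      dH <- dH + dHc
      di <- matrix(0, B, U); dG <- matrix(0, B, U)
      if (model@eq12AsPrinted) {
        dG <- dG + dH * st$i
        di <- di + dH * st$g
      }
      do <- dH * st$tc
      dC <- dCc + dH * st$o * (1 - st$tc^2)
      dzo <- do * st$o * (1 - st$o)
      g$Wo <- g$Wo + crossprod(dzo, st$Ao)
      g$bo <- g$bo + colSums(dzo)
      dAo <- dzo %*% par$Wo
      dC <- dC + dAo[, seq_len(U), drop = FALSE]
      dX <- dAo[, U + seq_len(D), drop = FALSE]
      dHp <- dAo[, U + D + seq_len(U), drop = FALSE]

      di <- di + dC * st$g
      dG <- dG + dC * st$i
      df <- dC * st$Cprev
      dCp <- dC * st$f

      dzg <- dG * (1 - st$g^2)
      g$Wc <- g$Wc + crossprod(dzg, st$XH)
      g$bc <- g$bc + colSums(dzg)
      dXH <- dzg %*% par$Wc
      dX <- dX + dXH[, seq_len(D), drop = FALSE]
      dHp <- dHp + dXH[, D + seq_len(U), drop = FALSE]

      dzi <- di * st$i * (1 - st$i)
      g$Wi <- g$Wi + crossprod(dzi, st$A)
      g$bi <- g$bi + colSums(dzi)
      dA <- dzi %*% par$Wi
      dCp <- dCp + dA[, seq_len(U), drop = FALSE]
      dX <- dX + dA[, U + seq_len(D), drop = FALSE]
      dHp <- dHp + dA[, U + D + seq_len(U), drop = FALSE]

      dzf <- df * st$f * (1 - st$f)
      g$Wf <- g$Wf + crossprod(dzf, st$A)
      g$bf <- g$bf + colSums(dzf)
      dA <- dzf %*% par$Wf
      dCp <- dCp + dA[, seq_len(U), drop = FALSE]
      dX <- dX + dA[, U + seq_len(D), drop = FALSE]
      dHp <- dHp + dA[, U + D + seq_len(U), drop = FALSE]

      dCc <- dCp; dHc <- dHp
      dXout[[t]] <- dX
    }
    grads$layers[[l]] <- g
    dOut <- dXout
  }
  grads
}

#' Training configuration
#'
#' @param epochs maximum number of epochs (default 200).
#' @param lr Nadam step size (default 2e-3).
#' @param beta1,beta2 Nadam moment decay rates.
#' @param eps Nadam numerical stabiliser.
#' @param patience consecutive non-improving validation epochs tolerated
#'   before early stopping (default 10); the best-validation weights are
#'   restored.
#' @param batchSize minibatch size.
#' @param classWeights logical; weight the cross-entropy loss by inverse
#'   class frequency (off by default).
#' @param seed integer seed covering shuffling, dropout masks and any other
#'   randomness during training.
#' @return A list of class \code{trainConfig}.
#' @export
trainConfig <- function(epochs = 200L, lr = 2e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8, patience = 10L,
                        batchSize = 32L, classWeights = FALSE, seed = 1L) {
  stopifnot(epochs >= 1)
  structure(list(epochs = as.integer(epochs), lr = lr, beta1 = beta1,
                 beta2 = beta2, eps = eps, patience = as.integer(patience),
                 batchSize = as.integer(batchSize),
                 classWeights = classWeights, seed = as.integer(seed)),
            class = "trainConfig")
}

.mapParams <- function(f, a, b = NULL) {
  recurse <- function(x, y) {
    if (is.list(x))
      Map(recurse, x, if (is.null(y)) vector("list", length(x)) else y)
    else if (is.null(y)) f(x) else f(x, y)
  }
  recurse(a, b)
}

.ceLoss <- function(probs, y, w) {
  -sum(w * log(pmax(probs[cbind(seq_along(y), y + 1L)], 1e-300))) / sum(w)
}

#' Train a stacked-LSTM classifier
#'
#' Minimises the (optionally class-weighted) cross-entropy with the Nadam
#' optimiser. Dropout is applied to every hidden layer's output during
#' training (units zeroed with probability \code{p}); at validation and
#' prediction time the outputs are scaled by \eqn{1-p} instead. The
#' validation loss is monitored each epoch: after \code{patience}
#' consecutive epochs without improvement, training stops and the weights
#' from the best-validation epoch are restored.
#'
#' @param model an untrained (or resumed) \code{\linkS4class{SLSTMModel}}.
#' @param x training feature matrix, one sample per row.
#' @param y training labels, 0 (negative) / 1 (positive).
#' @param xVal,yVal validation split used for early stopping.
#' @param config a \code{\link{trainConfig}}.
#' @return The trained model; \code{trainingLog(model)} holds the per-epoch
#'   training and validation losses and validation accuracy.
#' @export
trainSLSTM <- function(model, x, y, xVal, yVal, config = trainConfig()) {
  x <- as.matrix(x); xVal <- as.matrix(xVal)
  y <- as.integer(y); yVal <- as.integer(yVal)
  if (nrow(x) == 0L || nrow(xVal) == 0L) stop("empty training or validation split")
  if (length(unique(y)) < 2L)
    stop("training set contains a single class; cannot fit a classifier")
  if (ncol(x) != model@inputDim * model@chunks)
    stop("feature dimension does not match the model input width")
  set.seed(config$seed)
  p <- model@dropout
  nL <- length(model@layers)
  Tn <- model@chunks

  w <- rep(1, length(y))
  if (config$classWeights) {
    tab <- table(factor(y, levels = c(0L, 1L)))
    w <- (length(y) / (2 * as.numeric(tab)))[y + 1L]
  }
  yOne <- function(yy, B) {
    Y <- matrix(0, B, model@nClasses)
    Y[cbind(seq_len(B), yy + 1L)] <- 1
    Y
  }

  params <- list(layers = model@layers, head = model@head)
  mSt <- .mapParams(function(a) a * 0, params)
  vSt <- .mapParams(function(a) a * 0, params)
  step <- 0L
  bestLoss <- Inf; bestParams <- params; badEpochs <- 0L
  logRows <- list()
  n <- nrow(x)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batchLoss <- 0; nb <- 0L
    for (start in seq(1L, n, by = config$batchSize)) {
      idx <- ord[start:min(start + config$batchSize - 1L, n)]
      B <- length(idx)
      Xb <- x[idx, , drop = FALSE]; yb <- y[idx]; wb <- w[idx]
      masks <- NULL
      if (p > 0) {
        masks <- lapply(seq_len(nL), function(l)
          lapply(seq_len(Tn), function(t)
            matrix(as.numeric(stats::runif(B * model@hidden[l]) >= p),
                   B, model@hidden[l])))
      }
      model@layers <- params$layers; model@head <- params$head
      fp <- .forwardPass(model, .toSequence(Xb, Tn), masks = masks)
      loss <- .ceLoss(fp$probs, yb, wb)
      batchLoss <- batchLoss + loss; nb <- nb + 1L
      dlogits <- (fp$probs - yOne(yb, B)) * (wb / sum(wb))
      grads <- .backwardPass(model, fp, dlogits, masks = masks)

      step <- step + 1L
      b1 <- config$beta1; b2 <- config$beta2
      mSt <- .mapParams(function(m, g) b1 * m + (1 - b1) * g, mSt, grads)
      vSt <- .mapParams(function(v, g) b2 * v + (1 - b2) * g^2, vSt, grads)
      corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
      upd <- .mapParams(function(m, g) b1 * (m / corr1) +
                          (1 - b1) * (g / corr1), mSt, grads)
      den <- .mapParams(function(v) sqrt(v / corr2) + config$eps, vSt)
      delta <- .mapParams(function(u, d) config$lr * u / d, upd, den)
      params <- .mapParams(function(th, dl) th - dl, params, delta)
    }

    model@layers <- params$layers; model@head <- params$head
    fpVal <- .forwardPass(model, .toSequence(xVal, Tn))
    valLoss <- .ceLoss(fpVal$probs, yVal, rep(1, length(yVal)))
    valAcc <- mean((fpVal$probs[, 2L] >= 0.5) == (yVal == 1L))
    logRows[[epoch]] <- data.frame(epoch = epoch,
                                   trainLoss = batchLoss / nb,
                                   valLoss = valLoss, valAcc = valAcc)
    if (valLoss < bestLoss - 1e-12) {
      bestLoss <- valLoss; bestParams <- params; badEpochs <- 0L
    } else {
      badEpochs <- badEpochs + 1L
      if (badEpochs >= config$patience) break
    }
  }

  model@layers <- bestParams$layers
  model@head <- bestParams$head
  model@trained <- TRUE
  model@log <- do.call(rbind, logRows)
  model
}

#' Predict labels and scores
#'
#' @param model a trained \code{\linkS4class{SLSTMModel}}.
#' @param x feature matrix (rows = samples) or single vector.
#' @return data.frame with \code{score} (probability of the positive
#'   class) and \code{label} (1 when \code{score >= 0.5}; the tie at
#'   exactly 0.5 is broken toward the positive class).
#' @export
predictSLSTM <- function(model, x) {
  if (!model@trained)
    warning("model has not been trained; predictions use initial weights")
  pr <- slstmForward(model, x)
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
  score <- pr[, 2L]
  data.frame(score = score, label = as.integer(score >= 0.5))
}

#' Serialize / restore a model as JSON
#'
#' The checkpoint is a single JSON document holding the architecture,
#' dropout configuration, seed and all weights at full precision, plus the
#' training log.
#'
#' @param model an \code{\linkS4class{SLSTMModel}}.
#' @param file path to the checkpoint.
#' @return \code{writeSLSTMModel}: the path, invisibly;
#'   \code{readSLSTMModel}: the restored model.
#' @export
writeSLSTMModel <- function(model, file) {
  payload <- list(
    inputDim = model@inputDim, hidden = model@hidden,
    nClasses = model@nClasses, dropout = model@dropout,
    eq12AsPrinted = model@eq12AsPrinted, chunks = model@chunks,
    trained = model@trained, seed = model@seed,
    layers = stats::setNames(model@layers,
                             paste0("layer", seq_along(model@layers))),
    head = model@head, log = model@log)
  jsonlite::write_json(payload, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname writeSLSTMModel
#' @export
readSLSTMModel <- function(file) {
  pl <- jsonlite::fromJSON(file, simplifyVector = TRUE,
                           simplifyMatrix = TRUE)
  fixLayer <- function(l) {
    for (nm in c("Wi", "Wf", "Wo", "Wc")) l[[nm]] <- as.matrix(l[[nm]])
    for (nm in c("bi", "bf", "bo", "bc")) l[[nm]] <- as.numeric(l[[nm]])
    l
  }
  lg <- as.data.frame(pl$log)
  new("SLSTMModel", inputDim = as.integer(pl$inputDim),
      hidden = as.integer(pl$hidden), nClasses = as.integer(pl$nClasses),
      layers = unname(lapply(pl$layers, fixLayer)),
      head = list(Ws = as.matrix(pl$head$Ws),
                  bs = as.numeric(pl$head$bs)),
      dropout = pl$dropout, eq12AsPrinted = isTRUE(pl$eq12AsPrinted),
      chunks = as.integer(pl$chunks), trained = isTRUE(pl$trained),
      log = lg, seed = as.integer(pl$seed))
}
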