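zeroParams <- function(U, D) {
  list(Wi = matrix(0, U, 2 * U + D), bi = numeric(U),
       Wf = matrix(0, U, 2 * U + D), bf = numeric(U),
       Wo = matrix(0, U, 2 * U + D), bo = numeric(U),
       Wc = matrix(0, U, U + D), bc = numeric(U))
}

test_that("zero-parameter memory block has the closed-form output", {
  cPrev <- c(0.8, -0.3, 0)
  st <- memoryBlockStep(zeroParams(3, 4), rnorm(4),
                        prev = list(C = cPrev, h = numeric(3)))
  expect_equal(st$i, rep(0.5, 3))
  expect_equal(st$f, rep(0.5, 3))
  expect_equal(st$o, rep(0.5, 3))
  expect_equal(st$g, rep(0, 3))
  expect_equal(st$C, 0.5 * cPrev)
  expect_equal(st$h, 0.5 * tanh(0.5 * cPrev))
})

test_that("saturated gates conserve the cell state", {
  p <- zeroParams(2, 3)
  p$bf <- rep(40, 2)    # forget gate pinned open
  p$bi <- rep(-40, 2)   # input gate pinned shut
  cPrev <- c(1.3, -2.1)
  st <- memoryBlockStep(p, rnorm(3), prev = list(C = cPrev, h = numeric(2)))
  expect_equal(st$C, cPrev, tolerance = 1e-12)
})

test_that("block step matches an independent transcription of the gate equations", {
  set.seed(31)
  for (rep in 1:25) {
    U <- sample(2:6, 1); D <- sample(2:8, 1)
    par <- randomBlockParams(U, D)
    x <- rnorm(D); Cp <- rnorm(U); hp <- rnorm(U)
    for (eq12 in c(FALSE, TRUE)) {
      got <- memoryBlockStep(par, x, prev = list(C = Cp, h = hp),
                             eq12AsPrinted = eq12)
      want <- lstmStepOracle(par, x, Cp, hp, eq12 = eq12)
      for (nm in c("C", "h", "i", "f", "o", "g"))
        expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12)
    }
  }
})

test_that("gate outputs stay in (0,1) and the cell growth is bounded", {
  set.seed(32)
  for (rep in 1:10) {
    par <- randomBlockParams(4, 5)
    Cp <- rnorm(4, sd = 2)
    st <- memoryBlockStep(par, rnorm(5), prev = list(C = Cp, h = rnorm(4)))
    expect_true(all(st$i > 0 & st$i < 1))
    expect_true(all(st$f > 0 & st$f < 1))
    expect_true(all(st$o > 0 & st$o < 1))
    expect_true(all(abs(st$C) <= abs(Cp) + 1))
  }
})

test_that("forward pass yields normalised, deterministic probabilities", {
  set.seed(33)
  model <- newSLSTMModel(10, hidden = c(6, 5), dropout = 0.3, seed = 9)
  x <- matrix(rnorm(40), 4, 10)
  pr <- slstmForward(model, x)
  expect_equal(rowSums(pr), rep(1, 4), tolerance = 1e-12)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_identical(pr, slstmForward(model, x))  # no hidden randomness

  # a zero model is symmetric between the classes
  z <- model
  z@layers <- lapply(z@layers, function(l) lapply(l, function(w) w * 0))
  z@head <- lapply(z@head, function(w) w * 0)
  expect_equal(unname(slstmForward(z, rnorm(10))), c(0.5, 0.5))

  expect_error(slstmForward(model, rnorm(9)), "dimension")
})

test_that("softmax head is invariant to a constant shift of both logits", {
  set.seed(34)
  model <- newSLSTMModel(5, hidden = 4, dropout = 0, seed = 2)
  x <- rnorm(5)
  shifted <- model
  shifted@head$bs <- shifted@head$bs + 7.3
  expect_equal(slstmForward(model, x), slstmForward(shifted, x),
               tolerance = 1e-9)
})

test_that("scores are monotone in the logit difference", {
  set.seed(35)
  model <- newSLSTMModel(4, hidden = 3, dropout = 0, seed = 4)
  x <- matrix(rnorm(120), 30, 4)
  fp <- zernSIP:::.forwardPass(model, zernSIP:::.toSequence(x, 1))
  dlog <- fp$logits[, 2] - fp$logits[, 1]
  expect_equal(order(fp$probs[, 2]), order(dlog))
})

test_that("dropout follows the train/test contract", {
  x <- rnorm(50)
  expect_identical(applyDropout(x, 0, "train"), x)
  expect_identical(applyDropout(x, 0, "test"), x)
  # test mode: exact weight scaling by the retention probability
  expect_equal(applyDropout(x, 0.5, "test"), 0.5 * x)
  expect_equal(applyDropout(x, 0.2, "test"), 0.8 * x)
  expect_error(applyDropout(x, 1, "train"), "probability")
  expect_error(applyDropout(x, -0.1, "test"), "probability")

  # train mode: retained fraction concentrates at 1 - p (binomial 3 sigma)
  set.seed(36)
  n <- 1e5
  kept <- sum(applyDropout(rep(1, n), 0.5, "train"))
  expect_lt(abs(kept / n - 0.5), 3 * sqrt(0.25 / n))
  mh <- applyDropout(rep(1, n), 0.3, "train")
  expect_lt(abs(mean(mh) - 0.7), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(37)
  ns <- asNamespace("zernSIP")
  model <- newSLSTMModel(4, hidden = c(3, 3), dropout = 0, chunks = 2,
                         seed = 5)
  x <- matrix(rnorm(6 * 8), 6, 8)
  y <- c(0, 1, 1, 0, 1, 0)
  lossAt <- function(m) {
    fp <- ns$.forwardPass(m, ns$.toSequence(x, 2))
    ns$.ceLoss(fp$probs, y, rep(1, 6))
  }
  fp <- ns$.forwardPass(model, ns$.toSequence(x, 2))
  Y <- matrix(0, 6, 2); Y[cbind(1:6, y + 1)] <- 1
  gr <- ns$.backwardPass(model, fp, (fp$probs - Y) / 6)
  eps <- 1e-5
  for (l in 1:2) for (nm in c("Wi", "Wf", "Wo", "Wc", "bi", "bf", "bo",
                              "bc")) {
    w <- model@layers[[l]][[nm]]
    for (j in sample(length(w), min(4, length(w)))) {
      m2 <- model
      m2@layers[[l]][[nm]][j] <- w[j] + eps; up <- lossAt(m2)
      m2@layers[[l]][[nm]][j] <- w[j] - eps; dn <- lossAt(m2)
      expect_equal(gr$layers[[l]][[nm]][j], (up - dn) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})

separableData <- function(n, d = 6, gap = 2.5, seed = 41) {
  set.seed(seed)
  half <- n %/% 2
  x <- rbind(matrix(rnorm(half * d, mean = gap / 2), half, d),
             matrix(rnorm((n - half) * d, mean = -gap / 2), n - half, d))
  y <- c(rep(1, half), rep(0, n - half))
  ord <- sample(n)
  list(x = x[ord, ], y = y[ord])
}

test_that("training separates a well-separated two-class fixture", {
  tr <- separableData(120, seed = 42)
  va <- separableData(60, seed = 43)
  te <- separableData(60, seed = 44)
  model <- newSLSTMModel(6, hidden = c(8, 8), dropout = 0.3, seed = 1)
  model <- trainSLSTM(model, tr$x, tr$y, va$x, va$y,
                      trainConfig(epochs = 80, seed = 1))
  expect_true(isTrained(model))
  pred <- predictSLSTM(model, te$x)
  expect_gte(mean(pred$label == te$y), 0.95)
})

test_that("training loss decreases early on the separable fixture", {
  tr <- separableData(100, seed = 45)
  va <- separableData(40, seed = 46)
  model <- newSLSTMModel(6, hidden = 8, dropout = 0, seed = 2)
  model <- trainSLSTM(model, tr$x, tr$y, va$x, va$y,
                      trainConfig(epochs = 15, seed = 2))
  lg <- trainingLog(model)
  expect_lt(lg$trainLoss[nrow(lg)], lg$trainLoss[1])
})

test_that("early stopping halts at patience and restores the best weights", {
  # validation labels are flipped relative to training: any learning makes
  # validation loss rise from epoch 1
  tr <- separableData(80, seed = 47)
  va <- separableData(40, seed = 48)
  vaFlip <- list(x = va$x, y = 1 - va$y)
  model <- newSLSTMModel(6, hidden = 6, dropout = 0, seed = 3)
  cfg <- trainConfig(epochs = 200, patience = 5, seed = 3)
  model <- trainSLSTM(model, tr$x, tr$y, vaFlip$x, vaFlip$y, cfg)
  lg <- trainingLog(model)
  bestEpoch <- which.min(lg$valLoss)
  expect_lte(nrow(lg), bestEpoch + cfg$patience)
  # restored weights reproduce the best epoch's validation loss
  fp <- zernSIP:::.forwardPass(model, zernSIP:::.toSequence(vaFlip$x, 1))
  loss <- zernSIP:::.ceLoss(fp$probs, as.integer(vaFlip$y),
                            rep(1, length(vaFlip$y)))
  expect_equal(loss, min(lg$valLoss), tolerance = 1e-12)
})

test_that("training is deterministic given the seed", {
  tr <- separableData(60, seed = 49)
  va <- separableData(30, seed = 50)
  fit <- function() {
    m <- newSLSTMModel(6, hidden = 6, dropout = 0.4, seed = 7)
    trainSLSTM(m, tr$x, tr$y, va$x, va$y,
               trainConfig(epochs = 10, seed = 7))
  }
  m1 <- fit(); m2 <- fit()
  expect_identical(m1@layers, m2@layers)
  expect_identical(m1@head, m2@head)
  expect_identical(trainingLog(m1), trainingLog(m2))
})

test_that("degenerate training inputs are rejected", {
  x <- matrix(rnorm(40), 10, 4)
  model <- newSLSTMModel(4, hidden = 4, seed = 1)
  expect_error(trainSLSTM(model, x[0, ], integer(0), x, rep(0:1, 5),
                          trainConfig(epochs = 1)), "empty")
  expect_error(trainSLSTM(model, x, rep(1, 10), x, rep(0:1, 5),
                          trainConfig(epochs = 1)), "single class")
})

test_that("prediction thresholds scores at 0.5, ties toward positive", {
  set.seed(51)
  model <- newSLSTMModel(3, hidden = 3, dropout = 0, seed = 8)
  model@trained <- TRUE
  pred <- predictSLSTM(model, matrix(rnorm(30), 10, 3))
  expect_identical(pred$label, as.integer(pred$score >= 0.5))
  # an untrained model warns
  m0 <- newSLSTMModel(3, hidden = 3, seed = 8)
  expect_warning(predictSLSTM(m0, rnorm(3)), "not been trained")
})

test_that("checkpoint serialization round-trips the model", {
  tr <- separableData(40, seed = 52)
  va <- separableData(20, seed = 53)
  m <- newSLSTMModel(3, hidden = c(5, 4), dropout = 0.25, chunks = 2,
                     seed = 11)
  m <- trainSLSTM(m, tr$x, tr$y, va$x, va$y,
                  trainConfig(epochs = 5, seed = 11))
  f <- withr::local_tempfile(fileext = ".json")
  writeSLSTMModel(m, f)
  back <- readSLSTMModel(f)
  expect_equal(back@layers, m@layers, tolerance = 1e-12)
  expect_equal(back@head$Ws, m@head$Ws, tolerance = 1e-12)
  expect_identical(back@hidden, m@hidden)
  expect_identical(back@chunks, m@chunks)
  x <- matrix(rnorm(18), 3, 6)
  expect_equal(slstmForward(back, x), slstmForward(m, x),
               tolerance = 1e-12)
})
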