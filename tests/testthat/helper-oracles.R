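# Independent oracles used across the suite. Each one evaluates the target
# quantity by a route disjoint from the package implementation.

## ---- double-double (compensated) arithmetic -------------------------------
## Error-free transformations on pairs (hi, lo) with hi + lo the value and
## |lo| <= ulp(hi)/2. Gives ~32 significant digits; used to evaluate the
## alternating factorial sum of the radial polynomial without cancellation
## loss. All operations are vectorised.

ddQuickTwoSum <- function(a, b) {
  s <- a + b
  list(s = s, e = b - (s - a))
}

ddTwoSum <- function(a, b) {
  s <- a + b
  bb <- s - a
  list(s = s, e = (a - (s - bb)) + (b - bb))
}

ddSplit <- function(a) {
  c <- 134217729 * a  # 2^27 + 1 Dekker splitter
  hi <- c - (c - a)
  list(hi = hi, lo = a - hi)
}

ddTwoProd <- function(a, b) {
  p <- a * b
  A <- ddSplit(a); B <- ddSplit(b)
  e <- ((A$hi * B$hi - p) + A$hi * B$lo + A$lo * B$hi) + A$lo * B$lo
  list(p = p, e = e)
}

ddNew <- function(hi, lo = 0) list(hi = hi, lo = lo)

ddAdd <- function(x, y) {
  s <- ddTwoSum(x$hi, y$hi)
  r <- ddQuickTwoSum(s$s, s$e + x$lo + y$lo)
  ddNew(r$s, r$e)
}

ddMulD <- function(x, d) {
  p <- ddTwoProd(x$hi, d)
  r <- ddQuickTwoSum(p$p, p$e + x$lo * d)
  ddNew(r$s, r$e)
}

## ---- radial polynomial: exact-coefficient factorial sum in dd ------------
## Coefficient of rho^(n-2s) is (-1)^s (n-s)! / (s! ((n+m)/2-s)! ((n-m)/2-s)!)
## = (-1)^s C(n-s, s) C(n-2s, (n-m)/2 - s), an exact integer below 2^53.

radialOracleDD <- function(n, m, rho) {
  m <- abs(m)
  k <- (n - m) %/% 2
  pw <- vector("list", n + 1L)        # dd powers rho^0 .. rho^n
  pw[[1]] <- ddNew(rep(1, length(rho)))
  if (n >= 1) for (j in 1:n) pw[[j + 1L]] <- ddMulD(pw[[j]], rho)
  acc <- ddNew(rep(0, length(rho)))
  for (s in 0:k) {
    coef <- (-1)^s * round(choose(n - s, s)) *
      round(choose(n - 2 * s, (n - m) / 2 - s))
    acc <- ddAdd(acc, ddMulD(pw[[n - 2 * s + 1L]], coef))
  }
  acc$hi + acc$lo
}

## Plain-double factorial sum; adequate for low orders (n <= 12).
radialOracleSum <- function(n, m, rho) {
  m <- abs(m)
  out <- rep(0, length(rho))
  for (s in 0:((n - m) / 2)) {
    coef <- (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) *
         factorial((n - m) / 2 - s))
    out <- out + coef * rho^(n - 2 * s)
  }
  out
}

## ---- Zernike moment: brute-force sum over grid points --------------------
momentOracle <- function(img, n, m) {
  tot <- 0 + 0i
  for (j in seq_along(img$rho)) {
    v <- radialOracleSum(n, m, img$rho[j]) *
      (cos(m * img$theta[j]) - 1i * sin(m * img$theta[j]))
    tot <- tot + img$values[j] * v
  }
  (n + 1) / pi * tot
}

## ---- memory block: straight-line scalar transcription --------------------
lstmStepOracle <- function(par, x, Cprev, hprev, eq12 = FALSE) {
  U <- length(par$bi)
  sig <- function(z) 1 / (1 + exp(-z))
  i <- f <- o <- g <- Cn <- h <- numeric(U)
  cat1 <- c(Cprev, x, hprev)
  for (u in seq_len(U)) {
    i[u] <- sig(sum(par$Wi[u, ] * cat1) + par$bi[u])
    f[u] <- sig(sum(par$Wf[u, ] * cat1) + par$bf[u])
    g[u] <- tanh(sum(par$Wc[u, ] * c(x, hprev)) + par$bc[u])
    Cn[u] <- Cprev[u] * f[u] + g[u] * i[u]
  }
  cat2 <- c(Cn, x, hprev)
  for (u in seq_len(U)) {
    o[u] <- sig(sum(par$Wo[u, ] * cat2) + par$bo[u])
    h[u] <- tanh(Cn[u]) * o[u] + if (eq12) g[u] * i[u] else 0
  }
  list(C = Cn, h = h, i = i, f = f, o = o, g = g)
}

randomBlockParams <- function(U, D) {
  list(Wi = matrix(rnorm(U * (2 * U + D)), U), bi = rnorm(U),
       Wf = matrix(rnorm(U * (2 * U + D)), U), bf = rnorm(U),
       Wo = matrix(rnorm(U * (2 * U + D)), U), bo = rnorm(U),
       Wc = matrix(rnorm(U * (U + D)), U), bc = rnorm(U))
}

## ---- AUC: O(n^2) pairwise comparison, ties scored one half ---------------
aucOracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

## ---- MCC: phi coefficient as a Pearson correlation -----------------------
phiOracle <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(1, fn), rep(0, tn), rep(0, fp))
  pred <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
  suppressWarnings(cor(truth, pred))
}
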