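## Zernike moments of disk-mapped profile matrices.
##
## The radial polynomials are evaluated through the Jacobi three-term
## recurrence R_nm(rho) = (-1)^k rho^m P_k^{(m,0)}(1 - 2 rho^2) with
## k = (n - m)/2, which is numerically stable up to high orders; the
## textbook alternating factorial sum loses ~7 significant digits at
## n = 30 near rho = 1 and is kept only as a test oracle.

.checkZernikeIndex <- function(n, m) {
  if (n < 0 || n != round(n))
    stop("invalid Zernike index: order n must be a non-negative integer")
  if (abs(m) > n)
    stop("invalid Zernike index: |m| must not exceed n")
  if ((n - abs(m)) %% 2 != 0)
    stop("invalid Zernike index: n - |m| must be even")
  invisible(TRUE)
}

## Jacobi polynomials P_k^{(a,0)} evaluated at x for k = 0..kMax; returns a
## matrix length(x) x (kMax+1). Stable three-term recurrence.
.jacobiColumns <- function(x, a, kMax) {
  out <- matrix(0, length(x), kMax + 1L)
  out[, 1L] <- 1
  if (kMax >= 1L) out[, 2L] <- (a + (a + 2) * x) / 2
  if (kMax >= 2L) {
    for (j in 2:kMax) {
      den <- 2 * j * (j + a) * (2 * j + a - 2)
      c1 <- (2 * j + a - 1) * (2 * j + a) * (2 * j + a - 2)
      c2 <- (2 * j + a - 1) * a^2
      c3 <- 2 * (j + a - 1) * (j - 1) * (2 * j + a)
      out[, j + 1L] <- ((c1 * x + c2) * out[, j] - c3 * out[, j - 1L]) / den
    }
  }
  out
}

#' Zernike radial polynomial
#'
#' Evaluates the radial polynomial \eqn{R_{nm}(\rho)}, the real radial
#' factor of the Zernike basis, equal to the alternating factorial sum
#' \deqn{R_{nm}(\rho) = \sum_{s=0}^{(n-|m|)/2} (-1)^s
#'   \frac{(n-s)!}{s!\,\left(\frac{n+|m|}{2}-s\right)!\,
#'   \left(\frac{n-|m|}{2}-s\right)!} \rho^{n-2s}.}
#' Satisfies \eqn{R_{n,-m} = R_{nm}} and \eqn{R_{nm}(1) = 1}.
#'
#' @param n non-negative integer order.
#' @param m integer repetition with \eqn{|m| \le n} and \eqn{n - |m|} even.
#' @param rho numeric vector of radii in [0, 1].
#' @return Numeric vector of values, one per element of \code{rho}.
#' @examples
#' radialPolynomial(2, 0, 0.5)  # 2*0.25 - 1
#' radialPolynomial(8, 4, 1)    # 1 at the disk rim for every valid index
#' @export
radialPolynomial <- function(n, m, rho) {
  .checkZernikeIndex(n, m)
  m <- abs(m)
  k <- (n - m) %/% 2
  P <- .jacobiColumns(1 - 2 * rho^2, m, k)[, k + 1L]
  (-1)^k * rho^m * P
}

#' Complex Zernike basis function
#'
#' \eqn{V_{nm}(\rho, \theta) = R_{nm}(\rho) e^{i m \theta}} for
#' \eqn{\rho \le 1}. The basis is orthogonal over the unit disk:
#' \eqn{\int V^*_{nm} V_{pq}\, \rho\, d\rho\, d\theta = \pi/(n+1)\,
#' \delta_{np}\delta_{mq}}.
#'
#' @inheritParams radialPolynomial
#' @param theta polar angle(s) in radians.
#' @return Complex vector.
#' @export
zernikeBasis <- function(n, m, rho, theta) {
  .checkZernikeIndex(n, m)
  if (any(rho > 1 + 1e-12))
    stop("zernikeBasis is defined only inside the unit disk (rho <= 1)")
  radialPolynomial(n, abs(m), rho) * exp(1i * m * theta)
}

#' Valid Zernike moment indices up to an order cap
#'
#' Enumerates the non-negative-repetition index pairs \code{(n, m)} with
#' \code{0 <= n <= nMax}, \code{0 <= m <= n} and \code{n - m} even, in
#' n-major, m-ascending order.
#'
#' @param nMax order cap.
#' @return data.frame with integer columns \code{n}, \code{m}.
#' @export
zernikeIndices <- function(nMax) {
  ns <- integer(0); ms <- integer(0)
  for (n in 0:nMax) {
    m <- seq.int(n %% 2L, n, by = 2L)
    ns <- c(ns, rep.int(n, length(m))); ms <- c(ms, m)
  }
  data.frame(n = as.integer(ns), m = as.integer(ms))
}

#' Feature index list: the retained magnitudes
#'
#' The magnitude feature vector keeps \eqn{|A_{nm}|} for \code{1 <= n <=
#' nMax}, \code{m >= 1}, \code{n - m} even. Zero-order information
#' (\code{n = 0} and all \code{m = 0} moments) is dropped: \eqn{m = 0}
#' magnitudes duplicate what low-order radial averages carry and the
#' negative repetitions are redundant by conjugate symmetry. At
#' \code{nMax = 30} this enumeration has exactly 240 entries.
#'
#' @param nMax order cap (default 30).
#' @return data.frame with integer columns \code{n}, \code{m}, n-major and
#'   m-ascending.
#' @export
zernikeFeatureIndices <- function(nMax = 30L) {
  idx <- zernikeIndices(nMax)
  idx[idx$n >= 1L & idx$m >= 1L, , drop = FALSE]
}

## Polar grid for an nr x nc matrix inscribed in [-1,1]^2: pixel centres,
## anisotropic scaling per axis, matrix centre at the origin.
.diskGrid <- function(nr, nc) {
  yy <- (2 * seq_len(nr) - nr - 1) / nr   # row coordinate in (-1, 1)
  xx <- (2 * seq_len(nc) - nc - 1) / nc   # column coordinate in (-1, 1)
  X <- matrix(xx, nr, nc, byrow = TRUE)
  Y <- matrix(yy, nr, nc)
  rho <- sqrt(X^2 + Y^2)
  inside <- rho <= 1
  list(rho = rho[inside], theta = atan2(Y[inside], X[inside]),
       inside = inside,
       row = row(inside)[inside], col = col(inside)[inside])
}

#' Map a profile matrix into the unit disk
#'
#' Pixel centres of the Y x 20 profile are affinely mapped so the matrix
#' centre sits at the origin and each axis spans (-1, 1) (the full matrix
#' inscribed in the unit square, anisotropic row/column scaling); points
#' falling outside the unit circle are masked out and take no part in the
#' moment sums. By default profile values are squashed through the logistic
#' \eqn{1/(1+e^{-x})} so the disk image is bounded in (0, 1) regardless of
#' the log-odds scale; pass \code{squash = FALSE} for raw values.
#'
#' @param pswm a \code{\linkS4class{PSWM}} or a plain numeric matrix.
#' @param squash logical; apply the logistic transform (default TRUE).
#' @return An object of class \code{DiskImage}: a list with the in-disk
#'   \code{values}, polar \code{rho} and \code{theta}, source \code{row}
#'   and \code{col} indices, the logical \code{inside} mask and the source
#'   \code{dim}.
#' @export
mapToUnitDisk <- function(pswm, squash = TRUE) {
  mat <- if (is(pswm, "PSWM")) profileMatrix(pswm) else as.matrix(pswm)
  if (nrow(mat) < 1L || ncol(mat) < 1L) stop("empty matrix")
  if (squash) mat <- 1 / (1 + exp(-mat))
  g <- .diskGrid(nrow(mat), ncol(mat))
  structure(list(values = mat[g$inside], rho = g$rho, theta = g$theta,
                 row = g$row, col = g$col, inside = g$inside,
                 dim = dim(mat), squash = squash),
            class = "DiskImage")
}

## Radial polynomial values for every index pair in idx at the radii rho;
## columns aligned with rows of idx. Recurrence shared across k for fixed m.
.radialMatrix <- function(rho, idx) {
  out <- matrix(0, length(rho), nrow(idx))
  x <- 1 - 2 * rho^2
  for (m in unique(idx$m)) {
    cols <- which(idx$m == m)
    k <- (idx$n[cols] - m) %/% 2L
    P <- .jacobiColumns(x, m, max(k))
    rm <- rho^m
    for (j in seq_along(cols))
      out[, cols[j]] <- (-1)^k[j] * rm * P[, k[j] + 1L]
  }
  out
}

#' Compute Zernike moments of a disk image
#'
#' Discrete moments over the in-disk grid points:
#' \deqn{A_{nm} = \frac{n+1}{\pi} \sum_{\rho \le 1} f(\rho, \theta)\,
#'   V^*_{nm}(\rho, \theta).}
#' Only \eqn{m \ge 0} moments are stored; negative repetitions follow from
#' \eqn{A_{n,-m} = \overline{A_{nm}}} (see \code{\link{momentAt}}).
#'
#' @param img a \code{DiskImage} from \code{\link{mapToUnitDisk}}.
#' @param nMax order cap (default 30).
#' @return A \code{\linkS4class{ZernikeMomentSet}}.
#' @export
computeMoments <- function(img, nMax = 30L) {
  if (!inherits(img, "DiskImage")) stop("img must be a DiskImage")
  nMax <- as.integer(nMax)
  if (nMax < 1L) stop("nMax must be at least 1")
  idx <- zernikeIndices(nMax)
  R <- .radialMatrix(img$rho, idx)
  vals <- complex(length.out = nrow(idx))
  for (m in unique(idx$m)) {
    cols <- which(idx$m == m)
    fm <- img$values * exp(-1i * m * img$theta)
    vals[cols] <- crossprod(R[, cols, drop = FALSE], fm)
  }
  vals <- vals * (idx$n + 1) / pi
  new("ZernikeMomentSet", values = vals, n = idx$n, m = idx$m,
      nMax = nMax, imageDim = as.integer(img$dim))
}

#' Look up a single moment, including negative repetitions
#'
#' @param moments a \code{\linkS4class{ZernikeMomentSet}}.
#' @param n,m index pair; \code{m} may be negative, in which case the
#'   conjugate of the stored moment is returned.
#' @return A complex scalar.
#' @export
momentAt <- function(moments, n, m) {
  .checkZernikeIndex(n, m)
  if (n > moments@nMax) stop("order exceeds the computed set")
  j <- which(moments@n == n & moments@m == abs(m))
  if (length(j) != 1L) stop("moment not found")
  if (m < 0) Conj(moments@values[j]) else moments@values[j]
}

#' Magnitude feature vector from a moment set
#'
#' Returns the rotation-invariant magnitudes \eqn{|A_{nm}|} at the retained
#' indices of \code{\link{zernikeFeatureIndices}}, in their fixed n-major,
#' m-ascending order. At \code{nMax = 30} the vector has exactly 240
#' entries.
#'
#' @param moments a \code{\linkS4class{ZernikeMomentSet}}.
#' @param nMax order cap; must not exceed the order the set was computed to.
#' @return Named numeric vector (names "n,m").
#' @export
zernikeFeatureVector <- function(moments, nMax = moments@nMax) {
  if (nMax > moments@nMax)
    stop("requested order exceeds the computed moment set")
  idx <- zernikeFeatureIndices(nMax)
  key <- paste(moments@n, moments@m)
  j <- match(paste(idx$n, idx$m), key)
  out <- Mod(moments@values[j])
  names(out) <- paste(idx$n, idx$m, sep = ",")
  out
}

#' Extract Zernike magnitude features for a set of profiles
#'
#' Full feature-extraction step: each profile is squashed (optionally),
#' mapped into the unit disk, its moments computed to \code{nMax}, and the
#' retained magnitudes collected into one row of the output matrix.
#'
#' @param pswms list of \code{\linkS4class{PSWM}} objects (or matrices).
#' @param nMax order cap (default 30, giving 240 features).
#' @param squash logical, logistic squashing before disk mapping.
#' @return Numeric matrix, one row per profile, with feature names as
#'   column names and attributes \code{nMax} and \code{squash} recording
#'   the extraction settings.
#' @export
extractFeatures <- function(pswms, nMax = 30L, squash = TRUE) {
  rows <- lapply(pswms, function(p) {
    zernikeFeatureVector(computeMoments(mapToUnitDisk(p, squash = squash),
                                        nMax = nMax))
  })
  out <- do.call(rbind, rows)
  if (!is.null(names(pswms))) rownames(out) <- names(pswms)
  attr(out, "nMax") <- as.integer(nMax)
  attr(out, "squash") <- squash
  out
}

#' Fit a PCA reduction on training features
#'
#' Centers and projects the raw magnitude features onto their leading
#' principal components. The projection is fitted on the training split
#' only and then applied unchanged to held-out data
#' (\code{\link{applyFeaturePCA}}), so no information leaks from validation
#' or test samples into the representation.
#'
#' @param x numeric matrix of training feature vectors (rows = proteins).
#' @param nComponents number of components to keep (default 150).
#' @return An object of class \code{zernPCA} with the centring vector, the
#'   rotation matrix and the component standard deviations.
#' @export
fitFeaturePCA <- function(x, nComponents = 150L) {
  x <- as.matrix(x)
  if (nComponents > ncol(x))
    stop("nComponents must not exceed the feature dimension")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = nComponents)
  if (ncol(p$rotation) < nComponents)
    stop(sprintf(
      "training data support only %d components (%d rows); reduce nComponents",
      ncol(p$rotation), nrow(x)))
  structure(list(center = p$center,
                 rotation = p$rotation[, seq_len(nComponents), drop = FALSE],
                 sdev = p$sdev, nComponents = as.integer(nComponents)),
            class = "zernPCA")
}

#' Apply a fitted PCA projection
#'
#' @param pca a \code{zernPCA} from \code{\link{fitFeaturePCA}}.
#' @param x feature matrix (or single vector) in the raw feature space.
#' @return Matrix of reduced coordinates.
#' @export
applyFeaturePCA <- function(pca, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  sweep(as.matrix(x), 2L, pca$center) %*% pca$rotation
}

#' @export
print.zernPCA <- function(x, ...) {
  cat(sprintf("PCA projection: %d -> %d components\n",
              length(x$center), x$nComponents))
  invisible(x)
}
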