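test_that("radial polynomials match their closed forms", {
  rho <- seq(0, 1, length.out = 11)
  expect_equal(radialPolynomial(0, 0, 0.37), 1)
  expect_equal(radialPolynomial(1, 1, rho), rho)
  expect_equal(radialPolynomial(2, 0, rho), 2 * rho^2 - 1)
  expect_equal(radialPolynomial(3, 1, rho), 3 * rho^3 - 2 * rho,
               tolerance = 1e-14)
  expect_equal(radialPolynomial(4, 0, rho), 6 * rho^4 - 6 * rho^2 + 1,
               tolerance = 1e-14)
})

test_that("radial polynomials are 1 at the rim for every valid index", {
  for (n in 0:30)
    for (m in seq(n %% 2, n, by = 2))
      expect_equal(radialPolynomial(n, m, 1), 1, tolerance = 1e-11)
})

test_that("negative repetitions reuse the |m| radial factor", {
  rho <- c(0.2, 0.55, 0.9)
  for (nm in list(c(4, 2), c(7, 3), c(12, 6)))
    expect_identical(radialPolynomial(nm[1], -nm[2], rho),
                     radialPolynomial(nm[1], nm[2], rho))
})

test_that("invalid Zernike indices are rejected", {
  expect_error(radialPolynomial(3, 2, 0.5), "even")
  expect_error(radialPolynomial(2, 3, 0.5), "exceed")
  expect_error(radialPolynomial(-1, 1, 0.5), "non-negative")
  expect_error(zernikeBasis(5, 2, 0.5, 0), "even")
})

test_that("radial evaluation agrees with the exact-coefficient oracle", {
  # stable-recurrence implementation vs the factorial sum with exact
  # integer coefficients evaluated in double-double arithmetic
  set.seed(2)
  rho <- c(0, 1, runif(20))
  for (n in c(1, 5, 12, 21, 30))
    for (m in seq(n %% 2, n, by = 2)) {
      got <- radialPolynomial(n, m, rho)
      want <- radialOracleDD(n, m, rho)
      expect_equal(got, want, tolerance = 1e-10)
    }
})

test_that("basis functions take their analytic values and reject rho > 1", {
  expect_equal(zernikeBasis(0, 0, 0.3, 1.1), 1 + 0i)
  expect_equal(zernikeBasis(1, 1, 1, pi / 2), 1i, tolerance = 1e-12)
  expect_equal(zernikeBasis(2, -2, 0.5, pi / 4),
               Conj(zernikeBasis(2, 2, 0.5, pi / 4)), tolerance = 1e-12)
  expect_error(zernikeBasis(1, 1, 1.2, 0), "unit disk")
})

test_that("the discrete basis is near-orthogonal on a fine grid", {
  # quadrature of (n+1)/pi * sum V*_{nm} V_{pq} dA over an N x N grid
  g <- zernSIP:::.diskGrid(128, 128)
  dA <- (2 / 128)^2
  pairs <- list(c(2, 2), c(3, 1), c(4, 0), c(5, 3))
  for (a in pairs) for (b in pairs) {
    Va <- zernikeBasis(a[1], a[2], g$rho, g$theta)
    Vb <- zernikeBasis(b[1], b[2], g$rho, g$theta)
    ip <- (a[1] + 1) / pi * sum(Conj(Va) * Vb) * dA
    target <- if (identical(a, b)) 1 else 0
    expect_equal(abs(ip), target, tolerance = 0.02)
  }
})

test_that("disk mapping centres the matrix and masks the corners", {
  img <- mapToUnitDisk(matrix(1, 21, 21), squash = FALSE)
  centre <- which(img$row == 11 & img$col == 11)
  expect_equal(img$rho[centre], 0)
  expect_false(img$inside[1, 1])    # corners fall outside the disk
  expect_false(img$inside[21, 21])

  # masked-point count equals the count of grid points with rho > 1
  M <- matrix(rnorm(64 * 20), 64, 20)
  yy <- (2 * (1:64) - 65) / 64
  xx <- (2 * (1:20) - 21) / 20
  outside <- outer(yy^2, xx^2, "+") > 1
  expect_equal(sum(!mapToUnitDisk(M)$inside), sum(outside))
})

test_that("disk values are the (squashed) matrix entries at mapped indices", {
  set.seed(3)
  M <- matrix(rnorm(64 * 20), 64, 20)
  img <- mapToUnitDisk(M, squash = TRUE)
  want <- vapply(seq_along(img$rho), function(j)
    1 / (1 + exp(-M[img$row[j], img$col[j]])), numeric(1))
  expect_equal(img$values, want)
  imgRaw <- mapToUnitDisk(M, squash = FALSE)
  expect_equal(imgRaw$values,
               vapply(seq_along(imgRaw$rho),
                      function(j) M[imgRaw$row[j], imgRaw$col[j]],
                      numeric(1)))
})

test_that("moments match the brute-force sum and obey symmetry", {
  set.seed(4)
  M <- matrix(rnorm(32 * 32), 32, 32)
  img <- mapToUnitDisk(M, squash = FALSE)
  ms <- computeMoments(img, nMax = 8)
  idx <- momentIndices(ms)
  for (j in seq_len(nrow(idx))) {
    want <- momentOracle(img, idx$n[j], idx$m[j])
    expect_equal(momentAt(ms, idx$n[j], idx$m[j]), want,
                 tolerance = 1e-10)
  }
  # conjugate symmetry is exact
  expect_identical(momentAt(ms, 6, -4), Conj(momentAt(ms, 6, 4)))

  # all-zero image: every moment zero
  z <- img; z$values <- 0 * z$values
  expect_true(all(Mod(computeMoments(z, nMax = 8)@values) == 0))

  expect_error(computeMoments(img, nMax = 0), "at least 1")
})

test_that("moments are linear in the image", {
  set.seed(5)
  M1 <- matrix(rnorm(200), 10, 20); M2 <- matrix(rnorm(200), 10, 20)
  i1 <- mapToUnitDisk(M1, squash = FALSE)
  i2 <- mapToUnitDisk(M2, squash = FALSE)
  i12 <- mapToUnitDisk(1.7 * M1 - 0.4 * M2, squash = FALSE)
  a <- computeMoments(i12, nMax = 6)@values
  b <- 1.7 * computeMoments(i1, nMax = 6)@values -
    0.4 * computeMoments(i2, nMax = 6)@values
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("magnitudes are invariant under 90-degree rotation", {
  set.seed(6)
  M <- matrix(rnorm(33 * 33), 33, 33)
  f1 <- zernikeFeatureVector(computeMoments(mapToUnitDisk(M), nMax = 12))
  f2 <- zernikeFeatureVector(computeMoments(mapToUnitDisk(rotate90(M)),
                                            nMax = 12))
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("feature enumeration drops zero-order information", {
  idx <- zernikeFeatureIndices(30)
  expect_equal(nrow(idx), 240L)
  expect_true(all(idx$m >= 1))
  expect_true(all((idx$n - idx$m) %% 2 == 0))
  # the enumeration count follows the parity formula
  count <- sum(vapply(1:30, function(n)
    length(seq(2 - n %% 2, n, by = 2)), numeric(1)))
  expect_equal(nrow(idx), count)
  expect_equal(zernikeFeatureIndices(2),
               data.frame(n = c(1L, 2L), m = c(1L, 2L)),
               ignore_attr = TRUE)
})

test_that("feature vectors have the documented length and order", {
  set.seed(7)
  M <- matrix(rnorm(50 * 20), 50, 20)
  ms <- computeMoments(mapToUnitDisk(M), nMax = 30)
  f <- zernikeFeatureVector(ms)
  expect_length(f, 240L)
  expect_equal(names(f)[1:3], c("1,1", "2,2", "3,1"))
  expect_true(all(f >= 0))
  # requesting beyond the computed order fails
  expect_error(zernikeFeatureVector(ms, nMax = 31), "exceeds")
  # zero image gives the zero vector
  z <- mapToUnitDisk(matrix(0, 50, 20), squash = FALSE)
  expect_equal(unname(zernikeFeatureVector(computeMoments(z, 30))),
               rep(0, 240))
})

test_that("PCA matches the covariance eigendecomposition oracle", {
  set.seed(8)
  x <- matrix(rnorm(500 * 40), 500, 40)
  pca <- fitFeaturePCA(x, nComponents = 10)
  red <- applyFeaturePCA(pca, x)
  expect_equal(dim(red), c(500L, 10L))

  # oracle: eigenvectors of the sample covariance, up to sign
  ev <- eigen(cov(x), symmetric = TRUE)
  for (j in 1:10) {
    dotp <- sum(pca$rotation[, j] * ev$vectors[, j])
    expect_equal(abs(dotp), 1, tolerance = 1e-8)
  }
  # explained variance non-increasing
  expect_true(all(diff(pca$sdev) <= 1e-12))

  # data in an exact low-dimensional subspace reconstructs exactly
  basis <- qr.Q(qr(matrix(rnorm(40 * 10), 40, 10)))
  y <- matrix(rnorm(200 * 10), 200, 10) %*% t(basis)
  p2 <- fitFeaturePCA(y, nComponents = 10)
  recon <- applyFeaturePCA(p2, y) %*% t(p2$rotation) +
    matrix(p2$center, 200, 40, byrow = TRUE)
  expect_equal(recon, y, tolerance = 1e-10)

  expect_error(fitFeaturePCA(x, nComponents = 41), "exceed")
})
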