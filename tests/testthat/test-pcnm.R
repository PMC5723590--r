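test_that("Moran's I matches hand computation and its permutation null", {
  W <- connectivityFromTruncation(cbind(1:4, 0), 1)
  expect_equal(moransI(c(1, 2, 3, 4), W), 1 / 3)
  # permutation expectation is -1/(n-1)
  set.seed(5)
  n <- 12
  xy <- cbind(runif(n), runif(n))
  W <- connectivityFromTruncation(xy, 0.5)
  v <- rnorm(n)
  draws <- replicate(10000, moransI(sample(v), W))
  expect_equal(mean(draws), -1 / (n - 1), tolerance = 0.01)
  # checkerboard on a grid with rook neighbours is negatively autocorrelated
  g <- expand.grid(x = 1:4, y = 1:4)
  Wr <- connectivityFromTruncation(as.matrix(g), 1)
  expect_lt(moransI((-1)^(g$x + g$y), Wr), 0)
  expect_error(moransI(rep(1, 4), W[1:4, 1:4]), "zero-variance")
})

test_that("truncation connectivity builds the expected graphs", {
  xy <- cbind(seq(0, 90, by = 10), 0)
  W <- connectivityFromTruncation(xy, 10)
  expect_equal(sum(W) / 2, 9)                 # path graph
  Wc <- connectivityFromTruncation(xy, 100)
  expect_equal(sum(Wc) / 2, choose(10, 2))    # complete graph
  expect_error(connectivityFromTruncation(xy, 5), "empty graph")
  # the default truncation (longest MST edge) keeps the graph connected
  set.seed(8)
  pts <- cbind(runif(25, 0, 100), runif(25, 0, 100))
  b <- pcnm(pts)
  W <- connectivityFromTruncation(pts, truncationDistance(b))
  reach <- (diag(25) + W)
  for (i in 1:25) reach <- 1 * ((reach %*% (diag(25) + W)) > 0)
  expect_true(all(reach > 0))
})

test_that("PCNM eigenvectors have classical transect structure", {
  xy <- cbind(seq(0, 90, by = 10), 0)
  b <- pcnm(xy)
  V <- eigenvectors(b)
  signChanges <- function(v) sum(diff(sign(v)) != 0)
  # first vector is broad-scale (one sign change along the transect),
  # later vectors oscillate faster
  expect_equal(signChanges(V[, 1]), 1)
  expect_true(all(diff(vapply(seq_len(min(4, ncol(V))),
                              function(k) signChanges(V[, k]),
                              numeric(1))) > 0))
})

test_that("the basis is orthogonal, Moran-screened and spectrally faithful", {
  xy <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  b <- pcnm(xy)
  V <- eigenvectors(b)
  expect_equal(crossprod(V), diag(ncol(V)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(colMeans(V), rep(0, ncol(V)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(moran(b) > -1 / (nrow(xy) - 1)))
  # retained rank bound on the 130-grain design
  ce <- grainCentroids(makeGrainDesign(260, 200, 20))
  b130 <- pcnm(cbind(ce$cx, ce$cy))
  expect_lte(ncol(eigenvectors(b130)), 129L)
  expect_true(all(moran(b130) > -1 / 129))
  # spectral identity: the retained part of the centered Gower matrix
  set.seed(13)
  xy <- cbind(runif(9, 0, 50), runif(9, 0, 50))
  b <- pcnm(xy)
  D <- as.matrix(dist(xy))
  t <- truncationDistance(b)
  Dstar <- D; Dstar[D > t] <- 4 * t
  A <- -0.5 * Dstar^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  e <- eigen(G, symmetric = TRUE)
  pos <- e$values > 1e-8 * max(e$values)
  Gpos <- e$vectors[, pos] %*% diag(e$values[pos]) %*% t(e$vectors[, pos])
  V <- eigenvectors(b)
  expect_equal(V %*% diag(eigenvalues(b)) %*% t(V),
               V %*% crossprod(V, Gpos), tolerance = 1e-8)
  expect_error(pcnm(rbind(c(0, 0), c(0, 0), c(1, 1))), "duplicate")
})

test_that("the basis is invariant to uniform rescaling of the coordinates", {
  set.seed(17)
  xy <- cbind(runif(12, 0, 40), runif(12, 0, 40))
  b1 <- pcnm(xy)
  b2 <- pcnm(xy * 3, truncation = truncationDistance(b1) * 3)
  expect_equal(abs(eigenvectors(b1)), abs(eigenvectors(b2)), tolerance = 1e-8)
})

test_that("positive-Moran eigenvector count grows with grid resolution", {
  count <- function(n) {
    g <- expand.grid(x = seq_len(n), y = seq_len(n)) * 10
    ncol(eigenvectors(pcnm(as.matrix(g))))
  }
  counts <- vapply(c(3, 5, 7), count, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("eigenvalues agree with the reference PCNM implementation", {
  skip_if_not_installed("vegan")
  set.seed(23)
  xy <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  ours <- pcnm(xy)
  ref <- vegan::pcnm(dist(xy), threshold = truncationDistance(ours))
  # vegan keeps the positive eigenvalues; we additionally screen by
  # Moran's I, so every eigenvalue we retain must appear in its spectrum
  tol <- 1e-6 * max(ref$values)
  expect_true(all(vapply(eigenvalues(ours),
                         function(l) any(abs(ref$values - l) < tol),
                         logical(1))))
})
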