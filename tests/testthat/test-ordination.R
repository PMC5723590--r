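test_that("RDA recovers a perfect predictor and the Ezekiel adjustment", {
  set.seed(1)
  Y <- matrix(rnorm(20), 10, 2)
  x <- sweep(Y, 2, colMeans(Y))[, 1]
  fit <- rdaR2(Y[, 1, drop = FALSE], cbind(x))
  expect_equal(fit@r2, 1, tolerance = 1e-12)
  expect_equal(adjustedR2(0.5, 30, 5), 1 - 0.5 * 29 / 24)  # 0.3958333
  expect_equal(adjustedR2(1, 17, 4), 1)
  expect_equal(adjustedR2(0.42, 50, 0), 0.42)
  expect_error(adjustedR2(0.5, 6, 5), "n > m")
  expect_error(rdaR2(Y, cbind(x, 2 * x)), "collinear")
  expect_error(rdaR2(Y[1:3, ], matrix(rnorm(9), 3, 3)), "too few")
})

test_that("noise predictors explain nothing once adjusted", {
  set.seed(2)
  adj <- replicate(100, {
    Y <- matrix(rnorm(40 * 5), 40, 5)
    X <- matrix(rnorm(40 * 3), 40, 3)
    rdaR2(Y, X)@adjR2
  })
  expect_lt(abs(mean(adj)), 0.02)
})

test_that("multivariate R2 equals stacked univariate regressions", {
  set.seed(3)
  for (i in 1:10) {
    Y <- matrix(rnorm(40), 10, 4)
    X <- matrix(rnorm(40), 10, 4)
    fit <- rdaR2(Y, X)
    Yc <- sweep(Y, 2, colMeans(Y))
    ssf <- sum(vapply(seq_len(ncol(Y)), function(j)
      sum(lm(Yc[, j] ~ X)$fitted^2), numeric(1)))
    expect_equal(fit@r2, ssf / sum(Yc^2), tolerance = 1e-10)
  }
})

test_that("explained variance matches the reference RDA implementation", {
  skip_if_not_installed("vegan")
  set.seed(4)
  Y <- hellingerTransform(randomCounts(25, 8) + 1)
  X <- data.frame(a = rnorm(25), b = rnorm(25), c = rnorm(25))
  fit <- rdaR2(Y, X)
  ref <- vegan::rda(Y ~ ., data = X)
  expect_equal(fit@r2, vegan::RsquareAdj(ref)$r.squared, tolerance = 1e-10)
  expect_equal(fit@adjR2, vegan::RsquareAdj(ref)$adj.r.squared, tolerance = 1e-10)
  expect_equal(fit@statistic, as.numeric(vegan::anova.cca(ref)$F[1]),
               tolerance = 1e-8)
})

test_that("orthogonal predictors contribute additively to R2", {
  set.seed(5)
  X <- qr.Q(qr(matrix(rnorm(60), 20, 3)))   # orthonormal, centered below
  X <- sweep(X, 2, colMeans(X))
  X <- qr.Q(qr(X))
  Y <- matrix(rnorm(20 * 4), 20, 4)
  total <- rdaR2(Y, X, standardize = FALSE)@r2
  parts <- vapply(1:3, function(k)
    rdaR2(Y, X[, k, drop = FALSE], standardize = FALSE)@r2, numeric(1))
  expect_equal(total, sum(parts), tolerance = 1e-10)
})

test_that("semi-partial R2 satisfies the subtraction identity", {
  set.seed(6)
  for (i in 1:10) {
    Y <- matrix(rnorm(30 * 3), 30, 3)
    X <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("x1", "x2")))
    W <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("w1", "w2")))
    part <- permutationTest(Y, X, W = W, nPerm = 1)@r2
    rXW <- rdaR2(Y, cbind(X, W))@r2
    rW <- rdaR2(Y, W)@r2
    expect_equal(part, rXW - rW, tolerance = 1e-10)
  }
})

test_that("permutation tests are deterministic, maximal for perfect fits, and affine-invariant", {
  set.seed(7)
  Y <- matrix(rnorm(30 * 4), 30, 4)
  X <- matrix(rnorm(30 * 2), 30, 2)
  p1 <- permutationTest(Y, X, nPerm = 99, seed = 11)@pValue
  p2 <- permutationTest(Y, X, nPerm = 99, seed = 11)@pValue
  expect_identical(p1, p2)
  # affine transformation of the predictors changes nothing
  p3 <- permutationTest(Y, 3 * X + 7, nPerm = 99, seed = 11)@pValue
  expect_identical(p1, p3)
  # a perfect predictor attains the minimal p-value
  Yc <- sweep(Y[, 1, drop = FALSE], 2, colMeans(Y[, 1, drop = FALSE]))
  perfect <- permutationTest(Y[, 1, drop = FALSE], Yc, nPerm = 99, seed = 1)
  expect_equal(perfect@pValue, 1 / 100)
  expect_true(perfect@degenerate)
})

test_that("residual-permutation partial tests keep their level under conditioning", {
  # X pure noise given a real conditioning variable: p should be uniform
  # enough that rejection at 0.05 stays near 0.05
  set.seed(8)
  ps <- replicate(200, {
    w <- rnorm(25)
    Y <- outer(w, rnorm(3)) + matrix(rnorm(75), 25, 3)
    x <- rnorm(25)
    permutationTest(Y, cbind(x), W = cbind(w), nPerm = 199)@pValue
  })
  expect_gte(mean(ps <= 0.05), 0.02)
  expect_lte(mean(ps <= 0.05), 0.10)
  expect_gt(mean(ps), 0.4)   # roughly uniform null p-values
  expect_lt(mean(ps), 0.6)
})

test_that("forward selection keeps true predictors and drops noise", {
  set.seed(9)
  n <- 40
  cand <- matrix(rnorm(n * 6), n, 6,
                 dimnames = list(NULL, paste0("v", 1:6)))
  Y <- outer(cand[, 2], c(1, -1, 0.5)) + outer(cand[, 5], c(0.5, 1, -1)) +
    matrix(rnorm(n * 3, sd = 0.3), n, 3)
  sel <- forwardSelect(Y, cand, nPerm = 199, seed = 10, adjR2Ceiling = FALSE)
  expect_true(all(c("v2", "v5") %in% selectedVars(sel)))
  # a perfect single candidate is selected
  Y1 <- cand[, 1, drop = FALSE]
  sel1 <- forwardSelect(Y1, cand[, 1, drop = FALSE], nPerm = 99, seed = 1)
  expect_equal(selectedVars(sel1), "v1")
  # ... and the double-stopping ceiling is recorded
  expect_true(is.finite(sel@globalAdjR2))
})

test_that("the adjusted-R2 ceiling stops selection like the reference stepwise procedure", {
  # with the ceiling on, the selected model's adjusted R2 may never
  # exceed the all-candidate model's
  set.seed(12)
  for (i in 1:10) {
    cand <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(NULL, paste0("v", 1:8)))
    Y <- outer(cand[, 1], c(1, -1)) + outer(cand[, 2], c(0.6, 0.9)) +
      matrix(rnorm(80, sd = 0.4), 40, 2)
    sel <- forwardSelect(Y, cand, nPerm = 99)
    if (nrow(sel@steps))
      expect_true(all(sel@steps$adjR2Cum <= sel@globalAdjR2 + 1e-12))
  }
  skip_if_not_installed("vegan")
  withr::local_package("vegan")   # ordiR2step's update() needs rda attached
  # on identical data the ceiling-on selection and vegan's R2-scoped
  # stepwise RDA agree on the selected set (both implement the same
  # double stopping rule; signal strong enough that alpha never binds)
  set.seed(13)
  cand <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, paste0("v", 1:6)))
  Y <- outer(cand[, 4], c(2, -2, 1)) + matrix(rnorm(150, sd = 0.3), 50, 3)
  ours <- selectedVars(forwardSelect(Y, cand, nPerm = 199, seed = 1))
  d <- as.data.frame(cand)
  ref <- attr(terms(vegan::ordiR2step(vegan::rda(Y ~ 1, data = d),
                                      vegan::rda(Y ~ ., data = d),
                                      trace = FALSE, permutations = 199)),
              "term.labels")
  expect_setequal(ours, ref)
})

test_that("the global gate returns an empty set on pure noise", {
  set.seed(10)
  empty <- replicate(60, {
    Y <- matrix(rnorm(30 * 4), 30, 4)
    cand <- matrix(rnorm(30 * 8), 30, 8)
    length(selectedVars(forwardSelect(Y, cand, nPerm = 99))) == 0
  })
  expect_gte(mean(empty), 0.9)
})
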