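test_that("grain designs tile the plot with remainder strips excluded", {
  # the four standard designs on the 260 x 200 m plot
  expect_equal(nGrains(makeGrainDesign(260, 200, 20)), 130L)
  expect_equal(coveredArea(makeGrainDesign(260, 200, 20)), 5.2)
  expect_equal(nGrains(makeGrainDesign(260, 200, 30)), 48L)
  expect_equal(coveredArea(makeGrainDesign(260, 200, 30)), 4.32)
  expect_equal(nGrains(makeGrainDesign(260, 200, 40)), 30L)
  expect_equal(coveredArea(makeGrainDesign(260, 200, 40)), 4.8)
  expect_equal(nGrains(makeGrainDesign(260, 200, 50)), 20L)
  expect_equal(coveredArea(makeGrainDesign(260, 200, 50)), 5.0)
  # identity tiling
  d <- makeGrainDesign(100, 100, 100)
  expect_equal(nGrains(d), 1L)
  expect_equal(coveredArea(d), 1.0)
  expect_error(makeGrainDesign(100, 100, 150), "exceeds")
  # footprints are disjoint and inside the plot
  d <- makeGrainDesign(260, 200, 30)
  cc <- grainCorners(d)
  expect_false(anyDuplicated(cc[c("x0", "y0")]) > 0)
  expect_true(all(cc$x0 + 30 <= 260 & cc$y0 + 30 <= 200))
})

test_that("aggregation counts every stem inside the covered area exactly once", {
  # single stem at the origin lands in grain 1
  sm <- StemMap(0, 0, "A", 5, plotWidth = 260, plotHeight = 200)
  gc <- aggregateCommunity(sm, makeGrainDesign(260, 200, 20))
  X <- communityMatrix(gc)
  expect_equal(sum(X), 1)
  expect_equal(unname(X[1, "A"]), 1L)
  # stem in the 30 m remainder strip (covered region 240 x 180) is excluded
  sm <- StemMap(259.5, 199.5, "A", 5, plotWidth = 260, plotHeight = 200)
  X <- communityMatrix(aggregateCommunity(sm, makeGrainDesign(260, 200, 30)))
  expect_equal(sum(X), 0)
  expect_equal(ncol(X), 0L)  # zero-abundance species dropped
  expect_error(
    aggregateCommunity(sm, makeGrainDesign(100, 100, 20)),
    "plot dimensions")
})

test_that("full-coverage column sums reproduce per-species stem counts and row order is irrelevant", {
  set.seed(11)
  n <- 400
  sm <- StemMap(runif(n, 0, 260), runif(n, 0, 200),
                sample(letters[1:6], n, TRUE), 1 + rexp(n, 1 / 7),
                plotWidth = 260, plotHeight = 200)
  d20 <- makeGrainDesign(260, 200, 20)   # exact coverage
  X <- communityMatrix(aggregateCommunity(sm, d20))
  direct <- table(stems(sm)$species)
  expect_equal(colSums(X)[names(direct)], unclass(c(direct)),
               ignore_attr = TRUE)
  # permutation invariance to stem row order
  perm <- sample(n)
  smP <- StemMap(stems(sm)$x[perm], stems(sm)$y[perm],
                 stems(sm)$species[perm], stems(sm)$dbh[perm], 260, 200)
  expect_equal(communityMatrix(aggregateCommunity(smP, d20)), X)
})

test_that("upscaling is the identity at the native scale and exact for constants", {
  es <- syntheticEnvTable(260, 200)
  base <- makeGrainDesign(260, 200, 20)
  for (m in c("block_mean", "kriging")) {
    out <- upscaleEnvironment(es, base, m)
    expect_equal(out$ph, es@samples$ph)
    expect_equal(out$om, es@samples$om)
  }
  # constant soil field stays constant under both methods
  esC <- es
  esC@samples[c("om", "ph", "tn", "p", "k", "depth")] <-
    list(8, 5.5, 3000, 30, 150, 70)
  d40 <- makeGrainDesign(260, 200, 40)
  for (m in c("block_mean", "kriging")) {
    out <- upscaleEnvironment(esC, d40, m)
    expect_equal(out$om, rep(8, 30), tolerance = 1e-6)
    expect_equal(out$depth, rep(70, 30), tolerance = 1e-6)
  }
})

test_that("block means conserve the global mean on nesting designs", {
  es <- syntheticEnvTable(240, 200)   # 40 m design nests 20 m exactly
  out <- upscaleEnvironment(es, makeGrainDesign(240, 200, 40), "block_mean")
  for (v in c("om", "ph", "tn"))
    expect_equal(mean(out[[v]]), mean(es@samples[[v]]), tolerance = 1e-12)
})

test_that("kriging beats block means at predicting a smooth field at coarse centres", {
  # Monte-Carlo: on smooth random surfaces the point prediction at 40 m
  # grain centres should be at least as accurate from kriging as from
  # averaging the four surrounding base samples.
  nSeed <- 50
  rmseK <- rmseB <- numeric(nSeed)
  d40 <- makeGrainDesign(260, 200, 40)
  ce <- grainCentroids(d40)
  for (s in seq_len(nSeed)) {
    env <- generateEnvironment(260, 200, seed = s,
                               params = list(om = list(range = 90)))
    es <- sampleEnvTable(env)
    truth <- evalField(env, "om", ce$cx, ce$cy)
    k <- upscaleEnvironment(es, d40, "kriging")$om
    b <- upscaleEnvironment(es, d40, "block_mean")$om
    rmseK[s] <- sqrt(mean((k - truth)^2))
    rmseB[s] <- sqrt(mean((b - truth)^2))
  }
  expect_lt(mean(rmseK), mean(rmseB))
})

test_that("topographic metrics match plane geometry in closed form", {
  # inclined plane z = 0.1 x: slope atan(0.1), west-facing aspect
  es <- syntheticEnvTable(60, 40, elevFun = function(vx, vy) 0.1 * vx)
  topo <- topoMetrics(es, makeGrainDesign(60, 40, 20))
  expect_equal(topo$slope, rep(atan(0.1) * 180 / pi, 6), tolerance = 1e-8)
  expect_equal(topo$aspect, rep(270, 6))
  expect_false(any(topo$flat))
  # on a linear surface an interior grain equals its neighbour mean
  es5 <- syntheticEnvTable(100, 100, elevFun = function(vx, vy) 0.1 * vx)
  topo5 <- topoMetrics(es5, makeGrainDesign(100, 100, 20))
  interior <- c(7, 8, 9, 12, 13, 14, 17, 18, 19)  # 5 x 5 lattice centre
  expect_equal(topo5$convexity[interior], rep(0, 9), tolerance = 1e-8)
  # flat field: slope 0, aspect encoded 0 with flatness flag
  esF <- syntheticEnvTable(60, 40, elevFun = function(vx, vy) 5 + 0 * vx)
  topoF <- topoMetrics(esF, makeGrainDesign(60, 40, 20))
  expect_equal(topoF$slope, rep(0, 6), tolerance = 1e-10)
  expect_true(all(topoF$flat))
  expect_equal(topoF$aspect, rep(0, 6))
  # an elevated interior grain has positive convexity
  esB <- syntheticEnvTable(60, 60, elevFun = function(vx, vy)
    10 * exp(-((vx - 30)^2 + (vy - 30)^2) / 200))
  topoB <- topoMetrics(esB, makeGrainDesign(60, 60, 20))
  expect_gt(topoB$convexity[5], 0)   # centre grain of the 3 x 3 design
})

test_that("coarse-grain vertices interpolate from the base vertex grid", {
  es <- syntheticEnvTable(260, 200, elevFun = function(vx, vy) 0.05 * vx + 0.02 * vy)
  topo30 <- topoMetrics(es, makeGrainDesign(260, 200, 30))
  # a linear surface interpolates exactly, so every grain sees the same slope
  grad <- sqrt(0.05^2 + 0.02^2)
  expect_equal(topo30$slope, rep(atan(grad) * 180 / pi, 48), tolerance = 1e-8)
  em <- envMatrix(es, makeGrainDesign(260, 200, 30))
  expect_equal(nrow(em), 48L)
  expect_false(anyNA(em))
})
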