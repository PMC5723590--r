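test_that("environmental surfaces are deterministic and range-controlled", {
  e1 <- generateEnvironment(100, 100, seed = 7)
  e2 <- generateEnvironment(100, 100, seed = 7)
  expect_identical(e1@grids, e2@grids)
  e3 <- generateEnvironment(100, 100, seed = 8)
  expect_false(identical(e1@grids$ph, e3@grids$ph))
  # huge correlation range: essentially flat surface
  eFlat <- generateEnvironment(100, 100, seed = 1,
                               params = list(ph = list(range = 1e6)))
  v <- evalField(eFlat, "ph", c(0, 95), c(0, 95))
  expect_lt(abs(diff(v)), 0.02)
  expect_error(generateEnvironment(100, 100, params = list(ph = list(range = -5))),
               "range")
  # rootable depth respects its physical band
  depth <- evalField(e1, "depth", runif(200, 0, 99), runif(200, 0, 99))
  expect_true(all(depth >= 10 & depth <= 130))
})

test_that("the empirical correlogram decays at the configured range scale", {
  # Monte-Carlo over replicate fields: for exponential correlation the
  # correlation at lag = range is exp(-1), and far pairs decorrelate.
  phi <- 30
  lag1 <- lag3 <- numeric(100)
  for (s in 1:100) {
    env <- generateEnvironment(200, 200, seed = s, gridRes = 10,
                               params = list(ph = list(range = phi)))
    g <- env@grids$ph
    # standardize by the construction marginals (mean 5.5, sd 0.4);
    # per-field empirical centering would deflate long-range correlation
    z <- (g - 5.5) / 0.4
    nx <- nrow(g)
    # pairs 3 grid steps (30 m = phi) and 9 steps (3 phi) apart along x
    lag1[s] <- mean(z[1:(nx - 3), ] * z[4:nx, ])
    lag3[s] <- mean(z[1:(nx - 9), ] * z[10:nx, ])
  }
  # exponential correlation: exp(-1) at one range, exp(-3) at three
  expect_lt(abs(mean(lag1) - exp(-1)), 0.06)
  expect_lt(mean(lag3), mean(lag1))
  expect_lt(abs(mean(lag3) - exp(-3)), 0.06)
})

test_that("a niche-free, cluster-free community is complete spatial randomness", {
  # chi-square goodness of fit of per-grain totals against uniform
  # multinomial, across seeds; at alpha = 0.01 at most a few reject
  nSeed <- 100
  reject <- logical(nSeed)
  env <- generateEnvironment(100, 100, seed = 1)
  d <- makeGrainDesign(100, 100, 20)
  for (s in seq_len(nSeed)) {
    cp <- CommunityParams(nSpecies = 8, nStems = 500, nicheStrength = 0,
                          mixtureWeight = 0, seed = s)
    sm <- generateCommunity(env, cp)
    counts <- colSums(assay(aggregateCommunity(sm, d), "counts"))
    reject[s] <- suppressWarnings(chisq.test(counts)$p.value) < 0.01
  }
  expect_gte(mean(!reject), 0.95)
})

test_that("pure clustering yields an aggregated point pattern", {
  env <- generateEnvironment(100, 100, seed = 2)
  ce <- vapply(1:10, function(s) {
    cp <- CommunityParams(nSpecies = 5, nStems = 400, nicheStrength = 0,
                          mixtureWeight = 1, clusterSD = 5,
                          clusterRate = 5e-4, seed = s)
    sm <- generateCommunity(env, cp)
    clarkEvans(stems(sm)$x, stems(sm)$y, 1e4)
  }, numeric(1))
  expect_true(all(ce < 1))
})

test_that("the generator is deterministic and respects stem counts and census rules", {
  env <- generateEnvironment(100, 100, seed = 3)
  cp <- CommunityParams(nSpecies = 10, nStems = 800, seed = 4)
  s1 <- generateCommunity(env, cp)
  s2 <- generateCommunity(env, cp)
  expect_identical(stems(s1), stems(s2))
  expect_equal(nStems(s1), 800L)
  expect_true(all(stems(s1)$dbh >= 1))
  empty <- generateCommunity(env, CommunityParams(nSpecies = 5, nStems = 0, seed = 1))
  expect_equal(nStems(empty), 0L)
  expect_error(CommunityParams(nSpecies = 0), "species")
})

test_that("scenarios fix the canonical process mixtures", {
  sc <- scenario("pure_env", seed = 1, nStems = 200)
  expect_gt(sc$params@nicheStrength, 0)
  expect_equal(sc$params@mixtureWeight, 0)
  sc <- scenario("pure_dispersal", seed = 1, nStems = 200)
  expect_equal(sc$params@nicheStrength, 0)
  expect_equal(sc$params@mixtureWeight, 1)
  sc <- scenario("random", seed = 1, nStems = 200)
  expect_equal(sc$params@nicheStrength, 0)
  expect_equal(sc$params@mixtureWeight, 0)
  expect_error(scenario("exotic", seed = 1), "arg")
  # emulation envelope at defaults: community size of a censused 5.2-ha plot
  sc <- scenario("mixed", seed = 5)
  expect_true(nStems(sc$stems) >= 10000 && nStems(sc$stems) <= 30000)
  nSp <- length(unique(stems(sc$stems)$species))
  expect_true(nSp >= 20 && nSp <= 70)
})
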