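# Shared fixtures and independent oracles, all built in code.

# random grains-by-species count matrix
randomCounts <- function(n, p, lambda = 5) {
  matrix(rpois(n * p, lambda), nrow = n,
         dimnames = list(paste0("g", seq_len(n)), paste0("sp", seq_len(p))))
}

# Clark-Evans aggregation index: ratio of the mean nearest-neighbour
# distance to its expectation 1/(2 sqrt(density)) under CSR.  < 1 means
# aggregation.  Classical point-pattern oracle, computed from scratch.
clarkEvans <- function(x, y, area) {
  D <- as.matrix(dist(cbind(x, y)))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  mean(nn) / (0.5 / sqrt(length(x) / area))
}

# tiny synthetic environmental sample table on a w x h plot with 20 m
# base grains and an arbitrary vertex elevation function
syntheticEnvTable <- function(w, h, elevFun = function(vx, vy) 0 * vx,
                              baseGrain = 20) {
  d <- makeGrainDesign(w, h, baseGrain)
  ce <- grainCentroids(d)
  soil <- data.frame(cx = ce$cx, cy = ce$cy,
                     om = 8 + 0.01 * ce$cx, ph = 5.5 + 0.001 * ce$cy,
                     tn = 3000 + ce$cx, p = 30 + 0.05 * ce$cy,
                     k = 150 - 0.1 * ce$cx, depth = 70 + 0.05 * ce$cx)
  vx <- seq(0, d@nX) * baseGrain
  vy <- seq(0, d@nY) * baseGrain
  vert <- expand.grid(vx = vx, vy = vy)
  vert$elev <- elevFun(vert$vx, vert$vy)
  EnvSampleTable(soil, vert, w, h, baseGrain)
}
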