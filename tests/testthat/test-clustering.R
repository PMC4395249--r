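test_that("delta grid spans the off-diagonal range with L points", {
  D <- matrix(0, 4, 4)
  D[upper.tri(D)] <- c(0.2, 0.4, 0.5, 0.6, 0.7, 0.8)
  D <- D + t(D)
  g <- deltaGrid(D)
  expect_length(g, 4L)
  expect_equal(g[1], 0.2)
  expect_equal(g[4], 0.8)
  expect_equal(diff(g), rep(0.2, 3), tolerance = 1e-12)
  # L = 2: min and max coincide, collapsing the grid to one point
  D2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  expect_warning(g2 <- deltaGrid(D2), "constant")
  expect_equal(g2, 0.3)
  # constant matrix: single point with a warning
  Dc <- matrix(1, 3, 3); diag(Dc) <- 0
  expect_warning(g1 <- deltaGrid(Dc), "constant")
  expect_equal(g1, 1)
})

test_that("two disconnected cliques keep K = 2 with Delta -> 1", {
  W <- blockAffinity(c(4, 4), 1, 0, diagVal = 0)
  scan <- eigengapCurves(W, MLimit = 200L)
  expect_equal(unique(scan$K), 2L)
  expect_equal(length(scan$M), 200L)        # never mixes
  expect_gt(scan$Delta[200], 1 - 1e-6)
  expect_true(all(diff(scan$Delta) >= -1e-12))
  sel <- selectScale(list(c(scan, list(delta = 0.5))))
  expect_true(sel$splittable)
  expect_equal(sel$K, 2L)
})

test_that("a uniform complete graph is unsplittable at once", {
  W <- matrix(1, 4, 4); diag(W) <- 0
  scan <- eigengapCurves(W, MLimit = 200L)
  # magnitudes 1, 1/3, 1/3, 1/3: the gap at K = 1 dominates from M = 1
  expect_equal(scan$K, 1L)
  expect_length(scan$M, 1L)
  expect_equal(scan$lambda, c(1, 1/3, 1/3, 1/3), tolerance = 1e-12)
  sel <- selectScale(list(c(scan, list(delta = 1))))
  expect_false(sel$splittable)
})

test_that("any connected affinity reaches K = 1 at finite M", {
  withr::with_seed(13L, {
    for (rep in 1:5) {
      n <- sample(4:9, 1)
      W <- matrix(runif(n * n, 0.05, 1), n, n)
      W <- (W + t(W)) / 2; diag(W) <- 1
      scan <- eigengapCurves(W, MLimit = 5000L)
      expect_equal(scan$K[length(scan$K)], 1L)
    }
  })
})

test_that("eigengap curves match the dense brute-force oracle", {
  withr::with_seed(41L, {
    for (rep in 1:8) {
      n <- sample(4:10, 1)
      W <- matrix(runif(n * n, 0.02, 1), n, n)
      W <- (W + t(W)) / 2; diag(W) <- 1
      scan <- eigengapCurves(W, MLimit = 200L)
      oracle <- denseEigengapOracle(W, scan$M)
      expect_equal(scan$Delta, unname(oracle[, "Delta"]),
                   tolerance = 1e-7)
      expect_equal(scan$K, as.integer(oracle[, "K"]))
    }
  })
})

test_that("local extrema detection handles plateaus and boundaries", {
  le <- netscale:::localExtrema
  expect_equal(le(c(0, 1, 0))$max, 2L)
  expect_equal(le(c(1, 0, 1))$min, 2L)
  # plateau collapses to its leftmost index
  expect_equal(le(c(0, 1, 1, 1, 0))$max, 2L)
  # boundary extrema count
  expect_equal(le(c(2, 1, 3))$max, c(1L, 3L))
  expect_equal(le(c(2, 1, 3))$min, 2L)
  # a flat curve has no structure
  expect_length(le(rep(0.4, 6))$max, 0L)
})

test_that("scale selection prefers stability and larger delta on ties", {
  mk <- function(delta, Delta, K)
    list(delta = delta, M = seq_along(Delta), Delta = Delta, K = K)
  # one interior local max: the only candidate wins
  s1 <- mk(0.3, c(0.1, 0.6, 0.2, 0.1), rep(3L, 4))
  sel <- selectScale(list(s1))
  expect_equal(sel$delta, 0.3)
  expect_equal(sel$K, 3L)
  expect_equal(sel$M, 2L)
  expect_equal(sel$stability, 3L)   # bounds substitute for missing minima
  # longer-lived structure beats a sharper but short-lived one
  s2 <- mk(0.2, c(0.1, 0.9, 0.1, 0.1, 0.1), rep(2L, 5))
  s3 <- mk(0.5, c(0.1, 0.5, 0.5, 0.5, 0.2), rep(4L, 5))
  sel <- selectScale(list(s2, s3))
  expect_equal(sel$K, 4L)
  # exact tie -> larger delta
  s4 <- mk(0.1, c(0.1, 0.6, 0.1), rep(2L, 3))
  s5 <- mk(0.9, c(0.1, 0.6, 0.1), rep(5L, 3))
  sel <- selectScale(list(s4, s5))
  expect_equal(sel$delta, 0.9)
  expect_equal(sel$K, 5L)
})

test_that("baseline spectral clustering is exact on disconnected
           cliques", {
  W <- blockAffinity(c(3, 5), 1, 0)
  labs <- baselineSpectral(W, 2L, seed = 3L)
  expect_equal(truthAdjustedRand(labs, rep(1:2, c(3, 5))), 1)
  expect_error(baselineSpectral(W, 8L), "K must be")
  expect_error(baselineSpectral(W, 1L), "K must be")
})

test_that("baseline spectral clustering recovers a noisy planted
           3-block model", {
  truth <- rep(1:3, each = 8)
  ok <- 0L
  for (seed in 1:50) {
    W <- withr::with_seed(seed, {
      noise <- matrix(runif(24 * 24, 0, 0.05), 24, 24)
      W <- blockAffinity(rep(8, 3), 0.9, 0.1) + (noise + t(noise)) / 2
      diag(W) <- 1
      W
    })
    labs <- baselineSpectral(W, 3L, seed = seed)
    if (truthAdjustedRand(labs, truth) >= 0.95) ok <- ok + 1L
  }
  expect_gte(ok, 48L)
})

test_that("scanDeltaGrid surfaces eigensolver context on failure", {
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_silent(scanDeltaGrid(D, deltas = c(0.5, 1)))
})
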