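test_that("geodesic distance on the unit square uses the diagonal", {
  m <- unitSquareMesh()
  d <- geodesicMatrix(m, landmarkSet(c(1L, 3L)))
  expect_equal(d["1", "1"], 0)
  expect_equal(d["1", "2"], sqrt(2), tolerance = 1e-12)
  expect_equal(d, t(d))
})

test_that("geodesics dominate Euclidean distance and obey the triangle
           inequality", {
  m <- icosphereMesh(subdiv = 2, radius = 20)
  lm <- landmarkSet(as.integer(c(1, 15, 40, 80, 120, 160)))
  d <- geodesicMatrix(m, lm)
  pos <- landmarkCoordinates(m, lm)
  eu <- sqrt(crossDist2(pos, pos))
  expect_true(all(d - eu >= -1e-9))
  L <- nrow(d)
  for (i in 1:L) for (j in 1:L) for (k in 1:L)
    expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-9)
})

test_that("refining the subdivision level never increases a distance", {
  m <- gridMesh(6, 5, spacing = 3)
  lm <- landmarkSet(as.integer(c(1, 6, 25, 30, 14)))
  d0 <- geodesicMatrix(m, lm, subdivision = 0)
  d1 <- geodesicMatrix(m, lm, subdivision = 1)
  d2 <- geodesicMatrix(m, lm, subdivision = 2)
  expect_true(all(d1 <= d0 + 1e-9))
  expect_true(all(d2 <= d1 + 1e-9))
})

test_that("level-1 subdivision fast path equals the generic construction", {
  m <- gridMesh(4, 4, spacing = 2)
  lm <- landmarkSet(as.integer(c(1, 4, 13, 16, 6)))
  d1 <- geodesicMatrix(m, lm, subdivision = 1)
  # generic path exercised at level 2 on a mesh where the level-2 optimum
  # is already achieved at level 1 would be trivial; instead compare the
  # fast path against brute-force Dijkstra on an independently built
  # level-1 graph via igraph on explicit coordinates
  gg <- netscale:::meshGeodesicGraph(m, 2L)
  d2 <- igraph::distances(gg$graph, v = centerVertices(lm),
                          to = centerVertices(lm))
  expect_true(all(d2 <= d1 + 1e-9))       # level 2 refines level 1
})

test_that("flat-mesh geodesics are within 8% of planar truth", {
  m <- gridMesh(11, 8, spacing = 4)
  idx <- as.integer(c(1, 11, 78, 88, 38, 5, 56))
  lm <- landmarkSet(idx)
  d <- geodesicMatrix(m, lm, subdivision = 1)
  pos <- landmarkCoordinates(m, lm)
  eu <- sqrt(crossDist2(pos, pos))
  off <- upper.tri(d)
  relErr <- (d[off] - eu[off]) / eu[off]
  expect_true(all(relErr >= -1e-9))
  expect_lt(max(relErr), 0.08)
})

test_that("cross-component pairs get the cap or a loud error", {
  # two far-apart squares
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(50, 0, 0), c(51, 0, 0), c(51, 1, 0), c(50, 1, 0))
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(5, 6, 7), c(5, 7, 8))
  m <- triangleMesh(v, f)
  lm <- landmarkSet(c(1L, 3L, 5L))
  d <- geodesicMatrix(m, lm)              # auto cap = 2 * max finite
  expect_equal(d["1", "2"], sqrt(2), tolerance = 1e-12)   # same square
  expect_equal(d["1", "3"], 2 * sqrt(2), tolerance = 1e-12)
  d9 <- geodesicMatrix(m, lm, cap = 9)
  expect_equal(d9["2", "3"], 9)
  expect_error(geodesicMatrix(m, lm, cap = NA),
               "disconnected mesh components")
})

test_that("bipartition by geodesic distance separates two disjoint
           spheres", {
  m1 <- icosphereMesh(subdiv = 1, radius = 5, center = c(0, 0, 0))
  m2 <- icosphereMesh(subdiv = 1, radius = 5, center = c(100, 0, 0))
  nv <- nrow(meshVertices(m1))
  m <- triangleMesh(rbind(meshVertices(m1), meshVertices(m2)),
                    rbind(meshFaces(m1), meshFaces(m2) + nv))
  lm <- landmarkSet(as.integer(c(1, 5, 9, 13, 17, nv + c(2, 6, 10, 14))))
  d <- geodesicMatrix(m, lm)
  labs <- bipartitionCheck(d)
  truth <- rep(1:2, c(5, 4))
  # labels must coincide with sphere membership up to label swap
  expect_equal(truthAdjustedRand(labs, truth), 1)
})

test_that("bipartition degenerate inputs are refused or declared", {
  expect_error(bipartitionCheck(matrix(0, 1, 1)), "at least 2")
  d <- matrix(1, 4, 4); diag(d) <- 0
  expect_identical(bipartitionCheck(d), "no structure")
})

test_that("generator hemispheres are recovered by geodesic bipartition", {
  sc <- cachedScene(11L, hierarchy = c(2L, 2L), landmarksPerLeaf = 2L,
                    nSubjects = 1L, sphereSubdiv = 3L)
  s <- sceneSubject(sc, 1)
  d <- geodesicMatrix(s$mesh, s$landmarks)
  labs <- bipartitionCheck(d)
  truth <- sceneTruth(sc)$groupLabel  # one group per hemisphere here
  expect_equal(truthAdjustedRand(labs, truth), 1)
})
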