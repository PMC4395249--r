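# a flat wall of triangles in the z = 0 plane centred on the origin
wallMesh <- function() gridMesh(9, 9, spacing = 5)

test_that("endpoint snapping extends a fiber onto the surface", {
  m <- wallMesh()
  # fiber approaching the wall from below, stopping 2 mm short
  f <- fiberSet(list(rbind(c(11, 11, -10), c(11, 11, -2))))
  r <- snapFiberEndpoints(f, m)
  p <- fiberPoints(r$fibers, 1)
  expect_equal(p[nrow(p), ], c(11, 11, 0), tolerance = 1e-9)
})

test_that("a fiber already ending on a mesh vertex is unchanged", {
  m <- wallMesh()
  f <- fiberSet(list(rbind(c(10, 10, -6), c(10, 10, 0))))
  r <- snapFiberEndpoints(f, m)
  expect_equal(fiberPoints(r$fibers, 1)[2, ], c(10, 10, 0),
               tolerance = 1e-9)
})

test_that("a fiber overshooting the surface is truncated back", {
  m <- wallMesh()
  f <- fiberSet(list(rbind(c(11, 11, -6), c(11, 11, 4))))
  r <- snapFiberEndpoints(f, m)
  expect_equal(fiberPoints(r$fibers, 1)[2, ], c(11, 11, 0),
               tolerance = 1e-9)
})

test_that("a fiber pointing away within reach of nothing is flagged", {
  m <- wallMesh()
  f <- fiberSet(list(rbind(c(11, 11, -20), c(11, 11, -12))))
  r <- snapFiberEndpoints(f, m, maxExtension = 5)
  expect_equal(r$flagged, 1L)
  expect_equal(fiberPoints(r$fibers, 1),
               rbind(c(11, 11, -20), c(11, 11, -12)))
})

test_that("degenerate terminal segments fall back to the preceding one", {
  m <- wallMesh()
  f <- fiberSet(list(rbind(c(11, 11, -10), c(11, 11, -2),
                           c(11, 11, -2))))
  r <- snapFiberEndpoints(f, m)
  p <- fiberPoints(r$fibers, 1)
  expect_equal(p[nrow(p), 3], 0, tolerance = 1e-9)
})

test_that("fiber-landmark assignment recovers the planted pairs", {
  sc <- smallScene()
  s <- sceneSubject(sc, 1)
  sn <- snapFiberEndpoints(s$fibers, s$mesh)
  a <- fiberLandmarkPairs(sn$fibers, s$mesh, s$landmarks)
  planted <- s$fiberPairs
  match <- !is.na(a[, 1]) & a[, 1] == planted[, 1] & a[, 2] == planted[, 2]
  expect_gte(mean(match), 0.98)
})

test_that("both endpoints in one patch yield no assignment", {
  sc <- smallScene()
  s <- sceneSubject(sc, 1)
  pos <- landmarkCoordinates(s$mesh, s$landmarks)
  loop <- fiberSet(list(rbind(pos[1, ] + c(0.2, 0, 0), pos[1, ] * 0.9,
                              pos[1, ] + c(0, 0.2, 0))))
  a <- fiberLandmarkPairs(loop, s$mesh, s$landmarks)
  expect_true(all(is.na(a)))
})

test_that("connection matrix binarizes with a strict threshold", {
  a <- rbind(c(1L, 2L), c(1L, 2L), c(1L, 2L), c(2L, 3L), c(NA, NA))
  C <- connectionMatrix(a, 4L, thres = 1L)
  v <- connectionValues(C)
  expect_equal(v[1, 2], 1L)         # 3 fibers > 1
  expect_equal(v[2, 3], 0L)         # exactly at thres -> not connected
  expect_equal(fiberCounts(C)[2, 3], 1L)
  expect_equal(sum(connectionValues(connectionMatrix(
    a[0, , drop = FALSE], 4L))), 0L)
  expect_error(connectionMatrix(a, 4L, thres = -1), ">= 0")
})

test_that("hop matrix matches hand-checked small graphs", {
  path <- matrix(0L, 4, 4)
  path[cbind(1:3, 2:4)] <- 1L; path <- path + t(path)
  h <- hopMatrix(connectionMatrix(rbind(c(1L, 2L), c(1L, 2L),
                                        c(2L, 3L), c(2L, 3L),
                                        c(3L, 4L), c(3L, 4L)), 4L))
  expect_equal(h[1, 2], 1)          # direct connection
  expect_equal(h[1, 4], 3)          # 1-2-3-4
  iso <- matrix(0L, 6, 6)
  expect_equal(hopMatrix(iso)[1, 2], 6)   # cap = L
  expect_equal(unname(diag(hopMatrix(iso))), rep(0, 6))
})

test_that("hop matrix equals brute-force BFS on random graphs", {
  withr::with_seed(99L, {
    for (rep in 1:40) {
      n <- sample(3:12, 1)
      adj <- matrix(0L, n, n)
      up <- which(upper.tri(adj))
      adj[sample(up, min(length(up), rpois(1, n)))] <- 1L
      adj <- adj + t(adj); adj[adj > 1] <- 1L
      expect_equal(unname(hopMatrix(adj)), bfsHops(adj))
    }
  })
})

test_that("raising thres never decreases any hop value", {
  sc <- smallScene()
  s <- sceneSubject(sc, 1)
  sn <- snapFiberEndpoints(s$fibers, s$mesh)
  a <- fiberLandmarkPairs(sn$fibers, s$mesh, s$landmarks)
  L <- length(landmarkIds(s$landmarks))
  prev <- NULL
  for (th in 0:3) {
    h <- hopMatrix(connectionMatrix(a, L, thres = th), cap = L)
    if (!is.null(prev)) expect_true(all(h >= prev - 1e-12))
    prev <- h
  }
})
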