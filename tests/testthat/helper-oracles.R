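# Independent oracles and shared fixtures for the test suite.

# plain breadth-first search on a binary adjacency matrix; cap for
# unreachable pairs. Deliberately naive - the oracle for hopMatrix().
bfsHops <- function(adj, cap = nrow(adj)) {
  n <- nrow(adj)
  out <- matrix(cap, n, n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ] != 0)) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    out[s, dist >= 0L] <- dist[dist >= 0L]
  }
  diag(out) <- 0
  out
}

# dense eigengap oracle: eigenvalues of the random-walk matrix computed
# directly from the (possibly nonsymmetric) transition matrix, powered by
# brute force for each M.
denseEigengapOracle <- function(W, Ms) {
  P <- W / rowSums(W)
  mags <- sort(pmin(Mod(eigen(P)$values), 1), decreasing = TRUE)
  L <- length(mags)
  t(vapply(Ms, function(M) {
    pw <- mags^M
    gaps <- pw[-L] - pw[-1]
    k <- which.max(gaps)
    c(Delta = gaps[k], K = k)
  }, c(Delta = 0, K = 0)))
}

# block-constant affinity matrix; diagVal = 0 gives graph adjacency
# (cliques), diagVal = 1 a kernel-style affinity
blockAffinity <- function(sizes, within, between, diagVal = 1) {
  lab <- rep(seq_along(sizes), sizes)
  W <- ifelse(outer(lab, lab, `==`), within, between)
  diag(W) <- diagVal
  W
}

# unit square split into two triangles (diagonal 1-3)
unitSquareMesh <- function() {
  triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               rbind(c(1, 2, 3), c(1, 3, 4)))
}

# scenes are expensive; cache per seed/spec within a test run
.sceneCache <- new.env(parent = emptyenv())
cachedScene <- function(seed, ...) {
  key <- paste(seed, paste(deparse(list(...)), collapse = ""),
               sep = "|")
  if (is.null(.sceneCache[[key]]))
    .sceneCache[[key]] <- generateScene(sceneSpec(seed = seed, ...))
  .sceneCache[[key]]
}

# small cheap scene for plumbing tests
smallScene <- function(seed = 7L) {
  cachedScene(seed, hierarchy = c(2L, 2L), landmarksPerLeaf = 2L,
              nSubjects = 2L, sphereSubdiv = 3L)
}
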