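# per-mesh triangle arrays shared by every ray query (centroids and a
# circumradius bound support a cheap per-ray candidate prefilter)
meshTriData <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  v0 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - v0
  e2 <- v[f[, 3], , drop = FALSE] - v0
  ctr <- v0 + (e1 + e2) / 3
  rad2 <- pmax(rowSums((v0 - ctr)^2), rowSums((v0 + e1 - ctr)^2),
               rowSums((v0 + e2 - ctr)^2))
  list(v0 = v0, e1 = e1, e2 = e2, ctr = ctr,
       rmax = sqrt(max(rad2)))
}

# Moller-Trumbore ray/triangle intersection of one ray against all mesh
# faces. Returns the ray parameters t (distance along unit dir) of all hits,
# sorted ascending; numeric(0) if none.
rayMeshHits <- function(orig, dir, tri, tmax = Inf, eps = 1e-9) {
  if (is.finite(tmax)) {
    # only faces whose bounding sphere can touch the ray segment
    reach <- (tmax + tri$rmax)^2
    d2 <- (tri$ctr[, 1] - orig[1])^2 + (tri$ctr[, 2] - orig[2])^2 +
      (tri$ctr[, 3] - orig[3])^2
    keep <- d2 <= reach
    if (!any(keep)) return(numeric(0))
    tri <- list(v0 = tri$v0[keep, , drop = FALSE],
                e1 = tri$e1[keep, , drop = FALSE],
                e2 = tri$e2[keep, , drop = FALSE])
  }
  v0 <- tri$v0
  e1 <- tri$e1
  e2 <- tri$e2
  # h = dir x e2
  h1 <- dir[2] * e2[, 3] - dir[3] * e2[, 2]
  h2 <- dir[3] * e2[, 1] - dir[1] * e2[, 3]
  h3 <- dir[1] * e2[, 2] - dir[2] * e2[, 1]
  a <- e1[, 1] * h1 + e1[, 2] * h2 + e1[, 3] * h3
  ok <- abs(a) > eps
  s1 <- orig[1] - v0[, 1]; s2 <- orig[2] - v0[, 2]; s3 <- orig[3] - v0[, 3]
  u <- (s1 * h1 + s2 * h2 + s3 * h3) / a
  ok <- ok & u >= -eps & u <= 1 + eps
  q1 <- s2 * e1[, 3] - s3 * e1[, 2]
  q2 <- s3 * e1[, 1] - s1 * e1[, 3]
  q3 <- s1 * e1[, 2] - s2 * e1[, 1]
  vv <- (dir[1] * q1 + dir[2] * q2 + dir[3] * q3) / a
  ok <- ok & vv >= -eps & (u + vv) <= 1 + eps
  t <- (e2[, 1] * q1 + e2[, 2] * q2 + e2[, 3] * q3) / a
  ok <- ok & t >= -eps & t <= tmax + eps
  sort(t[ok & is.finite(t)])
}

# snap one fiber terminus; side is 1 (start) or 2 (end).
# Returns list(points, snapped)
snapTerminus <- function(p, side, tri, maxExtension) {
  n <- nrow(p)
  if (side == 1L) p <- p[n:1, , drop = FALSE]  # work on the "end" terminus
  # terminal direction: last segment, or the preceding one if degenerate
  k <- n
  dir <- NULL
  for (j in (n - 1):1) {
    d <- p[n, ] - p[j, ]
    len <- sqrt(sum(d^2))
    if (len > 1e-12) { dir <- d / len; break }
  }
  if (is.null(dir)) return(list(points = if (side == 1L)
    p[n:1, , drop = FALSE] else p, snapped = FALSE))
  segLen <- sqrt(sum((p[n, ] - p[n - 1, ])^2))
  snapped <- FALSE
  # truncation: terminal segment crosses the surface -> cut back to the
  # last crossing
  tIn <- rayMeshHits(p[n - 1, ], dir, tri, tmax = segLen)
  if (length(tIn)) {
    p[n, ] <- p[n - 1, ] + max(tIn) * dir
    snapped <- TRUE
  } else {
    # extension: cast the terminal direction forward
    tOut <- rayMeshHits(p[n, ], dir, tri, tmax = maxExtension)
    if (length(tOut)) {
      p[n, ] <- p[n, ] + min(tOut) * dir
      snapped <- TRUE
    }
  }
  if (side == 1L) p <- p[n:1, , drop = FALSE]
  list(points = p, snapped = snapped)
}

#' Snap fiber endpoints onto the cortical surface
#'
#' Tracked streamlines often stop short of (or overshoot) the grey-matter
#' sheet; before endpoint-to-landmark assignment each fiber's two terminal
#' segments are prolonged along their own direction until the first mesh
#' intersection, or cut back to their last mesh crossing. Fibers with no
#' intersection within `maxExtension` are returned unchanged and flagged.
#'
#' @param fibers a [FiberSet-class].
#' @param mesh a [TriangleMesh-class] in the same mm frame.
#' @param maxExtension maximum forward extension in mm (default 5).
#' @return list with elements `fibers` (the snapped [FiberSet-class]) and
#'   `flagged` (integer indices of fibers with at least one unsnappable
#'   terminus).
#' @export
snapFiberEndpoints <- function(fibers, mesh, maxExtension = 5) {
  tri <- meshTriData(mesh)
  out <- fibers@fibers
  flagged <- integer()
  for (i in seq_along(out)) {
    p <- out[[i]]
    if (nrow(p) < 2L) { flagged <- c(flagged, i); next }
    ok <- TRUE
    for (side in 1:2) {
      r <- snapTerminus(p, side, tri, maxExtension)
      p <- r$points
      ok <- ok && r$snapped
    }
    out[[i]] <- p
    if (!ok) flagged <- c(flagged, i)
  }
  list(fibers = fiberSet(out, fibers@scalars), flagged = flagged)
}

# map every mesh vertex to the landmark patch owning it (0 = none).
# Patch membership: geodesic distance (edge graph) from the landmark center
# vertex <= patchRadius; overlaps resolved toward the nearest center.
vertexPatchOwner <- function(mesh, landmarks) {
  ed <- meshEdges(mesh)
  w <- sqrt(rowSums((mesh@vertices[ed[, 1], , drop = FALSE] -
                     mesh@vertices[ed[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh@vertices) -
                                     igraph::vcount(g)))
  igraph::E(g)$weight <- w
  d <- igraph::distances(g, v = centerVertices(landmarks))
  d[d > patchRadius(landmarks)] <- Inf
  owner <- apply(d, 2, function(col) {
    j <- which.min(col)                 # ties: smaller landmark id
    if (is.finite(col[j])) j else 0L
  })
  as.integer(owner)
}

#' Assign each fiber to a landmark pair
#'
#' A fiber is assigned (i, j) when one (snapped) endpoint lies inside
#' landmark i's surface patch and the other inside landmark j's, i != j.
#' Endpoints are attributed to their nearest mesh vertex; a vertex belongs
#' to the patch of the geodesically nearest landmark center within the
#' patch radius.
#'
#' @param fibers a [FiberSet-class] with snapped endpoints.
#' @param mesh a [TriangleMesh-class].
#' @param landmarks a [LandmarkSet-class].
#' @return integer matrix with one row per fiber and columns `i`, `j`
#'   (i < j); unassignable fibers have NA in both columns.
#' @export
fiberLandmarkPairs <- function(fibers, mesh, landmarks) {
  owner <- vertexPatchOwner(mesh, landmarks)
  ends <- do.call(rbind, lapply(fibers@fibers,
                                function(p) p[c(1, nrow(p)), ]))
  nv <- crossDist2(ends, mesh@vertices)
  nearest <- max.col(-nv, ties.method = "first")
  lab <- owner[nearest]
  a <- lab[seq(1, length(lab), by = 2)]
  b <- lab[seq(2, length(lab), by = 2)]
  i <- pmin(a, b); j <- pmax(a, b)
  bad <- i == 0L | a == b
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Binary connection matrix from fiber assignments
#'
#' Counts fibers per unordered landmark pair and binarizes with a strict
#' `>` against the threshold: a pair is connected when it carries more than
#' `thres` fibers.
#'
#' @param assignments integer matrix from [fiberLandmarkPairs()] (columns
#'   i, j; NA rows ignored).
#' @param L number of landmarks.
#' @param thres nonnegative integer count threshold (default 1, i.e. at
#'   least two fibers make a connection).
#' @return a [ConnectionMatrix-class].
#' @export
connectionMatrix <- function(assignments, L, thres = 1L) {
  if (thres < 0) stop("thres must be >= 0")
  counts <- matrix(0L, L, L)
  a <- assignments[!is.na(assignments[, 1]), , drop = FALSE]
  if (nrow(a)) {
    t <- table(factor(a[, 1], levels = 1:L), factor(a[, 2], levels = 1:L))
    counts <- matrix(as.integer(t), L, L)
    counts <- counts + t(counts)
  }
  dimnames(counts) <- list(1:L, 1:L)
  new("ConnectionMatrix", counts = counts, threshold = as.integer(thres))
}

#' @rdname netscale-accessors
#' @export
setMethod("connectionValues", "ConnectionMatrix", function(x) {
  v <- (x@counts > x@threshold) * 1L
  diag(v) <- 0L
  v
})
#' @rdname netscale-accessors
#' @export
setMethod("fiberCounts", "ConnectionMatrix", function(x) x@counts)

setMethod("show", "ConnectionMatrix", function(object) {
  v <- connectionValues(object)
  cat(sprintf(
    "ConnectionMatrix: %d landmarks, %d connections (thres %d, %d fibers)\n",
    nrow(v), sum(v) / 2, object@threshold, sum(object@counts) / 2))
})

#' Hop matrix: shortest path lengths on the connection graph
#'
#' The long-range feature: the number of direct fiber-connection hops
#' between landmarks on the binarized connection graph (shortest path;
#' direct connections are 1). Pairs in different graph components get the
#' finite `cap` so max-normalization downstream stays defined and
#' unreachable pairs are maximally dissimilar.
#'
#' @param C a [ConnectionMatrix-class] (or a binary symmetric matrix).
#' @param cap value for disconnected pairs (default: L, the landmark
#'   count).
#' @return symmetric numeric L x L matrix of hop counts, zero diagonal.
#' @export
hopMatrix <- function(C, cap = NULL) {
  v <- if (is(C, "ConnectionMatrix")) connectionValues(C) else {
    m <- as.matrix(C)
    if (any(m != t(m))) stop("connection matrix must be symmetric")
    (m != 0) * 1L
  }
  L <- nrow(v)
  if (is.null(cap)) cap <- L
  g <- igraph::graph_from_adjacency_matrix(v, mode = "undirected")
  d <- igraph::distances(g)
  d[!is.finite(d)] <- cap
  diag(d) <- 0
  dimnames(d) <- dimnames(v)
  d
}
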