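#' Approximate geodesic distances between landmarks on a mesh
#'
#' The short-range feature: pairwise shortest-path lengths between landmark
#' center vertices along the cortical sheet. Geodesics are approximated by
#' Dijkstra's algorithm on a graph whose nodes are the mesh vertices plus
#' `subdivision` equally spaced interior points per edge; inside every face
#' all boundary nodes are linked by straight segments, so paths may cut
#' across triangles. Refining `subdivision` never increases a distance.
#'
#' Pairs whose centers lie on different mesh components have no geodesic;
#' they are set to a finite cap so downstream max-normalization stays
#' defined. With `cap = NULL` the cap is twice the largest finite distance;
#' `cap = NA` makes cross-component pairs an error instead.
#'
#' @param mesh a [TriangleMesh-class].
#' @param landmarks a [LandmarkSet-class] on `mesh`.
#' @param subdivision edge subdivision level (default 1; 0 is the plain
#'   edge graph; level s bisects each edge into 2^s segments, so each
#'   level's graph contains the previous one).
#' @param cap replacement for unreachable pairs: `NULL` (auto,
#'   2 x max finite), a positive number, or `NA` to treat unreachable pairs
#'   as an error.
#' @return symmetric L x L numeric matrix of lengths (mm), zero diagonal,
#'   dimnames the landmark ids; every entry is at least the Euclidean
#'   distance between the centers.
#' @examples
#' m <- triangleMesh(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)),
#'                   rbind(c(1,2,3), c(1,3,4)))
#' geodesicMatrix(m, landmarkSet(c(1L, 3L)))  # sqrt(2) off-diagonal
#' @export
geodesicMatrix <- function(mesh, landmarks, subdivision = 1L, cap = NULL) {
  cv <- centerVertices(landmarks)
  if (any(cv < 1L) || any(cv > nrow(meshVertices(mesh))))
    stop("landmark center vertex outside the mesh")
  gg <- meshGeodesicGraph(mesh, subdivision)
  d <- igraph::distances(gg$graph, v = cv, to = cv, algorithm = "dijkstra")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  if (any(!is.finite(d))) {
    if (length(cap) == 1L && is.na(cap)) {
      bad <- which(!is.finite(d), arr.ind = TRUE)
      bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
      stop(sprintf(
        "landmark pair(s) on disconnected mesh components: %s",
        paste(apply(bad, 1, paste, collapse = "-")[
          seq_len(min(5, nrow(bad)))], collapse = ", ")))
    }
    if (is.null(cap)) {
      fin <- d[is.finite(d)]
      if (!length(fin) || max(fin) == 0)
        stop("no finite geodesic distance to derive a cap from")
      cap <- 2 * max(fin)
    }
    if (!is.numeric(cap) || cap <= 0) stop("cap must be a positive number")
    d[!is.finite(d)] <- cap
  }
  dimnames(d) <- list(landmarkIds(landmarks), landmarkIds(landmarks))
  d
}

#' Baseline two-way spectral split of landmarks by geodesic distance
#'
#' Runs the baseline spectral clustering with K = 2 on the Gaussian
#' affinity of a geodesic distance matrix — the classic sanity check that a
#' two-hemisphere cortex splits into its hemispheres.
#'
#' @param distances symmetric finite distance matrix (zero diagonal).
#' @param delta Gaussian length scale; defaults to the median positive
#'   off-diagonal distance.
#' @param seed integer seed for the k-means step.
#' @return named integer vector of labels in {1, 2}, or the string
#'   `"no structure"` when all off-diagonal distances are equal (the
#'   partition would be arbitrary).
#' @export
bipartitionCheck <- function(distances, delta = NULL, seed = 1L) {
  d <- as.matrix(distances)
  if (nrow(d) < 2L) stop("need at least 2 landmarks for a bipartition")
  if (any(!is.finite(d))) stop("distances must be finite")
  if (max(abs(d - t(d))) > 1e-9) stop("distances must be symmetric")
  off <- d[row(d) != col(d)]
  if (max(off) - min(off) <= 1e-12 * max(1, max(off)))
    return("no structure")
  if (is.null(delta)) delta <- stats::median(off[off > 0])
  dn <- d / max(d)
  W <- affinityMatrix(dn, delta / max(d))
  labs <- baselineSpectral(W, 2L, seed = seed)
  names(labs) <- rownames(d)
  labs
}
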