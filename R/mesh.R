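#' Construct a triangle mesh
#'
#' @param vertices numeric matrix (or coercible) of vertex coordinates in
#'   mm, one row per vertex.
#' @param faces matrix of triangle vertex indices, one row per face.
#' @param zeroBased logical; if `TRUE`, `faces` are 0-based and converted.
#' @return a [TriangleMesh-class].
#' @examples
#' m <- triangleMesh(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)),
#'                   rbind(c(0,1,2), c(0,2,3)), zeroBased = TRUE)
#' @export
triangleMesh <- function(vertices, faces, zeroBased = FALSE) {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  f <- as.matrix(faces)
  storage.mode(f) <- "integer"
  if (zeroBased) f <- f + 1L
  new("TriangleMesh", vertices = v, faces = f)
}

#' Construct a landmark set
#'
#' @param centerVertex integer vector of 1-based mesh vertex indices; the
#'   i-th entry is the center of landmark id i.
#' @param ids landmark ids (default 1..L, the shared schema).
#' @param patchRadius geodesic patch radius in mm used for fiber endpoint
#'   capture (default 5).
#' @return a [LandmarkSet-class].
#' @export
landmarkSet <- function(centerVertex, ids = seq_along(centerVertex),
                        patchRadius = 5) {
  o <- order(ids)
  new("LandmarkSet", ids = as.integer(ids)[o],
      centerVertex = as.integer(centerVertex)[o],
      patchRadius = as.numeric(patchRadius))
}

#' @rdname netscale-accessors
#' @export
setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)
#' @rdname netscale-accessors
#' @export
setMethod("meshFaces", "TriangleMesh", function(x) x@faces)
#' @rdname netscale-accessors
#' @export
setMethod("landmarkIds", "LandmarkSet", function(x) x@ids)
#' @rdname netscale-accessors
#' @export
setMethod("centerVertices", "LandmarkSet", function(x) x@centerVertex)
#' @rdname netscale-accessors
#' @export
setMethod("patchRadius", "LandmarkSet", function(x) x@patchRadius)

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces, %d component(s)\n",
              nrow(object@vertices), nrow(object@faces),
              length(meshComponents(object))))
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet: %d landmarks, patch radius %.1f mm\n",
              length(object@ids), object@patchRadius))
})

# undirected edge list of a mesh (unique vertex pairs), rows sorted
meshEdges <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Connected components of a mesh's edge graph
#'
#' @param mesh a [TriangleMesh-class].
#' @return list of integer vectors of vertex indices, one per component.
#' @export
meshComponents <- function(mesh) {
  g <- igraph::graph_from_edgelist(meshEdges(mesh), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh@vertices) -
                                     igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  split(seq_along(comp), comp)
}

# Weighted graph for geodesic approximation: nodes are mesh vertices plus
# midpoint-bisection nodes on every edge (level s places 2^s - 1 interior
# points, so each level's node set contains the previous one and refining
# can only shorten paths); within every face all boundary nodes are joined
# by straight segments (Euclidean weights), letting shortest paths cut
# across triangles instead of hugging edges.
# Returns list(graph, nNodes); the first nrow(vertices) node ids are the
# original vertices.
meshGeodesicGraph <- function(mesh, subdivision = 1L) {
  v <- mesh@vertices
  nv <- nrow(v)
  ed <- meshEdges(mesh)
  s <- as.integer(subdivision)
  if (s < 0L) stop("subdivision must be >= 0")
  nIn <- if (s > 0L) 2L^s - 1L else 0L   # interior nodes per edge

  # node ids of the interior points of each edge, in order from ed[,1]
  edgeKey <- paste(ed[, 1], ed[, 2])
  edgeNode <- NULL
  coords <- v
  if (s > 0L) {
    t <- seq_len(nIn) / (nIn + 1L)
    p1 <- v[ed[, 1], , drop = FALSE]
    p2 <- v[ed[, 2], , drop = FALSE]
    extra <- do.call(rbind, lapply(t, function(tt) p1 + tt * (p2 - p1)))
    # extra is grouped by t then edge; reorder to edge-major
    idx <- as.vector(t(matrix(seq_len(nrow(ed) * nIn), nrow = nrow(ed))))
    extra <- extra[idx, , drop = FALSE]
    coords <- rbind(v, extra)
    edgeNode <- matrix(nv + seq_len(nrow(ed) * nIn), ncol = nIn,
                       byrow = TRUE)
    rownames(edgeNode) <- edgeKey
  }

  if (s == 1L) {
    # fast path for the default level: midpoint nodes only
    mid <- edgeNode[, 1]
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    f <- mesh@faces
    mab <- mid[match(key(f[, 1], f[, 2]), edgeKey)]
    mbc <- mid[match(key(f[, 2], f[, 3]), edgeKey)]
    mca <- mid[match(key(f[, 3], f[, 1]), edgeKey)]
    allp <- rbind(cbind(ed[, 1], mid), cbind(mid, ed[, 2]),
                  cbind(mab, mbc), cbind(mbc, mca), cbind(mca, mab),
                  cbind(f[, 1], mbc), cbind(f[, 2], mca),
                  cbind(f[, 3], mab))
    allp <- unique(cbind(pmin(allp[, 1], allp[, 2]),
                         pmax(allp[, 1], allp[, 2])))
    w <- sqrt(rowSums((coords[allp[, 1], , drop = FALSE] -
                       coords[allp[, 2], , drop = FALSE])^2))
    g <- igraph::graph_from_edgelist(allp, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nrow(coords) -
                                       igraph::vcount(g)))
    igraph::E(g)$weight <- w
    return(list(graph = g, nNodes = nrow(coords)))
  }

  nodesOnEdge <- function(i, j) {
    flip <- i > j
    k <- paste(min(i, j), max(i, j))
    inner <- if (s > 0L) edgeNode[k, ] else integer()
    if (flip) inner <- rev(inner)
    c(i, inner, j)
  }

  pairsFrom <- function(nodes) {
    # all unordered pairs among a small node vector
    n <- length(nodes)
    i <- rep(seq_len(n - 1), times = (n - 1):1)
    j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
    cbind(nodes[i], nodes[j])
  }

  f <- mesh@faces
  ep <- vector("list", nrow(f))
  for (k in seq_len(nrow(f))) {
    b <- unique(c(nodesOnEdge(f[k, 1], f[k, 2]),
                  nodesOnEdge(f[k, 2], f[k, 3]),
                  nodesOnEdge(f[k, 3], f[k, 1])))
    ep[[k]] <- pairsFrom(b)
  }
  allp <- do.call(rbind, ep)
  allp <- unique(cbind(pmin(allp[, 1], allp[, 2]),
                       pmax(allp[, 1], allp[, 2])))
  w <- sqrt(rowSums((coords[allp[, 1], , drop = FALSE] -
                     coords[allp[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(allp, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(coords) - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  list(graph = g, nNodes = nrow(coords))
}

#' Sphere mesh from a subdivided icosahedron
#'
#' @param subdiv number of 4-to-1 triangle subdivision rounds (0 gives the
#'   icosahedron; 3 gives 642 vertices).
#' @param radius sphere radius in mm.
#' @param center length-3 numeric center.
#' @return a [TriangleMesh-class].
#' @export
icosphereMesh <- function(subdiv = 3L, radius = 70, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (round in seq_len(subdiv)) {
    midCache <- new.env(hash = TRUE)
    newV <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midCache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (newV[i, ] + newV[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      newV <<- rbind(newV, m)
      idx <- nrow(newV)
      midCache[[key]] <- idx
      idx
    }
    newF <- matrix(0L, nrow(f) * 4L, 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newF[(k - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- newV; f <- newF
  }
  v <- sweep(v * radius, 2, center, `+`)
  triangleMesh(v, f)
}

#' Flat rectangular grid mesh in the z = 0 plane
#'
#' A right-triangle triangulation of an nx-by-ny grid with the given
#' spacing (mm). Cell diagonals alternate direction (criss-cross pattern)
#' so the discrete direction set is isotropic. Useful as an analytic
#' oracle: true geodesic distances on this mesh are planar Euclidean
#' distances.
#'
#' @param nx,ny number of grid vertices along x and y.
#' @param spacing grid spacing in mm.
#' @return a [TriangleMesh-class].
#' @export
gridMesh <- function(nx = 10, ny = 10, spacing = 1) {
  xy <- expand.grid(x = (seq_len(nx) - 1) * spacing,
                    y = (seq_len(ny) - 1) * spacing)
  v <- cbind(xy$x, xy$y, 0)
  id <- function(i, j) (j - 1L) * nx + i
  f <- NULL
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    f <- if ((i + j) %% 2 == 0) rbind(
      f,
      c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
      c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
    else rbind(
      f,
      c(id(i, j), id(i + 1, j), id(i, j + 1)),
      c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  triangleMesh(v, f)
}
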