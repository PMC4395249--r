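#' @import methods
NULL

#' Triangle mesh of a cortical surface
#'
#' Vertices are world coordinates in millimetres; faces are 1-based triples
#' of vertex indices (0-based indices are converted at the file-format
#' boundary, see [readSurface()]).
#'
#' @slot vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @slot faces integer matrix, one row per triangle, 1-based vertex indices.
#'
#' @seealso [triangleMesh()], [geodesicMatrix()]
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix"))

setValidity("TriangleMesh", function(object) {
  v <- object@vertices; f <- object@faces
  msg <- character()
  if (ncol(v) != 3L) msg <- c(msg, "vertices must have 3 columns")
  if (ncol(f) != 3L) msg <- c(msg, "faces must have 3 columns")
  if (nrow(f) > 0L) {
    if (any(f < 1L) || any(f > nrow(v)))
      msg <- c(msg, "face indices out of vertex range")
    else {
      # degenerate faces: repeated index or (near-)zero area
      if (any(f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]))
        msg <- c(msg, "degenerate face with repeated vertex index")
      else {
        a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
        b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
        cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
        cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
        cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
        if (any(cx^2 + cy^2 + cz^2 <= 1e-24))
          msg <- c(msg, "zero-area face present")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ordered landmark set on a mesh
#'
#' Landmark ids are 1-based and shared across subjects (the correspondence
#' schema); each id points at a center vertex of the subject's mesh. The
#' patch radius (mm, geodesic) controls fiber endpoint capture.
#'
#' @slot ids integer vector of landmark ids, consecutive 1..L.
#' @slot centerVertex integer vector, 1-based mesh vertex index per id.
#' @slot patchRadius numeric, geodesic patch radius in mm.
#'
#' @seealso [landmarkSet()]
#' @export
setClass("LandmarkSet",
  representation(ids = "integer", centerVertex = "integer",
                 patchRadius = "numeric"))

setValidity("LandmarkSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@ids)) msg <- c(msg, "landmark ids must be unique")
  if (length(object@ids) && !identical(sort(object@ids),
                                       seq_along(object@ids)))
    msg <- c(msg, "ids must be consecutive 1..L")
  if (length(object@centerVertex) != length(object@ids))
    msg <- c(msg, "centerVertex length must match ids")
  if (length(object@patchRadius) != 1L || object@patchRadius < 0)
    msg <- c(msg, "patchRadius must be a single nonnegative number")
  if (length(msg)) msg else TRUE
})

#' Set of streamline fibers
#'
#' Each fiber is a polyline of ordered 3-D points in mm. Optional per-point
#' scalars (e.g. FA, MD) are stored per scalar name as a list of numeric
#' vectors matching the point counts.
#'
#' @slot fibers list of numeric matrices (n_i x 3), n_i >= 2.
#' @slot scalars named list; each element is a list of numeric vectors,
#'   one per fiber, lengths matching the fiber point counts.
#'
#' @seealso [fiberSet()], [readFibers()]
#' @export
setClass("FiberSet",
  representation(fibers = "list", scalars = "list"))

setValidity("FiberSet", function(object) {
  msg <- character()
  bad <- vapply(object@fibers, function(p)
    !is.matrix(p) || ncol(p) != 3L || nrow(p) < 2L, logical(1))
  if (any(bad)) msg <- c(msg, sprintf(
    "fiber(s) %s are not matrices of >= 2 3-D points",
    paste(which(bad)[seq_len(min(3, sum(bad)))], collapse = ", ")))
  for (nm in names(object@scalars)) {
    sc <- object@scalars[[nm]]
    if (length(sc) != length(object@fibers)) {
      msg <- c(msg, sprintf("scalar '%s' must have one vector per fiber", nm))
    } else {
      n1 <- vapply(sc, length, integer(1))
      n2 <- vapply(object@fibers, nrow, integer(1))
      if (any(n1 != n2))
        msg <- c(msg, sprintf("scalar '%s' lengths mismatch point counts", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Binary landmark connection matrix with fiber counts
#'
#' values(i,j) = 1 exactly when more than `threshold` fibers join landmarks
#' i and j (strict inequality).
#'
#' @slot counts integer matrix of fiber counts per unordered landmark pair.
#' @slot threshold single integer, the count threshold (strict `>`).
#'
#' @seealso [connectionMatrix()], [hopMatrix()]
#' @export
setClass("ConnectionMatrix",
  representation(counts = "matrix", threshold = "integer"))

setValidity("ConnectionMatrix", function(object) {
  m <- object@counts
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "counts must be square")
  else {
    if (any(m != t(m))) msg <- c(msg, "counts must be symmetric")
    if (any(diag(m) != 0)) msg <- c(msg, "counts diagonal must be zero")
    if (any(m < 0)) msg <- c(msg, "counts must be nonnegative")
  }
  if (length(object@threshold) != 1L || object@threshold < 0L)
    msg <- c(msg, "threshold must be a single nonnegative integer")
  if (length(msg)) msg else TRUE
})

#' Group-averaged similarity features
#'
#' G: group mean of per-subject max-normalized geodesic matrices.
#' P: group mean of per-subject histogram-equalized, max-normalized hop
#' matrices. D = alpha * G + (1 - alpha) * P, the combined distance fed to
#' the Gaussian affinity.
#'
#' @slot G,P,D numeric L x L matrices in [0, 1], zero diagonal.
#' @slot alpha tradeoff coefficient between short-range (G) and long-range
#'   (P) information.
#' @slot nSubjects number of subjects averaged.
#'
#' @seealso [groupFeatures()], [affinityMatrix()]
#' @export
setClass("GroupFeature",
  representation(G = "matrix", P = "matrix", D = "matrix",
                 alpha = "numeric", nSubjects = "integer"))

setValidity("GroupFeature", function(object) {
  msg <- character()
  for (nm in c("G", "P", "D")) {
    m <- slot(object, nm)
    if (nrow(m) != ncol(m)) { msg <- c(msg, paste(nm, "not square")); next }
    if (max(abs(m - t(m))) > 1e-9) msg <- c(msg, paste(nm, "not symmetric"))
    if (any(abs(diag(m)) > 1e-12)) msg <- c(msg, paste(nm, "diagonal not 0"))
  }
  if (any(object@G < -1e-12) || any(object@G > 1 + 1e-12))
    msg <- c(msg, "G entries outside [0,1]")
  if (any(object@P < -1e-12) || any(object@P > 1 + 1e-12))
    msg <- c(msg, "P entries outside [0,1]")
  a <- object@alpha
  if (length(a) != 1L || a < 0 || a > 1)
    msg <- c(msg, "alpha must be in [0,1]")
  else if (max(abs(object@D - (a * object@G + (1 - a) * object@P))) > 1e-9)
    msg <- c(msg, "D != alpha*G + (1-alpha)*P")
  if (length(msg)) msg else TRUE
})

#' Recursive multi-scale partition of the landmark set
#'
#' Each internal node records the automatically selected length scale
#' delta*, cluster count K* and random-walk step M* of its split; children
#' partition the parent's landmark ids. Scale-s labels are obtained by
#' cutting the tree at depth s (non-split nodes persist).
#'
#' @slot root list; recursive node structure (fields: id, depth, ids,
#'   delta, K, M, stability, children).
#' @slot ids integer vector of all landmark ids at the root.
#' @slot params list of clustering parameters used to build the tree.
#'
#' @seealso [buildTree()], [scaleLabels()], [treeToJSON()]
#' @export
setClass("NetworkTree",
  representation(root = "list", ids = "integer", params = "list"))

setValidity("NetworkTree", function(object) {
  msg <- character()
  check <- function(node) {
    if (!length(node$children)) return(invisible())
    kid <- unlist(lapply(node$children, `[[`, "ids"))
    if (length(kid) != length(node$ids) ||
        !setequal(kid, node$ids) || anyDuplicated(kid))
      msg <<- c(msg, sprintf("children of node %s do not partition it",
                             node$id))
    for (ch in node$children) check(ch)
  }
  if (!setequal(object@root$ids, object@ids))
    msg <- c(msg, "root ids do not match tree ids")
  check(object@root)
  if (length(msg)) msg else TRUE
})

#' Multi-scale fiber-bundle atlas at one scale
#'
#' Backbone fibers are those whose two endpoint landmarks share a
#' sub-network label at this scale; remaining fibers are classified to the
#' nearest backbone bundle by mean closest distance, subject to a distance
#' threshold.
#'
#' @slot scale integer scale index the atlas was built at.
#' @slot assignments data.frame with columns fiber (index into the
#'   originating FiberSet), bundle (label or NA), backbone (logical),
#'   distance (mm; 0 for backbone members, classification distance
#'   otherwise).
#' @slot threshold classification threshold in mm.
#'
#' @seealso [backboneBundles()], [classifyFibers()]
#' @export
setClass("BundleAtlas",
  representation(scale = "integer", assignments = "data.frame",
                 threshold = "numeric"))

setValidity("BundleAtlas", function(object) {
  a <- object@assignments
  msg <- character()
  need <- c("fiber", "bundle", "backbone", "distance")
  if (!all(need %in% names(a)))
    msg <- c(msg, "assignments must have fiber, bundle, backbone, distance")
  else {
    if (anyDuplicated(a$fiber))
      msg <- c(msg, "a fiber may appear in at most one bundle")
    bad <- !a$backbone & !is.na(a$bundle) &
      a$distance > object@threshold + 1e-9
    if (any(bad))
      msg <- c(msg, "classified fiber assigned beyond the distance threshold")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic multi-subject cortical scene with planted structure
#'
#' @slot subjects list; per subject a list with elements mesh
#'   (TriangleMesh), landmarks (LandmarkSet), fibers (FiberSet), and
#'   fiberPairs (integer matrix of planted endpoint landmark pairs).
#' @slot truth list with elements groupLabel, leafLabel (named integer
#'   vectors over landmark ids; nested) and fiberClass (character vector per
#'   fiber: "leaf", "group" or "inter").
#' @slot spec list, the [sceneSpec()] the scene was generated from.
#'
#' @seealso [generateScene()]
#' @export
setClass("SyntheticScene",
  representation(subjects = "list", truth = "list", spec = "list"))

setValidity("SyntheticScene", function(object) {
  msg <- character()
  tr <- object@truth
  if (!all(c("groupLabel", "leafLabel") %in% names(tr)))
    msg <- c(msg, "truth must contain groupLabel and leafLabel")
  else {
    # nestedness: each leaf label maps into exactly one group label
    tab <- table(tr$leafLabel, tr$groupLabel)
    if (any(rowSums(tab > 0) != 1L))
      msg <- c(msg, "leaf labels are not nested within group labels")
  }
  if (length(msg)) msg else TRUE
})
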