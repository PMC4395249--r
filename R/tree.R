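#' Build the multi-scale network tree
#'
#' Recursive top-down construction: for the current landmark set, build
#' the delta grid on its own sub-matrix of D, scan eigengap curves over
#' (M, delta), select the most stable (delta*, K*, M*), split with the
#' baseline spectral clustering, and recurse into every cluster. Recursion
#' stops when a node is unsplittable (no eigengap structure), smaller than
#' `minSize`, or at `maxDepth`.
#'
#' @param x a [GroupFeature-class] or a combined distance matrix.
#' @param minSize do not split clusters smaller than this (default 3; a
#'   pair has no meaningful spectrum).
#' @param maxDepth maximum tree depth / number of scales (default 5).
#' @param seed integer master seed for the k-means steps.
#' @param MLimit,powering,kernelDenom,flatTol see [eigengapCurves()],
#'   [affinityMatrix()], [selectScale()].
#' @return a [NetworkTree-class].
#' @export
buildTree <- function(x, minSize = 3L, maxDepth = 5L, seed = 1L,
                      MLimit = 10000L, powering = "magnitude",
                      kernelDenom = "2delta2", flatTol = 1e-6) {
  D <- if (is(x, "GroupFeature")) combinedDistance(x) else as.matrix(x)
  ids <- if (!is.null(rownames(D))) as.integer(rownames(D))
         else seq_len(nrow(D))
  counter <- 0L
  build <- function(idx, depth) {
    counter <<- counter + 1L
    node <- list(id = counter, depth = depth, ids = ids[idx],
                 delta = NA_real_, K = NA_integer_, M = NA_integer_,
                 stability = NA_real_, children = list())
    if (length(idx) < max(minSize, 2L) || depth >= maxDepth)
      return(node)
    subD <- D[idx, idx, drop = FALSE]
    scans <- suppressWarnings(
      scanDeltaGrid(subD, MLimit = MLimit, powering = powering,
                    kernelDenom = kernelDenom))
    sel <- selectScale(scans, flatTol)
    if (!sel$splittable) return(node)
    W <- affinityMatrix(subD, sel$delta, kernelDenom)
    labs <- tryCatch(baselineSpectral(W, sel$K, seed = seed),
                     error = function(e) NULL)
    if (is.null(labs) || length(unique(labs)) < 2L) return(node)
    node$delta <- sel$delta; node$K <- as.integer(sel$K)
    node$M <- as.integer(sel$M); node$stability <- sel$stability
    groups <- split(idx, labs)
    groups <- groups[order(vapply(groups, function(g) min(ids[g]),
                                  numeric(1)))]
    node$children <- lapply(groups, function(g) build(g, depth + 1L))
    names(node$children) <- NULL
    node
  }
  root <- build(seq_len(nrow(D)), 1L)
  new("NetworkTree", root = root, ids = ids,
      params = list(minSize = as.integer(minSize),
                    maxDepth = as.integer(maxDepth),
                    seed = as.integer(seed), MLimit = as.integer(MLimit),
                    powering = powering, kernelDenom = kernelDenom,
                    flatTol = flatTol))
}

treeNodesAtCut <- function(root, scale) {
  out <- list()
  walk <- function(node) {
    if (node$depth == scale || !length(node$children)) {
      out[[length(out) + 1L]] <<- node
    } else {
      for (ch in node$children) walk(ch)
    }
  }
  walk(root)
  out
}

#' @rdname netscale-accessors
#' @export
setMethod("nScales", "NetworkTree", function(x) {
  depth <- 1L
  walk <- function(node) {
    depth <<- max(depth, node$depth)
    for (ch in node$children) walk(ch)
  }
  walk(x@root)
  depth
})

#' @rdname scaleLabels
#' @export
setMethod("scaleLabels", "NetworkTree", function(x, scale) {
  scale <- as.integer(scale)
  if (scale < 1L) stop("scale must be >= 1")
  blocks <- treeNodesAtCut(x@root, scale)
  blocks <- blocks[order(vapply(blocks, function(b) min(b$ids),
                                numeric(1)))]
  ids <- sort(x@ids)
  labs <- integer(length(ids)); names(labs) <- ids
  for (b in seq_along(blocks))
    labs[as.character(blocks[[b]]$ids)] <- b
  labs
})

setMethod("show", "NetworkTree", function(object) {
  S <- nScales(object)
  counts <- vapply(seq_len(S), function(s)
    length(unique(scaleLabels(object, s))), integer(1))
  cat(sprintf(
    "NetworkTree: %d landmarks, %d scale(s); sub-networks per scale: %s\n",
    length(object@ids), S, paste(counts, collapse = ", ")))
})

#' Within-sub-network consistency profile across scales
#'
#' Consistency of a sub-network is measured by the mean of
#' 0.5 * G + 0.5 * P over its within-block off-diagonal landmark pairs —
#' a distance, so smaller values mean tighter (more consistent) blocks.
#' With planted modular structure the curve is non-increasing from scale 1
#' to the deepest scale: deeper sub-networks are tighter.
#'
#' @param tree a [NetworkTree-class].
#' @param feature a [GroupFeature-class] over the same landmark ids (its
#'   G and P slots are used).
#' @return list with `curve` (data.frame: scale, consistency, nBlocks,
#'   nPairs) and `blocks` (per scale, the per-block 0.5G+0.5P matrices;
#'   singleton blocks contribute no pairs and are noted by an attribute).
#' @export
consistencyProfile <- function(tree, feature) {
  G <- featureG(feature); P <- featureP(feature)
  Cmat <- 0.5 * G + 0.5 * P
  ids <- sort(tree@ids)
  stopifnot(identical(as.integer(rownames(Cmat)), ids) ||
            nrow(Cmat) == length(ids))
  idx <- if (!is.null(rownames(Cmat)))
    match(ids, as.integer(rownames(Cmat))) else seq_along(ids)
  S <- nScales(tree)
  curve <- data.frame(scale = integer(), consistency = numeric(),
                      nBlocks = integer(), nPairs = integer())
  blocks <- vector("list", S)
  for (s in seq_len(S)) {
    labs <- scaleLabels(tree, s)
    tot <- 0; np <- 0L
    bl <- list()
    singletons <- 0L
    for (b in sort(unique(labs))) {
      member <- idx[labs == b]
      sub <- Cmat[member, member, drop = FALSE]
      bl[[as.character(b)]] <- sub
      if (length(member) < 2L) { singletons <- singletons + 1L; next }
      off <- sub[upper.tri(sub)]
      tot <- tot + sum(off); np <- np + length(off)
    }
    attr(bl, "singletonsExcluded") <- singletons
    blocks[[s]] <- bl
    curve <- rbind(curve, data.frame(
      scale = s, consistency = if (np) tot / np else NA_real_,
      nBlocks = length(unique(labs)), nPairs = np))
  }
  list(curve = curve, blocks = blocks)
}

#' Transfer model labels to a new subject by landmark id
#'
#' The whole point of a shared landmark schema: the model tree's per-scale
#' labels transfer to any new subject carrying the same ids — no
#' re-clustering.
#'
#' @param tree the model [NetworkTree-class].
#' @param newLandmarks the new subject's [LandmarkSet-class] (or an
#'   integer vector of its landmark ids).
#' @return list with one named label vector per scale, ordered as the new
#'   subject's ids.
#' @export
transferLabels <- function(tree, newLandmarks) {
  newIds <- if (is(newLandmarks, "LandmarkSet"))
    landmarkIds(newLandmarks) else as.integer(newLandmarks)
  missing <- setdiff(tree@ids, newIds)
  if (length(missing))
    stop(sprintf("new subject is missing landmark id(s): %s",
                 paste(sort(missing), collapse = ", ")))
  extra <- setdiff(newIds, tree@ids)
  if (length(extra))
    stop(sprintf("new subject has unknown landmark id(s): %s",
                 paste(sort(extra), collapse = ", ")))
  S <- nScales(tree)
  out <- lapply(seq_len(S), function(s) {
    labs <- scaleLabels(tree, s)
    labs[as.character(newIds)]
  })
  names(out) <- paste0("scale", seq_len(S))
  out
}

#' Displacement between model and predicted sub-networks
#'
#' Per block, the representative landmark (minimum mean Euclidean distance
#' to the other block members) is found independently in the model and the
#' subject coordinate sets; the reported displacement is the Euclidean
#' distance between the two representatives' positions. A singleton
#' block's sole member is its representative.
#'
#' @param modelCoords,subjectCoords numeric matrices (L x 3, mm) with
#'   landmark ids as rownames.
#' @param labels named label vector (e.g. from [scaleLabels()]).
#' @return list with `perBlock` (data.frame: block, repModel, repSubject,
#'   distance) and `average` (mean distance over blocks, mm).
#' @export
subnetworkDisplacement <- function(modelCoords, subjectCoords, labels) {
  idsl <- names(labels)
  if (is.null(rownames(modelCoords)) || is.null(rownames(subjectCoords)))
    stop("coordinate matrices need landmark ids as rownames")
  if (!all(idsl %in% rownames(modelCoords)) ||
      !all(idsl %in% rownames(subjectCoords)))
    stop("coordinates must cover every labelled landmark id")
  representative <- function(coords, member) {
    member <- member[order(as.integer(member))]
    if (length(member) == 1L) return(member)
    pts <- coords[member, , drop = FALSE]
    d <- sqrt(crossDist2(pts, pts))
    member[which.min(rowSums(d) / (length(member) - 1L))]
  }
  perBlock <- NULL
  for (b in sort(unique(labels))) {
    member <- idsl[labels == b]
    rm_ <- representative(modelCoords, member)
    rs <- representative(subjectCoords, member)
    dist <- sqrt(sum((modelCoords[rm_, ] - subjectCoords[rs, ])^2))
    perBlock <- rbind(perBlock, data.frame(
      block = b, repModel = rm_, repSubject = rs, distance = dist))
  }
  rownames(perBlock) <- NULL
  list(perBlock = perBlock, average = mean(perBlock$distance))
}

# recursive node -> plain list for serialization (deterministic field
# order; ids sorted)
nodeToList <- function(node) {
  list(id = node$id, depth = node$depth, ids = sort(node$ids),
       delta = node$delta, K = node$K, M = node$M,
       stability = node$stability,
       children = lapply(node$children, nodeToList))
}

#' Serialize a network tree to JSON
#'
#' Deterministic serialization (node fields in fixed order, ids sorted):
#' two runs with the same seed and inputs produce byte-identical output.
#'
#' @param tree a [NetworkTree-class].
#' @param file optional path; when given the JSON is written there.
#' @return the JSON string, invisibly when `file` is given.
#' @export
treeToJSON <- function(tree, file = NULL) {
  obj <- list(ids = sort(tree@ids), params = tree@params,
              root = nodeToList(tree@root))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}

#' Read a network tree back from JSON
#'
#' @param file path or JSON string produced by [treeToJSON()].
#' @return a [NetworkTree-class].
#' @export
treeFromJSON <- function(file) {
  obj <- jsonlite::fromJSON(file, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  fix <- function(node) {
    node$ids <- as.integer(node$ids)
    node$id <- as.integer(node$id); node$depth <- as.integer(node$depth)
    node$K <- if (is.null(node$K)) NA_integer_ else as.integer(node$K)
    node$M <- if (is.null(node$M)) NA_integer_ else as.integer(node$M)
    node$delta <- if (is.null(node$delta)) NA_real_
                  else as.numeric(node$delta)
    node$stability <- if (is.null(node$stability)) NA_real_
                      else as.numeric(node$stability)
    node$children <- lapply(node$children, fix)
    node
  }
  new("NetworkTree", root = fix(obj$root), ids = as.integer(obj$ids),
      params = obj$params)
}

#' Newick string of the tree topology
#'
#' Landmarks are leaves; unsplit multi-landmark nodes become polytomies.
#'
#' @param tree a [NetworkTree-class].
#' @return a single Newick string (terminated by ";").
#' @export
treeToNewick <- function(tree) {
  rec <- function(node) {
    if (!length(node$children))
      return(if (length(node$ids) == 1L) paste0("L", node$ids)
             else paste0("(", paste0("L", sort(node$ids),
                                     collapse = ","), ")"))
    paste0("(", paste(vapply(node$children, rec, character(1)),
                      collapse = ","), ")")
  }
  paste0(rec(tree@root), ";")
}
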