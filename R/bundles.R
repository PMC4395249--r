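#' Backbone fiber bundles at one scale
#'
#' A fiber whose two endpoint landmarks fall inside the same sub-network
#' joins that sub-network's backbone bundle; fibers bridging two blocks
#' (or unassigned to a landmark pair) stay unbundled. Backbones are the
#' most consistent fibers and seed the classification of the rest.
#'
#' @param assignments integer matrix from [fiberLandmarkPairs()].
#' @param labels named label vector over landmark ids (e.g. from
#'   [scaleLabels()] or [transferLabels()]).
#' @param scale integer scale index recorded in the atlas.
#' @param threshold classification threshold (mm) recorded for the later
#'   [classifyFibers()] step (default 4).
#' @return a [BundleAtlas-class] containing backbone members only.
#' @export
backboneBundles <- function(assignments, labels, scale = 1L,
                            threshold = 4) {
  lab <- function(id) unname(labels[as.character(id)])
  i <- assignments[, 1]; j <- assignments[, 2]
  li <- lab(i); lj <- lab(j)
  bundle <- ifelse(!is.na(i) & !is.na(li) & !is.na(lj) & li == lj,
                   li, NA_integer_)
  a <- data.frame(fiber = seq_len(nrow(assignments)),
                  bundle = as.integer(bundle),
                  backbone = !is.na(bundle),
                  distance = ifelse(is.na(bundle), NA_real_, 0))
  new("BundleAtlas", scale = as.integer(scale), assignments = a,
      threshold = as.numeric(threshold))
}

#' @rdname netscale-accessors
#' @export
setMethod("bundleAssignments", "BundleAtlas", function(x) x@assignments)

setMethod("show", "BundleAtlas", function(object) {
  a <- object@assignments
  cat(sprintf(paste0(
    "BundleAtlas (scale %d): %d bundles, %d backbone + %d classified",
    " fibers, %d unassigned (threshold %.1f mm)\n"),
    object@scale, length(unique(stats::na.omit(a$bundle))),
    sum(a$backbone), sum(!a$backbone & !is.na(a$bundle)),
    sum(is.na(a$bundle)), object@threshold))
})

#' Classify remaining fibers onto backbone bundles
#'
#' Each not-yet-bundled fiber is measured against every bundle by the
#' minimum over that bundle's backbone fibers of the mean closest distance
#' (single linkage; `linkage = "center"` measures to the bundle center
#' fiber instead). The fiber joins the nearest bundle if the distance is
#' at most `threshold` mm, else it stays unassigned. Near-exact ties go to
#' the smaller bundle label. Fibers are resampled to a fixed arc-length
#' step first so distances are sampling independent. Re-running on a
#' complete atlas changes nothing.
#'
#' @param atlas a [BundleAtlas-class] with at least one nonempty backbone.
#' @param fibers the [FiberSet-class] the atlas indexes into.
#' @param threshold assignment threshold in mm (default: the atlas's).
#' @param resampleStep arc-length resampling step in mm (default 1).
#' @param linkage `"single"` (default) or `"center"`.
#' @return the completed [BundleAtlas-class].
#' @export
classifyFibers <- function(atlas, fibers, threshold = NULL,
                           resampleStep = 1,
                           linkage = c("single", "center")) {
  linkage <- match.arg(linkage)
  if (is.null(threshold)) threshold <- atlas@threshold
  a <- atlas@assignments
  if (!any(a$backbone)) stop("atlas has no backbone fibers")
  todo <- which(!a$backbone & is.na(a$bundle))
  if (!length(todo)) return(atlas)
  res <- lapply(fibers@fibers, resampleFiber, step = resampleStep)
  bundles <- sort(unique(a$bundle[a$backbone]))
  # centroid/radius prescreen: mcd(a, b) >= |centroids| - r_a - r_b, so
  # members that cannot come near the running best are skipped
  ctr <- lapply(res, colMeans)
  rad <- vapply(seq_along(res), function(i)
    sqrt(max(rowSums(sweep(res[[i]], 2, ctr[[i]])^2))), numeric(1))
  refIdx <- lapply(bundles, function(b) {
    member <- a$fiber[a$backbone & a$bundle == b]
    if (linkage == "center" && length(member) > 1L)
      member <- member[bundleCenter(res[member])]
    member
  })
  for (f in todo) {
    dist <- rep(Inf, length(bundles))
    cutoff <- threshold + 1e-6
    for (bi in seq_along(bundles)) {
      dmin <- Inf
      for (m in refIdx[[bi]]) {
        lb <- sqrt(sum((ctr[[f]] - ctr[[m]])^2)) - rad[f] - rad[m]
        if (lb > min(dmin, cutoff)) next
        dmin <- min(dmin, meanClosestDistance(res[[f]], res[[m]]))
      }
      dist[bi] <- dmin
      cutoff <- min(cutoff, dmin + 1e-6)
    }
    best <- which(dist <= min(dist) + 1e-9)[1]   # tie: smaller label
    if (dist[best] <= threshold) {
      a$bundle[f] <- bundles[best]
      a$distance[f] <- dist[best]
    }
  }
  new("BundleAtlas", scale = atlas@scale, assignments = a,
      threshold = as.numeric(threshold))
}

#' Representative (center) fiber of a bundle
#'
#' The bundle member minimizing the maximum Hausdorff distance to its
#' co-members; a single-fiber bundle is its own center.
#'
#' @param fibers list of fiber point matrices (one bundle's members).
#' @return index of the center fiber within `fibers`.
#' @export
bundleCenter <- function(fibers) {
  n <- length(fibers)
  if (n == 0L) stop("empty bundle")
  if (n == 1L) return(1L)
  H <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    H[i, j] <- H[j, i] <- hausdorffDistance(fibers[[i]], fibers[[j]])
  }
  which.min(apply(H, 1, max))
}

#' Cross-subject bundle consistency by Hausdorff distance
#'
#' For every bundle label shared across subjects, the Hausdorff distance
#' between the subjects' center fibers is averaged over all subject pairs;
#' the per-scale value is the mean over bundles. Smaller values mean the
#' corresponding bundles agree better across individuals.
#'
#' @param centersBySubject list (one element per subject) of named lists
#'   mapping bundle label to the subject's center-fiber point matrix.
#' @param averaging `"pairwise"` (default; mean over all subject pairs) or
#'   `"reference"` (mean of distances to the first subject).
#' @return list with `perBundle` (data.frame: bundle, meanHausdorff,
#'   nSubjects) and `scaleMean`.
#' @export
crossSubjectConsistency <- function(centersBySubject,
                                    averaging = c("pairwise",
                                                  "reference")) {
  averaging <- match.arg(averaging)
  if (length(centersBySubject) < 2L) stop("need at least two subjects")
  labels <- Reduce(intersect, lapply(centersBySubject, names))
  if (!length(labels)) stop("no bundle label shared by all subjects")
  perBundle <- NULL
  for (b in labels) {
    ctr <- lapply(centersBySubject, `[[`, b)
    n <- length(ctr)
    d <- if (averaging == "pairwise") {
      vals <- c()
      for (i in seq_len(n - 1)) for (j in (i + 1):n)
        vals <- c(vals, hausdorffDistance(ctr[[i]], ctr[[j]]))
      mean(vals)
    } else {
      mean(vapply(ctr[-1], hausdorffDistance, numeric(1), b = ctr[[1]]))
    }
    perBundle <- rbind(perBundle, data.frame(
      bundle = b, meanHausdorff = d, nSubjects = n))
  }
  rownames(perBundle) <- NULL
  list(perBundle = perBundle, scaleMean = mean(perBundle$meanHausdorff))
}

#' Per-bundle two-tailed group comparison of a diffusion scalar
#'
#' Welch (unequal-variance) two-tailed t-test per bundle on per-subject
#' bundle means of a scalar such as FA or MD. Zero-variance degenerate
#' input (both groups constant) is flagged rather than crashing: equal
#' constants give t = 0, p = 1; different constants are reported as an
#' exact difference with no finite t.
#'
#' @param groupA,groupB numeric matrices, subjects x bundles, of
#'   per-subject per-bundle mean scalar values (shared bundle columns).
#' @param scalarName label carried into the output (default "scalar").
#' @return data.frame: bundle, scalar, statistic, df, p.value,
#'   exactDifference.
#' @export
bundleScalarTest <- function(groupA, groupB, scalarName = "scalar") {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (nrow(groupA) < 2L || nrow(groupB) < 2L)
    stop("each group needs at least 2 subjects")
  if (ncol(groupA) != ncol(groupB))
    stop("groups must share the bundle columns")
  bundles <- colnames(groupA)
  if (is.null(bundles)) bundles <- as.character(seq_len(ncol(groupA)))
  out <- NULL
  for (k in seq_len(ncol(groupA))) {
    xa <- groupA[, k]; xb <- groupB[, k]
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      same <- isTRUE(all.equal(mean(xa), mean(xb)))
      row <- data.frame(bundle = bundles[k], scalar = scalarName,
                        statistic = if (same) 0 else NA_real_,
                        df = NA_real_, p.value = if (same) 1 else NA_real_,
                        exactDifference = !same)
    } else {
      tt <- stats::t.test(xa, xb, var.equal = FALSE,
                          alternative = "two.sided")
      row <- data.frame(bundle = bundles[k], scalar = scalarName,
                        statistic = unname(tt$statistic),
                        df = unname(tt$parameter),
                        p.value = tt$p.value, exactDifference = FALSE)
    }
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}
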