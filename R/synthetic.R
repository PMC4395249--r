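#' Landmark coordinates in mm
#'
#' @param mesh a [TriangleMesh-class].
#' @param landmarks a [LandmarkSet-class] on it.
#' @return numeric matrix (L x 3) with landmark ids as rownames.
#' @export
landmarkCoordinates <- function(mesh, landmarks) {
  out <- meshVertices(mesh)[centerVertices(landmarks), , drop = FALSE]
  rownames(out) <- landmarkIds(landmarks)
  out
}

#' Specification of a synthetic cortical scene
#'
#' Defines the planted hierarchical modular structure used to validate the
#' pipeline: two hemisphere meshes, landmark leaf clusters nested in
#' groups, streamline counts Poisson-distributed with dense rates inside
#' leaves, intermediate rates across leaves of one group and sparse rates
#' across groups, plus per-fiber and per-subject geometric jitter.
#'
#' Defaults emulate the study conditions the method targets: a [4, 3]
#' hierarchy (4 groups of 3 leaf clusters) with 3 landmarks per leaf (36
#' landmarks), 70 mm hemispheres, and 3 subjects sharing the landmark id
#' schema.
#'
#' @param hierarchy integer vector of branching factors, length 1 or 2
#'   (e.g. `c(4, 3)` = 4 groups x 3 subgroups); all entries >= 2.
#' @param landmarksPerLeaf landmarks per leaf cluster.
#' @param lambdaLeaf,lambdaGroup,lambdaInter Poisson means of fiber counts
#'   for within-leaf, within-group (cross-leaf) and cross-group landmark
#'   pairs; must be decreasing, `lambdaInter >= 0`.
#' @param fiberJitter per-point fiber jitter sigma in mm.
#' @param subjectJitter per-subject vertex jitter sigma in mm.
#' @param nSubjects number of subjects.
#' @param seed single integer; all randomness derives from it.
#' @param sphereRadius hemisphere radius in mm.
#' @param sphereSubdiv icosphere subdivision level per hemisphere.
#' @param hemisphereGap gap between the two hemisphere meshes in mm.
#' @param arcPoints sample points per fiber.
#' @param patchRadius landmark patch radius in mm.
#' @return a validated list of class `sceneSpec`.
#' @export
sceneSpec <- function(hierarchy = c(4L, 3L), landmarksPerLeaf = 3L,
                      lambdaLeaf = 4, lambdaGroup = 1.2,
                      lambdaInter = 0.2, fiberJitter = 0.5,
                      subjectJitter = 1, nSubjects = 3L, seed = 1L,
                      sphereRadius = 70, sphereSubdiv = 4L,
                      hemisphereGap = 20, arcPoints = 15L,
                      patchRadius = 5) {
  hierarchy <- as.integer(hierarchy)
  if (!length(hierarchy) %in% 1:2 || any(hierarchy < 2L))
    stop("hierarchy must have 1 or 2 levels with branching >= 2")
  if (!(lambdaLeaf >= lambdaGroup && lambdaGroup > lambdaInter &&
        lambdaInter >= 0))
    stop("need lambdaLeaf >= lambdaGroup > lambdaInter >= 0")
  if (fiberJitter < 0 || subjectJitter < 0) stop("jitter must be >= 0")
  if (landmarksPerLeaf < 1L) stop("landmarksPerLeaf must be >= 1")
  if (nSubjects < 1L) stop("nSubjects must be >= 1")
  spec <- list(hierarchy = hierarchy,
               landmarksPerLeaf = as.integer(landmarksPerLeaf),
               lambdaLeaf = lambdaLeaf, lambdaGroup = lambdaGroup,
               lambdaInter = lambdaInter, fiberJitter = fiberJitter,
               subjectJitter = subjectJitter,
               nSubjects = as.integer(nSubjects), seed = as.integer(seed),
               sphereRadius = sphereRadius,
               sphereSubdiv = as.integer(sphereSubdiv),
               hemisphereGap = hemisphereGap,
               arcPoints = as.integer(arcPoints),
               patchRadius = patchRadius)
  class(spec) <- "sceneSpec"
  spec
}

# orthonormal tangent basis at a unit vector
tangentBasis <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# direction at angular distance `ang` from u, azimuth phi
rotateFrom <- function(u, ang, phi) {
  tb <- tangentBasis(u)
  cos(ang) * u + sin(ang) * (cos(phi) * tb$e1 + sin(phi) * tb$e2)
}

#' Generate a seeded synthetic cortical scene
#'
#' Two unit-icosphere-derived hemisphere meshes are scaled to the
#' requested radius and placed left/right of the midline; groups of
#' landmark leaf clusters are laid out as well separated geodesic patches
#' (groups alternate hemispheres, subgroup centers ring their group
#' center, leaf landmarks sit on adjacent mesh vertices). Streamlines are
#' drawn as jittered interior arcs between landmark patches with Poisson
#' pair counts at the spec's three rates; each subject gets an
#' independently jittered copy of the geometry. All randomness derives
#' from the spec seed — the same spec reproduces the scene bitwise.
#'
#' @param spec a [sceneSpec()].
#' @return a [SyntheticScene-class].
#' @export
generateScene <- function(spec = sceneSpec()) {
  stopifnot(inherits(spec, "sceneSpec"))
  withr::with_seed(spec$seed, generateSceneImpl(spec))
}

generateSceneImpl <- function(spec) {
  nG <- spec$hierarchy[1]
  nSub <- if (length(spec$hierarchy) > 1L) spec$hierarchy[2] else 1L
  m <- spec$landmarksPerLeaf
  r <- spec$sphereRadius
  base <- icosphereMesh(spec$sphereSubdiv, radius = 1, center = c(0, 0, 0))
  bv <- meshVertices(base)
  nV <- nrow(bv)
  hemiCenter <- rbind(c(-(r + spec$hemisphereGap / 2), 0, 0),
                      c(r + spec$hemisphereGap / 2, 0, 0))

  # layout: group -> hemisphere, group center direction, subgroup centers,
  # leaf landmark directions; map each direction to an unused base vertex
  hemiOf <- ((seq_len(nG) - 1L) %% 2L) + 1L
  used <- rep(FALSE, 2L * nV)
  pickVertex <- function(dir, hemi) {
    sc <- bv %*% dir
    ord <- order(sc, decreasing = TRUE)
    for (k in ord) {
      gi <- (hemi - 1L) * nV + k
      if (!used[gi]) { used[gi] <<- TRUE; return(gi) }
    }
    stop("landmark count exceeds mesh vertex capacity")
  }
  angSub <- 35 * pi / 180
  angLm <- 6 * pi / 180
  centerVertexGlobal <- integer(0)
  groupLabel <- integer(0); leafLabel <- integer(0)
  for (g in seq_len(nG)) {
    h <- hemiOf[g]
    q <- sum(hemiOf[seq_len(g)] == h)        # index within hemisphere
    nGh <- sum(hemiOf == h)
    theta <- 2 * pi * (q - 1) / nGh + 0.3    # offset avoids the poles
    u <- c(0, cos(theta), sin(theta))
    for (s in seq_len(nSub)) {
      ctr <- if (nSub == 1L) u else
        rotateFrom(u, angSub, 2 * pi * (s - 1) / nSub + 0.5 * g)
      for (l in seq_len(m)) {
        dir <- if (l == 1L) ctr else
          rotateFrom(ctr, angLm, 2 * pi * (l - 2) / max(1L, m - 1L))
        centerVertexGlobal <- c(centerVertexGlobal, pickVertex(dir, h))
        groupLabel <- c(groupLabel, g)
        leafLabel <- c(leafLabel, (g - 1L) * nSub + s)
      }
    }
  }
  L <- length(centerVertexGlobal)
  ids <- seq_len(L)
  names(groupLabel) <- names(leafLabel) <- ids

  # planted Poisson fiber counts per unordered pair, per subject
  rateOf <- function(i, j) {
    if (leafLabel[i] == leafLabel[j]) spec$lambdaLeaf
    else if (groupLabel[i] == groupLabel[j]) spec$lambdaGroup
    else spec$lambdaInter
  }
  pairIdx <- which(upper.tri(diag(L)), arr.ind = TRUE)
  rates <- apply(pairIdx, 1, function(p) rateOf(p[1], p[2]))

  subjects <- vector("list", spec$nSubjects)
  for (n in seq_len(spec$nSubjects)) {
    # per-subject jittered two-component mesh
    vhemi <- lapply(1:2, function(h) {
      v <- bv * r
      v <- v + matrix(stats::rnorm(length(v), 0, spec$subjectJitter),
                      ncol = 3)
      sweep(v, 2, hemiCenter[h, ], `+`)
    })
    verts <- rbind(vhemi[[1]], vhemi[[2]])
    faces <- rbind(meshFaces(base), meshFaces(base) + nV)
    # medial bridge: a two-triangle strip joining the hemispheres at the
    # midline (the cortical sheet is one connected surface; without it the
    # interhemispheric geodesic is an artifact of the cap convention)
    vL <- which.max(bv[, 1]); vR <- which.min(bv[, 1])
    nb <- function(v) {
      f <- meshFaces(base)
      hit <- f[rowSums(f == v) > 0, ]
      min(setdiff(as.vector(hit), v))
    }
    faces <- rbind(faces,
                   c(vL, nb(vL), nV + vR),
                   c(nb(vL), nV + nb(vR), nV + vR))
    mesh <- triangleMesh(verts, faces)
    lms <- landmarkSet(centerVertexGlobal, ids,
                       patchRadius = spec$patchRadius)
    lmPos <- verts[centerVertexGlobal, , drop = FALSE]
    lmHemi <- ifelse(centerVertexGlobal <= nV, 1L, 2L)

    counts <- stats::rpois(nrow(pairIdx), rates)
    totalFibers <- sum(counts)
    fibs <- vector("list", totalFibers)
    fpairs <- matrix(NA_integer_, totalFibers, 2L,
                     dimnames = list(NULL, c("i", "j")))
    fclass <- character(totalFibers)
    fi <- 0L
    for (pk in which(counts > 0L)) {
      i <- pairIdx[pk, 1]; j <- pairIdx[pk, 2]
      cls <- if (leafLabel[i] == leafLabel[j]) "leaf"
             else if (groupLabel[i] == groupLabel[j]) "group"
             else "inter"
      for (rep in seq_len(counts[pk])) {
        fi <- fi + 1L
        fibs[[fi]] <- syntheticFiber(lmPos[i, ], lmPos[j, ],
                                     hemiCenter[lmHemi[i], ],
                                     hemiCenter[lmHemi[j], ],
                                     spec$fiberJitter, spec$arcPoints)
        fpairs[fi, ] <- c(i, j)
        fclass[fi] <- cls
      }
    }
    subjects[[n]] <- list(mesh = mesh, landmarks = lms,
                          fibers = fiberSet(fibs),
                          fiberPairs = fpairs, fiberClass = fclass)
  }
  new("SyntheticScene", subjects = subjects,
      truth = list(groupLabel = groupLabel, leafLabel = leafLabel,
                   fiberClass = subjects[[1]]$fiberClass),
      spec = unclass(spec))
}

# one jittered interior arc between two cortical points (quadratic Bezier
# sagging toward the deep white matter), endpoints nudged just under the
# surface so endpoint snapping has to recover them
syntheticFiber <- function(p1, p2, c1, c2, sigma, nPts) {
  n1 <- (p1 - c1); n1 <- n1 / sqrt(sum(n1^2))
  n2 <- (p2 - c2); n2 <- n2 / sqrt(sum(n2^2))
  # tangential endpoint jitter
  jit <- function(p, nrm) {
    e <- stats::rnorm(3, 0, sigma)
    e <- e - sum(e * nrm) * nrm
    p + e
  }
  a <- jit(p1, n1) - 0.5 * n1
  b <- jit(p2, n2) - 0.5 * n2
  mid <- (a + b) / 2
  deep <- (c1 + c2) / 2
  ctrl <- mid + 0.45 * (deep - mid)
  t <- seq(0, 1, length.out = nPts)
  pts <- outer((1 - t)^2, a) + outer(2 * t * (1 - t), ctrl) +
    outer(t^2, b)
  # per-point jitter on the interior, lightly smoothed
  if (nPts > 2L) {
    noise <- matrix(stats::rnorm(3L * nPts, 0, sigma), ncol = 3)
    noise[c(1L, nPts), ] <- 0
    sm <- (noise + rbind(noise[-1, ], 0) + rbind(0, noise[-nPts, ])) / 3
    pts <- pts + sm
  }
  pts
}

#' @rdname netscale-accessors
#' @export
setMethod("sceneSubject", "SyntheticScene", function(x, i) x@subjects[[i]])
#' @rdname netscale-accessors
#' @export
setMethod("sceneTruth", "SyntheticScene", function(x) x@truth)

setMethod("show", "SyntheticScene", function(object) {
  s1 <- object@subjects[[1]]
  cat(sprintf(paste0(
    "SyntheticScene: %d subject(s), %d landmarks (%d groups / %d leaves),",
    " %d fibers in subject 1\n"),
    length(object@subjects), length(object@truth$groupLabel),
    length(unique(object@truth$groupLabel)),
    length(unique(object@truth$leafLabel)), nFibers(s1$fibers)))
})

#' Jittered copies of fibers
#'
#' Utility for probe fibers in classification experiments: every point of
#' every fiber is perturbed by isotropic Gaussian noise and lightly
#' smoothed along the fiber.
#'
#' @param fibers a [FiberSet-class].
#' @param sigma jitter standard deviation in mm.
#' @param seed integer seed.
#' @return a [FiberSet-class] of the same size.
#' @export
jitterFibers <- function(fibers, sigma, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    out <- lapply(fibers@fibers, function(p) {
      n <- nrow(p)
      noise <- matrix(stats::rnorm(3L * n, 0, sigma), ncol = 3)
      sm <- (noise + rbind(noise[-1, , drop = FALSE], 0) +
               rbind(0, noise[-n, , drop = FALSE])) / 3
      p + sm
    })
    fiberSet(out)
  })
}

#' Adjusted Rand index against a reference labelling
#'
#' Chance-corrected agreement between a computed partition and the
#' generator's planted labels; 1 for identical partitions, about 0 for
#' independent ones.
#'
#' @param labels,truthLabels label vectors; when both are named they are
#'   aligned by name.
#' @return the adjusted Rand index in [-1, 1].
#' @export
truthAdjustedRand <- function(labels, truthLabels) {
  if (!length(labels) || !length(truthLabels))
    stop("labels must be nonempty")
  if (!is.null(names(labels)) && !is.null(names(truthLabels))) {
    if (!setequal(names(labels), names(truthLabels)))
      stop("label names do not cover the same ids")
    truthLabels <- truthLabels[names(labels)]
  } else if (length(labels) != length(truthLabels)) {
    stop("label vectors differ in length")
  }
  mclust::adjustedRandIndex(labels, truthLabels)
}
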