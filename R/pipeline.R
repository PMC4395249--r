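#' Pipeline configuration
#'
#' Collects every tunable of the network-construction pipeline with its
#' documented default, validates ranges, and serializes into the run
#' manifest so a run is reconstructible from its manifest alone.
#'
#' @param alpha tradeoff between geodesic and hop features (default 0.5).
#' @param thres fiber-count threshold of the connection matrix (strict
#'   `>`, default 1).
#' @param hopCap hop value for disconnected pairs (default NULL = L).
#' @param geodesicCap geodesic value for cross-component pairs (default
#'   NULL = twice the maximum finite distance).
#' @param kernelDenom Gaussian kernel denominator convention, `"2delta2"`
#'   or `"delta2"`.
#' @param minSize,maxDepth tree stopping rules (defaults 3 and 5).
#' @param patchRadius landmark patch radius in mm (default 5).
#' @param classifyThreshold fiber classification threshold in mm
#'   (default 4).
#' @param resampleStep fiber resampling step in mm (default 1).
#' @param maxExtension endpoint snapping reach in mm (default 5).
#' @param subdivision geodesic edge-subdivision level (default 1).
#' @param seed master seed (default 1).
#' @return a validated list of class `netscaleConfig`.
#' @export
pipelineConfig <- function(alpha = 0.5, thres = 1L, hopCap = NULL,
                           geodesicCap = NULL,
                           kernelDenom = c("2delta2", "delta2"),
                           minSize = 3L, maxDepth = 5L, patchRadius = 5,
                           classifyThreshold = 4, resampleStep = 1,
                           maxExtension = 5, subdivision = 1L,
                           seed = 1L) {
  kernelDenom <- match.arg(kernelDenom)
  stopifnot(alpha >= 0, alpha <= 1, thres >= 0, minSize >= 1,
            maxDepth >= 1, patchRadius >= 0, classifyThreshold > 0,
            resampleStep > 0, maxExtension >= 0, subdivision >= 0)
  cfg <- list(alpha = alpha, thres = as.integer(thres), hopCap = hopCap,
              geodesicCap = geodesicCap, kernelDenom = kernelDenom,
              minSize = as.integer(minSize),
              maxDepth = as.integer(maxDepth), patchRadius = patchRadius,
              classifyThreshold = classifyThreshold,
              resampleStep = resampleStep, maxExtension = maxExtension,
              subdivision = as.integer(subdivision),
              seed = as.integer(seed))
  class(cfg) <- "netscaleConfig"
  cfg
}

#' Per-subject features from raw geometry
#'
#' Runs the subject-level half of the pipeline: geodesic matrix, endpoint
#' snapping, fiber-to-landmark assignment, connection matrix and hop
#' matrix.
#'
#' @param mesh a [TriangleMesh-class].
#' @param landmarks a [LandmarkSet-class].
#' @param fibers a [FiberSet-class].
#' @param config a [pipelineConfig()].
#' @return list with `G` (geodesic matrix), `P` (hop matrix), `C`
#'   ([ConnectionMatrix-class]), `assignments`, `snappedFlagged`.
#' @export
subjectFeatures <- function(mesh, landmarks, fibers,
                            config = pipelineConfig()) {
  if (patchRadius(landmarks) != config$patchRadius)
    landmarks <- landmarkSet(centerVertices(landmarks),
                             landmarkIds(landmarks),
                             patchRadius = config$patchRadius)
  G <- geodesicMatrix(mesh, landmarks, subdivision = config$subdivision,
                      cap = config$geodesicCap)
  sn <- snapFiberEndpoints(fibers, mesh,
                           maxExtension = config$maxExtension)
  assignments <- fiberLandmarkPairs(sn$fibers, mesh, landmarks)
  C <- connectionMatrix(assignments, length(landmarkIds(landmarks)),
                        thres = config$thres)
  P <- hopMatrix(C, cap = config$hopCap)
  list(G = G, P = P, C = C, assignments = assignments,
       snappedFlagged = sn$flagged)
}

#' Full multi-scale analysis of a (synthetic or loaded) scene
#'
#' Executes geodesic -> connectivity -> group similarity -> multi-scale
#' tree -> consistency profile -> fiber bundles on a list of subjects, and
#' returns all intermediate objects.
#'
#' @param subjects list; per subject a list with `mesh`, `landmarks`,
#'   `fibers` (a [SyntheticScene-class]'s subjects slot qualifies).
#' @param config a [pipelineConfig()].
#' @param bundleScale scale at which the fiber atlas is built (default:
#'   the deepest scale).
#' @return list with `perSubject`, `feature` ([GroupFeature-class]),
#'   `tree` ([NetworkTree-class]), `consistency`, `atlas` (subject 1's
#'   completed [BundleAtlas-class]), `backboneFraction`.
#' @export
analyzeScene <- function(subjects, config = pipelineConfig(),
                         bundleScale = NULL) {
  if (is(subjects, "SyntheticScene")) subjects <- subjects@subjects
  per <- lapply(subjects, function(s)
    subjectFeatures(s$mesh, s$landmarks, s$fibers, config))
  feat <- groupFeatures(lapply(per, `[[`, "G"), lapply(per, `[[`, "P"),
                        alpha = config$alpha)
  tree <- buildTree(feat, minSize = config$minSize,
                    maxDepth = config$maxDepth, seed = config$seed,
                    kernelDenom = config$kernelDenom)
  cons <- consistencyProfile(tree, feat)
  if (is.null(bundleScale)) bundleScale <- nScales(tree)
  labs <- scaleLabels(tree, bundleScale)
  atlas <- backboneBundles(per[[1]]$assignments, labs,
                           scale = bundleScale,
                           threshold = config$classifyThreshold)
  nBackbone <- sum(bundleAssignments(atlas)$backbone)
  atlas <- classifyFibers(atlas, subjects[[1]]$fibers,
                          resampleStep = config$resampleStep)
  list(perSubject = per, feature = feat, tree = tree,
       consistency = cons, atlas = atlas,
       backboneFraction = nBackbone /
         max(1L, nFibers(subjects[[1]]$fibers)))
}

#' Run the pipeline end to end on files
#'
#' Reads per-subject surface, landmark and fiber files, executes the full
#' analysis, and writes the artifacts: per-subject geodesic/hop TSVs, the
#' group G/P/D TSVs, the tree JSON, per-scale label TSV, the bundle atlas
#' TSV, and a JSON manifest recording the full configuration, the package
#' version, the seed and per-subject input provenance. Rerunning with the
#' same inputs and config reproduces identical artifacts.
#'
#' @param surfaces,landmarks,fibers character vectors of per-subject file
#'   paths (equal lengths).
#' @param outDir output directory (created if needed).
#' @param config a [pipelineConfig()].
#' @return the [analyzeScene()] result, invisibly.
#' @export
runPipeline <- function(surfaces, landmarks, fibers, outDir,
                        config = pipelineConfig()) {
  stopifnot(length(surfaces) == length(landmarks),
            length(landmarks) == length(fibers))
  for (p in c(surfaces, landmarks, fibers))
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p))
  subjects <- lapply(seq_along(surfaces), function(n)
    list(mesh = readSurface(surfaces[n]),
         landmarks = readLandmarks(landmarks[n],
                                   patchRadius = config$patchRadius),
         fibers = readFibers(fibers[n])))
  res <- analyzeScene(subjects, config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (n in seq_along(subjects)) {
    writeMatrixTSV(res$perSubject[[n]]$G,
                   file.path(outDir, sprintf("geodesic_s%02d.tsv", n)))
    writeMatrixTSV(res$perSubject[[n]]$P,
                   file.path(outDir, sprintf("hops_s%02d.tsv", n)))
  }
  writeMatrixTSV(featureG(res$feature), file.path(outDir, "group_G.tsv"))
  writeMatrixTSV(featureP(res$feature), file.path(outDir, "group_P.tsv"))
  writeMatrixTSV(combinedDistance(res$feature),
                 file.path(outDir, "group_D.tsv"))
  treeToJSON(res$tree, file.path(outDir, "tree.json"))
  S <- nScales(res$tree)
  labTab <- data.frame(landmark_id = sort(res$tree@ids))
  for (s in seq_len(S))
    labTab[[paste0("scale", s)]] <- unname(scaleLabels(res$tree, s))
  utils::write.table(labTab, file.path(outDir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundleAssignments(res$atlas),
                     file.path(outDir, "bundles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "netscale",
    version = as.character(utils::packageVersion("netscale")),
    config = unclass(config),
    inputs = lapply(seq_along(surfaces), function(n) list(
      surface = surfaces[n], landmarks = landmarks[n],
      fibers = fibers[n], surface_md5 = unname(tools::md5sum(surfaces[n])),
      fibers_md5 = unname(tools::md5sum(fibers[n])))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null", na = "null"),
             file.path(outDir, "manifest.json"))
  invisible(res)
}
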