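#' Construct a fiber set
#'
#' @param fibers list of numeric matrices (points x 3, mm), one per
#'   streamline; each must have at least 2 points.
#' @param scalars optional named list of per-point scalars (e.g.
#'   `list(FA = <list of vectors>)`), lengths matching point counts.
#' @return a [FiberSet-class].
#' @export
fiberSet <- function(fibers, scalars = list()) {
  fibers <- lapply(fibers, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    dimnames(p) <- NULL
    p
  })
  new("FiberSet", fibers = fibers, scalars = scalars)
}

#' @rdname netscale-accessors
#' @export
setMethod("nFibers", "FiberSet", function(x) length(x@fibers))
#' @rdname netscale-accessors
#' @export
setMethod("fiberPoints", "FiberSet", function(x, i) x@fibers[[i]])
#' @rdname netscale-accessors
#' @export
setMethod("fiberScalar", "FiberSet", function(x, name) x@scalars[[name]])

setMethod("show", "FiberSet", function(object) {
  np <- vapply(object@fibers, nrow, integer(1))
  cat(sprintf("FiberSet: %d fibers, %d points total", length(np), sum(np)))
  if (length(object@scalars))
    cat(sprintf(", scalars: %s", paste(names(object@scalars),
                                       collapse = ", ")))
  cat("\n")
})

setMethod("length", "FiberSet", function(x) length(x@fibers))

#' Resample a polyline to a fixed arc-length step
#'
#' Linear interpolation at multiples of `step` mm along the fiber (both
#' endpoints kept). Distance computations resample fibers first so that
#' point-sampled distances are sampling-independent.
#'
#' @param points numeric matrix (n x 3).
#' @param step arc-length step in mm (default 1).
#' @return numeric matrix of resampled points.
#' @export
resampleFiber <- function(points, step = 1) {
  p <- as.matrix(points)
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] -
                       p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(p[c(1, nrow(p)), , drop = FALSE])
  at <- unique(c(seq(0, total, by = step), total))
  out <- cbind(stats::approx(s, p[, 1], xout = at, ties = "ordered")$y,
               stats::approx(s, p[, 2], xout = at, ties = "ordered")$y,
               stats::approx(s, p[, 3], xout = at, ties = "ordered")$y)
  out
}

# squared Euclidean cross-distance between two point sets (n x 3, m x 3)
crossDist2 <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# row minima of a matrix (C-level, via max.col on the negation)
rowMins <- function(d) d[cbind(seq_len(nrow(d)),
                               max.col(-d, ties.method = "first"))]

#' Mean closest distance between two fibers
#'
#' Symmetrized point-sampled distance: the average over points of `a` of
#' the distance to the nearest point of `b`, averaged with the reverse
#' direction. The workhorse of fiber-to-bundle classification.
#'
#' @param a,b numeric matrices of fiber points (mm).
#' @return distance in mm.
#' @export
meanClosestDistance <- function(a, b) {
  d2 <- crossDist2(as.matrix(a), as.matrix(b))
  (mean(sqrt(rowMins(d2))) + mean(sqrt(rowMins(t(d2))))) / 2
}

#' Hausdorff distance between two fibers
#'
#' Worst-case point-to-nearest-point distance, symmetrized by the maximum
#' over the two directions. Always at least the mean closest distance.
#'
#' @param a,b numeric matrices of fiber points (mm).
#' @return distance in mm.
#' @export
hausdorffDistance <- function(a, b) {
  d2 <- crossDist2(as.matrix(a), as.matrix(b))
  sqrt(max(max(rowMins(d2)), max(rowMins(t(d2)))))
}
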