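#' Histogram-equalize a collection of values
#'
#' Maps every value x to its empirical CDF F(x) = #\{y <= x\} / m. The hop
#' distribution is heavily concentrated at small counts; equalization
#' stretches it toward uniform on (0, 1] so the long-range feature
#' contributes to the affinity as efficiently as the geodesic one. The map
#' is order preserving and ties stay tied.
#'
#' @param values nonempty numeric vector (typically in [0, 1]).
#' @return numeric vector of equalized values in (0, 1].
#' @examples
#' histogramEqualize(c(0.25, 0.5, 0.5, 1))  # 0.25 0.75 0.75 1.00
#' @export
histogramEqualize <- function(values) {
  if (!length(values)) stop("values must be nonempty")
  ecdf <- rank(values, ties.method = "max") / length(values)
  ecdf
}

#' Group-averaged similarity features
#'
#' Per subject, the geodesic matrix is normalized by its maximum; the hop
#' matrix is normalized by its maximum and then histogram-equalized over
#' the off-diagonal entries. Both are averaged over subjects (landmark
#' correspondence across subjects is assumed and enforced), and combined as
#' D = alpha * G + (1 - alpha) * P.
#'
#' @param Gs list of per-subject geodesic matrices ([geodesicMatrix()]).
#' @param Ps list of per-subject hop matrices ([hopMatrix()]).
#' @param alpha tradeoff between short-range (G) and long-range (P)
#'   information, in [0, 1] (default 0.5).
#' @return a [GroupFeature-class].
#' @export
groupFeatures <- function(Gs, Ps, alpha = 0.5) {
  if (!is.list(Gs)) Gs <- list(Gs)
  if (!is.list(Ps)) Ps <- list(Ps)
  N <- length(Gs)
  if (N == 0L) stop("need at least one subject")
  if (length(Ps) != N) stop("Gs and Ps must have one matrix per subject")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  L <- nrow(Gs[[1]])
  dims <- dimnames(Gs[[1]])
  for (n in seq_len(N)) {
    if (!all(dim(Gs[[n]]) == L) || !all(dim(Ps[[n]]) == L))
      stop("all subjects must share the landmark count and order")
    if (!is.null(dimnames(Gs[[n]])) && !is.null(dims) &&
        !identical(dimnames(Gs[[n]])[[1]], dims[[1]]))
      stop("landmark id order differs across subjects")
    if (max(Gs[[n]]) <= 0)
      stop(sprintf("subject %d has an all-zero geodesic matrix", n))
  }
  off <- row(diag(L)) != col(diag(L))
  G <- Reduce(`+`, lapply(Gs, function(g) g / max(g))) / N
  P <- Reduce(`+`, lapply(Ps, function(p) {
    p <- p / max(p)
    p[off] <- histogramEqualize(p[off])
    p
  })) / N
  diag(G) <- 0; diag(P) <- 0
  G <- (G + t(G)) / 2; P <- (P + t(P)) / 2
  D <- alpha * G + (1 - alpha) * P
  dimnames(G) <- dimnames(P) <- dimnames(D) <- dims
  new("GroupFeature", G = G, P = P, D = D, alpha = as.numeric(alpha),
      nSubjects = as.integer(N))
}

#' @rdname netscale-accessors
#' @export
setMethod("featureG", "GroupFeature", function(x) x@G)
#' @rdname netscale-accessors
#' @export
setMethod("featureP", "GroupFeature", function(x) x@P)
#' @rdname netscale-accessors
#' @export
setMethod("combinedDistance", "GroupFeature", function(x) x@D)

setMethod("show", "GroupFeature", function(object) {
  cat(sprintf(
    "GroupFeature: %d landmarks, %d subject(s), alpha = %.2f\n",
    nrow(object@D), object@nSubjects, object@alpha))
})

#' Gaussian affinity of a combined distance matrix
#'
#' W(delta) = exp(-D^2 / (2 delta^2)) elementwise; delta is the length
#' scale of the Gaussian similarity (the smaller, the smaller a landmark's
#' neighbourhood). The denominator convention is switchable between the
#' standard `2 delta^2` and plain `delta^2`.
#'
#' @param D symmetric combined distance matrix (zero diagonal), or a
#'   [GroupFeature-class].
#' @param delta positive length scale.
#' @param kernelDenom `"2delta2"` (default) or `"delta2"`.
#' @return symmetric affinity matrix in (0, 1], unit diagonal.
#' @export
affinityMatrix <- function(D, delta, kernelDenom = c("2delta2", "delta2")) {
  if (is(D, "GroupFeature")) D <- combinedDistance(D)
  kernelDenom <- match.arg(kernelDenom)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("delta must be a single positive number")
  denom <- if (kernelDenom == "2delta2") 2 * delta^2 else delta^2
  W <- exp(-(D^2) / denom)
  diag(W) <- 1
  W
}
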