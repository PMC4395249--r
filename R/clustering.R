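#' Length-scale grid for the multi-scale scan
#'
#' Evenly spaced delta values from the smallest positive off-diagonal
#' entry of the combined distance matrix to its largest entry, with as
#' many points as the matrix order. Each recursive split re-grids on its
#' own sub-matrix, so deeper splits see smaller deltas.
#'
#' @param D symmetric combined distance matrix (zero diagonal).
#' @return increasing numeric vector of delta values (the scan itself is
#'   executed from the largest delta down).
#' @export
deltaGrid <- function(D) {
  D <- as.matrix(D)
  L <- nrow(D)
  if (L < 2L) stop("need at least 2 landmarks")
  off <- D[upper.tri(D)]
  pos <- off[off > 0]
  if (!length(pos)) {
    warning("all off-diagonal distances are zero; single-point grid")
    return(1)
  }
  lo <- min(pos); hi <- max(off)
  if (hi - lo <= 1e-12 * max(1, hi)) {
    warning("constant distance matrix; single-point delta grid")
    return(hi)
  }
  seq(lo, hi, length.out = L)
}

# eigenvalue magnitudes of the degree-normalized random-walk matrix of W,
# sorted descending. Computed through the similar symmetric matrix
# D^{-1/2} W D^{-1/2}; magnitudes are clamped at 1.
randomWalkSpectrum <- function(W) {
  d <- rowSums(W)
  if (any(d <= 0)) stop("affinity matrix has a zero-degree node")
  s <- 1 / sqrt(d)
  S <- W * tcrossprod(s)
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE)
  list(values = ev$values, vectors = ev$vectors, sinv = s)
}

#' Eigengap and cluster-count curves for one delta
#'
#' Scans random-walk steps M = 1, 2, 3, ... For each M the eigenvalue
#' magnitudes of the degree-normalized random-walk matrix are raised to
#' the M-th power; Delta(M) is the largest gap between consecutive powered
#' magnitudes and K(M) the gap's position — the number of clusters the
#' M-step walk suggests. The scan stops at the first M with K = 1 (the
#' walk has mixed; for connected affinities this always happens) or at
#' `MLimit`.
#'
#' Powering uses magnitudes, which keeps Delta well defined for all M when
#' the walk has negative eigenvalues; `powering = "signed"` restores raw
#' signed powers.
#'
#' @param W symmetric affinity matrix with positive entries (see
#'   [affinityMatrix()]).
#' @param MLimit hard cap on the M scan (default 10000).
#' @param powering `"magnitude"` (default) or `"signed"`.
#' @return list with elements `M` (1..Mstop), `Delta`, `K`, and `lambda`
#'   (the sorted eigenvalue magnitudes).
#' @export
eigengapCurves <- function(W, MLimit = 10000L,
                           powering = c("magnitude", "signed")) {
  powering <- match.arg(powering)
  sp <- randomWalkSpectrum(W)
  if (powering == "magnitude") {
    mags <- sort(pmin(abs(sp$values), 1), decreasing = TRUE)
    scan <- scanEigengaps(mags, MLimit)
    scan$lambda <- mags
  } else {
    vals <- sp$values[order(abs(sp$values), decreasing = TRUE)]
    vals <- pmin(pmax(vals, -1), 1)
    scan <- scanEigengapsSigned(vals, MLimit)
    scan$lambda <- vals
  }
  scan
}

# vectorized chunked M-scan on magnitudes (all in [0, 1], descending)
scanEigengaps <- function(mags, MLimit = 10000L) {
  L <- length(mags)
  if (L < 2L) stop("need at least 2 eigenvalues")
  lm <- log(mags)                      # log(0) = -Inf is fine: exp -> 0
  Delta <- numeric(0); K <- integer(0)
  M0 <- 1L; chunk <- 512L
  repeat {
    Ms <- M0:min(M0 + chunk - 1L, MLimit)
    pw <- exp(outer(lm, Ms))           # L x |Ms|
    gaps <- pw[-L, , drop = FALSE] - pw[-1, , drop = FALSE]
    k <- max.col(t(gaps), ties.method = "first")
    Delta <- c(Delta, gaps[cbind(k, seq_along(Ms))])
    K <- c(K, k)
    hit <- which(k == 1L)
    if (length(hit)) {
      n <- M0 - 1L + hit[1]
      Delta <- Delta[seq_len(n)]; K <- K[seq_len(n)]
      break
    }
    if (max(Ms) >= MLimit) break
    M0 <- max(Ms) + 1L
  }
  list(M = seq_along(Delta), Delta = Delta, K = as.integer(K))
}

# signed variant: powers keep sign, gaps computed on re-sorted powers
scanEigengapsSigned <- function(vals, MLimit = 10000L) {
  L <- length(vals)
  Delta <- numeric(0); K <- integer(0)
  for (M in seq_len(MLimit)) {
    pw <- sort(vals^M, decreasing = TRUE)
    gaps <- pw[-L] - pw[-1]
    k <- which.max(gaps)
    Delta <- c(Delta, gaps[k]); K <- c(K, k)
    if (k == 1L) break
  }
  list(M = seq_along(Delta), Delta = Delta, K = as.integer(K))
}

# local extrema of a discrete curve with a flatness tolerance.
# Plateaus collapse to their leftmost index; curve endpoints count.
# Returns list(max = indices, min = indices); a globally flat curve has
# neither.
localExtrema <- function(y, tol = 1e-6) {
  n <- length(y)
  if (n == 1L) return(list(max = integer(0), min = integer(0)))
  s <- diff(y)
  s <- ifelse(s > tol, 1L, ifelse(s < -tol, -1L, 0L))
  runStart <- c(1L, which(s != 0L) + 1L)
  v <- y[runStart]
  r <- length(v)
  if (r == 1L) return(list(max = integer(0), min = integer(0)))
  isMax <- vapply(seq_len(r), function(j)
    (j == 1L || v[j] > v[j - 1L]) && (j == r || v[j] > v[j + 1L]),
    logical(1))
  isMin <- vapply(seq_len(r), function(j)
    (j == 1L || v[j] < v[j - 1L]) && (j == r || v[j] < v[j + 1L]),
    logical(1))
  list(max = runStart[isMax], min = runStart[isMin])
}

#' Select the most stable (delta*, K*, M*) across the delta grid
#'
#' For each delta, M1 is the step maximizing Delta over the local maxima
#' of Delta(., delta); its stability is M_b - M_a, the span between the
#' local minima bracketing M1 (scan bounds substitute when a side has
#' none) — the number of steps the revealed structure survives. The delta
#' with the largest stability wins; ties break toward larger delta (coarse
#' structure lives at large length scales).
#'
#' @param scans list with one element per delta: the [eigengapCurves()]
#'   result plus a `delta` field. Typically built by [scanDeltaGrid()].
#' @param flatTol flatness tolerance for local-extremum detection.
#' @return list with `splittable` (logical); when splittable also `delta`,
#'   `K`, `M`, `stability`, `Delta` (the eigengap at the optimum).
#' @export
selectScale <- function(scans, flatTol = 1e-6) {
  best <- NULL
  for (sc in scans) {
    ext <- localExtrema(sc$Delta, flatTol)
    if (!length(ext$max)) next
    m1 <- ext$max[which.max(sc$Delta[ext$max])]
    K1 <- sc$K[m1]
    if (K1 < 2L) next
    leftMin <- ext$min[ext$min < m1]
    rightMin <- ext$min[ext$min > m1]
    Ma <- if (length(leftMin)) max(leftMin) else 1L
    Mb <- if (length(rightMin)) min(rightMin) else length(sc$Delta)
    stab <- sc$M[Mb] - sc$M[Ma]
    cand <- list(splittable = TRUE, delta = sc$delta, K = K1,
                 M = sc$M[m1], stability = stab, Delta = sc$Delta[m1])
    if (is.null(best) || stab > best$stability ||
        (stab == best$stability && cand$delta > best$delta))
      best <- cand
  }
  if (is.null(best)) list(splittable = FALSE) else best
}

#' Run the eigengap scan over a whole delta grid
#'
#' @param D combined distance matrix (or [GroupFeature-class]).
#' @param deltas delta grid; defaults to [deltaGrid()] of `D`. The scan
#'   runs from the largest delta down.
#' @param MLimit,powering,kernelDenom passed to [eigengapCurves()] /
#'   [affinityMatrix()].
#' @return list of per-delta scans (each with a `delta` field), ordered by
#'   decreasing delta; feed to [selectScale()].
#' @export
scanDeltaGrid <- function(D, deltas = NULL, MLimit = 10000L,
                          powering = "magnitude",
                          kernelDenom = "2delta2") {
  if (is(D, "GroupFeature")) D <- combinedDistance(D)
  if (is.null(deltas)) deltas <- deltaGrid(D)
  deltas <- sort(deltas, decreasing = TRUE)
  lapply(deltas, function(dl) {
    W <- affinityMatrix(D, dl, kernelDenom)
    sc <- tryCatch(eigengapCurves(W, MLimit, powering),
                   error = function(e) stop(sprintf(
                     "eigen scan failed at delta = %g: %s", dl,
                     conditionMessage(e)), call. = FALSE))
    sc$delta <- dl
    sc
  })
}

#' Baseline spectral clustering at a fixed K
#'
#' Embeds the landmarks in the top-K eigenvectors of the random-walk
#' matrix (rows normalized to unit length) and runs seeded k-means with
#' multiple restarts.
#'
#' @param W symmetric affinity matrix.
#' @param K number of clusters, 2 <= K <= L - 1.
#' @param seed integer seed for k-means.
#' @param nstart k-means restarts (default 20; best inertia wins).
#' @return integer vector of labels in 1..K (all labels nonempty).
#' @export
baselineSpectral <- function(W, K, seed = 1L, nstart = 20L) {
  L <- nrow(W)
  K <- as.integer(K)
  if (K < 2L || K > L - 1L)
    stop(sprintf("K must be in 2..L-1 (K = %d, L = %d)", K, L))
  sp <- randomWalkSpectrum(W)
  ord <- order(abs(sp$values), decreasing = TRUE)
  U <- sp$vectors[, ord[seq_len(K)], drop = FALSE]
  U <- sp$sinv * U                     # right eigenvectors of the walk
  rn <- sqrt(rowSums(U^2)); rn[rn == 0] <- 1
  U <- U / rn
  km <- withr::with_seed(as.integer(seed),
    stats::kmeans(U, centers = K, nstart = nstart, iter.max = 100L))
  as.integer(km$cluster)
}
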