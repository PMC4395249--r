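# ---- surfaces: ASCII PLY / OFF ------------------------------------------

#' Read a surface mesh from PLY or OFF (ASCII)
#'
#' Face indices in both formats are 0-based on disk and converted to the
#' in-memory 1-based convention.
#'
#' @param path file path; format chosen by extension (.ply / .off).
#' @return a [TriangleMesh-class].
#' @export
readSurface <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = readPLY(path),
         off = readOFF(path),
         stop(sprintf("unsupported surface format '.%s'", ext)))
}

#' Write a surface mesh to PLY or OFF (ASCII)
#'
#' @param mesh a [TriangleMesh-class].
#' @param path output path (.ply or .off).
#' @return `path`, invisibly.
#' @export
writeSurface <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- meshVertices(mesh); f <- meshFaces(mesh) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y",
                 "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else if (ext == "off") {
    writeLines(c("OFF", sprintf("%d %d 0", nrow(v), nrow(f))), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else stop(sprintf("unsupported surface format '.%s'", ext))
  invisible(path)
}

readPLY <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || trimws(lines[1]) != "ply")
    stop(sprintf("%s: not a PLY file", path))
  hdrEnd <- match("end_header", trimws(lines))
  if (is.na(hdrEnd)) stop(sprintf("%s: missing end_header", path))
  hdr <- trimws(lines[seq_len(hdrEnd)])
  if (!any(grepl("^format ascii", hdr)))
    stop(sprintf("%s: only ASCII PLY is supported", path))
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex ", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element face ", "",
                       grep("^element face ", hdr, value = TRUE)[1]))
  body <- lines[(hdrEnd + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vtx <- do.call(rbind, lapply(body[seq_len(nv)], function(ln)
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][1:3])))
  faces <- do.call(rbind, lapply(body[nv + seq_len(nf)], function(ln) {
    x <- as.integer(strsplit(trimws(ln), "\\s+")[[1]])
    if (x[1] != 3L) stop(sprintf("%s: non-triangle face", path))
    x[2:4]
  }))
  triangleMesh(vtx, faces, zeroBased = TRUE)
}

readOFF <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (lines[1] != "OFF") stop(sprintf("%s: not an OFF file", path))
  hdr <- as.integer(strsplit(lines[2], "\\s+")[[1]])
  nv <- hdr[1]; nf <- hdr[2]
  vtx <- do.call(rbind, lapply(lines[2 + seq_len(nv)], function(ln)
    as.numeric(strsplit(ln, "\\s+")[[1]][1:3])))
  faces <- do.call(rbind, lapply(lines[2 + nv + seq_len(nf)],
                                 function(ln) {
    x <- as.integer(strsplit(ln, "\\s+")[[1]])
    if (x[1] != 3L) stop(sprintf("%s: non-triangle face", path))
    x[2:4]
  }))
  triangleMesh(vtx, faces, zeroBased = TRUE)
}

# ---- landmarks and matrices: TSV ----------------------------------------

#' Read landmarks from TSV
#'
#' Expects columns `landmark_id` and `vertex_index`; vertex indices are
#' 0-based on disk (converted to 1-based in memory).
#'
#' @param path TSV path.
#' @param patchRadius patch radius (mm) to attach (default 5).
#' @return a [LandmarkSet-class].
#' @export
readLandmarks <- function(path, patchRadius = 5) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE)
  need <- c("landmark_id", "vertex_index")
  if (!all(need %in% names(tab)))
    stop(sprintf("%s: need columns %s", path, paste(need, collapse = ", ")))
  landmarkSet(as.integer(tab$vertex_index) + 1L,
              ids = as.integer(tab$landmark_id),
              patchRadius = patchRadius)
}

#' @rdname readLandmarks
#' @param landmarks a [LandmarkSet-class].
#' @export
writeLandmarks <- function(landmarks, path) {
  utils::write.table(
    data.frame(landmark_id = landmarkIds(landmarks),
               vertex_index = centerVertices(landmarks) - 1L),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a symmetric landmark matrix as TSV
#'
#' Matrices carry a landmark-id header row and column. Reading rejects
#' asymmetric input, naming the offending cell.
#'
#' @param path TSV path.
#' @param tol symmetry tolerance on read.
#' @return numeric matrix with id dimnames.
#' @export
readMatrixTSV <- function(path, tol = 1e-9) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m)) stop(sprintf("%s: matrix not square", path))
  bad <- which(abs(m - t(m)) > tol, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("%s: asymmetric entry at (%s, %s): %g vs %g", path,
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
                 m[bad[1, 1], bad[1, 2]], m[bad[1, 2], bad[1, 1]]))
  m
}

#' @rdname readMatrixTSV
#' @param m matrix to write (dimnames become the id header).
#' @export
writeMatrixTSV <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m)))
    dimnames(m) <- list(seq_len(nrow(m)), seq_len(ncol(m)))
  utils::write.table(format(m, digits = 12, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

# ---- fibers: plain text, TCK, TRK ---------------------------------------

#' Read streamlines
#'
#' Dispatches on extension: `.tck` (MRtrix), `.trk` (TrackVis; voxel-space
#' coordinates are converted to world mm with the header transform), or
#' plain text (one fiber per blank-line-separated block, `x y z
#' [scalars...]` per line; scalar names may be declared in a leading
#' `# scalars: ...` comment).
#'
#' @param path file path.
#' @return a [FiberSet-class].
#' @export
readFibers <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tck = readTCK(path),
         trk = readTRK(path),
         readFibersText(path))
}

#' @rdname readFibers
#' @param fibers a [FiberSet-class].
#' @export
writeFibers <- function(fibers, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tck = writeTCK(fibers, path),
         trk = writeTRK(fibers, path),
         writeFibersText(fibers, path))
  invisible(path)
}

readFibersText <- function(path) {
  lines <- readLines(path)
  scalarNames <- character()
  hdr <- grep("^#\\s*scalars:", lines, value = TRUE)
  if (length(hdr))
    scalarNames <- strsplit(trimws(sub("^#\\s*scalars:", "", hdr[1])),
                            "\\s+")[[1]]
  lines <- lines[!startsWith(trimws(lines), "#")]
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(blank)               # split fibers on blank-line runs
  keep <- !blank
  pieces <- split(seq_along(lines)[keep], grp[keep])
  fibs <- list(); scal <- list()
  for (p in pieces) {
    rows <- lapply(lines[p], function(ln) {
      x <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
      if (length(x) < 3 || anyNA(x[1:3]))
        stop(sprintf("%s: malformed fiber point at line %d", path, p[1]))
      x
    })
    mat <- do.call(rbind, rows)
    fibs[[length(fibs) + 1L]] <- mat[, 1:3, drop = FALSE]
    if (ncol(mat) > 3)
      scal[[length(fibs)]] <- mat[, -(1:3), drop = FALSE]
  }
  scalars <- list()
  if (length(scal) == length(fibs) && length(scal) &&
      !any(vapply(scal, is.null, logical(1)))) {
    ns <- ncol(scal[[1]])
    if (!length(scalarNames)) scalarNames <- paste0("scalar", seq_len(ns))
    for (k in seq_len(ns))
      scalars[[scalarNames[k]]] <- lapply(scal, function(m) m[, k])
  }
  fiberSet(fibs, scalars)
}

writeFibersText <- function(fibers, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sn <- names(fibers@scalars)
  if (length(sn))
    writeLines(paste("# scalars:", paste(sn, collapse = " ")), con)
  for (i in seq_len(nFibers(fibers))) {
    p <- fibers@fibers[[i]]
    cols <- lapply(sn, function(nm) fibers@scalars[[nm]][[i]])
    mat <- do.call(cbind, c(list(p), cols))
    writeLines(apply(format(mat, digits = 12, trim = TRUE,
                            scientific = FALSE), 1, paste,
                     collapse = " "), con)
    if (i < nFibers(fibers)) writeLines("", con)
  }
  invisible(path)
}

writeTCK <- function(fibers, path) {
  hdr <- c("mrtrix tracks", "datatype: Float32LE",
           sprintf("count: %d", nFibers(fibers)))
  # offset must cover the header incl. the "file: . <offset>" line + END
  offset <- 0L
  for (try in 1:3) {
    lines <- c(hdr, sprintf("file: . %d", offset), "END")
    need <- sum(nchar(lines, type = "bytes") + 1L)
    if (need == offset) break
    offset <- need
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(lines, collapse = "\n"), "\n"), con,
            eos = NULL)
  for (p in fibers@fibers) {
    writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

readTCK <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!identical(trimws(first), "mrtrix tracks"))
    stop(sprintf("%s: not a TCK file", path))
  offset <- NA_integer_
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop(sprintf("%s: truncated TCK header", path))
    if (trimws(ln) == "END") break
    if (grepl("^file:", ln))
      offset <- as.integer(sub("^file:\\s*\\.\\s*", "", trimws(ln)))
    if (grepl("^datatype:", ln) &&
        !grepl("Float32LE", ln))
      stop(sprintf("%s: only Float32LE TCK supported", path))
  }
  close(con); on.exit(NULL)
  con <- file(path, "rb"); on.exit(close(con))
  seek(con, offset)
  raw <- readBin(con, "numeric", n = file.size(path), size = 4L,
                 endian = "little")
  pts <- matrix(raw, ncol = 3, byrow = TRUE)
  fibs <- list(); cur <- NULL
  for (r in seq_len(nrow(pts))) {
    row <- pts[r, ]
    if (all(is.infinite(row))) break
    if (all(is.nan(row))) {
      if (!is.null(cur)) fibs[[length(fibs) + 1L]] <- cur
      cur <- NULL
    } else cur <- rbind(cur, row)
  }
  if (!is.null(cur)) fibs[[length(fibs) + 1L]] <- cur
  fibs <- lapply(fibs, function(m) { dimnames(m) <- NULL; m })
  fiberSet(fibs)
}

writeTRK <- function(fibers, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  sn <- names(fibers@scalars)
  nScalars <- length(sn)
  writeChar("TRACK", con, nchars = 5, eos = NULL)
  writeBin(raw(1), con)                          # pad id_string to 6
  writeBin(as.integer(c(1, 1, 1)), con, size = 2, endian = "little")
  writeBin(c(1, 1, 1), con, size = 4, endian = "little")   # voxel_size
  writeBin(c(0, 0, 0), con, size = 4, endian = "little")   # origin
  writeBin(as.integer(nScalars), con, size = 2, endian = "little")
  for (k in 1:10) {
    nm <- if (k <= nScalars) sn[k] else ""
    writeBin(c(charToRaw(substr(nm, 1, 19)),
               raw(20 - min(19, nchar(nm)))), con)
  }
  writeBin(0L, con, size = 2, endian = "little")  # n_properties
  for (k in 1:10) writeBin(raw(20), con)
  M <- diag(4)                                    # vox_to_ras
  writeBin(as.numeric(t(M)), con, size = 4, endian = "little")
  writeBin(raw(444), con)
  writeChar("RAS", con, nchars = 3, eos = NULL); writeBin(raw(1), con)
  writeBin(raw(4), con)                           # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4, endian = "little")
  writeBin(raw(2), con)                           # pad1
  writeBin(raw(6), con)                           # invert/swap flags
  writeBin(as.integer(nFibers(fibers)), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")  # version
  writeBin(1000L, con, size = 4, endian = "little")
  for (i in seq_len(nFibers(fibers))) {
    p <- fibers@fibers[[i]]
    writeBin(nrow(p), con, size = 4, endian = "little")
    row <- t(p)
    if (nScalars) {
      sc <- do.call(rbind, lapply(sn, function(nm)
        fibers@scalars[[nm]][[i]]))
      row <- rbind(row, sc)
    }
    writeBin(as.numeric(row), con, size = 4, endian = "little")
  }
  invisible(path)
}

readTRK <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 5, useBytes = TRUE)
  if (!identical(magic, "TRACK")) stop(sprintf("%s: not a TRK file", path))
  readBin(con, raw(), n = 1)
  readBin(con, integer(), n = 3, size = 2, endian = "little")  # dims
  voxelSize <- readBin(con, numeric(), n = 3, size = 4, endian = "little")
  readBin(con, numeric(), n = 3, size = 4, endian = "little")  # origin
  nScalars <- readBin(con, integer(), n = 1, size = 2, endian = "little")
  scalarNames <- vapply(1:10, function(k) {
    r <- readBin(con, raw(), n = 20)
    rawToChar(r[seq_len(max(0, which(r != 0)))])
  }, character(1))
  nProps <- readBin(con, integer(), n = 1, size = 2, endian = "little")
  readBin(con, raw(), n = 200)                    # property names
  M <- matrix(readBin(con, numeric(), n = 16, size = 4,
                      endian = "little"), 4, 4, byrow = TRUE)
  readBin(con, raw(), n = 444 + 4 + 4 + 24 + 2 + 6)
  nCount <- readBin(con, integer(), n = 1, size = 4, endian = "little")
  version <- readBin(con, integer(), n = 1, size = 4, endian = "little")
  readBin(con, integer(), n = 1, size = 4, endian = "little")  # hdr size
  if (version < 2 || M[4, 4] == 0) M <- diag(4)
  voxelSize[voxelSize == 0] <- 1
  fibs <- list(); scal <- rep(list(list()), max(1, nScalars))
  repeat {
    n <- readBin(con, integer(), n = 1, size = 4, endian = "little")
    if (!length(n)) break
    dat <- readBin(con, numeric(), n = n * (3 + nScalars), size = 4,
                   endian = "little")
    if (nProps) readBin(con, numeric(), n = nProps, size = 4,
                        endian = "little")
    m <- matrix(dat, ncol = 3 + nScalars, byrow = TRUE)
    vox <- sweep(m[, 1:3, drop = FALSE], 2, voxelSize, `/`)
    world <- t(M %*% rbind(t(vox), 1))[, 1:3, drop = FALSE]
    dimnames(world) <- NULL
    fibs[[length(fibs) + 1L]] <- world
    if (nScalars)
      for (k in seq_len(nScalars))
        scal[[k]][[length(fibs)]] <- m[, 3 + k]
  }
  scalars <- list()
  if (nScalars)
    for (k in seq_len(nScalars))
      scalars[[scalarNames[k]]] <- scal[[k]]
  fiberSet(fibs, scalars)
}
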