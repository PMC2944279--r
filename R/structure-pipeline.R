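## From coordinates and secondary-structure assignments to a
## StructureEntry: C-alpha extraction, SSE segmentation, axis fitting,
## signed interaxial angles, tableau codes and centroid distances.

#' Read C-alpha coordinates from a PDB file
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}), keeps one C-alpha per
#' residue (alternate locations resolved by highest occupancy, ties by
#' file order), preserves insertion codes, and returns residues in file
#' order. For multi-model (NMR) files only the first model is used.
#'
#' @param pdbFile path to a PDB-format file.
#' @param chainFilter optional chain identifier; keep only that chain.
#' @return A data frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resid}, \code{x}, \code{y}, \code{z}, one row per
#'   residue in chain/sequence order.
#' @export
readCAlpha <- function(pdbFile, chainFilter = NULL) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(pdbFile, multi = FALSE,
                                     rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", pdbFile, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$elety == "CA" & at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!is.null(chainFilter))
    at <- at[!is.na(at$chain) & at$chain == chainFilter, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no C-alpha atoms found in '", pdbFile, "'")
  ins <- at$insert
  ins[is.na(ins)] <- ""
  key <- paste(at$chain, at$resno, ins, sep = "|")
  ## altloc: keep highest occupancy, ties resolved by first occurrence
  occ <- at$o
  occ[is.na(occ)] <- 1
  keep <- !logical(nrow(at))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    best <- idx[which.max(occ[idx])]
    keep[setdiff(idx, best)] <- FALSE
  }
  at <- at[keep, , drop = FALSE]
  ins <- ins[keep]
  data.frame(chain = at$chain, resno = at$resno, insert = ins,
             resid = at$resid, x = at$x, y = at$y, z = at$z,
             stringsAsFactors = FALSE)
}

## Parse the residue table of a DSSP output file. Handles the classic
## fixed-column layout ("  #  RESIDUE AA STRUCTURE ..."): chain at column
## 12, summary letter at column 17. Chain-break records ('!') split runs.
.parseDSSP <- function(dsspFile) {
  lines <- readLines(dsspFile, warn = FALSE)
  hdr <- grep("^\\s*#\\s+RESIDUE", lines)
  if (length(hdr) == 0L)
    stop("not a DSSP file (no '#  RESIDUE' header): ", dsspFile)
  body <- lines[seq(hdr[1L] + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]
  aa <- substr(body, 14L, 14L)
  data.frame(
    resno = suppressWarnings(as.integer(substr(body, 6L, 10L))),
    icode = trimws(substr(body, 11L, 11L)),
    chain = trimws(substr(body, 12L, 12L)),
    brk = aa == "!",
    ss = substr(body, 17L, 17L),
    stringsAsFactors = FALSE)
}

.SS_TO_TYPE <- c(H = "xa", G = "xg", I = "xi", E = "e")

#' Segment DSSP secondary structure into SSE descriptors
#'
#' Maximal runs of the DSSP summary letters H, G, I and E become
#' alpha-helix (\code{xa}), 3-10 helix (\code{xg}), pi-helix (\code{xi})
#' and strand (\code{e}) elements; runs shorter than the per-class minimum
#' length are discarded. Chain breaks terminate runs. SSEs are numbered 1..N
#' from the N- to the C-terminus.
#'
#' @param dsspFile path to a DSSP-format file.
#' @param minHelix,minStrand minimum run lengths (residues) for helices and
#'   strands.
#' @param chainFilter optional chain identifier.
#' @return A data frame with one row per SSE: \code{index}, \code{type},
#'   \code{chain}, \code{resnoFirst}, \code{resnoLast}, \code{icodeFirst},
#'   \code{icodeLast}, \code{nres}; or a zero-row frame if no SSE survives
#'   filtering (such structures are skipped when building a database).
#' @export
assignSSEs <- function(dsspFile, minHelix = 3L, minStrand = 2L,
                       chainFilter = NULL) {
  res <- .parseDSSP(dsspFile)
  if (!is.null(chainFilter))
    res <- res[res$chain == chainFilter | res$brk, , drop = FALSE]
  letters <- ifelse(res$brk, "!", res$ss)
  segStart <- which(c(TRUE, letters[-1L] != letters[-length(letters)] |
                            res$chain[-1L] != res$chain[-length(res$chain)]))
  segEnd <- c(segStart[-1L] - 1L, length(letters))
  out <- list()
  for (s in seq_along(segStart)) {
    a <- segStart[s]; b <- segEnd[s]
    let <- letters[a]
    if (!let %in% names(.SS_TO_TYPE)) next
    type <- .SS_TO_TYPE[[let]]
    n <- b - a + 1L
    minLen <- if (type == "e") minStrand else minHelix
    if (n < minLen) next
    out[[length(out) + 1L]] <- data.frame(
      type = type, chain = res$chain[a],
      resnoFirst = res$resno[a], resnoLast = res$resno[b],
      icodeFirst = res$icode[a], icodeLast = res$icode[b],
      nres = n, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    sses <- data.frame(index = integer(), type = character(),
                       chain = character(), resnoFirst = integer(),
                       resnoLast = integer(), icodeFirst = character(),
                       icodeLast = character(), nres = integer(),
                       stringsAsFactors = FALSE)
    return(sses)
  }
  sses <- do.call(rbind, out)
  sses <- cbind(index = seq_len(nrow(sses)), sses)
  rownames(sses) <- NULL
  sses
}

#' Fit an axis to an SSE's C-alpha trace
#'
#' Total-least-squares fit: the axis point is the coordinate centroid and
#' the direction is the principal direction of the centered coordinates,
#' oriented from the first toward the last residue (N to C). For exactly
#' two residues the direction is the normalized difference.
#'
#' @param ca numeric matrix (n x 3) of C-alpha coordinates in residue
#'   order, n >= 2.
#' @return List with \code{point} (centroid, 3-vector) and \code{dir}
#'   (unit 3-vector).
#' @export
fitAxis <- function(ca) {
  ca <- as.matrix(ca)
  if (nrow(ca) < 2L) stop("need at least 2 coordinates to fit an axis")
  ctr <- colMeans(ca)
  span <- ca[nrow(ca), ] - ca[1L, ]
  if (nrow(ca) == 2L) {
    len <- sqrt(sum(span^2))
    if (len < 1e-9) stop("degenerate axis: coincident points")
    return(list(point = ctr, dir = span / len))
  }
  x <- sweep(ca, 2L, ctr)
  if (max(abs(x)) < 1e-9) stop("degenerate axis: coincident points")
  dir <- svd(x, nu = 0L, nv = 1L)$v[, 1L]
  if (sum(dir * span) < 0) dir <- -dir
  list(point = ctr, dir = dir)
}

#' Signed interaxial angle between two SSEs
#'
#' The angle between the two axis vectors projected onto the plane normal
#' to their mutual perpendicular, signed by a fixed chirality convention:
#' the mutual perpendicular \code{n = u x w / |u x w|} is flipped, if
#' needed, so that it points from the centroid of the first SSE toward the
#' centroid of the second. Near-parallel axes (|u x w| below
#' \code{tol}) give 0 or 180 by the sign of the dot product.
#'
#' @param dirI,dirJ unit axis direction vectors.
#' @param centroidI,centroidJ SSE C-alpha centroids (used only for the
#'   sign reference).
#' @param tol degeneracy tolerance on |u x w|.
#' @return Signed angle in degrees in (-180, 180].
#' @export
interaxialAngle <- function(dirI, dirJ, centroidI, centroidJ, tol = 1e-9) {
  u <- dirI; w <- dirJ
  cr <- c(u[2L] * w[3L] - u[3L] * w[2L],
          u[3L] * w[1L] - u[1L] * w[3L],
          u[1L] * w[2L] - u[2L] * w[1L])
  nc <- sqrt(sum(cr^2))
  dp <- sum(u * w)
  if (nc < tol) return(if (dp > 0) 0 else 180)
  n <- cr / nc
  if (sum(n * (centroidJ - centroidI)) < 0) n <- -n
  ang <- atan2(sum(cr * n), dp) * 180 / pi
  .normalizeAngle(ang)
}

#' Build a StructureEntry from SSE axes and centroids
#'
#' The tableau diagonal records the SSE types; each off-diagonal code is
#' the double-quadrant encoding of the signed interaxial angle, computed
#' for i < j (the sign reference points from centroid i to centroid j) and
#' mirrored to (j, i). Distances are Euclidean distances between C-alpha
#' centroids.
#'
#' @param id structure identifier.
#' @param types character vector of SSE type codes, N- to C-terminal order.
#' @param axes list of axis fits as returned by \code{\link{fitAxis}}, one
#'   per SSE.
#' @param centroids numeric matrix (n x 3) of SSE C-alpha centroids.
#' @return A \linkS4class{StructureEntry}.
#' @export
buildEntry <- function(id, types, axes, centroids) {
  n <- length(types)
  centroids <- matrix(as.numeric(centroids), ncol = 3L)
  if (length(axes) != n || nrow(centroids) != n)
    stop("types, axes and centroids must agree in length")
  if (n == 1L)
    return(StructureEntry(id, Tableau(types),
                          matrix(0, 1L, 1L)))
  codes <- matrix(NA_character_, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ang <- interaxialAngle(axes[[i]]$dir, axes[[j]]$dir,
                             centroids[i, ], centroids[j, ])
      codes[i, j] <- codes[j, i] <- encodeAngle(ang)
    }
  }
  d <- as.matrix(stats::dist(centroids))
  dimnames(d) <- NULL
  StructureEntry(id, Tableau(types, codes), d)
}

#' Build a StructureEntry from PDB and DSSP files
#'
#' Convenience wrapper chaining \code{\link{readCAlpha}},
#' \code{\link{assignSSEs}}, \code{\link{fitAxis}} and
#' \code{\link{buildEntry}}.
#'
#' @param id structure identifier.
#' @param pdbFile,dsspFile input file paths.
#' @param chainFilter optional chain identifier.
#' @param minHelix,minStrand minimum SSE lengths (residues).
#' @return A \linkS4class{StructureEntry}, or \code{NULL} (with a warning)
#'   if no SSE survives filtering — mirroring the omission of structures
#'   for which no SSEs are assigned.
#' @export
entryFromFiles <- function(id, pdbFile, dsspFile, chainFilter = NULL,
                           minHelix = 3L, minStrand = 2L) {
  ca <- readCAlpha(pdbFile, chainFilter)
  sses <- assignSSEs(dsspFile, minHelix = minHelix, minStrand = minStrand,
                     chainFilter = chainFilter)
  if (nrow(sses) == 0L) {
    warning("no SSEs found for '", id, "'; entry skipped")
    return(NULL)
  }
  axes <- vector("list", nrow(sses))
  centroids <- matrix(NA_real_, nrow(sses), 3L)
  for (k in seq_len(nrow(sses))) {
    sel <- ca$chain == sses$chain[k] &
      ca$resno >= sses$resnoFirst[k] & ca$resno <= sses$resnoLast[k]
    coords <- as.matrix(ca[sel, c("x", "y", "z")])
    if (nrow(coords) < 2L)
      stop("SSE ", k, " of '", id, "' has fewer than 2 C-alpha atoms")
    axes[[k]] <- fitAxis(coords)
    centroids[k, ] <- colMeans(coords)
  }
  buildEntry(id, sses$type, axes, centroids)
}
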