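## Synthetic inputs with known structure: random geometrically-consistent
## entries, planted motifs, ideal-geometry coordinates, and the exhaustive
## matching oracle used to validate the annealer.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a random structure entry
#'
#' Places \code{n} SSEs with random centroids in a cube of the given side,
#' random unit axis directions, and types drawn with the given strand
#' fraction, then builds the entry through the same angle-encoding and
#' centroid-distance path as real structures — so codes and distances are
#' mutually consistent and distances are metric.
#'
#' @param n number of SSEs.
#' @param strandFrac probability that an SSE is a strand (\code{e}); the
#'   rest are alpha-helices (\code{xa}).
#' @param seed integer seed; the same seed reproduces the same entry.
#' @param id entry identifier.
#' @param box side length (Angstroms) of the placement cube.
#' @return A \linkS4class{StructureEntry}.
#' @export
#' @examples
#' genRandomEntry(5, seed = 42)
genRandomEntry <- function(n, strandFrac = 0.4, seed = 1L,
                           id = paste0("synth", seed, "n", n), box = 40) {
  stopifnot(n >= 1L)
  .withSeed(seed, {
    centroids <- matrix(stats::runif(3L * n, 0, box), ncol = 3L)
    dirs <- matrix(stats::rnorm(3L * n), ncol = 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    types <- ifelse(stats::runif(n) < strandFrac, "e", "xa")
    axes <- lapply(seq_len(n), function(i)
      list(point = centroids[i, ], dir = dirs[i, ]))
    buildEntry(id, types, axes, centroids)
  })
}

#' Plant a motif inside a random host entry
#'
#' Generates a random host of \code{hostN} SSEs and extracts an exact
#' sub-entry at the given positions: the motif's codes and distances are
#' copies of the host's restricted to those positions, so the planted
#' correspondence scores \code{2 m (m - 1)} for a motif of size m.
#'
#' @param hostN host size.
#' @param positions strictly increasing SSE indices within the host
#'   (at least 2).
#' @param seed integer seed.
#' @param strandFrac passed to \code{\link{genRandomEntry}}.
#' @return List with \code{host} and \code{motif}
#'   (\linkS4class{StructureEntry}) and \code{plantedMap} (integer vector:
#'   motif SSE i sits at host position \code{plantedMap[i]}).
#' @export
#' @examples
#' fx <- plantMotif(12, c(2, 5, 9), seed = 3)
#' objectiveFull(fx$motif, fx$host, fx$plantedMap)  # 12
plantMotif <- function(hostN, positions, seed = 1L, strandFrac = 0.4) {
  positions <- as.integer(positions)
  if (length(positions) < 2L || anyDuplicated(positions) ||
      is.unsorted(positions, strictly = TRUE) ||
      any(positions < 1L) || any(positions > hostN))
    stop("positions must be >= 2 strictly increasing indices in 1..hostN")
  host <- genRandomEntry(hostN, strandFrac = strandFrac, seed = seed,
                         id = paste0("host", seed, "n", hostN))
  m <- tableau(host)@codes[positions, positions, drop = FALSE]
  d <- sseDistances(host)[positions, positions, drop = FALSE]
  motif <- StructureEntry(
    paste0("motif", seed, "m", length(positions)),
    Tableau(sseTypes(host)[positions],
            if (length(positions) > 1L) m else NULL),
    d)
  list(host = host, motif = motif, plantedMap = positions)
}

#' Ideal-geometry C-alpha coordinates
#'
#' Builds an ideal alpha-helix (1.5 Angstrom rise and 100 degrees of twist
#' per residue, 2.3 Angstrom radius) or an ideal extended strand (3.5
#' Angstroms per residue along the axis with a small alternating zigzag)
#' along an arbitrary direction, and returns the generating axis for
#' validating axis fits.
#'
#' @param kind \code{"helix"} or \code{"strand"}.
#' @param nRes number of residues (>= 4 for a helix, >= 2 for a strand).
#' @param origin 3-vector; position of the first residue's axis point.
#' @param direction unit 3-vector; the helical/strand axis.
#' @param phase starting phase angle (radians) of the helix.
#' @return List with \code{coords} (nRes x 3 matrix), \code{axisPoint} and
#'   \code{axisDir} (the generating axis).
#' @export
genIdealCoords <- function(kind = c("helix", "strand"), nRes,
                           origin = c(0, 0, 0), direction = c(0, 0, 1),
                           phase = 0) {
  kind <- match.arg(kind)
  if (kind == "helix" && nRes < 4L) stop("helix needs >= 4 residues")
  if (kind == "strand" && nRes < 2L) stop("strand needs >= 2 residues")
  direction <- direction / sqrt(sum(direction^2))
  ## orthonormal frame (e1, e2, direction)
  ref <- if (abs(direction[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * direction) * direction
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(direction[2L] * e1[3L] - direction[3L] * e1[2L],
          direction[3L] * e1[1L] - direction[1L] * e1[3L],
          direction[1L] * e1[2L] - direction[2L] * e1[1L])
  k <- seq_len(nRes) - 1L
  if (kind == "helix") {
    theta <- phase + k * 100 * pi / 180
    along <- k * 1.5
    coords <- outer(along, direction) +
      2.3 * (outer(cos(theta), e1) + outer(sin(theta), e2))
  } else {
    coords <- outer(k * 3.5, direction) +
      0.5 * (outer(rep_len(c(1, -1), nRes), e1))
  }
  coords <- sweep(coords, 2L, origin, `+`)
  list(coords = coords, axisPoint = origin, axisDir = direction)
}

#' Exhaustive matching oracle
#'
#' Enumerates every type-valid injective (and, optionally, ordered) partial
#' mapping of query SSEs to entry SSEs and returns the exact maximum of
#' \code{\link{objectiveFull}} with one optimal state (ties broken by the
#' lexicographically smallest state vector). Feasible only for small
#' instances; refuses when the enumeration bound (nB + 1)^nA exceeds 2^21
#' (a 7x7 pair is admitted, an 8x8 pair is not).
#'
#' @inheritParams objectiveFull
#' @return List with \code{score} (integer) and \code{state} (integer
#'   vector).
#' @export
#' @examples
#' e <- genRandomEntry(3, seed = 1)
#' bruteForceOptimum(e, e, sequential = TRUE)  # score 12, identity
bruteForceOptimum <- function(A, B, tau = 4.0, sequential = FALSE) {
  nA <- length(A); nB <- length(B)
  if ((nB + 1)^nA > 2^21)
    stop("brute-force enumeration refused: instance too large")
  tbA <- tableau(A)@codes; tbB <- tableau(B)@codes
  dA <- sseDistances(A); dB <- sseDistances(B)
  clsA <- sseTypeClass(sseTypes(A))
  clsB <- sseTypeClass(sseTypes(B))
  best <- list(score = 0L, state = integer(nA))
  v <- integer(nA)
  recurse <- function(i, score) {
    if (i > nA) {
      if (score > best$score) best <<- list(score = score, state = v)
      return(invisible(NULL))
    }
    ## candidates in ascending order, 0 first, so the first optimum found
    ## is the lexicographically smallest
    for (j in c(0L, seq_len(nB))) {
      if (j != 0L) {
        if (clsB[j] != clsA[i]) next
        if (j %in% v[seq_len(i - 1L)]) next
        if (sequential) {
          prev <- v[seq_len(i - 1L)]
          if (any(prev != 0L) && j <= max(prev)) next
        }
      }
      add <- 0L
      if (j != 0L) {
        for (k in seq_len(i - 1L)) {
          if (v[k] == 0L) next
          if (abs(dA[i, k] - dB[j, v[k]]) <= tau)
            add <- add + 2L * zetaScore(tbA[i, k], tbB[j, v[k]])
        }
      }
      v[i] <<- j
      recurse(i + 1L, score + add)
      v[i] <<- 0L
    }
  }
  recurse(1L, 0L)
  best
}

#' Write ideal-geometry fixtures as PDB and DSSP-like files
#'
#' Emits a minimal valid PDB file for a set of ideal SSEs laid head to
#' tail, plus a matching DSSP-format annotation, for end-to-end pipeline
#' tests without external data. The files are synthetic stand-ins, not
#' real protein structures.
#'
#' @param sses data frame with columns \code{kind} ("helix"/"strand"),
#'   \code{nRes}, and optionally \code{gap} (coil residues after each SSE,
#'   default 2).
#' @param pdbFile,dsspFile output paths.
#' @param seed seed for the random placement of successive SSE directions.
#' @return Invisibly, the number of residues written.
#' @export
writeIdealFixture <- function(sses, pdbFile, dsspFile, seed = 1L) {
  if (is.null(sses$gap)) sses$gap <- 2L
  .withSeed(seed, {
    coords <- NULL
    ss <- character(0)
    origin <- c(0, 0, 0)
    for (r in seq_len(nrow(sses))) {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      g <- genIdealCoords(sses$kind[r], sses$nRes[r], origin, dir)
      coords <- rbind(coords, g$coords)
      ss <- c(ss, rep(if (sses$kind[r] == "helix") "H" else "E",
                      sses$nRes[r]))
      ## coil linker drifting away from the SSE end
      end <- g$coords[nrow(g$coords), ]
      for (q in seq_len(sses$gap[r])) {
        step <- stats::rnorm(3)
        end <- end + 3.8 * step / sqrt(sum(step^2))
        coords <- rbind(coords, end)
        ss <- c(ss, " ")
      }
      origin <- end + c(4, 0, 0)
    }
    n <- nrow(coords)
    pdb <- sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n), seq_len(n), coords[, 1L], coords[, 2L], coords[, 3L])
    writeLines(c(pdb, "END"), pdbFile)
    hdr <- c("==== Secondary Structure Definition (synthetic) ====",
             "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC")
    rows <- sprintf("%5d%5d A A  %s", seq_len(n), seq_len(n), ss)
    writeLines(c(hdr, rows), dsspFile)
    invisible(n)
  })
}
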