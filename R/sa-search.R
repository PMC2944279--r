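## The matcher: objective with distance-difference constraint, move and
## initialization rules, simulated annealing with restarts (compiled inner
## loop), and size normalization of scores.

## integer code for C++: first char index * 4 + second char index; -1 diag
.codesToInt <- function(tb) {
  m <- tb@codes
  n <- nrow(m)
  out <- matrix(-1L, n, n)
  if (n > 1L) {
    off <- upper.tri(m) | lower.tri(m)
    f <- match(substr(m[off], 1L, 1L), .FIRST_CHARS) - 1L
    s <- match(substr(m[off], 2L, 2L), .SECOND_CHARS) - 1L
    out[off] <- f * 4L + s
  }
  out
}

.typeClassInt <- function(types) as.integer(sseTypeClass(types) == "helix")

#' Validate a match state
#'
#' A match state for query A against entry B is an integer vector \code{v}
#' of length \code{length(A)} with \code{v[i] = j} meaning query SSE i is
#' matched to entry SSE j, and \code{v[i] = 0} meaning unmatched. Nonzero
#' entries must be distinct, respect the helix/strand type classes, and,
#' in sequential mode, be strictly increasing.
#'
#' @param A,B \linkS4class{StructureEntry} objects (query, database entry).
#' @param v integer match state vector.
#' @param sequential logical; also require strict N-to-C ordering.
#' @return Invisibly \code{TRUE}; errors if any invariant is violated.
#' @export
validateMatchState <- function(A, B, v, sequential = FALSE) {
  nA <- length(A); nB <- length(B)
  v <- as.integer(v)
  if (length(v) != nA || anyNA(v) || any(v < 0L) || any(v > nB))
    stop("v must have length ", nA, " with entries in 0..", nB)
  nz <- v[v != 0L]
  if (anyDuplicated(nz))
    stop("nonzero entries of v must be pairwise distinct")
  if (length(nz)) {
    ta <- sseTypes(A)[v != 0L]
    tb <- sseTypes(B)[nz]
    if (!all(sameTypeClass(ta, tb)))
      stop("v matches SSEs of different type classes")
  }
  if (sequential && length(nz) > 1L && any(diff(nz) <= 0L))
    stop("v violates the sequential ordering constraint")
  invisible(TRUE)
}

#' Matching objective with distance-difference constraint
#'
#' The score of a match state is the sum, over all ordered pairs (i, k) of
#' distinct matched query SSEs with images (j, l), of the pairwise code
#' score \code{zetaScore} of the corresponding tableau entries — counted
#' only when the intra-structure centroid distances agree to within
#' \code{tau} Angstroms (pairs beyond the threshold contribute zero).
#' Each unordered pair therefore counts twice; a full self-match of an
#' entry with N SSEs scores 2N(N-1).
#'
#' @inheritParams validateMatchState
#' @param tau distance-difference threshold in Angstroms.
#' @return Integer score.
#' @export
#' @examples
#' e <- genRandomEntry(4, seed = 1)
#' objectiveFull(e, e, seq_len(4), tau = 4)  # 2 * 4 * 3
objectiveFull <- function(A, B, v, tau = 4.0, sequential = FALSE) {
  validateMatchState(A, B, v, sequential)
  v <- as.integer(v)
  idx <- which(v != 0L)
  if (length(idx) < 2L) return(0L)
  tbA <- tableau(A)@codes; tbB <- tableau(B)@codes
  dA <- sseDistances(A); dB <- sseDistances(B)
  s <- 0L
  for (i in idx) for (k in idx) {
    if (i == k) next
    if (abs(dA[i, k] - dB[v[i], v[k]]) <= tau)
      s <- s + zetaScore(tbA[i, k], tbB[v[i], v[k]])
  }
  s
}

#' Incremental objective change for a single reassignment
#'
#' Returns \code{objectiveFull} of the state with \code{v[i]} changed to
#' \code{jNew}, minus \code{objectiveFull(v)}, computed in O(N) by summing
#' only the pair terms involving SSE i. Exact integer arithmetic:
#' accumulating deltas never drifts from the full recomputation.
#'
#' @inheritParams objectiveFull
#' @param i query SSE index to reassign.
#' @param jNew new image in \code{0..length(B)} (0 removes the match).
#' @return Integer score change.
#' @export
objectiveDelta <- function(A, B, v, i, jNew, tau = 4.0, sequential = FALSE) {
  validateMatchState(A, B, v, sequential)
  v <- as.integer(v); i <- as.integer(i); jNew <- as.integer(jNew)
  vNew <- v; vNew[i] <- jNew
  validateMatchState(A, B, vNew, sequential)
  .contrib <- function(vv, j) {
    if (j == 0L) return(0L)
    tbA <- tableau(A)@codes; tbB <- tableau(B)@codes
    dA <- sseDistances(A); dB <- sseDistances(B)
    s <- 0L
    for (k in which(vv != 0L)) {
      if (k == i) next
      if (abs(dA[i, k] - dB[j, vv[k]]) <= tau)
        s <- s + zetaScore(tbA[i, k], tbB[j, vv[k]])
    }
    2L * s
  }
  .contrib(v, jNew) - .contrib(v, v[i])
}

#' Random initial match state
#'
#' Scans query SSEs in order; each is matched, with probability \code{pm},
#' to the lowest-index entry SSE of the same type class that lies beyond
#' the last assigned index (so the result is sequential-valid regardless of
#' mode); otherwise (or when no such SSE exists) it is left unmatched.
#' Draws come from R's RNG.
#'
#' @inheritParams objectiveFull
#' @param pm matching probability in [0, 1].
#' @return Integer match state vector.
#' @export
randomInit <- function(A, B, pm = 0.5, sequential = FALSE) {
  clsA <- sseTypeClass(sseTypes(A))
  clsB <- sseTypeClass(sseTypes(B))
  nA <- length(clsA); nB <- length(clsB)
  v <- integer(nA)
  last <- 0L
  for (i in seq_len(nA)) {
    if (stats::runif(1) < pm) {
      j <- which(clsB == clsA[i] & seq_len(nB) > last)
      if (length(j)) {
        v[i] <- j[1L]
        last <- j[1L]
      }
    }
  }
  v
}

#' Propose a neighbour state
#'
#' Chooses a query SSE i uniformly at random and a new image j uniformly
#' from the feasible set: same type class, not used by any other query SSE,
#' ordering-feasible given the other assignments in sequential mode, and
#' different from the current \code{v[i]}. If the feasible set is empty the
#' SSE is removed from the mapping (\code{j = 0}). Draws come from R's RNG.
#'
#' @inheritParams objectiveFull
#' @return List with elements \code{i} and \code{jNew}.
#' @export
proposeMove <- function(A, B, v, sequential = FALSE, tau = 4.0) {
  v <- as.integer(v)
  nA <- length(A)
  i <- sample.int(nA, 1L)
  J <- .moveCandidates(A, B, v, i, sequential)
  jNew <- if (length(J) == 0L) 0L else J[sample.int(length(J), 1L)]
  list(i = i, jNew = jNew)
}

.moveCandidates <- function(A, B, v, i, sequential) {
  clsA <- sseTypeClass(sseTypes(A))
  clsB <- sseTypeClass(sseTypes(B))
  nB <- length(clsB)
  J <- which(clsB == clsA[i])
  J <- setdiff(J, c(v[i], v[-i]))
  if (sequential) {
    before <- v[seq_len(i - 1L)]
    after <- if (i < length(v)) v[seq(i + 1L, length(v))] else integer(0)
    lo <- if (any(before != 0L)) max(before[before != 0L]) else 0L
    hi <- if (any(after != 0L)) min(after[after != 0L]) else nB + 1L
    J <- J[J > lo & J < hi]
  }
  J
}

#' One simulated-annealing run
#'
#' Starts from \code{randomInit}, performs \code{iterations} proposed
#' moves with geometric cooling (temperature \code{T0 * alpha^k} at move
#' k), accepting a move when its new objective exceeds the best found so
#' far or when \code{exp(delta/T) > p} for a uniform draw p (improving
#' moves are always accepted), and returns the maximum-objective state
#' visited. Runs on the deterministic per-restart stream indexed by
#' \code{restart}.
#'
#' @param A,B \linkS4class{StructureEntry} objects.
#' @param params a \linkS4class{SearchParams}.
#' @param restart restart index selecting the RNG stream.
#' @return List with \code{state} (integer vector) and \code{score}
#'   (integer).
#' @export
annealOnce <- function(A, B, params = SearchParams(), restart = 0L) {
  res <- .cppSearchPair(.codesToInt(tableau(A)),
                        .typeClassInt(sseTypes(A)), sseDistances(A),
                        .codesToInt(tableau(B)),
                        .typeClassInt(sseTypes(B)), sseDistances(B),
                        params@tau, params@sequential, params@T0,
                        params@alpha, params@iterations, params@pm,
                        1L, as.integer(restart), params@seed,
                        entryId(A), entryId(B))
  list(state = res$state, score = res$raw)
}

#' Size normalization of a raw matching score
#'
#' \code{2 * raw / (nA + nB)}: twice the raw tableau matching score divided
#' by the sum of the two tableau dimensions, making scores comparable
#' across structures of different sizes.
#'
#' @param raw raw (integer) matching score.
#' @param nA,nB SSE counts of the two structures (positive).
#' @return Numeric normalized score.
#' @export
#' @examples
#' norm2Score(12, 3, 3)  # 4
norm2Score <- function(raw, nA, nB) {
  if (any(nA < 1L) || any(nB < 1L))
    stop("structure sizes must be positive")
  2 * raw / (nA + nB)
}

#' Match a query against one database entry
#'
#' Runs \code{restarts} independent annealing runs (each on its own
#' deterministic RNG stream derived from the seed, the two ids and the
#' restart index) and returns the best state found, with raw and
#' size-normalized scores. Results are reproducible for a given seed
#' regardless of scheduling.
#'
#' @param A,B \linkS4class{StructureEntry} objects (query, database entry).
#' @param params a \linkS4class{SearchParams}.
#' @return List with \code{dbId}, \code{rawScore}, \code{normScore} and
#'   \code{state}.
#' @export
#' @examples
#' e <- genRandomEntry(4, seed = 1)
#' searchPair(e, e, SearchParams(sequential = TRUE))$rawScore  # 24
searchPair <- function(A, B, params = SearchParams()) {
  res <- .cppSearchPair(.codesToInt(tableau(A)),
                        .typeClassInt(sseTypes(A)), sseDistances(A),
                        .codesToInt(tableau(B)),
                        .typeClassInt(sseTypes(B)), sseDistances(B),
                        params@tau, params@sequential, params@T0,
                        params@alpha, params@iterations, params@pm,
                        params@restarts, 0L, params@seed,
                        entryId(A), entryId(B))
  list(dbId = entryId(B), rawScore = res$raw,
       normScore = norm2Score(res$raw, length(A), length(B)),
       state = res$state)
}

#' Search a database with a query structure
#'
#' Matches the query against every entry and ranks results by descending
#' normalized score (ties by id). Per-pair RNG streams make the output
#' bit-identical for any number of workers and independent of database
#' order.
#'
#' @param query a \linkS4class{StructureEntry}.
#' @param db a \linkS4class{TableauDatabase}.
#' @param params a \linkS4class{SearchParams}.
#' @param workers number of parallel worker processes (forked).
#' @return A data frame with columns \code{db_id}, \code{raw_score},
#'   \code{norm_score} and a list column \code{state}, one row per entry,
#'   ranked best-first.
#' @export
searchDatabase <- function(query, db, params = SearchParams(),
                           workers = 1L) {
  stopifnot(is(query, "StructureEntry"), is(db, "TableauDatabase"))
  run <- function(e) searchPair(query, e, params)
  results <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(db@entries, run, mc.cores = workers)
  } else {
    lapply(db@entries, run)
  }
  if (length(results) == 0L)
    return(data.frame(db_id = character(), raw_score = integer(),
                      norm_score = numeric()))
  out <- data.frame(
    db_id = vapply(results, `[[`, character(1), "dbId"),
    raw_score = vapply(results, `[[`, integer(1), "rawScore"),
    norm_score = vapply(results, `[[`, numeric(1), "normScore"),
    stringsAsFactors = FALSE)
  out$state <- lapply(results, `[[`, "state")
  ord <- order(-out$norm_score, out$db_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
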