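#' @import methods
NULL

## Alphabets. Orientation codes are uppercase, SSE type codes lowercase;
## comparisons are case-sensitive throughout.
.FIRST_CHARS <- c("P", "O", "L", "R")
.SECOND_CHARS <- c("E", "D", "S", "T")
.SSE_TYPES <- c("e", "xa", "xi", "xg")
.TYPE_CLASS <- c(e = "strand", xa = "helix", xi = "helix", xg = "helix")

#' All 16 valid tableau codes
#'
#' The double-quadrant encoding yields a two-character alphabet: the first
#' character is P, O, L or R (parallel, anti-parallel, crossing-left,
#' crossing-right) and the second E, D, S or T (the same quadrants rotated
#' by 45 degrees).
#'
#' @return Character vector of the 16 valid codes.
#' @export
#' @examples
#' tableauCodeAlphabet()
tableauCodeAlphabet <- function() {
  as.vector(outer(.FIRST_CHARS, .SECOND_CHARS, paste0))
}

.validTableauCode <- function(x) {
  is.character(x) & nchar(x) == 2L &
    substr(x, 1L, 1L) %in% .FIRST_CHARS &
    substr(x, 2L, 2L) %in% .SECOND_CHARS
}

.validSSEType <- function(x) {
  is.character(x) & x %in% .SSE_TYPES
}

#' Tableau: discrete pairwise SSE orientation codes
#'
#' A tableau for a structure with \code{n} secondary structure elements
#' (SSEs) is an \code{n x n} symmetric matrix of two-character orientation
#' codes; the main diagonal, which would be redundant, stores the SSE type
#' code (\code{e}, \code{xa}, \code{xi} or \code{xg}) of each element
#' instead.
#'
#' @slot codes character matrix; diagonal holds lowercase SSE type codes,
#'   off-diagonal entries hold uppercase orientation codes and are
#'   symmetric.
#' @export
setClass("Tableau", representation(codes = "matrix"))

setValidity("Tableau", function(object) {
  m <- object@codes
  if (!is.character(m) || !is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 1L)
    return("codes must be a square character matrix with n >= 1")
  d <- diag(m)
  if (!all(.validSSEType(d)))
    return("diagonal must hold SSE type codes (e, xa, xi, xg)")
  if (nrow(m) > 1L) {
    off <- m[lower.tri(m)]
    if (!all(.validTableauCode(off)))
      return("off-diagonal entries must be valid two-character tableau codes")
    if (!identical(m[lower.tri(m)], t(m)[lower.tri(m)]))
      return("off-diagonal codes must be symmetric")
  }
  TRUE
})

#' Construct a Tableau
#'
#' @param types character vector of SSE type codes, one per SSE in
#'   N- to C-terminal order.
#' @param codes for \code{n > 1}, a symmetric \code{n x n} character matrix
#'   of orientation codes (the diagonal is ignored and replaced by
#'   \code{types}); may be omitted when \code{n == 1}.
#' @return A \linkS4class{Tableau}.
#' @export
#' @examples
#' Tableau(c("xa", "e"), matrix(c(NA, "OT", "OT", NA), 2, 2))
Tableau <- function(types, codes = NULL) {
  n <- length(types)
  if (n == 1L) {
    m <- matrix(types, 1L, 1L)
  } else {
    if (is.null(codes))
      stop("codes matrix required for n > 1")
    m <- codes
    diag(m) <- types
  }
  new("Tableau", codes = m)
}

#' @describeIn Tableau-class Number of SSEs.
#' @param x,object a \code{Tableau}.
#' @export
setMethod("length", "Tableau", function(x) nrow(x@codes))

#' SSE types on a tableau diagonal
#'
#' @param x a \linkS4class{Tableau} or \linkS4class{StructureEntry}.
#' @return Character vector of SSE type codes.
#' @export
setGeneric("sseTypes", function(x) standardGeneric("sseTypes"))

#' @rdname sseTypes
#' @export
setMethod("sseTypes", "Tableau", function(x) diag(x@codes))

#' Orientation code for a pair of SSEs
#'
#' Lookup is symmetric: \code{tableauCode(x, i, j) == tableauCode(x, j, i)}.
#'
#' @param x a \linkS4class{Tableau} or \linkS4class{StructureEntry}.
#' @param i,j SSE indices, \code{i != j}.
#' @return The two-character orientation code.
#' @export
setGeneric("tableauCode", function(x, i, j) standardGeneric("tableauCode"))

#' @rdname tableauCode
#' @export
setMethod("tableauCode", "Tableau", function(x, i, j) {
  if (any(i == j)) stop("diagonal holds SSE types, not orientation codes")
  x@codes[cbind(i, j)]
})

setMethod("show", "Tableau", function(object) {
  n <- length(object)
  cat("Tableau with", n, "SSEs:", paste(diag(object@codes), collapse = " "),
      "\n")
  if (n > 1L) {
    m <- object@codes
    m[upper.tri(m)] <- ""
    prmatrix(m, rowlab = rep("", n), collab = rep("", n), quote = FALSE)
  }
  invisible(NULL)
})

#' StructureEntry: tableau plus SSE centroid distance matrix
#'
#' A database/search unit: a structure identifier, its tableau, and the
#' symmetric matrix of distances (in Angstroms) between the C-alpha
#' centroids of its SSEs.
#'
#' @slot id character identifier.
#' @slot tableau a \linkS4class{Tableau}.
#' @slot distances numeric symmetric matrix, zero diagonal, same dimension
#'   as the tableau.
#' @export
setClass("StructureEntry",
         representation(id = "character", tableau = "Tableau",
                        distances = "matrix"))

setValidity("StructureEntry", function(object) {
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    return("id must be a single non-empty string")
  if (grepl("\\s", object@id))
    return("id must not contain whitespace")
  n <- length(object@tableau)
  d <- object@distances
  if (!is.numeric(d) || !is.matrix(d) || nrow(d) != n || ncol(d) != n)
    return("distance matrix dimension must equal the tableau dimension")
  if (any(!is.finite(d)) || any(d < 0))
    return("distances must be finite and non-negative")
  if (any(abs(diag(d)) > 1e-9))
    return("distance matrix diagonal must be zero")
  if (max(abs(d - t(d))) > 1e-6)
    return("distance matrix must be symmetric")
  TRUE
})

#' Construct a StructureEntry
#'
#' @param id structure identifier (no whitespace).
#' @param tableau a \linkS4class{Tableau}.
#' @param distances symmetric numeric matrix of SSE centroid distances
#'   (Angstroms), zero diagonal.
#' @return A \linkS4class{StructureEntry}.
#' @export
StructureEntry <- function(id, tableau, distances) {
  new("StructureEntry", id = id, tableau = tableau,
      distances = as.matrix(distances))
}

#' @describeIn StructureEntry-class Number of SSEs.
#' @param x,object a \code{StructureEntry}.
#' @export
setMethod("length", "StructureEntry", function(x) length(x@tableau))

#' Structure identifier
#' @param x a \linkS4class{StructureEntry}.
#' @return Character scalar.
#' @export
setGeneric("entryId", function(x) standardGeneric("entryId"))

#' @rdname entryId
#' @export
setMethod("entryId", "StructureEntry", function(x) x@id)

#' Tableau of an entry
#' @param x a \linkS4class{StructureEntry}.
#' @return The \linkS4class{Tableau}.
#' @export
setGeneric("tableau", function(x) standardGeneric("tableau"))

#' @rdname tableau
#' @export
setMethod("tableau", "StructureEntry", function(x) x@tableau)

#' SSE centroid distance matrix of an entry
#' @param x a \linkS4class{StructureEntry}.
#' @return Numeric symmetric matrix (Angstroms).
#' @export
setGeneric("sseDistances", function(x) standardGeneric("sseDistances"))

#' @rdname sseDistances
#' @export
setMethod("sseDistances", "StructureEntry", function(x) x@distances)

#' @rdname sseTypes
#' @export
setMethod("sseTypes", "StructureEntry", function(x) sseTypes(x@tableau))

#' @rdname tableauCode
#' @export
setMethod("tableauCode", "StructureEntry",
          function(x, i, j) tableauCode(x@tableau, i, j))

setMethod("show", "StructureEntry", function(object) {
  cat("StructureEntry", object@id, "with", length(object), "SSEs\n")
  invisible(NULL)
})

#' TableauDatabase: an ordered collection of structure entries
#'
#' @slot entries list of \linkS4class{StructureEntry} with unique ids.
#' @export
setClass("TableauDatabase", representation(entries = "list"))

setValidity("TableauDatabase", function(object) {
  es <- object@entries
  if (!all(vapply(es, is, logical(1), "StructureEntry")))
    return("entries must all be StructureEntry objects")
  ids <- vapply(es, entryId, character(1))
  if (anyDuplicated(ids))
    return(paste("duplicate entry id:", ids[duplicated(ids)][1L]))
  TRUE
})

#' Construct a TableauDatabase
#'
#' @param entries list of \linkS4class{StructureEntry} objects (unique ids).
#' @return A \linkS4class{TableauDatabase}.
#' @export
TableauDatabase <- function(entries = list()) {
  new("TableauDatabase", entries = entries)
}

#' @describeIn TableauDatabase-class Number of entries.
#' @param x,object a \code{TableauDatabase}.
#' @export
setMethod("length", "TableauDatabase", function(x) length(x@entries))

#' Ids of all database entries
#' @param db a \linkS4class{TableauDatabase}.
#' @return Character vector in database order.
#' @export
dbIds <- function(db) vapply(db@entries, entryId, character(1))

#' @describeIn TableauDatabase-class Extract an entry by position or id.
#' @param i integer position or character id.
#' @param j,... unused.
#' @export
setMethod("[[", "TableauDatabase", function(x, i, j, ...) {
  if (is.character(i)) {
    pos <- match(i, dbIds(x))
    if (is.na(pos)) stop("no entry with id ", i)
    i <- pos
  }
  x@entries[[i]]
})

setMethod("show", "TableauDatabase", function(object) {
  n <- length(object)
  cat("TableauDatabase with", n, "entries\n")
  if (n > 0L) {
    sizes <- vapply(object@entries, length, integer(1))
    cat("  SSE counts:", min(sizes), "-", max(sizes), "\n")
  }
  invisible(NULL)
})

#' Search parameters for simulated annealing
#'
#' Defaults are the tuned schedule: initial temperature \code{T0 = 10},
#' geometric cooling \code{alpha = 0.95}, 100 iterations per restart,
#' initial matching probability \code{pm = 0.5}, \code{restarts = 128}
#' independent runs, and distance-difference threshold \code{tau = 4}
#' Angstroms. \code{sequential = FALSE} permits non-sequential matchings.
#'
#' @slot T0 positive initial temperature.
#' @slot alpha cooling multiplier in (0, 1).
#' @slot iterations positive number of moves per restart.
#' @slot pm probability in [0, 1] of matching each query SSE at
#'   initialization.
#' @slot restarts positive number of independent annealing runs.
#' @slot tau non-negative distance-difference threshold (Angstroms).
#' @slot sequential logical; enforce N-to-C ordering of the matching.
#' @slot seed integer base seed for the deterministic per-restart streams.
#' @export
setClass("SearchParams",
         representation(T0 = "numeric", alpha = "numeric",
                        iterations = "integer", pm = "numeric",
                        restarts = "integer", tau = "numeric",
                        sequential = "logical", seed = "integer"))

setValidity("SearchParams", function(object) {
  if (object@T0 <= 0) return("T0 must be positive")
  if (object@alpha <= 0 || object@alpha >= 1)
    return("alpha must be in (0, 1)")
  if (object@iterations < 1L) return("iterations must be positive")
  if (object@pm < 0 || object@pm > 1) return("pm must be in [0, 1]")
  if (object@restarts < 1L) return("restarts must be positive")
  if (object@tau < 0) return("tau must be non-negative")
  TRUE
})

#' @rdname SearchParams-class
#' @param T0,alpha,iterations,pm,restarts,tau,sequential,seed see slots.
#' @return A \linkS4class{SearchParams}.
#' @export
#' @examples
#' SearchParams(restarts = 64, sequential = TRUE, seed = 7)
SearchParams <- function(T0 = 10, alpha = 0.95, iterations = 100L, pm = 0.5,
                         restarts = 128L, tau = 4.0, sequential = FALSE,
                         seed = 1L) {
  new("SearchParams", T0 = as.numeric(T0), alpha = as.numeric(alpha),
      iterations = as.integer(iterations), pm = as.numeric(pm),
      restarts = as.integer(restarts), tau = as.numeric(tau),
      sequential = as.logical(sequential), seed = as.integer(seed))
}

setMethod("show", "SearchParams", function(object) {
  cat(sprintf(paste0("SearchParams: T0=%g alpha=%g iterations=%d pm=%g ",
                     "restarts=%d tau=%g sequential=%s seed=%d\n"),
              object@T0, object@alpha, object@iterations, object@pm,
              object@restarts, object@tau, object@sequential, object@seed))
  invisible(NULL)
})

#' Result of an AUC computation with Hanley-McNeil interval
#'
#' @slot auc area under the ROC curve in [0, 1].
#' @slot se Hanley-McNeil standard error.
#' @slot ciLow,ciHigh 95 percent confidence limits (auc +/- 1.96 se,
#'   clipped to [0, 1]).
#' @slot nPos,nNeg counts of positive and negative scores.
#' @export
setClass("ROCResult",
         representation(auc = "numeric", se = "numeric", ciLow = "numeric",
                        ciHigh = "numeric", nPos = "integer",
                        nNeg = "integer"))

setValidity("ROCResult", function(object) {
  if (object@auc < 0 || object@auc > 1) return("auc must be in [0, 1]")
  if (object@se < 0) return("se must be non-negative")
  if (object@ciLow > object@auc || object@ciHigh < object@auc)
    return("interval must contain auc")
  TRUE
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("AUC = %.4f (SE %.4f, 95%% CI %.4f-%.4f; %d pos, %d neg)\n",
              object@auc, object@se, object@ciLow, object@ciHigh,
              object@nPos, object@nNeg))
  invisible(NULL)
})

#' @describeIn ROCResult-class Extract a field by name
#'   (\code{auc}, \code{se}, \code{ciLow}, \code{ciHigh}, \code{nPos},
#'   \code{nNeg}).
#' @param x a \code{ROCResult}.
#' @param name slot name.
#' @export
setMethod("$", "ROCResult", function(x, name) slot(x, name))
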