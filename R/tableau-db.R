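## Plain-text database of tableaux and distance matrices.
##
## Entry layout:
##   <id> <N>
##   N lines of the lower-triangular tableau: line i holds the type code
##     of SSE i followed by the codes (i,1) .. (i,i-1)
##   N lines of lower-triangular distances: d(i,1) .. d(i,i-1) then the
##     0.000 diagonal, 3 decimals
##   blank line between entries

#' Serialize a tableau database to text
#'
#' The format is canonical: writing, reading back and writing again is
#' byte-identical. Distances are printed with 3 decimals, which round-trips
#' exactly.
#'
#' @param db a \linkS4class{TableauDatabase}.
#' @param file path or connection to write to; \code{""} returns the text
#'   invisibly only.
#' @return Invisibly, the character vector of lines written.
#' @export
writeTableauDB <- function(db, file) {
  stopifnot(is(db, "TableauDatabase"))
  out <- character(0)
  for (e in db@entries) {
    n <- length(e)
    tb <- tableau(e)@codes
    lines <- character(2L * n + 1L)
    lines[1L] <- paste(entryId(e), n)
    for (i in seq_len(n)) {
      row <- tb[i, i]
      if (i > 1L) row <- c(row, tb[i, seq_len(i - 1L)])
      lines[1L + i] <- paste(row, collapse = " ")
    }
    d <- sseDistances(e)
    for (i in seq_len(n))
      lines[1L + n + i] <- paste(sprintf("%.3f", d[i, seq_len(i)]),
                                 collapse = " ")
    out <- c(out, lines, "")
  }
  writeLines(out, file)
  invisible(out)
}

.parseError <- function(lineNo, msg) {
  stop(sprintf("database parse error at line %d: %s", lineNo, msg),
       call. = FALSE)
}

#' Read a tableau database from text
#'
#' Validates code alphabets, matrix shapes and id uniqueness; malformed
#' input aborts with the offending line number unless \code{skipBad} is
#' set, in which case bad entries are dropped with a warning.
#'
#' @param file path or connection in the format written by
#'   \code{\link{writeTableauDB}}.
#' @param skipBad logical; skip malformed entries instead of aborting.
#' @return A \linkS4class{TableauDatabase} with entries in file order.
#' @export
readTableauDB <- function(file, skipBad = FALSE) {
  lines <- readLines(file, warn = FALSE)
  entries <- list()
  ids <- character(0)
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    first <- i
    entry <- tryCatch(.readEntryAt(lines, i), error = function(e) e)
    if (inherits(entry, "error")) {
      if (!skipBad) stop(entry)
      warning("skipping malformed entry at line ", first, ": ",
              conditionMessage(entry))
      ## resynchronize at the next blank line
      nxt <- which(!nzchar(trimws(lines)) & seq_along(lines) > first)
      i <- if (length(nxt)) nxt[1L] + 1L else length(lines) + 1L
      next
    }
    if (entry$entry@id %in% ids)
      .parseError(first, paste("duplicate id", entry$entry@id))
    ids <- c(ids, entry$entry@id)
    entries[[length(entries) + 1L]] <- entry$entry
    i <- entry$nextLine
  }
  TableauDatabase(entries)
}

.readEntryAt <- function(lines, i) {
  hdr <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
  if (length(hdr) != 2L)
    .parseError(i, "header must be '<id> <N>'")
  id <- hdr[1L]
  n <- suppressWarnings(as.integer(hdr[2L]))
  if (is.na(n) || n < 1L)
    .parseError(i, "N must be a positive integer")
  if (i + 2L * n > length(lines))
    .parseError(i, "truncated entry")
  codes <- matrix(NA_character_, n, n)
  types <- character(n)
  for (r in seq_len(n)) {
    ln <- i + r
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(tok) != r)
      .parseError(ln, sprintf("expected %d tableau tokens, found %d",
                              r, length(tok)))
    if (!.validSSEType(tok[1L]))
      .parseError(ln, paste("invalid SSE type code", tok[1L]))
    types[r] <- tok[1L]
    if (r > 1L) {
      off <- tok[-1L]
      bad <- !.validTableauCode(off)
      if (any(bad))
        .parseError(ln, paste("invalid tableau code", off[bad][1L]))
      codes[r, seq_len(r - 1L)] <- off
      codes[seq_len(r - 1L), r] <- off
    }
  }
  d <- matrix(0, n, n)
  for (r in seq_len(n)) {
    ln <- i + n + r
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(tok) != r)
      .parseError(ln, sprintf("expected %d distance tokens, found %d",
                              r, length(tok)))
    val <- suppressWarnings(as.numeric(tok))
    if (any(is.na(val)))
      .parseError(ln, paste("non-numeric distance", tok[is.na(val)][1L]))
    if (any(val < 0))
      .parseError(ln, "negative distance")
    if (abs(val[r]) > 1e-9)
      .parseError(ln, "diagonal distance must be 0")
    d[r, seq_len(r)] <- val
    d[seq_len(r), r] <- val
  }
  entry <- tryCatch(
    StructureEntry(id, Tableau(types, if (n > 1L) codes else NULL), d),
    error = function(e) .parseError(i, conditionMessage(e)))
  list(entry = entry, nextLine = i + 2L * n + 1L)
}

#' Sort database entries by size
#'
#' Orders entries by ascending SSE count, ties broken by id. This is a
#' scheduling aid for batch searches; ranked search results do not depend
#' on database order.
#'
#' @param db a \linkS4class{TableauDatabase}.
#' @return The sorted \linkS4class{TableauDatabase}.
#' @export
sortBySize <- function(db) {
  stopifnot(is(db, "TableauDatabase"))
  sizes <- vapply(db@entries, length, integer(1))
  ids <- dbIds(db)
  TableauDatabase(db@entries[order(sizes, ids, method = "radix")])
}
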