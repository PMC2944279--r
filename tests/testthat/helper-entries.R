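# Build a StructureEntry directly from explicit code and distance matrices
# (bypassing geometry) for hand-crafted cases.
makeEntry <- function(id, types, codes = NULL, dist = NULL) {
  n <- length(types)
  if (is.null(dist)) dist <- matrix(0, n, n)
  StructureEntry(id, Tableau(types, codes), dist)
}

# Two-SSE entry with a single off-diagonal code and distance.
makePairEntry <- function(id, code, d, types = c("xa", "xa")) {
  makeEntry(id, types,
            matrix(c(NA, code, code, NA), 2, 2),
            matrix(c(0, d, d, 0), 2, 2))
}

# Random small database of geometrically consistent entries.
makeRandomDb <- function(nEntries, sizes = 3:6, seedBase = 100) {
  entries <- lapply(seq_len(nEntries), function(k) {
    genRandomEntry(sample(sizes, 1), seed = seedBase + k,
                   id = sprintf("d%02d", k))
  })
  TableauDatabase(entries)
}

# Apply a random rigid-body motion to a coordinate matrix.
rigidMotion <- function(coords, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t(R %*% t(coords)) + matrix(runif(3, -20, 20), nrow(coords), 3,
                              byrow = TRUE)
}
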