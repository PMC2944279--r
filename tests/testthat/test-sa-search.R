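test_that("the objective scores matched pairs under the distance constraint", {
  A <- makePairEntry("A", "OT", 10)
  B <- makePairEntry("B", "OT", 20)
  expect_identical(objectiveFull(A, B, c(1, 2), tau = 4), 0L)
  expect_identical(objectiveFull(A, B, c(1, 2), tau = 15), 4L)
  expect_identical(objectiveFull(A, B, c(0, 0)), 0L)
  e <- genRandomEntry(3, seed = 5)
  expect_identical(objectiveFull(e, e, 1:3, tau = 4), 12L)
})

test_that("the distance constraint admits a nested pair set and vanishes at tau = Inf", {
  A <- genRandomEntry(5, seed = 21, id = "A")
  B <- genRandomEntry(6, seed = 22, id = "B")
  dA <- sseDistances(A); dB <- sseDistances(B)
  admitted <- function(v, tau) {
    idx <- which(v != 0)
    pairs <- expand.grid(i = idx, k = idx)
    pairs <- pairs[pairs$i != pairs$k, ]
    with(pairs, abs(dA[cbind(i, k)] - dB[cbind(v[i], v[k])]) <= tau)
  }
  set.seed(1)
  for (rep in 1:5) {
    repeat {
      v <- randomInit(A, B, pm = 0.7)
      if (sum(v != 0) >= 2) break
    }
    taus <- c(0, 2, 4, 8, 16, 64, Inf)
    adm <- lapply(taus, function(t) admitted(v, t))
    # enlarging tau only ever adds admitted pairs
    for (t in seq_along(taus)[-1])
      expect_true(all(adm[[t]] | !adm[[t - 1]]))
    # unconstrained score computed directly from the code matrices
    idx <- which(v != 0)
    s <- 0L
    for (i in idx) for (k in idx) {
      if (i != k)
        s <- s + zetaScore(tableauCode(A, i, k),
                           tableauCode(B, v[i], v[k]))
    }
    expect_identical(objectiveFull(A, B, v, tau = Inf), s)
  }
})

test_that("invalid match states are rejected", {
  A <- genRandomEntry(4, seed = 31, strandFrac = 0, id = "A")  # all helix
  B <- genRandomEntry(4, seed = 32, strandFrac = 0, id = "B")
  expect_error(objectiveFull(A, B, c(1, 1, 0, 0)), "distinct")
  expect_error(objectiveFull(A, B, c(1, 2, 3, 9)), "0..4")
  expect_error(objectiveFull(A, B, c(2, 1, 0, 0), sequential = TRUE),
               "sequential")
  mixed <- makeEntry("m", c("e", "xa"),
                     matrix(c(NA, "PE", "PE", NA), 2, 2))
  helices <- makeEntry("h", c("xa", "xa"),
                       matrix(c(NA, "PE", "PE", NA), 2, 2))
  expect_error(objectiveFull(mixed, helices, c(1, 0)), "type class")
})

test_that("the incremental delta equals the full recomputation everywhere", {
  set.seed(2024)
  checks <- 0
  while (checks < 1000) {
    nA <- sample(2:8, 1); nB <- sample(2:8, 1)
    A <- genRandomEntry(nA, seed = sample.int(1e6, 1), id = "A")
    B <- genRandomEntry(nB, seed = sample.int(1e6, 1), id = "B")
    v <- randomInit(A, B, pm = 0.5)
    # a short random move sequence, accumulating deltas
    g <- objectiveFull(A, B, v)
    for (m in 1:10) {
      mv <- proposeMove(A, B, v)
      if (mv$jNew == v[mv$i]) next
      d <- objectiveDelta(A, B, v, mv$i, mv$jNew)
      v[mv$i] <- mv$jNew
      g <- g + d
      expect_identical(g, objectiveFull(A, B, v))
      checks <- checks + 1
    }
  }
  expect_gte(checks, 1000)
})

test_that("no-op reassignment has zero delta; unmapping the only match cancels the score", {
  A <- genRandomEntry(4, seed = 41, id = "A")
  v <- c(1L, 2L, 0L, 0L)
  expect_identical(objectiveDelta(A, A, v, 1, 1), 0L)
  g <- objectiveFull(A, A, v)
  expect_identical(objectiveDelta(A, A, v, 2, 0), -g)
})

test_that("random initialization follows the Bernoulli matching rule", {
  A <- genRandomEntry(10, seed = 51, strandFrac = 0.5, id = "A")
  B <- genRandomEntry(10, seed = 52, strandFrac = 0.5, id = "B")
  expect_identical(randomInit(A, B, pm = 0), integer(10))
  # identical type sequences: pm = 1 gives the identity mapping
  e <- genRandomEntry(6, seed = 53)
  expect_identical(randomInit(e, e, pm = 1), 1:6)
  # matched fraction of assignable SSEs is pm on average
  set.seed(99)
  matched <- 0; assignable <- 0
  for (r in 1:10000) {
    v <- randomInit(e, e, pm = 0.5)
    matched <- matched + sum(v != 0)
    assignable <- assignable + 6
  }
  expect_equal(matched / assignable, 0.5, tolerance = 0.04)
  # states are always sequential-valid
  set.seed(100)
  for (r in 1:50) {
    v <- randomInit(A, B, pm = 0.8)
    nz <- v[v != 0]
    if (length(nz) > 1) expect_true(all(diff(nz) > 0))
    expect_silent(validateMatchState(A, B, v, sequential = TRUE))
  }
})

test_that("proposed moves are uniform over the feasible set", {
  # all wrong class: always unmaps
  helices <- makeEntry("h", c("xa", "xa"),
                       matrix(c(NA, "PE", "PE", NA), 2, 2))
  strands <- makeEntry("s", c("e", "e"),
                       matrix(c(NA, "PE", "PE", NA), 2, 2))
  set.seed(7)
  for (r in 1:20) {
    mv <- proposeMove(helices, strands, c(0L, 0L))
    expect_identical(mv$jNew, 0L)
  }
  # single compatible SSE
  one <- makeEntry("one", "xa")
  mv <- proposeMove(one, one, 0L)
  expect_identical(c(mv$i, mv$jNew), c(1L, 1L))
  # frequency check on a 1-SSE query against 6 same-class entries
  A1 <- makeEntry("a1", "xa")
  B6 <- genRandomEntry(6, seed = 61, strandFrac = 0, id = "b6")
  set.seed(8)
  draws <- replicate(12000, proposeMove(A1, B6, 0L)$jNew)
  freq <- table(factor(draws, levels = 1:6)) / length(draws)
  p <- 1 / 6
  sigma <- sqrt(p * (1 - p) / length(draws))
  expect_true(all(abs(freq - p) < 3.5 * sigma))
  # the current assignment is excluded from the candidates
  set.seed(9)
  draws2 <- replicate(2000, proposeMove(A1, B6, 3L)$jNew)
  expect_false(any(draws2 == 3))
})

test_that("sequential proposals respect the ordering of other assignments", {
  e <- genRandomEntry(5, seed = 71, strandFrac = 0, id = "e")
  v <- c(0L, 2L, 0L, 4L, 0L)
  set.seed(10)
  for (r in 1:200) {
    mv <- proposeMove(e, e, v, sequential = TRUE)
    vNew <- v
    vNew[mv$i] <- mv$jNew
    expect_silent(validateMatchState(e, e, vNew, sequential = TRUE))
  }
})

test_that("a single annealing run is deterministic per restart stream and bounded by the oracle", {
  A <- genRandomEntry(5, seed = 81, id = "A")
  B <- genRandomEntry(5, seed = 82, id = "B")
  p <- SearchParams(seed = 4)
  r1 <- annealOnce(A, B, p, restart = 0)
  r2 <- annealOnce(A, B, p, restart = 0)
  expect_identical(r1, r2)
  bf <- bruteForceOptimum(A, B)
  expect_lte(r1$score, bf$score)
  # the returned best state actually achieves the returned score
  expect_identical(objectiveFull(A, B, r1$state), r1$score)
})

test_that("single-SSE self comparison scores zero (no pairs exist)", {
  one <- makeEntry("one", "xa")
  r <- searchPair(one, one, SearchParams(restarts = 8, seed = 1))
  expect_identical(r$rawScore, 0L)
  expect_true(all(r$state %in% c(0L, 1L)))
})

test_that("self-matches recover the identity mapping with score 2N(N-1)", {
  for (n in 3:7) {
    e <- genRandomEntry(n, seed = 90 + n)
    r <- searchPair(e, e, SearchParams(restarts = 512, sequential = TRUE,
                                       seed = n))
    expect_identical(r$rawScore, as.integer(2 * n * (n - 1)))
    expect_identical(r$state, seq_len(n))
    expect_equal(r$normScore, 2 * (n - 1))
  }
})

test_that("annealing attains the exhaustive optimum on small instances and never exceeds it", {
  hits <- 0
  for (k in 1:60) {
    nA <- sample(2:5, 1); nB <- sample(2:5, 1)
    A <- genRandomEntry(nA, seed = 5000 + k, id = sprintf("A%d", k))
    B <- genRandomEntry(nB, seed = 6000 + k, id = sprintf("B%d", k))
    bf <- bruteForceOptimum(A, B)
    sa <- searchPair(A, B, SearchParams(restarts = 512, seed = k))
    expect_lte(sa$rawScore, bf$score)
    if (sa$rawScore == bf$score) hits <- hits + 1
  }
  expect_gte(hits, 57)  # 95% bound on a 60-instance sample
})

test_that("searchPair is reproducible and monotone in the number of restarts", {
  A <- genRandomEntry(6, seed = 101, id = "A")
  B <- genRandomEntry(7, seed = 102, id = "B")
  p <- SearchParams(restarts = 64, seed = 11)
  expect_identical(searchPair(A, B, p), searchPair(A, B, p))
  scores <- vapply(c(1, 2, 4, 8, 16, 32), function(m) {
    searchPair(A, B, SearchParams(restarts = m, seed = 11))$rawScore
  }, integer(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("an exact substructure is found with the full motif score", {
  fx <- plantMotif(12, c(2, 4, 7, 9, 11), seed = 33)
  r <- searchPair(fx$motif, fx$host,
                  SearchParams(sequential = TRUE, restarts = 256,
                               seed = 2))
  expect_identical(r$rawScore, as.integer(2 * 5 * 4))
})

test_that("database search ranks the query itself first and is order- and worker-invariant", {
  db <- makeRandomDb(10, sizes = 3:6, seedBase = 300)
  query <- db[[4]]
  p <- SearchParams(restarts = 64, seed = 5)
  res <- searchDatabase(query, db, p)
  expect_equal(nrow(res), 10)
  expect_identical(res$db_id[1], entryId(query))
  # self-match achieves the maximal norm2 among equal-size entries
  expect_equal(res$norm_score[1], 2 * (length(query) - 1))
  # invariant to database presorting by size
  resSorted <- searchDatabase(query, sortBySize(db), p)
  expect_identical(res[, c("db_id", "raw_score", "norm_score")],
                   resSorted[, c("db_id", "raw_score", "norm_score")])
  expect_identical(res$state, resSorted$state)
  # invariant to the worker count
  res4 <- searchDatabase(query, db, p, workers = 4)
  expect_identical(res, res4)
})

test_that("searching an empty database returns an empty ranking", {
  q <- genRandomEntry(3, seed = 1)
  res <- searchDatabase(q, TableauDatabase())
  expect_equal(nrow(res), 0)
})

test_that("norm2 halves the raw score by the mean size", {
  expect_equal(norm2Score(12, 3, 3), 4)
  expect_equal(norm2Score(0, 5, 9), 0)
  expect_equal(norm2Score(10, 4, 6), 2)
  expect_error(norm2Score(1, 0, 3), "positive")
})
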