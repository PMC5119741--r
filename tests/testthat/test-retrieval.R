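# a deliberately small hand-built index for arithmetic checks:
# 3 represented clusters (sizes 4, 2, 2) + a pool of 2
handIndex <- function() {
  clusters <- list(`1` = c("a1", "a2", "a3", "a4"),
                   `2` = c("b1", "b2"),
                   `3` = c("c1", "c2"))
  new("ClusteredIndex", clusters = clusters,
      representatives = c(`1` = "a1", `2` = "b1", `3` = "c1"),
      singletonPool = c("s1", "s2"), overlapped = FALSE,
      sourceParams = list(method = "connected_components", psi = 95))
}

# scorer over an explicit named vector
fixedScorer <- function(scores) function(query, targets) scores[targets]

test_that("retrieve counts comparisons exactly as K + cluster size + M", {
  idx <- handIndex()
  scores <- c(a1 = 99, a2 = 98, a3 = 50, a4 = 96, b1 = 20, b2 = 10,
              c1 = 30, c2 = 5, s1 = 97, s2 = 1)
  r <- retrieve("q", fixedScorer(scores), idx, phi = 95)
  nc <- ncBreakdown(r)
  expect_equal(nc[["kComparisons"]], 3)
  expect_equal(nc[["clusterComparisons"]], 4)
  expect_equal(nc[["mComparisons"]], 2)
  expect_equal(nc[["total"]], 9)
  expect_equal(r@bestCluster, "1")
  # hits: scored members of the chosen cluster plus pool, >= phi, sorted
  expect_equal(hits(r)$target, c("a1", "a2", "s1", "a4"))
  expect_equal(hits(r)$score, c(99, 98, 97, 96))
})

test_that("stage-1 ties break toward the lowest cluster index", {
  idx <- handIndex()
  scores <- c(a1 = 50, a2 = 0, a3 = 0, a4 = 0, b1 = 50, b2 = 0,
              c1 = 20, c2 = 0, s1 = 0, s2 = 0)
  r <- retrieve("q", fixedScorer(scores), idx, phi = 95)
  expect_equal(r@bestCluster, "1")
})

test_that("retrieval on an overlapped index performs no singleton comparisons", {
  bench <- separatedBenchmark(seed = 303)
  idx <- overlapAssign(buildCrispIndex(
    clusterConnectedComponents(bench$S, 95), bench$S), bench$S)
  q <- makeQueryVector(bench$S, profileIds(bench$S)[1], noiseSd = 1, seed = 5)
  r <- retrieve(q, vectorQueryScorer(), idx, phi = 95)
  expect_equal(ncBreakdown(r)[["mComparisons"]], 0)
  expect_equal(ncBreakdown(r)[["total"]],
               length(representatives(idx)) +
                 length(clusterMembers(idx)[[r@bestCluster]]))
})

test_that("planted-block queries return exactly the brute-force filtered block", {
  bench <- separatedBenchmark(seed = 404)
  truthBlocks <- Filter(function(x) length(x) > 1,
                        clusterMembers(bench$truth))
  idx <- buildCrispIndex(clusterConnectedComponents(bench$S, 95), bench$S)
  src <- truthBlocks[[3]][1]
  q <- makeQueryVector(bench$S, src, noiseSd = 0.5, seed = 6)
  r <- retrieve(q, vectorQueryScorer(), idx, phi = 95)
  seqR <- sequentialSearch(q, vectorQueryScorer(), profileIds(bench$S), phi = 95)
  # brute-force oracle: threshold filter of the query vector
  oracle <- sort(names(q)[q >= 95])
  expect_setequal(hits(seqR)$target, oracle)
  expect_setequal(hits(r)$target, oracle)   # block is fully inside one cluster
  expect_true(all(oracle %in% truthBlocks[[3]]))
})

test_that("sequential search scores every profile and filters at phi", {
  one <- sequentialSearch("x", function(q, t) c(x = 100), "x", phi = 95)
  expect_equal(hits(one)$target, "x")
  expect_equal(ncBreakdown(one)[["total"]], 1)

  set.seed(61)
  ids <- sprintf("d%02d", 1:30)
  scores <- setNames(runif(30, 0, 100), ids)
  scorer <- fixedScorer(scores)
  r0 <- sequentialSearch("q", scorer, ids, phi = 0)
  expect_equal(nrow(hits(r0)), 30)               # no filtering
  r <- sequentialSearch("q", scorer, ids, phi = 80)
  expect_setequal(hits(r)$target, names(scores)[scores >= 80])
  expect_equal(ncBreakdown(r)[["total"]], 30)
})

test_that("retrieved hits are always a subset of sequential hits", {
  bench <- separatedBenchmark(seed = 505)
  for (overlap in c(FALSE, TRUE)) {
    idx <- buildCrispIndex(clusterConnectedComponents(bench$S, 95), bench$S)
    if (overlap) idx <- overlapAssign(idx, bench$S)
    queries <- makeQueryBatch(bench$S, 25, noiseSd = 2, seed = 19)
    for (i in seq_along(queries)) {
      r <- retrieve(queries[[i]], vectorQueryScorer(), idx, phi = 95)
      sq <- sequentialSearch(queries[[i]], vectorQueryScorer(),
                             profileIds(bench$S), phi = 95)
      expect_true(all(hits(r)$target %in% hits(sq)$target))
      # NC bound: at most N + K for a crisp index
      expect_lte(ncBreakdown(r)[["total"]],
                 length(profileIds(bench$S)) + length(representatives(idx)))
    }
  }
})

test_that("retrieve is deterministic and errors on an empty index", {
  bench <- separatedBenchmark(seed = 606)
  idx <- buildCrispIndex(clusterConnectedComponents(bench$S, 95), bench$S)
  q <- makeQueryVector(bench$S, profileIds(bench$S)[10], noiseSd = 1, seed = 3)
  r1 <- retrieve(q, vectorQueryScorer(), idx, phi = 95)
  r2 <- retrieve(q, vectorQueryScorer(), idx, phi = 95)
  expect_equal(hits(r1), hits(r2))
  expect_equal(ncBreakdown(r1), ncBreakdown(r2))

  empty <- new("ClusteredIndex", clusters = list(),
               representatives = character(), singletonPool = character(),
               overlapped = FALSE, sourceParams = list())
  expect_error(retrieve(q, vectorQueryScorer(), empty), "empty")
})

test_that("batchRetrieve preserves order, accumulates NC, and skips failures", {
  bench <- separatedBenchmark(seed = 707)
  idx <- overlapAssign(buildCrispIndex(
    clusterConnectedComponents(bench$S, 95), bench$S), bench$S)
  queries <- makeQueryBatch(bench$S, 10, noiseSd = 1, seed = 23)

  single <- retrieve(queries[[1]], vectorQueryScorer(), idx, phi = 95,
                     queryId = names(queries)[1])
  batch1 <- batchRetrieve(queries[1], vectorQueryScorer(), idx, phi = 95)
  expect_equal(hits(batch1[[1]]), hits(single))

  results <- batchRetrieve(queries, vectorQueryScorer(), idx, phi = 95)
  expect_equal(names(results), names(queries))
  # Eq.-4 accumulation with M = 0: sum NC == sum(K + |chosen cluster|)
  expected <- vapply(results, function(r)
    length(representatives(idx)) +
      length(clusterMembers(idx)[[r@bestCluster]]), 1)
  expect_equal(vapply(results, function(r) ncBreakdown(r)[["total"]], 1),
               expected)

  # a broken query is recorded, not fatal
  broken <- c(queries, list(bad = c(nope = 1)))
  res2 <- batchRetrieve(broken, vectorQueryScorer(), idx, phi = 95)
  expect_length(res2, length(queries))
  expect_match(attr(res2, "failures")[["bad"]], "lacks scores")
})
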