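test_that("connected components match the breadth-first-search oracle", {
  v <- matrix(c(100, 80, 15,
                80, 100, 20,
                15, 20, 100), 3, 3, byrow = TRUE)
  S <- tinySim(v)
  p <- clusterConnectedComponents(S, 50)
  expect_equal(canonClusters(clusterMembers(p)),
               list(c("a", "b"), "c"))

  for (seed in 1:5) {
    S <- randomSim(25, seed = seed)
    for (psi in c(20, 50, 80, 95)) {
      p <- clusterConnectedComponents(S, psi)
      expect_equal(canonClusters(clusterMembers(p)),
                   canonClusters(bfsComponents(scoreValues(S), psi)),
                   info = sprintf("seed %d psi %g", seed, psi))
    }
  }
})

test_that("connected components honor the threshold edge cases", {
  S <- randomSim(10, seed = 3, lo = 0, hi = 99)
  all1 <- clusterConnectedComponents(S, 0)
  expect_length(clusterMembers(all1), 1L)
  singl <- clusterConnectedComponents(S, 100)  # no off-diagonal 100s
  expect_length(clusterMembers(singl), 10L)
  expect_error(clusterConnectedComponents(S, 101), "psi")
})

test_that("raising psi only refines connected components", {
  isRefinement <- function(fine, coarse) {
    all(vapply(fine, function(f)
      any(vapply(coarse, function(co) all(f %in% co), TRUE)), TRUE))
  }
  for (seed in 1:4) {
    S <- randomSim(30, seed = 100 + seed)
    parts <- lapply(c(30, 60, 90), function(psi)
      clusterMembers(clusterConnectedComponents(S, psi)))
    expect_true(isRefinement(parts[[2]], parts[[1]]))
    expect_true(isRefinement(parts[[3]], parts[[2]]))
  }
})

test_that("single linkage matches the naive oracle on a zeta grid", {
  for (seed in 1:4) {
    S <- randomSim(sample(10:30, 1), seed = 200 + seed)
    for (zeta in c(0.5, 1, 2, 3, 4)) {
      p <- clusterSingleLinkage(S, zeta)
      expect_equal(canonClusters(clusterMembers(p)),
                   canonClusters(singleLinkOracle(scoreValues(S), zeta)),
                   info = sprintf("seed %d zeta %g", seed, zeta))
    }
  }
})

test_that("single linkage separates tight pairs and respects the root", {
  # two tight pairs: within-pair row distance well under the cut,
  # between-pair well over it
  v <- matrix(10, 4, 4)
  v[1, 2] <- v[2, 1] <- 99
  v[3, 4] <- v[4, 3] <- 99
  diag(v) <- 100
  S <- tinySim(v)
  p <- clusterSingleLinkage(S, 0.5)
  expect_equal(canonClusters(clusterMembers(p)),
               list(c("a", "b"), c("c", "d")))
  # zeta above the dendrogram root height: a single cluster
  root <- max(hclust(dist(scoreValues(S) / 100), "single")$height)
  pAll <- clusterSingleLinkage(S, root + 1)
  expect_length(clusterMembers(pAll), 1L)
  expect_error(clusterSingleLinkage(S, 0), "positive")
})

test_that("raising the distance cutoff only coarsens single linkage", {
  isRefinement <- function(fine, coarse) {
    all(vapply(fine, function(f)
      any(vapply(coarse, function(co) all(f %in% co), TRUE)), TRUE))
  }
  for (seed in 1:3) {
    S <- randomSim(20, seed = 300 + seed)
    fine <- clusterMembers(clusterSingleLinkage(S, 1))
    coarse <- clusterMembers(clusterSingleLinkage(S, 2.5))
    expect_true(isRefinement(fine, coarse))
  }
})

test_that("the inconsistency criterion cuts where links stand out", {
  # two tight pairs joined by one long link: the top link is inconsistent,
  # the within-pair links are not
  v <- matrix(10, 4, 4)
  v[1, 2] <- v[2, 1] <- 99
  v[3, 4] <- v[4, 3] <- 99
  diag(v) <- 100
  S <- tinySim(v)
  p <- clusterSingleLinkage(S, 1.1, criterion = "inconsistent")
  expect_equal(canonClusters(clusterMembers(p)),
               list(c("a", "b"), c("c", "d")))
  # a huge inconsistency cutoff severs nothing
  pAll <- clusterSingleLinkage(S, 100, criterion = "inconsistent")
  expect_length(clusterMembers(pAll), 1L)
})

test_that("kmeans recovers planted blocks and honors k edge cases", {
  gen <- plantedMatrix(tightSpec(nProfiles = 30, nBlocks = 2, seed = 8))
  S <- symmetrize(gen$raw)
  p <- clusterKmeans(S, 2, seed = 4)
  expect_equal(canonClusters(clusterMembers(p)),
               canonClusters(clusterMembers(gen$truth)))

  n <- length(profileIds(S))
  pN <- clusterKmeans(S, n, seed = 4)
  expect_length(clusterMembers(pN), n)
  p1 <- clusterKmeans(S, 1, seed = 4)
  expect_length(clusterMembers(p1), 1L)
  expect_error(clusterKmeans(S, n + 1), "k must lie")
})

test_that("kmeans is deterministic under a fixed seed and its WSS trace never rises", {
  S <- randomSim(40, seed = 17)
  a <- clusterKmeans(S, 5, seed = 99)
  b <- clusterKmeans(S, 5, seed = 99)
  expect_identical(clusterMembers(a), clusterMembers(b))
  trace <- a@params$wssTrace
  expect_true(all(diff(trace) <= 1e-10))
})

test_that("kmeans agrees with the reference implementation on separated data", {
  gen <- plantedMatrix(tightSpec(nProfiles = 40, nBlocks = 4, seed = 12))
  S <- symmetrize(gen$raw)
  ours <- clusterKmeans(S, 4, seed = 2)
  set.seed(2)
  ref <- stats::kmeans(scoreValues(S) / 100, centers = 4, nstart = 5)
  refClusters <- split(profileIds(S), ref$cluster)
  expect_equal(canonClusters(clusterMembers(ours)),
               canonClusters(refClusters))
})

test_that("all backends are invariant under simultaneous permutation", {
  S <- randomSim(20, seed = 55)
  set.seed(56)
  perm <- sample(20)
  v <- scoreValues(S)
  Sp <- SimilarityMatrix(v[perm, perm])
  expect_equal(canonClusters(clusterMembers(clusterConnectedComponents(S, 70))),
               canonClusters(clusterMembers(clusterConnectedComponents(Sp, 70))))
  expect_equal(canonClusters(clusterMembers(clusterSingleLinkage(S, 2))),
               canonClusters(clusterMembers(clusterSingleLinkage(Sp, 2))))
  # k-means sees permuted feature columns; only the well-separated case is
  # permutation-stable
  gen <- plantedMatrix(tightSpec(nProfiles = 30, nBlocks = 3, seed = 9))
  St <- symmetrize(gen$raw)
  vt <- scoreValues(St)
  permT <- sample(nrow(vt))
  expect_equal(canonClusters(clusterMembers(clusterKmeans(St, 3, seed = 1))),
               canonClusters(clusterMembers(
                 clusterKmeans(SimilarityMatrix(vt[permT, permT]), 3, seed = 1))))
})

test_that("partitionStats counts sizes exactly", {
  p <- new("Partition",
           clusters = list("a", c("b", "c"), c("d", "e", "f")),
           method = "connected_components", params = list(psi = 95))
  st <- partitionStats(p)
  expect_equal(st$nClusters, 3L)
  expect_equal(st$nSingletons, 1L)
  expect_equal(st$nNonSingleton, 2L)
  expect_equal(st$maxSize, 3L)
  expect_equal(st$histogram, c(`1` = 1L, `2` = 1L, `3` = 1L))
  expect_equal(st$nClusters, st$nSingletons + st$nNonSingleton)
  expect_equal(sum(st$histogram), st$nClusters)

  allSingle <- new("Partition", clusters = as.list(letters[1:6]),
                   method = "connected_components", params = list(psi = 100))
  expect_equal(partitionStats(allSingle)$nSingletons, 6L)
})

test_that("partition JSON round trip preserves structure", {
  S <- randomSim(12, seed = 77)
  p <- clusterConnectedComponents(S, 60)
  path <- withr::local_tempfile(fileext = ".json")
  savePartition(p, path)
  p2 <- loadPartition(path)
  expect_equal(clusterMembers(p2), clusterMembers(p))
  expect_equal(p2@method, p@method)
})
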