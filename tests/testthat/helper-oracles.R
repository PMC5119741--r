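# Independent oracles and tiny fixtures, deliberately naive implementations
# that never share code with the package internals.

tinySim <- function(values, ids = NULL) {
  if (is.null(ids)) ids <- letters[seq_len(nrow(values))]
  dimnames(values) <- list(ids, ids)
  SimilarityMatrix(values)
}

# random symmetric similarity matrix with 100 diagonal
randomSim <- function(n, seed, lo = 0, hi = 100) {
  set.seed(seed)
  v <- matrix(runif(n * n, lo, hi), n, n)
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  diag(v) <- 100
  tinySim(v, sprintf("R%03d", seq_len(n)))
}

# breadth-first search over the thresholded score graph
bfsComponents <- function(values, psi) {
  n <- nrow(values)
  adj <- values >= psi
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  split(rownames(values), comp)
}

# single-linkage cut at height h == connected components of the graph whose
# edges are point pairs at Euclidean distance <= h (rows of S/100)
singleLinkOracle <- function(values, zeta) {
  X <- values / 100
  d <- as.matrix(dist(X))
  adj <- (d <= zeta) * 100  # reuse the BFS over a 0/100 "score" graph
  diag(adj) <- 100
  dimnames(adj) <- dimnames(values)
  bfsComponents(adj, psi = 50)
}

# Eq.-1-style representative by literal double loop
bruteRepresentative <- function(cluster, values) {
  cluster <- sort(cluster)
  best <- cluster[1]; bestSum <- -Inf
  for (i in cluster) {
    s <- 0
    for (j in cluster) s <- s + values[i, j]
    if (s > bestSum) { bestSum <- s; best <- i }
  }
  best
}

# canonical form of a clustering for set comparison up to label order
canonClusters <- function(clusters) {
  cl <- lapply(clusters, function(x) sort(as.character(x)))
  unname(cl[order(vapply(cl, `[`, "", 1L))])
}

# separated planted spec whose row geometry is also tight, so all three
# clustering backends recover the blocks
tightSpec <- function(nProfiles = 96L, nBlocks = 6L, singletonFraction = 0,
                      seed = 42L) {
  plantedSpec(nProfiles = nProfiles, nBlocks = nBlocks,
              withinRange = c(97, 99), betweenRange = c(10, 12),
              asymmetryJitter = 0.5, singletonFraction = singletonFraction,
              seed = seed)
}

separatedBenchmark <- function(seed = 1337L, singletonFraction = 0.1) {
  spec <- plantedSpec(seed = seed, singletonFraction = singletonFraction)
  gen <- plantedMatrix(spec)
  list(spec = spec, truth = gen$truth, S = symmetrize(gen$raw))
}
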