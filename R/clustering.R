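# Clustering backends. All three treat the similarity matrix as the data:
# connected components works on the score graph directly; single-linkage and
# k-means treat the rows of S/100 as N-dimensional feature vectors.

.newPartition <- function(memberList, method, params) {
  memberList <- lapply(memberList, function(x) sort(as.character(x)))
  ord <- order(vapply(memberList, `[`, "", 1L))
  new("Partition", clusters = unname(memberList[ord]),
      method = method, params = params)
}

#' @describeIn profileIds all member ids of a partition
#' @export
setMethod("profileIds", "Partition", function(x)
  sort(unlist(x@clusters, use.names = FALSE)))

#' @describeIn clusterMembers clusters of a crisp partition
#' @export
setMethod("clusterMembers", "Partition", function(x) x@clusters)

setMethod("show", "Partition", function(object) {
  sizes <- vapply(object@clusters, length, 1L)
  cat(sprintf("Partition (%s): %d profiles in %d clusters (%d singletons, max size %d)\n",
              object@method, sum(sizes), length(sizes),
              sum(sizes == 1L), max(sizes)))
  cat("  params:", paste(names(object@params), unlist(object@params),
                         sep = "=", collapse = ", "), "\n")
})

#' Connected-components clustering of the similarity graph
#'
#' Profiles are vertices of an undirected graph; an edge joins two profiles
#' whose similarity is at least `psi`. Clusters are the connected components
#' of that graph.
#'
#' @param S a [SimilarityMatrix-class].
#' @param psi edge-weight threshold on the 0-100 scale; edges with weight
#'   below `psi` are removed.
#' @return a [Partition-class] with method "connected_components".
#' @export
clusterConnectedComponents <- function(S, psi) {
  stopifnot(is(S, "SimilarityMatrix"))
  if (psi < 0 || psi > 100) stop("psi must lie in [0, 100]")
  v <- scoreValues(S)
  adj <- (v >= psi)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  members <- split(rownames(v), comp$membership)
  .newPartition(members, "connected_components", list(psi = psi))
}

#' Single-linkage hierarchical clustering of matrix rows
#'
#' Rows of S/100 are taken as N-dimensional feature vectors; pairwise
#' Euclidean distances feed agglomerative single-linkage clustering, and the
#' dendrogram is cut at `zeta`. With `criterion = "distance"` the cut is at
#' merge height zeta; with `criterion = "inconsistent"` links whose
#' inconsistency coefficient (computed over the link and its descendants to
#' `depth` levels) reaches zeta are severed, as in classic numerical-computing
#' toolboxes.
#'
#' @param S a [SimilarityMatrix-class].
#' @param zeta positive cutoff.
#' @param criterion "distance" (default) or "inconsistent".
#' @param depth subtree depth for the inconsistency coefficient (default 2).
#' @return a [Partition-class] with method "single_linkage".
#' @export
clusterSingleLinkage <- function(S, zeta, criterion = c("distance", "inconsistent"),
                                 depth = 2L) {
  stopifnot(is(S, "SimilarityMatrix"))
  criterion <- match.arg(criterion)
  if (zeta <= 0) stop("zeta must be positive")
  v <- scoreValues(S) / 100
  ids <- rownames(v)
  if (length(ids) == 1L)
    return(.newPartition(list(ids), "single_linkage",
                         list(zeta = zeta, criterion = criterion)))
  hc <- stats::hclust(stats::dist(v), method = "single")
  assign <- if (criterion == "distance") {
    stats::cutree(hc, h = zeta)
  } else {
    .cutInconsistent(hc, zeta, depth)
  }
  members <- split(ids, assign[ids])
  .newPartition(members, "single_linkage",
                list(zeta = zeta, criterion = criterion))
}

# Inconsistency coefficient of each merge: (height - mean)/sd over the
# heights of the link and its descendant links down to `depth` levels
# (sd with n-1 denominator; coefficient 0 when sd is 0). A link is severed
# when its coefficient >= zeta; clusters are the leaf groups connected by
# surviving links.
.cutInconsistent <- function(hc, zeta, depth = 2L) {
  m <- hc$merge; h <- hc$height
  nLinks <- nrow(m)
  # heights of links within `depth` levels below (and including) link k
  subHeights <- function(k, d) {
    hs <- h[k]
    if (d > 1L) {
      for (child in m[k, ]) {
        if (child > 0) hs <- c(hs, subHeights(child, d - 1L))
      }
    }
    hs
  }
  coef <- vapply(seq_len(nLinks), function(k) {
    hs <- subHeights(k, depth)
    s <- stats::sd(hs)
    if (length(hs) < 2L || s == 0) 0 else (h[k] - mean(hs)) / s
  }, 1)
  keep <- coef < zeta
  # union-find over leaves joined by surviving merges; a merge joins its
  # children only if it is kept and both child merges were kept transitively
  n <- nLinks + 1L
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  repLeaf <- integer(nLinks)  # one leaf inside each link's subtree
  linkOk <- logical(nLinks)
  for (k in seq_len(nLinks)) {
    children <- m[k, ]
    leaves <- ifelse(children < 0, -children, repLeaf[pmax(children, 1L)])
    childOk <- ifelse(children < 0, TRUE, linkOk[pmax(children, 1L)])
    linkOk[k] <- keep[k] && all(childOk)
    if (linkOk[k]) {
      a <- find(leaves[1]); b <- find(leaves[2])
      parent[a] <- b
    }
    repLeaf[k] <- leaves[1]
  }
  roots <- vapply(seq_len(n), find, 1L)
  assign <- match(roots, unique(roots))
  names(assign) <- hc$labels
  assign
}

#' k-means clustering of matrix rows
#'
#' Rows of S/100 are the samples. Initial centroids are spread by the
#' k-means++ careful-seeding heuristic; Lloyd iterations (squared Euclidean
#' assignment, centroid means) run to convergence (maximum centroid movement
#' below `tol`) or `maxIter` iterations. Assignment ties break toward the
#' lowest centroid index; clusters that end empty are dropped from the
#' returned partition.
#'
#' @param S a [SimilarityMatrix-class].
#' @param k number of clusters, 1 <= k <= N.
#' @param seed integer RNG seed for the careful seeding.
#' @param nRestarts number of seeded restarts; the run with the lowest
#'   within-cluster sum of squares wins (default 1).
#' @param tol convergence tolerance on centroid movement (default 1e-6).
#' @param maxIter iteration cap (default 300).
#' @return a [Partition-class] with method "kmeans"; the within-cluster
#'   sum-of-squares trace of the winning run is available as
#'   `params$wssTrace`.
#' @export
clusterKmeans <- function(S, k, seed = 1L, nRestarts = 1L,
                          tol = 1e-6, maxIter = 300L) {
  stopifnot(is(S, "SimilarityMatrix"))
  X <- scoreValues(S) / 100
  n <- nrow(X)
  if (k < 1 || k > n) stop(sprintf("k must lie in [1, %d], got %g", n, k))
  best <- NULL
  for (r in seq_len(nRestarts)) {
    run <- withSeed(seed + r - 1L, .lloyd(X, k, tol, maxIter))
    if (is.null(best) || run$wss < best$wss) best <- run
  }
  members <- split(rownames(X), best$assign)
  members <- members[vapply(members, length, 1L) > 0L]
  .newPartition(members, "kmeans",
                list(k = k, seed = seed, nRestarts = nRestarts,
                     wssTrace = best$trace))
}

# squared Euclidean distances from every row of X to every center row
.sqDistToCenters <- function(X, centers) {
  outer(rowSums(X^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(X)), rowSums(centers^2)) - 2 * X %*% t(centers)
}

.lloyd <- function(X, k, tol, maxIter) {
  n <- nrow(X)
  # k-means++ careful seeding
  centers <- X[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- pmax(0, apply(.sqDistToCenters(X, centers), 1, min))
    idx <- if (sum(d2) == 0) sample.int(n, 1L)
           else sample.int(n, 1L, prob = d2)
    centers <- rbind(centers, X[idx, , drop = FALSE])
  }
  assign <- rep(1L, n)
  trace <- numeric(0)
  for (iter in seq_len(maxIter)) {
    d2 <- .sqDistToCenters(X, centers)
    assign <- max.col(-d2, ties.method = "first")  # ties -> lowest index
    trace <- c(trace, sum(d2[cbind(seq_len(n), assign)]))
    newCenters <- centers
    for (j in seq_len(k)) {
      rows <- which(assign == j)
      if (length(rows) > 0L)
        newCenters[j, ] <- colMeans(X[rows, , drop = FALSE])
      # empty cluster: centroid kept in place, dropped at the end if it
      # never reacquires members
    }
    moved <- max(sqrt(rowSums((newCenters - centers)^2)))
    centers <- newCenters
    if (moved < tol) break
  }
  d2 <- .sqDistToCenters(X, centers)
  assign <- max.col(-d2, ties.method = "first")
  wss <- sum(pmax(0, d2[cbind(seq_len(n), assign)]))
  list(assign = assign, wss = wss, trace = trace)
}

#' Cluster-distribution statistics of a partition
#'
#' Reports the counts the method's tuning protocol monitors: total clusters,
#' singleton clusters, non-singleton clusters, largest cluster size, and the
#' full size histogram (cluster size -> frequency).
#'
#' @param p a [Partition-class] (or a [ClusteredIndex-class], whose
#'   represented clusters plus singleton-pool members are counted).
#' @return a list with elements nClusters, nSingletons, nNonSingleton,
#'   maxSize and histogram (named integer vector).
#' @export
partitionStats <- function(p) {
  sizes <- if (is(p, "ClusteredIndex")) {
    c(vapply(p@clusters, length, 1L), rep(1L, length(p@singletonPool)))
  } else {
    vapply(clusterMembers(p), length, 1L)
  }
  tab <- table(sizes)
  hist <- as.integer(tab)
  names(hist) <- names(tab)
  list(nClusters = length(sizes),
       nSingletons = sum(sizes == 1L),
       nNonSingleton = sum(sizes >= 2L),
       maxSize = max(sizes),
       histogram = hist)
}

#' Serialize a partition to JSON
#' @param p a [Partition-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
savePartition <- function(p, path) {
  jsonlite::write_json(
    list(method = p@method,
         params = p@params[setdiff(names(p@params), "wssTrace")],
         clusters = clusterMembers(p)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a partition from JSON written by [savePartition()]
#' @param path input path.
#' @return a [Partition-class].
#' @export
loadPartition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  clusters <- if (is.list(x$clusters)) x$clusters else list(x$clusters)
  .newPartition(clusters, x$method, as.list(x$params))
}
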