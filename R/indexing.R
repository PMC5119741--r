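# Representative selection and index assembly.
#
# Each non-singleton cluster gets the member with the maximum within-cluster
# similarity sum (a medoid-like choice). Singleton clusters receive no
# representative: their sole members form the pool of M profiles scanned
# exhaustively at query time. The overlap step then re-assigns every profile
# to each cluster whose representative scores it at or above the mean of its
# scores against all K representatives, which guarantees at least one
# membership per profile and hence M = 0.

#' Select a cluster's representative by maximum similarity sum
#'
#' For each member i, f(i) is the sum of the within-cluster similarity
#' submatrix row S'(i, j) over members j; the representative is argmax f,
#' with ties broken toward the lexicographically smallest id.
#'
#' @param cluster character vector of member ids (non-empty).
#' @param S a [SimilarityMatrix-class] containing all members.
#' @return the representative's id.
#' @examples
#' v <- matrix(c(100, 90, 50, 90, 100, 60, 50, 60, 100), 3, 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' selectRepresentative(c("a", "b", "c"), SimilarityMatrix(v))
#' @export
selectRepresentative <- function(cluster, S) {
  stopifnot(is(S, "SimilarityMatrix"), length(cluster) >= 1L)
  missing <- setdiff(cluster, profileIds(S))
  if (length(missing) > 0L)
    stop("cluster member(s) missing from similarity matrix: ",
         paste(missing, collapse = ", "))
  cluster <- sort(as.character(cluster))  # lexicographic tie-break
  sub <- scoreValues(S)[cluster, cluster, drop = FALSE]
  sums <- rowSums(sub)
  cluster[which.max(sums)]
}

#' Build a crisp clustered index from a partition
#'
#' Representatives are assigned to every cluster of size >= 2; singleton
#' clusters contribute their members to the singleton pool, which sequential
#' search covers at query time.
#'
#' @param p a [Partition-class] over the matrix's ids.
#' @param S the [SimilarityMatrix-class] the partition was built from.
#' @return a [ClusteredIndex-class] with `overlapped = FALSE`.
#' @export
buildCrispIndex <- function(p, S) {
  stopifnot(is(p, "Partition"), is(S, "SimilarityMatrix"))
  if (!setequal(profileIds(p), profileIds(S)))
    stop("partition and similarity matrix cover different profile sets")
  members <- clusterMembers(p)
  sizes <- vapply(members, length, 1L)
  big <- members[sizes >= 2L]
  pool <- unlist(members[sizes == 1L], use.names = FALSE)
  if (is.null(pool)) pool <- character()
  reps <- vapply(big, selectRepresentative, "", S = S)
  names(big) <- as.character(seq_along(big))
  names(reps) <- names(big)
  new("ClusteredIndex", clusters = big, representatives = reps,
      singletonPool = sort(pool), overlapped = FALSE,
      sourceParams = c(list(method = p@method),
                       p@params[setdiff(names(p@params), "wssTrace")]))
}

#' @describeIn clusterMembers represented clusters of an index
#' @export
setMethod("clusterMembers", "ClusteredIndex", function(x) x@clusters)

#' @describeIn representatives representative ids of an index
#' @export
setMethod("representatives", "ClusteredIndex", function(x) x@representatives)

#' @describeIn singletonPool singleton-pool ids of an index
#' @export
setMethod("singletonPool", "ClusteredIndex", function(x) x@singletonPool)

#' @describeIn isOverlapped overlap flag of an index
#' @export
setMethod("isOverlapped", "ClusteredIndex", function(x) x@overlapped)

#' @describeIn profileIds all ids covered by an index
#' @export
setMethod("profileIds", "ClusteredIndex", function(x)
  sort(unique(c(unlist(x@clusters, use.names = FALSE), x@singletonPool))))

setMethod("show", "ClusteredIndex", function(object) {
  cat(sprintf("ClusteredIndex: K = %d represented clusters, M = %d singletons, %s\n",
              length(object@clusters), length(object@singletonPool),
              if (object@overlapped) "overlapped" else "crisp"))
  cat("  source:", paste(names(object@sourceParams),
                         vapply(object@sourceParams, function(x)
                           paste(format(x), collapse = "/"), ""),
                         sep = "=", collapse = ", "), "\n")
})

#' Cluster memberships of one profile under the self-regulated threshold
#'
#' Given a profile's scores against the K representatives, the threshold is
#' their mean; the profile joins every cluster whose representative scores
#' it at or above that mean. Because the maximum of a finite score vector is
#' never below its mean, at least one cluster always qualifies. This is also
#' how a newly added profile can be placed without re-clustering.
#'
#' @param repScores numeric vector of length K: score(representative_i,
#'   profile), in representative (cluster) order.
#' @return integer vector of qualifying cluster indices.
#' @export
overlapMemberships <- function(repScores) {
  if (length(repScores) < 1L) stop("need at least one representative score")
  which(repScores >= mean(repScores))
}

#' Overlap re-assignment of a crisp index
#'
#' Every database profile j is scored against all K representatives; its
#' self-regulated threshold is the mean of those K scores, and it is added
#' to every cluster whose representative meets the threshold. Crisp members
#' of represented clusters are retained (the step only adds memberships),
#' former singleton clusters are dissolved, and the singleton pool empties:
#' M = 0 is guaranteed. Representatives are unchanged.
#'
#' @param index a crisp [ClusteredIndex-class] with K >= 1.
#' @param S the [SimilarityMatrix-class] (representative-vs-profile scores
#'   are read from its symmetric entries).
#' @return the overlapped [ClusteredIndex-class].
#' @export
overlapAssign <- function(index, S) {
  stopifnot(is(index, "ClusteredIndex"), is(S, "SimilarityMatrix"))
  if (index@overlapped) stop("index is already overlapped")
  K <- length(index@clusters)
  if (K == 0L)
    stop("no represented clusters: overlap is undefined, use sequential search")
  v <- scoreValues(S)
  reps <- index@representatives
  allIds <- profileIds(index)
  repScores <- v[reps, allIds, drop = FALSE]  # K x N
  clusters <- index@clusters
  for (j in allIds) {
    for (ci in overlapMemberships(repScores[, j])) {
      clusters[[ci]] <- union(clusters[[ci]], j)
    }
  }
  clusters <- lapply(clusters, sort)
  new("ClusteredIndex", clusters = clusters, representatives = reps,
      singletonPool = character(), overlapped = TRUE,
      sourceParams = index@sourceParams)
}

#' Serialize a clustered index to JSON
#'
#' The index is loadable for retrieval without the similarity matrix.
#'
#' @param index a [ClusteredIndex-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
saveIndex <- function(index, path) {
  jsonlite::write_json(
    list(sourceParams = index@sourceParams,
         overlapped = index@overlapped,
         representatives = as.list(index@representatives),
         clusters = index@clusters,
         singletonPool = index@singletonPool),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a clustered index written by [saveIndex()]
#' @param path input path.
#' @return a [ClusteredIndex-class].
#' @export
loadIndex <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  clusters <- lapply(x$clusters, as.character)
  reps <- unlist(x$representatives)
  new("ClusteredIndex", clusters = clusters,
      representatives = reps[names(clusters)],
      singletonPool = as.character(x$singletonPool %||% character()),
      overlapped = isTRUE(x$overlapped),
      sourceParams = as.list(x$sourceParams))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
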