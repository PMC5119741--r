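#' @import methods
NULL

# Scores live on the 0-100 profile-profile "probability" scale throughout;
# thresholds phi and psi are on the same scale. Symmetry tolerance for
# validity checks is 1e-9 on that scale.
.SYM_TOL <- 1e-9

#' ProfileDB: an ordered collection of profile identifiers
#'
#' A lightweight container for a profile-HMM database. Profiles are opaque:
#' the package never parses model files, it only needs stable, unique
#' identifiers (which define matrix row/column order) and, optionally,
#' per-profile payloads that a user-supplied pairwise scorer can consume.
#'
#' @slot ids character vector of unique profile identifiers; their order is
#'   the canonical matrix row/column order.
#' @slot payloads optional named list of opaque per-profile data for scorers.
#' @export
setClass("ProfileDB",
  representation(ids = "character", payloads = "list"),
  prototype(ids = character(), payloads = list())
)

setValidity("ProfileDB", function(object) {
  if (length(object@ids) < 1L) return("database must contain at least one profile")
  if (anyDuplicated(object@ids)) return("profile ids must be unique")
  if (length(object@payloads) > 0L &&
      !all(names(object@payloads) %in% object@ids))
    return("payload names must be profile ids")
  TRUE
})

#' RawScoreMatrix: asymmetric all-against-all scores
#'
#' Holds the direct output of an all-against-all comparison: entry (i, j) is
#' the score of profile i as query against profile j as target, on the 0-100
#' scale. Profile-profile scores are length-dependent, so the matrix is not
#' symmetric in general; the diagonal is forced to 100 (self-homology is
#' certain by definition).
#'
#' @slot values numeric N x N matrix with profile ids as dimnames.
#' @export
setClass("RawScoreMatrix", representation(values = "matrix"))

.validateScoreValues <- function(values, symmetric = FALSE) {
  if (!is.numeric(values)) return("scores must be numeric")
  if (nrow(values) != ncol(values)) return("score matrix must be square")
  ids <- rownames(values)
  if (is.null(ids) || is.null(colnames(values)))
    return("score matrix must carry profile ids as dimnames")
  if (!identical(ids, colnames(values)))
    return("row and column ids must agree")
  if (anyDuplicated(ids)) return("profile ids must be unique")
  if (anyNA(values)) return("scores must not contain NA")
  if (min(values) < 0 || max(values) > 100)
    return("scores must lie in [0, 100]")
  if (any(abs(diag(values) - 100) > .SYM_TOL))
    return("diagonal self-scores must equal 100")
  if (symmetric && max(abs(values - t(values))) > .SYM_TOL)
    return(sprintf("matrix is not symmetric (max |S - t(S)| = %g)",
                   max(abs(values - t(values)))))
  TRUE
}

setValidity("RawScoreMatrix", function(object) {
  .validateScoreValues(object@values, symmetric = FALSE)
})

#' SimilarityMatrix: max-symmetrized all-against-all similarity
#'
#' The central data object: a symmetric N x N matrix of 0-100 similarity
#' scores where each off-diagonal entry is the maximum of the two raw
#' orientations it was built from, and the diagonal is 100.
#'
#' @slot values symmetric numeric matrix with profile ids as dimnames.
#' @export
setClass("SimilarityMatrix", representation(values = "matrix"))

setValidity("SimilarityMatrix", function(object) {
  .validateScoreValues(object@values, symmetric = TRUE)
})

#' Partition: a crisp clustering of the profile database
#'
#' @slot clusters list of non-empty, disjoint character vectors of profile
#'   ids, jointly covering the id set; ordered by smallest member id.
#' @slot method one of "single_linkage", "kmeans", "connected_components".
#' @slot params named list with the method's parameter values (zeta cutoff
#'   and criterion; k and seed; psi threshold).
#' @export
setClass("Partition",
  representation(clusters = "list", method = "character", params = "list")
)

setValidity("Partition", function(object) {
  cl <- object@clusters
  if (length(cl) == 0L) return("partition must contain at least one cluster")
  if (any(vapply(cl, length, 1L) == 0L)) return("empty clusters are not allowed")
  members <- unlist(cl, use.names = FALSE)
  if (anyDuplicated(members)) return("clusters must be disjoint")
  if (!object@method %in% c("single_linkage", "kmeans", "connected_components"))
    return("unknown clustering method tag")
  firsts <- vapply(cl, function(x) min(x), "")
  if (is.unsorted(firsts)) return("clusters must be ordered by smallest member id")
  TRUE
})

#' ClusteredIndex: clusters, representatives and the singleton pool
#'
#' The searchable form of the database. Non-singleton clusters each carry a
#' representative (the member maximizing the within-cluster similarity sum);
#' singleton clusters' members form the pool of M profiles scanned
#' exhaustively at query time. After overlap re-assignment the pool is empty
#' (M = 0) and clusters may share members.
#'
#' @slot clusters named list (cluster index -> character vector of member
#'   ids); overlapping membership allowed when `overlapped`.
#' @slot representatives named character vector, cluster index -> member id.
#' @slot singletonPool character vector of ids in no represented cluster.
#' @slot overlapped logical flag.
#' @slot sourceParams list describing the originating clustering run.
#' @export
setClass("ClusteredIndex",
  representation(clusters = "list", representatives = "character",
                 singletonPool = "character", overlapped = "logical",
                 sourceParams = "list")
)

setValidity("ClusteredIndex", function(object) {
  K <- length(object@clusters)
  if (length(object@representatives) != K)
    return("every represented cluster needs exactly one representative")
  if (K > 0L) {
    if (!identical(names(object@clusters), names(object@representatives)))
      return("cluster and representative names must agree")
    inOwn <- mapply(function(rep, members) rep %in% members,
                    object@representatives, object@clusters)
    if (!all(inOwn)) return("each representative must be a member of its cluster")
    if (any(vapply(object@clusters, length, 1L) == 0L))
      return("represented clusters must be non-empty")
  }
  if (object@overlapped && length(object@singletonPool) > 0L)
    return("an overlapped index must have an empty singleton pool (M = 0)")
  if (length(intersect(object@singletonPool,
                       unlist(object@clusters, use.names = FALSE))) > 0L)
    return("singleton pool must be disjoint from represented clusters")
  TRUE
})

#' QueryResult: one query's hits and exact comparison accounting
#'
#' @slot queryId character identifier for the query.
#' @slot hits data.frame with columns `target` and `score`, sorted by
#'   descending score, ties by id; only scores >= phi are reported.
#' @slot bestCluster character, the chosen cluster index (NA for sequential
#'   search or an index with no represented clusters).
#' @slot nc named numeric with elements kComparisons, clusterComparisons,
#'   mComparisons, total; total is their sum.
#' @slot phi numeric match threshold used.
#' @slot elapsed numeric wall-clock seconds spent scoring.
#' @export
setClass("QueryResult",
  representation(queryId = "character", hits = "data.frame",
                 bestCluster = "character", nc = "numeric",
                 phi = "numeric", elapsed = "numeric")
)

setValidity("QueryResult", function(object) {
  need <- c("kComparisons", "clusterComparisons", "mComparisons", "total")
  if (!all(need %in% names(object@nc)))
    return("nc must carry kComparisons, clusterComparisons, mComparisons, total")
  nc <- object@nc
  if (abs(nc[["total"]] -
          (nc[["kComparisons"]] + nc[["clusterComparisons"]] + nc[["mComparisons"]])) > 0)
    return("nc total must equal the sum of its parts")
  if (!all(c("target", "score") %in% names(object@hits)))
    return("hits must have target and score columns")
  if (nrow(object@hits) > 0L) {
    if (any(object@hits$score < object@phi))
      return("all reported hits must score at least phi")
    if (is.unsorted(rev(object@hits$score)))
      return("hits must be sorted by descending score")
  }
  TRUE
})

#' EvalReport: batch recall and time/comparison reduction
#'
#' @slot perQueryRecall numeric vector in \[0, 1\], one entry per query.
#' @slot batchRecall total-matches ratio in \[0, 1\].
#' @slot rtWallclock reduction in wall-clock time, 1 - sum(alpha)/sum(alpha').
#' @slot rtComparisons reduction in comparisons, 1 - sum(NC)/sum(NC_seq).
#' @slot nQueries number of queries T.
#' @export
setClass("EvalReport",
  representation(perQueryRecall = "numeric", batchRecall = "numeric",
                 rtWallclock = "numeric", rtComparisons = "numeric",
                 nQueries = "integer")
)

setValidity("EvalReport", function(object) {
  if (length(object@batchRecall) != 1L ||
      object@batchRecall < 0 || object@batchRecall > 1)
    return("batch recall must be a single value in [0, 1]")
  if (any(object@perQueryRecall < 0 | object@perQueryRecall > 1))
    return("per-query recall values must lie in [0, 1]")
  if (object@rtComparisons > 1) return("comparison reduction cannot exceed 1")
  TRUE
})
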