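#' Profile identifiers of an object
#' @param x a ProfileDB, RawScoreMatrix, SimilarityMatrix, Partition or
#'   ClusteredIndex.
#' @return character vector of profile ids.
#' @export
setGeneric("profileIds", function(x) standardGeneric("profileIds"))

#' Numeric score matrix of a score-matrix object
#' @param x a RawScoreMatrix or SimilarityMatrix.
#' @return the numeric matrix with ids as dimnames.
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' Cluster membership lists
#' @param x a Partition or ClusteredIndex.
#' @return list of character vectors of member ids.
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' Representatives of a clustered index
#' @param x a ClusteredIndex.
#' @return named character vector, cluster index -> representative id.
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' Singleton pool of a clustered index
#' @param x a ClusteredIndex.
#' @return character vector of the M profiles scanned exhaustively.
#' @export
setGeneric("singletonPool", function(x) standardGeneric("singletonPool"))

#' Whether an index has been overlap-assigned
#' @param x a ClusteredIndex.
#' @return logical.
#' @export
setGeneric("isOverlapped", function(x) standardGeneric("isOverlapped"))

#' Hits of a query result
#' @param x a QueryResult.
#' @return data.frame with target and score columns.
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))

#' Comparison-count breakdown of a query result
#' @param x a QueryResult.
#' @return named numeric: kComparisons, clusterComparisons, mComparisons, total.
#' @export
setGeneric("ncBreakdown", function(x) standardGeneric("ncBreakdown"))
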