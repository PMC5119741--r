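# Recall and reduction-in-time evaluation against the sequential baseline.
#
# Because the staged search only ever scores a subset of the database, its
# hit set is a subset of the sequential hit set under the same scorer and
# phi; precision is therefore trivially 1 and only recall is measured.

#' Per-query recall
#'
#' |baseline ∩ proposed| / |baseline|. When the baseline is empty there are
#' no relevant matches to miss and recall is defined as 1.
#'
#' @param proposed character vector (or [QueryResult-class]) of proposed
#'   hit targets.
#' @param baseline character vector (or [QueryResult-class]) of sequential
#'   hit targets, computed with the identical scorer and phi.
#' @return a ratio in \[0, 1\].
#' @export
recallSingle <- function(proposed, baseline) {
  proposed <- .hitTargets(proposed)
  baseline <- .hitTargets(baseline)
  if (length(baseline) == 0L) return(1.0)
  length(intersect(baseline, proposed)) / length(baseline)
}

.hitTargets <- function(x) {
  if (is(x, "QueryResult")) hits(x)$target else as.character(x)
}

#' Batch recall
#'
#' Total proposed matches over total baseline matches, summed across the
#' aligned query lists. Valid as an intersection ratio because every
#' proposed hit set is a subset of its baseline; a subset violation is
#' diagnosed as an error since it indicates an inconsistent scorer.
#'
#' @param proposedSets list of proposed hit-target vectors (or QueryResults).
#' @param baselineSets list of baseline hit-target vectors, pairwise aligned.
#' @return a ratio in \[0, 1\] (1 when the baseline total is zero).
#' @export
recallBatch <- function(proposedSets, baselineSets) {
  if (length(proposedSets) != length(baselineSets))
    stop("proposed and baseline lists must have equal length")
  proposedSets <- lapply(proposedSets, .hitTargets)
  baselineSets <- lapply(baselineSets, .hitTargets)
  for (i in seq_along(proposedSets)) {
    extra <- setdiff(proposedSets[[i]], baselineSets[[i]])
    if (length(extra) > 0L)
      stop(sprintf(paste0("query %d: proposed hits not in the sequential ",
                          "baseline (%s) - scorer inconsistency?"),
                   i, paste(utils::head(extra, 3L), collapse = ", ")))
  }
  denom <- sum(lengths(baselineSets))
  if (denom == 0L) return(1.0)
  sum(lengths(proposedSets)) / denom
}

#' Reduction in time
#'
#' 1 - sum(alpha) / sum(alpha'), where alpha are per-query times under the
#' clustered search and alpha' under sequential search.
#'
#' @param alphas positive per-query times, clustered search.
#' @param alphaPrimes positive per-query times, sequential search (aligned).
#' @return the reduction ratio (1 means free, 0 means no gain, negative
#'   means overhead).
#' @export
reductionInTime <- function(alphas, alphaPrimes) {
  if (length(alphas) != length(alphaPrimes))
    stop("time vectors must have equal length")
  denom <- sum(alphaPrimes)
  if (denom <= 0) stop("baseline total time must be positive")
  1 - sum(alphas) / denom
}

#' Comparison-count reduction
#'
#' Hardware-independent analogue of the reduction in time: one minus the
#' ratio of total comparisons performed by the clustered search to the
#' t * N comparisons sequential search would perform for t queries.
#'
#' @param ncTotals per-query NC totals (clustered search).
#' @param nDb database size N.
#' @param t number of queries; defaults to length(ncTotals).
#' @return the reduction ratio.
#' @export
comparisonReduction <- function(ncTotals, nDb, t = length(ncTotals)) {
  if (t < 1L || nDb < 1L) stop("need at least one query and one profile")
  1 - sum(ncTotals) / (t * nDb)
}

#' Evaluate a batch of clustered retrievals against sequential baselines
#'
#' @param proposed list of [QueryResult-class] from [batchRetrieve()] /
#'   [retrieve()].
#' @param baseline aligned list of [QueryResult-class] from
#'   [sequentialSearch()].
#' @param nDb database size N (defaults to the baseline NC total, which is
#'   N for sequential results).
#' @return an [EvalReport-class].
#' @export
evaluateRetrieval <- function(proposed, baseline,
                              nDb = ncBreakdown(baseline[[1]])[["total"]]) {
  if (length(proposed) != length(baseline))
    stop("proposed and baseline lists must have equal length")
  perQuery <- mapply(recallSingle, proposed, baseline)
  batch <- recallBatch(proposed, baseline)
  alphas <- vapply(proposed, function(r) r@elapsed, 1)
  alphaPrimes <- vapply(baseline, function(r) r@elapsed, 1)
  rtWall <- if (sum(alphaPrimes) > 0) reductionInTime(alphas, alphaPrimes)
            else NA_real_
  ncs <- vapply(proposed, function(r) ncBreakdown(r)[["total"]], 1)
  new("EvalReport", perQueryRecall = unname(perQuery), batchRecall = batch,
      rtWallclock = rtWall,
      rtComparisons = comparisonReduction(ncs, nDb),
      nQueries = length(proposed))
}

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport over T = %d queries\n", object@nQueries))
  cat(sprintf("  batch recall:          %.4f\n", object@batchRecall))
  cat(sprintf("  mean per-query recall: %.4f\n", mean(object@perQueryRecall)))
  cat(sprintf("  comparison reduction:  %.4f\n", object@rtComparisons))
  if (!is.na(object@rtWallclock))
    cat(sprintf("  wall-clock reduction:  %.4f (informational)\n",
                object@rtWallclock))
})

#' Serialize an evaluation report to JSON
#' @param report an [EvalReport-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
saveEvalReport <- function(report, path) {
  jsonlite::write_json(
    list(nQueries = report@nQueries,
         batchRecall = report@batchRecall,
         meanPerQueryRecall = mean(report@perQueryRecall),
         rtComparisons = report@rtComparisons,
         rtWallclock = report@rtWallclock,
         perQueryRecall = report@perQueryRecall),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
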