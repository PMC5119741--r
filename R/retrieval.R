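# Staged retrieval with exact comparison-count accounting.
#
# A query is scored against the K cluster representatives first; the best
# representative's cluster is then searched in full, and finally the
# singleton pool is scanned. Total comparisons per query:
#   NC = K + size(best cluster) + M,
# which the result reports exactly, stage by stage. Sequential search over
# all N profiles is the recall and cost baseline.

.makeQueryResult <- function(queryId, scored, phi, kComp, clComp, mComp,
                             bestCluster, elapsed) {
  scored <- scored[!duplicated(names(scored))]  # keep max: pre-sorted below
  keep <- scored >= phi
  df <- data.frame(target = names(scored)[keep], score = unname(scored[keep]),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$target), , drop = FALSE]
  rownames(df) <- NULL
  nc <- c(kComparisons = kComp, clusterComparisons = clComp,
          mComparisons = mComp, total = kComp + clComp + mComp)
  new("QueryResult", queryId = as.character(queryId), hits = df,
      bestCluster = as.character(bestCluster), nc = nc,
      phi = phi, elapsed = elapsed)
}

#' @describeIn hits hit table of a query result
#' @export
setMethod("hits", "QueryResult", function(x) x@hits)

#' @describeIn ncBreakdown comparison counts of a query result
#' @export
setMethod("ncBreakdown", "QueryResult", function(x) x@nc)

setMethod("show", "QueryResult", function(object) {
  cat(sprintf("QueryResult '%s': %d hits (phi = %g), NC = %d (K %d + cluster %d + M %d)\n",
              object@queryId, nrow(object@hits), object@phi,
              object@nc[["total"]], object@nc[["kComparisons"]],
              object@nc[["clusterComparisons"]], object@nc[["mComparisons"]]))
})

#' Staged retrieval against a clustered index
#'
#' Stage 1 scores the query against all K representatives and picks the best
#' match (ties toward the lowest cluster index). Stage 2 scores the query
#' against every member of that cluster; stage 3 against every singleton-pool
#' profile. Hits are the stage-2 and stage-3 targets scoring at least `phi`,
#' deduplicated by target keeping the maximum score; representatives are
#' reported only through their cluster membership.
#'
#' @param query a query object the scorer understands: an id for
#'   [matrixQueryScorer()], or a named score vector for
#'   [vectorQueryScorer()].
#' @param scorer function(query, targets) -> named numeric scores in
#'   \[0, 100\]; each call performs length(targets) comparisons.
#' @param index a [ClusteredIndex-class].
#' @param phi match threshold on the 0-100 scale; scores >= phi are
#'   homologous matches. Default 95, the near-certain homology level.
#' @param queryId identifier recorded in the result (defaults to the query
#'   itself when it is a single string).
#' @return a [QueryResult-class].
#' @export
retrieve <- function(query, scorer, index, phi = 95,
                     queryId = if (is.character(query) && length(query) == 1L)
                       query else "query") {
  stopifnot(is(index, "ClusteredIndex"))
  K <- length(index@clusters)
  pool <- index@singletonPool
  if (K == 0L && length(pool) == 0L)
    stop("index is empty: no represented clusters and no singleton pool")
  t0 <- proc.time()[["elapsed"]]
  clComp <- 0L
  best <- NA_character_
  clusterScores <- numeric(0)
  if (K > 0L) {
    reps <- index@representatives
    repScores <- scorer(query, unname(reps))
    names(repScores) <- names(reps)  # by cluster index
    best <- names(repScores)[which.max(repScores)]  # ties -> lowest index
    members <- index@clusters[[best]]
    clusterScores <- scorer(query, members)
    names(clusterScores) <- members
    clComp <- length(members)
  }
  poolScores <- numeric(0)
  if (length(pool) > 0L) {
    poolScores <- scorer(query, pool)
    names(poolScores) <- pool
  }
  scored <- c(clusterScores, poolScores)
  scored <- sort(scored, decreasing = TRUE)  # so dedup keeps the max
  .makeQueryResult(queryId, scored, phi,
                   kComp = K, clComp = clComp, mComp = length(pool),
                   bestCluster = best,
                   elapsed = proc.time()[["elapsed"]] - t0)
}

#' Exhaustive sequential search baseline
#'
#' Scores the query against all N database profiles; NC = N.
#'
#' @param query query object (see [retrieve()]).
#' @param scorer function(query, targets) -> named numeric scores.
#' @param db a [ProfileDB-class], [SimilarityMatrix-class], or character
#'   vector of target ids.
#' @param phi match threshold (default 95).
#' @param queryId identifier recorded in the result.
#' @return a [QueryResult-class] with `bestCluster` NA and all comparisons
#'   counted as cluster comparisons' baseline (kComparisons = 0,
#'   mComparisons = 0, total = N).
#' @export
sequentialSearch <- function(query, scorer, db, phi = 95,
                             queryId = if (is.character(query) && length(query) == 1L)
                               query else "query") {
  ids <- if (is.character(db)) db
         else if (is(db, "ProfileDB")) profileIds(db)
         else profileIds(db)
  if (length(ids) == 0L) stop("database is empty")
  t0 <- proc.time()[["elapsed"]]
  scored <- scorer(query, ids)
  names(scored) <- ids
  scored <- sort(scored, decreasing = TRUE)
  .makeQueryResult(queryId, scored, phi,
                   kComp = 0L, clComp = length(ids), mComp = 0L,
                   bestCluster = NA_character_,
                   elapsed = proc.time()[["elapsed"]] - t0)
}

#' Batch retrieval
#'
#' Runs [retrieve()] for each query in input order. Individual query
#' failures are recorded and skipped rather than aborting the batch; failed
#' queries are reported in the "failures" attribute of the result list.
#'
#' @param queries list of query objects (named list names become query ids).
#' @param scorer,index,phi as in [retrieve()].
#' @return list of [QueryResult-class] in input order (failures omitted),
#'   with attribute "failures": a named character vector of error messages.
#' @export
batchRetrieve <- function(queries, scorer, index, phi = 95) {
  if (length(queries) == 0L) stop("need at least one query")
  qids <- names(queries)
  if (is.null(qids)) qids <- paste0("q", seq_along(queries))
  results <- list()
  failures <- character()
  for (i in seq_along(queries)) {
    r <- tryCatch(
      retrieve(queries[[i]], scorer, index, phi, queryId = qids[i]),
      error = function(e) e)
    if (inherits(r, "error")) failures[qids[i]] <- conditionMessage(r)
    else results[[qids[i]]] <- r
  }
  attr(results, "failures") <- failures
  results
}

#' Write batch hits as TSV
#'
#' One row per hit: query_id, target_id, score, rank.
#'
#' @param results list of [QueryResult-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
saveHits <- function(results, path) {
  rows <- lapply(results, function(r) {
    h <- hits(r)
    if (nrow(h) == 0L) return(NULL)
    data.frame(query_id = r@queryId, target_id = h$target,
               score = h$score, rank = seq_len(nrow(h)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(query_id = character(), target_id = character(),
                      score = numeric(), rank = integer())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
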