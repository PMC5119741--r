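# Pipeline convenience and the parameter-sweep protocol: one clustering run
# per parameter value, each evaluated end-to-end against the sequential
# baseline on the same query batch.

#' Cluster a similarity matrix with a chosen backend
#'
#' Thin dispatcher over [clusterSingleLinkage()], [clusterKmeans()] and
#' [clusterConnectedComponents()]. Defaults follow the tuned operating point
#' for a curated-family corpus: k = 160, zeta = 0.9, psi = 95.
#'
#' @param S a [SimilarityMatrix-class].
#' @param method one of "single_linkage", "kmeans", "connected_components".
#' @param param the method's parameter (zeta, k, or psi); if NULL, the
#'   method's tuned default is used.
#' @param seed RNG seed (k-means only).
#' @param criterion dendrogram cut criterion (single-linkage only).
#' @return a [Partition-class].
#' @export
clusterMatrix <- function(S, method = c("single_linkage", "kmeans",
                                        "connected_components"),
                          param = NULL, seed = 1L,
                          criterion = "distance") {
  method <- match.arg(method)
  switch(method,
    single_linkage = clusterSingleLinkage(S, param %||% 0.9,
                                          criterion = criterion),
    kmeans = clusterKmeans(S, param %||% 160L, seed = seed),
    connected_components = clusterConnectedComponents(S, param %||% 95))
}

#' Run the full clustered-retrieval pipeline on one matrix
#'
#' Clusters, builds the crisp index, optionally overlap-assigns, retrieves
#' the query batch, and evaluates against the sequential baseline.
#'
#' @param S a [SimilarityMatrix-class].
#' @param queries named list of query vectors (see [makeQueryBatch()]).
#' @param method,param,seed,criterion as in [clusterMatrix()].
#' @param overlap apply the overlap re-assignment (default TRUE).
#' @param phi match threshold (default 95).
#' @return list with elements partition, index, results, baseline, report.
#' @export
runPipeline <- function(S, queries, method, param = NULL, seed = 1L,
                        criterion = "distance", overlap = TRUE, phi = 95) {
  p <- clusterMatrix(S, method, param, seed = seed, criterion = criterion)
  index <- buildCrispIndex(p, S)
  if (overlap && length(representatives(index)) > 0L)
    index <- overlapAssign(index, S)
  scorer <- vectorQueryScorer()
  results <- batchRetrieve(queries, scorer, index, phi)
  baseline <- lapply(seq_along(queries), function(i)
    sequentialSearch(queries[[i]], scorer, profileIds(S), phi,
                     queryId = names(queries)[i]))
  report <- evaluateRetrieval(results, baseline, nDb = length(profileIds(S)))
  list(partition = p, index = index, results = results,
       baseline = baseline, report = report)
}

#' Sweep a clustering parameter and evaluate each setting
#'
#' Reproduces the tuning protocol: for each parameter value, cluster, index
#' (with or without overlap), retrieve the batch, and record the partition's
#' distribution statistics alongside batch recall and comparison reduction.
#'
#' @param S a [SimilarityMatrix-class].
#' @param queries named list of query vectors.
#' @param method clustering backend (see [clusterMatrix()]).
#' @param values vector of parameter values to sweep.
#' @param overlap apply overlap re-assignment per setting (default TRUE).
#' @param phi match threshold (default 95).
#' @param seed RNG seed for k-means.
#' @param criterion single-linkage cut criterion.
#' @return data.frame, one row per parameter value: param, nClusters,
#'   nSingletons, nNonSingleton, maxSize, K, M, batchRecall,
#'   comparisonReduction.
#' @export
parameterSweep <- function(S, queries, method, values, overlap = TRUE,
                           phi = 95, seed = 1L, criterion = "distance") {
  rows <- lapply(values, function(val) {
    run <- runPipeline(S, queries, method, param = val, seed = seed,
                       criterion = criterion, overlap = overlap, phi = phi)
    st <- partitionStats(run$partition)
    data.frame(param = val,
               nClusters = st$nClusters,
               nSingletons = st$nSingletons,
               nNonSingleton = st$nNonSingleton,
               maxSize = st$maxSize,
               K = length(representatives(run$index)),
               M = length(singletonPool(run$index)),
               batchRecall = run$report@batchRecall,
               comparisonReduction = run$report@rtComparisons)
  })
  do.call(rbind, rows)
}
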