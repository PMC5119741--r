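# Evaluate `code` under a temporary RNG state so package functions never
# disturb the caller's random stream.
withSeed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Construct a profile database
#'
#' @param ids character vector of unique profile identifiers; their order
#'   defines the row/column order of every matrix built from this database.
#' @param payloads optional named list of opaque per-profile data consumed by
#'   a pairwise scorer (e.g. numeric signature vectors for the toy dot-product
#'   scorer, or file paths for an external-tool adapter).
#' @return a [ProfileDB-class] object.
#' @examples
#' db <- ProfileDB(c("TIGR00001", "TIGR00002"))
#' profileIds(db)
#' @export
ProfileDB <- function(ids, payloads = list()) {
  new("ProfileDB", ids = as.character(ids), payloads = payloads)
}

.asScoreMatrix <- function(values, ids = NULL) {
  values <- as.matrix(values)
  if (!is.null(ids)) dimnames(values) <- list(ids, ids)
  storage.mode(values) <- "double"
  values
}

#' Construct a raw (possibly asymmetric) score matrix
#'
#' The diagonal is forced to 100 even if the supplied scores disagree
#' (self-homology is certain by definition); a warning reports any
#' disagreement.
#'
#' @param values square numeric matrix of 0-100 scores.
#' @param ids profile identifiers; defaults to the matrix dimnames.
#' @return a [RawScoreMatrix-class].
#' @export
RawScoreMatrix <- function(values, ids = NULL) {
  values <- .asScoreMatrix(values, ids)
  values <- .forceDiagonal(values)
  new("RawScoreMatrix", values = values)
}

.forceDiagonal <- function(values) {
  d <- diag(values)
  off <- abs(d - 100) > .SYM_TOL
  if (any(off)) {
    warning(sprintf("%d diagonal self-score(s) differed from 100 and were reset",
                    sum(off)))
    diag(values) <- 100
  }
  values
}

#' Construct a symmetric similarity matrix
#'
#' @param values square numeric matrix of 0-100 scores. Must already be
#'   symmetric unless `symmetrizeOnLoad` is TRUE, in which case each entry
#'   pair is replaced by its maximum.
#' @param ids profile identifiers; defaults to the matrix dimnames.
#' @param symmetrizeOnLoad symmetrize asymmetric input instead of erroring.
#' @return a [SimilarityMatrix-class].
#' @export
SimilarityMatrix <- function(values, ids = NULL, symmetrizeOnLoad = FALSE) {
  values <- .asScoreMatrix(values, ids)
  values <- .forceDiagonal(values)
  if (symmetrizeOnLoad) values <- pmax(values, t(values))
  new("SimilarityMatrix", values = values)
}

#' @describeIn profileIds ids of a profile database
#' @export
setMethod("profileIds", "ProfileDB", function(x) x@ids)
#' @describeIn profileIds row/column ids of a raw score matrix
#' @export
setMethod("profileIds", "RawScoreMatrix", function(x) rownames(x@values))
#' @describeIn profileIds row/column ids of a similarity matrix
#' @export
setMethod("profileIds", "SimilarityMatrix", function(x) rownames(x@values))

#' @describeIn scoreValues raw scores
#' @export
setMethod("scoreValues", "RawScoreMatrix", function(x) x@values)
#' @describeIn scoreValues symmetrized scores
#' @export
setMethod("scoreValues", "SimilarityMatrix", function(x) x@values)

setMethod("show", "ProfileDB", function(object) {
  cat(sprintf("ProfileDB with %d profiles\n", length(object@ids)))
  cat("  ids:", paste(utils::head(object@ids, 5L), collapse = ", "),
      if (length(object@ids) > 5L) "..." else "", "\n")
})

.showScoreMatrix <- function(object, label) {
  v <- scoreValues(object)
  cat(sprintf("%s: %d x %d profiles, scores in [%.4g, %.4g]\n",
              label, nrow(v), ncol(v), min(v), max(v)))
}
setMethod("show", "RawScoreMatrix", function(object)
  .showScoreMatrix(object, "RawScoreMatrix (asymmetric)"))
setMethod("show", "SimilarityMatrix", function(object)
  .showScoreMatrix(object, "SimilarityMatrix (max-symmetrized)"))

#' Build the all-against-all raw score matrix
#'
#' Compares each profile against every profile in the database with the
#' supplied pairwise scorer, producing the asymmetric N x N score matrix.
#' The scorer is the package's abstraction of a profile-profile comparison
#' tool's 0-100 probability score; an adapter that shells out to such a tool
#' can stand behind the same contract.
#'
#' @param db a [ProfileDB-class].
#' @param scorer function(idA, idB, payloadA, payloadB) returning a single
#'   score in \[0, 100\]; must be deterministic, with self-score 100.
#' @return a [RawScoreMatrix-class]; entry (i, j) is scorer(profile i as
#'   query, profile j as target), diagonal forced to 100.
#' @export
buildRawMatrix <- function(db, scorer) {
  stopifnot(is(db, "ProfileDB"), is.function(scorer))
  ids <- profileIds(db)
  n <- length(ids)
  values <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- scorer(ids[i], ids[j],
                  db@payloads[[ids[i]]], db@payloads[[ids[j]]])
      if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s > 100)
        stop(sprintf("scorer returned an invalid score for pair (%s, %s): %s",
                     ids[i], ids[j], paste(format(s), collapse = ",")))
      values[i, j] <- s
    }
  }
  RawScoreMatrix(values)
}

#' Max-symmetrize a raw score matrix
#'
#' Profile-profile scores depend on which profile is the query, so the raw
#' matrix is asymmetric; only the maximum of the two orientations is kept.
#'
#' @param raw a [RawScoreMatrix-class] (or a square numeric matrix).
#' @return a [SimilarityMatrix-class] with out\[i, j\] = max(raw\[i, j\],
#'   raw\[j, i\]).
#' @examples
#' raw <- RawScoreMatrix(matrix(c(100, 70, 80, 100), 2, 2,
#'                              dimnames = list(c("a", "b"), c("a", "b"))))
#' scoreValues(symmetrize(raw))
#' @export
symmetrize <- function(raw) {
  values <- if (is(raw, "RawScoreMatrix")) scoreValues(raw) else .asScoreMatrix(raw)
  if (nrow(values) != ncol(values)) stop("raw score matrix must be square")
  new("SimilarityMatrix", values = pmax(values, t(values)))
}

#' Write a similarity or raw score matrix as tab-separated text
#'
#' Format: first row and first column carry profile ids, cells use 6
#' significant digits. This is also the format [loadMatrix()] reads back.
#'
#' @param m a [SimilarityMatrix-class] or [RawScoreMatrix-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
saveMatrix <- function(m, path) {
  v <- scoreValues(m)
  out <- cbind(id = rownames(v), format(v, digits = 6, trim = TRUE,
                                        scientific = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix from delimited text
#'
#' Accepts two dialects: (a) the package's own format with an id header row
#' and id first column; (b) a headerless square numeric dump with the id
#' list in a sidecar file (one id per line), as supplementary matrix dumps
#' are often distributed.
#'
#' @param path matrix file path.
#' @param idsPath optional sidecar id-list path for the headerless dialect;
#'   if the dump has no sidecar either, ids default to "P1"..."PN".
#' @param symmetrizeOnLoad if TRUE, an asymmetric stored matrix is
#'   max-symmetrized; if FALSE (default) asymmetry beyond 1e-9 is an error.
#' @return a [SimilarityMatrix-class].
#' @export
loadMatrix <- function(path, idsPath = NULL, symmetrizeOnLoad = FALSE) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  first <- readLines(path, n = 1L)
  headerless <- !is.na(suppressWarnings(
    as.numeric(strsplit(first, "[\t ,;]+")[[1]][1])))
  if (headerless) {
    values <- as.matrix(utils::read.table(path, header = FALSE))
    ids <- if (!is.null(idsPath)) readLines(idsPath)
           else paste0("P", seq_len(nrow(values)))
    if (length(ids) != nrow(values))
      stop(sprintf("sidecar lists %d ids but matrix has %d rows",
                   length(ids), nrow(values)))
    dimnames(values) <- list(ids, ids)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = NA)
    ids <- as.character(tab[[1]])
    values <- as.matrix(tab[, -1, drop = FALSE])
    if (anyDuplicated(ids))
      stop("duplicate profile ids in matrix file: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (!identical(colnames(values), ids))
      stop("header ids and first-column ids disagree")
    rownames(values) <- ids
  }
  if (nrow(values) != ncol(values))
    stop(sprintf("matrix is not square: %d x %d", nrow(values), ncol(values)))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell at row %d, column %d",
                 bad[1, 1], bad[1, 2]))
  SimilarityMatrix(values, symmetrizeOnLoad = symmetrizeOnLoad)
}

#' Pairwise scorer over numeric signature payloads
#'
#' A toy deterministic [buildRawMatrix()] scorer for synthetic databases
#' whose payloads are numeric vectors: the score is 100 times the cosine
#' similarity of the two signatures, damped by a length-ratio factor so that
#' the two orientations differ (as real profile-profile scores do, being
#' query-length dependent).
#'
#' @return a scorer function suitable for [buildRawMatrix()].
#' @export
dotProductScorer <- function() {
  function(idA, idB, payloadA, payloadB) {
    a <- as.numeric(payloadA); b <- as.numeric(payloadB)
    n <- min(length(a), length(b))
    cosine <- sum(a[1:n] * b[1:n]) /
      (sqrt(sum(a[1:n]^2)) * sqrt(sum(b[1:n]^2)) + 1e-12)
    lenFactor <- min(length(a), length(b)) / length(a)  # query-length dependent
    max(0, min(100, 100 * abs(cosine) * lenFactor))
  }
}

#' Query scorer backed by a similarity matrix (leave-one-in mode)
#'
#' Returns a scorer for [retrieve()] / [sequentialSearch()] where the query
#' is an id present in the matrix: scores are read from the query's row.
#'
#' @param m a [SimilarityMatrix-class].
#' @return function(query, targets) -> named numeric score vector.
#' @export
matrixQueryScorer <- function(m) {
  values <- scoreValues(m)
  function(query, targets) {
    if (!query %in% rownames(values)) stop("unknown query id: ", query)
    values[query, targets]
  }
}

#' Query scorer over precomputed score vectors
#'
#' Returns a scorer where the query object itself is a named numeric vector
#' of scores over database ids (e.g. produced by [makeQueryVector()] or
#' loaded from an external tool's output).
#'
#' @return function(query, targets) -> named numeric score vector.
#' @export
vectorQueryScorer <- function() {
  function(query, targets) {
    missing <- setdiff(targets, names(query))
    if (length(missing) > 0L)
      stop("query vector lacks scores for: ",
           paste(utils::head(missing, 3L), collapse = ", "))
    query[targets]
  }
}
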