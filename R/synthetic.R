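# Seeded planted-partition generators.
#
# The generators emulate, at desk scale, the structure of an all-against-all
# profile-profile similarity matrix over a curated family database:
# within-family scores are high, between-family scores low, raw scores are
# asymmetric (query-length dependence), and a fraction of profiles belong to
# no family ("unattached" singletons). Score distributions are uniform on
# configurable ranges - the simplest structure satisfying the clustering
# method's assumptions.

#' Specification of a planted-partition benchmark
#'
#' Defaults describe the package's desk-scale benchmark: 200 profiles in 12
#' balanced blocks with 10% unattached singletons, well-separated scores
#' (within-block 96-100, between-block 0-60 on the 0-100 scale), and a small
#' asymmetry jitter so raw matrices are genuinely asymmetric.
#'
#' @param nProfiles total number of profiles N.
#' @param nBlocks number of planted blocks (families).
#' @param blockSizes optional explicit block sizes; by default the
#'   non-singleton profiles are split as evenly as possible.
#' @param withinRange,betweenRange numeric \[lo, hi\] score ranges on the
#'   0-100 scale; a "separated" spec has withinRange\[1\] > betweenRange\[2\].
#' @param asymmetryJitter maximum absolute perturbation applied
#'   independently to each raw orientation (0 gives a symmetric raw matrix).
#' @param singletonFraction fraction of profiles planted as unattached.
#' @param seed integer RNG seed.
#' @return a list of class "plantedSpec".
#' @export
plantedSpec <- function(nProfiles = 200L, nBlocks = 12L, blockSizes = NULL,
                        withinRange = c(96, 100), betweenRange = c(0, 60),
                        asymmetryJitter = 1, singletonFraction = 0.1,
                        seed = 1337L) {
  nSingle <- round(nProfiles * singletonFraction)
  if (is.null(blockSizes)) {
    nBlocked <- nProfiles - nSingle
    base <- nBlocked %/% nBlocks
    blockSizes <- rep(base, nBlocks)
    extra <- nBlocked - base * nBlocks
    if (extra > 0L) blockSizes[seq_len(extra)] <- base + 1L
  } else {
    nSingle <- nProfiles - sum(blockSizes)
  }
  spec <- list(nProfiles = nProfiles, nBlocks = length(blockSizes),
               blockSizes = blockSizes, withinRange = withinRange,
               betweenRange = betweenRange,
               asymmetryJitter = asymmetryJitter,
               nSingletons = nSingle, seed = seed)
  if (nSingle < 0 || sum(blockSizes) + nSingle != nProfiles)
    stop("block sizes plus singletons must sum to nProfiles")
  if (any(blockSizes < 2L))
    stop("planted blocks must have at least 2 members")
  if (diff(withinRange) < 0 || diff(betweenRange) < 0 ||
      min(withinRange, betweenRange) < 0 || max(withinRange, betweenRange) > 100)
    stop("score ranges must be ordered sub-intervals of [0, 100]")
  class(spec) <- "plantedSpec"
  spec
}

#' Generate a planted-partition raw score matrix
#'
#' Off-diagonal raw scores are drawn uniformly from the within range for
#' co-blocked pairs and the between range otherwise (planted singletons
#' score in the between range against everyone); each orientation is then
#' perturbed independently by up to `asymmetryJitter` and clipped to
#' \[0, 100\]. The diagonal is 100. Deterministic under the spec's seed.
#'
#' @param spec a [plantedSpec()].
#' @return list with elements `raw` (a [RawScoreMatrix-class]) and `truth`
#'   (the planted [Partition-class], method "connected_components", each
#'   singleton its own cluster).
#' @export
plantedMatrix <- function(spec) {
  stopifnot(inherits(spec, "plantedSpec"))
  n <- spec$nProfiles
  ids <- sprintf("SYN%04d", seq_len(n))
  block <- rep(0L, n)  # 0 = unattached singleton
  block[seq_len(sum(spec$blockSizes))] <-
    rep(seq_along(spec$blockSizes), spec$blockSizes)
  withSeed(spec$seed, {
    sameBlock <- outer(block, block, `==`) & block > 0
    base <- matrix(stats::runif(n * n, spec$betweenRange[1],
                                spec$betweenRange[2]), n, n)
    # co-blocked pairs share one base value per unordered pair (symmetric
    # before jitter)
    base[upper.tri(base)] <- t(base)[upper.tri(base)]
    w <- matrix(stats::runif(n * n, spec$withinRange[1],
                             spec$withinRange[2]), n, n)
    w[upper.tri(w)] <- t(w)[upper.tri(w)]
    values <- ifelse(sameBlock, w, base)
    if (spec$asymmetryJitter > 0) {
      jit <- matrix(stats::runif(n * n, -spec$asymmetryJitter,
                                 spec$asymmetryJitter), n, n)
      values <- values + jit
    }
    values <- matrix(pmin(100, pmax(0, values)), n, n)
    diag(values) <- 100
    dimnames(values) <- list(ids, ids)
  })
  memberList <- c(split(ids[block > 0], block[block > 0]),
                  as.list(ids[block == 0]))
  truth <- .newPartition(memberList, "connected_components",
                         list(planted = TRUE, seed = spec$seed))
  list(raw = new("RawScoreMatrix", values = values), truth = truth)
}

#' Generate a noisy query score vector from a database profile
#'
#' Emulates an external query resembling one database family: the source
#' profile's similarity row perturbed by seeded Gaussian noise and clipped
#' to \[0, 100\]. With zero noise the vector equals the source row.
#'
#' @param m a [SimilarityMatrix-class].
#' @param sourceId the database profile the query resembles.
#' @param noiseSd Gaussian noise standard deviation on the 0-100 scale.
#' @param seed integer RNG seed.
#' @return named numeric score vector over all database ids, usable with
#'   [vectorQueryScorer()].
#' @export
makeQueryVector <- function(m, sourceId, noiseSd = 1, seed = 1L) {
  stopifnot(is(m, "SimilarityMatrix"))
  v <- scoreValues(m)
  if (!sourceId %in% rownames(v)) stop("unknown source id: ", sourceId)
  row <- v[sourceId, ]
  if (noiseSd > 0) {
    row <- withSeed(seed, row + stats::rnorm(length(row), 0, noiseSd))
    row <- stats::setNames(pmin(100, pmax(0, row)), names(v[sourceId, ]))
    row[sourceId] <- 100  # the query is most similar to its own source
  }
  row
}

#' Generate a seeded batch of query vectors
#'
#' Draws `nQueries` source profiles (with replacement when the database is
#' smaller) and produces one noisy query vector per draw.
#'
#' @param m a [SimilarityMatrix-class].
#' @param nQueries number of queries.
#' @param noiseSd Gaussian noise standard deviation.
#' @param seed integer RNG seed.
#' @param sourceIds optional pool of source profiles to draw from (default:
#'   all database ids).
#' @return named list of query vectors; names record the source id with a
#'   running suffix.
#' @export
makeQueryBatch <- function(m, nQueries, noiseSd = 1, seed = 1L,
                           sourceIds = profileIds(m)) {
  sources <- withSeed(seed,
    sample(sourceIds, nQueries, replace = nQueries > length(sourceIds)))
  queries <- lapply(seq_len(nQueries), function(i)
    makeQueryVector(m, sources[i], noiseSd, seed = seed + i))
  names(queries) <- sprintf("%s_q%03d", sources, seq_len(nQueries))
  queries
}
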