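---
title: "Cluster-based retrieval from profile-HMM databases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-based retrieval from profile-HMM databases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phmmindex)
```

## The problem

Searching a database of N profile hidden Markov models for homologs of a
query costs N profile–profile comparisons: every query is aligned against
every database profile. Each comparison is expensive (a full
profile–profile alignment), so batch querying against growing family
databases is dominated by this sequential scan. `phmmindex` reduces the
search scope instead of the alignment cost: the database is remodeled as
clusters of mutually similar profiles, each cluster summarized by a
representative, and a query is compared first with the K representatives
and then only with the members of the best-matching cluster.

Scores throughout are on the 0–100 profile–profile "probability" scale
produced by profile–profile comparison tools, where a score of 95 or more
is treated as near-certain homology. The package never computes these
scores itself — it consumes a precomputed all-against-all matrix, or a
user-supplied scorer behind a small functional contract — so it can sit on
top of any profile–profile alignment tool.

## The method

**Similarity matrix.** An all-against-all comparison yields a raw N×N score
matrix. Profile–profile scores depend on which profile plays the query (the
score depends on query length), so the raw matrix is asymmetric; only the
maximum of the two orientations is stored, giving a symmetric similarity
matrix S with a 100 diagonal.

**Clustering.** Three crisp backends operate on S:

* *connected components*: profiles are vertices, edges join pairs with
  S ≥ ψ; clusters are the components. ψ is on the 0–100 score scale.
* *single linkage*: the rows of S/100 are treated as N-dimensional feature
  vectors; Euclidean distances feed agglomerative single-linkage
  clustering, and the dendrogram is cut at ζ (see *Numerical choices*).
* *k-means*: the same row vectors, k-means++ careful seeding, Lloyd
  iterations with squared Euclidean assignment.

**Representatives.** For each cluster of size ≥ 2 the representative is the
member maximizing the sum of its within-cluster similarities — a
medoid-like "most homologous to everyone" choice. Singleton clusters get no
representative; their members form a pool of M profiles that crisp-mode
retrieval scans exhaustively, since a cluster of one cannot be summarized
more cheaply than it can be scanned.

**Overlap re-assignment.** Crisp boundaries lose recall: similarity under
local alignment is not transitive, so a profile can be genuinely similar to
two clusters while belonging to one. The overlap step re-assigns every
profile j using a self-regulated threshold: j's scores against the K
representatives are averaged, and j joins every cluster whose
representative meets that mean. Because a maximum is never below the mean,
every profile lands in at least one cluster — former singletons included —
so the pool empties (M = 0). Existing memberships of represented clusters
are retained (the step only adds), and representatives are unchanged.

**Retrieval.** A query is scored against the K representatives, then
against every member of the best representative's cluster, then against
the M pooled singletons; targets scoring at least φ (default 95) are the
hits. The exact per-query cost is

    NC = K + size(chosen cluster) + M

and the result object reports this breakdown stage by stage. Only the
single best representative's cluster is searched; searching the top-n
clusters is exposed as a deliberate extension point but defaults to 1.

**Evaluation.** The staged search scores a subset of what sequential
search scores, so its hits are a subset of the sequential hits and
precision is trivially 1; only recall is interesting. Per query, recall is
|baseline ∩ proposed| / |baseline| (defined as 1 when the baseline is
empty — there is nothing to miss); per batch it is the ratio of total hit
counts, which the subset property makes equivalent to the summed
intersection ratio. Cost reduction is reported two ways: wall-clock
(1 − Σα/Σα′, informational, hardware-dependent) and comparison counts
(1 − ΣNC/(T·N), exact and hardware-independent — the package's primary
cost measure).

## Parameters that matter

| parameter | meaning | scale | default | why |
|---|---|---|---|---|
| φ | match threshold for hits | 0–100 score | 95 | the near-certain homology level; hits use ≥ |
| ψ | component edge threshold | 0–100 score | 95 | edges below ψ are removed; ≥ keeps the verbatim "less than" removal rule |
| ζ | dendrogram cutoff | row-space distance | none | geometry-dependent; tune on a held-out query batch (see below) |
| k | number of k-means clusters | count | none | tune near the expected family count |
| seed | k-means++ seeding | integer | 1 | all randomness is seeded |

ζ deserves a warning: it lives on the Euclidean distance scale of the
row vectors of S/100, which depends on N and on the score distribution,
not on the 0–100 score scale. A ζ that works for one corpus is meaningless
for another; the package exposes `parameterSweep()` to tune it (and k) on
an independent query batch, which is also what `scripts/acceptance.R`
does on the synthetic benchmark.

## The synthetic benchmark

Real inputs for this method — a curated family database, an external
profile–profile alignment tool, and a batch of query sequences — are large
and external. The package therefore ships a seeded planted-partition
generator so the entire pipeline is testable at desk scale:

* profiles are partitioned into planted blocks (families) plus a fraction
  of unattached singletons;
* within-block raw scores are drawn uniformly from `withinRange`,
  everything else from `betweenRange`; singletons score in the between
  range against everyone;
* each raw orientation is jittered independently (profile–profile scores
  are asymmetric in reality because they are query-length dependent) and
  clipped to [0, 100];
* queries are noisy copies of database rows, emulating external sequences
  that resemble a database family.

The default spec is 200 profiles, 12 balanced blocks, 10% singletons,
within 96–100, between 0–60, jitter ±1, seed 1337 — small enough that the
O(N³) test oracles stay fast, separated enough that thresholded components
recover the planted truth exactly.

What the generator does **not** emulate: realistic score distributions
(real "probability" scores pile up near 0 and 100 rather than spreading
uniformly), length- and composition-dependent score structure, hierarchical
family/subfamily nesting, and any actual sequence content. Passing tests
demonstrate the correctness of the clustering, indexing, accounting and
evaluation machinery under the method's assumptions — not the recall the
method would achieve on a particular real corpus, which depends on how well
that corpus's similarity structure matches those assumptions.

One geometric consequence of the uniform between-range noise is worth
noting: in row space the within-block and between-block distances are only
moderately separated (the 0–60 noise dominates both), so k-means and
single linkage are exercised both on the default spec and on a
"tight-range" spec (within 97–99, between 10–12) whose row geometry is
cleanly separated. Connected components read the scores directly and do
not care.

## Numerical choices

* **Diagonal.** Self-scores are forced to 100 at construction (with a
  warning if the input disagreed): self-homology is certain by definition.
  Representative selection is invariant to any constant diagonal, since it
  shifts every member's similarity sum equally.
* **Symmetry tolerance.** Loaded matrices must be symmetric within 1e-9;
  `symmetrizeOnLoad = TRUE` max-symmetrizes raw input instead.
* **Dendrogram cut criterion.** ζ can cut the single-linkage tree either
  at merge height (`criterion = "distance"`, the default) or by the
  inconsistency coefficient (`criterion = "inconsistent"`, depth 2), the
  two conventions numerical-computing toolboxes use; both are implemented
  because published cutoff values rarely say which convention they assume.
* **k-means.** k-means++ seeding, Lloyd iterations, convergence when the
  maximum centroid movement drops below 1e-6 or after 300 iterations.
  Assignment ties break toward the lowest centroid index for determinism;
  clusters that end empty are dropped (matching the observation that large
  k produces empty clusters). `nRestarts` (default 1, seeded) is exposed
  because "best of many restarts" is common practice.
* **Ties.** Representative ties break to the lexicographically smallest
  id; stage-1 representative ties break to the lowest cluster index; hit
  lists sort by descending score, then id.
* **Degenerate inputs.** An all-singleton partition produces an index with
  K = 0 whose retrieval degenerates to sequential search over the pool;
  overlap requires K ≥ 1 and says so. A 1-profile database yields the
  1×1 matrix [[100]].
* **Edge rules.** Hits use score ≥ φ; component edges use S ≥ ψ (the
  removal rule drops edges strictly below ψ).

## Design decisions

* **Additive overlap.** The re-assignment retains crisp members of
  represented clusters and adds qualifying profiles, rather than dropping
  crisp members that score below the threshold: the step exists to enhance
  sensitivity, and removal would contradict that purpose. Representatives
  always remain members of their own clusters.
* **Singletons get no representative.** K counts only represented
  clusters; the M singletons are scanned exhaustively in crisp mode. This
  is the only reading under which a separate M term in the cost formula is
  coherent.
* **Representative scores from S.** The overlap threshold reads
  representative-vs-profile scores from the symmetric matrix, so
  orientation is moot; when only a scorer is available, the convention is
  (representative as query, profile as target).
* **Feature space.** Hierarchical and k-means clustering operate on rows
  of S/100, i.e. each profile is described by its similarity to everything
  (N samples in N dimensions) — not on 1 − S/100 as a pairwise
  dissimilarity. The row reading treats the similarity profile itself as
  the feature vector.
* **Expansion without re-clustering.** `overlapMemberships()` accepts a
  single new profile's representative-score vector and returns its cluster
  memberships, so a growing database can be absorbed incrementally.
* **Empty-baseline queries** contribute per-query recall 1 but are
  naturally weightless in batch recall (zero terms in both sums).

## Problem sizes

The test suite and the acceptance script run on 96–200-profile synthetic
databases with 10–100 queries per batch, sizes at which the naive O(N³)
oracles (literal double loops, breadth-first searches, exhaustive
agglomeration) remain exact and fast; the implementation itself is
vectorized and handles thousands of profiles comfortably, with the dense
N×N matrix as the memory bound.

## Known limitations

* No sparse matrix support: the method is defined on a dense all-vs-all
  matrix, and missing pairs are not permitted.
* The package does not run or parse any external alignment tool; adapters
  must implement the two scorer contracts.
* Only the best cluster is searched per query; recall lost to a wrong
  stage-1 choice is recoverable only through overlap, not through
  multi-cluster search.
* Wall-clock reduction numbers from the synthetic benchmark are not
  meaningful (the vector scorer makes "comparisons" nearly free);
  comparison counts are the cost measure that transfers.
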