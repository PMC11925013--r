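---
title: "Duplication networks: models, reconstruction and design notes"
author: "segdupnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplication networks: models, reconstruction and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segdupnet)
library(GenomicRanges)
```

# The problem

Segmental duplications (SDs) are genomic duplications at least 1 kbp long
whose copies retain more than 90% sequence identity.  Annotations such as
UCSC's genomicSuperDups report them as pairwise alignments between two
genomic intervals.  Not every alignment is a duplication event: when a new
duplication copies sequence that already overlaps an older duplicated
locus, the new copy aligns to *both* older loci, and one of the two
alignments is a *secondary* by-product of the overlap rather than an event.

`segdupnet` represents the annotation as a network.  A *duplicated region*
is the union of all transitively overlapping alignment intervals on a
chromosome; regions are nodes and an edge joins two regions whenever an
alignment connects them.  The package's central task is to decide which
edges are *primary* (real duplication events) and thereby estimate how many
duplications each region has undergone — a quantity that downstream
association analyses (random-forest importance, partial rank correlations,
signature factorization) explain in terms of genomic features.

# Network construction

`parseSdAnnotation()` reads the alignment table (0-based half-open input
coordinates; sex chromosomes dropped by default; sub-threshold alignments
filtered), `buildDuplicatedRegions()` merges intervals that overlap by at
least 1 bp (bookended intervals are deliberately *not* merged: the region
definition is about overlap, not adjacency), and `buildNetwork()` builds a
simple graph: alignments internal to one region become per-node self-loop
counts, parallel alignments collapse into a single edge that remembers its
multiplicity.  These pre-trim counts are retained as node features because
locally repeated alignments are themselves a signature of actively
duplicating loci.

Internally all interval arithmetic is done with `GRanges`/`IRanges`
(1-based closed, the Bioconductor convention); the parser converts on read
and every emitted table converts back to the 0-based half-open dialect.
This buys the package battle-tested overlap machinery at the cost of one
well-defined conversion at each boundary.

# Event reconstruction

Under a copying growth model, a daughter region inherits neighbors from
its mother, so endpoints of a *primary* edge tend to share many neighbors.
Each edge $(a, b)$ receives the weight

$$w_{ab} = 1 - \frac{\lVert N(a) \cap N(b) \rVert}{\min(k_a, k_b)},$$

where $N(\cdot)$ is the neighbor set (excluding the node itself) and $k$
the degree.  Weights lie in $(0, 1]$: exactly 1 when no neighbors are
shared, and always positive because $a \notin N(a)$ and $b \notin N(b)$.
A per-component minimum spanning tree (Kruskal) of this weighted graph is
the predicted set of primary events; it always has $N - C$ edges for $N$
nodes in $C$ components.  Kruskal is implemented with a union-find and a
*seeded* random tie-break among equal-weight edges, so runs are
reproducible; tests verify the output weight against exhaustive
enumeration of spanning trees on small graphs and against `igraph::mst`.

Edges whose alignment shares a breakpoint coordinate with another edge at
the same node are flagged *suspicious* — matching breakpoints are the
hallmark of a secondary alignment — unless the breakpoint lies within 50
bp of an assembly gap (there, matching cuts are an assembly artifact).
The exact supplementary matching rule of the original analysis is not in
the main text; the package's rule (exact coordinate match, `tolBp = 0`,
gap pad 50 bp — the flank width used throughout) is a documented stand-in,
and both knobs are exposed.  Suspicious edges receive a penalty weight
(default 2) that exceeds every legitimate weight, so they enter the forest
only when a component has no other way to stay spanned (a warning reports
this).

Per-node duplication counts are forest degrees.  Assigning direction
(mother vs daughter) would require knowing each component's ancestral
node, and the count is invariant to that choice except at the starting
nodes, so the package deliberately does not root the forest.

# The growth model used for validation

`pcmSimulate()` grows networks by preferential copying (PCM): a mother
node is chosen with probability proportional to degree + `alpha`
(`alpha = 1` keeps degree-0 remnants selectable), a daughter is attached
by a primary edge, and each mother neighbor is inherited independently
with probability `f` as a secondary edge.  With probability `pNew` a step
instead seeds a fresh two-node component.  Two molecular processes are
layered on top:

* **identity decay** — every edge carries a scalar identity, 1.0 at
  creation, decreasing by `delta` per step; below 0.9 (the annotation
  floor) the edge is removed, though the event log keeps the truth.
  Inherited edges inherit the mother edge's current identity.
* **non-allelic gene conversion (NAGC)** — each eligible edge converts
  with probability `rGc` per step: identity resets to 1.0 and, with a
  uniformly chosen donor endpoint, the acceptor's identities to all
  shared neighbors are overwritten by the donor's.  With evasion on
  (default) edges below the floor are never converted; without it a
  conversion resurrects a removed edge.  The donor choice is uniform
  because the data give no reason to prefer either endpoint.

Each step runs growth, then NAGC, then decay (configurable).  Decay is
deterministic-linear — the clock is an expectation, and a stochastic clock
would only add variance without changing any quantity the package
estimates.

## Default parameters and their calibration

The defaults are calibrated once, to the published summary of the human
autosomal SD network (6,656 nodes, 16,042 edges, 1,999 components, giant
component with 19.9% of nodes), and are not tuned per analysis:

* `nFinal = 6600`, `pNew = 0.43` — innovations make the final component
  count about 30% of nodes, matching 1,999/6,656.
* `f = 0.35` — mean surviving-edge count across seeds is about 16k at
  this scale.  The distribution is strongly heavy-tailed (single runs
  range from ~10k to ~33k edges): a few early hubs dominate edge
  production, which is a property of preferential copying itself.
* `delta` — derived from the duplication-to-mutation rate ratio
  `rdRmRatio` as `delta = 0.1 / (rdRmRatio * T)` with `T` the expected
  number of growth steps.  The default ratio 1.5 is the midpoint of the
  biologically supported interval [1.0, 2.0]; at the calibrated topology
  it realizes a mean surviving-edge divergence of ~5%, the level expected
  when the two rates are comparable.
* `rGc` — calibrated at run time by `calibrateRgc()` (bisection over
  probe simulations) so that ~34% of surviving edges have been hit by a
  conversion at the end of a run, the published human-genome estimate.

`benchmarkReconstruction()` replicates the accuracy table: per simulated
network it scores the spanning-forest reconstruction, the raw degree
vector, a random spanning forest (Kruskal on i.i.d. uniform weights — not
exactly uniform over trees, but a seeded, cheap and adequate baseline)
and five centralities (betweenness, closeness, eigenvector, PageRank at
damping 0.85, radiality), using the fraction of predicted edges that are
truly primary and the squared Pearson correlation with true counts.
Squared correlation is used rather than regression error because
centralities live on arbitrary scales; only a scale-free measure makes
them commensurable with counts.

A caveat worth stating explicitly: with ~2,000 components most components
are small trees, and on a tree the network degree *is* the degree of
every spanning tree — the degree-vector and random-tree baselines then
differ only inside the few cyclic components and can effectively tie.
The baselines separate cleanly in single-component growth (`pNew = 0`),
where the package reproduces the familiar ordering (reconstruction >
degrees > random tree, with closeness and radiality weakest); a test
covers that regime separately.

# Enrichment tests

`mstEnrichmentTest()` asks whether forest edges are enriched or depleted
in a property (e.g. identity > 0.99, or the suspicious flag): each round
draws `|forest|` edges without replacement from the non-forest edges; the
empirical p-value uses the add-one convention `(1 + extreme) /
(rounds + 1)`, so 10,000 rounds can report at best p < 1e-4 and never an
exact zero.

# Genomic features

`extractFeatures()` measures count, coverage-fraction, coverage-weighted
mean and span (max − min, the replication-pausing proxy) kinds either
inside a region or on its two 50-bp flanks (flanks are not distinguished:
counts are summed, means averaged).  Regions with no value-track coverage
get the chromosome mean (for means; 0 for spans) plus an explicit
missingness flag column, so imputation is visible to every downstream
model.  `backgroundComparison()` places length-preserving random
intervals outside assembly gaps (placement is rejection-sampled,
chromosome chosen proportional to length), summarizes shuffle means by a
normal approximation, and Bonferroni-adjusts across features; the default
of 100 shuffles balances the granularity of the normal fit against
runtime and is exposed.  `breakpointWindowProfile()` slides 50-bp window
pairs 5 steps into and 30 steps out of every region (offsets −250..−201
through 1,450..1,499 relative to each breakpoint) and reports repeat
overlap frequencies against a 10-placement random band; a repeat counts
for every window it overlaps by ≥ 1 bp, the same overlap rule used for
region features.

`rfImportance()` fits a random forest (500 trees, default mtry) and
calibrates its impurity importances by refitting under `nPerm` response
permutations; the empirical p-value is the fraction of permutations
reaching the observed importance.  Cross-validated R² (5-fold, pooled
1 − SSE/SST) reports model quality.  `partialSpearman()` rank-transforms
everything and computes each feature's correlation with the response
controlling for all other features, by two independent routes
(residualization and the precision-matrix identity) that must agree to
numerical precision; confidence intervals use the Fisher transform with
variance 1/(n − g − 3).

# Signatures

`buildWindowMatrix()` sums region features over non-overlapping 10-Mbp
windows (a region contributes to every window it overlaps), after
replacing length, G/C content (inside/flank) and identity by
below/above-mean indicator pairs, and min–max scales columns.
`nmfKl()` implements the multiplicative-update NMF under generalized
Kullback–Leibler divergence from seeded uniform initialization; the loss
trace is checked nonincreasing.  `selectK()` reports two rank
diagnostics: the Fogel–Young volume, interpreted here as the determinant
of the correlation matrix of the (row-normalized) signature rows — the
precise matrix is not fixed by the method's description, and this choice
makes the score dimensionless and comparable across k — and a stability
score, the mean cosine of greedily one-to-one-matched signatures across
restarts, reported as a curve rather than thresholded.  The two
diagnostics can legitimately disagree; the package never overrides the
user's k.  `assignSignatures()` encodes each region exactly as the window
matrix columns (same bin means, same min–max parameters) and solves a
nonnegative least-squares problem against the signature rows; the largest
weight wins, exact ties stay unassigned.  `chromosomeZone()` labels
regions within 5 Mbp of a centromere as pericentromeric (which wins over
subtelomeric when both apply, since centromeric proximity is the rarer
and more specific condition) and within 5 Mbp of a telomere as
subtelomeric.

# The synthetic fixture

`generateFixture()` forward-simulates duplications on a coordinate
genome: each event copies a source interval to a fresh locus (one primary
alignment); with probability `overlapProb` the source sits inside an
existing copy, implying one secondary alignment between the corresponding
part of that copy's partner and the new target.  Identities fall linearly
with event age across [0.9, 1.0].  A repeat family is planted at copy
breakpoints at a stated fold enrichment and a value track is generated
with a stated correlation to per-locus event counts, so the association
machinery can be tested against known effects.  What the fixture does
*not* emulate: sequence content (identities are scalars, repeats are
anonymous intervals), tandem expansions, real human repeat families and
density gradients, assembly-gap clustering near heterochromatin.  Tests
passing on the fixture demonstrate the correctness of the bookkeeping and
the detectability of planted effects at stated strengths — not biological
conclusions about real genomes.

# Problem sizes used in the packaged checks

The test suite exercises graph algorithms on 3–12-node oracles, simulator
properties at 150–500 nodes, and the full benchmark at the calibrated
scale (6,600 nodes, 20 replicates) in the acceptance tests; the
association tests use 100–2,000 synthetic rows.  These sizes were chosen
so each check isolates one property with comfortable statistical margins.

# Known limitations

* The suspicious-edge rule is a stand-in for an unpublished supplementary
  definition (see above); its two knobs default to the most conservative
  exact-match reading.
* The per-node duplication count is the undirected forest degree; it
  over-counts the birth event of interior nodes by design and the
  package makes no attempt to root trees.
* `calibrateRgc()` targets a mean over probe runs; with few probes the
  heavy-tailed edge counts make the realized affected fraction vary by a
  few points across seeds.
* Radiality and closeness are computed per component and concatenated,
  which is the only meaningful option on fragmented graphs but makes
  their absolute values incomparable across differently fragmented
  networks.
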