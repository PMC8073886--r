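---
title: "Gene-centric Hi-C contact networks: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-centric Hi-C contact networks: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HiCGeneNet)
```

## The data model

A Hi-C run summarised at gene level is a weighted graph: vertices are
genes, an edge records that at least one valid read pair spans the two
genes, the edge weight is the number of supporting read pairs, and an
edge probability scores contact confidence. HiCGeneNet's store holds
many such graphs over one shared gene universe, mirroring a
labelled-property graph database: a gene node is created exactly once
and reused by every experiment that touches it, while each contact is
a relationship labelled with its experiment's name. This "gene stored
once" discipline is what makes cross-experiment queries (neighbour
overlap of one gene in two conditions, edge-set similarity of two
runs) cheap and unambiguous.

Three modelling commitments worth stating explicitly:

* **Undirected edges.** Contact relationships in a graph database are
  formally directed; physical proximity is not. The store drops input
  direction on ingestion and every algorithm treats edges as
  undirected. Callers who care about read orientation should encode it
  as an extra edge property.
* **Duplicate contacts aggregate.** Re-inserting an unordered gene
  pair within one experiment sums the weights (read counts are
  additive evidence) and keeps the larger probability. This makes
  ingestion idempotent at the record level without double-counting
  support.
* **Self-contacts are rejected.** A gene-centric proximity graph has
  no use for a gene's contact with itself, and silently keeping
  self-loops would distort degree and modularity.

Gene identity is the symbol alone; the same symbol with conflicting
coordinates is a hard error rather than a silent merge, because a
merged pair of distinct loci corrupts every downstream neighbourhood.
Coordinates follow the 0-based half-open BED convention, since gene
annotation arrives as BED and round-tripping coordinates through two
conventions is a classic source of off-by-one bugs. Strand is ignored
throughout.

The contact-table dialect (columns `Gene1 Chr1 Start1 End1 Gene2 Chr2
Start2 End2 Weight Probability`, tab-separated, extra columns preserved
as edge properties) is this package's canonical interchange format;
`parse_contact_table(col_map = ...)` adapts variant headers. Weight
and probability are deliberately kept as two separate fields — one is
a read count, the other a model score — and never conflated.

## Progressive exploration

Exploration mimics the STRING-style interaction viewers: start from
one gene, expand one step at a time, step back, prune at an edge. The
entire state is the session — an ordered list of steps, each holding
anchor genes, an experiment filter and a weight threshold. Resolving a
session against a store is a pure function, so a session is also a
provenance record: serialise it to JSON (`session_to_json`), replay it
later, and the same display graph comes back. `render_pattern` prints
the session as a Cypher-flavoured path pattern for human inspection.

Two semantics questions were genuinely open and are exposed as
options:

* **Union vs. conjunction of experiments.** When several experiments
  are selected, the default shows a neighbour if it qualifies in *any*
  of them; `require_all_experiments = TRUE` restricts to genes with at
  least one qualifying contact in *each*, which is the filter an
  analyst wants when hunting contacts stable across conditions.
* **Threshold scope.** The weight threshold applies to the latest step
  by default (each expansion can have its own stringency);
  `explore_set_threshold(session_wide = TRUE)` re-filters the whole
  session. The threshold filters on read-count weight, not
  probability; a separate probability cutoff can be emulated through
  edge properties if needed.

## Graph analytics

The analytics layer works on one experiment's simple undirected
weighted subgraph (vertices ordered lexicographically so results are
reproducible). Standard centralities (betweenness via Brandes,
distances, local clustering coefficients, triangle counts) are
delegated to igraph; the conventions the package fixes on top are:

* **Betweenness** is unnormalised, endpoints excluded, each unordered
  pair counted once. A `normalized` flag divides by `(n-1)(n-2)/2`.
* **Closeness** is component-restricted: `c(v) = (n_v - 1) / sum of
  distances within v's component`, 0 for isolated vertices. This keeps
  values finite on fragmented contact graphs at the cost of
  cross-component comparability; harmonic closeness is available
  behind a flag when that trade-off goes the other way.
* **Clustering attitude** is reported as *both* the [0,1] local
  clustering coefficient and the raw triangle count. The two answer
  different questions (neighbourhood density vs. absolute triangle
  participation) and published "attitude" tables do not always say
  which is meant, so the caller picks explicitly.
* **Shortest paths** come in `hops` mode (BFS) and `probability` mode,
  where an edge of probability `p` has length `-log2(p)` bits; the
  shortest path then maximises the product of edge probabilities, and
  the reported length is the negative log2 of that product. Ties are
  broken by lexicographically smallest gene sequence, so results are
  deterministic. An unreachable pair is a result (`reachable = FALSE`,
  length `Inf`), not an error.

Two algorithms are implemented in the package rather than delegated,
because their contracts are stricter than the library defaults:

* **Louvain** (`louvain_communities`) is the classical two-phase
  greedy modularity maximisation, weighted by read counts by default
  (an unweighted flag exists). The vertex sweep order is shuffled by a
  mandatory seed and all tie-breaks are deterministic, so a (graph,
  seed) pair always yields the same partition. The reported modularity
  is not whatever the optimiser last saw: it is recomputed by
  `modularity_value`, a direct evaluation of
  `Q = sum_c [ w_in(c)/m - gamma (d(c)/2m)^2 ]`, and the two agree to
  machine precision by construction. Two disjoint triangles give the
  closed-form `Q = 2 (3/6 - (6/12)^2) = 0.5`, which the tests pin.
* **PageRank** (`pagerank_centrality`) is a plain power iteration with
  an L1 stopping tolerance and an iteration cap that *errors* on
  non-convergence (reporting the iteration count) instead of returning
  a silently unconverged vector. Mass of dangling (isolated) vertices
  is redistributed uniformly, the standard convention that keeps the
  result summing to exactly 1. The walk ignores weights by default —
  topological influence — with a `weighted` flag for
  proportional-to-weight transitions.

Per-gene neighbourhood Jaccard (`gene_neighbor_jaccard`) compares one
gene's threshold-passing neighbour sets in two experiments. When both
sets are empty the similarity is defined as 1: identical absence is
agreement, and returning 0 (or NaN) there would make sparse genes look
maximally discordant. The same convention applies to experiment-level
edge-set Jaccard.

## Cross-experiment comparison

`jaccard_matrix` assembles all pairwise edge-set similarities —
symmetric, unit diagonal, weights ignored (a weighted min/max-ratio
variant exists behind a flag). Note the terminology: the quantity is a
*similarity* (self-comparison is 1); tables of it are sometimes
labelled "distance" in the literature, which this package does not
follow. `degree_table` aligns per-experiment degree histograms on
shared bins for side-by-side plotting; `community_profile` summarises
a Louvain run; `partition_agreement` computes the adjusted Rand index
from the standard contingency formula (label-permutation invariant,
1 for identical partitions); `metric_delta` joins one metric across
two experiments and ranks genes by absolute change — the screen used
to shortlist genes whose local wiring shifts between conditions.

## Omics overlays and the two p-value conventions

`classify_direction` splits an overlay value table (e.g. log fold
changes) into `over`/`under` groups at a threshold, excluding exact
ties with a count. `metric_by_group` computes one graph metric per
experiment, summarises it per group (mean, sample `n-1` variance,
standard deviation) and reports the Welch two-sample t statistic.

The p-value has two conventions. The default, `"welch"`, is the
standard two-sided p with Welch–Satterthwaite degrees of freedom.
The alternative, `"paper_compat"`, evaluates the same t statistic
against a t distribution with **one** degree of freedom — equivalently
a standard Cauchy, `p = 2 (0.5 - atan(|t|)/pi)`. This convention
exists because published group-comparison tables in this area print
(t, p) pairs that match the df = 1 tail exactly (e.g. |t| = 0.957 with
p = 0.514, |t| = 0.650 with 0.633, |t| = 0.663 with 0.627); the
acceptance tests verify those pairs to three decimals. With df = 1 the
test is extremely conservative; the convention is provided for
comparability with such tables and flagged as a quirk, not a
recommendation.

The metric map is computed once per experiment and can be passed in
(`metric_map =`) when several group comparisons reuse it.

## The synthetic generator

No public Hi-C dataset is small enough to sit inside a test suite, so
every layer is exercised against seeded synthetic data whose structure
— not whose statistics — matches real gene-centric contact networks:

* Genes are laid out sequentially on a few chromosomes with
  exponential lengths and gaps. Same-chromosome gene pairs at index
  distance `d` contact with probability `intra_base (1 + d)^(-alpha)`,
  the power-law distance decay characteristic of chromatin contact
  frequency; cross-chromosome pairs contact at a small constant rate.
  Defaults (300 genes, 3 chromosomes, `alpha = 1`, `intra_base = 0.5`,
  `inter_rate = 0.002`) give a few hundred edges — dense near-diagonal
  neighbourhoods, sparse trans contacts — at a size every test can
  afford.
* Weights are geometric (mode 1, long tail), the qualitative shape of
  read-support counts; probabilities are uniform on [0.05, 1].
* `perturb_experiment(f)` builds pseudo-replicates by deleting
  `floor(f E)` edges and adding as many fresh pairs. The edge-set
  Jaccard against the base is then `(E - fE)/(E + fE) =
  (1 - f)/(1 + f)` up to floor rounding, which gives the comparison
  layer a sharp, analytically known target.
* `planted_partition_experiment` plants `k` equal communities with
  within/between rates `p_in > p_out`, the ground truth for Louvain
  recovery checks (at `n = 120, k = 4, p_in = 0.3, p_out = 0.01` the
  mean adjusted Rand index across ten seeds exceeds 0.9).

Every generator requires an explicit seed and is byte-reproducible.
What the generator does *not* emulate: polymer physics, domain
boundaries, replicate-specific coverage biases, or the empirical
weight distribution of any particular dataset. Tests passing on
synthetic data therefore certify algorithmic correctness and
contract stability, not biological conclusions about any real cell
line.

## Numerical and testing choices

* Problem sizes in the suite are deliberate: exhaustive oracle
  comparison runs over **all** labeled connected graphs on up to 5
  vertices (about 750 graphs) and seeded random samples at 6, 7 and up
  to 30 vertices, against Floyd–Warshall distances and
  shortest-path-count dynamic programming written independently of the
  implementation path. Stochastic checks (rewiring law, planted
  recovery) use 10–20 seeds.
* Modularity identity is asserted to 1e-12; PageRank mass to 1e-8 or
  better; path lengths in bits to 1e-12.
* Degenerate inputs have defined behaviour rather than accidents:
  empty experiments are valid (empty subgraph), empty neighbour sets
  compare as identical, an unreachable path is a value, stepping back
  from a one-step session is the identity, and Louvain on an edgeless
  graph is an error (there is nothing to optimise).

## Known limitations

* The store is single-process and in-memory; persistence is a plain
  TSV directory, not a transactional database. Property values
  containing `=`, `;` or tabs are rejected at serialisation time.
* Binned-matrix projection assigns probability 1.0 (matrices carry no
  probability) and tags such edges `source=matrix`; probability-mode
  paths through them degrade gracefully to hop-like behaviour.
* `.hic`/`.cool` binary formats are out of scope (text matrices and
  contact tables are the adapters); so is any machine-learning link
  prediction.
* The df = 1 compatibility p-value should not be used for new
  inference; it exists to reproduce existing tables.
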