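---
title: "Similarity scores, compartment clustering and layered path analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity scores, compartment clustering and layered path analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synconn)
```

This vignette is the package's own account of the methods it implements:
the three similarity scores, the compartment clustering, the layered path
analysis, the synthetic data that exercises them, and the numerical and
design choices made along the way.

## Data model

The package works from flat CATMAID-style exports. A **skeleton** is a
rooted tree of treenodes with nm coordinates (`read_swc()`, exactly one
root, acyclic parent links — `validate_skeleton()` reports each defect
separately). A **connector** is one polyadic chemical synapse: a single
presynaptic site contacting one or more postsynaptic neurites, stored as
one CSV row per postsynaptic site. The directed synaptic graph
(`build_graph()`) counts each postsynaptic site as one synaptic
connection, so a connector with m postsynaptic rows contributes m units of
edge weight and the graph's total weight equals the row count of the
connector table — an exact integer invariant the tests assert. Multiple
postsynaptic sites of the same neuron on one connector are each counted
(the flat export cannot distinguish them from genuinely distinct contacts;
our connector generator never produces duplicates within a connector, so
the choice is exercised but not load-bearing). Autapses are retained in
the graph but never traversed by path enumeration and excluded from the
connectivity score by its self-connection rule. Hemisphere (`side`) is
carried as metadata only; no mirroring or co-registration is attempted.

All positions are nm. Parameters are accepted in nm throughout
(`sigma = 2000`, not `2`), because mixing µm and nm conventions is the
single easiest way to silently destroy a Gaussian score whose scale enters
squared.

## Morphology similarity

`to_dotprops()` resamples each skeleton at ~`spacing` intervals of arc
length (segment-wise, between branch points) and fits the tangent at every
point as the first principal direction of its `k` nearest resampled
points. `morphology_score(Q, T)` then averages, over query points i,

$$ |q_i \cdot t_j| \; e^{-d_{ij}^2 / 2\sigma^2}, $$

with j the nearest target point. Choices worth stating:

* **σ = 2000 nm** is the reference spatial scale; it is the distance at
  which a parallel-tangent match decays to exp(−0.5) ≈ 0.607.
* **Resampling spacing (1000 nm) and k (5)** are not dictated by the score
  itself; the defaults follow common dotprops practice and both are
  exposed. The tests pin the arc-length contract (a 10 µm unbranched
  segment at 1 µm spacing yields 11 ± 1 points).
* **Absolute dot product.** Tangent sign is an artifact of fitting, so the
  score uses |q·t|; a signed product would make the score depend on
  traversal orientation.
* **Asymmetry.** The raw score is asymmetric (it averages over the query's
  points). The matrix routine keeps the raw values unless
  `symmetrize = TRUE` (the default), which averages M and Mᵀ — the form
  clustering consumes.
* **Exact self-identity.** Unit tangents stored as floats give
  |q·q| = 1 − O(1e−16); dot products within 1e−12 of parallel are snapped
  to 1 so S(Q,Q) = 1 holds exactly, as the identity tests require.

## Synapse-placement similarity

For each site s of neuron i, with k the nearest *same-polarity* site of
neuron j:

$$ f(s,k) = e^{-d_{sk}^2/2\sigma^2} \; e^{-|n_{is}-n_{jk}|/(n_{is}+n_{jk})}, $$

averaged over the sites of i; σ = ω = 2000 nm by default. The density
counts n are same-polarity sites within radius ω in the site's *own*
cloud, inclusive of the site itself — so n ≥ 1 and the denominator can
never vanish. The density factor lives in [exp(−1), 1]: co-located sites
can disagree in local crowding by at most a factor exp(−1) ≈ 0.368.

The density exponent is implemented as the *negative absolute* difference
ratio. Written with a positive (or signed) exponent the factor could not
push f toward zero under density disparity, which is the factor's entire
purpose; the negative-absolute form is the only one consistent with that
behaviour.

Sites of i with no same-polarity counterpart in j contribute 0 by default
(`unmatched = "zero"`), so sparse mismatched clouds score low; passing
`"skip"` drops them from the mean instead. Pre- and postsynaptic sites are
scored jointly in one mean by default; restrict the cloud to one polarity
before scoring if separate matrices are wanted.

## Normalized connectivity similarity

Two neurons' synaptic partner vectors are compared entry-wise with

$$ f(a, b) = \min(a,b) - C_1 \max(a,b)\, e^{-C_2 \min(a,b)}, $$

summed over the partner universe and linearly rescaled by the minimal
(−C₁·M) and maximal (M) achievable sums, M = Σ max(a,b). Defaults C₁ = 0.5,
C₂ = 1. Self-connections and the direct i↔j connections are excluded; if
the universe is empty after exclusion the score is undefined and returned
as `NA`, never coerced to a number. Incoming and outgoing vectors are
concatenated into one universe with direction-tagged partners
(`direction = "both"`), since a partner that is an input to one neuron and
an output of the other should not be conflated; `"in"`/`"out"` restrict
the comparison. The normalized score is symmetric exactly (computed once
per unordered pair) and reaches 1 only in the limit — identical vectors
score 1 − ε because of the exp(−C₂·min) residue, so the tests assert
strict dominance over perturbed vectors rather than equality with 1.

## Compartment clustering

Similarity is converted to distance by **d = 1 − s** (the conversion is a
convention, not a law; it is the one under which "clusters formed at a
score of 0.06" means merges stop where mean inter-cluster similarity falls
below 0.06, i.e. a dendrogram cut at height 0.94). Undefined similarities
become maximal distance 1 with a warning. Clustering is UPGMA
(`stats::hclust(method = "average")`), with labels canonically sorted
first so the merge sequence — and therefore tie resolution — is
independent of input order; an independent naive UPGMA implementation
serves as the test oracle via cophenetic matrices. UPGMA heights are
non-decreasing in exact arithmetic, but numerically tied inter-cluster
means (distances of 1 − e^{−50} between well-separated compartments) can
emerge microscopically inverted in floating point; inversions below 1e−8
are repaired by a running maximum, larger ones are an error.

`cut_dendrogram()` cuts at height 1 − `score_cut` and relabels clusters by
their lexicographically smallest member, making assignments invariant to
leaf order. Decreasing the cut similarity coarsens the clustering
monotonically (asserted as a property).

## Path enumeration and layers

All path analysis happens on the graph thresholded at ≥ t synapses per
directed edge (t = 2 by default). Paths are simple, and only neurons of
class `interneuron` may be intermediates. 1-hop paths are direct
source→target edges; 2-hop paths route through one interneuron; 3-hop
paths are found by backward traversal from the target's direct
(≥ t) interneuron upstream set U1: the second interneuron is drawn from
U1, the first from U1's own ≥ t upstream. With a uniform per-edge
threshold these frontier restrictions are *implied* by path validity —
any valid s→I1→I2→target path already has I2 ∈ U1 — so
`restrict_3hop = FALSE` provably enumerates the same set; the flag exists
to make the search semantics explicit, and the tests assert the superset
relation (which holds as equality). An exhaustive DFS with the same
constraints is the oracle on hundreds of random annotated graphs.

**Layers** are assigned output-centrically, by backward traversal, not by
membership in complete sensory-rooted paths:

* `L1-source`: sensory neurons with a direct ≥ t edge onto the target;
* `L2`: members of U1 that sit on at least one valid 2-hop path
  (equivalently: also receive ≥ t input from a source);
* layer 3: interneurons *not* in U1 with a ≥ t edge onto U1, split into
  `L3a` (receive ≥ t input from at least one sensory neuron) and `L3b`
  (receive none).

The defining feature of this scheme is that L3b can be non-empty: an
interneuron two steps upstream of an output can participate in the
circuit's upstream scaffold without integrating any direct sensory
input. A definition that required complete sensory-rooted 3-hop paths
would make L3b vacuously empty (every such path starts with a ≥ t sensory
edge onto the first interneuron), so the backward-traversal reading is the
only self-consistent one; direct-upstream interneurons lacking sensory
input are deliberately left out of both L2 and L3 rather than shoehorned
into a layer. Divergence (distinct interneuron routes per source) and
convergence degree (distinct sources per interneuron) are tallied from the
2-hop paths.

`percent_synaptic_connections()` and `ranking_index()` follow the counting
conventions above: percentages are of a neuron's total connections in one
direction (undefined, with a warning, when that total is zero), and a
ranking index of 1.0 marks the strongest input of the target.

## Synthetic data: what it emulates, and what it does not

`generate_compartment_dataset()` plants K convergence zones on a cubic
lattice of pitch `separation` (default 20 µm = 10σ, so the minimum
centroid distance is exactly the pitch) and gives each sensory neuron an
isotropic Gaussian presynaptic cloud (spread 1 µm, 8 neurons per zone,
10–30 sites each), emitted as polyadic connectors with 1–3 postsynaptic
sites jittered ≤ 200 nm — EM connectors are point-like at this scale.
These defaults are the package's study conditions: at 10σ separation
inter-zone similarity is ~e^{−50} while intra-zone similarity is high
(nearest-site distances of a few hundred nm), so the 0.06 cut must recover
exactly K compartments with adjusted Rand index 1 — asserted for K = 2…9
across seeds. Degenerate regimes behave as they should: with K = 1 all
pairwise similarities stay high; with the spread blown up to absurdity the
within/between similarity distributions become indistinguishable.

`generate_reflex_connectome()` wires 30 sensory, 40 interneurons (half a
layer-2 pool, half a layer-3 pool) and 10 outputs: direct sensory→output
edges with probability 0.1, layer-2 wiring at 0.3, layer-3→layer-2 at 0.2,
sensory input onto the layer-3 pool at 0.2 — the last is what makes both
L3a and L3b arise. Edge weights are 1 + Geometric(0.5) synapses, so the
t = 2 threshold prunes roughly half the edges, mirroring the use of a low
absolute threshold on real reconstructions. The generator computes its
ground truth (monosynaptic edge list, per-target layer memberships, the
full 1/2/3-hop path inventory) by direct bookkeeping on the sampled weight
matrix — a separate code path from the join-based enumeration it
validates — and the tests demand exact recovery on 50 seeded instances.

What passing these tests does **not** show: real axon terminals are not
isotropic Gaussians (they are elongated, curved, and hemisphere-paired),
real degree and weight distributions are heavier-tailed than geometric,
and real compartments touch. Perfect planted recovery validates the
machinery, not the biological robustness of any particular cut value.

Skeleton generation (biased random walk with branching) provides shapes
for the morphology score's resampling and tangent fitting; successive
neurons are laid out in disjoint territories, so the pipeline's morphology
summary shows self-similarity exactly 1 against cross-similarity near 0 —
a discrimination sanity check, not a morphological clustering benchmark.

## Determinism and the pipeline

`run_pipeline()` validates every parameter before any computation,
orchestrates compartments (generate → score → cluster → composition),
circuit (generate → graph → paths → layers → convergence → ranking) and a
morphology summary, and writes CSV/Newick/GraphML/JSON outputs. The
exemplar path target is chosen as the output neuron with the most ≥ t
monosynaptic sensory inputs. Everything is seeded through the config; two
runs with the same config are byte-identical (asserted), and the report
records the package version, the full config and its hash. Newick export
writes leaf depths equal to merge heights (a two-leaf tree merged at 0.3
serializes as `(a:0.3,b:0.3);`); nearest-neighbour queries go through a
kd-tree with distance ties broken toward the lowest point index.

Problem sizes in the shipped tests — compartment datasets up to K = 9 × 8
neurons, circuits of 30/40/10 neurons, oracle comparisons on clouds up to
200 points and graphs up to 50 nodes — were chosen as the smallest scales
at which every contract (separation ratios, layer occupancy, non-empty
path sets) is genuinely exercised.

## Known limitations

* No NBLAST-style empirical scoring matrix; the morphology score is the
  plain Gaussian × |dot| form only.
* No electrical synapses or peptidergic connectivity; chemical polyadic
  connectors are the only edge source.
* Clustering variants other than average linkage are untested against the
  compartment conventions.
* The path metrics stop at 3 hops and do not attempt flow or centrality
  analytics; probabilistic path weighting is out of scope.
* With per-edge thresholding the `restrict_3hop` flag cannot change
  results (see above); it would only matter under mixed per-leg
  thresholds, which the package does not currently offer.
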