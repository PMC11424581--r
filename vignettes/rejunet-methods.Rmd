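---
title: "Models and methods behind rejunet"
author: "rejunet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rejunet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rejunet)
```

# Scope and data model

`rejunet` analyses the transcriptional response to rejuvenation
interventions at several scales: cell-level quality control, gene-level
differential expression, network-level regulatory logic, pathway-level
signaling crosstalk and tissue-level cell–cell communication. The package
deliberately consumes *processed* inputs — raw counts with cell metadata,
per-cell-type DE tables, a signed prior knowledge network (PKN) of
TF → gene interactions, per-condition signaling activity scores, and a
ligand–receptor scaffold — because normalisation, integration, doublet
removal, DE estimation and hotspot computation are mature upstream tools
with their own ecosystems. What this package owns is the regulatory logic
that connects those inputs.

Containers follow Bioconductor conventions: `CellMatrix` is a
`SingleCellExperiment` subclass whose validity enforces integral,
non-negative counts and the metadata columns the pipeline needs
(`cell_type`, `condition`, `replicate`); `EdgeList`, `BooleanProfile`,
`TRN`, `PlantedNetwork` and `CrosstalkComponent` are small S4 classes with
validity methods and accessors (`edges()`, `nodes()`, `networkSize()`,
`profileStates()`).

Gene identifiers are plain, case-sensitive symbols. Species conventions
(mouse `Jun` vs human `JUN`) and any ortholog mapping are the caller's
responsibility; mixing symbol spaces silently would corrupt every
downstream join, so the package never remaps. Duplicate symbols in a count
matrix are resolved at read time by keeping the row with the larger total
count (and logging the collision): downstream network nodes must be unique,
so a make-unique suffix scheme would orphan edges instead.

# Cell quality control

`madFilter()` keeps a cell only if it passes **all** of:

* `pct_mito` at most `nmads` MADs above the median (one-sided: low
  mitochondrial content is never a damage signal);
* `pct_ribo`, `log10(n_features)` and `log10(n_counts)` within
  `nmads` MADs of their medians (two-sided);
* the residual of the least-squares fit
  `log10(n_features) ~ log10(n_counts)` within `nmads` MADs of the median
  residual — this catches cells with anomalous library complexity at a
  normal depth, which the marginal filters cannot see.

`nmads` defaults to 3; MADs use the 1.4826 normal-consistency constant.
Cells with zero counts are removed unconditionally. A criterion whose
values are all identical carries no information and passes every cell
(logged); a zero MAD over non-identical values collapses the band onto the
median, so genuine gross outliers are still removed.

# Clustering selection

Clustering algorithms are treated as a callback contract: any procedure
that labels cells at some resolution can produce candidates. The package
owns only the *selection*: each candidate is scored with the
Calinski–Harabasz index

$$CH = \frac{B/(k-1)}{W/(n-k)},$$

with $B$ the size-weighted squared distance of cluster centroids to the
grand centroid and $W$ the pooled within-cluster sum of squares. The
highest-scoring candidate wins; ties break toward fewer clusters
(parsimony) and then candidate order, for determinism. All-singleton
scatter ($W = 0$) maps to $+\infty$ and outranks every finite score.
If the winner has more than `max_clusters` (default 30) clusters, the
user-supplied fallback partition is returned instead — an over-fragmented
optimum is a sign the resolution sweep has left the useful regime.

# Booleanization and inhibition-dominant pruning

DE tables are filtered by `filterDE()`: a gene is kept when
$|\mathrm{logFC}| > 0.25$ *or* it is detected in more than 10% of cells in
*both* conditions (both comparisons strict). `booleanize()` then maps
positive fold changes to state 1 and negative to 0; a fold change of
exactly zero defines neither state and the gene is excluded.

`prunePKN()` retains the maximum set of PKN edges consistent with the
profile under inhibition dominance, where one up-regulated inhibitor
explains a down-regulated target regardless of activators. For a target
$g$ with candidate in-edges:

* state$(g) = 1$: no up-regulated inhibitor may be kept, and if any edge
  is kept at least one must be an up-regulated activator;
* state$(g) = 0$: either an up-regulated inhibitor is kept (which excuses
  any activators), or no up-regulated activator is kept.

Because no constraint couples two different targets, the per-target
subproblems are independent; each is solved exactly (subset enumeration up
to 16 candidate edges, above which a closed-form rule that attains the
same optimum is applied and logged). The objective is lexicographic:
explained genes first, then retained edges. Genes that keep no edge leave
the network; the network size $N$ is the number of unique regulators plus
targets of retained edges. Self-loops are allowed and may explain a
gene's own state. Re-pruning a pruned network is a no-op.

Hierarchy of the result is quantified with the Krackhardt hierarchy score:
among unordered node pairs reachable in at least one direction, the
fraction *not* mutually reachable. Out-trees score 1, a two-cycle scores 0.

# Master-regulator scoring

`simulateActivation()` clamps one TF active, starts every other node
undetermined, and propagates: a node becomes 0 if any *determined* active
inhibitor points at it, else 1 if any determined active activator does,
else stays undetermined. Propagation runs depth-first from the activated
TF (out-edges in lexicographic target order) and is then stabilised by
synchronous sweeps, bounded by $N$; the sweep makes the fixed point
independent of traversal order. Cyclic inhibition can oscillate — nodes
still changing at the bound are forced undetermined with a warning.

`tfScore()` is the fraction of the network whose booleanized state the
activation reproduces (counting only determined, matching nodes, the TF
itself included), with denominator $N$ — the full network size, not the
TF's reachable set. Three corner cases pin the semantics down:

* the root of a fully hierarchical, fully consistent network scores 1.0;
* an up-regulated end node explains only itself: exactly $1/N$;
* a TF booleanized to 0 scores 0 outright — activating it contradicts its
  own observed state, so no downstream credit is given. This global
  short-circuit is the only reading under which all three corner cases
  are mutually consistent.

TFs scoring at least `mr_threshold = 0.30` (inclusive, "at least 30% of
the network") are classified master regulators. `aggregateTopTFs()`
averages scores across conditions with absent TFs scored 0, reports the
top 30 by mean score, and also emits a mean-rank column and the full
TF × condition matrix, leaving rank-based aggregation and any heatmap
clustering to the user's tool of choice.

# Signaling intermediates and crosstalk

`differentialIntermediates()` selects molecules that switch state between
conditions: treated activity present and > 0.70, control activity < 0.30
*or missing* — a missing control score counts as inhibited, while a
missing treated score disqualifies the molecule. Both tables must be
non-empty: a condition with no results at all invalidates the comparison
rather than producing vacuous selections. These two rules reconcile the
network-level "both conditions must have results" requirement with the
molecule-level "NA entries included" convention.

`sharedComponent()` extracts TRN–signaling crosstalk only when some TF has
*outgoing* edges in both networks — a shared sink node is not crosstalk,
since nothing is transmitted through it. When the gate passes, the edge
sets are concatenated and weak connected components computed; a single
component is returned whole, otherwise only the component containing the
signaling intermediate. Directions are preserved in the output; only the
connectivity computation ignores them.

`oraTest()` is a generic overrepresentation analysis: hypergeometric
upper-tail p-values of query/set overlaps against a user-supplied
background, BH-adjusted, flagged at an FDR of 0.05. Gene-set collections
come from user GMT files; no database is bundled.

# Cell–cell communication

`interactionScore()` multiplies the mean ligand expression over
*expressing* sender cells by the mean receptor expression over expressing
receiver cells (count > 0; empty expressing set gives 0). Scores are
compared only within their (sender type, receiver type) stratum across the
whole scaffold: significance is the fraction of stratum scores strictly
below the record's score (ties share the lower rank), and the top decile
(significance ≥ 0.90) is significant. With raw versus normalised input the
absolute scores change, but any per-gene monotone scaling leaves the
within-stratum ranks, and hence the decile calls, unchanged.

`treatedUnique()` keeps treated records with significance strictly above
0.90 whose channel is not significant in control. Uniqueness is defined at
the significant-interaction level — a channel present but weak in control
still counts as treated-unique, matching the interpretation of reported
interaction sets. Records tied exactly at the cutoff are excluded and
logged, making the measure-zero ambiguity between "above 0.90" and "top
decile" visible instead of silent. An optional `keep_records` hook accepts
an externally computed receptor–TF compatibility list, since intracellular
consistency filtering is upstream of this package.

# Synthetic data with planted truth

Each generator emulates one pipeline input and returns machine-checkable
truth; a global seed is split per operation, so adding a generator never
perturbs another's fixtures.

* `simulatePlantedTRN()` builds a rooted out-tree: TF nodes form the upper
  levels with activating TF→TF edges (so every TF is active when the root
  is), targets are leaves reached by activating or inhibiting edges. The
  profile is the forward simulation from the active root; `noise_fraction`
  of non-root nodes then have their state flipped. State-flipping (rather
  than edge rewiring) is the right noise model here because the TF score
  is defined over states, not edges. At zero noise the tree is fully
  explained and its hierarchy is exactly 1.
* `simulateCounts()` draws negative-binomial counts (dispersion 0.4 by
  default, i.e. clearly overdispersed; 0 gives Poisson) with a
  multiplicative $2^{\mathrm{logFC}}$ treated-condition effect on each
  cell type's planted DE genes and independent dropout (0.2). The returned
  DE tables are *truth* — planted log2 fold changes and closed-form
  expected detection fractions $(1-\mathrm{dropout})\,P(\mathrm{count}>0)$
  — because DE estimation itself is out of scope.
* `simulateIntermediateTables()` plants differential molecules with
  treated scores on (0.70, 1] and control on [0, 0.30), among decoys that
  are mid-range in both conditions or missing in one.
* `simulateLRExperiment()` plants treated-only ligand–receptor channels an
  order of magnitude above the decoy score scale and silent elsewhere.
  Decoy counts are drawn once and shared verbatim between the condition
  matrices, so decoy channels rank identically in both conditions and can
  never leak into the treated-unique set; recovery of the planted truth is
  exact by construction.

What the generators deliberately do **not** emulate: ambient RNA,
doublets, batch effects, cell-cycle structure, or realistic gene–gene
correlation. Passing tests therefore demonstrate the correctness of the
pipeline's logic under its stated assumptions, not robustness to every
artefact of real single-cell data — those artefacts are handled by the
out-of-scope upstream preprocessing.

# Numerical choices and problem sizes

* Strictness mirrors the thresholds' wording: DE filters, the 0.70/0.30
  intermediate cutoffs and the 0.90 uniqueness cutoff are strict; the 30%
  master-regulator call and the top-decile significance flag are
  inclusive.
* Calinski–Harabasz ties break toward fewer clusters, then candidate
  order; degenerate candidates ($k = 1$ or $k = n$) are invalid.
* The activation simulation is bounded by $N$ synchronous sweeps;
  non-convergence forces the oscillating nodes undetermined rather than
  returning an order-dependent state.
* The test suite checks the simulation against a naive re-implementation
  exhaustively on all 3-node signed digraphs (with 3-state fixed-point
  enumeration as a spot check) and on seeded random 4-node digraphs with
  self-loops; pruning against brute-force edge-subset enumeration on
  instances up to 12 edges; the hierarchy score against a
  reachability-closure oracle exhaustively up to 4 nodes and on sampled
  5-node digraphs; and ORA against direct combinatorial summation on
  backgrounds up to 20 genes. Planted-truth recovery runs 200 seeded
  networks of 10–100 nodes at up to 10% state-flip noise for the master
  regulator, and 50 seeded ligand–receptor experiments. These sizes keep
  the suite exhaustive where exhaustiveness is cheap and densely sampled
  where it is not.

# Limitations

* The pruning objective (maximise explained genes, then retained edges) is
  one defensible formalisation of profile-consistent subnetwork selection;
  other objectives (e.g. edge-weighted) would need a different solver, and
  the per-gene decomposition would no longer be exact if constraints
  coupled targets.
* Whether a pruned gene may lose its only up-activator yet remain in the
  network is answered here by membership-through-retained-edges: a gene
  with no surviving edge is not part of the network.
* The TF score rewards reach: hub TFs in star-like networks score highly
  even when biological causality is uncertain; scores are evidence for
  prioritisation, not proof of regulation.
* Cell-communication scoring ignores extracellular vesicles and any
  ligand transport not captured by expression, and the intracellular
  receptor→TF consistency check is delegated to the `keep_records` hook.
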