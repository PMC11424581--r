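# rejunet

Multiscale regulatory network analysis of rejuvenation interventions in R.

Single-cell studies of rejuvenation interventions (caloric restriction,
heterochronic parabiosis, exercise, partial reprogramming) report
differential expression per cell type, but the question that matters is
*which regulators drive those changes*. `rejunet` implements a unified
pipeline that moves from QC'd expression data up through regulatory logic:

1. **Cell QC** — MAD-based outlier filtering on mitochondrial/ribosomal
   fractions, feature and count depth, plus a residual filter on the
   `log10(features) ~ log10(counts)` regression (`computeQCMetrics`,
   `madFilter`), and Calinski–Harabasz-optimised clustering selection with
   a fallback partition above 30 clusters (`selectClustering`).
2. **Booleanization & TRN pruning** — DE tables are filtered
   (|logFC| > 0.25 or detection > 10% in both conditions) and booleanized
   (positive → 1, negative → 0). A signed prior knowledge network of
   TF → gene edges is then pruned under *inhibition-dominant* logic — one
   up-regulated inhibitor suffices to explain a down-regulated target, no
   matter how many activators point at it — keeping the maximum edge set
   consistent with the profile (`filterDE`, `booleanize`, `prunePKN`).
   Network hierarchy is quantified with the Krackhardt hierarchy score
   (`krackhardtHierarchy`).
3. **Master-regulator scoring** — every TF is scored by Boolean activation
   simulation: all states start undetermined, the TF is clamped active, and
   inhibition-dominant updates propagate to a fixed point. The score is
   the fraction of the network whose booleanized state the activation
   reproduces; TFs at ≥ 30% are classified master regulators
   (`simulateActivation`, `tfScore`, `scoreAllTFs`, `aggregateTopTFs`).
4. **Signaling crosstalk** — signaling intermediates active in the treated
   condition (> 0.70) and inhibited or absent in control (< 0.30 or NA) are
   selected, and the weakly connected component joining the TRN with the
   signaling edges through a shared emitting TF is extracted
   (`differentialIntermediates`, `sharedComponent`); generic
   overrepresentation analysis with BH-FDR is included (`oraTest`).
5. **Cell–cell communication** — ligand–receptor channels are scored as the
   product of mean expressing-cell expression in sender and receiver
   populations, called significant in the top decile of their cell-type
   stratum, and filtered to channels unique to the treated condition
   (`scoreInteractions`, `treatedUnique`).

Every stage has a synthetic generator with planted, machine-checkable
ground truth (`simulatePlantedTRN`, `simulateCounts`,
`simulateIntermediateTables`, `simulateLRExperiment`), so the whole
pipeline is testable without any external download.

## Worked example

```r
library(rejunet)

# a planted regulatory tree: root TF1, 3 TFs + 4 targets, no noise
pn  <- simulatePlantedTRN(n_tfs = 3, n_targets = 4, seed = 1)
trn <- prunePKN(pn@pkn, pn@profile)
trn
#> TRN: N = 7 nodes, 6 edges, 3 regulators

scoreAllTFs(trn)
#>    tf     score determined n is_mr
#> 1 TF1 1.0000000          7 7  TRUE
#> 2 TF2 0.4285714          3 7  TRUE
#> 3 TF3 0.4285714          3 7  TRUE

krackhardtHierarchy(trn)
#> [1] 1
```

The root `TF1` explains all 7 node states when activated (score 1.0) and
is called a master regulator; the deeper TFs each determine 3 of 7 states.
The hierarchy score of 1 says reachability in the pruned network is fully
antisymmetric — the signature of a hierarchical regulatory response, which
is what motivates looking for master regulators at all.

## Documentation

See the methods vignette (`vignettes/rejunet-methods.Rmd`) for the models,
the inhibition-dominance semantics, parameter defaults, synthetic-data
design and known limitations.
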