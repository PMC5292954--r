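---
title: "Methods: from five-group expression profiles to a target axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from five-group expression profiles to a target axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

`herbnet` infers a candidate therapeutic signal axis for an herb-pair
combination from a five-group expression design: normal control (Con), a
disease model (Mod), the single herb (DJ_alone), a synergistic combination
(DJGC_synergy) and an antagonistic combination (DJGC_antagonism). This
vignette explains each stage's model and assumptions, the tunable
parameters, the synthetic-data generator used for validation, and the
design decisions taken where the method description left genuine freedom.

## Differential-expression screening

Expression is assumed pre-normalized on the log2 scale. For a comparison
"test vs reference", each gene's log2 fold change is the difference of
group means and its p-value comes from a two-sample t-test; a gene passes
at `|log2FC| >= 1` (inclusive) and `p < 0.05` (strict). Both thresholds
are arguments of `screen_degs()`.

**Choice of test.** The default is the pooled-variance Student t. With
three samples per group — the design this package targets — the Welch
test's Satterthwaite degrees-of-freedom approximation is noticeably
conservative, so under a common-variance Gaussian model the pooled test is
the calibrated choice (it is exact there, and the screening criterion is a
raw, uncorrected p-value by design). `method = "welch"` and
`method = "limma"` (moderated t, borrowing variance strength across genes)
are available when heteroscedasticity or very low replication argue for
them. Missing values are handled pairwise-complete; a gene is testable
only with at least two non-missing samples per group.

No multiple-testing correction is applied in the screen itself: the
screening rule is deliberately a raw p threshold combined with an effect
threshold, and downstream stages (network construction, hub selection)
act as the effective filters.

Hierarchical clustering of the passing DEGs (`cluster_degs()`) uses
Euclidean distance with average linkage, for genes and samples; rows and
columns are sorted lexicographically beforehand so merge order is
deterministic under ties.

## Direction-reversal categories

Six categories describe how a treatment relates to the model
dysregulation; each requires a *passing DEG with the stated sign in both
comparisons* (a merely non-significant treatment effect does not count as
a reversal):

| category | model vs control | second comparison |
|---|---|---|
| C1 | up | down, DJ_alone vs Mod |
| C2 | up | down, DJGC_synergy vs Mod |
| C3 | up | up, DJGC_antagonism vs Con |
| C4 | down | up, DJ_alone vs Mod |
| C5 | down | up, DJGC_synergy vs Mod |
| C6 | down | down, DJGC_antagonism vs Con |

The antagonism categories compare against the control group by default:
the operative definition of "dysregulated in both model and antagonism" is
a statement about the antagonism group relative to normal, and a
model-referenced alternative (`antagonism_comparison = "vs_mod"`) is kept
as an option since the comparison list of the underlying design also
includes that contrast. Categories may overlap; the union is
de-duplicated, and both the per-category counts and the union size are
reported without forcing agreement between them.

## Network construction and topology

Candidate interactions are those whose endpoints both carry at least one
role — disease-related DEG, combination-related gene, or known
therapeutic target. The retention threshold is the *median combined score
of the candidate interactions*, applied inclusively (score ≥ median is
kept): the boundary convention is not dictated by the method description,
and keeping it is the conservative reading of "median as a threshold".
Isolated nodes are dropped; node roles are unions, so a gene may be both
a DEG and a known target.

Four per-node features are computed on the unweighted graph:

* **degree** — incident edge count;
* **betweenness** — exact Brandes counts, unnormalized, with fractional
  credit over tied shortest paths (unnormalized values are directly
  checkable against path enumeration, and only ranks/medians matter
  downstream);
* **closeness** — Wasserman–Faust component scaling,
  `((nc-1)/sum d) * ((nc-1)/(n-1))` with `nc` the component size: hub
  subnetworks are typically disconnected and raw within-component
  closeness would inflate small components;
* **k-coreness** — the largest k whose k-core (iterative pruning of
  degree < k nodes) retains the node.

**Hubs** are nodes with degree strictly greater than twice the median
degree of all network nodes. **Major hubs** are hubs strictly exceeding
the median of *all four* features. Those medians are computed over the
full network by default: requiring most of a subnetwork's nodes to exceed
four of its own medians is arithmetically implausible, whereas
full-network medians measure each hub against the complete candidate
gene population. `major_hub_scope = "subnetwork"` switches to
subnetwork-based medians for sensitivity analysis.

## Markov clustering

The hub subnetwork is partitioned with the canonical MCL iteration on a
column-stochastic flow matrix built from the combined-score-weighted
adjacency with self-loops (loop weight = the node's maximum incident edge
weight, which damps oscillation on bipartite-ish structures). Defaults
are expansion 2, inflation 2.0, pruning threshold 1e-5, convergence
tolerance 1e-8 and at most 200 iterations — the standard parameterization
when none is prescribed; all are exposed in the configuration and echoed
into the run summary. Clusters are read off the attractor structure of
the limit matrix; a node claimed by several attractor systems goes to the
one holding most of its flow mass, with ties resolved towards the module
whose smallest gene sorts first, and module ids are assigned by
decreasing size (then smallest member) so the partition is a pure
function of the graph up to relabeling. Non-convergence is reported with
a warning and a flagged partial result rather than an error.

## Pathway enrichment

Over-representation uses the hypergeometric upper tail P(X ≥ k)
(one-sided Fisher). The universe defaults to the genes present in the
expression data after probe collapse — the population actually screened —
and the Bonferroni multiplier is the number of pathways with nonzero
universe overlap (pathways that could not have been hit are not counted
as tests). Corrected p-values are capped at 1. Only Bonferroni is
offered: the downstream claims are about a handful of top pathways, where
family-wise control is the appropriate guarantee.

## Axis extraction

Given a combination-related seed and a known-target seed, the search
space is the induced subgraph on the seeds plus the major hubs (whose
edges are exactly those incident to a seed or between major hubs). The
axis is the shortest path between the seeds; among equally short paths
the one with the higher minimum combined score wins (a path is only as
credible as its weakest interaction), then the lexicographically smallest
gene sequence — a total order, so extraction is deterministic.
Disconnected seeds yield a reported "no axis" result, not an error. The
axis is annotated with every pathway containing at least a configurable
fraction (default 0.8) of its genes.

## The synthetic-data generator

`simulate_study()` emulates the study design the package targets, with
planted ground truth:

* **Expression.** 2000 genes x 5 groups x 3 samples; per-gene baselines
  N(7, 1) on the log2 scale; i.i.d. Gaussian noise with sd 0.5 — the
  magnitude of replicate scatter typical for pooled-sample two-color
  arrays; 100 up and 50 down model-vs-control DEGs shifted by ±2.5 log2
  units. Category genes (25/35/4/10/26/1 for C1..C6, the observed scale
  of reversal classes in such designs, planted disjointly so the truth is
  unambiguous) follow their reversal patterns exactly; non-category DEGs
  persist under the single herb and the synergy combination and revert
  under antagonism; category fractions, sizes, effect and noise are all
  configurable.
* **Interactions.** A preferential-attachment background (2 edges per
  step) over the planted DEGs and 30 known targets gives a heavy-tailed
  degree distribution; 12 planted hubs (including the axis interior)
  receive 30 high-score spokes each plus a dense mutual core. Combined
  scores are STRING-like integers: background 150–900, hub edges
  700–950, axis edges 999 — above every other score, hence above any
  median threshold.
* **The axis.** A five-gene chain from the first synergy-reversed (C2)
  gene through three interior planted hubs to the first known target.
  The endpoints carry only their single chain edge, no chord connects
  non-consecutive axis genes, and the interior genes are also placed on
  the known-target list — real signal axes run through established
  targets, and this anchors the chain in the network independently of
  screening noise on any one comparison. Together these make the planted
  chain the unique score-preferred shortest route between the seeds
  whenever the interior is selected as major hubs.
* **Pathways.** Nineteen random sets of 10–40 genes plus one set
  containing the full axis.

Everything is a pure function of the configuration, including its seed.

**What the generator does not emulate:** dye bias, spatial artifacts,
intensity-dependent variance, correlated co-expression blocks, or
empirical mouse expression distributions; and its interaction scores are
independent of the expression signal. Passing the planted-truth tests
therefore demonstrates the pipeline's correctness and calibration under
an idealized homoscedastic model, not robustness to microarray artifacts.

**What noise does to exact recovery.** With three samples per group and
noise sd 0.5, the fold-change threshold of 1 sits at about 2.4 standard
errors of a group-mean difference. Single-comparison error rates of a few
per mil to a percent are therefore unavoidable, and because the six
categories intersect *pairs* of screens over ~2000 genes, a handful of
false category members and occasional misses per run are expected even
though per-gene power exceeds 99%. The validation suite consequently
checks planted-DEG recovery as a rate (≥90%) and axis recovery across
seeds (≥19/20), and it also records the strict expectation of exact
category recovery — which the above arithmetic shows cannot hold at these
noise conditions — so the measured misclassification stays visible rather
than hidden behind a loosened assertion.

## Degenerate inputs and numerical conventions

Empty interaction files parse to empty tables with a warning; self-pairs
are dropped with a warning; duplicate interactions collapse to their
maximum score (conservative and order-independent). Gene symbols are
case-folded to capitalized style at every reader boundary. Zero-variance
genes with a nonzero mean difference get p = 0 (an infinite t).
Closeness of an isolated vertex is 0. Probe-to-gene collapse keeps the
probe with maximal mean absolute log2 value (ties by probe id);
`max_var` and `mean` rules are available.

## Problem sizes used in validation

The test suite runs the full pipeline on the default 2000-gene
configuration across 20 seeds, checks the four centralities against
exhaustive enumeration on 100 random graphs of up to 25 nodes, and
estimates the screen's type-I error from 50 null replicates of 2000 genes
— sizes at which every property is checkable exactly while the whole
suite remains quick to run routinely.

## Known limitations

* The screen assumes pre-normalized log2 data; no within-package
  normalization is offered.
* The axis search considers unweighted path length first and scores only
  as a tie-break; weighted-shortest-path variants are out of scope.
* Identifier mapping is the user's responsibility beyond the optional
  probe map and interaction id map; no mapping services are consulted.
* Enrichment p-values depend strongly on the pathway snapshot and
  universe definition; they are comparable across runs of the same
  inputs, not across database releases.
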