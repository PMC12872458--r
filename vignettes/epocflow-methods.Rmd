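---
title: "Methods: sister-clade inference by constrained-topology ELW testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sister-clade inference by constrained-topology ELW testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the model and its assumptions, the tunable parameters, what the
synthetic generator does and does not emulate, and the numerical and design
choices made where the procedure was genuinely open. It states no empirical
result that the test suite does not itself compute.

## The inference problem

A gene family here is one eukaryotic protein family together with its
prokaryotic homologs: an alignment, a gene tree with branch lengths in
expected substitutions per site, and a taxonomy mapping every sequence to a
class label, a domain, and (for eukaryotes) one of the deep supergroups
Amorphea or Diaphoretickes. The target of inference is, per eukaryotic
clade, the prokaryotic class whose clade is its sister — the proxy for the
donor lineage from which the eukaryotic family descends.

Rather than trusting the estimated topology, the pipeline treats each
candidate sister as a hypothesis: the eukaryotic clade is pruned and
regrafted as sister to the candidate clade root, branch lengths are
re-optimized under the same substitution model, and the per-site
log-likelihoods of all candidate topologies are compared with expected
likelihood weights (ELW). ELW is estimated by RELL: resample site indices
with replacement (identically across topologies), form replicate
log-likelihoods by summation, convert to normalized weights by softmax, and
average over replicates. The resulting vector sums to one and is read as
model-selection confidence. No tree search is performed per hypothesis: at
this scale the three-group constraint (eukaryotic clade, candidate, all
other prokaryotes) is dominated by the attachment point, which the regraft
fixes. The real study evaluates constrained trees on slices of the
alignment; since no slicing scheme is defined, this implementation
evaluates the full trimmed alignment — simpler and strictly specified.

## The likelihood engine

The likelihood is standard Felsenstein pruning under a reversible
amino-acid CTMC. The rate matrix is `Q = S diag(pi)` (S the symmetric
exchangeability matrix), rescaled to one expected substitution per site at
stationarity. Transition matrices come from the eigendecomposition of the
symmetrized matrix `diag(sqrt(pi)) Q diag(1/sqrt(pi))`, which is real for
reversible models; the decomposition is cached per model. Rate
heterogeneity uses an equal-weight discrete gamma with category rates at
the category medians (`qgamma((i-0.5)/k, a, a)`), normalized to mean one.
Gaps and ambiguity codes are missing data (partial likelihood one). Sites
with exactly zero likelihood — possible on zero-length branches with
conflicting states — are clamped to a finite sentinel (−1e9) so RELL
resampling stays finite. Per-node column rescaling keeps partials in range
for hundreds of leaves.

The gamma shape is estimated once per family on the master tree over the
grid {0.3, 0.5, 0.75, 1, 1.5, 2, 5} and reused unchanged for all of that
family's constrained topologies, mirroring the practice of fixing the
model estimated on the unconstrained tree.

Branch-length optimization is coordinate-wise bracketed scalar search in a
depth-first traversal that maintains exact partial likelihoods on both
sides of the edge being optimized, so each one-dimensional objective costs
four small matrix products rather than a full pruning pass. Because
lengths carry over from an already-reasonable tree, most branches are near
their optimum: a local triple plus one parabolic refinement settles those
in about four evaluations, and a full Brent search over the bounded
interval runs only when the triple shows the optimum elsewhere. A
candidate length is accepted only if it improves the likelihood, making
the trace monotone non-decreasing by construction. Bounds are
[1e-8, 10] substitutions/site; optimization stops when a full round gains
less than `tol` (default 0.01 log units) or after `max_rounds`.

## Tree curation

*Outlier removal.* A log-normal distribution is fitted by maximum
likelihood to all positive branch lengths — terminal and internal, since
both long leaf branches and long-stemmed clades occur — and every subtree
whose stem is strictly longer than the 99.5% quantile is removed.
Zero-length branches are excluded from the fit and never removed; with
fewer than ten positive branches nothing is done (degenerate fits). The
family is discarded when pruning would delete a whole maximal eukaryotic
clade or more than 30% of all leaves. The strict inequality at the
quantile means equal-length trees (sigma = 0) lose nothing.

*Rooting.* The root is placed at the point minimizing the absolute
difference between the total branch lengths of the two sides, each side
including its share of the split edge. The imbalance is linear in the
offset along any edge, so the optimum is exact per edge and the global
optimum is a scan over edges; ties break toward the lexicographically
smallest leaf below the edge, making re-rooting idempotent. This is a
data-structure root, not a biological one.

## Clade detection and the soft-LCA score

Strictly monophyletic labeling is brittle: a single misplaced leaf (local
topology error or within-prokaryote transfer) destroys an otherwise clean
clade. The soft-LCA score, purity times scope, is computed for every node
on the paths from maximal monophyletic label-clade roots to the tree root.
Clade calls are selected per label greedily by descending score among
leaf-disjoint candidates. One deviation from a literal reading: nodes at
or below the purity threshold are *skipped* during selection rather than
selected-and-flagged. Otherwise a large impure ancestor — typically the
root when the eukaryotes are paraphyletic — would win on scope, block all
its descendants by the disjointness rule, and make the paraphyly discard
rule unreachable. Validity thresholds are at least 3 sequences
(prokaryotic) or 5 (eukaryotic) at purity strictly above 0.8; families
with no valid eukaryotic or no valid prokaryotic clade, or with more than
three valid eukaryotic clades, are discarded with machine-readable reason
codes.

Topological distance between clades counts the internal nodes strictly
between the two clade roots, excluding both endpoints and the tree root:
sisters under a non-root parent are at distance 1. The root is excluded
deliberately (rooting is arbitrary here); endpoint exclusion is a
convention fixed for a clean metric.

## Stem metrics

`SL` is the branch from the eukaryote+sister common ancestor to the
eukaryotic clade root in the best-supported topology; `NSL` divides by
the median root-to-leaf distance within the eukaryotic clade (even counts:
mean of the central pair), making the statistic invariant to uniform
rescaling of the tree. Distributional comparisons between ancestor taxa
use the empirical CDFs of 200 bootstrap resamples of the family records,
evaluated on a shared grid of 200 points from 0 to the pooled 99th
percentile, with a two-sided Mann–Whitney U test per grid point. The U
test enumerates the exact null (mid-ranks, so ties are exact) up to a
total sample size of 14 and uses the tie- and continuity-corrected normal
approximation beyond. Both taxa's bootstraps are driven by the same seed,
so identical record sets give an exactly flat p = 1 profile. NSL is not a
clock: the package makes no claim that stem lengths measure acquisition
time.

## Filters and aggregation

The soft-core pangenome rule keeps a cluster for a class when it covers at
least 50% of that class's species (prokaryotes) or 20% (eukaryotes),
inclusive thresholds, configurable to the 10/25/50/67% alternates. The
core-set filter requires a non-empty functional category (the stand-in for
an external profile annotation, which is out of scope), more than five
distinct eukaryotic labels including both Amorphea and Diaphoretickes
(the LECA-coverage proxy), and candidate ELW strictly inside (0.4, 0.99).
ELW at or above 0.99 usually flags a prokaryotic sequence nested inside
the eukaryotes — late horizontal transfer — and is rejected, except that
ELW = 1 is admitted for Alphaproteobacteria with oxidative
phosphorylation, where near-certain assignments are biologically expected
rather than artifactual. Families whose best candidate falls below 0.4
are dropped whole as low-quality; the rejection log distinguishes
candidate-level from family-level drops by a scope column while keeping
the five stated reason codes. aELW is the arithmetic mean of ELW per
(category, taxon) cell with counts kept alongside; the reference
comparison reports, per taxon, the best-aELW pathway among pathways with
at least 20 records, against the reference taxon's aELW on the same
pathway.

## Cluster annealing

Superclustering is greedy set cover on the similarity graph after
filtering edges at 80% probability and 50% coverage: repeatedly seed a
cluster at the node with the largest uncovered closed neighborhood (ties
lexicographic). Tree partitioning embeds the patristic distance matrix in
two dimensions and density-clusters the embedding. The packaged embedder
is classical metric scaling with fixed axis signs — deterministic, which
the test surface requires; the manifold method used at scale (UMAP with
n_neighbors = 50, min_dist = 0.3, then HDBSCAN) is not available in this
environment, but both strategies are injectable functions with a
determinism-under-seed contract, so it can be plugged in where installed.
The packaged clusterer cuts the single-linkage dendrogram at the largest
multiplicative jump in merge heights when that jump exceeds a factor of 8,
else returns a single partition — trees with uniform pairwise distances
stay whole by design. Clusters below 5 leaves are noise and are
reassigned to the nearest surviving centroid (the noise rule is an
artifact decision; the source procedure does not state one).

## The synthetic generator: what a green test establishes

The generator emulates the statistical structure the analysis assumes: a
Yule backbone of prokaryotic classes (depth 1.0) with Yule within-class
subtrees (depth 0.25), one to three eukaryotic clades (depth 0.3) attached
beside a chosen donor class by a stem of known length, sequences evolved
under the same LG+Γ model family used for inference, and post-hoc
injection of HGT leaves and long-branch outliers purely to exercise the
filters. Eukaryotic leaves draw class labels from a 12-label vocabulary
with both deep supergroups guaranteed present in any clade of two or more
leaves. Defaults — 10 classes, 3–8 leaves per class, 6–10 eukaryotic
leaves, stem 0.3, 150 columns, gamma shape 1 — describe a small but
realistic family. The depth choices (backbone ≫ within-class) are the
package's own, made once: classes must be resolvable units for
clade detection to be meaningful.

What the generator does not emulate: alignment error and indels (columns
arrive aligned and gap-free), compositional heterogeneity across lineages,
model misspecification (simulation and inference share the LG family),
site-specific selection, and real Asgard sequence composition. A green
recovery test therefore establishes that the pipeline is a correct and
well-calibrated implementation of the stated procedure under its own
modeling assumptions — not that the procedure is robust to the failure
modes of real database-scale data.

## Numerical choices and degenerate inputs

* All ties (cherry collapse, candidate ordering, rooting, set cover)
  break lexicographically by identifier, so every stage is deterministic.
* Seeded stages restore the caller's RNG state; per-family seeds are
  derived arithmetically from a master seed and kept below 2^31.
* Sites with zero likelihood report the −1e9 sentinel; ELW normalization
  is exact to 1e-9 by construction.
* Degenerate cases with defined behavior: all-gap columns (0 bits),
  single-leaf trees (stationary log-likelihood), sigma = 0 branch sets
  (no pruning), constant bootstrap samples (degenerate CDFs), identical
  Mann–Whitney samples (p = 1 exactly).
* Replication sizes in the slow recovery experiments (30 families for
  sister recovery; 8 families per stem-grid point) were sized so that
  Monte-Carlo error of the estimated means sits well below the effect
  being asserted, while keeping the suite inside its runtime budget.

## Known limitations

Constrained hypotheses differ only in the regraft attachment point; a
full constrained tree search could in principle relocate the eukaryotic
clade within a candidate clade. ELW is the only test statistic (no
AU/SH/KH). The annotation rule is a category-label stand-in for profile
search against an external functional database. Branch-length
re-optimization uses one pass per candidate topology by default
(carried-over lengths make this adequate for ranking; raise `opt_rounds`
for publication-grade stems).
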