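---
title: "Methods: models, parameters and design choices in screpair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in screpair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`screpair` analyses single-cell RNA-seq cohorts of graded tissue injury to
separate adaptive from fibrotic repair. This vignette documents the models
behind each stage, the parameters that matter, the synthetic cohort the
package validates itself against, and the design decisions taken where the
design was genuinely open.

## The synthetic cohort: what it emulates, and what it does not

Every downstream stage is exercised on cohorts from `generate_cohort()`,
whose ground truth is known by construction.

**Count model.** Counts are negative binomial per gene with cell-specific
expected library sizes — the standard generative stand-in for UMI data.
A cell of type $t$ in condition $c$ draws
$x_{gi} \sim \mathrm{NB}(\mu = L_i \, p_{g}^{(t,c)},\ \mathrm{size} = 1/\phi)$
where $L_i$ is log-normal (mean 5000 counts, log-sd 0.35), $p^{(t,c)}$ is a
normalized relative-abundance profile, and $\phi = 0.4$ is a shared
dispersion. The baseline profile is log-normal across genes (log-sd 1,
giving the usual heavy-tailed abundance spectrum); defaults are
config-exposed because real datasets vary and the source data report none.
They were chosen once as typical of whole-kidney 10x data and not tuned.

**Structure planted on top of the baseline.**

* *Composition:* three conditions with immune fractions 0.10/0.45/0.66 and
  proximal-tubule fractions 0.54/0.12/0.08 — the immune influx and PT
  depletion characteristic of increasing ischemic dose. Cell types are
  drawn i.i.d. per cell, so realized fractions are multinomial around the
  targets.
* *Markers:* each cell type carries a marker block at fold change 4 —
  strong but not degenerate, comparable to canonical kidney markers.
* *Condition programs:* every cell of a condition upregulates that
  condition's program (fold change 3 on ~50 genes): a healthy/repair
  program in controls, an injury program shared by both injured arms, and
  a 60-gene fibrosis block restricted to the long-injury arm whose first
  five genes (pyroptosis sensors/executioners) carry fold change 6 and act
  as designated hubs.
* *Maladaptive PT:* a separate cell type upregulating an inflammatory
  chemokine block (fold change 6), present almost only in the injured arms.
* *Artifacts:* 5% planted low-quality cells (alternating shallow-depth
  cells with ~50–120 total counts, hence < 200 detected genes, and
  mito-loaded cells with ~75% mitochondrial reads) and 5% doublets
  (element-wise sums of two same-sample cells, binomially thinned to ~55%
  of the summed depth — a reasonable stand-in for droplet doublet physics).
  Mitochondrial genes are a reserved `mt-` block of 13 genes (the mouse
  mtDNA protein-gene count) at ~12% of a healthy cell's reads.

**Not emulated:** ambient RNA, batch effects, spliced/unspliced layers,
cell-cycle structure, and continuous differentiation trajectories. Passing
tests therefore demonstrate correctness of the statistics on data with the
planted covariance and composition structure — not robustness to ambient
contamination or integration artifacts, which upstream tools handle.

## Quality control

Cells are retained when $200 < \text{nFeatures} < 3000$ and
$\text{mito\%} \le 50$. The permissive mitochondrial bound reflects the
physiologically high mitochondrial content of proximal tubule cells. Two
boundary conventions circulate (exclude-at-bound versus retain-at-bound);
`screpair` retains strictly inside the gene bounds (a cell at exactly 200
or 3000 detected genes is excluded) and retains a cell at exactly 50%
mitochondrial reads, and both bounds are parameters of `qc_thresholds()`.
Doublet removal consumes a boolean metadata column — ground truth from the
generator or an external detector's verdict; no detection algorithm is
reimplemented. All-zero cells are defined to have mito% 0 and 0 detected
genes, so they fall to the gene filter rather than dividing by zero.

## Injury-state scoring

Signatures are the top `n_top_degs = 100` most specific genes per
condition: genes detected in ≥ 5% of in-group cells with natural-log fold
change ≥ 0.2 (Seurat dialect:
$\ln\frac{\overline{\exp(x)-1}_{in}+1}{\overline{\exp(x)-1}_{out}+1}$,
stated explicitly because dialects differ), ranked by two-sided Wilcoxon
rank-sum p (normal approximation with tie correction), ties by |lnFC| then
gene id. A rank-sum test replaces a hurdle model deliberately: for strong
markers the orderings agree, and no additional dependency is needed. Only
upregulated genes enter a condition's signature (`only_pos = TRUE`), since
the scoring contrast needs each list to represent its own condition.

Signature pairs are pruned in a single pass on the initial sets: a gene is
kept iff its mean Pearson correlation with its own set is ≥ `auto_r_min`
(default 0.1) and with the opposite set is ≤ `cross_r_max` (default 0).
The source procedure names no cutoffs and does not say whether pruning was
iterated; single-pass with exposed thresholds is the least-surprising
reading, and iterating would only shrink sets further.

Scoring follows the binned-control strategy: genes are cut into 24
equal-size bins by dataset-wide mean expression; each signature gene draws
100 control genes from its bin (with replacement for small bins); the cell
score is mean signature expression minus mean pooled-control expression.
24/100 are the conventional defaults for this scoring family; the expected
score of a cell expressing the signature no higher than its bin background
is 0. Classification: injured if the injury score exceeds the control
score by more than `margin` (default 0) **and** is positive; symmetric for
control; otherwise `neither` — ties and doubly non-positive scores are
`neither`. Whether the original classification used a margin is unstated;
0 is the neutral choice and the margin is exposed.

The recovery criterion (sensitivity and specificity ≥ 0.9) is evaluated on
a single-lineage two-condition cohort, so that it measures recovery of the
planted transcriptional program. On a multi-type cohort, condition-correlated
composition (immune expansion) would let cell-type markers enter the
signatures and the metric would conflate two real signals.

## Differential proportion analysis

For clusters $k$ and groups $A, B$: the observed statistic is
$d_k = \hat f_k^A - \hat f_k^B$. Each null iteration draws a subsample
fraction $f \sim U(w, 1)$, selects $\lceil f n \rceil$ cells uniformly,
permutes the **cluster** labels within that subsample (group labels
fixed), and recomputes $d_k$. Two-sided p values use the add-one
estimator $(1 + \#\{|d^{null}_k| \ge |d_k|\})/(1 + n_{iter})$, so p is
never 0 and is floored at $1/(n_{iter}+1)$. With $w = 0.1$, lower values
of $w$ shuffle smaller subsamples, produce a tighter null and hence a
stricter test — an averaged monotonicity the test suite checks. The
original implementation is not published in the source text; this
reconstruction follows its verbal description, and its validity rests on
the calibration property (null rejection at $\alpha = 0.05$ stays below
0.07; empirically it is conservative, ~0.00–0.01). The inner loop is a
small C++ kernel driven by R's RNG, so results are reproducible from
`set.seed()` alone. Multi-group designs are tested pairwise with explicit
group arguments; no automatic all-pairs sweep is performed.

## Metacell coexpression networks

Sparsity defeats gene–gene correlation on raw cells, so the network is
estimated on metacells: each is the mean log-normalized profile of
`k = 20` cells drawn with replacement from one (cell type × experimental
group) stratum, `n = 50` metacells per stratum. Mean (not sum) keeps the
scale independent of `k`; aggregating on log-normalized values keeps the
downstream correlations comparable to cell-level intuition. Averaging 20
cells cuts gene-wise variance several-fold (a tested property) while the
stratum constraint preserves type- and group-level contrasts.

Signed adjacency $a_{ij} = ((1+r_{ij})/2)^\beta$ with $\beta = 12$ — the
conventional signed-network power, exposed in `network_config()` with a
scale-free-fit diagnostic (`scale_free_fit()`) provided but never
auto-selected, because silent power selection makes runs incomparable.
The topological overlap transform and module extraction follow the
standard pipeline: average-linkage clustering on $1-\mathrm{TOM}$, cut at
height $1 - 0.2$ (the "correlation threshold 0.2" is read as the cut
correlation; the original's dynamic-tree-cut deepSplit parameter belongs
to an algorithm not reimplemented here), minimum module size 50 with
smaller clusters pooled into `grey`, then eigengene-based merging at
$r > 0.8$ iterated to a fixpoint. Module eigengenes are first principal
components of the standardized module submatrix, unit variance,
sign-oriented so the mean gene–eigengene correlation is positive; kME is
the gene–eigengene correlation and the hub is the own-module argmax (ties
by gene id). Grey genes keep kME columns but are never hubs. Module labels
are color names ordered by module size, so labels are deterministic up to
gene permutation.

## Ligand–receptor interactions

Only genes detected in **strictly more than** 5% of a cluster's cells are
considered expressed there (detection means count > 0; whether the
original gate counted detection or normalized expression is unstated, and
detection is the simpler invariant choice). For each (pair, sender,
receiver) triple passing the gate on both sides, the interaction mean is
the average of the ligand's sender mean and the receptor's receiver mean;
gated-out triples are absent, not zero. The null shuffles cluster labels
over all cells (1000 iterations), p is add-one one-sided on the
interaction mean, and Benjamini–Hochberg FDR is applied across all tested
triples (significance at q < 0.05). Multi-subunit complexes are not
modeled — pairs are single genes, which covers the chemokine/interleukin
axes of interest here.

## Druggability screen

Per experiment, the drug effect per gene is the weighted average
fold-change difference between treated and untreated replicates; genes are
ranked descending (ties by gene id, so rankings are total orders). Per
drug, experiment rankings are merged into a prototype ranked list by
hierarchical Borda merging: repeatedly merge the two most
Spearman-correlated rankings by summing ranks and re-ranking, until one
consensus remains — merging similar lists first prevents an outlier
experiment from dominating the consensus.

Pre-ranked GSEA of a signature against a PRL uses the weighted
Kolmogorov–Smirnov running sum (hit increments $|s_g|^p$ normalized over
hits, default $p = 1$, with $p = 0$ supported for closed-form unweighted
tests; miss decrement $1/(N - |S|)$); ES is the signed extremum, computed
in closed form at hit boundaries. The null permutes gene labels (random
same-size sets), since PRLs carry no phenotype replicates. NES divides ES
by the mean |null ES| of the same sign. The p value is the two-sided
add-one estimator over all permutations,
$(1 + \#\{|ES^{null}| \ge |ES|\})/(1 + n_{perm})$: it is uniform under the
null and floored at $1/1001$ for 1000 permutations, so Bonferroni
correction across 50 drugs can still reach significance — a same-sign-only
estimator would floor near $1/500$ and could not. Bonferroni
($\min(1, p \cdot n_{drugs})$) is applied across drugs, results sorted by
NES descending. Leading edges are the set members at or before the
running-sum maximum (positive ES) or at or after the minimum (negative
ES); their binary occurrence across the top 24 drugs, tallied per gene,
identifies recurrently driven signature genes.

## Numerical choices and degenerate inputs

* All empirical p values use add-one estimators and can never be 0.
* All ties (DEG ranking, drug rankings, Borda consensus, hub selection)
  break lexicographically by gene id, making every output deterministic
  under a seed.
* Zero-variance genes: dropped with a warning before adjacency; defined as
  all-zero z rows (and flagged) in cluster enrichment; correlation NAs in
  pruning are treated as r = 0.
* All-zero cells score 0 and are called `neither`; an all-zero count
  matrix is a valid limit of the generator (`library_size_mean = 0`).
* A single global seed derives per-stage sub-seeds by hashing the stage
  name (kept below $2^{31}$), so toggling one pipeline stage never
  perturbs another's randomness.

## Problem sizes

The validation suite runs cohorts of 2000 genes × 6000 cells (the default
three-condition cohort), 700 metacells, 200 replicate null datasets of
2000 cells for DPA calibration (2000 permutation iterations each,
scaled down from the 100,000 used for a production comparison), 1000
permutations for the ligand–receptor and GSEA nulls, and a 50-drug screen
with 3 experiments per drug on a 978-gene universe (the L1000
landmark-panel size). These sizes were chosen so the full suite exercises
every claim in minutes on a laptop while keeping all planted effects at
the effect sizes stated above.

## Known limitations

* The DPA null is a reconstruction from a verbal description; it is
  validated by calibration, not by code identity with the original.
* Module cutting is a fixed-height approximation of dynamic tree cut;
  very nested module structure may resolve differently.
* The GSEA weighting exponent and permutation count of the original
  screen are unstated; defaults follow the standard convention and are
  exposed.
* Complex (multi-subunit) receptors, ambient RNA, batch integration and
  trajectory inference are out of scope; the package expects cleaned,
  integrated input where those matter.
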