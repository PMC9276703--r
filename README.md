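# screpair

Single-cell analysis of adaptive versus fibrotic kidney repair.

After acute kidney injury, proximal tubule (PT) cells either regenerate
(adaptive repair) or collapse into a profibrotic, cytokine-secreting state
that recruits myeloid cells and drives chronic kidney disease. `screpair`
implements the computational stages needed to dissect this transition in
single-cell RNA-seq cohorts spanning graded injury conditions, together
with a ground-truth synthetic cohort generator so that every stage is
testable end to end without external data.

## What it computes

* **Quality control** — cells retained when
  200 < nFeatures < 3000 and mito% ≤ 50 (PT cells physiologically carry
  high mitochondrial content), doublets dropped by flag; gene breadth
  filter (≥ 3 reads in ≥ 10 cells); balanced per-cluster downsampling.
* **Injury-state scoring** — per-condition signatures from the top 100 most
  specific DEGs (Wilcoxon rank-sum, min.pct = 0.05, |lnFC| ≥ 0.2), pruned
  by within/cross-set Pearson correlation, scored per cell against
  expression-bin-matched control genes (24 bins × 100 controls, Tirosh-style):
  `score(c) = mean(x_Sc) − mean(x_Cc)`, and cells called
  injured / control / neither by the sign-and-margin rule.
* **Differential proportion analysis (DPA)** — per-cluster permutation test
  of fraction shifts between groups: each of 100,000 iterations shuffles the
  cluster labels of a random `f ~ U(w, 1)` subsample (`w = 0.1`) and the
  two-sided add-one p compares the observed fraction difference with that
  null.
* **Metacell coexpression networks** — bootstrapped k-cell metacells per
  (cell type × group) stratum; signed adjacency `a_ij = ((1 + r_ij)/2)^β`
  (β = 12), topological overlap matrix, average-linkage modules (cut
  correlation 0.2, min size 50, eigengene merge at r > 0.8), module
  eigengenes (first PC), kME hub genes, and group specificity.
* **Ligand–receptor interactions** — 5% detection gate per cluster,
  interaction mean = (sender ligand mean + receiver receptor mean)/2,
  1000-permutation test with Benjamini–Hochberg FDR.
* **Druggability screen** — per-experiment weighted fold-change drug
  rankings merged into prototype ranked lists (hierarchical Spearman-guided
  Borda), pre-ranked GSEA of a maladaptive signature (running-sum ES, NES
  against gene-label permutation nulls, Bonferroni across drugs), leading
  edges and their cross-drug frequency.

## Worked example

```r
library(screpair)

cohort <- generate_cohort(default_cohort_config(seed = 1))
cohort
#> cell_table: 2000 genes x 6000 cells, 8 metadata columns

qc   <- compute_cell_qc(cohort)
kept <- filter_cells(qc, qc_thresholds(), drop_doublets = TRUE)
length(kept)
#> [1] 5400
filt <- subset_cells(cohort, cells = kept)

dpa_test(filt$meta$cluster, filt$meta$condition, "Control", "IRI_long",
         dpa_config(n_iter = 100000, seed = 2))
#>          cluster count_A count_B frac_A frac_B    diff       p
#> 1           Endo     369     135  0.205 0.0750  0.1300 0.00030
#> 2         Immune     187    1199  0.104 0.6661 -0.5622 0.00001
#> 3             PT     965     139  0.536 0.0772  0.4589 0.00001
#> 4 PT_maladaptive       0     212  0.000 0.1178 -0.1178 0.00001
#> 5        Stromal     279     115  0.155 0.0639  0.0911 0.00115

mc  <- build_metacells(filt, k = 20, n_metacells_per_stratum = 50, seed = 3)
net <- run_coexpression(mc)
net
#> coexpression_network: 2000 genes, 2 modules (+grey)
#>      blue      grey turquoise
#>        50      1891        59
net$hubs[["turquoise"]]
#> [1] "Casp4"
round(net$specificity$group_means["turquoise", ], 2)
#>  Control IRI_long IRI_short
#>    -0.73     1.34     -0.75
```

The generator plants immune expansion (10/45/66% of cells across
Control/short/long injury), PT depletion (54/12/8%), and a fibrosis gene
block restricted to the long-injury arm: DPA flags the immune and PT
shifts at the permutation floor (p = 1e-5 at 100,000 iterations), the
coexpression stage recovers the planted 60-gene block as the `turquoise`
module whose hub is one of the designated pyroptosis genes and whose
eigengene peaks in `IRI_long`. `run_all(run_config(...))` chains all seven
stages and writes per-stage TSV/MTX outputs plus a JSON manifest.

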