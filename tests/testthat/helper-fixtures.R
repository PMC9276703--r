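## Shared fixtures: all built in code, no files.

## small random count table with cluster/condition metadata
rand_cell_table <- function(n_genes = 50, n_cells = 200, seed = 1,
                            n_mito = 5, lambda = 2) {
  set.seed(seed)
  genes <- c(paste0("mt-", seq_len(n_mito)),
             sprintf("g%03d", seq_len(n_genes - n_mito)))
  counts <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells,
                   dimnames = list(genes, sprintf("cell%04d",
                                                  seq_len(n_cells))))
  meta <- data.frame(
    barcode = colnames(counts),
    cluster = sample(paste0("c", 1:4), n_cells, replace = TRUE),
    condition = sample(c("A", "B"), n_cells, replace = TRUE),
    row.names = colnames(counts), stringsAsFactors = FALSE)
  cell_table(counts, meta)
}

## two-condition single-lineage cohort with planted injury/control programs
scoring_cohort_config <- function(seed = 7, n = 800) {
  injury <- c("Havcr1", "Krt20", "Vcam1", "Nupr1", sprintf("Inj%02d", 5:50))
  healthy <- c("Slc34a1", "Acsm2", "Tmem27", "Slc27a2",
               sprintf("Hlth%02d", 5:50))
  cohort_config(
    conditions = list(Control = c(PT = 1), IRI = c(PT = 1)),
    cell_types = list(cell_type_spec("PT", sprintf("PTmk%02d", 1:20))),
    programs = list(Control = list(genes = healthy, fold_change = 3),
                    IRI = list(genes = injury, fold_change = 3)),
    n_cells_per_sample = n, samples_per_condition = 1,
    lowq_fraction = 0, doublet_fraction = 0, seed = seed)
}

injury_program_genes <- function()
  c("Havcr1", "Krt20", "Vcam1", "Nupr1", sprintf("Inj%02d", 5:50))

fibrotic_block_genes <- function()
  c("Gsdmd", "Nlrp3", "Casp1", "Casp4", "Il18", sprintf("Fib%02d", 6:60))

## three-cluster cohort with a planted ligand (cluster A) / receptor
## (cluster B) pair
lr_cohort_config <- function(seed = 9, n = 900) {
  cohort_config(
    conditions = list(One = c(A = 0.34, B = 0.33, C = 0.33)),
    cell_types = list(
      cell_type_spec("A", c("Cxcl2", sprintf("Amk%02d", 2:10)),
                     marker_fold_change = 8),
      cell_type_spec("B", c("Cxcr2", sprintf("Bmk%02d", 2:10)),
                     marker_fold_change = 8),
      cell_type_spec("C", sprintf("Cmk%02d", 1:10))),
    n_cells_per_sample = n, samples_per_condition = 1,
    lowq_fraction = 0, doublet_fraction = 0, n_genes = 600, seed = seed)
}

## O(n^3) triple-loop TOM oracle, independent of the matrix-product path
naive_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

## per-experiment rankings -> consensus PRLs for a generated drug screen
prls_from_screen <- function(tables) {
  lapply(tables, function(exps)
    merge_prl(lapply(exps, function(tb)
      ranking_from_effects(stats::setNames(tb$log2fc, tb$gene_id)))))
}
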