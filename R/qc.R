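#' Per-cell quality-control statistics
#'
#' Computes, for every cell, the number of detected genes (count > 0) and the
#' mitochondrial percentage `100 * mito counts / total counts`. Cells with
#' zero total counts get `mito_pct = 0`. The mitochondrial threshold is kept
#' permissive downstream because proximal tubule cells physiologically carry
#' high mitochondrial content.
#'
#' @param x a [cell_table()]
#' @param mito_gene_ids mitochondrial gene ids; default: all genes whose id
#'   starts with `mt-`
#' @return data frame (`barcode`, `n_genes_detected`, `mito_pct`,
#'   `is_doublet`); `is_doublet` is taken from metadata when present, else
#'   `FALSE`
#' @export
compute_cell_qc <- function(x, mito_gene_ids = NULL) {
  stopifnot(inherits(x, "cell_table"))
  genes <- rownames(x$counts)
  if (is.null(mito_gene_ids)) mito_gene_ids <- grep("^mt-", genes, value = TRUE)
  unknown <- setdiff(mito_gene_ids, genes)
  if (length(unknown))
    stop("unknown mito gene id(s): ", paste(unknown, collapse = ", "))
  tot <- Matrix::colSums(x$counts)
  mito <- if (length(mito_gene_ids))
    Matrix::colSums(x$counts[mito_gene_ids, , drop = FALSE]) else 0
  ndet <- Matrix::colSums(x$counts > 0)
  mito_pct <- ifelse(tot > 0, 100 * mito / tot, 0)
  is_db <- if ("is_doublet" %in% names(x$meta)) x$meta$is_doublet
           else rep(FALSE, ncol(x$counts))
  data.frame(barcode = colnames(x$counts),
             n_genes_detected = as.integer(ndet),
             mito_pct = as.numeric(mito_pct),
             is_doublet = is_db,
             row.names = colnames(x$counts), stringsAsFactors = FALSE)
}

#' Quality-control thresholds
#'
#' Defaults follow the strictly-inside convention: cells are retained when
#' `min_genes < n_genes_detected < max_genes` and `mito_pct <= max_mito_pct`,
#' so a cell at exactly 200 or 3000 detected genes is excluded while a cell
#' at exactly 50% mitochondrial reads is retained.
#'
#' @param min_genes lower bound on detected genes (exclusive; default 200)
#' @param max_genes upper bound on detected genes (exclusive; default 3000)
#' @param max_mito_pct mitochondrial percentage bound (inclusive; default 50)
#' @return a `qc_thresholds` list
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 3000,
                          max_mito_pct = 50) {
  if (min_genes >= max_genes) stop("min_genes must be < max_genes")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_pct = max_mito_pct), class = "qc_thresholds")
}

#' Filter cells on QC statistics
#'
#' @param qc data frame from [compute_cell_qc()]
#' @param thresholds a [qc_thresholds()]
#' @param drop_doublets also drop cells flagged `is_doublet`
#' @return character vector of retained barcodes
#' @export
filter_cells <- function(qc, thresholds = qc_thresholds(),
                         drop_doublets = TRUE) {
  keep <- qc$n_genes_detected > thresholds$min_genes &
    qc$n_genes_detected < thresholds$max_genes &
    qc$mito_pct <= thresholds$max_mito_pct
  if (drop_doublets) keep <- keep & !qc$is_doublet
  qc$barcode[keep]
}

#' Filter genes by minimum expression breadth
#'
#' Retains genes carried by at least `min_cells` cells with at least
#' `min_reads` counts each — the gene filter used upstream of trajectory-style
#' analyses.
#'
#' @param x a [cell_table()]
#' @param min_reads minimum counts per qualifying cell (default 3)
#' @param min_cells minimum number of qualifying cells (default 10)
#' @return character vector of retained gene ids
#' @export
filter_genes_min_expression <- function(x, min_reads = 3, min_cells = 10) {
  stopifnot(inherits(x, "cell_table"))
  n_ok <- Matrix::rowSums(x$counts >= min_reads)
  rownames(x$counts)[n_ok >= min_cells]
}

#' Stratified downsampling to equal cluster sizes
#'
#' Samples exactly `n_per_cluster` cells per cluster without replacement,
#' e.g. 150 cells from each of 11 proximal tubule subclusters to obtain a
#' balanced 1650-cell set for trajectory analysis.
#'
#' @param cluster_labels per-cell cluster labels, named by barcode (or a
#'   factor/character vector whose names default to element order)
#' @param n_per_cluster cells to keep per cluster
#' @param seed RNG seed
#' @return character vector of sampled barcodes
#' @export
stratified_downsample <- function(cluster_labels, n_per_cluster, seed = 1L) {
  if (is.null(names(cluster_labels)))
    stop("cluster_labels must be named by barcode")
  cl <- as.character(cluster_labels)
  sizes <- table(cl)
  small <- sizes[sizes < n_per_cluster]
  if (length(small))
    stop("cluster(s) smaller than n_per_cluster: ",
         paste(sprintf("%s (%d)", names(small), small), collapse = ", "))
  with_seed(seed, {
    unlist(lapply(sort(unique(cl)), function(k) {
      bc <- names(cluster_labels)[cl == k]
      sample(bc, n_per_cluster)
    }), use.names = FALSE)
  })
}
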