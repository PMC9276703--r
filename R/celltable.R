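#' Cell table: sparse counts plus per-cell metadata
#'
#' A `cell_table` bundles a sparse gene-by-cell UMI count matrix with a
#' per-cell metadata data frame. It is the substrate of every analysis stage
#' in the package: quality control, injury scoring, proportion testing,
#' coexpression and ligand-receptor analysis all consume a `cell_table`.
#'
#' @param counts gene-by-cell matrix of non-negative counts; coerced to
#'   `Matrix::dgCMatrix`. Must carry gene rownames and barcode colnames.
#' @param meta data frame with one row per cell, rownames matching the
#'   barcode colnames of `counts`. Typical columns: `sample`, `condition`,
#'   `timepoint`, `cell_type`, `cluster`, `is_doublet`, `is_lowq`.
#' @return An object of class `cell_table` with elements `counts` and `meta`.
#' @export
cell_table <- function(counts, meta = NULL) {
  counts <- if (inherits(counts, "Matrix"))
    methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  else Matrix::Matrix(as.matrix(counts) * 1, sparse = TRUE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and barcode colnames")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (is.null(meta)) {
    meta <- data.frame(row.names = colnames(counts))
  }
  if (!is.data.frame(meta)) stop("meta must be a data.frame")
  if (!identical(rownames(meta), colnames(counts)))
    stop("rownames(meta) must equal colnames(counts)")
  structure(list(counts = counts, meta = meta), class = "cell_table")
}

#' @method print cell_table
#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("cell_table: %d genes x %d cells, %d metadata columns\n",
              nrow(x$counts), ncol(x$counts), ncol(x$meta)))
  invisible(x)
}

#' @export
dim.cell_table <- function(x) dim(x$counts)

#' Subset a cell table by gene and/or cell
#'
#' @param x a `cell_table`
#' @param genes gene ids or indices to keep (default all)
#' @param cells barcodes or indices to keep (default all)
#' @return a `cell_table` restricted to the requested genes and cells
#' @export
subset_cells <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "cell_table"))
  if (is.null(genes)) genes <- seq_len(nrow(x$counts))
  if (is.null(cells)) cells <- seq_len(ncol(x$counts))
  cnt <- x$counts[genes, cells, drop = FALSE]
  if (is.character(cells)) {
    meta <- x$meta[cells, , drop = FALSE]
  } else {
    meta <- x$meta[cells, , drop = FALSE]
  }
  cell_table(cnt, meta)
}

#' Library-size log-normalization
#'
#' Scales each cell to a common library size and log-transforms:
#' `log1p(count / cell_total * scale_factor)`, the standard normalization
#' used before scoring, marker detection and coexpression analysis.
#' All-zero cells are left as zero columns.
#'
#' @param x a `cell_table` or a gene-by-cell matrix of counts
#' @param scale_factor target library size (default 1e4)
#' @return sparse gene-by-cell matrix of log-normalized expression
#' @export
lognormalize <- function(x, scale_factor = 1e4) {
  counts <- if (inherits(x, "cell_table")) x$counts else x
  tot <- Matrix::colSums(counts)
  sf <- ifelse(tot > 0, scale_factor / tot, 0)
  out <- counts %*% Matrix::Diagonal(x = sf)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  methods::as(out, "CsparseMatrix")
}

## Deterministic per-stage sub-seed: a stable polynomial hash of the stage
## name folded into the global seed, kept inside 32-bit integer range so it
## is a legal set.seed() argument everywhere.
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147480009
  as.integer((as.numeric(seed) %% 2147480009 + h) %% 2147480009)
}

## run code under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
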