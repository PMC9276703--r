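#' Write a cohort as MatrixMarket + TSV sidecars
#'
#' Writes `matrix.mtx` (gene x cell counts), `features.tsv`, `barcodes.tsv`
#' and `cell_metadata.tsv` (tab-delimited, header row, UTF-8) into `dir`.
#'
#' @param x a [cell_table()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cell_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  write_tsv(x$meta, file.path(dir, "cell_metadata.tsv"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` and optionally `cell_metadata.tsv`
#' @return a [cell_table()]
#' @export
read_cohort <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "features.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  meta_path <- file.path(dir, "cell_metadata.tsv")
  meta <- if (file.exists(meta_path)) {
    m <- read_tsv(meta_path)
    rownames(m) <- m$barcode
    m
  } else NULL
  cell_table(counts, meta)
}

#' Write a data frame as tab-delimited text with header
#'
#' @param df data frame
#' @param path output path
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' Read a tab-delimited file written by [write_tsv()]
#'
#' @param path input path
#' @return data frame
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "", comment.char = "")
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character gene sets
#' @param path output path
#' @param description per-set description column (recycled)
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' Read gene sets from a GMT file
#'
#' @param path input path
#' @return named list of character gene sets
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}
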