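#' Scoring configuration
#'
#' Parameters for condition-signature derivation and binned-control module
#' scoring. Defaults: top 100 most specific differentially expressed genes
#' per condition (detection in at least 5% of in-group cells, natural-log
#' fold change at least 0.2), 24 expression bins with 100 control genes
#' sampled per signature gene, and single-pass correlation pruning keeping
#' genes with mean within-set Pearson r >= `auto_r_min` and mean cross-set
#' r <= `cross_r_max`.
#'
#' @param n_top_degs signature size per condition (default 100)
#' @param n_bins number of mean-expression bins for control-gene matching
#' @param n_ctrl_per_gene control genes sampled per signature gene
#' @param min_pct minimum in-group detection fraction
#' @param logfc_threshold minimum absolute natural-log fold change
#' @param auto_r_min pruning floor on mean within-set correlation
#' @param cross_r_max pruning ceiling on mean cross-set correlation
#' @param margin classification margin between the two scores
#' @param seed RNG seed for control-gene sampling
#' @return a `score_config` list
#' @export
score_config <- function(n_top_degs = 100, n_bins = 24, n_ctrl_per_gene = 100,
                         min_pct = 0.05, logfc_threshold = 0.2,
                         auto_r_min = 0.1, cross_r_max = 0.0,
                         margin = 0, seed = 1L) {
  stopifnot(n_top_degs > 0, n_bins > 0, n_ctrl_per_gene > 0,
            min_pct > 0, min_pct < 1, logfc_threshold >= 0)
  structure(list(n_top_degs = as.integer(n_top_degs),
                 n_bins = as.integer(n_bins),
                 n_ctrl_per_gene = as.integer(n_ctrl_per_gene),
                 min_pct = min_pct, logfc_threshold = logfc_threshold,
                 auto_r_min = auto_r_min, cross_r_max = cross_r_max,
                 margin = margin, seed = as.integer(seed)),
            class = "score_config")
}

## vectorized two-sided Wilcoxon rank-sum p (normal approximation with tie
## correction, no continuity correction) for a genes-by-cells dense matrix
.ranksum_p <- function(mat, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  apply(mat, 1L, function(v) {
    r <- rank(v)
    U <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(1)
    z <- (U - n1 * n2 / 2) / sqrt(sig2)
    2 * stats::pnorm(-abs(z))
  })
}

## Seurat-dialect natural-log fold change on log-normalized expression
.log_fc <- function(expr, in_group) {
  m_in <- Matrix::rowMeans(expm1(expr[, in_group, drop = FALSE]))
  m_out <- Matrix::rowMeans(expm1(expr[, !in_group, drop = FALSE]))
  log((m_in + 1) / (m_out + 1))
}

#' Rank condition-specific differentially expressed genes
#'
#' For each condition (one versus rest), genes detected in at least
#' `min_pct` of in-group cells with absolute log fold change at least
#' `logfc_threshold` are ranked by two-sided Wilcoxon rank-sum p value,
#' ties broken by decreasing absolute log fold change, then gene id. By
#' default only upregulated genes are reported so that the per-condition
#' lists are usable directly as signatures.
#'
#' @param lognorm_expr gene-by-cell log-normalized matrix
#' @param condition_labels per-cell condition labels
#' @param config a [score_config()]
#' @param only_pos keep only genes upregulated in the condition (default
#'   `TRUE`)
#' @return named list: condition -> data frame (`gene`, `p`, `logfc`,
#'   `pct_in`, `pct_out`) of the top `n_top_degs` genes
#' @export
rank_condition_degs <- function(lognorm_expr, condition_labels,
                                config = score_config(), only_pos = TRUE) {
  condition_labels <- as.character(condition_labels)
  conds <- sort(unique(condition_labels))
  if (length(conds) < 2) stop("need >= 2 conditions")
  small <- names(which(table(condition_labels) < 2))
  if (length(small))
    stop("condition(s) with < 2 cells: ", paste(small, collapse = ", "))
  out <- list()
  for (cn in conds) {
    ing <- condition_labels == cn
    pct_in <- Matrix::rowMeans(lognorm_expr[, ing, drop = FALSE] > 0)
    pct_out <- Matrix::rowMeans(lognorm_expr[, !ing, drop = FALSE] > 0)
    lfc <- .log_fc(lognorm_expr, ing)
    cand <- pct_in >= config$min_pct & abs(lfc) >= config$logfc_threshold
    if (only_pos) cand <- cand & lfc > 0
    cand <- which(cand)
    if (!length(cand)) {
      out[[cn]] <- data.frame(gene = character(), p = numeric(),
                              logfc = numeric(), pct_in = numeric(),
                              pct_out = numeric())
      next
    }
    sub <- as.matrix(lognorm_expr[cand, , drop = FALSE])
    p <- .ranksum_p(sub, ing)
    df <- data.frame(gene = rownames(lognorm_expr)[cand], p = p,
                     logfc = lfc[cand], pct_in = pct_in[cand],
                     pct_out = pct_out[cand], stringsAsFactors = FALSE)
    df <- df[order(df$p, -abs(df$logfc), df$gene), , drop = FALSE]
    out[[cn]] <- utils::head(df, config$n_top_degs)
    rownames(out[[cn]]) <- NULL
  }
  out
}

#' Construct a condition signature object
#'
#' @param condition condition label
#' @param genes ordered gene ids (most specific first)
#' @return a `signature` list with empty pruning provenance
#' @export
new_signature <- function(condition, genes) {
  structure(list(condition = condition, genes_initial = genes,
                 genes_pruned = genes, prune_log = NULL),
            class = "signature")
}

#' Prune a pair of signatures by within/cross-set correlation
#'
#' Computed single-pass on the initial sets: a gene is kept iff its mean
#' Pearson correlation with the other genes of its own set is at least
#' `auto_r_min` and its mean correlation with the opposite set is at most
#' `cross_r_max`, enforcing high intra-set correlation and cross-set
#' anticorrelation. Zero-variance genes get r = 0 against everything.
#'
#' @param lognorm_expr gene-by-cell log-normalized matrix
#' @param sigA,sigB [new_signature()] objects
#' @param auto_r_min,cross_r_max pruning thresholds
#' @return list of the two pruned signatures with filled `prune_log`
#' @export
prune_signature_by_correlation <- function(lognorm_expr, sigA, sigB,
                                           auto_r_min = 0.1,
                                           cross_r_max = 0.0) {
  gA <- sigA$genes_initial; gB <- sigB$genes_initial
  if (!length(gA) || !length(gB)) stop("signatures must be non-empty")
  all_g <- c(gA, gB)
  missing <- setdiff(all_g, rownames(lognorm_expr))
  if (length(missing))
    stop("signature genes absent from matrix: ",
         paste(missing, collapse = ", "))
  mat <- t(as.matrix(lognorm_expr[all_g, , drop = FALSE]))
  cc <- suppressWarnings(stats::cor(mat))
  cc[!is.finite(cc)] <- 0
  prune_one <- function(sig, own, other) {
    auto <- vapply(own, function(g) {
      others <- setdiff(own, g)
      if (!length(others)) 1 else mean(cc[g, others])
    }, numeric(1))
    cross <- vapply(own, function(g) mean(cc[g, other]), numeric(1))
    kept <- auto >= auto_r_min & cross <= cross_r_max
    if (!any(kept))
      stop("pruning removed every gene of signature '", sig$condition,
           "'; relax auto_r_min/cross_r_max")
    sig$prune_log <- data.frame(gene = own, auto_r = auto, cross_r = cross,
                                kept = kept, stringsAsFactors = FALSE)
    sig$genes_pruned <- own[kept]
    sig
  }
  list(prune_one(sigA, gA, gB), prune_one(sigB, gB, gA))
}

#' Binned-control module score
#'
#' All genes are cut into `n_bins` equal-size bins by dataset-wide mean
#' expression; for each signature gene, `n_ctrl_per_gene` control genes are
#' sampled from its bin (with replacement when the bin is small). The score
#' of a cell is its mean expression over the signature minus its mean
#' expression over the pooled controls, so a cell expressing the signature
#' no higher than expression-matched background scores near zero.
#'
#' @param lognorm_expr gene-by-cell log-normalized matrix
#' @param gene_set signature gene ids
#' @param config a [score_config()] (uses `n_bins`, `n_ctrl_per_gene`, `seed`)
#' @return named per-cell numeric score
#' @export
module_score <- function(lognorm_expr, gene_set, config = score_config()) {
  if (!length(gene_set)) stop("gene_set must be non-empty")
  missing <- setdiff(gene_set, rownames(lognorm_expr))
  if (length(missing))
    stop("gene_set not in universe: ", paste(missing, collapse = ", "))
  G <- nrow(lognorm_expr)
  avg <- Matrix::rowMeans(lognorm_expr)
  bin <- ceiling(rank(avg, ties.method = "first") * config$n_bins / G)
  names(bin) <- rownames(lognorm_expr)
  ctrl <- with_seed(config$seed, {
    unlist(lapply(sort(unique(gene_set)), function(g) {
      pool <- names(bin)[bin == bin[g]]
      sample(pool, config$n_ctrl_per_gene,
             replace = length(pool) < config$n_ctrl_per_gene)
    }), use.names = FALSE)
  })
  set_mean <- Matrix::colMeans(lognorm_expr[gene_set, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(lognorm_expr[ctrl, , drop = FALSE])
  as.numeric(set_mean - ctrl_mean) |> stats::setNames(colnames(lognorm_expr))
}

#' Classify cells from a pair of opposing module scores
#'
#' A cell is called for the injured state when its injury score exceeds the
#' control score by more than `margin` and is positive; symmetrically for
#' the control state; otherwise `neither` (including exact ties and cells
#' with no positive score).
#'
#' @param iri_scores,control_scores aligned per-cell score vectors
#' @param margin required score separation (default 0)
#' @param labels labels used for the three calls
#' @return data frame (`barcode`, `iri_score`, `control_score`, `call`)
#' @export
classify_cells <- function(iri_scores, control_scores, margin = 0,
                           labels = c("IRI", "Control", "neither")) {
  if (length(iri_scores) != length(control_scores))
    stop("score vectors must be aligned")
  call <- rep(labels[3], length(iri_scores))
  call[iri_scores > control_scores + margin & iri_scores > 0] <- labels[1]
  call[control_scores > iri_scores + margin & control_scores > 0] <- labels[2]
  bc <- names(iri_scores)
  if (is.null(bc)) bc <- as.character(seq_along(iri_scores))
  data.frame(barcode = bc, iri_score = as.numeric(iri_scores),
             control_score = as.numeric(control_scores), call = call,
             row.names = bc, stringsAsFactors = FALSE)
}

#' Injury-score pipeline: signatures, pruning, scoring, classification
#'
#' Chains [rank_condition_degs()] on a two-condition labelling,
#' [prune_signature_by_correlation()], two [module_score()] passes and
#' [classify_cells()].
#'
#' @param lognorm_expr gene-by-cell log-normalized matrix
#' @param condition_labels per-cell labels with exactly two levels
#' @param config a [score_config()]
#' @param control_condition label of the uninjured condition; default: the
#'   level matching "control" case-insensitively, else the first level
#' @return list with `signatures` (pruned pair), `calls` (per-cell data
#'   frame) and `degs` (the ranked lists)
#' @export
iri_score_pipeline <- function(lognorm_expr, condition_labels,
                               config = score_config(),
                               control_condition = NULL) {
  condition_labels <- as.character(condition_labels)
  conds <- sort(unique(condition_labels))
  if (length(conds) != 2)
    stop("iri_score_pipeline expects exactly two conditions")
  if (is.null(control_condition)) {
    hit <- grep("control", conds, ignore.case = TRUE, value = TRUE)
    control_condition <- if (length(hit)) hit[1] else conds[1]
  }
  iri_condition <- setdiff(conds, control_condition)
  degs <- rank_condition_degs(lognorm_expr, condition_labels, config)
  sig_iri <- new_signature(iri_condition, degs[[iri_condition]]$gene)
  sig_ctl <- new_signature(control_condition, degs[[control_condition]]$gene)
  if (!length(sig_iri$genes_initial) || !length(sig_ctl$genes_initial)) {
    warning("no differential signal between conditions; all cells called ",
            "'neither'")
    zero <- stats::setNames(rep(0, ncol(lognorm_expr)),
                            colnames(lognorm_expr))
    calls <- classify_cells(zero, zero, config$margin,
                            labels = c(iri_condition, control_condition,
                                       "neither"))
    return(list(signatures = list(sig_iri, sig_ctl), calls = calls,
                degs = degs))
  }
  pruned <- prune_signature_by_correlation(lognorm_expr, sig_iri, sig_ctl,
                                           config$auto_r_min,
                                           config$cross_r_max)
  s_iri <- module_score(lognorm_expr, pruned[[1]]$genes_pruned, config)
  s_ctl <- module_score(lognorm_expr, pruned[[2]]$genes_pruned, config)
  calls <- classify_cells(s_iri, s_ctl, config$margin,
                          labels = c(iri_condition, control_condition,
                                     "neither"))
  list(signatures = pruned, calls = calls, degs = degs)
}

#' Mean per-cluster z score of a gene list
#'
#' Standardizes each gene across all cells (mean 0, sd 1) then averages the
#' z scores within each cluster — the enrichment summary used to project
#' bulk differentially expressed genes onto single-cell clusters.
#' Zero-variance genes get an all-zero row and are reported in the
#' `flagged_zero_variance` attribute.
#'
#' @param bulk_deg_genes gene ids to project
#' @param lognorm_expr gene-by-cell log-normalized matrix
#' @param cluster_labels per-cell cluster labels
#' @return gene-by-cluster matrix of mean z scores
#' @export
bulk_cluster_enrichment <- function(bulk_deg_genes, lognorm_expr,
                                    cluster_labels) {
  missing <- setdiff(bulk_deg_genes, rownames(lognorm_expr))
  if (length(missing))
    stop("genes absent from matrix: ", paste(missing, collapse = ", "))
  mat <- as.matrix(lognorm_expr[bulk_deg_genes, , drop = FALSE])
  mu <- rowMeans(mat)
  sd <- apply(mat, 1, stats::sd)
  flagged <- rownames(mat)[sd == 0]
  sd[sd == 0] <- 1
  z <- (mat - mu) / sd
  z[flagged, ] <- 0
  cl <- as.character(cluster_labels)
  res <- t(rowsum(t(z), cl) / as.vector(table(cl)[sort(unique(cl))]))
  attr(res, "flagged_zero_variance") <- flagged
  res
}
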