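#' Per-cluster expressed-gene gate
#'
#' A gene is considered expressed in a cluster when it is detected
#' (expression > 0) in strictly more than `min_frac` of that cluster's
#' cells — the gate applied to both ligands and receptors before any
#' interaction is scored.
#'
#' @param lognorm_expr gene-by-cell log-normalized matrix
#' @param cluster_labels per-cell cluster labels
#' @param min_frac detection-fraction gate (default 0.05)
#' @return named list: cluster -> character vector of expressed genes
#' @export
expression_gate <- function(lognorm_expr, cluster_labels, min_frac = 0.05) {
  cl <- as.character(cluster_labels)
  clusters <- sort(unique(cl))
  out <- lapply(clusters, function(k) {
    frac <- Matrix::rowMeans(lognorm_expr[, cl == k, drop = FALSE] > 0)
    rownames(lognorm_expr)[frac > min_frac]
  })
  stats::setNames(out, clusters)
}

## cluster mean expression for a set of genes: genes x clusters
.cluster_means <- function(mat, cl, clusters) {
  sapply(clusters, function(k)
    rowMeans(mat[, cl == k, drop = FALSE]))
}

#' Ligand-receptor interaction means per cluster pair
#'
#' For each (pair, sender, receiver) triple passing the expression gate in
#' both the sender (ligand) and receiver (receptor) cluster, the interaction
#' mean is the average of the ligand's mean expression in the sender and the
#' receptor's mean expression in the receiver. Gated-out triples are absent
#' from the result, not reported as zero.
#'
#' @param lognorm_expr gene-by-cell log-normalized matrix
#' @param cluster_labels per-cell cluster labels
#' @param pairs data frame with columns `ligand`, `receptor`
#' @param min_frac gate passed to [expression_gate()]
#' @return data frame (`ligand`, `receptor`, `sender`, `receiver`,
#'   `interaction_mean`)
#' @export
interaction_means <- function(lognorm_expr, cluster_labels, pairs,
                              min_frac = 0.05) {
  unknown <- setdiff(c(pairs$ligand, pairs$receptor), rownames(lognorm_expr))
  if (length(unknown))
    stop("pair gene(s) not in matrix: ", paste(unknown, collapse = ", "))
  cl <- as.character(cluster_labels)
  clusters <- sort(unique(cl))
  gate <- expression_gate(lognorm_expr, cl, min_frac)
  genes <- unique(c(pairs$ligand, pairs$receptor))
  mat <- as.matrix(lognorm_expr[genes, , drop = FALSE])
  mu <- .cluster_means(mat, cl, clusters)
  if (is.null(dim(mu)))
    mu <- matrix(mu, nrow = length(genes),
                 dimnames = list(genes, clusters))
  res <- list()
  for (i in seq_len(nrow(pairs))) {
    lg <- pairs$ligand[i]; rc <- pairs$receptor[i]
    for (s in clusters) for (r in clusters) {
      if (lg %in% gate[[s]] && rc %in% gate[[r]]) {
        res[[length(res) + 1L]] <- data.frame(
          ligand = lg, receptor = rc, sender = s, receiver = r,
          interaction_mean = (mu[lg, s] + mu[rc, r]) / 2,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(ligand = character(), receptor = character(),
                      sender = character(), receiver = character(),
                      interaction_mean = numeric()))
  do.call(rbind, res)
}

#' Permutation test for ligand-receptor interactions
#'
#' Builds the null by shuffling cluster labels over all cells each
#' iteration and recomputing the interaction means of all gated triples;
#' `p = (1 + #(null >= observed)) / (1 + n_iter)` per triple, adjusted
#' across all tested triples with Benjamini-Hochberg FDR. A triple is called
#' significant at `q < 0.05`.
#'
#' @param lognorm_expr gene-by-cell log-normalized matrix
#' @param cluster_labels per-cell cluster labels
#' @param pairs data frame with columns `ligand`, `receptor`
#' @param n_iter permutation iterations (default 1000)
#' @param min_frac expression gate (default 0.05)
#' @param seed RNG seed
#' @return data frame (`ligand`, `receptor`, `sender`, `receiver`,
#'   `interaction_mean`, `p`, `q`, `significant`)
#' @export
lr_permutation_test <- function(lognorm_expr, cluster_labels, pairs,
                                n_iter = 1000, min_frac = 0.05, seed = 1L) {
  cl <- as.character(cluster_labels)
  clusters <- sort(unique(cl))
  if (length(clusters) < 2) stop("need >= 2 clusters")
  obs <- interaction_means(lognorm_expr, cl, pairs, min_frac)
  if (!nrow(obs)) {
    obs$p <- numeric(); obs$q <- numeric(); obs$significant <- logical()
    return(obs)
  }
  genes <- unique(c(obs$ligand, obs$receptor))
  mat <- as.matrix(lognorm_expr[genes, , drop = FALSE])
  li <- match(obs$ligand, genes); ri <- match(obs$receptor, genes)
  si <- match(obs$sender, clusters); vi <- match(obs$receiver, clusters)
  exceed <- integer(nrow(obs))
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      pcl <- sample(cl)
      mu <- .cluster_means(mat, pcl, clusters)
      if (is.null(dim(mu)))
        mu <- matrix(mu, nrow = length(genes))
      nullm <- (mu[cbind(li, si)] + mu[cbind(ri, vi)]) / 2
      exceed <- exceed + (nullm >= obs$interaction_mean)
    }
  })
  obs$p <- (1 + exceed) / (1 + n_iter)
  obs$q <- stats::p.adjust(obs$p, method = "BH")
  obs$significant <- obs$q < 0.05
  obs
}
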