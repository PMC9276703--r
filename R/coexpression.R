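#' Coexpression network configuration
#'
#' @param beta soft-threshold power applied to the signed similarity
#'   (default 12, the usual signed-network convention)
#' @param min_module_size smallest allowed module (default 50 genes)
#' @param cut_correlation_threshold tree cut parameter: the dendrogram on
#'   1 - TOM is cut at height `1 - cut_correlation_threshold` (default 0.2)
#' @param merge_me_correlation modules whose eigengenes correlate above this
#'   are merged, iterated to a fixpoint (default 0.8)
#' @param signed use signed similarity (1 + r)/2; unsigned uses |r|
#' @return a `network_config` list
#' @export
network_config <- function(beta = 12, min_module_size = 50,
                           cut_correlation_threshold = 0.2,
                           merge_me_correlation = 0.8, signed = TRUE) {
  stopifnot(beta >= 1, min_module_size >= 2,
            cut_correlation_threshold >= -1, cut_correlation_threshold <= 1,
            merge_me_correlation >= -1, merge_me_correlation <= 1)
  structure(list(beta = beta, min_module_size = as.integer(min_module_size),
                 cut_correlation_threshold = cut_correlation_threshold,
                 merge_me_correlation = merge_me_correlation,
                 signed = isTRUE(signed)),
            class = "network_config")
}

## module label palette, assigned by decreasing module size
.module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta")

#' Build metacells by bootstrapped aggregation
#'
#' De-sparsifies single-cell expression before coexpression analysis: each
#' metacell is the mean log-normalized profile of `k` cells sampled with
#' replacement from one (cell type x group) stratum, so every metacell
#' inherits one cell type and one experimental group.
#'
#' @param x a [cell_table()]
#' @param k cells aggregated per metacell (default 20)
#' @param n_metacells_per_stratum metacells built per stratum (default 50)
#' @param cell_type_col,group_col metadata columns defining the strata
#' @param seed RNG seed
#' @return list with `expr` (gene x metacell matrix of mean log-normalized
#'   expression) and `provenance` (per-metacell data frame: `metacell`,
#'   `cell_type`, `group`, `k`, `members` semicolon-joined)
#' @export
build_metacells <- function(x, k = 20, n_metacells_per_stratum = 50,
                            cell_type_col = "cell_type",
                            group_col = "condition", seed = 1L) {
  stopifnot(inherits(x, "cell_table"), k >= 1, n_metacells_per_stratum >= 1)
  expr <- lognormalize(x)
  ct <- as.character(x$meta[[cell_type_col]])
  gr <- as.character(x$meta[[group_col]])
  strata <- unique(data.frame(ct = ct, gr = gr, stringsAsFactors = FALSE))
  strata <- strata[order(strata$ct, strata$gr), , drop = FALSE]
  with_seed(seed, {
    members <- list(); prov <- list()
    for (i in seq_len(nrow(strata))) {
      idx <- which(ct == strata$ct[i] & gr == strata$gr[i])
      if (!length(idx)) { warning("empty stratum skipped"); next }
      for (m in seq_len(n_metacells_per_stratum)) {
        mem <- sample(idx, k, replace = TRUE)
        members[[length(members) + 1L]] <- mem
        prov[[length(prov) + 1L]] <- data.frame(
          cell_type = strata$ct[i], group = strata$gr[i], k = k,
          members = paste(colnames(expr)[mem], collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
    ## one sparse weight matrix (cells x metacells) instead of a rowMeans
    ## pass per metacell; entries are membership multiplicities / k
    W <- Matrix::sparseMatrix(
      i = unlist(members),
      j = rep(seq_along(members), lengths(members)),
      x = 1 / k, dims = c(ncol(expr), length(members)))
    mat <- as.matrix(expr %*% W)
    provenance <- do.call(rbind, prov)
    provenance$metacell <- sprintf("mc%04d", seq_len(nrow(provenance)))
    colnames(mat) <- provenance$metacell
    rownames(mat) <- rownames(expr)
    list(expr = mat,
         provenance = provenance[, c("metacell", "cell_type", "group",
                                     "k", "members")])
  })
}

#' Signed soft-thresholded adjacency
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^beta` (signed) or `|cor|^beta`
#' (unsigned); the diagonal is 1. Genes with zero variance across metacells
#' are dropped with a warning.
#'
#' @param expr gene x metacell matrix (e.g. `build_metacells()$expr`)
#' @param config a [network_config()]
#' @return gene x gene adjacency matrix in `[0, 1]`
#' @export
signed_adjacency <- function(expr, config = network_config()) {
  if (ncol(expr) < 3) stop("need >= 3 metacells")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) dropped")
    expr <- expr[v > 0, , drop = FALSE]
  }
  cc <- stats::cor(t(expr))
  a <- if (config$signed) ((1 + cc) / 2)^config$beta else abs(cc)^config$beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj - 2 a_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with connectivity `k_i = sum_{u != i} a_iu` (unit diagonals assumed), the
#' neighborhood-sharing-corrected similarity used for module clustering.
#' The diagonal is set to 1.
#'
#' @param adjacency symmetric adjacency with unit diagonal
#' @return TOM of the same dimension
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  L <- a %*% a - diag(a) * a - t(a * diag(a)) + a
  k <- rowSums(a) - diag(a)
  mins <- outer(k, k, pmin)
  tom <- L / (mins + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect coexpression modules
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at height
#' `1 - cut_correlation_threshold`; clusters below `min_module_size` are
#' assigned to the unassigned "grey" pool; modules whose eigengenes (on
#' `expr`) correlate above `merge_me_correlation` are merged, iterating to a
#' fixpoint. Surviving modules get color labels ordered by decreasing size.
#'
#' @param tom topological overlap matrix with gene dimnames
#' @param expr gene x metacell expression used for eigengene-based merging
#' @param config a [network_config()]
#' @return named character vector: gene -> module color ("grey" =
#'   unassigned)
#' @export
detect_modules <- function(tom, expr, config = network_config()) {
  genes <- rownames(tom)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = 1 - config$cut_correlation_threshold)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= config$min_module_size]
  modules <- ifelse(cl %in% keep, as.character(cl), "grey")
  names(modules) <- genes
  if (all(modules == "grey")) {
    warning("no module reaches min_module_size; all genes unassigned")
    return(modules)
  }
  repeat {
    ids <- setdiff(unique(modules), "grey")
    if (length(ids) < 2) break
    mes <- module_eigengene(expr, modules)
    cc <- stats::cor(mes)
    diag(cc) <- 0
    if (max(cc) <= config$merge_me_correlation) break
    pair <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    a <- colnames(cc)[pair[2]]; b <- rownames(cc)[pair[1]]
    modules[modules == b] <- a
  }
  ids <- setdiff(unique(modules), "grey")
  ids <- ids[order(-as.vector(table(modules)[ids]), ids)]
  relabel <- stats::setNames(.module_colors[seq_along(ids)], ids)
  out <- ifelse(modules == "grey", "grey", relabel[modules])
  names(out) <- genes
  out
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized gene submatrix across metacells, scaled to unit variance and
#' sign-oriented so that the mean gene-eigengene correlation is positive.
#'
#' @param expr gene x metacell matrix
#' @param modules named gene -> module vector ("grey" excluded)
#' @return metacell x module matrix of eigengene scores
#' @export
module_eigengene <- function(expr, modules) {
  ids <- setdiff(unique(modules), "grey")
  if (!length(ids)) stop("no modules")
  mes <- sapply(sort(ids), function(m) {
    g <- names(modules)[modules == m]
    if (length(g) < 2) stop("module '", m, "' has < 2 genes")
    sub <- t(as.matrix(expr[g, , drop = FALSE]))   # metacells x genes
    sdv <- apply(sub, 2, stats::sd)
    if (any(sdv == 0)) stop("zero-variance gene in module '", m, "'")
    sub <- scale(sub)
    pc <- stats::prcomp(sub, center = FALSE, scale. = FALSE)$x[, 1]
    pc <- pc / stats::sd(pc)
    if (mean(stats::cor(sub, pc)) < 0) pc <- -pc
    pc
  })
  rownames(mes) <- colnames(expr)
  mes
}

#' Intra-modular connectivity (kME) and hub genes
#'
#' `kME[g, m] = cor(expression of g, eigengene of m)` across metacells. The
#' hub gene of a module is the member with the largest own-module kME (ties
#' broken by gene id). Grey genes keep kME columns but are never hubs.
#'
#' @param expr gene x metacell matrix
#' @param mes eigengene matrix from [module_eigengene()]
#' @param modules named gene -> module vector
#' @return list with `kme` (gene x module matrix) and `hubs` (named module ->
#'   gene)
#' @export
kme <- function(expr, mes, modules) {
  kk <- stats::cor(t(as.matrix(expr)), mes)
  hubs <- vapply(colnames(mes), function(m) {
    g <- names(modules)[modules == m]
    v <- kk[g, m]
    g[order(-v, g)][1]
  }, character(1))
  list(kme = kk, hubs = hubs)
}

#' Module specificity across experimental groups
#'
#' Mean eigengene per group per module, plus the point-biserial correlation
#' of each eigengene with each group indicator — the summary used to ask
#' which experimental arm a module tracks.
#'
#' @param mes eigengene matrix (metacell x module)
#' @param provenance metacell provenance with a `group` column (from
#'   [build_metacells()])
#' @return list with `group_means` (module x group) and `indicator_cor`
#'   (module x group point-biserial correlations)
#' @export
module_group_specificity <- function(mes, provenance) {
  gr <- as.character(provenance$group)
  groups <- sort(unique(gr))
  gm <- sapply(groups, function(g) colMeans(mes[gr == g, , drop = FALSE]))
  ic <- sapply(groups, function(g) {
    ind <- as.numeric(gr == g)
    apply(mes, 2, function(v) stats::cor(v, ind))
  })
  if (is.null(dim(gm))) {
    gm <- matrix(gm, ncol = length(groups),
                 dimnames = list(colnames(mes), groups))
    ic <- matrix(ic, ncol = length(groups),
                 dimnames = list(colnames(mes), groups))
  }
  list(group_means = gm, indicator_cor = ic)
}

#' Scale-free topology fit diagnostic
#'
#' R-squared of the log-log regression of the connectivity distribution for
#' a set of candidate powers, offered as a diagnostic for choosing `beta`
#' (never auto-selected).
#'
#' @param expr gene x metacell matrix
#' @param powers candidate soft powers
#' @param n_breaks histogram bins of the connectivity distribution
#' @param signed signed similarity as in [signed_adjacency()]
#' @return data frame (`power`, `rsq`, `mean_k`)
#' @export
scale_free_fit <- function(expr, powers = c(2, 4, 6, 8, 10, 12, 14),
                           n_breaks = 10, signed = TRUE) {
  cc <- stats::cor(t(as.matrix(expr)))
  sim <- if (signed) (1 + cc) / 2 else abs(cc)
  res <- lapply(powers, function(b) {
    a <- sim^b; diag(a) <- 0
    k <- rowSums(a)
    br <- cut(k, n_breaks)
    dk <- tapply(k, br, mean)
    pk <- as.vector(table(br)) / length(k)
    ok <- pk > 0 & !is.na(dk) & dk > 0
    fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
    data.frame(power = b, rsq = summary(fit)$r.squared, mean_k = mean(k))
  })
  do.call(rbind, res)
}

#' Full coexpression analysis on a metacell matrix
#'
#' Chains [signed_adjacency()], [topological_overlap()],
#' [detect_modules()], [module_eigengene()], [kme()] and
#' [module_group_specificity()].
#'
#' @param metacells output of [build_metacells()]
#' @param config a [network_config()]
#' @return a `coexpression_network` list: `adjacency`, `tom`, `modules`,
#'   `mes`, `kme`, `hubs`, `specificity`, `config`
#' @export
run_coexpression <- function(metacells, config = network_config()) {
  adj <- signed_adjacency(metacells$expr, config)
  expr <- metacells$expr[rownames(adj), , drop = FALSE]
  tom <- topological_overlap(adj)
  modules <- detect_modules(tom, expr, config)
  if (all(modules == "grey")) {
    return(structure(list(adjacency = adj, tom = tom, modules = modules,
                          mes = NULL, kme = NULL, hubs = NULL,
                          specificity = NULL, config = config),
                     class = "coexpression_network"))
  }
  mes <- module_eigengene(expr, modules)
  km <- kme(expr, mes, modules)
  spec <- module_group_specificity(mes, metacells$provenance)
  structure(list(adjacency = adj, tom = tom, modules = modules, mes = mes,
                 kme = km$kme, hubs = km$hubs, specificity = spec,
                 config = config),
            class = "coexpression_network")
}

#' @method print coexpression_network
#' @export
print.coexpression_network <- function(x, ...) {
  tab <- table(x$modules)
  cat(sprintf("coexpression_network: %d genes, %d modules (+grey)\n",
              length(x$modules), sum(names(tab) != "grey")))
  print(tab)
  invisible(x)
}
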