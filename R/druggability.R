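#' Weighted drug-effect ranking from treated/untreated replicate tables
#'
#' The per-gene drug effect is the weighted average, over paired replicates,
#' of the treated minus untreated fold-change difference:
#' `effect_g = sum_r w_r (treated_rg - untreated_rg) / sum_r w_r`. Genes are
#' ranked by decreasing effect (rank 1 = most upregulated), ties broken by
#' gene id.
#'
#' @param treated,untreated replicate-by-gene numeric matrices (or data
#'   frames) sharing the same gene columns
#' @param weights per-replicate weights, sum > 0 (default equal)
#' @return list with `effects` (named per-gene effect) and `ranking`
#'   (character vector, rank 1 first)
#' @export
drug_effect_ranking <- function(treated, untreated, weights = NULL) {
  treated <- as.matrix(treated); untreated <- as.matrix(untreated)
  if (!identical(colnames(treated), colnames(untreated)))
    stop("treated and untreated gene universes differ")
  if (nrow(treated) != nrow(untreated))
    stop("treated and untreated must have paired replicates")
  if (is.null(weights)) weights <- rep(1, nrow(treated))
  if (sum(weights) <= 0) stop("weights must sum > 0")
  d <- treated - untreated
  eff <- as.numeric(crossprod(d, weights)) / sum(weights)
  names(eff) <- colnames(treated)
  list(effects = eff, ranking = ranking_from_effects(eff))
}

#' Rank genes by a per-gene effect, ties by gene id
#'
#' @param effects named numeric vector of per-gene effects
#' @return character vector of gene ids, most upregulated first
#' @export
ranking_from_effects <- function(effects) {
  names(effects)[order(-effects, names(effects))]
}

#' Merge per-experiment rankings into a prototype ranked list (PRL)
#'
#' Hierarchical Borda merging: repeatedly merge the two most Spearman-
#' correlated rankings into one by summing their ranks and re-ranking (ties
#' by gene id) until a single consensus ranking remains. A single input is
#' returned unchanged; identical inputs are a fixpoint.
#'
#' @param rankings list of character rankings over the same gene universe
#' @return character consensus ranking (rank 1 first)
#' @export
merge_prl <- function(rankings) {
  if (!length(rankings)) stop("need >= 1 ranking")
  universe <- sort(rankings[[1]])
  for (r in rankings)
    if (!identical(sort(r), universe)) stop("inconsistent gene universes")
  ranks <- lapply(rankings, function(r) {
    stats::setNames(match(universe, r), universe)
  })
  while (length(ranks) > 1) {
    mat <- do.call(cbind, ranks)
    cc <- stats::cor(mat, method = "spearman")
    diag(cc) <- -Inf
    pair <- which(cc == max(cc), arr.ind = TRUE)
    i <- min(pair[1, ]); j <- max(pair[1, ])
    borda <- ranks[[i]] + ranks[[j]]
    merged <- stats::setNames(
      match(universe, universe[order(borda, universe)]), universe)
    ranks <- c(ranks[-c(i, j)], list(merged))
  }
  universe[order(ranks[[1]])]
}

## running-sum extremum of the weighted Kolmogorov-Smirnov statistic.
## pos: sorted 1-based hit positions; w: per-hit weights (>= 0); N: universe
## size. Returns the signed extremum and the index of the defining hit.
.running_es <- function(N, pos, w) {
  m <- length(pos)
  if (m == 0) stop("empty hit set")
  if (m >= N) stop("gene set must be a proper subset of the universe")
  sw <- sum(w)
  if (sw <= 0) w <- rep(1, m) else w <- w
  cw <- cumsum(w) / sum(w)
  miss <- (pos - seq_len(m)) / (N - m)
  top <- cw - miss
  bottom <- c(0, cw[-m]) - miss
  i_top <- which.max(top); i_bot <- which.min(bottom)
  if (top[i_top] >= -bottom[i_bot])
    list(es = as.numeric(top[i_top]), hit = i_top, positive = TRUE)
  else
    list(es = as.numeric(bottom[i_bot]), hit = i_bot, positive = FALSE)
}

.hit_weights <- function(ranking, pos, scores, weight_exponent) {
  if (is.null(scores) || weight_exponent == 0) return(rep(1, length(pos)))
  abs(scores[ranking[pos]])^weight_exponent
}

#' Pre-ranked gene set enrichment of one ranking
#'
#' Computes the weighted Kolmogorov-Smirnov running-sum enrichment score of
#' `gene_set` in `ranking`: hits increment by `|score|^p` (normalized over
#' hits; uniform when `scores` is `NULL` or `p = 0`), misses decrement by
#' `1/(N - |S|)`; ES is the signed extremum. The null distribution comes
#' from `n_perm` random gene sets of the same size (gene-label
#' permutations); `NES = ES / mean(|null ES| of the same sign)` and the
#' two-sided empirical p value uses the add-one estimator over all
#' permutations, `(1 + #(|null ES| >= |ES|)) / (1 + n_perm)`, so it is
#' uniform under the null, never zero, and floored at 1/1001 for 1000
#' permutations.
#'
#' @param ranking character gene ranking, rank 1 = most upregulated (or a
#'   PRL from [merge_prl()])
#' @param gene_set character gene set; must intersect the ranking
#' @param scores optional named per-gene ranking metric used for weighting
#' @param weight_exponent GSEA weighting exponent p (default 1; 0 gives the
#'   classic unweighted statistic)
#' @param n_perm permutation count (default 1000)
#' @param seed RNG seed
#' @return list (`es`, `nes`, `p`, `leading_edge`, `n_hits`)
#' @export
gsea_preranked <- function(ranking, gene_set, scores = NULL,
                           weight_exponent = 1, n_perm = 1000, seed = 1L) {
  N <- length(ranking)
  pos <- sort(match(intersect(gene_set, ranking), ranking))
  if (!length(pos)) stop("gene_set does not intersect the ranking")
  m <- length(pos)
  w <- .hit_weights(ranking, pos, scores, weight_exponent)
  res <- .running_es(N, pos, w)
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p2 <- sort(sample.int(N, m))
      .running_es(N, p2, .hit_weights(ranking, p2, scores,
                                      weight_exponent))$es
    }, numeric(1))
  })
  same <- if (res$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  nes <- if (length(same)) res$es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(null_es) >= abs(res$es))) / (1 + n_perm)
  le <- if (res$positive) ranking[pos[seq_len(res$hit)]]
        else ranking[pos[seq(res$hit, m)]]
  list(es = res$es, nes = nes, p = p, leading_edge = le, n_hits = m)
}

#' Leading-edge genes of an enrichment result
#'
#' For positive ES, the gene-set members at or before the running-sum
#' maximum; for negative ES, the members at or after the minimum.
#'
#' @param ranking character gene ranking
#' @param gene_set character gene set
#' @param es enrichment score whose sign selects the side
#' @param scores,weight_exponent weighting as in [gsea_preranked()]
#' @return character vector of leading-edge genes (subset of `gene_set`)
#' @export
leading_edge <- function(ranking, gene_set, es, scores = NULL,
                         weight_exponent = 1) {
  N <- length(ranking)
  pos <- sort(match(intersect(gene_set, ranking), ranking))
  if (!length(pos)) return(character())
  w <- .hit_weights(ranking, pos, scores, weight_exponent)
  m <- length(pos)
  cw <- cumsum(w / sum(w))
  miss <- (pos - seq_len(m)) / (N - m)
  if (es >= 0) {
    ranking[pos[seq_len(which.max(cw - miss))]]
  } else {
    ranking[pos[seq(which.min(c(0, cw[-m]) - miss), m)]]
  }
}

#' Screen drugs against a signature by pre-ranked GSEA
#'
#' Runs [gsea_preranked()] of the signature against every drug's prototype
#' ranked list, applies Bonferroni correction across drugs
#' (`p_bonferroni = min(1, p * n_drugs)`), and sorts by decreasing NES so
#' that drugs most strongly upregulating the signature rank first.
#'
#' @param prls named list: drug id -> character ranking
#' @param signature character gene set
#' @param scores optional per-drug named list of ranking metrics (or `NULL`)
#' @param weight_exponent GSEA weighting exponent
#' @param n_perm permutations per drug
#' @param seed global seed; each drug gets a derived sub-seed
#' @return data frame (`drug`, `es`, `nes`, `p`, `p_bonferroni`,
#'   `leading_edge` semicolon-joined), sorted by NES descending
#' @export
screen_drugs <- function(prls, signature, scores = NULL,
                         weight_exponent = 1, n_perm = 1000, seed = 1L) {
  if (!length(prls)) stop("need >= 1 PRL")
  if (is.null(names(prls))) names(prls) <- sprintf("drug%02d",
                                                   seq_along(prls))
  n_drugs <- length(prls)
  rows <- lapply(names(prls), function(d) {
    sc <- if (is.null(scores)) NULL else scores[[d]]
    g <- gsea_preranked(prls[[d]], signature, sc, weight_exponent, n_perm,
                        seed = derive_seed(seed, d))
    data.frame(drug = d, es = g$es, nes = g$nes, p = g$p,
               p_bonferroni = min(1, g$p * n_drugs),
               leading_edge = paste(g$leading_edge, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$nes, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Leading-edge occurrence across the top enriched drugs
#'
#' Binary occurrence of each signature gene in the leading edges of the
#' `top_k` highest-NES drugs, plus per-gene total frequency sorted
#' decreasingly — the summary used to ask which signature genes recur as
#' drivers of drug enrichment.
#'
#' @param results data frame from [screen_drugs()] (sorted by NES)
#' @param top_k number of top drugs to tally (default 24; clipped with a
#'   warning when fewer results exist)
#' @return list with `occurrence` (gene x drug binary matrix) and
#'   `frequency` (named, sorted decreasing)
#' @export
leading_edge_frequency <- function(results, top_k = 24) {
  if (!nrow(results)) stop("need >= 1 result")
  if (top_k > nrow(results)) {
    warning("top_k clipped to ", nrow(results), " results")
    top_k <- nrow(results)
  }
  top <- results[seq_len(top_k), , drop = FALSE]
  les <- strsplit(top$leading_edge, ";", fixed = TRUE)
  genes <- sort(unique(unlist(les)))
  occ <- vapply(les, function(le) as.integer(genes %in% le),
                integer(length(genes)))
  occ <- matrix(occ, nrow = length(genes),
                dimnames = list(genes, top$drug))
  freq <- sort(rowSums(occ), decreasing = TRUE)
  list(occurrence = occ, frequency = freq)
}
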