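#' Differential proportion analysis configuration
#'
#' @param w lower bound of the per-iteration subsample fraction, in (0, 1].
#'   Default 0.1; lower values make the test stricter (fewer significant
#'   clusters), higher values more liberal.
#' @param n_iter number of permutation iterations (default 100000)
#' @param seed RNG seed
#' @return a `dpa_config` list
#' @export
dpa_config <- function(w = 0.1, n_iter = 100000, seed = 1L) {
  stopifnot(w > 0, w <= 1, n_iter >= 100)
  structure(list(w = w, n_iter = as.integer(n_iter), seed = as.integer(seed)),
            class = "dpa_config")
}

#' Cluster-by-group proportion table
#'
#' @param cluster_labels per-cell cluster labels
#' @param group_labels per-cell group labels
#' @return list with `counts` (cluster x group) and `fractions`
#'   (column-normalized)
#' @export
proportion_table <- function(cluster_labels, group_labels) {
  if (length(cluster_labels) != length(group_labels))
    stop("labels must be aligned")
  counts <- table(cluster = as.character(cluster_labels),
                  group = as.character(group_labels))
  if (any(colSums(counts) == 0)) stop("empty group")
  fr <- sweep(counts, 2, colSums(counts), "/")
  list(counts = unclass(counts), fractions = unclass(fr))
}

#' Permutation test for differential cluster proportions
#'
#' Tests, per cluster, whether the difference in its cell fraction between
#' two groups exceeds what label exchange can produce. The null is built by
#' repeatedly drawing a subsample fraction f ~ Uniform(w, 1), shuffling the
#' cluster labels of ceil(f * n) randomly chosen cells across the pooled
#' groups, and recomputing the per-cluster fraction difference. Two-sided
#' empirical p values use the add-one estimator
#' `(1 + #(|null| >= |observed|)) / (1 + n_iter)` and can never be zero.
#'
#' @param cluster_labels per-cell cluster labels
#' @param group_labels per-cell group labels
#' @param groupA,groupB the two groups to compare
#' @param config a [dpa_config()]
#' @return data frame (`cluster`, `count_A`, `count_B`, `frac_A`, `frac_B`,
#'   `diff`, `p`), one row per cluster present in either group
#' @export
dpa_test <- function(cluster_labels, group_labels, groupA, groupB,
                     config = dpa_config()) {
  cl <- as.character(cluster_labels)
  gr <- as.character(group_labels)
  if (length(cl) != length(gr)) stop("labels must be aligned")
  if (!groupA %in% gr || !groupB %in% gr)
    stop("both groups must be present")
  clusters <- sort(unique(cl))
  absent <- vapply(clusters, function(k)
    !any(cl == k & (gr == groupA | gr == groupB)), logical(1))
  if (any(absent)) {
    warning("cluster(s) absent from both groups excluded: ",
            paste(clusters[absent], collapse = ", "))
    clusters <- clusters[!absent]
  }
  code <- match(cl, clusters)
  keep <- !is.na(code)
  code <- code[keep]; gr <- gr[keep]
  grp <- integer(length(gr))
  grp[gr == groupA] <- 1L
  grp[gr == groupB] <- 2L
  nA <- sum(grp == 1L); nB <- sum(grp == 2L)
  cntA <- tabulate(code[grp == 1L], length(clusters))
  cntB <- tabulate(code[grp == 2L], length(clusters))
  obs <- cntA / nA - cntB / nB
  exceed <- with_seed(config$seed,
    .dpa_null_count(code, grp, length(clusters), config$w,
                    config$n_iter, abs(obs)))
  data.frame(cluster = clusters, count_A = cntA, count_B = cntB,
             frac_A = cntA / nA, frac_B = cntB / nB, diff = obs,
             p = (1 + exceed) / (1 + config$n_iter),
             row.names = NULL, stringsAsFactors = FALSE)
}
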