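make_expr <- function(counts) lognormalize(cell_table(counts))

test_that("condition DEG ranking: separation, null exclusion, planted recovery", {
  set.seed(41)
  n <- 200
  genes <- c("sep", "null", sprintf("f%02d", 1:40))
  counts <- matrix(rpois(length(genes) * 2 * n, 5), length(genes),
                   dimnames = list(genes, paste0("c", seq_len(2 * n))))
  labels <- rep(c("A", "B"), each = n)
  counts["sep", labels == "B"] <- 0          # expressed only in A
  counts["sep", labels == "A"] <- rpois(n, 20)
  ## "null": identical distribution in both groups (left as is)
  expr <- make_expr(counts)
  degs <- rank_condition_degs(expr, labels, score_config())
  expect_equal(degs$A$gene[1], "sep")
  expect_false("null" %in% degs$A$gene)
  expect_false("null" %in% degs$B$gene)
  expect_error(rank_condition_degs(expr, c("A", rep("B", 2 * n - 1))),
               "< 2 cells")

  ## planted markers: >= 18/20 recovered in each top-100 list
  cfg <- cohort_config(
    conditions = list(G1 = c(T1 = 1), G2 = c(T2 = 1)),
    cell_types = list(
      cell_type_spec("T1", sprintf("M1_%02d", 1:20), marker_fold_change = 4),
      cell_type_spec("T2", sprintf("M2_%02d", 1:20), marker_fold_change = 4)),
    n_cells_per_sample = 300, samples_per_condition = 1,
    lowq_fraction = 0, doublet_fraction = 0, n_genes = 500, seed = 42)
  ct <- generate_cohort(cfg)
  degs <- rank_condition_degs(lognormalize(ct), ct$meta$condition)
  expect_gte(sum(sprintf("M1_%02d", 1:20) %in% degs$G1$gene), 18)
  expect_gte(sum(sprintf("M2_%02d", 1:20) %in% degs$G2$gene), 18)
})

test_that("rank-sum p values agree with stats::wilcox.test", {
  set.seed(7)
  v <- matrix(rpois(3 * 60, 3), nrow = 3)
  ing <- rep(c(TRUE, FALSE), c(25, 35))
  p <- screpair:::.ranksum_p(v, ing)
  for (i in 1:3) {
    ref <- stats::wilcox.test(v[i, ing], v[i, !ing], exact = FALSE,
                              correct = FALSE)$p.value
    expect_equal(p[i], ref, tolerance = 1e-10)
  }
})

test_that("correlation pruning keeps ideal blocks and drops noise genes", {
  set.seed(17)
  n <- 300
  base <- rnorm(n)
  ## two perfectly anticorrelated blocks plus one white-noise intruder
  A <- t(sapply(1:5, function(i) base + rnorm(n, sd = 0.1)))
  B <- t(sapply(1:5, function(i) -base + rnorm(n, sd = 0.1)))
  noise <- rnorm(n)
  mat <- rbind(A, noise, B)
  rownames(mat) <- c(paste0("a", 1:5), "noise", paste0("b", 1:5))
  colnames(mat) <- paste0("c", 1:n)
  sigA <- new_signature("A", c(paste0("a", 1:5), "noise"))
  sigB <- new_signature("B", paste0("b", 1:5))
  pr <- prune_signature_by_correlation(mat, sigA, sigB,
                                       auto_r_min = 0.1, cross_r_max = 0)
  expect_setequal(pr[[1]]$genes_pruned, paste0("a", 1:5))
  expect_setequal(pr[[2]]$genes_pruned, paste0("b", 1:5))
  ## prune log matches a brute-force mean-correlation computation
  cc <- cor(t(mat))
  auto_noise <- mean(cc["noise", paste0("a", 1:5)])
  log_row <- pr[[1]]$prune_log[pr[[1]]$prune_log$gene == "noise", ]
  expect_equal(log_row$auto_r, auto_noise, tolerance = 1e-12)
  expect_false(log_row$kept)
  ## vacuous thresholds: identity
  pr2 <- prune_signature_by_correlation(mat, sigA, sigB,
                                        auto_r_min = -1, cross_r_max = 1)
  expect_identical(pr2[[1]]$genes_pruned, sigA$genes_initial)
  ## pruning that empties a set errors with advice
  expect_error(prune_signature_by_correlation(mat, sigA, sigB,
                                              auto_r_min = 2,
                                              cross_r_max = -2),
               "relax")
})

test_that("module score: zero sets, analytic shift, seed stability, invariances", {
  ## bin-stable construction: genes constant within each of 10 expression
  ## tiers (value 10 * tier); one set gene per tier sits at tier + 1, which
  ## leaves its rank bin unchanged. Expected score per cell is then
  ## 1 - 1/24 (the set gene itself occupies 1 of the 24 slots of its bin's
  ## control pool).
  G <- 240; N <- 150
  tier <- rep(1:10, each = 24)
  vals <- 10 * tier
  base <- matrix(vals, G, N, dimnames = list(sprintf("g%03d", 1:G),
                                             sprintf("c%03d", 1:N)))
  set_genes <- sprintf("g%03d", seq(12, 240, by = 24))
  shifted <- base
  shifted[set_genes, ] <- shifted[set_genes, ] + 1
  sc <- module_score(shifted, set_genes, score_config(n_bins = 10, seed = 2))
  expect_equal(mean(sc), 1 - 1 / 24, tolerance = 0.05)
  expect_lt(sd(sc), 1e-12)

  ## all-zero expression: score exactly 0
  zeros <- matrix(0, G, 5, dimnames = list(rownames(base), paste0("z", 1:5)))
  expect_true(all(module_score(zeros, set_genes) == 0))

  ## gene-set permutation invariance
  sc2 <- module_score(shifted, rev(set_genes),
                      score_config(n_bins = 10, seed = 2))
  expect_equal(sc2, sc)

  ## appending all-zero cells: they score 0, others unchanged
  both <- cbind(shifted, zeros)
  sc3 <- module_score(both, set_genes, score_config(n_bins = 10, seed = 2))
  expect_true(all(sc3[colnames(zeros)] == 0))

  ## two seeds differ by < 0.05 RMS (control-sampling noise bound)
  sA <- module_score(shifted, set_genes, score_config(n_bins = 10, seed = 5))
  sB <- module_score(shifted, set_genes, score_config(n_bins = 10, seed = 6))
  expect_lt(sqrt(mean((sA - sB)^2)), 0.05)
  expect_error(module_score(shifted, character()), "non-empty")
})

test_that("classification rule is exhaustive, exclusive, and handles ties", {
  calls <- classify_cells(c(0.5, -0.1, 0.2, 0.3),
                          c(-0.2, -0.3, 0.2, 0.6))
  expect_equal(calls$call, c("IRI", "neither", "neither", "Control"))
  ## every cell gets exactly one of three calls under random scores
  set.seed(3)
  r <- classify_cells(rnorm(500), rnorm(500))
  expect_true(all(r$call %in% c("IRI", "Control", "neither")))
  expect_equal(nrow(r), 500)
  ## margin widens the neither zone
  m <- classify_cells(0.5, 0.45, margin = 0.1)
  expect_equal(m$call, "neither")
})

test_that("injury-score pipeline recovers planted programs; shuffled labels collapse", {
  ct <- generate_cohort(scoring_cohort_config(seed = 7, n = 700))
  expr <- lognormalize(ct)
  res <- iri_score_pipeline(expr, ct$meta$condition)
  truth <- ct$meta$condition
  sens <- mean(res$calls$call[truth == "IRI"] == "IRI")
  spec <- mean(res$calls$call[truth == "Control"] == "Control")
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
  ## signature captures the planted injury program
  iri_sig <- res$signatures[[which(vapply(res$signatures, `[[`, "",
                                          "condition") == "IRI")]]
  expect_gte(sum(injury_program_genes() %in% iri_sig$genes_initial), 40)

  ## identical rerun gives identical calls
  res2 <- iri_score_pipeline(expr, ct$meta$condition)
  expect_identical(res2$calls, res$calls)

  ## label shuffle: signature derivation finds no signal; calls collapse
  set.seed(99)
  shuffled <- sample(ct$meta$condition)
  res3 <- suppressWarnings(iri_score_pipeline(expr, shuffled))
  acc <- mean(res3$calls$call == shuffled)
  expect_lt(acc, 0.6)
})

test_that("bulk-DEG cluster z enrichment matches a dense two-step oracle", {
  ct <- rand_cell_table(n_genes = 40, n_cells = 250, seed = 29, lambda = 3)
  expr <- lognormalize(ct)
  cl <- ct$meta$cluster
  genes <- rownames(expr)[6:15]
  z <- bulk_cluster_enrichment(genes, expr, cl)
  ## dense oracle: scale each gene, then average per cluster
  dense <- as.matrix(expr[genes, ])
  zz <- t(scale(t(dense)))
  for (k in sort(unique(cl)))
    expect_equal(z[, k], rowMeans(zz[, cl == k]),
                 tolerance = 1e-8, ignore_attr = TRUE)

  ## weighted mean of each row by cluster sizes is ~ 0 (z conservation)
  sizes <- table(cl)[colnames(z)]
  expect_lt(max(abs(as.matrix(z) %*% as.numeric(sizes) / sum(sizes))), 1e-9)

  ## a gene expressed only in cluster c2 peaks there
  counts <- as.matrix(ct$counts)
  counts["g010", ] <- 0
  counts["g010", cl == "c2"] <- 5
  z2 <- bulk_cluster_enrichment("g010", lognormalize(cell_table(counts,
                                                                ct$meta)),
                                cl)
  expect_equal(colnames(z2)[which.max(z2)], "c2")

  ## zero-variance gene: all-zero row, flagged
  counts["g011", ] <- 0
  z3 <- bulk_cluster_enrichment(c("g010", "g011"),
                                lognormalize(cell_table(counts, ct$meta)),
                                cl)
  expect_true(all(z3["g011", ] == 0))
  expect_true("g011" %in% attr(z3, "flagged_zero_variance"))
})
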