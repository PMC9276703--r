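test_that("metacell construction: k = 1, constant strata, variance reduction", {
  ct <- rand_cell_table(n_genes = 30, n_cells = 120, seed = 3, lambda = 4)
  ct$meta$cell_type <- rep(c("T1", "T2"), each = 60)
  ct$meta$condition <- rep(c("g1", "g2"), 60)
  expr <- lognormalize(ct)

  ## k = 1: metacells are resampled single cells
  mc1 <- build_metacells(ct, k = 1, n_metacells_per_stratum = 10, seed = 5)
  members <- mc1$provenance$members
  for (i in c(1, 11, 25))
    expect_equal(mc1$expr[, i], as.numeric(expr[, members[i]]),
                 ignore_attr = TRUE)
  expect_true(all(mc1$provenance$k == 1))

  ## a stratum of identical cells gives back exactly that profile
  counts <- matrix(rep(c(3, 0, 7, 1, 2), 8), nrow = 5,
                   dimnames = list(paste0("g", 1:5), paste0("c", 1:8)))
  ident <- cell_table(counts, data.frame(
    cell_type = rep("T", 8), condition = rep("g", 8),
    row.names = colnames(counts)))
  mcI <- build_metacells(ident, k = 4, n_metacells_per_stratum = 3, seed = 1)
  prof <- as.numeric(lognormalize(ident)[, 1])
  for (j in 1:3) expect_equal(mcI$expr[, j], prof, ignore_attr = TRUE)

  ## averaging k = 20 cells shrinks gene-wise variance
  mc20 <- build_metacells(ct, k = 20, n_metacells_per_stratum = 30, seed = 5)
  v_cell <- apply(as.matrix(expr), 1, var)
  v_meta <- apply(mc20$expr, 1, var)
  expect_lt(mean(v_meta), mean(v_cell) / 2)

  ## every metacell inherits one cell type and one group
  expect_true(all(mc20$provenance$cell_type %in% c("T1", "T2")))
  expect_identical(build_metacells(ct, k = 20, n_metacells_per_stratum = 30,
                                   seed = 5)$expr, mc20$expr)
})

test_that("signed adjacency: endpoints, soft power arithmetic, dense oracle", {
  set.seed(7)
  n <- 40
  base <- rnorm(n)
  expr <- rbind(up = base, same = base, down = -base,
                matrix(rnorm(20 * n), 20))
  rownames(expr) <- c("up", "same", "down", paste0("r", 1:20))
  colnames(expr) <- paste0("m", 1:n)
  a <- signed_adjacency(expr, network_config(beta = 12))
  expect_equal(a["up", "same"], 1)            # cor +1 -> 1 at any beta
  expect_equal(a["up", "down"], 0)            # cor -1 -> 0
  expect_equal(unname(diag(a)), rep(1, nrow(a)))
  ## cor 0 at beta 12 -> 0.5^12
  expect_equal(((1 + 0) / 2)^12, 2.44140625e-4)
  ## dense brute-force: cor then power
  cc <- cor(t(expr))
  oracle <- ((1 + cc) / 2)^12; diag(oracle) <- 1
  expect_lt(max(abs(a - oracle)), 1e-10)
  ## symmetry and range
  expect_lt(max(abs(a - t(a))), 1e-12)
  expect_true(all(a >= 0 & a <= 1))
  expect_error(signed_adjacency(expr[, 1:2]), ">= 3")
  expect_warning(signed_adjacency(rbind(expr, flat = rep(1, n))), "zero-variance")
})

test_that("topological overlap matches closed forms and a naive cubic oracle", {
  ## diagonal-only adjacency: off-diagonal TOM is 0
  d <- diag(4); dimnames(d) <- list(paste0("g", 1:4), paste0("g", 1:4))
  tom <- topological_overlap(d)
  expect_true(all(tom[upper.tri(tom)] == 0))
  expect_equal(unname(diag(tom)), rep(1, 4))

  ## 3-node all-equal off-diagonal a: TOM_12 = (a^2 + a) / (a + 1)
  for (aval in c(0.2, 0.5, 0.9)) {
    m <- matrix(aval, 3, 3); diag(m) <- 1
    dimnames(m) <- list(paste0("g", 1:3), paste0("g", 1:3))
    tom <- topological_overlap(m)
    expect_equal(tom[1, 2], (aval^2 + aval) / (2 * aval + 1 - aval),
                 tolerance = 1e-12)
  }

  ## 30-gene random adjacency vs O(n^3) triple-loop oracle
  set.seed(11)
  r <- matrix(runif(30 * 30), 30)
  a <- (r + t(r)) / 2; diag(a) <- 1
  dimnames(a) <- list(sprintf("g%02d", 1:30), sprintf("g%02d", 1:30))
  tom <- topological_overlap(a)
  expect_lt(max(abs(tom - naive_tom(a))), 1e-10)
  expect_lt(max(abs(tom - t(tom))), 1e-12)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
})

## correlated block generator: n_genes rows sharing a latent factor
.block <- function(n_genes, latent, noise = 0.3, prefix = "b") {
  m <- t(sapply(seq_len(n_genes), function(i)
    latent + rnorm(length(latent), sd = noise)))
  rownames(m) <- paste0(prefix, sprintf("%02d", seq_len(n_genes)))
  m
}

test_that("module detection recovers planted blocks, applies size and merge rules", {
  set.seed(13)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  expr <- rbind(.block(60, f1, prefix = "A"),
                .block(60, f2, prefix = "B"),
                matrix(rnorm(80 * n), 80,
                       dimnames = list(paste0("noise", 1:80), NULL)))
  colnames(expr) <- paste0("m", 1:n)
  cfg <- network_config(beta = 6, min_module_size = 50)
  tom <- topological_overlap(signed_adjacency(expr, cfg))
  mods <- detect_modules(tom, expr, cfg)
  ## exactly two non-grey modules recovering >= 90% of planted members
  ids <- setdiff(unique(mods), "grey")
  expect_length(ids, 2)
  mA <- names(which.max(table(mods[paste0("A", sprintf("%02d", 1:60))])))
  mB <- names(which.max(table(mods[paste0("B", sprintf("%02d", 1:60))])))
  expect_false(mA == "grey" || mB == "grey")
  expect_false(mA == mB)
  expect_gte(mean(mods[paste0("A", sprintf("%02d", 1:60))] == mA), 0.9)
  expect_gte(mean(mods[paste0("B", sprintf("%02d", 1:60))] == mB), 0.9)
  ## labels ordered by size from the fixed palette
  expect_true(all(ids %in% c("turquoise", "blue")))

  ## a 30-gene block is below min size -> grey
  expr2 <- rbind(.block(30, f1, prefix = "S"),
                 matrix(rnorm(120 * n), 120,
                        dimnames = list(paste0("noise", 1:120), NULL)))
  colnames(expr2) <- paste0("m", 1:n)
  tom2 <- topological_overlap(signed_adjacency(expr2, cfg))
  mods2 <- suppressWarnings(detect_modules(tom2, expr2, cfg))
  expect_true(all(mods2[paste0("S", sprintf("%02d", 1:30))] == "grey"))

  ## two blocks with strongly correlated latents are merged (> 0.8 rule)
  f3 <- f1 + rnorm(n, sd = 0.15)              # cor(f1, f3) ~ 0.95
  expr3 <- rbind(.block(60, f1, noise = 0.2, prefix = "A"),
                 .block(60, f3, noise = 0.2, prefix = "C"),
                 matrix(rnorm(60 * n), 60,
                        dimnames = list(paste0("noise", 1:60), NULL)))
  colnames(expr3) <- paste0("m", 1:n)
  tom3 <- topological_overlap(signed_adjacency(expr3, cfg))
  mods3 <- detect_modules(tom3, expr3, cfg)
  blockmods <- unique(mods3[c(paste0("A", sprintf("%02d", 1:60)),
                              paste0("C", sprintf("%02d", 1:60)))])
  expect_length(setdiff(blockmods, "grey"), 1)
})

test_that("module eigengenes: unit variance, identical-gene module, SVD oracle", {
  set.seed(17)
  n <- 50
  common <- rnorm(n)
  expr <- rbind(t(sapply(1:6, function(i) common * 2 + 5)),
                .block(10, rnorm(n), prefix = "r"))
  rownames(expr)[1:6] <- paste0("same", 1:6)
  ## add tiny jitter so genes are not exactly constant multiples
  expr[1:6, ] <- expr[1:6, ] + rnorm(6 * n, sd = 1e-6)
  colnames(expr) <- paste0("m", 1:n)
  mods <- setNames(c(rep("black", 6), rep("red", 10)), rownames(expr))
  mes <- module_eigengene(expr, mods)
  expect_equal(apply(mes, 2, sd), c(black = 1, red = 1), tolerance = 1e-9)
  ## identical-profile module: ME correlates r ~ 1 with each member
  expect_gt(min(cor(t(expr[1:6, ]), mes[, "black"])), 0.999)
  ## SVD-based dense oracle up to sign
  sub <- scale(t(expr[7:16, ]))
  sv <- svd(sub)
  pc <- sv$u[, 1] * sv$d[1]
  pc <- pc / sd(pc)
  agree <- abs(cor(pc, mes[, "red"]))
  expect_gt(agree, 1 - 1e-8)
  ## eigengene scores are centered
  expect_lt(max(abs(colMeans(mes))), 1e-9)
  expect_error(module_eigengene(expr, setNames(rep("solo", 1),
                                               rownames(expr)[1])))
})

test_that("kME and hubs: self-correlation, bounds, null magnitude", {
  set.seed(19)
  n <- 200
  latent <- rnorm(n)
  expr <- rbind(.block(8, latent, noise = 0.2, prefix = "h"),
                matrix(rnorm(12 * n), 12,
                       dimnames = list(paste0("nz", 1:12), NULL)))
  colnames(expr) <- paste0("m", 1:n)
  mods <- setNames(c(rep("blue", 8), rep("grey", 12)), rownames(expr))
  mes <- module_eigengene(expr, mods)
  km <- kme(expr, mes, mods)
  expect_true(all(km$kme >= -1 & km$kme <= 1))
  ## a gene nearly identical to its ME has kME ~ 1
  expect_gt(max(km$kme[paste0("h", sprintf("%02d", 1:8)), "blue"]), 0.95)
  ## noise genes against the ME: |kME| below the 3/sqrt(n) null bound
  expect_lt(max(abs(km$kme[paste0("nz", 1:12), "blue"])), 3 / sqrt(n))
  ## hub comes from the module's own members
  expect_true(km$hubs[["blue"]] %in% paste0("h", sprintf("%02d", 1:8)))
})

test_that("group specificity: planted group-specific module tracks its group", {
  set.seed(23)
  groups <- rep(c("g1", "g2"), each = 30)
  latent <- ifelse(groups == "g2", 2, -2) + rnorm(60, sd = 0.3)
  expr <- rbind(.block(6, latent, noise = 0.3, prefix = "s"),
                .block(6, rnorm(60), prefix = "r"))
  colnames(expr) <- paste0("m", 1:60)
  mods <- setNames(c(rep("black", 6), rep("grey", 6)), rownames(expr))
  mes <- module_eigengene(expr, mods)
  prov <- data.frame(metacell = colnames(expr), group = groups)
  spec <- module_group_specificity(mes, prov)
  expect_equal(names(which.max(spec$group_means["black", ])), "g2")
  expect_gt(abs(spec$indicator_cor["black", "g2"]), 0.8)
  ## group-size-weighted mean of group means equals overall mean ~ 0
  w <- table(groups)[colnames(spec$group_means)]
  expect_lt(abs(sum(spec$group_means["black", ] * w) / sum(w)), 1e-9)
})

test_that("network results are invariant to gene-order permutation", {
  set.seed(29)
  n <- 40
  expr <- rbind(.block(55, rnorm(n), prefix = "A"),
                matrix(rnorm(30 * n), 30,
                       dimnames = list(paste0("z", 1:30), NULL)))
  colnames(expr) <- paste0("m", 1:n)
  cfg <- network_config(beta = 6, min_module_size = 40)
  run <- function(e) {
    tom <- topological_overlap(signed_adjacency(e, cfg))
    detect_modules(tom, e, cfg)
  }
  m1 <- run(expr)
  perm <- sample(nrow(expr))
  m2 <- run(expr[perm, ])
  expect_identical(m1[rownames(expr)], m2[rownames(expr)])
})
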