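#' Cell type specification for the synthetic cohort generator
#'
#' @param name cell-type label
#' @param marker_genes character vector of marker gene ids (must belong to the
#'   cohort gene universe)
#' @param marker_fold_change fold change (> 1) applied to marker genes in this
#'   cell type relative to the shared baseline profile
#' @param maladaptive if `TRUE`, the cohort's inflammatory gene block is
#'   additionally upregulated in this type (the profibrotic phenotype)
#' @return a `cell_type_spec` list
#' @export
cell_type_spec <- function(name, marker_genes = character(),
                           marker_fold_change = 4, maladaptive = FALSE) {
  if (length(marker_genes) && marker_fold_change <= 1)
    stop("marker_fold_change must be > 1")
  structure(list(name = name, marker_genes = marker_genes,
                 marker_fold_change = marker_fold_change,
                 maladaptive = isTRUE(maladaptive)),
            class = "cell_type_spec")
}

#' Configuration of a synthetic single-cell injury cohort
#'
#' Defines a multi-condition cohort with known ground truth: per-condition
#' cell-type composition, cell-type marker blocks, condition-wide response
#' programs (e.g. an injury program expressed by every cell of the injured
#' conditions), an inflammatory block for maladaptive cells, a reserved
#' mitochondrial gene block (ids prefixed `mt-`), planted low-quality cells
#' and doublets. Counts are negative binomial with log-normal cell library
#' sizes.
#'
#' @param conditions named list: condition label -> named numeric vector of
#'   cell-type proportions (must sum to 1)
#' @param cell_types list of [cell_type_spec()] objects
#' @param programs named list: condition label -> list(genes, fold_change);
#'   `fold_change` is a scalar or per-gene vector (> 1), applied to every cell
#'   of that condition regardless of type
#' @param n_cells_per_sample cells drawn per sample
#' @param samples_per_condition biological replicates per condition
#' @param timepoints named list: condition -> timepoint labels recycled over
#'   that condition's samples
#' @param n_genes total gene universe size (including mito block)
#' @param mito_gene_count number of reserved `mt-` genes
#' @param mito_target_frac expected mitochondrial fraction of a healthy cell
#' @param library_size_mean,library_size_sdlog mean and log-sd of the
#'   log-normal cell library-size distribution
#' @param nb_dispersion negative-binomial dispersion (1/size) shared by genes
#' @param baseline_sdlog log-sd of the log-normal baseline gene abundances
#' @param inflammatory_genes gene ids upregulated in maladaptive cell types
#' @param inflammatory_fold_change fold change of the inflammatory block
#' @param lowq_fraction fraction of cells planted as low quality (shallow
#'   depth or high mitochondrial content)
#' @param doublet_fraction fraction of cells planted as doublets
#' @param genes optional explicit gene universe; autogenerated when `NULL`
#' @param seed integer RNG seed; all randomness of [generate_cohort()] flows
#'   from it
#' @return a validated `cohort_config` list
#' @export
cohort_config <- function(conditions, cell_types, programs = list(),
                          n_cells_per_sample = 1000,
                          samples_per_condition = 2,
                          timepoints = NULL,
                          n_genes = 2000, mito_gene_count = 13,
                          mito_target_frac = 0.12,
                          library_size_mean = 5000,
                          library_size_sdlog = 0.35,
                          nb_dispersion = 0.4,
                          baseline_sdlog = 1,
                          inflammatory_genes = character(),
                          inflammatory_fold_change = 6,
                          lowq_fraction = 0.05,
                          doublet_fraction = 0.05,
                          genes = NULL,
                          seed = 1L) {
  if (!length(conditions) || is.null(names(conditions)))
    stop("conditions must be a named list of proportion vectors")
  type_names <- vapply(cell_types, function(s) s$name, character(1))
  if (anyDuplicated(type_names)) stop("duplicate cell type names")
  for (cn in names(conditions)) {
    p <- conditions[[cn]]
    if (is.null(names(p)) || !all(names(p) %in% type_names))
      stop("proportion vector of condition '", cn,
           "' must be named by cell types")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("proportions of condition '", cn, "' must be >= 0 and sum to 1")
  }
  stopifnot(n_cells_per_sample > 0, samples_per_condition > 0,
            n_genes > 0, mito_gene_count >= 0, mito_gene_count < n_genes,
            library_size_mean >= 0, library_size_sdlog >= 0,
            nb_dispersion > 0,
            lowq_fraction >= 0, lowq_fraction < 1,
            doublet_fraction >= 0, doublet_fraction < 1)
  for (pg in programs) {
    fc <- pg$fold_change
    if (any(fc <= 1)) stop("program fold changes must be > 1")
    if (!(length(fc) %in% c(1L, length(pg$genes))))
      stop("program fold_change must be scalar or per-gene")
  }
  mito_genes <- if (mito_gene_count > 0)
    paste0("mt-", seq_len(mito_gene_count)) else character()
  named <- unique(c(unlist(lapply(cell_types, `[[`, "marker_genes")),
                    unlist(lapply(programs, `[[`, "genes")),
                    inflammatory_genes))
  if (is.null(genes)) {
    n_fill <- n_genes - mito_gene_count - length(named)
    if (n_fill < 0) stop("n_genes too small for the named gene blocks")
    fill <- sprintf("g%04d", seq_len(n_fill + length(named)))
    fill <- setdiff(fill, named)[seq_len(n_fill)]
    genes <- c(mito_genes, named, fill)
  } else {
    if (length(genes) != n_genes) stop("length(genes) must equal n_genes")
    if (!all(mito_genes %in% genes)) stop("gene universe lacks mito block")
    missing <- setdiff(named, genes)
    if (length(missing))
      stop("genes not in universe: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(genes)) stop("duplicate gene ids in universe")
  structure(list(conditions = conditions, cell_types = cell_types,
                 programs = programs,
                 n_cells_per_sample = as.integer(n_cells_per_sample),
                 samples_per_condition = as.integer(samples_per_condition),
                 timepoints = timepoints,
                 n_genes = as.integer(n_genes),
                 mito_gene_count = as.integer(mito_gene_count),
                 mito_target_frac = mito_target_frac,
                 library_size_mean = library_size_mean,
                 library_size_sdlog = library_size_sdlog,
                 nb_dispersion = nb_dispersion,
                 baseline_sdlog = baseline_sdlog,
                 inflammatory_genes = inflammatory_genes,
                 inflammatory_fold_change = inflammatory_fold_change,
                 lowq_fraction = lowq_fraction,
                 doublet_fraction = doublet_fraction,
                 genes = genes, mito_genes = mito_genes,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Reference cohort emulating graded ischemia-reperfusion injury
#'
#' Three conditions (Control, short and long ischemia) with immune-cell
#' expansion (10/45/66% of cells) and proximal tubule depletion (54/12/8%),
#' a maladaptive proximal tubule type upregulating an inflammatory chemokine
#' block, a condition-wide injury program shared by both injured arms, a
#' healthy/repair program in controls, and a fibrosis program restricted to
#' the long-ischemia arm whose first five genes (pyroptosis executioners and
#' sensors) carry a boosted fold change and act as designated hub genes.
#'
#' @param seed RNG seed
#' @param n_cells_per_sample cells per sample (default 1000; 2 samples per
#'   condition)
#' @return a `cohort_config`
#' @export
default_cohort_config <- function(seed = 1L, n_cells_per_sample = 1000) {
  inflammatory <- c("Il1b", "Cxcl2", "Ccl3", "Tyrobp", "C3",
                    sprintf("Infl%02d", 6:20))
  injury <- c("Havcr1", "Krt20", "Vcam1", "Nupr1",
              sprintf("Inj%02d", 5:50))
  healthy <- c("Slc34a1", "Acsm2", "Tmem27", "Slc27a2",
               sprintf("Hlth%02d", 5:50))
  fib_hubs <- c("Gsdmd", "Nlrp3", "Casp1", "Casp4", "Il18")
  fibrotic <- c(fib_hubs, sprintf("Fib%02d", 6:60))
  cts <- list(
    cell_type_spec("PT", c("Slc5a2", "Slc5a12", "Gatm", "Slc22a30",
                           "Atp11a", "Inmt", sprintf("PTmk%02d", 7:20))),
    cell_type_spec("PT_maladaptive",
                   c("Krt20mal", sprintf("Malmk%02d", 2:10)),
                   maladaptive = TRUE),
    cell_type_spec("Immune", c("Ptprc", "Cd3e", "Lyz2", "Itgam",
                               sprintf("Immk%02d", 5:20))),
    cell_type_spec("Endo", c("Pecam1", "Emcn", sprintf("Endmk%02d", 3:12))),
    cell_type_spec("Stromal", c("Col1a1", "Col3a1", "Fn1", "Tgfb1",
                                sprintf("Stmk%02d", 5:12)))
  )
  conds <- list(
    Control   = c(PT = 0.54, PT_maladaptive = 0.00, Immune = 0.10,
                  Endo = 0.20, Stromal = 0.16),
    IRI_short = c(PT = 0.12, PT_maladaptive = 0.03, Immune = 0.45,
                  Endo = 0.22, Stromal = 0.18),
    IRI_long  = c(PT = 0.08, PT_maladaptive = 0.12, Immune = 0.66,
                  Endo = 0.08, Stromal = 0.06)
  )
  programs <- list(
    Control   = list(genes = healthy, fold_change = 3),
    IRI_short = list(genes = injury, fold_change = 3),
    IRI_long  = list(genes = c(injury, fibrotic),
                     fold_change = c(rep(3, length(injury)),
                                     rep(6, 5), rep(3, 55)))
  )
  cohort_config(conditions = conds, cell_types = cts, programs = programs,
                n_cells_per_sample = n_cells_per_sample,
                samples_per_condition = 2,
                timepoints = list(Control = "d0",
                                  IRI_short = c("d3", "d14"),
                                  IRI_long = c("d3", "d14")),
                inflammatory_genes = inflammatory,
                seed = seed)
}

## per-(type, condition) gene sampling probabilities
.expression_profiles <- function(config, base_rel) {
  genes <- config$genes
  profs <- list()
  for (ct in config$cell_types) {
    rel <- base_rel
    if (length(ct$marker_genes))
      rel[ct$marker_genes] <- rel[ct$marker_genes] * ct$marker_fold_change
    if (ct$maladaptive && length(config$inflammatory_genes))
      rel[config$inflammatory_genes] <-
        rel[config$inflammatory_genes] * config$inflammatory_fold_change
    for (cn in names(config$conditions)) {
      rel2 <- rel
      pg <- config$programs[[cn]]
      if (!is.null(pg)) rel2[pg$genes] <- rel2[pg$genes] * pg$fold_change
      profs[[paste(ct$name, cn, sep = "\r")]] <- rel2 / sum(rel2)
    }
  }
  profs
}

#' Generate a synthetic single-cell cohort with known ground truth
#'
#' Draws cell types per condition from the configured multinomial
#' composition, counts from a per-gene negative binomial with log-normal cell
#' library sizes, then plants low-quality cells (shallow depth < 200 detected
#' genes, or mitochondrial content > 50%) and doublets (depth-rescaled sums
#' of two cells from the same sample). Ground-truth labels (`cell_type`,
#' `condition`, `is_doublet`, `is_lowq`) are recorded in the metadata;
#' `cluster` is initialized to the true cell type.
#'
#' @param config a [cohort_config()]
#' @return a [cell_table()] with truth metadata
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    genes <- config$genes
    G <- length(genes)
    base_rel <- stats::rlnorm(G, meanlog = 0, sdlog = config$baseline_sdlog)
    names(base_rel) <- genes
    mito <- config$mito_genes
    if (length(mito)) {
      nonmito_sum <- sum(base_rel[setdiff(genes, mito)])
      tgt <- config$mito_target_frac
      base_rel[mito] <- base_rel[mito] / sum(base_rel[mito]) *
        nonmito_sum * tgt / (1 - tgt)
    }
    profs <- .expression_profiles(config, base_rel)
    size <- 1 / config$nb_dispersion
    mu_log <- if (config$library_size_mean > 0)
      log(config$library_size_mean) - config$library_size_sdlog^2 / 2 else -Inf

    blocks <- list(); metas <- list()
    for (cn in names(config$conditions)) {
      props <- config$conditions[[cn]]
      tps <- config$timepoints[[cn]]
      if (is.null(tps)) tps <- "d14"
      for (s in seq_len(config$samples_per_condition)) {
        n <- config$n_cells_per_sample
        n_lq <- round(config$lowq_fraction * n)
        n_db <- round(config$doublet_fraction * n)
        n_model <- n - n_db
        types <- sample(names(props), n_model, replace = TRUE, prob = props)
        libs <- if (is.finite(mu_log))
          stats::rlnorm(n_model, mu_log, config$library_size_sdlog)
          else rep(0, n_model)
        cnt <- matrix(0L, G, n_model)
        for (tp in unique(types)) {
          idx <- which(types == tp)
          p <- profs[[paste(tp, cn, sep = "\r")]]
          mu <- p %o% libs[idx]
          cnt[, idx] <- stats::rnbinom(length(mu), mu = mu, size = size)
        }
        is_lowq <- rep(FALSE, n_model)
        if (n_lq > 0 && is.finite(mu_log)) {
          lq_idx <- sample.int(n_model, min(n_lq, n_model))
          is_lowq[lq_idx] <- TRUE
          for (j in seq_along(lq_idx)) {
            i <- lq_idx[j]
            if (j %% 2L == 1L) {       # shallow cell: < 200 detected genes
              tot <- sum(cnt[, i])
              if (tot > 0) {
                keep <- min(1, stats::runif(1, 50, 120) / tot)
                cnt[, i] <- stats::rbinom(G, cnt[, i], keep)
              }
            } else {                   # mito-loaded cell: mito share ~ 75%
              p <- profs[[paste(types[i], cn, sep = "\r")]]
              p2 <- p
              p2[mito] <- p2[mito] / sum(p2[mito]) *
                sum(p[setdiff(genes, mito)]) * 3
              p2 <- p2 / sum(p2)
              cnt[, i] <- stats::rnbinom(G, mu = p2 * libs[i], size = size)
            }
          }
        }
        is_db <- rep(FALSE, n_model)
        if (n_db > 0) {
          good <- which(!is_lowq)
          pa <- sample(good, n_db, replace = n_db > length(good))
          pb <- sample(good, n_db, replace = n_db > length(good))
          dcnt <- matrix(0L, G, n_db)
          for (j in seq_len(n_db)) {
            s2 <- cnt[, pa[j]] + cnt[, pb[j]]
            dcnt[, j] <- stats::rbinom(G, s2, 0.55)
          }
          cnt <- cbind(cnt, dcnt)
          types <- c(types, types[pa])
          is_lowq <- c(is_lowq, rep(FALSE, n_db))
          is_db <- c(is_db, rep(TRUE, n_db))
        }
        sample_id <- paste0(cn, "_s", s)
        bc <- sprintf("%s_c%05d", sample_id, seq_len(ncol(cnt)))
        colnames(cnt) <- bc
        rownames(cnt) <- genes
        blocks[[sample_id]] <- Matrix::Matrix(cnt, sparse = TRUE)
        metas[[sample_id]] <- data.frame(
          barcode = bc, sample = sample_id, condition = cn,
          timepoint = tps[(s - 1L) %% length(tps) + 1L],
          cell_type = types, cluster = types,
          is_doublet = is_db, is_lowq = is_lowq,
          row.names = bc, stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(cbind, blocks)
    meta <- do.call(rbind, metas)
    rownames(meta) <- meta$barcode
    cell_table(counts, meta)
  })
}

#' Configuration of a synthetic L1000-style drug screen
#'
#' @param n_drugs number of drugs (ids `drug01`, `drug02`, ...)
#' @param n_experiments_per_drug independent experiments per drug
#' @param genes character gene universe of the screen
#' @param planted_drugs named numeric: drug id -> effect added to the log2
#'   fold change of every signature gene in that drug's experiments
#' @param noise_sd standard deviation of the background log2 fold changes
#' @param seed RNG seed
#' @return a `drug_screen_config`
#' @export
drug_screen_config <- function(n_drugs = 50, n_experiments_per_drug = 3,
                               genes, planted_drugs = numeric(),
                               noise_sd = 1, seed = 1L) {
  stopifnot(n_drugs > 0, n_experiments_per_drug > 0, noise_sd > 0,
            length(genes) >= 10)
  ids <- sprintf("drug%02d", seq_len(n_drugs))
  if (length(planted_drugs)) {
    if (is.null(names(planted_drugs)) ||
        !all(names(planted_drugs) %in% ids))
      stop("planted_drugs must be named by drug ids drug01..drug",
           sprintf("%02d", n_drugs))
    if (any(!is.finite(planted_drugs))) stop("effect sizes must be finite")
  }
  structure(list(n_drugs = as.integer(n_drugs),
                 n_experiments_per_drug = as.integer(n_experiments_per_drug),
                 genes = genes, drug_ids = ids,
                 planted_drugs = planted_drugs,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "drug_screen_config")
}

#' Generate synthetic drug-response fold-change tables
#'
#' Non-planted drugs are pure noise; planted drugs have the configured effect
#' added to the log2 fold change of every signature gene in every experiment.
#'
#' @param config a [drug_screen_config()]
#' @param signature gene ids whose fold changes the planted drugs shift
#' @return named list: drug id -> list of data frames (`gene_id`, `log2fc`)
#' @export
generate_drug_screen <- function(config, signature) {
  stopifnot(inherits(config, "drug_screen_config"))
  if (!length(signature)) stop("signature must be non-empty")
  if (!all(signature %in% config$genes))
    stop("signature genes outside the screen gene universe")
  with_seed(config$seed, {
    G <- length(config$genes)
    sig_idx <- match(signature, config$genes)
    out <- lapply(config$drug_ids, function(d) {
      eff <- if (d %in% names(config$planted_drugs))
        config$planted_drugs[[d]] else 0
      lapply(seq_len(config$n_experiments_per_drug), function(e) {
        fc <- stats::rnorm(G, 0, config$noise_sd)
        fc[sig_idx] <- fc[sig_idx] + eff
        data.frame(gene_id = config$genes, log2fc = fc,
                   stringsAsFactors = FALSE)
      })
    })
    names(out) <- config$drug_ids
    out
  })
}

#' Generate a synthetic ligand-receptor pair table
#'
#' Draws `2 * n_pairs` distinct genes from the universe and pairs them into
#' disjoint ordered (ligand, receptor) tuples, standing in for a curated
#' interaction database.
#'
#' @param n_pairs number of pairs
#' @param gene_universe character gene ids to draw from
#' @param seed RNG seed
#' @return data frame with columns `ligand`, `receptor`
#' @export
generate_lr_pairs <- function(n_pairs, gene_universe, seed = 1L) {
  stopifnot(n_pairs >= 0)
  if (2 * n_pairs > length(gene_universe))
    stop("gene universe too small for ", n_pairs, " disjoint pairs")
  if (n_pairs == 0)
    return(data.frame(ligand = character(), receptor = character(),
                      stringsAsFactors = FALSE))
  with_seed(seed, {
    g <- sample(gene_universe, 2 * n_pairs)
    data.frame(ligand = g[seq_len(n_pairs)],
               receptor = g[n_pairs + seq_len(n_pairs)],
               stringsAsFactors = FALSE)
  })
}
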