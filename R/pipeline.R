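#' End-to-end run configuration
#'
#' Bundles per-stage configurations, stage toggles and the global seed. Each
#' stage draws a sub-seed deterministically derived from the global seed and
#' the stage name, so toggling one stage never perturbs another's randomness.
#'
#' @param outdir output directory
#' @param seed global integer seed
#' @param stages named logical toggles; defaults run everything
#' @param cohort a [cohort_config()]; default [default_cohort_config()] with
#'   the derived synthdata sub-seed
#' @param thresholds a [qc_thresholds()]
#' @param score a [score_config()]
#' @param dpa a [dpa_config()] (default scaled to 10000 iterations for an
#'   interactive run)
#' @param network a [network_config()]
#' @param metacell_k,metacells_per_stratum metacell construction parameters
#' @param n_lr_pairs ligand-receptor pairs drawn for the interaction stage
#' @param lr_iters permutations of the ligand-receptor test
#' @param n_drugs,drug_effect drugs in the synthetic screen and the planted
#'   effect size of `drug01`
#' @param gsea_perms permutations per drug in the screen
#' @return a `run_config` list
#' @export
run_config <- function(outdir = tempfile("screpair_run_"), seed = 1L,
                       stages = NULL,
                       cohort = NULL,
                       thresholds = qc_thresholds(),
                       score = NULL,
                       dpa = NULL,
                       network = network_config(),
                       metacell_k = 20, metacells_per_stratum = 50,
                       n_lr_pairs = 25, lr_iters = 1000,
                       n_drugs = 50, drug_effect = 3,
                       gsea_perms = 1000) {
  all_stages <- c("synthdata", "qc", "scoring", "proportions",
                  "coexpression", "lri", "druggability")
  st <- stats::setNames(rep(TRUE, length(all_stages)), all_stages)
  if (!is.null(stages)) st[names(stages)] <- stages
  if (is.null(cohort))
    cohort <- default_cohort_config(seed = derive_seed(seed, "synthdata"))
  if (is.null(score)) score <- score_config(seed = derive_seed(seed, "scoring"))
  if (is.null(dpa))
    dpa <- dpa_config(n_iter = 10000, seed = derive_seed(seed, "proportions"))
  structure(list(outdir = outdir, seed = as.integer(seed), stages = st,
                 cohort = cohort, thresholds = thresholds, score = score,
                 dpa = dpa, network = network, metacell_k = metacell_k,
                 metacells_per_stratum = metacells_per_stratum,
                 n_lr_pairs = n_lr_pairs, lr_iters = lr_iters,
                 n_drugs = n_drugs, drug_effect = drug_effect,
                 gsea_perms = gsea_perms),
            class = "run_config")
}

.stage_dir <- function(config, stage) {
  d <- file.path(config$outdir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

.require_stage <- function(results, stage, needed_by) {
  if (is.null(results[[stage]]))
    stop("stage '", needed_by, "' requires output of disabled stage '",
         stage, "'")
  results[[stage]]
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes synthdata -> qc -> scoring -> proportions -> coexpression ->
#' lri -> druggability, writing each stage's outputs under
#' `<outdir>/<stage>/` and a machine-readable manifest (seeds, per-stage
#' wall time and counters) to `<outdir>/manifest.json`.
#'
#' @param config a [run_config()]
#' @return invisibly, a list with per-stage results and the manifest
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  manifest <- list(seed = config$seed, stages = list())
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[stage]] <<- list(
      seed = derive_seed(config$seed, stage),
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }

  if (config$stages[["synthdata"]]) {
    results$synthdata <- tick("synthdata", {
      cohort <- generate_cohort(config$cohort)
      write_cohort(cohort, .stage_dir(config, "synthdata"))
      cohort
    })
    manifest$stages$synthdata$cells <- ncol(results$synthdata$counts)
    manifest$stages$synthdata$genes <- nrow(results$synthdata$counts)
  }

  if (config$stages[["qc"]]) {
    results$qc <- tick("qc", {
      cohort <- .require_stage(results, "synthdata", "qc")
      qc <- compute_cell_qc(cohort)
      kept <- filter_cells(qc, config$thresholds, drop_doublets = TRUE)
      write_tsv(data.frame(barcode = kept),
                file.path(.stage_dir(config, "qc"), "retained_barcodes.tsv"))
      write_tsv(qc, file.path(config$outdir, "qc", "cell_qc.tsv"))
      list(qc = qc, kept = kept,
           filtered = subset_cells(cohort, cells = kept))
    })
    manifest$stages$qc$cells_in <- nrow(results$qc$qc)
    manifest$stages$qc$cells_out <- length(results$qc$kept)
  }

  if (config$stages[["scoring"]]) {
    results$scoring <- tick("scoring", {
      filt <- .require_stage(results, "qc", "scoring")$filtered
      expr <- lognormalize(filt)
      labels <- ifelse(filt$meta$condition == "Control", "Control", "IRI")
      res <- iri_score_pipeline(expr, labels, config$score)
      d <- .stage_dir(config, "scoring")
      write_tsv(res$calls, file.path(d, "cell_state_calls.tsv"))
      for (s in res$signatures)
        write_tsv(s$prune_log,
                  file.path(d, paste0("prune_log_", s$condition, ".tsv")))
      write_gmt(stats::setNames(lapply(res$signatures, `[[`, "genes_pruned"),
                                vapply(res$signatures, `[[`, "",
                                       "condition")),
                file.path(d, "signatures.gmt"))
      res
    })
    manifest$stages$scoring$calls <- as.list(table(results$scoring$calls$call))
  }

  if (config$stages[["proportions"]]) {
    results$proportions <- tick("proportions", {
      filt <- .require_stage(results, "qc", "proportions")$filtered
      res <- dpa_test(filt$meta$cluster, filt$meta$condition,
                      "Control", "IRI_long", config$dpa)
      write_tsv(res, file.path(.stage_dir(config, "proportions"),
                               "dpa_control_vs_long.tsv"))
      res
    })
    manifest$stages$proportions$clusters <- nrow(results$proportions)
  }

  if (config$stages[["coexpression"]]) {
    results$coexpression <- tick("coexpression", {
      filt <- .require_stage(results, "qc", "coexpression")$filtered
      mc <- build_metacells(filt, k = config$metacell_k,
                            n_metacells_per_stratum =
                              config$metacells_per_stratum,
                            seed = derive_seed(config$seed, "coexpression"))
      net <- run_coexpression(mc, config$network)
      d <- .stage_dir(config, "coexpression")
      write_tsv(data.frame(gene = names(net$modules), module = net$modules),
                file.path(d, "modules.tsv"))
      if (!is.null(net$mes)) {
        write_tsv(data.frame(metacell = rownames(net$mes), net$mes,
                             check.names = FALSE),
                  file.path(d, "MEs.tsv"))
        write_tsv(data.frame(gene = rownames(net$kme), net$kme,
                             check.names = FALSE),
                  file.path(d, "kME.tsv"))
      }
      list(metacells = mc, network = net)
    })
    manifest$stages$coexpression$modules <-
      length(setdiff(unique(results$coexpression$network$modules), "grey"))
  }

  if (config$stages[["lri"]]) {
    results$lri <- tick("lri", {
      filt <- .require_stage(results, "qc", "lri")$filtered
      expr <- lognormalize(filt)
      pairs <- generate_lr_pairs(config$n_lr_pairs,
                                 grep("^mt-", rownames(expr), value = TRUE,
                                      invert = TRUE),
                                 seed = derive_seed(config$seed, "lri"))
      res <- lr_permutation_test(expr, filt$meta$cluster, pairs,
                                 n_iter = config$lr_iters,
                                 seed = derive_seed(config$seed, "lri"))
      d <- .stage_dir(config, "lri")
      write_tsv(pairs, file.path(d, "lr_pairs.tsv"))
      write_tsv(res, file.path(d, "lr_results.tsv"))
      res
    })
    manifest$stages$lri$tested <- nrow(results$lri)
    manifest$stages$lri$significant <- sum(results$lri$significant)
  }

  if (config$stages[["druggability"]]) {
    results$druggability <- tick("druggability", {
      scoring <- .require_stage(results, "scoring", "druggability")
      signature <- scoring$signatures[[1]]$genes_pruned
      cohort <- .require_stage(results, "synthdata", "druggability")
      dcfg <- drug_screen_config(
        n_drugs = config$n_drugs, n_experiments_per_drug = 3,
        genes = rownames(cohort$counts),
        planted_drugs = c(drug01 = config$drug_effect),
        seed = derive_seed(config$seed, "druggability"))
      tables <- generate_drug_screen(dcfg, signature)
      prls <- lapply(tables, function(exps) {
        merge_prl(lapply(exps, function(tb)
          ranking_from_effects(stats::setNames(tb$log2fc, tb$gene_id))))
      })
      res <- screen_drugs(prls, signature, n_perm = config$gsea_perms,
                          seed = derive_seed(config$seed, "druggability"))
      d <- .stage_dir(config, "druggability")
      write_tsv(res, file.path(d, "drug_screen.tsv"))
      lef <- leading_edge_frequency(res, top_k = min(24, nrow(res)))
      write_tsv(data.frame(gene = names(lef$frequency),
                           frequency = as.integer(lef$frequency)),
                file.path(d, "leading_edge_frequency.tsv"))
      list(results = res, frequency = lef)
    })
    manifest$stages$druggability$top_drug <-
      results$druggability$results$drug[1]
  }

  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, manifest = manifest))
}
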