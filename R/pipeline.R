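#' Configuration for a full pipeline run
#'
#' Collects every stage's parameters with the conventional defaults surfaced
#' (1.5 CPM in 6 samples, FDR 0.05, display fold-change 0.5, soft power 14,
#' minimum module size 40, deepSplit 1, PAM distance 0.90, 10th-percentile
#' connectivity filter, 9999 rotations, 200 permutations, 1000-gene random
#' module, 1500/200 bp promoters, 90% motif match). Input paths may point at
#' a real study (counts + metadata TSV); otherwise a synthetic study is
#' generated from `sim`.
#'
#' @param out_dir run directory for artefacts.
#' @param seed master seed; every stochastic stage derives its stream from it.
#' @param sim a [sim_config()] for the counts/promoters/peptides study.
#' @param module_sim a [sim_config()] for the two-species network study
#'   (smaller by default to keep the adjacency tractable).
#' @param thresholds a [pattern_thresholds()].
#' @param network a [network_params()].
#' @param n_rot rotations for gene-set testing.
#' @param n_perm permutations for module preservation.
#' @param random_module_size size of the random preservation baseline.
#' @param counts_path,meta_path optional TSV inputs replacing simulation.
#' @param gmt_path optional gene-set collection; defaults to sets built from
#'   the synthetic truth.
#' @param stages named logical vector enabling stages (de, patterns, gst,
#'   network, preservation, enrichment, proteomics).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("ageomics_run_"),
                            seed = 1L,
                            sim = sim_config(seed = seed),
                            module_sim = sim_config(n_genes = 1200,
                                                    n_modules = 5,
                                                    module_size_range = c(50, 80),
                                                    preserved_fraction = 0.6,
                                                    seed = seed + 1L),
                            thresholds = pattern_thresholds(),
                            network = network_params(),
                            n_rot = 9999,
                            n_perm = 200,
                            random_module_size = 1000,
                            counts_path = NULL,
                            meta_path = NULL,
                            gmt_path = NULL,
                            stages = c(de = TRUE, patterns = TRUE,
                                       gst = TRUE, network = TRUE,
                                       preservation = TRUE,
                                       enrichment = TRUE,
                                       proteomics = TRUE)) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 module_sim = module_sim, thresholds = thresholds,
                 network = network, n_rot = n_rot, n_perm = n_perm,
                 random_module_size = random_module_size,
                 counts_path = counts_path, meta_path = meta_path,
                 gmt_path = gmt_path, stages = stages),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks paths, threshold ranges, and cross-stage consistency; returns the
#' itemised problems rather than stopping, so callers can report them.
#'
#' @param config a [pipeline_config()].
#' @return character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk(inherits(config, "pipeline_config"), "not a pipeline_config")
  for (p in c("counts_path", "meta_path", "gmt_path")) {
    v <- config[[p]]
    if (!is.null(v) && !file.exists(v))
      problems <- c(problems, paste0(p, " does not exist: ", v))
  }
  th <- config$thresholds
  chk(th$fdr_primary > 0 && th$fdr_primary <= 1, "fdr_primary out of (0, 1]")
  chk(th$p_secondary > 0 && th$p_secondary <= 1, "p_secondary out of (0, 1]")
  chk(config$n_rot >= 99, "n_rot must be >= 99")
  chk(config$n_perm >= 20, "n_perm must be >= 20")
  chk(is.integer(config$seed) && length(config$seed) == 1, "seed must be one integer")
  v <- tryCatch({ validate_sim_config(config$sim); NULL },
                error = function(e) conditionMessage(e))
  if (!is.null(v)) problems <- c(problems, paste0("sim: ", v))
  v <- tryCatch({ validate_sim_config(config$module_sim); NULL },
                error = function(e) conditionMessage(e))
  if (!is.null(v)) problems <- c(problems, paste0("module_sim: ", v))
  if (is.null(config$counts_path) != is.null(config$meta_path))
    problems <- c(problems, "counts_path and meta_path must be given together")
  problems
}

# gene sets derived from the planted truth: one per pattern plus size-matched
# random sets as a null backdrop
truth_gene_sets <- function(truth, seed) {
  set.seed(sub_seed(seed, 50000L))
  pats <- setdiff(unique(truth$pattern), "null")
  sets <- lapply(pats, function(p) names(truth$pattern)[truth$pattern == p])
  names(sets) <- paste0("planted_", pats)
  genes <- names(truth$pattern)
  for (i in seq_along(pats))
    sets[[paste0("random_", i)]] <- sample(genes, length(sets[[i]]))
  sets
}

#' Run the full study pipeline
#'
#' Executes the enabled stages in dependency order (simulate or ingest,
#' differential expression, pattern classification, gene-set testing,
#' network construction, module preservation with a random baseline, promoter
#' motif enrichment, proteomics), writes each stage's artefacts under
#' `out_dir`, and returns (and writes) a machine-readable summary. Identical
#' configurations give byte-identical summaries.
#'
#' @param config a [pipeline_config()].
#' @return the summary list, invisibly; artefacts and `summary.json` are in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  on_stage <- function(s) isTRUE(config$stages[[s]])
  summary <- list(seed = config$seed)

  # -- inputs -----------------------------------------------------------------
  if (is.null(config$counts_path)) {
    sim <- simulate_counts(config$sim)
    counts <- sim$counts
    study <- sim$design
    truth <- sim$truth
    write_simulated_study(sim, file.path(config$out_dir, "input"))
  } else {
    counts <- read_counts_tsv(config$counts_path)
    study <- read_study_tsv(config$meta_path)
    truth <- NULL
  }

  de <- NULL
  if (on_stage("de")) {
    de <- run_de(counts, study)
    write_de_tables(de, file.path(config$out_dir, "de"))
    summary$de_counts <- lapply(de$tables, function(t)
      sum(t$fdr < config$thresholds$fdr_primary))
    summary$n_genes_tested <- nrow(de$tables[[1]])
  }

  if (on_stage("patterns") && !is.null(de)) {
    pats <- classify_patterns(de, config$thresholds)
    write.table(pats, file.path(config$out_dir, "patterns.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$pattern_sizes <- as.list(table(pats$label))
    conc <- concordance_fraction(de, "youngHet_vs_youngWt",
                                 "agedWt_vs_youngWt", config$thresholds)
    summary$concordance <- conc
    summary$aging_signature_size <- length(aging_signature(de,
                                                           config$thresholds))
  }

  if (on_stage("gst") && !is.null(de)) {
    sets <- if (!is.null(config$gmt_path)) read_gmt(config$gmt_path)
            else truth_gene_sets(truth, config$seed)
    gst <- lapply(contrast_names(), function(cn)
      fry_test(de$logcpm, de$design, de$contrasts[, cn, drop = FALSE], sets))
    names(gst) <- contrast_names()
    for (cn in contrast_names())
      write.table(gst[[cn]], file.path(config$out_dir,
                                       paste0("gst_", cn, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    summary$gst_significant <- lapply(gst, function(g)
      sum(g$fdr_mixed < 0.05, na.rm = TRUE))
  }

  net <- NULL
  msim <- NULL
  if (on_stage("network")) {
    msim <- simulate_module_expression(config$module_sim)
    net <- build_network(msim$expr_a, config$network)
    write.table(data.frame(gene_id = names(net$labels),
                           module = unname(net$labels)),
                file.path(config$out_dir, "modules.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$n_modules <- sum(net$sizes > 0)
    summary$module_sizes <- as.list(net$sizes)
  }

  if (on_stage("preservation") && !is.null(net)) {
    pres <- zsummary(net$expr, msim$expr_b, net$labels,
                     ortho = msim$ortholog_map, n_perm = config$n_perm,
                     seed = config$seed, beta = config$network$soft_power)
    write.table(pres, file.path(config$out_dir, "preservation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summary$preserved_modules <- sum(pres$Z_summary > 2, na.rm = TRUE)
    summary$strongly_preserved <- sum(pres$Z_summary > 10, na.rm = TRUE)
    # the random baseline is evaluated between two independently simulated
    # networks (no shared latent factors), where its expectation is Z < 2
    ind_cfg <- config$module_sim
    ind_cfg$preserved_fraction <- 0
    ind_cfg$seed <- sub_seed(config$seed, 13L)
    ind <- simulate_module_expression(ind_cfg)
    rnd <- random_module_baseline(ind$expr_a, ind$expr_b,
                                  ortho = ind$ortholog_map,
                                  size = min(config$random_module_size,
                                             nrow(ind$expr_a)),
                                  n_perm = config$n_perm, seed = config$seed,
                                  beta = config$network$soft_power)
    summary$random_module_z <- rnd$Z_summary
  }

  if (on_stage("enrichment") && !is.null(truth)) {
    pwms <- read_jaspar_motifs(system.file("extdata",
                                           "synthetic_motifs.jaspar",
                                           package = "ageomics"))
    target_pool <- names(truth$pattern)[truth$pattern == "inverted"]
    prom <- simulate_promoters(names(truth$pattern), pwms,
                               target_genes = target_pool,
                               motif_id = pwms[[1]]$id,
                               target_fraction = config$sim$motif_target_fraction,
                               seed = config$seed)
    target <- if (on_stage("patterns") && !is.null(de)) {
      pats <- classify_patterns(de, config$thresholds)
      pats$gene_id[pats$label == "inverted"]
    } else target_pool
    bg <- names(truth$pattern)
    target <- intersect(target, bg)
    if (length(target) >= 3) {
      enr <- motif_enrichment(prom, pwms, target, bg)
      write.table(enr$enrichment,
                  file.path(config$out_dir, "motif_enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summary$enriched_motifs <-
        enr$enrichment$term[enr$enrichment$p_bonferroni < 0.05]
    }
  }

  if (on_stage("proteomics") && !is.null(truth)) {
    pep <- simulate_peptides(truth, config$sim)
    pt <- run_proteomics(pep$peptides, study)
    da <- differential_abundance(pt, study)
    write_de_tables(da, file.path(config$out_dir, "proteomics"))
    summary$n_proteins_complete <- nrow(pt$abundance)
    summary$da_counts <- lapply(da$tables, function(t) sum(t$fdr < 0.05))
    if (!is.null(de)) {
      rs <- mrna_protein_correlation(de$logcpm, pt, pep$gene_map,
                                     groups = setNames(as.character(study$age),
                                                       study$sample_id))
      summary$mrna_protein_rs <- setNames(as.list(rs$rs), rs$group)
    }
  }

  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, file.path(config$out_dir, "summary.json"))
  invisible(summary)
}
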