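#' Simulate a 2x2 study count matrix with planted expression patterns
#'
#' Generates negative-binomial counts for `n_reps_per_condition` replicates of
#' each of the four conditions (young/aged x wt/het). Per-gene baseline
#' abundances are log-normal; each gene's pattern label adds condition
#' offsets in log2 space (see [sim_config()]); one batch level per replicate
#' index adds N(0, `batch_effect_sd`) per-gene offsets shared by all samples
#' of that replicate group, balanced across conditions so the unwanted
#' variation is estimable from replicate structure.
#'
#' Counts are drawn as `NB(mean = lib_j * q_gj, size = 1/dispersion)` where
#' `q_gj` is the per-sample relative abundance (columns sum to 1). The truth
#' object records the pattern labels, all offsets, `q`, and library sizes so
#' that downstream recovery is well defined; it is never consumed by the
#' analysis stages.
#'
#' @param config a [sim_config()].
#' @return A list with elements
#'   \item{counts}{integer matrix, genes x samples;}
#'   \item{design}{data.frame with sample_id, genotype, age, condition,
#'     replicate_group (the batch);}
#'   \item{truth}{a `planted_truth` list: `pattern` (named by gene),
#'     `offsets` (genes x conditions, log2), `batch_offsets`
#'     (genes x batches, log2), `q`, `lib_sizes`, `baseline_log2`.}
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  set.seed(sub_seed(config$seed, 0L))
  ng <- config$n_genes
  nr <- config$n_reps_per_condition
  lv <- condition_levels()
  gene_ids <- sprintf("gene%05d", seq_len(ng))

  design <- data.frame(
    sample_id = as.vector(t(outer(lv, seq_len(nr), paste, sep = "_rep"))),
    condition = factor(rep(lv, each = nr), levels = lv),
    stringsAsFactors = FALSE
  )
  design$genotype <- factor(ifelse(grepl("het", design$condition),
                                   "het", "wt"), levels = c("wt", "het"))
  design$age <- factor(ifelse(grepl("aged", design$condition),
                              "aged", "young"), levels = c("young", "aged"))
  design$replicate_group <- factor(paste0("batch", rep(seq_len(nr), 4)))

  pattern <- assign_patterns(gene_ids, config$pattern_counts)
  offsets <- pattern_offsets(pattern, config$effect_size, lv)

  baseline_log2 <- rnorm(ng, mean = 5, sd = 2)
  batch_offsets <- matrix(rnorm(ng * nr, 0, config$batch_effect_sd),
                          ng, nr, dimnames = list(gene_ids,
                                                  levels(design$replicate_group)))

  log2_expr <- baseline_log2 +
    offsets[, as.character(design$condition), drop = FALSE] +
    batch_offsets[, as.integer(design$replicate_group), drop = FALSE]
  w <- 2^log2_expr
  q <- sweep(w, 2, colSums(w), "/")
  dimnames(q) <- list(gene_ids, design$sample_id)

  lib_sizes <- round(runif(nrow(design), config$lib_size_range[1],
                           config$lib_size_range[2]))
  names(lib_sizes) <- design$sample_id
  mu <- sweep(q, 2, lib_sizes, "*")
  counts <- matrix(
    if (config$dispersion > 0)
      rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    else rpois_matrix(mu),
    ng, ncol(mu), dimnames = dimnames(mu))

  truth <- list(pattern = pattern, offsets = offsets,
                batch_offsets = batch_offsets, q = q, lib_sizes = lib_sizes,
                baseline_log2 = setNames(baseline_log2, gene_ids),
                dispersion = config$dispersion)
  class(truth) <- "planted_truth"
  list(counts = counts, design = design, truth = truth)
}

rpois_matrix <- function(mu) stats::rpois(length(mu), lambda = mu)

# deterministically assign pattern labels to the first sum(pattern_counts)
# genes, in pattern order; the rest are null
assign_patterns <- function(gene_ids, pattern_counts) {
  pattern <- rep("null", length(gene_ids))
  i <- 1L
  for (p in names(pattern_counts)) {
    n <- pattern_counts[[p]]
    if (n > 0) {
      pattern[i:(i + n - 1L)] <- p
      i <- i + as.integer(n)
    }
  }
  setNames(pattern, gene_ids)
}

# per-gene log2 offsets for the four conditions implied by each pattern label
pattern_offsets <- function(pattern, effect_size, lv = condition_levels()) {
  e <- effect_size
  scheme <- rbind(
    null          = c(young_wt = 0, young_het = 0, aged_wt = 0, aged_het = 0),
    inverted      = c(0,  e, 0, -e),
    accel_aging   = c(0,  e, e,  e),
    fail_up       = c(0,  0, e,  0),
    fail_down     = c(0,  0, -e, 0),
    inapprop_down = c(0,  0, 0, -e),
    aging_only    = c(0,  0, e,  e)
  )
  colnames(scheme) <- lv
  out <- scheme[pattern, , drop = FALSE]
  rownames(out) <- names(pattern)
  out
}
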