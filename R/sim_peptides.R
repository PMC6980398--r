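#' Simulate a peptide intensity table coupled to mRNA truth
#'
#' Protein abundance profiles are generated as linear mixes of the
#' standardised per-sample mRNA log-abundance (from a [simulate_counts()]
#' truth object) and independent per-gene noise, with the mixing weight
#' calibrated through the Gaussian copula identity
#' `rho_pearson = 2 sin(pi rho_spearman / 6)` so the across-gene Spearman
#' correlation between mRNA and protein matches `protein_rho`. Per-protein
#' condition effects therefore follow the planted mRNA patterns, attenuated
#' by the mixing weight. Each protein yields 1 + Poisson(2) peptides with
#' constant peptide offsets and i.i.d. measurement error; intensities below
#' the global `censor_quantile` are recorded as missing (left-censored).
#'
#' @param truth `planted_truth` from [simulate_counts()].
#' @param config the same [sim_config()].
#' @param genes gene ids to attach proteins to (default: a seeded sample of
#'   300, or all genes if fewer).
#' @param sample_noise_sd per-sample protein noise sd (log2 intensity units).
#' @param peptide_noise_sd peptide-level measurement error sd.
#' @return list with `peptides` (data.frame peptide_id, protein_id,
#'   sample_id, raw-scale intensity with NA = censored), `protein_truth` (protein x
#'   sample true log2 intensities), `gene_map` (data.frame protein_id,
#'   gene_id), and `censor_threshold`.
#' @export
simulate_peptides <- function(truth, config, genes = NULL,
                              sample_noise_sd = 0.15,
                              peptide_noise_sd = 0.2) {
  validate_sim_config(config)
  set.seed(sub_seed(config$seed, 30000L))
  logcpm_true <- log2(truth$q * 1e6)
  all_genes <- rownames(logcpm_true)
  if (is.null(genes))
    genes <- if (length(all_genes) <= 300) all_genes else
      sort(sample(all_genes, 300))
  x <- logcpm_true[genes, , drop = FALSE]
  z <- (x - mean(x)) / sd(x)   # global affine: no per-condition leakage
  rho_p <- 2 * sin(pi * config$protein_rho / 6)
  # independent component (gene-level noise + per-sample wiggle) standardised
  # as a whole so the latent Pearson correlation is rho_p by construction
  ind <- rnorm(length(genes)) +
    matrix(rnorm(length(z), 0, sample_noise_sd), nrow(z))
  ind <- ind - z * (sum(ind * z) / sum(z * z))  # exactly orthogonal to z
  ind <- (ind - mean(ind)) / sd(ind)
  protein_z <- rho_p * z + sqrt(max(0, 1 - rho_p^2)) * ind
  protein_true <- 23 + 1.5 * protein_z
  protein_ids <- sprintf("prot%04d", seq_along(genes))
  dimnames(protein_true) <- list(protein_ids, colnames(logcpm_true))

  # ~5.3 peptides per protein, the ratio reported for brain LC-MS/MS batches
  n_pep <- 1L + stats::rpois(length(genes), 4.3)
  pep_protein <- rep(protein_ids, n_pep)
  pep_ids <- sprintf("pep%05d", seq_along(pep_protein))
  pep_offset <- rnorm(length(pep_ids), 0, 1)

  long <- do.call(rbind, lapply(seq_along(pep_ids), function(i) {
    y <- protein_true[pep_protein[i], ] + pep_offset[i] +
      rnorm(ncol(protein_true), 0, peptide_noise_sd)
    data.frame(peptide_id = pep_ids[i], protein_id = pep_protein[i],
               sample_id = colnames(protein_true), intensity = 2^unname(y),
               stringsAsFactors = FALSE)
  }))
  censor_threshold <- -Inf
  if (config$censor_quantile > 0) {
    censor_threshold <- quantile(long$intensity, config$censor_quantile,
                                 names = FALSE)
    long$intensity[long$intensity < censor_threshold] <- NA_real_
  }
  rownames(long) <- NULL
  list(peptides = long, protein_truth = protein_true,
       gene_map = data.frame(protein_id = protein_ids, gene_id = genes,
                             stringsAsFactors = FALSE),
       censor_threshold = censor_threshold)
}
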