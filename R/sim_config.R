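#' Configuration for a synthetic 2x2 brain aging study
#'
#' Describes the full stated world of the generator: a young/aged x
#' wild-type/heterozygous design with three biological replicates per
#' condition, negative-binomial counts with a common dispersion, one batch
#' factor aligned with replicate index, planted multi-contrast expression
#' patterns, correlated gene modules replicated with varying fidelity in a
#' second species, motif-annotated promoters, and peptide tables with
#' left-censoring.
#'
#' Pattern labels and their condition offsets (log2 units, `e = effect_size`):
#' \describe{
#'   \item{inverted}{+e in young het, -e in aged het, 0 in wt.}
#'   \item{accel_aging}{+e in aged wt and in het at both ages (the aging
#'     offset arrives early in the mutant).}
#'   \item{fail_up}{+e in aged wt only (gene rises in normal aging, mutant
#'     fails to follow).}
#'   \item{fail_down}{-e in aged wt only.}
#'   \item{inapprop_down}{-e in aged het only.}
#'   \item{aging_only}{+e in aged wt and aged het (a genotype-independent
#'     aging response).}
#'   \item{null}{no offsets.}
#' }
#'
#' @param n_genes number of genes to simulate.
#' @param n_reps_per_condition biological replicates per condition (default 3).
#' @param pattern_counts named integer vector of planted genes per pattern;
#'   remaining genes are null. Defaults mirror the group sizes reported for a
#'   zebrafish psen1 mutant brain study (63 inverted, 57 inappropriately
#'   down-regulated, 94 failure-to-up-regulate, 26 failure-to-down-regulate)
#'   plus accelerated-aging and aging-signature genes.
#' @param effect_size planted offset in log2 units (default 2).
#' @param dispersion common negative-binomial dispersion phi, with
#'   var = mu + phi mu^2 (default 0.1, typical for bulk brain RNA-seq).
#' @param lib_size_range range of library sizes sampled uniformly.
#' @param batch_effect_sd sd (log2) of per-gene batch offsets; one batch level
#'   per replicate index so the batch is balanced across conditions.
#' @param n_modules number of co-expression modules for the module simulator.
#' @param module_size_range range of module sizes.
#' @param module_cor target mean within-module correlation, in (0,1).
#' @param preserved_fraction fraction of modules replicated with the same
#'   membership and loadings in species B; the rest are re-drawn with
#'   scrambled membership so their species-A structure is not preserved.
#' @param motif_library character vector of PWM ids available for planting.
#' @param motif_target_fraction fraction of a designated gene group whose
#'   promoters carry a planted motif occurrence.
#' @param protein_rho target Spearman correlation between mRNA and protein
#'   abundance across genes (default 0.4, as reported for young brains).
#' @param censor_quantile fraction of lowest peptide intensities recorded as
#'   missing (left-censored).
#' @param seed integer seed; identical configs give bit-identical output.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 4000,
                       n_reps_per_condition = 3,
                       pattern_counts = c(inverted = 63, accel_aging = 65,
                                          fail_up = 94, fail_down = 26,
                                          inapprop_down = 57,
                                          aging_only = 200),
                       effect_size = 2,
                       dispersion = 0.1,
                       lib_size_range = c(1e6, 2e6),
                       batch_effect_sd = 0.3,
                       n_modules = 5,
                       module_size_range = c(50, 80),
                       module_cor = 0.8,
                       preserved_fraction = 0.5,
                       motif_library = c("GRE_synth", "ETS_synth",
                                         "HOX_synth"),
                       motif_target_fraction = 0.6,
                       protein_rho = 0.4,
                       censor_quantile = 0.05,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_reps_per_condition = as.integer(n_reps_per_condition),
              pattern_counts = pattern_counts,
              effect_size = effect_size,
              dispersion = dispersion,
              lib_size_range = lib_size_range,
              batch_effect_sd = batch_effect_sd,
              n_modules = as.integer(n_modules),
              module_size_range = as.integer(module_size_range),
              module_cor = module_cor,
              preserved_fraction = preserved_fraction,
              motif_library = motif_library,
              motif_target_fraction = motif_target_fraction,
              protein_rho = protein_rho,
              censor_quantile = censor_quantile,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config` object.
#' @return `cfg`, invisibly; stops with an informative message on violation.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  known <- c("inverted", "accel_aging", "fail_up", "fail_down",
             "inapprop_down", "aging_only", "null")
  pc <- cfg$pattern_counts
  if (length(pc)) {
    if (is.null(names(pc)) || !all(names(pc) %in% known))
      stop("pattern_counts must be named with patterns among: ",
           paste(known, collapse = ", "))
    if (any(pc < 0)) stop("pattern_counts must be non-negative")
    if (sum(pc) > cfg$n_genes)
      stop("configuration error: sum of pattern_counts (", sum(pc),
           ") exceeds n_genes (", cfg$n_genes, ")")
  }
  if (cfg$n_genes <= 0 || cfg$n_reps_per_condition <= 0 || cfg$n_modules < 0)
    stop("counts must be positive")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (any(cfg$lib_size_range <= 0) || diff(cfg$lib_size_range) < 0)
    stop("lib_size_range must be positive and non-decreasing")
  if (cfg$module_cor <= 0 || cfg$module_cor >= 1)
    stop("configuration error: module_cor must be in (0, 1)")
  if (cfg$preserved_fraction < 0 || cfg$preserved_fraction > 1)
    stop("preserved_fraction must be in [0, 1]")
  if (cfg$motif_target_fraction < 0 || cfg$motif_target_fraction > 1)
    stop("motif_target_fraction must be in [0, 1]")
  if (abs(cfg$protein_rho) > 1)
    stop("configuration error: protein_rho must be in [-1, 1]")
  if (cfg$censor_quantile < 0 || cfg$censor_quantile >= 1)
    stop("censor_quantile must be in [0, 1)")
  invisible(cfg)
}
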