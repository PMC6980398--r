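# shared fixture builders for the test suite

make_study <- function(n_reps = 3) {
  lv <- condition_levels()
  study <- data.frame(
    sample_id = as.vector(t(outer(lv, seq_len(n_reps), paste, sep = "_rep"))),
    condition = factor(rep(lv, each = n_reps), levels = lv),
    stringsAsFactors = FALSE)
  study$age <- factor(ifelse(grepl("aged", study$condition), "aged", "young"),
                      levels = c("young", "aged"))
  study$genotype <- factor(ifelse(grepl("het", study$condition), "het", "wt"),
                           levels = c("wt", "het"))
  study
}

# a de_result assembled by hand from per-contrast statistics
fake_de <- function(gene_ids, ...) {
  stats <- list(...)
  tables <- lapply(stats, function(s) {
    tab <- data.frame(gene_id = gene_ids,
                      logFC = s$logFC,
                      t = s$logFC,
                      p = s$p,
                      fdr = if (!is.null(s$fdr)) s$fdr else s$p,
                      ave_expr = 5,
                      row.names = gene_ids,
                      stringsAsFactors = FALSE)
    tab
  })
  structure(list(tables = tables, params = list()), class = "de_result")
}

# Gaussian expression with the 2x2 design layout, no signal
null_expr <- function(n_genes, study, sd = 1) {
  m <- matrix(rnorm(n_genes * nrow(study), sd = sd), n_genes, nrow(study),
              dimnames = list(sprintf("g%05d", seq_len(n_genes)),
                              study$sample_id))
  m
}

# independent step-up BH oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
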