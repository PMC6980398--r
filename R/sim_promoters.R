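#' Simulate promoter sequences with planted motif occurrences
#'
#' Background promoters are i.i.d. draws from `base_probs`. For a fraction
#' (`target_fraction`) of the designated target genes, one occurrence of the
#' planted PWM is inserted at a uniform position on a uniform strand; in
#' `"consensus"` mode the inserted sequence is the PWM consensus (whose scan
#' score equals the maximum score by construction), in `"sample"` mode each
#' base is drawn from the PWM column distributions. Insertions are recorded
#' so scanner recovery is well defined.
#'
#' @param genes character vector of gene ids needing promoters.
#' @param pwms named list of [pwm()] objects available for planting.
#' @param target_genes genes eligible for an insertion (default none).
#' @param motif_id id of the PWM to plant (default the first in `pwms`).
#' @param target_fraction fraction of `target_genes` receiving an insertion.
#' @param length promoter length in bases; every PWM must fit.
#' @param base_probs background probabilities for A, C, G, T.
#' @param mode `"consensus"` or `"sample"`.
#' @param seed integer seed.
#' @return a `promoter_set` (see [extract_promoters()]) with an extra
#'   `insertions` data.frame (gene, motif, position, strand).
#' @export
simulate_promoters <- function(genes, pwms, target_genes = character(0),
                               motif_id = if (length(pwms)) pwms[[1]]$id else NULL,
                               target_fraction = 1,
                               length = 1700,
                               base_probs = rep(0.25, 4),
                               mode = c("consensus", "sample"),
                               seed = 1L) {
  mode <- match.arg(mode)
  set.seed(sub_seed(seed, 20000L))
  stopifnot(abs(sum(base_probs) - 1) < 1e-8)
  widths <- vapply(pwms, function(p) ncol(p$mat), integer(1))
  if (any(widths > length))
    stop("configuration error: PWM wider than promoter length")
  bases <- c("A", "C", "G", "T")

  seqs <- vapply(genes, function(g)
    paste(sample(bases, length, replace = TRUE, prob = base_probs),
          collapse = ""), character(1))

  ins <- data.frame(gene = character(0), motif = character(0),
                    position = integer(0), strand = character(0),
                    stringsAsFactors = FALSE)
  target_genes <- intersect(target_genes, genes)
  n_ins <- round(target_fraction * base::length(target_genes))
  if (n_ins > 0 && !is.null(motif_id)) {
    p <- pwms[[which(vapply(pwms, `[[`, "", "id") == motif_id)[1]]]
    w <- ncol(p$mat)
    chosen <- sample(target_genes, n_ins)
    for (g in chosen) {
      pos <- sample.int(length - w + 1L, 1)
      strand <- sample(c("+", "-"), 1)
      site <- if (mode == "consensus") pwm_consensus(p) else
        paste(vapply(seq_len(w), function(j)
          sample(bases, 1, prob = p$mat[, j]), character(1)), collapse = "")
      if (strand == "-")
        site <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(site)))
      substr(seqs[g], pos, pos + w - 1L) <- site
      ins <- rbind(ins, data.frame(gene = g, motif = p$id, position = pos,
                                   strand = strand, stringsAsFactors = FALSE))
    }
  }
  structure(list(sequences = Biostrings::DNAStringSet(seqs),
                 upstream = NA_integer_, downstream = NA_integer_,
                 truncated = setNames(rep(FALSE, base::length(genes)), genes),
                 insertions = ins),
            class = "promoter_set")
}
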