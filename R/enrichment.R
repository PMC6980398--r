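#' Position weight matrix
#'
#' @param id motif identifier.
#' @param mat 4 x W matrix of per-position base probabilities, rows A,C,G,T;
#'   columns must sum to 1 (tolerance 1e-6); width >= 4.
#' @param threshold score threshold as a fraction of the maximum log-odds
#'   score (default 0.90, the "90% match" convention), or an absolute
#'   log-odds value if `absolute = TRUE` at scan time.
#' @return object of class `pwm`.
#' @export
pwm <- function(id, mat, threshold = 0.90) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("pwm matrix must have 4 rows (A, C, G, T)")
  rownames(mat) <- c("A", "C", "G", "T")
  if (ncol(mat) < 4) stop("pwm width must be >= 4")
  if (any(abs(colSums(mat) - 1) > 1e-6))
    stop("pwm columns must sum to 1")
  if (threshold <= 0 || threshold > 1)
    stop("fractional threshold must be in (0, 1]")
  structure(list(id = id, mat = mat, threshold = threshold), class = "pwm")
}

#' Consensus sequence of a PWM (argmax base per position)
#' @param x a [pwm()].
#' @return character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$mat)[apply(x$mat, 2, which.max)], collapse = "")
}

# log2-odds score matrix vs background, with a 5th zero row for N bases
pwm_score_matrix <- function(x, bg = rep(0.25, 4), floor_prob = 1e-4) {
  s <- log2(pmax(x$mat, floor_prob) / bg)
  rbind(s, N = 0)
}

#' Maximum attainable log-odds score of a PWM
#' @param x a [pwm()].
#' @param bg background base probabilities (A,C,G,T).
#' @return numeric scalar.
#' @export
pwm_max_score <- function(x, bg = rep(0.25, 4)) {
  sum(apply(pwm_score_matrix(x, bg)[1:4, , drop = FALSE], 2, max))
}

# reverse-complement a pwm
pwm_revcomp <- function(x) {
  m <- x$mat[4:1, ncol(x$mat):1, drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  pwm(x$id, m, x$threshold)
}

#' Read JASPAR-format motifs
#'
#' Parses the classic JASPAR PFM text format (`>ID name` header followed by
#' four `A [ ... ]` count rows); counts are column-normalised to
#' probabilities.
#'
#' @param path file path.
#' @param threshold fractional score threshold stored on each motif.
#' @return named list of [pwm()] objects.
#' @export
read_jaspar_motifs <- function(path, threshold = 0.90) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records found in ", path)
  out <- list()
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(hdr, "\\s+")[[1]][1]
    rows <- lines[(starts[i] + 1):(starts[i] + 4)]
    num <- lapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", trimws(r))
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    })
    mat <- do.call(rbind, num)
    mat <- sweep(mat, 2, colSums(mat), "/")
    out[[id]] <- pwm(id, mat, threshold)
  }
  out
}

#' Read HOMER-format motifs
#'
#' Parses HOMER `.motif` files: `>consensus name threshold` header followed
#' by one row per position with four probabilities (A, C, G, T).
#'
#' @inheritParams read_jaspar_motifs
#' @return named list of [pwm()] objects.
#' @export
read_homer_motifs <- function(path, threshold = 0.90) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no HOMER records found in ", path)
  bounds <- c(starts, length(lines) + 1L)
  out <- list()
  for (i in seq_along(starts)) {
    hdr <- strsplit(sub("^>", "", lines[starts[i]]), "\\s+")[[1]]
    id <- if (length(hdr) >= 2) hdr[2] else hdr[1]
    body <- lines[(starts[i] + 1):(bounds[i + 1] - 1L)]
    mat <- t(vapply(body, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])[1:4], numeric(4)))
    out[[id]] <- pwm(id, sweep(t(mat), 2, colSums(t(mat)), "/"), threshold)
  }
  out
}

#' Extract promoter sequences around transcription start sites
#'
#' Promoters are defined as `upstream` bases before and `downstream` bases
#' after the TSS (defaults 1500/200). BED input is 0-based half-open with a
#' strand column; for plus-strand genes the window is
#' `[TSS - upstream, TSS + downstream)` in 0-based coordinates, and for
#' minus-strand genes the mirrored window is taken and reverse-complemented.
#' Windows truncated at contig edges are flagged; TSSs off their contig are
#' skipped with a warning.
#'
#' @param tss a `GRanges` (e.g. from [rtracklayer::import()]) with names or a
#'   `name` column identifying genes, or a path to a BED file.
#' @param genome a named [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param upstream,downstream window sizes in bases.
#' @return object of class `promoter_set`: list with `sequences`
#'   (DNAStringSet named by gene), `upstream`, `downstream`, `truncated`
#'   (named logical).
#' @export
extract_promoters <- function(tss, genome, upstream = 1500, downstream = 200) {
  if (is.character(tss)) tss <- rtracklayer::import(tss)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom <- as.character(GenomicRanges::seqnames(tss))
  strand <- as.character(GenomicRanges::strand(tss))
  gene <- if (!is.null(tss$name)) tss$name else names(tss)
  if (is.null(gene)) gene <- sprintf("region%04d", seq_along(tss))
  # 0-based TSS coordinate
  t0 <- ifelse(strand == "-", GenomicRanges::end(tss) - 1L,
               GenomicRanges::start(tss) - 1L)

  seqs <- character(0)
  trunc <- logical(0)
  kept <- character(0)
  for (i in seq_along(tss)) {
    contig <- genome[[chrom[i]]]
    len <- length(contig)
    if (is.na(t0[i]) || t0[i] < 0 || t0[i] >= len) {
      warning("TSS for ", gene[i], " is off contig ", chrom[i], "; skipped")
      next
    }
    if (strand[i] == "-") {
      from0 <- t0[i] - downstream + 1L
      to0 <- t0[i] + upstream + 1L   # half-open
    } else {
      from0 <- t0[i] - upstream
      to0 <- t0[i] + downstream
    }
    cf <- max(from0, 0L)
    ct <- min(to0, len)
    s <- Biostrings::subseq(contig, start = cf + 1L, end = ct)
    if (strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs <- c(seqs, as.character(s))
    trunc <- c(trunc, cf != from0 || ct != to0)
    kept <- c(kept, gene[i])
  }
  sequences <- Biostrings::DNAStringSet(setNames(seqs, kept))
  structure(list(sequences = sequences, upstream = upstream,
                 downstream = downstream, truncated = setNames(trunc, kept)),
            class = "promoter_set")
}

#' Scan promoters with a PWM
#'
#' Log-odds scoring against a uniform background at every position on both
#' strands; a position is a hit if its score reaches `threshold x max-score`
#' (fractional mode, the "90% match" convention) or an absolute log-odds
#' cutoff. `N` bases contribute zero to the score. Positions are 1-based and
#' refer to the leftmost base of the motif footprint on the promoter's
#' forward (reported) orientation.
#'
#' @param promoters a `promoter_set` or a named [Biostrings::DNAStringSet].
#' @param x a [pwm()].
#' @param threshold overrides `x$threshold` when given.
#' @param absolute if TRUE, `threshold` is an absolute log-odds score.
#' @param bg background base probabilities.
#' @return data.frame with columns gene, position, strand, score.
#' @export
scan_pwm <- function(promoters, x, threshold = NULL, absolute = FALSE,
                     bg = rep(0.25, 4)) {
  seqs <- if (inherits(promoters, "promoter_set")) promoters$sequences
          else Biostrings::DNAStringSet(promoters)
  thr_frac <- if (is.null(threshold)) x$threshold else threshold
  cutoff <- if (absolute) thr_frac else thr_frac * pwm_max_score(x, bg)
  sm_fwd <- pwm_score_matrix(x, bg)
  sm_rev <- pwm_score_matrix(pwm_revcomp(x), bg)
  w <- ncol(x$mat)
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

  res <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    chars <- strsplit(as.character(seqs[[i]]), "")[[1]]
    v <- unname(code[chars])
    v[is.na(v)] <- 5L
    L <- length(v)
    if (L < w) { res[[i]] <- NULL; next }
    np <- L - w + 1L
    sc_f <- numeric(np)
    sc_r <- numeric(np)
    for (j in seq_len(w)) {
      b <- v[j:(j + np - 1L)]
      sc_f <- sc_f + sm_fwd[cbind(b, j)]
      sc_r <- sc_r + sm_rev[cbind(b, j)]
    }
    hf <- which(sc_f >= cutoff)
    hr <- which(sc_r >= cutoff)
    if (length(hf) + length(hr) == 0) { res[[i]] <- NULL; next }
    res[[i]] <- data.frame(
      gene = names(seqs)[i],
      position = c(hf, hr),
      strand = rep(c("+", "-"), c(length(hf), length(hr))),
      score = c(sc_f[hf], sc_r[hr]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene = character(0), position = integer(0),
                      strand = character(0), score = numeric(0))
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric test of each annotation term against a
#' target gene list over a background universe, with Bonferroni adjustment
#' across the tested terms. Serves the roles of known-motif enrichment and
#' GO/KEGG over-representation; annotation terms are consumed as flat sets.
#'
#' @param target character vector of genes of interest; must be a subset of
#'   `background`.
#' @param background character vector: the gene universe (e.g. all genes
#'   passing the expression filter).
#' @param annotation named list mapping term -> gene ids.
#' @return data.frame with term, overlap, target_size, term_size,
#'   background_size, p, p_bonferroni; one row per term, input order.
#' @export
overrepresentation_test <- function(target, background, annotation) {
  target <- unique(target)
  background <- unique(background)
  bad <- setdiff(target, background)
  if (length(bad))
    stop("target genes missing from background: ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  n_terms <- length(annotation)
  rows <- lapply(names(annotation), function(tm) {
    term_bg <- intersect(unique(annotation[[tm]]), background)
    ov <- length(intersect(target, term_bg))
    m <- length(term_bg)
    N <- length(background)
    k <- length(target)
    p <- phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(term = tm, overlap = ov, target_size = k, term_size = m,
               background_size = N, p = p,
               p_bonferroni = min(1, p * n_terms),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Motif over-representation in a gene set
#'
#' Scans all promoters with each PWM, reduces hits to a per-gene indicator
#' (a gene "has" the motif if it has >= 1 hit at the threshold), and runs
#' [overrepresentation_test()] of the target list against the background.
#'
#' @param promoters a `promoter_set` covering at least the background genes.
#' @param pwms named list of [pwm()] objects.
#' @param target,background gene id vectors.
#' @param ... passed to [scan_pwm()].
#' @return list with `enrichment` (data.frame) and `hits` (named list of
#'   genes with >= 1 hit per motif).
#' @export
motif_enrichment <- function(promoters, pwms, target, background, ...) {
  hits <- lapply(pwms, function(p) unique(scan_pwm(promoters, p, ...)$gene))
  names(hits) <- vapply(pwms, `[[`, "", "id")
  list(enrichment = overrepresentation_test(target, background, hits),
       hits = hits)
}
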