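test_that("PWM construction and motif file parsing", {
  expect_error(pwm("x", matrix(0.25, 4, 3)), "width")
  bad <- matrix(0.3, 4, 5)
  expect_error(pwm("x", bad), "sum to 1")

  pwms <- read_jaspar_motifs(system.file("extdata", "synthetic_motifs.jaspar",
                                         package = "ageomics"))
  expect_named(pwms, c("GRE_synth", "ETS_synth", "HOX_synth"))
  expect_equal(vapply(pwms, function(p) ncol(p$mat), integer(1)),
               c(GRE_synth = 15L, ETS_synth = 10L, HOX_synth = 8L))
  for (p in pwms) expect_equal(colSums(p$mat), rep(1, ncol(p$mat)),
                               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(pwm_consensus(pwms$ETS_synth), "ACAGGAAGTG")

  homer <- withr::local_tempfile(fileext = ".motif")
  writeLines(c(">ACGT demo_motif 5.0",
               "0.85 0.05 0.05 0.05",
               "0.05 0.85 0.05 0.05",
               "0.05 0.05 0.85 0.05",
               "0.05 0.05 0.05 0.85"), homer)
  hm <- read_homer_motifs(homer)
  expect_equal(pwm_consensus(hm$demo_motif), "ACGT")
})

test_that("promoter extraction uses BED-style half-open windows per strand", {
  genome_seq <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                      collapse = "")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 test contig", genome_seq), fa)
  bed <- withr::local_tempfile(fileext = ".bed")
  # BED: 0-based half-open; name, score, strand
  writeLines(c("chr1\t2000\t2001\tplus_gene\t0\t+",
               "chr1\t2000\t2001\tminus_gene\t0\t-",
               "chr1\t100\t101\tedge_gene\t0\t+"), bed)
  prom <- extract_promoters(bed, fa, upstream = 1500, downstream = 200)

  expected_plus <- substr(genome_seq, 501, 2200)    # [500, 2200) 0-based
  expect_equal(as.character(prom$sequences[["plus_gene"]]), expected_plus)
  # minus strand: mirrored window [1801, 3501) 0-based, reverse-complemented
  mirror <- substr(genome_seq, 1802, 3501)
  expect_equal(as.character(prom$sequences[["minus_gene"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(mirror))))
  expect_true(prom$truncated[["edge_gene"]])
  expect_false(prom$truncated[["plus_gene"]])

  # boundary: upstream 0, downstream 1 is the TSS base itself
  p1 <- extract_promoters(bed, fa, upstream = 0, downstream = 1)
  expect_equal(as.character(p1$sequences[["plus_gene"]]),
               substr(genome_seq, 2001, 2001))

  bad_bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99999\t100000\toff_gene\t0\t+", bad_bed)
  expect_warning(off <- extract_promoters(bad_bed, fa), "off contig")
  expect_equal(length(off$sequences), 0L)
})

test_that("PWM scanning is exact against a naive rescanning oracle", {
  pwms <- read_jaspar_motifs(system.file("extdata", "synthetic_motifs.jaspar",
                                         package = "ageomics"))
  ets <- pwms$ETS_synth
  set.seed(89)
  seqs <- vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- sprintf("p%03d", 1:100)
  # plant a forward consensus and a reverse-complement consensus
  cons <- pwm_consensus(ets)
  rcons <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons)))
  substr(seqs[1], 11, 20) <- cons
  substr(seqs[2], 31, 40) <- rcons
  hits <- scan_pwm(Biostrings::DNAStringSet(seqs), ets, threshold = 0.85)

  expect_true(any(hits$gene == "p001" & hits$position == 11 &
                    hits$strand == "+" & abs(hits$score - pwm_max_score(ets)) < 1e-9))
  expect_true(any(hits$gene == "p002" & hits$position == 31 &
                    hits$strand == "-" & abs(hits$score - pwm_max_score(ets)) < 1e-9))

  # naive oracle: per-position loop over both strands
  smat <- rbind(log2(pmax(ets$mat, 1e-4) / 0.25), N = 0)
  rownames(smat) <- c("A", "C", "G", "T", "N")
  cutoff <- 0.85 * pwm_max_score(ets)
  w <- ncol(ets$mat)
  oracle <- list()
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (g in names(seqs)) {
    ch <- strsplit(seqs[[g]], "")[[1]]
    for (pos in seq_len(length(ch) - w + 1)) {
      win <- ch[pos:(pos + w - 1)]
      sf <- sum(smat[cbind(match(win, rownames(smat)), seq_len(w))])
      rcw <- rev(unname(comp[win]))
      sr <- sum(smat[cbind(match(rcw, rownames(smat)), seq_len(w))])
      if (sf >= cutoff)
        oracle[[length(oracle) + 1]] <- c(g, pos, "+", sf)
      if (sr >= cutoff)
        oracle[[length(oracle) + 1]] <- c(g, pos, "-", sr)
    }
  }
  odf <- as.data.frame(do.call(rbind, oracle), stringsAsFactors = FALSE)
  names(odf) <- c("gene", "position", "strand", "score")
  odf$position <- as.integer(odf$position)
  odf$score <- as.numeric(odf$score)
  key <- function(d) sort(paste(d$gene, d$position, d$strand,
                                round(d$score, 9)))
  expect_identical(key(hits), key(odf))

  # short promoter yields no hits rather than an error
  expect_equal(nrow(scan_pwm(Biostrings::DNAStringSet(c(tiny = "ACGT")), ets)),
               0L)
  # N bases contribute zero: consensus with one N scores max minus that column
  n_seq <- sub("^(.)", "N", cons)
  sc <- scan_pwm(Biostrings::DNAStringSet(c(n = n_seq)), ets, threshold = 0.5)
  col1 <- max(log2(pmax(ets$mat[, 1], 1e-4) / 0.25))
  expect_equal(sc$score[sc$strand == "+"], pwm_max_score(ets) - col1,
               tolerance = 1e-9)
})

test_that("scanning is strand-symmetric", {
  pwms <- read_jaspar_motifs(system.file("extdata", "synthetic_motifs.jaspar",
                                         package = "ageomics"))
  ets <- pwms$ETS_synth
  set.seed(97)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  # plant one site per strand so the comparison is non-trivial
  cons <- pwm_consensus(ets)
  substr(s, 21, 30) <- cons
  substr(s, 101, 110) <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons)))
  fwd <- scan_pwm(Biostrings::DNAStringSet(c(x = s)), ets, threshold = 0.7)
  rev <- scan_pwm(Biostrings::DNAStringSet(c(x = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))))), ets,
    threshold = 0.7)
  w <- ncol(ets$mat)
  mirrored <- data.frame(position = 200 - w + 2 - rev$position,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         score = rev$score)
  o1 <- fwd[order(fwd$position, fwd$strand), c("position", "strand", "score")]
  o2 <- mirrored[order(mirrored$position, mirrored$strand), ]
  expect_equal(o1$position, o2$position)
  expect_equal(o1$strand, o2$strand)
  expect_equal(o1$score, o2$score, tolerance = 1e-9)
})

test_that("hypergeometric over-representation matches enumeration", {
  bg <- paste0("g", 1:20)
  annot <- list(term = bg[1:5])
  # closed form: universe 20, term 5, target 5, overlap 4
  res <- overrepresentation_test(bg[c(1:4, 10)], bg, annot)
  exact <- sum(vapply(4:5, function(k)
    choose(5, k) * choose(15, 5 - k), numeric(1))) / choose(20, 5)
  expect_equal(res$p, exact, tolerance = 1e-12)
  expect_equal(res$overlap, 4L)

  # target = background: p = 1 for every term
  res2 <- overrepresentation_test(bg, bg, list(a = bg[1:5], b = bg[6:7]))
  expect_equal(res2$p, c(1, 1))

  # enumeration oracle on random small universes
  set.seed(101)
  for (i in 1:20) {
    N <- sample(8:25, 1)
    u <- paste0("u", seq_len(N))
    term <- sample(u, sample(2:(N - 2), 1))
    targ <- sample(u, sample(2:(N - 2), 1))
    p <- overrepresentation_test(targ, u, list(t = term))$p
    ov <- length(intersect(targ, term))
    m <- length(term); k <- length(targ)
    oracle <- sum(vapply(ov:min(m, k), function(x)
      choose(m, x) * choose(N - m, k - x), numeric(1))) / choose(N, k)
    expect_equal(p, oracle, tolerance = 1e-10)
  }

  expect_error(overrepresentation_test(c("g1", "zzz"), bg, annot),
               "missing from background")
  # Bonferroni is order-invariant
  ann <- list(a = bg[1:5], b = bg[3:9], c = bg[10:12])
  r1 <- overrepresentation_test(bg[1:6], bg, ann)
  r2 <- overrepresentation_test(bg[1:6], bg, rev(ann))
  expect_equal(r1$p_bonferroni[match(r2$term, r1$term)], r2$p_bonferroni)
})
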