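test_that("inversion rule requires a sign flip and the two-tier significance", {
  g <- c("a", "b", "c", "d")
  de <- fake_de(g,
    youngHet_vs_youngWt = list(logFC = c(1, 1, 1, 0),
                               p = c(0.001, 0.001, 0.3, 0.001),
                               fdr = c(0.01, 0.01, 0.5, 0.01)),
    agedHet_vs_agedWt = list(logFC = c(-1, 1, -1, -1),
                             p = c(0.03, 0.03, 0.03, 0.03),
                             fdr = c(0.2, 0.2, 0.2, 0.2)))
  inv <- classify_inverted(de)
  expect_identical(inv, "a")      # b: same sign; c: not significant anywhere
  # d: zero fold-change carries no sign, never inverted
  expect_false("d" %in% inv)
  # orientation symmetry: FDR in the aged contrast, raw p in the young one
  de2 <- fake_de(g[1],
    youngHet_vs_youngWt = list(logFC = 1, p = 0.03, fdr = 0.4),
    agedHet_vs_agedWt = list(logFC = -1, p = 0.001, fdr = 0.01))
  expect_identical(classify_inverted(de2), "a")
  expect_error(classify_inverted(fake_de("a",
    youngHet_vs_youngWt = list(logFC = 1, p = 1, fdr = 1))),
    "agedHet_vs_agedWt")
})

test_that("failure and inappropriate-down rules follow their definitions", {
  g <- c("fup", "inap", "normal_ager", "fdown")
  de <- fake_de(g,
    youngHet_vs_youngWt = list(logFC = c(0, 0, 0, 0), p = rep(0.9, 4)),
    agedHet_vs_agedWt = list(logFC = c(-0.1, -2, 0.1, 0.3),
                             p = c(0.8, 1e-4, 0.8, 0.4),
                             fdr = c(0.9, 1e-3, 0.9, 0.6)),
    agedWt_vs_youngWt = list(logFC = c(2, 0, 2, -2),
                             p = c(1e-4, 0.9, 1e-4, 1e-4),
                             fdr = c(1e-3, 0.9, 1e-3, 1e-3)),
    agedHet_vs_youngHet = list(logFC = c(0, -2, 2, 0),
                               p = c(0.9, 1e-4, 1e-4, 0.9),
                               fdr = c(0.9, 1e-3, 1e-3, 0.9)))
  sets <- classify_failure_and_inappropriate(de)
  # "not up-regulated" = failing the FDR-and-sign criterion: both the flat
  # gene and the genuinely concordant ager satisfy the literal rule
  expect_setequal(sets$failure_up, c("fup", "normal_ager"))
  expect_identical(sets$failure_down, "fdown")
  expect_identical(sets$inappropriately_down, "inap")
})

test_that("pattern labels form a partition under the precedence order", {
  # one gene satisfying both the inversion and inappropriate-down rules
  g <- "dual"
  de <- fake_de(g,
    youngHet_vs_youngWt = list(logFC = 2, p = 0.001, fdr = 0.01),
    agedHet_vs_agedWt = list(logFC = -2, p = 0.001, fdr = 0.01),
    agedWt_vs_youngWt = list(logFC = 0, p = 0.9, fdr = 0.9),
    agedHet_vs_youngHet = list(logFC = -4, p = 0.001, fdr = 0.01))
  pats <- classify_patterns(de)
  expect_identical(pats$label, "inverted")
  raw <- attr(pats, "raw_sets")
  expect_true("dual" %in% raw$inverted)
  expect_true("dual" %in% raw$inappropriately_down)
})

test_that("concordance fraction counts matching fold-change signs", {
  g <- c("a", "b", "c", "d")
  de <- fake_de(g,
    youngHet_vs_youngWt = list(logFC = c(1, -1, 1, 1),
                               p = c(0.001, 0.001, 0.001, 0.5),
                               fdr = c(0.01, 0.01, 0.01, 0.8)),
    agedWt_vs_youngWt = list(logFC = c(2, -3, -1, 2), p = rep(0.5, 4)))
  cc <- concordance_fraction(de, "youngHet_vs_youngWt", "agedWt_vs_youngWt")
  expect_equal(cc$numerator, 2L)
  expect_equal(cc$denominator, 3L)
  expect_equal(cc$fraction, 2 / 3)
  # identity comparison is fully concordant
  de2 <- fake_de(g, A = list(logFC = c(1, -1, 2, 0.5),
                             p = rep(0.001, 4), fdr = rep(0.01, 4)))
  de2$tables$B <- de2$tables$A
  expect_equal(concordance_fraction(de2, "A", "B")$fraction, 1)
  # empty denominator is flagged, not fatal
  de3 <- fake_de("a", A = list(logFC = 1, p = 0.9, fdr = 0.9))
  de3$tables$B <- de3$tables$A
  expect_warning(cc3 <- concordance_fraction(de3, "A", "B"), "undefined")
  expect_true(is.na(cc3$fraction))
})

test_that("aging signature is the sign-concordant FDR intersection", {
  g <- c("a", "b", "c")
  de <- fake_de(g,
    agedWt_vs_youngWt = list(logFC = c(1, 1, -1), p = rep(0.001, 3),
                             fdr = c(0.01, 0.01, 0.01)),
    agedHet_vs_youngHet = list(logFC = c(1, -1, -1), p = rep(0.001, 3),
                               fdr = c(0.01, 0.01, 0.6)))
  expect_identical(aging_signature(de), "a")
  de$tables$agedHet_vs_youngHet <- de$tables$agedWt_vs_youngWt
  expect_identical(aging_signature(de), g)
})

test_that("fold-change display clustering matches a brute-force agglomerator", {
  set.seed(31)
  fc <- matrix(rnorm(8 * 4, sd = 2), 8, 4,
               dimnames = list(letters[1:8], contrast_names()))
  fc[1, ] <- fc[2, ]                       # identical profiles
  de <- fake_de(letters[1:8],
    youngHet_vs_youngWt = list(logFC = fc[, 1], p = 1),
    agedHet_vs_agedWt = list(logFC = fc[, 2], p = 1),
    agedWt_vs_youngWt = list(logFC = fc[, 3], p = 1),
    agedHet_vs_youngHet = list(logFC = fc[, 4], p = 1))
  out <- cluster_fc_profiles(de, k = 3)
  cl <- setNames(out$cluster, out$gene_id)
  expect_equal(cl[["a"]], cl[["b"]])

  # naive complete-linkage agglomeration oracle
  naive_complete <- function(d, k) {
    groups <- as.list(seq_len(nrow(d)))
    while (length(groups) > k) {
      best <- c(Inf, NA, NA)
      for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
        h <- max(d[groups[[i]], groups[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
      groups[[best[3]]] <- c(groups[[best[3]]], groups[[best[2]]])
      groups[[best[2]]] <- NULL
    }
    lab <- integer(nrow(d))
    for (i in seq_along(groups)) lab[groups[[i]]] <- i
    lab
  }
  d <- as.matrix(dist(fc))
  oracle <- naive_complete(d, 3)
  expect_equal(adjusted_rand_index(cl[rownames(fc)], oracle), 1)

  # opposite profiles separate at k = 2; display filter drops small changes
  g2 <- fake_de(c("up", "down", "tiny"),
    youngHet_vs_youngWt = list(logFC = c(2, -2, 0.1), p = 1),
    agedHet_vs_agedWt = list(logFC = c(2, -2, 0.1), p = 1),
    agedWt_vs_youngWt = list(logFC = c(-2, 2, -0.1), p = 1),
    agedHet_vs_youngHet = list(logFC = c(-2, 2, 0.1), p = 1))
  out2 <- cluster_fc_profiles(g2, k = 2)
  expect_false("tiny" %in% out2$gene_id)
  cl2 <- setNames(out2$cluster, out2$gene_id)
  expect_true(cl2[["up"]] != cl2[["down"]])
})

test_that("aging-signature recovery tracks the joint two-contrast detection
           rate", {
  # requiring FDR < 0.05 in both aging contrasts compounds the per-contrast
  # sensitivities, so the honest oracle is their product
  cfg <- sim_config(n_genes = 800, seed = 3,
                    pattern_counts = c(aging_only = 80))
  sim <- simulate_counts(cfg)
  de <- run_de(sim$counts, sim$design)
  planted <- names(sim$truth$pattern)[sim$truth$pattern == "aging_only"]
  wt <- de$tables$agedWt_vs_youngWt[planted, ]
  het <- de$tables$agedHet_vs_youngHet[planted, ]
  s1 <- mean(wt$fdr < 0.05 & wt$logFC > 0)
  s2 <- mean(het$fdr < 0.05 & het$logFC > 0)
  sig <- aging_signature(de)
  sens <- mean(planted %in% sig)
  expect_gt(sens, 0.8)
  expect_lt(abs(sens - s1 * s2), 0.05)
  # and no null gene sneaks in at a meaningful rate
  expect_lt(mean(!sig %in% planted), 0.05)
})

test_that("classifier output is pure and deterministic", {
  cfg <- sim_config(n_genes = 300, seed = 17,
                    pattern_counts = c(inverted = 30, fail_up = 20))
  sim <- simulate_counts(cfg)
  de <- run_de(sim$counts, sim$design)
  p1 <- classify_patterns(de)
  p2 <- classify_patterns(de)
  expect_identical(p1, p2)
})
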