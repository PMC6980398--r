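test_that("peptide matrix construction validates its contract", {
  long <- data.frame(peptide_id = rep(c("p1", "p2"), each = 2),
                     protein_id = "prA",
                     sample_id = rep(c("s1", "s2"), 2),
                     intensity = c(4, 8, 16, NA))
  pm <- peptide_matrix(long)
  expect_equal(pm$mat["p2", "s2"], NA_real_)
  expect_equal(unname(pm$protein), c("prA", "prA"))
  expect_error(peptide_matrix(rbind(long, long[1, ])), "unique")
  expect_error(peptide_matrix(long[, 1:3]), "columns")
})

test_that("quantile normalisation equalises sorted columns and matches a
           rank/mean oracle", {
  set.seed(103)
  raw <- matrix(2^rnorm(18, 20, 2), 6, 3,
                dimnames = list(paste0("p", 1:6), paste0("s", 1:3)))
  norm <- normalize_peptides(raw)
  sorted <- apply(norm, 2, sort)
  expect_equal(sorted[, 1], sorted[, 2], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sorted[, 1], sorted[, 3], tolerance = 1e-12,
               ignore_attr = TRUE)

  # independent oracle: replace each value by the mean of the order
  # statistics at its rank (no ties in this fixture)
  lg <- log2(raw)
  ref <- rowMeans(apply(lg, 2, sort))
  oracle <- apply(lg, 2, function(x) ref[rank(x)])
  expect_equal(unname(norm), unname(oracle), tolerance = 1e-10)

  # two samples already identical in distribution stay put up to rank mapping
  same <- cbind(a = 2^c(1, 2, 3), b = 2^c(3, 1, 2))
  n2 <- normalize_peptides(same)
  expect_equal(sort(n2[, "a"]), sort(n2[, "b"]), ignore_attr = TRUE)
  expect_error(normalize_peptides(cbind(a = c(1, NA), b = c(NA, NA))),
               "zero observed")
  expect_error(normalize_peptides(cbind(a = c(-1, 2), b = c(1, 2))), "> 0")
})

test_that("censored imputation respects the censor point and beats
           minimum substitution", {
  full <- matrix(rnorm(40, 20, 1), 8, 5,
                 dimnames = list(paste0("p", 1:8), paste0("s", 1:5)))
  expect_identical(impute_censored(full), full)

  # left-censor the lowest 20% and compare recovery strategies
  set.seed(107)
  truth <- matrix(rnorm(200 * 6, 20, 2), 200, 6,
                  dimnames = list(sprintf("p%03d", 1:200), paste0("s", 1:6)))
  thr <- quantile(truth, 0.2)
  obs <- truth
  obs[obs < thr] <- NA
  keep <- rowSums(!is.na(obs)) > 0
  obs <- obs[keep, ]
  imp <- impute_censored(obs)
  cmin <- apply(obs, 2, min, na.rm = TRUE)
  cens <- is.na(obs)
  expect_true(all(imp[cens] <= matrix(cmin, nrow(obs), 6,
                                      byrow = TRUE)[cens] + 1e-9))
  err_aft <- mean(abs(imp[cens] - truth[keep, ][cens]))
  naive <- matrix(cmin, nrow(obs), 6, byrow = TRUE)
  err_min <- mean(abs(naive[cens] - truth[keep, ][cens]))
  expect_lt(err_aft, err_min)

  allc <- rbind(obs, gone = rep(NA_real_, 6))
  expect_warning(out <- impute_censored(allc), "censored in every sample")
  expect_false("gone" %in% rownames(out))
})

test_that("median polish summarisation matches Tukey sweeps", {
  # single-peptide protein passes through
  m1 <- matrix(seq(2, 12, by = 2), 1, 6,
               dimnames = list("pep1", paste0("s", 1:6)))
  pt1 <- median_polish_summarize(m1, protein = c(pep1 = "A"))
  expect_equal(pt1$abundance["A", ], m1[1, ])

  # two peptides offset by a constant: offset splits into row effects
  v <- c(10, 11, 12, 9, 8, 10)
  m2 <- rbind(pep1 = v, pep2 = v + 3)
  colnames(m2) <- paste0("s", 1:6)
  pt2 <- median_polish_summarize(m2, protein = c(pep1 = "B", pep2 = "B"))
  expect_equal(pt2$abundance["B", ], v + 1.5, tolerance = 1e-9,
               ignore_attr = TRUE)

  # independent sweep oracle on random matrices
  polish_oracle <- function(x, eps = 1e-4, maxiter = 10) {
    t0 <- 0; r <- numeric(nrow(x)); cc <- numeric(ncol(x)); z <- x
    oldsum <- 0
    for (i in seq_len(maxiter)) {
      rdelta <- apply(z, 1, median, na.rm = TRUE)
      z <- z - rdelta; r <- r + rdelta
      delta <- median(cc, na.rm = TRUE)
      cc <- cc - delta; t0 <- t0 + delta
      cdelta <- apply(z, 2, median, na.rm = TRUE)
      z <- sweep(z, 2, cdelta); cc <- cc + cdelta
      delta <- median(r, na.rm = TRUE)
      r <- r - delta; t0 <- t0 + delta
      newsum <- sum(abs(z), na.rm = TRUE)
      if (newsum == 0 || abs(newsum - oldsum) < eps * newsum) break
      oldsum <- newsum
    }
    t0 + cc
  }
  set.seed(109)
  for (i in 1:10) {
    x <- matrix(rnorm(30, 20, 2), 5, 6)
    dimnames(x) <- list(paste0("p", 1:5), paste0("s", 1:6))
    pt <- median_polish_summarize(x, protein = setNames(rep("P", 5),
                                                        rownames(x)))
    expect_equal(unname(pt$abundance["P", ]), unname(polish_oracle(x)),
                 tolerance = 1e-6)
    # residual row/col medians vanish at convergence
    # with an even number of columns the polish can settle in a two-cycle
    # whose residual medians stay at the 1e-3 scale rather than vanishing
    mp <- suppressWarnings(medpolish(x, eps = 1e-6, maxiter = 500,
                                     trace.iter = FALSE))
    expect_lt(max(abs(apply(mp$residuals, 1, median))), 2e-3)
    expect_lt(max(abs(apply(mp$residuals, 2, median))), 2e-3)
  }
})

test_that("complete-case filtering keeps only fully observed proteins", {
  ab <- rbind(full = 1:4, hole = c(1, NA, 3, 4))
  colnames(ab) <- paste0("s", 1:4)
  pt <- structure(list(abundance = ab,
                       n_peptides = c(full = 2L, hole = 3L),
                       complete = c(full = TRUE, hole = FALSE)),
                  class = "protein_table")
  f <- filter_complete(pt)
  expect_identical(rownames(f$abundance), "full")
  expect_identical(filter_complete(ab), ab["full", , drop = FALSE])
})

test_that("differential abundance power matches the closed-form moderated-t
           oracle at effect 2 SD, n = 3 per group", {
  study <- make_study()
  set.seed(113)
  hits <- matrix(NA_real_, 10, 2)
  dfs <- numeric(10)
  for (r in 1:10) {
    ab <- null_expr(300, study)
    ab[1:50, study$condition == "young_het"] <-
      ab[1:50, study$condition == "young_het"] + 2
    da <- differential_abundance(ab, study)
    tab <- da$tables[["youngHet_vs_youngWt"]]
    hits[r, ] <- c(mean(tab$p[1:50] < 0.05), mean(tab$fdr[1:50] < 0.05))
    dfs[r] <- da$params$d0 + da$params$df_resid
  }
  power_hat <- mean(hits[, 1])
  df <- median(dfs)
  ncp <- 2 / sqrt(2 / 3)
  power_theory <- pt(qt(0.025, df), df, ncp) + 1 - pt(qt(0.975, df), df, ncp)
  se <- sqrt(power_theory * (1 - power_theory) / 500)
  expect_lt(abs(power_hat - power_theory), 3 * se + 0.02)
})

test_that("mRNA-protein Spearman behaves at its limits", {
  set.seed(127)
  logcpm <- matrix(rep(rnorm(50, 8, 2), 4), 50, 4,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  prot <- 2^(logcpm / 4)      # strictly monotone transform of the profile
  rownames(prot) <- paste0("pr", 1:50)
  map <- data.frame(protein_id = rownames(prot), gene_id = rownames(logcpm))
  expect_equal(mrna_protein_correlation(logcpm, prot, map)$rs, 1)

  indep <- matrix(rnorm(50 * 4), 50, 4, dimnames = dimnames(prot))
  rs0 <- mrna_protein_correlation(logcpm, indep, map)$rs
  expect_lt(abs(rs0), 2.58 / sqrt(49))
  expect_warning(
    r <- mrna_protein_correlation(logcpm[1:2, ], prot[1:2, ], map[1:2, ]),
    "fewer than 3")
  expect_true(is.na(r$rs))
})

test_that("the two-batch proteomics flow reproduces planted completeness", {
  cfg <- sim_config(n_genes = 200, seed = 31, censor_quantile = 0.05,
                    pattern_counts = c(aging_only = 20))
  sim <- simulate_counts(cfg)
  pep <- simulate_peptides(sim$truth, cfg)
  pt <- suppressWarnings(run_proteomics(pep$peptides, sim$design))
  expect_true(all(pt$complete))
  expect_false(any(is.na(pt$abundance)))
  expect_true(all(rownames(pt$abundance) %in% pep$gene_map$protein_id))
  # survivors equal the direct completeness count
  expect_equal(nrow(pt$abundance), sum(rowSums(is.na(pt$abundance)) == 0))
})
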