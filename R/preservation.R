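#' @name module_preservation
#' @title Cross-network module preservation statistics
#'
#' @description Permutation-based assessment of whether modules defined in a
#' reference network keep their density and connectivity structure in a test
#' network. Three density statistics are computed in the test network on the
#' reference-defined module (mean intra-module correlation, mean intra-module
#' signed adjacency, proportion of variance explained by the module
#' eigengene) and three connectivity statistics as cross-network correlations
#' (of intramodular connectivity, of eigengene-based connectivity kME, and of
#' the intra-module correlation entries). The null is built by permuting
#' gene-module assignments in the test network with module sizes preserved;
#' `Z = (obs - mean_perm) / sd_perm` per statistic, `Z_density` and
#' `Z_connectivity` are the medians of their groups and
#' `Z_summary = (Z_density + Z_connectivity) / 2`. Scores below 2 indicate no
#' preservation, 2-10 weak-to-moderate and above 10 strong preservation.
NULL

# align ref and test expression through an ortholog map; rows end up in the
# same (ref-id) order in both matrices
align_networks <- function(expr_ref, expr_test, ortho = NULL) {
  if (is.null(ortho)) {
    shared <- intersect(rownames(expr_ref), rownames(expr_test))
    if (!length(shared)) stop("no shared genes between the networks")
    return(list(R = expr_ref[shared, , drop = FALSE],
                T = expr_test[shared, , drop = FALSE]))
  }
  from <- as.character(ortho[[1]])
  to <- as.character(ortho[[2]])
  keep <- from %in% rownames(expr_ref) & to %in% rownames(expr_test)
  keep <- keep & !duplicated(from) & !duplicated(to)   # one-to-one universe
  if (!any(keep)) stop("ortholog map links no genes across the networks")
  R <- expr_ref[from[keep], , drop = FALSE]
  T <- expr_test[to[keep], , drop = FALSE]
  rownames(T) <- from[keep]
  list(R = R, T = T)
}

# fast Pearson correlation between the rows of m
row_cor <- function(m) {
  s <- t(scale(t(m)))
  cc <- tcrossprod(s) / (ncol(m) - 1)
  cc[cc > 1] <- 1
  cc[cc < -1] <- -1
  cc
}

# eigengene (unit-norm samples vector, aligned with mean profile) and the
# proportion of variance it explains, from a genes x samples block
block_eigengene <- function(x) {
  xs <- t(scale(t(x)))
  sv <- svd(xs, nu = 0, nv = 1)
  v <- sv$v[, 1]
  if (cor(v, colMeans(xs)) < 0) v <- -v
  list(me = v, var_explained = sv$d[1]^2 / sum(sv$d^2))
}

# the six preservation statistics of one module; ref is a precomputed list
module_stat_vector <- function(ref, test_rows, beta) {
  ct <- row_cor(test_rows)
  ut <- ct[upper.tri(ct)]
  at <- ((1 + ut) / 2)^beta
  eg <- block_eigengene(test_rows)
  kim_test <- colSums(((1 + ct) / 2)^beta) - 1
  kme_test <- as.vector(cor(t(test_rows), eg$me))
  c(mean_cor = mean(ut),
    mean_adj = mean(at),
    prop_var_explained = eg$var_explained,
    cor_kIM = cor(ref$kim, kim_test),
    cor_kME = cor(ref$kme, kme_test),
    cor_cor = cor(ref$cor_upper, ut))
}

# precompute the reference-side quantities of one module
ref_stats <- function(ref_rows, beta) {
  cr <- row_cor(ref_rows)
  eg <- block_eigengene(ref_rows)
  list(cor_upper = cr[upper.tri(cr)],
       kim = colSums(((1 + cr) / 2)^beta) - 1,
       kme = as.vector(cor(t(ref_rows), eg$me)),
       prop_var = eg$var_explained)
}

density_stat_names <- c("mean_cor", "mean_adj", "prop_var_explained")
connectivity_stat_names <- c("cor_kIM", "cor_kME", "cor_cor")

#' Observed preservation statistics per module
#'
#' @param expr_ref,expr_test genes x samples expression matrices for the
#'   reference and test networks.
#' @param labels_ref named integer module labels on reference genes (0 =
#'   unassigned).
#' @param ortho optional data.frame mapping reference ids (column 1) to test
#'   ids (column 2); defaults to matching rownames.
#' @param beta soft-thresholding power for the signed adjacency.
#' @return data.frame: module, n_genes, the three density and three
#'   connectivity statistics, and an `untestable` flag for modules with
#'   fewer than 3 surviving genes.
#' @export
observed_stats <- function(expr_ref, expr_test, labels_ref, ortho = NULL,
                           beta = 14) {
  al <- align_networks(expr_ref, expr_test, ortho)
  labs <- labels_ref[rownames(al$R)]
  mods <- sort(setdiff(unique(labs[!is.na(labs)]), 0L))
  rows <- lapply(mods, function(m) {
    ix <- which(labs == m)
    if (length(ix) < 3)
      return(data.frame(module = m, n_genes = length(ix),
                        mean_cor = NA, mean_adj = NA,
                        prop_var_explained = NA, cor_kIM = NA, cor_kME = NA,
                        cor_cor = NA, untestable = TRUE))
    rs <- ref_stats(al$R[ix, , drop = FALSE], beta)
    st <- module_stat_vector(rs, al$T[ix, , drop = FALSE], beta)
    cbind(data.frame(module = m, n_genes = length(ix)),
          as.data.frame(as.list(st)), untestable = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation Z-summary module preservation
#'
#' See [module_preservation] for the statistic battery and aggregation. The
#' permutation null reassigns which test-network genes play the role of each
#' module's genes (drawn from the whole aligned universe, module sizes
#' preserved), keeping the reference side fixed.
#'
#' @inheritParams observed_stats
#' @param n_perm number of permutations (>= 20; 200 is conventional).
#' @param seed integer seed; permutation draws are reproducible.
#' @return data.frame of class `preservation_result`: module, n_genes,
#'   observed statistics, per-statistic Z, Z_density, Z_connectivity,
#'   Z_summary, and classification (none / weak-moderate / strong).
#' @export
zsummary <- function(expr_ref, expr_test, labels_ref, ortho = NULL,
                     n_perm = 200, seed = 1L, beta = 14) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  al <- align_networks(expr_ref, expr_test, ortho)
  labs <- labels_ref[rownames(al$R)]
  mods <- sort(setdiff(unique(labs[!is.na(labs)]), 0L))
  mods <- mods[vapply(mods, function(m) sum(labs == m, na.rm = TRUE) >= 3,
                      logical(1))]
  if (!length(mods)) stop("no testable module (need >= 3 mapped genes)")
  idx <- lapply(mods, function(m) which(labs == m))
  refs <- lapply(idx, function(ix) ref_stats(al$R[ix, , drop = FALSE], beta))

  obs <- t(mapply(function(rs, ix)
    module_stat_vector(rs, al$T[ix, , drop = FALSE], beta), refs, idx))

  nuniv <- nrow(al$T)
  set.seed(sub_seed(seed, 40000L))
  perm_stats <- array(NA_real_, c(n_perm, length(mods), 6))
  for (p in seq_len(n_perm)) {
    perm <- sample.int(nuniv)
    for (m in seq_along(mods))
      perm_stats[p, m, ] <- module_stat_vector(
        refs[[m]], al$T[perm[idx[[m]]], , drop = FALSE], beta)
  }
  stat_names <- c(density_stat_names, connectivity_stat_names)
  z <- matrix(NA_real_, length(mods), 6,
              dimnames = list(NULL, paste0("z_", stat_names)))
  for (m in seq_along(mods)) for (s in 1:6) {
    mu <- mean(perm_stats[, m, s], na.rm = TRUE)
    sdev <- sd(perm_stats[, m, s], na.rm = TRUE)
    z[m, s] <- if (is.na(sdev) || sdev == 0) NA_real_
               else (obs[m, s] - mu) / sdev
  }
  z_density <- apply(z[, paste0("z_", density_stat_names), drop = FALSE],
                     1, median, na.rm = TRUE)
  z_connectivity <- apply(z[, paste0("z_", connectivity_stat_names),
                            drop = FALSE], 1, median, na.rm = TRUE)
  z_summary <- (z_density + z_connectivity) / 2
  classification <- cut(z_summary, c(-Inf, 2, 10, Inf),
                        labels = c("none", "weak-moderate", "strong"),
                        right = FALSE)
  out <- cbind(data.frame(module = mods, n_genes = lengths(idx)),
               as.data.frame(obs), as.data.frame(z),
               data.frame(Z_density = z_density,
                          Z_connectivity = z_connectivity,
                          Z_summary = z_summary,
                          classification = as.character(classification),
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("preservation_result", "data.frame")
  out
}

#' Random-module preservation baseline
#'
#' Evaluates a pseudo-module of uniformly sampled genes exactly as a real
#' module; between genuinely independent networks its Z-summary is expected
#' below 2 (non-significant preservation).
#'
#' @inheritParams zsummary
#' @param size pseudo-module size (default 1000).
#' @return one-row `preservation_result` (module id 0 marks the pseudo
#'   module).
#' @export
random_module_baseline <- function(expr_ref, expr_test, ortho = NULL,
                                   size = 1000, n_perm = 200, seed = 1L,
                                   beta = 14) {
  al <- align_networks(expr_ref, expr_test, ortho)
  if (size > nrow(al$R))
    stop("size exceeds the shared gene universe (", nrow(al$R), ")")
  set.seed(sub_seed(seed, 41000L))
  chosen <- sample(rownames(al$R), size)
  labels <- setNames(rep(0L, nrow(al$R)), rownames(al$R))
  labels[chosen] <- 1L
  res <- zsummary(al$R, al$T, labels, ortho = NULL, n_perm = n_perm,
                  seed = seed, beta = beta)
  res$module <- 0L
  res
}
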