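#' Counts per million
#'
#' CPM on raw library sizes (column sums by default). `log = TRUE` adds a
#' 0.5-count offset before the log2 so zeros stay finite.
#'
#' @param counts genes x samples non-negative matrix.
#' @param lib_sizes optional library sizes (e.g. TMM-scaled effective sizes);
#'   defaults to column sums.
#' @param log return log2-CPM.
#' @return matrix of the same shape.
#' @export
cpm_matrix <- function(counts, lib_sizes = NULL, log = FALSE) {
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("every sample needs a positive library size")
  if (log) log2(sweep(counts + 0.5, 2, lib_sizes, "/") * 1e6)
  else sweep(counts, 2, lib_sizes, "/") * 1e6
}

#' Filter genes by CPM in a minimum number of samples
#'
#' Keeps genes with CPM strictly greater than `min_cpm` in at least
#' `min_samples` samples, computed on raw library sizes; gene order is
#' preserved. The conventional bulk brain filter is >1.5 CPM in at least 6 of
#' 12 libraries.
#'
#' @param counts genes x samples count matrix.
#' @param min_cpm CPM threshold (strict inequality).
#' @param min_samples minimum number of samples exceeding the threshold.
#' @return the retained submatrix.
#' @export
filter_by_cpm <- function(counts, min_cpm = 1.5, min_samples = 6) {
  if (min_samples > ncol(counts))
    stop("min_samples exceeds the number of samples")
  keep <- rowSums(cpm_matrix(counts) > min_cpm) >= min_samples
  if (!any(keep)) warning("no genes pass the CPM filter")
  counts[keep, , drop = FALSE]
}

#' TMM normalisation factors
#'
#' Weighted trimmed mean of M-values: per-sample log2 ratios versus a
#' reference sample are trimmed by 30% on M and 5% on A, weighted by inverse
#' asymptotic (binomial) variances, and exponentiated; genes with a zero
#' count in either sample are excluded from M/A. Factors are normalised so
#' their logs sum to zero. The reference defaults to the sample whose 75th
#' percentile of CPM is closest to the mean of those percentiles.
#'
#' @param counts genes x samples count matrix.
#' @param ref_sample optional reference sample id or index.
#' @param logratio_trim,sum_trim trim fractions for M and A.
#' @return named numeric vector of scale factors (one per sample).
#' @export
tmm_factors <- function(counts, ref_sample = NULL,
                        logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample needs a positive library size")
  if (is.null(ref_sample)) {
    q75 <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
    ref_sample <- which.min(abs(q75 - mean(q75)))
  }
  if (is.character(ref_sample)) ref_sample <- match(ref_sample, colnames(counts))
  ref <- counts[, ref_sample]
  nR <- lib[ref_sample]

  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]
    nO <- lib[j]
    fin <- obs > 0 & ref > 0
    if (!any(fin))
      stop("sample ", colnames(counts)[j] %||% j,
           " shares no positive genes with the reference")
    o <- obs[fin]; r <- ref[fin]
    logR <- log2((o / nO) / (r / nR))
    absE <- (log2(o / nO) + log2(r / nR)) / 2
    v <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1
    hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1
    hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    f <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
    if (!is.finite(f)) 1 else 2^f
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate factors of unwanted variation from replicate groups
#'
#' RUVs-style estimate: expression is centred within each replicate group
#' (groups of samples sharing the same biology, e.g. the four condition
#' groups), removing biological signal by construction; the first `k` right
#' singular vectors of the centred matrix are returned as sample-level
#' covariates W. Columns are unit-norm and mutually orthogonal, with the
#' sign fixed so the first element of each column is non-negative.
#'
#' @param logcpm genes x samples matrix (log scale).
#' @param replicate_groups factor/vector of length `ncol(logcpm)`; every
#'   group must have >= 2 samples.
#' @param k number of unwanted-variation factors (k < number of samples).
#' @return samples x k matrix W.
#' @export
ruv_factors <- function(logcpm, replicate_groups, k = 1) {
  replicate_groups <- as.factor(replicate_groups)
  if (length(replicate_groups) != ncol(logcpm))
    stop("replicate_groups must have one entry per sample")
  if (any(table(replicate_groups) < 2))
    stop("every replicate group needs >= 2 samples")
  if (k >= ncol(logcpm)) stop("k must be < number of samples")
  centred <- logcpm
  for (g in levels(replicate_groups)) {
    cols <- replicate_groups == g
    centred[, cols] <- logcpm[, cols] - rowMeans(logcpm[, cols, drop = FALSE])
  }
  sv <- svd(centred)
  r <- sum(sv$d > max(dim(centred)) * .Machine$double.eps * sv$d[1])
  if (k > r) stop("k = ", k, " exceeds the rank (", r, ") of the centred matrix")
  W <- sv$v[, seq_len(k), drop = FALSE]
  sgn <- ifelse(W[1, ] < 0, -1, 1)
  W <- sweep(W, 2, sgn, "*")
  dimnames(W) <- list(colnames(logcpm), paste0("W", seq_len(k)))
  W
}

#' Build the linear-model design matrix for the 2x2 study
#'
#' Cell-means coding of the four conditions plus optional unwanted-variation
#' covariates.
#'
#' @param study data.frame with a `condition` column (see
#'   [simulate_counts()]).
#' @param W optional samples x k matrix from [ruv_factors()].
#' @return design matrix with one column per condition (and W columns).
#' @export
design_matrix <- function(study, W = NULL) {
  condition <- factor(study$condition, levels = condition_levels())
  X <- model.matrix(~ 0 + condition)
  colnames(X) <- levels(condition)
  rownames(X) <- study$sample_id
  if (!is.null(W)) X <- cbind(X, W)
  X
}

# expand the 4-condition contrast matrix to the full design (zero rows for W)
expand_contrasts <- function(design) {
  cm <- condition_contrast_matrix()
  full <- matrix(0, ncol(design), ncol(cm),
                 dimnames = list(colnames(design), colnames(cm)))
  full[rownames(cm), ] <- cm
  full
}

#' Moderated differential expression for the four pairwise contrasts
#'
#' Per-gene least squares on log-CPM followed by empirical-Bayes variance
#' moderation (prior df and prior variance estimated by closed-form method
#' of moments on the log residual variances; posterior variance
#' `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`), moderated t on `d0 + d_g` degrees
#' of freedom, and Benjamini-Hochberg FDR within each contrast. The fit is
#' performed by limma; results are reorganised into one table per contrast.
#'
#' @param logcpm genes x samples matrix.
#' @param design design matrix (e.g. [design_matrix()]); must be full rank.
#' @param contrasts coefficients x contrasts numeric matrix; defaults to the
#'   four canonical comparisons when the design has the condition columns.
#' @return object of class `de_result`: list with `tables` (named list of
#'   data.frames: gene_id, logFC, t, p, fdr, ave_expr) and `params`
#'   (prior df `d0`, prior variance `s0_2`, residual df, posterior
#'   variances), plus the design and contrast matrices.
#' @export
fit_moderated <- function(logcpm, design, contrasts = NULL) {
  design <- as.matrix(design)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    aliased <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop("singular design; aliased columns: ", paste(aliased, collapse = ", "))
  }
  if (nrow(design) - ncol(design) < 1) stop("residual df must be >= 1")
  if (is.null(contrasts)) contrasts <- expand_contrasts(design)
  fit <- limma::lmFit(logcpm, design)
  fit <- limma::contrasts.fit(fit, contrasts)
  fit <- limma::eBayes(fit)
  d0 <- fit$df.prior
  if (is.finite(d0) && d0 > 1e6) d0 <- Inf  # numeric-stability cap treated as flag
  tables <- lapply(colnames(contrasts), function(cn) {
    p <- fit$p.value[, cn]
    data.frame(gene_id = rownames(logcpm),
               logFC = fit$coefficients[, cn],
               t = fit$t[, cn],
               p = p,
               fdr = bh_adjust(p),
               ave_expr = fit$Amean,
               row.names = rownames(logcpm),
               stringsAsFactors = FALSE)
  })
  names(tables) <- colnames(contrasts)
  structure(list(tables = tables,
                 params = list(d0 = d0, s0_2 = fit$s2.prior,
                               df_resid = nrow(design) - ncol(design),
                               s2_post = fit$s2.post, s2_g = fit$sigma^2),
                 design = design, contrasts = contrasts),
            class = "de_result")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH with cumulative-minimum enforcement; monotone in ranks and
#' bounded by \[0, 1\]; output is elementwise >= input.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Run the full differential-expression stage
#'
#' CPM filter, TMM factors, log-CPM on TMM-scaled effective library sizes,
#' RUV covariates from the condition replicate groups, and the moderated fit
#' for the four pairwise contrasts.
#'
#' @param counts genes x samples counts.
#' @param study study design data.frame (needs `condition`, `sample_id`).
#' @param min_cpm,min_samples CPM filter (defaults 1.5 CPM in >= 6 samples).
#' @param ruv_k number of unwanted-variation factors (0 disables RUV).
#' @return a `de_result` (see [fit_moderated()]) with the filtered `logcpm`
#'   and `W` attached.
#' @export
run_de <- function(counts, study, min_cpm = 1.5, min_samples = 6, ruv_k = 1) {
  filtered <- filter_by_cpm(counts, min_cpm, min_samples)
  f <- tmm_factors(filtered)
  eff_lib <- colSums(filtered) * f
  logcpm <- cpm_matrix(filtered, lib_sizes = eff_lib, log = TRUE)
  W <- if (ruv_k > 0) ruv_factors(logcpm, study$condition, k = ruv_k) else NULL
  de <- fit_moderated(logcpm, design_matrix(study, W))
  de$logcpm <- logcpm
  de$W <- W
  de$tmm <- f
  de
}

#' Average marker expression per cell type and sample
#'
#' Arithmetic mean of log-CPM over the markers of each cell type found in
#' the matrix; used as a QC check that expression changes are not driven by
#' shifting proportions of major brain cell types. Cell types with zero
#' overlap are flagged absent (row of NA), not fatal.
#'
#' @param logcpm genes x samples matrix.
#' @param marker_sets named list: cell type -> marker gene ids.
#' @return cell types x samples matrix with attributes `n_found` and
#'   `n_requested`.
#' @export
celltype_marker_profile <- function(logcpm, marker_sets) {
  found <- lapply(marker_sets, function(m) intersect(m, rownames(logcpm)))
  if (all(lengths(found) == 0))
    stop("no marker set overlaps the expression matrix")
  out <- t(vapply(names(marker_sets), function(ct) {
    g <- found[[ct]]
    if (!length(g)) return(rep(NA_real_, ncol(logcpm)))
    colMeans(logcpm[g, , drop = FALSE])
  }, numeric(ncol(logcpm))))
  colnames(out) <- colnames(logcpm)
  attr(out, "n_found") <- lengths(found)
  attr(out, "n_requested") <- lengths(marker_sets)
  out
}
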