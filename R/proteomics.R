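#' Convert a long peptide table to a peptides x samples matrix
#'
#' @param peptides data.frame with peptide_id, protein_id, sample_id,
#'   intensity (NA = censored); (peptide, sample) pairs must be unique.
#' @return list with `mat` (peptides x samples) and `protein` (named map
#'   peptide -> protein).
#' @export
peptide_matrix <- function(peptides) {
  need <- c("peptide_id", "protein_id", "sample_id", "intensity")
  if (!all(need %in% names(peptides)))
    stop("peptide table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(peptides[c("peptide_id", "sample_id")]))
    stop("(peptide_id, sample_id) pairs must be unique")
  peps <- unique(peptides$peptide_id)
  samp <- unique(peptides$sample_id)
  mat <- matrix(NA_real_, length(peps), length(samp),
                dimnames = list(peps, samp))
  mat[cbind(match(peptides$peptide_id, peps),
            match(peptides$sample_id, samp))] <- peptides$intensity
  protein <- peptides$protein_id[match(peps, peptides$peptide_id)]
  list(mat = mat, protein = setNames(protein, peps))
}

#' Log2-transform and quantile-normalise peptide intensities
#'
#' Intensities are log2-transformed and quantile normalisation equalises the
#' per-sample marginal distributions (ties averaged); censored (missing)
#' entries are excluded from the reference distribution and interpolated to
#' matching quantiles, as implemented by limma's normalizeQuantiles.
#'
#' @param peptides long peptide data.frame (see [peptide_matrix()]) or a
#'   peptides x samples matrix of raw intensities.
#' @return matrix of log2 quantile-normalised intensities (NA preserved),
#'   with the peptide -> protein map attached as attribute `protein` when a
#'   long table was given.
#' @export
normalize_peptides <- function(peptides) {
  prot <- NULL
  if (is.data.frame(peptides)) {
    pm <- peptide_matrix(peptides)
    mat <- pm$mat
    prot <- pm$protein
  } else mat <- as.matrix(peptides)
  if (ncol(mat) < 2) stop("need >= 2 samples")
  if (any(colSums(!is.na(mat)) == 0))
    stop("sample(s) with zero observed peptides: ",
         paste(colnames(mat)[colSums(!is.na(mat)) == 0], collapse = ", "))
  if (any(mat <= 0, na.rm = TRUE)) stop("intensities must be > 0")
  norm <- limma::normalizeQuantiles(log2(mat), ties = TRUE)
  dimnames(norm) <- dimnames(mat)
  if (!is.null(prot)) attr(norm, "protein") <- prot
  norm
}

#' Impute left-censored peptide intensities with an AFT model
#'
#' Censored entries are treated as left-censored at the per-sample minimum
#' observed (log2) intensity. For each peptide with at least one censored and
#' two observed values, an accelerated failure time regression with Gaussian
#' errors is fitted on optional sample covariates (survival::survreg); each
#' censored entry is replaced by the model's conditional expectation below
#' its censor point, `mu - sigma * dnorm(z) / pnorm(z)` with
#' `z = (c - mu) / sigma`, which never exceeds the censor point. Peptides
#' censored everywhere are dropped with a warning; peptides with too few
#' observations for the model fall back to an intercept-only fit.
#'
#' @param mat peptides x samples log2-intensity matrix with NA = censored
#'   (e.g. from [normalize_peptides()]).
#' @param covariates optional data.frame/factor of per-sample covariates
#'   (e.g. condition) used in the regression.
#' @return completed matrix (possibly with all-censored peptides removed);
#'   attribute `protein` is carried over when present.
#' @export
impute_censored <- function(mat, covariates = NULL) {
  prot <- attr(mat, "protein")
  censor_point <- apply(mat, 2, min, na.rm = TRUE)
  all_censored <- rowSums(!is.na(mat)) == 0
  if (any(all_censored)) {
    warning(sum(all_censored), " peptide(s) censored in every sample dropped")
    mat <- mat[!all_censored, , drop = FALSE]
    if (!is.null(prot)) prot <- prot[rownames(mat)]
  }
  covar <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  for (i in which(rowSums(is.na(mat)) > 0)) {
    y <- mat[i, ]
    cens <- is.na(y)
    yfit <- ifelse(cens, censor_point, y)
    event <- as.numeric(!cens)   # 0 = left-censored at yfit
    fit <- NULL
    if (!is.null(covar) && sum(!cens) >= length(unique(interaction(covar))) + 1) {
      df <- cbind(data.frame(.y = yfit, .e = event), covar)
      fit <- tryCatch(
        suppressWarnings(
          survival::survreg(survival::Surv(.y, .e, type = "left") ~ .,
                            data = df, dist = "gaussian")),
        error = function(e) NULL)
    }
    if (is.null(fit)) {
      df <- data.frame(.y = yfit, .e = event)
      fit <- tryCatch(
        suppressWarnings(
          survival::survreg(survival::Surv(.y, .e, type = "left") ~ 1,
                            data = df, dist = "gaussian")),
        error = function(e) NULL)
    }
    if (is.null(fit) || !is.finite(fit$scale) || fit$scale <= 0) {
      # degenerate fit: fall back to the censor point itself
      mat[i, cens] <- censor_point[cens]
      next
    }
    mu <- stats::predict(fit, newdata = if (is.null(covar))
      data.frame(.y = yfit, .e = event) else
        cbind(data.frame(.y = yfit, .e = event), covar))
    sigma <- fit$scale
    z <- (censor_point - mu) / sigma
    imput <- mu - sigma * dnorm(z) / pmax(pnorm(z), 1e-300)
    mat[i, cens] <- pmin(imput[cens], censor_point[cens])
  }
  if (!is.null(prot)) attr(mat, "protein") <- prot
  mat
}

#' Summarise peptides to proteins by Tukey median polish
#'
#' For each protein, the peptide x sample matrix is decomposed by
#' alternating row and column median sweeps (residual change < 1e-4 or 10
#' iterations); the protein abundance profile is the overall effect plus the
#' column effects, so constant peptide offsets are absorbed into the row
#' effects. Single-peptide proteins reduce to the peptide profile.
#'
#' @param mat peptides x samples log2-intensity matrix.
#' @param protein named map peptide -> protein (defaults to attribute
#'   `protein` of `mat`).
#' @param eps,maxiter convergence constants of the polish.
#' @return list of class `protein_table`: `abundance` (protein x sample
#'   log2 matrix), `n_peptides` (named), `complete` (observed in every
#'   sample).
#' @export
median_polish_summarize <- function(mat, protein = attr(mat, "protein"),
                                    eps = 1e-4, maxiter = 10) {
  if (is.null(protein)) stop("need a peptide -> protein map")
  protein <- protein[rownames(mat)]
  prots <- unique(unname(protein))
  ab <- matrix(NA_real_, length(prots), ncol(mat),
               dimnames = list(prots, colnames(mat)))
  npep <- setNames(integer(length(prots)), prots)
  for (p in prots) {
    rows <- names(protein)[protein == p]
    npep[p] <- length(rows)
    x <- mat[rows, , drop = FALSE]
    if (nrow(x) == 1) {
      ab[p, ] <- x[1, ]
      next
    }
    mp <- tryCatch(
      suppressWarnings(  # hitting maxiter is the documented stopping rule
        medpolish(x, eps = eps, maxiter = maxiter, trace.iter = FALSE,
                  na.rm = TRUE)),
      error = function(e) NULL)
    if (is.null(mp)) next  # unpolishable missingness pattern: flagged NA
    ab[p, ] <- mp$overall + mp$col
  }
  structure(list(abundance = ab, n_peptides = npep,
                 complete = rowSums(is.na(ab)) == 0),
            class = "protein_table")
}

#' Keep proteins quantified in every sample
#'
#' @param pt a `protein_table` from [median_polish_summarize()], or a matrix.
#' @return same type, restricted to complete cases.
#' @export
filter_complete <- function(pt) {
  if (inherits(pt, "protein_table")) {
    keep <- pt$complete
    structure(list(abundance = pt$abundance[keep, , drop = FALSE],
                   n_peptides = pt$n_peptides[keep],
                   complete = pt$complete[keep]),
              class = "protein_table")
  } else pt[complete.cases(pt), , drop = FALSE]
}

#' Differential protein abundance
#'
#' Moderated t-tests on protein log2 abundances for the four pairwise
#' contrasts, delegating to [fit_moderated()]; Benjamini-Hochberg FDR within
#' each contrast.
#'
#' @param pt `protein_table` or protein x sample matrix.
#' @param study study design data.frame (see [design_matrix()]).
#' @param W optional unwanted-variation covariates.
#' @return a `de_result` over proteins.
#' @export
differential_abundance <- function(pt, study, W = NULL) {
  ab <- if (inherits(pt, "protein_table")) pt$abundance else as.matrix(pt)
  ab <- ab[, study$sample_id, drop = FALSE]
  fit_moderated(ab, design_matrix(study, W))
}

#' Spearman correlation of mRNA and protein abundance
#'
#' Rank correlation (ties mid-ranked) across matched gene-protein pairs of
#' the mean log2 mRNA expression and mean protein abundance within each
#' sample group (e.g. age), reported with the pair count. Requires >= 3
#' matched pairs per group.
#'
#' @param logcpm genes x samples log-expression matrix.
#' @param pt `protein_table` or protein x sample abundance matrix.
#' @param idmap data.frame with columns protein_id, gene_id.
#' @param groups named vector/factor mapping sample ids (shared by both
#'   matrices) to groups; defaults to one overall group.
#' @return data.frame: group, rs, n_pairs.
#' @export
mrna_protein_correlation <- function(logcpm, pt, idmap, groups = NULL) {
  ab <- if (inherits(pt, "protein_table")) pt$abundance else as.matrix(pt)
  idmap <- idmap[idmap$protein_id %in% rownames(ab) &
                   idmap$gene_id %in% rownames(logcpm), , drop = FALSE]
  shared <- intersect(colnames(logcpm), colnames(ab))
  if (is.null(groups)) groups <- setNames(rep("all", length(shared)), shared)
  groups <- groups[shared]
  rows <- lapply(unique(groups), function(g) {
    s <- shared[groups == g]
    m <- rowMeans(logcpm[idmap$gene_id, s, drop = FALSE])
    p <- rowMeans(ab[idmap$protein_id, s, drop = FALSE])
    ok <- is.finite(m) & is.finite(p)
    if (sum(ok) < 3) {
      warning("fewer than 3 matched pairs in group ", g)
      return(data.frame(group = g, rs = NA_real_, n_pairs = sum(ok)))
    }
    data.frame(group = g, rs = cor(m[ok], p[ok], method = "spearman"),
               n_pairs = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full proteomics stage
#'
#' Normalise, impute, summarise with median polish, and keep complete
#' proteins — optionally per batch first (e.g. the two age batches processed
#' separately before combining), mirroring the two-batch label-free flow.
#'
#' @param peptides long peptide data.frame.
#' @param study study design (needs sample_id; `age` used for batching).
#' @param batch_column study column defining separate processing batches
#'   (NULL = single batch).
#' @return `protein_table` of complete proteins across all samples.
#' @export
run_proteomics <- function(peptides, study, batch_column = "age") {
  batches <- if (!is.null(batch_column) && batch_column %in% names(study))
    split(study$sample_id, study[[batch_column]])
  else list(all = study$sample_id)
  parts <- lapply(batches, function(s) {
    sub <- peptides[peptides$sample_id %in% s, , drop = FALSE]
    norm <- normalize_peptides(sub)
    cond <- study$condition[match(colnames(norm), study$sample_id)]
    imp <- impute_censored(norm, covariates = data.frame(condition = cond))
    median_polish_summarize(imp)
  })
  prots <- Reduce(union, lapply(parts, function(p) rownames(p$abundance)))
  ab <- matrix(NA_real_, length(prots), nrow(study),
               dimnames = list(prots, study$sample_id))
  for (p in parts) ab[rownames(p$abundance), colnames(p$abundance)] <-
    p$abundance
  dn <- dimnames(ab)
  ab <- limma::normalizeQuantiles(ab, ties = TRUE)
  dimnames(ab) <- dn
  npep <- parts[[1]]$n_peptides[prots]
  names(npep) <- prots
  filter_complete(structure(list(abundance = ab, n_peptides = npep,
                                 complete = rowSums(is.na(ab)) == 0),
                            class = "protein_table"))
}
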