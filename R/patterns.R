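#' Thresholds for multi-contrast pattern classification
#'
#' @param fdr_primary FDR cut-off for the primary significance requirement.
#' @param p_secondary unadjusted p cut-off for the supporting comparison in
#'   the inversion rule.
#' @param display_abs_log2fc absolute log2 fold-change display filter used by
#'   [cluster_fc_profiles()].
#' @return object of class `pattern_thresholds`.
#' @export
pattern_thresholds <- function(fdr_primary = 0.05, p_secondary = 0.05,
                               display_abs_log2fc = 0.5) {
  stopifnot(fdr_primary > 0, fdr_primary <= 1,
            p_secondary > 0, p_secondary <= 1,
            display_abs_log2fc > 0)
  structure(list(fdr_primary = fdr_primary, p_secondary = p_secondary,
                 display_abs_log2fc = display_abs_log2fc),
            class = "pattern_thresholds")
}

# fetch one contrast table, failing with the contrast's name
get_contrast <- function(de, contrast) {
  stopifnot(inherits(de, "de_result"))
  tab <- de$tables[[contrast]]
  if (is.null(tab)) stop("contrast not found in DE result: ", contrast)
  tab
}

#' Genes with an age-dependent inverted mutant effect
#'
#' A gene is "inverted" when its mutant-vs-wild-type fold-change flips sign
#' between young and aged brains, with FDR < `fdr_primary` in one of the two
#' het-vs-wt comparisons and unadjusted p < `p_secondary` in the other
#' (either orientation). Fold-changes of exactly zero carry no sign and
#' never qualify.
#'
#' @param de a `de_result` containing both het-vs-wt contrasts.
#' @param th a [pattern_thresholds()].
#' @param young,aged contrast names for the two het-vs-wt comparisons.
#' @return character vector of gene ids.
#' @export
classify_inverted <- function(de, th = pattern_thresholds(),
                              young = "youngHet_vs_youngWt",
                              aged = "agedHet_vs_agedWt") {
  a <- get_contrast(de, young)
  b <- get_contrast(de, aged)
  opposite <- sign(a$logFC) * sign(b$logFC) < 0
  sig <- (a$fdr < th$fdr_primary & b$p < th$p_secondary) |
    (b$fdr < th$fdr_primary & a$p < th$p_secondary)
  a$gene_id[opposite & sig]
}

#' Failure-to-regulate and inappropriate down-regulation gene sets
#'
#' Three patterns over the four pairwise comparisons:
#' \describe{
#'   \item{inappropriately_down}{FDR-significant negative fold-change in both
#'     het aging (aged het vs young het) and aged het vs aged wt.}
#'   \item{failure_up}{FDR-significant positive fold-change in normal aging
#'     (aged wt vs young wt) but \emph{not} significantly up in aged het vs
#'     aged wt ("not up-regulated" = failing the FDR-and-sign criterion, not
#'     requiring significance in the opposite direction).}
#'   \item{failure_down}{the mirror image of failure_up.}
#' }
#'
#' @param de a `de_result` with all four canonical contrasts.
#' @param th a [pattern_thresholds()].
#' @return named list of three character vectors
#'   (`inappropriately_down`, `failure_up`, `failure_down`).
#' @export
classify_failure_and_inappropriate <- function(de, th = pattern_thresholds()) {
  het_aging <- get_contrast(de, "agedHet_vs_youngHet")
  het_vs_wt_aged <- get_contrast(de, "agedHet_vs_agedWt")
  wt_aging <- get_contrast(de, "agedWt_vs_youngWt")
  fdr <- th$fdr_primary

  inapp <- het_aging$fdr < fdr & het_aging$logFC < 0 &
    het_vs_wt_aged$fdr < fdr & het_vs_wt_aged$logFC < 0

  up_in_aging <- wt_aging$fdr < fdr & wt_aging$logFC > 0
  up_in_het <- het_vs_wt_aged$fdr < fdr & het_vs_wt_aged$logFC > 0
  fail_up <- up_in_aging & !up_in_het

  down_in_aging <- wt_aging$fdr < fdr & wt_aging$logFC < 0
  down_in_het <- het_vs_wt_aged$fdr < fdr & het_vs_wt_aged$logFC < 0
  fail_down <- down_in_aging & !down_in_het

  list(inappropriately_down = wt_aging$gene_id[inapp],
       failure_up = wt_aging$gene_id[fail_up],
       failure_down = wt_aging$gene_id[fail_down])
}

#' Classify every gene into one pattern by precedence
#'
#' Applies the precedence order inverted > inappropriately_down > failure_up
#' > failure_down so the labels partition the gene universe; the raw,
#' possibly overlapping sets are attached as an attribute.
#'
#' @inheritParams classify_failure_and_inappropriate
#' @return data.frame (gene_id, label) with attribute `raw_sets`.
#' @export
classify_patterns <- function(de, th = pattern_thresholds()) {
  universe <- get_contrast(de, "agedHet_vs_agedWt")$gene_id
  raw <- c(list(inverted = classify_inverted(de, th)),
           classify_failure_and_inappropriate(de, th))
  label <- setNames(rep("none", length(universe)), universe)
  for (nm in c("failure_down", "failure_up", "inappropriately_down",
               "inverted"))
    label[intersect(raw[[nm]], universe)] <- nm
  out <- data.frame(gene_id = universe, label = unname(label[universe]),
                    stringsAsFactors = FALSE)
  attr(out, "raw_sets") <- raw
  out
}

#' Fraction of DE genes concordant between two contrasts
#'
#' Denominator: genes DE (FDR < threshold) in contrast A; numerator: those
#' whose fold-change sign matches in contrast B (zero fold-changes are
#' non-concordant). Used e.g. for "x% of the genes DE in young mutant brains
#' change in the same direction during normal aging".
#'
#' @param de a `de_result`.
#' @param contrast_a,contrast_b contrast names.
#' @param th a [pattern_thresholds()].
#' @return list(fraction, numerator, denominator); fraction is NA with a
#'   warning when no gene is DE in contrast A.
#' @export
concordance_fraction <- function(de, contrast_a, contrast_b,
                                 th = pattern_thresholds()) {
  a <- get_contrast(de, contrast_a)
  b <- get_contrast(de, contrast_b)
  de_a <- a$fdr < th$fdr_primary
  num <- sum(de_a & sign(a$logFC) != 0 & sign(a$logFC) == sign(b$logFC))
  den <- sum(de_a)
  if (den == 0) {
    warning("no DE genes in ", contrast_a, "; fraction undefined")
    return(list(fraction = NA_real_, numerator = 0L, denominator = 0L))
  }
  list(fraction = num / den, numerator = num, denominator = den)
}

#' Shared aging signature across genotypes
#'
#' Genes FDR-significant in both the wild-type and mutant aging contrasts
#' with concordant fold-change signs.
#'
#' @param de a `de_result`.
#' @param th a [pattern_thresholds()].
#' @param wt_aging,het_aging contrast names.
#' @return character vector of gene ids.
#' @export
aging_signature <- function(de, th = pattern_thresholds(),
                            wt_aging = "agedWt_vs_youngWt",
                            het_aging = "agedHet_vs_youngHet") {
  a <- get_contrast(de, wt_aging)
  b <- get_contrast(de, het_aging)
  keep <- a$fdr < th$fdr_primary & b$fdr < th$fdr_primary &
    sign(a$logFC) != 0 & sign(a$logFC) == sign(b$logFC)
  a$gene_id[keep]
}

#' Cluster fold-change profiles for display
#'
#' Hierarchical clustering (Euclidean distance on the vector of log2
#' fold-changes across the four comparisons, complete linkage) of the genes
#' passing the display filter (absolute log2 fold-change > threshold in at
#' least one comparison), with the deterministic leaf order of the
#' dendrogram.
#'
#' @param de a `de_result` with the four canonical contrasts.
#' @param genes gene ids to consider (default: all genes in the result).
#' @param k number of clusters (used if `h` is NULL).
#' @param h cut height (overrides `k`).
#' @param th a [pattern_thresholds()] supplying the display filter.
#' @return data.frame (gene_id, cluster) ordered by dendrogram leaf order;
#'   attribute `hclust` carries the tree. Fewer than 2 genes yield a single
#'   cluster.
#' @export
cluster_fc_profiles <- function(de, genes = NULL, k = 2, h = NULL,
                                th = pattern_thresholds()) {
  fc <- sapply(contrast_names(), function(cn) {
    tab <- get_contrast(de, cn)
    setNames(tab$logFC, tab$gene_id)
  })
  if (!is.null(genes)) fc <- fc[intersect(genes, rownames(fc)), , drop = FALSE]
  fc <- fc[apply(abs(fc), 1, max) > th$display_abs_log2fc, , drop = FALSE]
  if (nrow(fc) < 2) {
    return(data.frame(gene_id = rownames(fc),
                      cluster = rep(1L, nrow(fc)),
                      stringsAsFactors = FALSE))
  }
  tree <- hclust(dist(fc, method = "euclidean"), method = "complete")
  cl <- if (!is.null(h)) cutree(tree, h = h) else
    cutree(tree, k = min(k, nrow(fc)))
  out <- data.frame(gene_id = tree$labels[tree$order],
                    cluster = unname(cl[tree$labels[tree$order]]),
                    stringsAsFactors = FALSE)
  attr(out, "hclust") <- tree
  out
}
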