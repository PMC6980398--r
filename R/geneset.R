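#' Read a GMT gene-set collection
#'
#' Tab-separated: set name, description, then gene ids. Empty sets are
#' rejected; duplicate ids within a set are dropped.
#'
#' @param path GMT file path.
#' @return named list of character vectors with attribute `provenance`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("empty gene set in GMT: ", parts[1])
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (any(lengths(sets) == 0)) stop("empty gene set(s) in ", path)
  attr(sets, "provenance") <- path
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' Map a gene-set collection through an ortholog table
#'
#' Each source id is replaced by all of its mapped target ids (many-to-many),
#' de-duplicated; sets that lose all members are dropped with a warning. A
#' mapping report is attached as an attribute.
#'
#' @param sets named list of character vectors.
#' @param ortho data.frame whose first two columns are source id, target id.
#' @return mapped collection with attribute `mapping_report` (data.frame of
#'   per-set original and mapped sizes).
#' @export
map_orthologs <- function(sets, ortho) {
  if (!nrow(ortho)) stop("empty ortholog map")
  from <- as.character(ortho[[1]])
  to <- as.character(ortho[[2]])
  mapped <- lapply(sets, function(g)
    unique(to[from %in% g]))
  report <- data.frame(set = names(sets),
                       n_original = lengths(sets),
                       n_mapped = lengths(mapped),
                       stringsAsFactors = FALSE)
  empty <- lengths(mapped) == 0
  if (any(empty))
    warning(sum(empty), " set(s) lost all members in ortholog mapping: ",
            paste(head(names(sets)[empty], 5), collapse = ", "))
  out <- mapped[!empty]
  attr(out, "provenance") <- attr(sets, "provenance")
  attr(out, "mapping_report") <- report
  out
}

# drop genes absent from the expression matrix; NULL if none left
set_indices <- function(sets, expr) {
  idx <- lapply(sets, function(g) which(rownames(expr) %in% g))
  idx[lengths(idx) > 0]
}

#' Rotation gene-set testing (ROAST)
#'
#' Self-contained rotation test of each set for one contrast: per-gene
#' moderated statistics are computed in the residual rotation space and the
#' null is generated by random rotations, giving p-values with granularity
#' `1/(n_rot+1)`. The `"mean"` set statistic is used, whose up/down gene
#' proportions count moderated z-scores beyond +/- sqrt(2). The seed is reset
#' before each set so all sets share one rotation stream and their p-values
#' are comparable; the Mixed FDR is Benjamini-Hochberg across sets.
#'
#' @param expr genes x samples log-expression matrix.
#' @param design design matrix.
#' @param contrast numeric contrast vector over design columns (or a design
#'   column name).
#' @param sets named list of gene-id vectors.
#' @param n_rot number of rotations (default 9999).
#' @param set_stat set statistic (default "mean").
#' @param seed integer seed for the rotation stream.
#' @param share_rotations reset the stream before every set so all sets see
#'   the same rotations (comparable p-values, less Monte-Carlo noise in the
#'   FDR; the default). With `FALSE` each set gets independent rotations,
#'   which makes set p-values approximately independent — the right mode for
#'   calibration experiments that assume independence across sets.
#' @return data.frame (class `rotation_result`): set, n_genes, p_up, p_down,
#'   p_dir (two-sided directional), p_mixed, fdr_mixed, prop_up, prop_down.
#'   Sets with no genes in the data are reported untestable (NA rows).
#' @export
roast_test <- function(expr, design, contrast, sets, n_rot = 9999,
                       set_stat = "mean", seed = 1L,
                       share_rotations = TRUE) {
  idx <- set_indices(sets, expr)
  set.seed(seed)
  rows <- lapply(names(sets), function(nm) {
    if (is.null(idx[[nm]]))
      return(data.frame(set = nm, n_genes = 0L, p_up = NA_real_,
                        p_down = NA_real_, p_dir = NA_real_,
                        p_mixed = NA_real_,
                        prop_up = NA_real_, prop_down = NA_real_,
                        stringsAsFactors = FALSE))
    if (share_rotations) set.seed(seed)  # one stream for every set
    r <- limma::roast(expr, index = idx[[nm]], design = design,
                      contrast = contrast, nrot = n_rot,
                      set.statistic = set_stat)
    data.frame(set = nm, n_genes = length(idx[[nm]]),
               p_up = r$p.value["Up", "P.Value"],
               p_down = r$p.value["Down", "P.Value"],
               p_dir = r$p.value["UpOrDown", "P.Value"],
               p_mixed = r$p.value["Mixed", "P.Value"],
               prop_up = r$p.value["Up", "Active.Prop"],
               prop_down = r$p.value["Down", "Active.Prop"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_mixed <- NA_real_
  testable <- !is.na(out$p_mixed)
  out$fdr_mixed[testable] <- bh_adjust(out$p_mixed[testable])
  rownames(out) <- NULL
  class(out) <- c("rotation_result", "data.frame")
  out
}

#' Fast analytic rotation gene-set testing (FRY)
#'
#' Analytic approximation to ROAST with an infinite number of rotations under
#' an equal-variance-across-set assumption; directional and mixed p-values
#' per set with Benjamini-Hochberg Mixed FDR across sets. Up/down gene
#' proportions are computed from the per-gene moderated z-scores at the
#' +/- sqrt(2) threshold (the `"mean"` statistic convention), so FRY output
#' carries the same columns as [roast_test()].
#'
#' @inheritParams roast_test
#' @return data.frame (class `rotation_result`): set, n_genes, direction,
#'   p_value (directional two-sided), fdr, p_mixed, fdr_mixed, prop_up,
#'   prop_down.
#' @export
fry_test <- function(expr, design, contrast, sets, seed = NULL) {
  idx <- set_indices(sets, expr)
  if (!length(idx)) stop("no set has genes present in the data")
  r <- limma::fry(expr, index = idx, design = design, contrast = contrast,
                  sort = "none")
  z <- moderated_z(expr, design, contrast)
  out <- data.frame(set = names(sets),
                    n_genes = 0L, direction = NA_character_,
                    p_value = NA_real_, fdr = NA_real_,
                    p_mixed = NA_real_, fdr_mixed = NA_real_,
                    prop_up = NA_real_, prop_down = NA_real_,
                    stringsAsFactors = FALSE)
  rownames(out) <- out$set
  hit <- intersect(rownames(r), out$set)
  out[hit, "n_genes"] <- r[hit, "NGenes"]
  out[hit, "direction"] <- as.character(r[hit, "Direction"])
  out[hit, "p_value"] <- r[hit, "PValue"]
  out[hit, "p_mixed"] <- r[hit, "PValue.Mixed"]
  out[hit, "prop_up"] <- vapply(hit, function(nm)
    mean(z[idx[[nm]]] > sqrt(2)), numeric(1))
  out[hit, "prop_down"] <- vapply(hit, function(nm)
    mean(z[idx[[nm]]] < -sqrt(2)), numeric(1))
  out$fdr[match(hit, out$set)] <- bh_adjust(out[hit, "p_value"])
  out$fdr_mixed[match(hit, out$set)] <- bh_adjust(out[hit, "p_mixed"])
  rownames(out) <- NULL
  class(out) <- c("rotation_result", "data.frame")
  out
}

# per-gene moderated z-scores for a contrast (limma t mapped through the
# t -> z quantile transform)
moderated_z <- function(expr, design, contrast) {
  fit <- limma::lmFit(expr, design)
  if (is.character(contrast)) {
    cm <- matrix(0, ncol(design), 1, dimnames = list(colnames(design), contrast))
    cm[contrast, 1] <- 1
    contrast <- cm
  }
  fit <- limma::contrasts.fit(fit, contrast)
  fit <- limma::eBayes(fit)
  limma::zscoreT(fit$t[, 1], df = fit$df.total)
}
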