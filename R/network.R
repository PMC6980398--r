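#' Parameters for signed co-expression network construction
#'
#' Defaults follow common practice for brain bulk RNA-seq signed networks:
#' soft-thresholding power 14, minimum module size 40, deep-split 1, PAM
#' maximum assignment distance 0.90, and a connectivity filter at the 10th
#' percentile.
#'
#' @param soft_power soft-thresholding exponent beta (>= 1).
#' @param min_module_size smallest accepted module.
#' @param deep_split split sensitivity, integer 0-4 (higher = more, smaller
#'   modules).
#' @param pam_max_distance maximum dissimilarity at which an unassigned gene
#'   is attached to its nearest module in the PAM-like stage, in (0, 1].
#' @param connectivity_percentile percentile of connectivities below which
#'   genes are dropped, in \[0, 100).
#' @param cut_height_frac static-cut height as a fraction of the dendrogram
#'   merge-height range.
#' @return object of class `network_params`.
#' @export
network_params <- function(soft_power = 14, min_module_size = 40,
                           deep_split = 1, pam_max_distance = 0.90,
                           connectivity_percentile = 10,
                           cut_height_frac = 0.99) {
  stopifnot(soft_power >= 1,
            min_module_size >= 2,
            deep_split %in% 0:4,
            pam_max_distance > 0, pam_max_distance <= 1,
            connectivity_percentile >= 0, connectivity_percentile < 100,
            cut_height_frac > 0, cut_height_frac <= 1)
  structure(list(soft_power = soft_power, min_module_size = min_module_size,
                 deep_split = deep_split, pam_max_distance = pam_max_distance,
                 connectivity_percentile = connectivity_percentile,
                 cut_height_frac = cut_height_frac),
            class = "network_params")
}

#' Signed adjacency matrix
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^beta` with Pearson correlation; negative
#' correlation maps toward 0 rather than being folded. Symmetric, values in
#' \[0, 1\], unit diagonal.
#'
#' @param expr genes x samples matrix with no constant genes.
#' @param beta soft-thresholding power.
#' @return genes x genes adjacency matrix.
#' @export
signed_adjacency <- function(expr, beta = 14) {
  sds <- apply(expr, 1, sd)
  if (any(sds == 0))
    stop("constant expression (undefined correlation) for genes: ",
         paste(head(rownames(expr)[sds == 0], 5), collapse = ", "))
  cc <- cor(t(expr))
  if (any(!is.finite(cc)))
    stop("non-finite correlations for genes: ",
         paste(head(rownames(cc)[rowSums(!is.finite(cc)) > 0], 5),
               collapse = ", "))
  a <- ((1 + cc) / 2)^beta
  diag(a) <- 1
  a
}

#' Whole-network connectivity of each gene
#'
#' `k_i = sum_{j != i} a_ij` from the signed adjacency.
#'
#' @param expr genes x samples matrix.
#' @param beta soft-thresholding power.
#' @return named numeric vector.
#' @export
connectivity <- function(expr, beta = 14) {
  a <- signed_adjacency(expr, beta)
  rowSums(a) - 1
}

#' Filter genes by network connectivity
#'
#' Drops genes whose signed-network connectivity is not strictly above the
#' given percentile (midpoint-interpolated, `stats::quantile` type 7) of all
#' connectivities; when several datasets are supplied (e.g. two species),
#' a gene must pass in every dataset. Constant genes are dropped with a
#' warning before the computation. With all-equal connectivities the
#' strictly-above rule removes nothing.
#'
#' @param expr genes x samples matrix, or a list of matrices sharing row
#'   order (one per dataset).
#' @param params a [network_params()].
#' @return the filtered matrix (or list of matrices), same gene order.
#' @export
connectivity_filter <- function(expr, params = network_params()) {
  mats <- if (is.list(expr)) expr else list(expr)
  if (ncol(mats[[1]]) < 2) stop("need >= 2 samples")
  n <- nrow(mats[[1]])
  ok <- rep(TRUE, n)
  for (m in mats) {
    const <- apply(m, 1, sd) == 0
    if (any(const)) {
      warning(sum(const), " constant gene(s) dropped")
      ok <- ok & !const
    }
  }
  keep <- ok
  for (m in mats) {
    k <- connectivity(m[ok, , drop = FALSE], beta = params$soft_power)
    thr <- quantile(k, params$connectivity_percentile / 100, names = FALSE)
    pass <- rep(FALSE, n)
    pass[ok] <- k > thr | all(k == k[1])
    keep <- keep & pass
  }
  out <- lapply(mats, function(m) m[keep, , drop = FALSE])
  if (is.list(expr)) out else out[[1]]
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i = sum_{u != i} a_iu`;
#' unit diagonal, symmetric, values in \[0, 1\].
#'
#' @param a symmetric adjacency in \[0, 1\] with unit diagonal.
#' @return TOM matrix of the same shape.
#' @export
topological_overlap <- function(a) {
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  k <- rowSums(a) - 1
  ell <- a %*% a - 2 * a          # removes u = i and u = j terms (diag = 1)
  kmin <- outer(k, k, pmin)
  tom <- (ell + a) / (kmin + 1 - a)
  diag(tom) <- 1
  (tom + t(tom)) / 2
}

# -- dynamic-hybrid tree cut (documented variant) -----------------------------
#
# Branches of the average-linkage dendrogram are found by a static cut that
# is applied recursively: any branch large enough to contain two modules is
# re-cut at the same fractional height of its own internal merge range, and
# the recursion continues while the cut produces >= 2 children of at least
# the minimum size. A terminal branch is accepted as a module when (i) it
# reaches the minimum size, (ii) its core scatter (mean dissimilarity among
# the most-connected half of its genes) is below both a deep-split-dependent
# fraction of the dissimilarity range and the absolute PAM assignment
# distance, and (iii) it is separated from the rest of the network by a
# minimum gap. Remaining genes are attached to their nearest accepted module
# by average dissimilarity when that distance is at most pam_max_distance
# (PAM-like stage), else labelled 0. Exact parity with the reference hybrid
# tree cut is not promised; the variant is validated by planted-structure
# recovery.

#' Detect modules by a dynamic-hybrid cut of the TOM dendrogram
#'
#' @param dissim symmetric dissimilarity matrix, typically `1 - TOM`.
#' @param params a [network_params()].
#' @return object of class `module_assignment`: list with `labels` (named
#'   integer; 0 = unassigned, modules numbered by decreasing size), `sizes`,
#'   `tree` (the hclust object), and `params`.
#' @export
cut_modules <- function(dissim, params = network_params()) {
  dissim <- as.matrix(dissim)
  n <- nrow(dissim)
  genes <- rownames(dissim) %||% as.character(seq_len(n))
  dimnames(dissim) <- list(genes, genes)
  empty <- structure(list(labels = setNames(integer(n), genes),
                          sizes = integer(0), tree = NULL, params = params),
                     class = "module_assignment")
  if (n < params$min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    return(empty)
  }
  tree <- hclust(as.dist(dissim), method = "average")

  off <- dissim[upper.tri(dissim)]
  base <- quantile(off, 0.05, names = FALSE)
  maxh <- max(tree$height)
  rng <- max(maxh - base, .Machine$double.eps)
  mcs_frac <- c(0.64, 0.73, 0.82, 0.91, 0.95)[params$deep_split + 1]
  max_core_scatter <- min(base + mcs_frac * rng, params$pam_max_distance)
  min_gap <- (1 - mcs_frac) * 3 / 4 * rng

  core_scatter <- function(ix) {
    sub <- dissim[ix, ix, drop = FALSE]
    core_n <- max(2L, as.integer(ceiling(length(ix) / 2)))
    core <- order(rowMeans(sub))[seq_len(core_n)]
    mean(sub[core, core][upper.tri(diag(core_n))])
  }

  modules <- list()
  evaluate <- function(ix) {
    cs <- core_scatter(ix)
    sub <- dissim[ix, ix]
    mean_intra <- mean(sub[upper.tri(sub)])
    outside <- setdiff(seq_len(n), ix)
    sep <- if (length(outside)) mean(dissim[ix, outside]) else maxh
    if (cs <= max_core_scatter && mean_intra <= params$pam_max_distance &&
        sep - cs >= min_gap) {
      modules[[length(modules) + 1L]] <<- ix
      TRUE
    } else FALSE
  }
  # leaves under each internal node of the dendrogram
  node_leaves <- vector("list", nrow(tree$merge))
  leaves_of <- function(x) if (x < 0) -x else node_leaves[[x]]
  for (i in seq_len(nrow(tree$merge)))
    node_leaves[[i]] <- c(leaves_of(tree$merge[i, 1]),
                          leaves_of(tree$merge[i, 2]))
  # top-down binary walk: descend while the two children are separated by
  # more than the PAM distance (they cannot belong to one module), otherwise
  # evaluate the cohesive branch; on rejection, retry the children
  walk <- function(node) {
    if (node < 0) return()
    g1 <- leaves_of(tree$merge[node, 1])
    g2 <- leaves_of(tree$merge[node, 2])
    members <- c(g1, g2)
    if (length(members) < params$min_module_size) return()
    cross <- mean(dissim[g1, g2, drop = FALSE])
    if (cross > params$pam_max_distance &&
        max(length(g1), length(g2)) >= params$min_module_size) {
      walk(tree$merge[node, 1])
      walk(tree$merge[node, 2])
      return()
    }
    if (evaluate(members)) return()
    walk(tree$merge[node, 1])
    walk(tree$merge[node, 2])
  }
  walk(nrow(tree$merge))

  # prune loosely attached members (average dissimilarity to the rest of the
  # module above the PAM distance); they may be re-attached by the PAM stage
  modules <- lapply(modules, function(ix) {
    repeat {
      if (length(ix) < params$min_module_size) return(integer(0))
      avg <- (colSums(dissim[ix, ix]) ) / (length(ix) - 1)
      drop <- avg > params$pam_max_distance
      if (!any(drop)) return(ix)
      ix <- ix[!drop]
    }
  })
  modules <- modules[lengths(modules) >= params$min_module_size]

  labels <- setNames(integer(n), genes)
  for (i in seq_along(modules)) labels[modules[[i]]] <- i

  # PAM-like stage: attach leftovers to the nearest module if close enough
  if (length(modules)) {
    for (g in which(labels == 0L)) {
      dmod <- vapply(modules, function(ix) mean(dissim[g, ix]), numeric(1))
      j <- which.min(dmod)
      if (dmod[j] <= params$pam_max_distance) labels[g] <- j
    }
  }
  labels <- renumber_by_size(labels)
  structure(list(labels = labels, sizes = tabulate(labels), tree = tree,
                 params = params),
            class = "module_assignment")
}

# modules renumbered 1..K by decreasing size; 0 stays unassigned
renumber_by_size <- function(labels) {
  mods <- setdiff(unique(labels), 0L)
  if (!length(mods)) return(labels)
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  new <- setNames(order(order(-sizes)), mods)
  out <- labels
  for (m in mods) out[labels == m] <- new[[as.character(m)]]
  out
}

#' Module eigengenes
#'
#' First principal component of each module's standardised expression,
#' returned as a unit-norm samples-length vector, sign-aligned so its
#' correlation with the module's mean expression profile is non-negative.
#' The proportion of variance explained is recorded.
#'
#' @param expr genes x samples matrix.
#' @param labels named integer vector (0 = unassigned), e.g. from
#'   [cut_modules()].
#' @return list with `eigengenes` (samples x modules matrix, columns
#'   `ME1`, ...) and `var_explained` (named numeric).
#' @export
module_eigengene <- function(expr, labels) {
  if (ncol(expr) < 2) stop("need >= 2 samples for eigengenes")
  mods <- sort(setdiff(unique(labels), 0L))
  me <- matrix(NA_real_, ncol(expr), length(mods),
               dimnames = list(colnames(expr), paste0("ME", mods)))
  ve <- setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    rows <- names(labels)[labels == mods[i]]
    if (length(rows) < 2) stop("module ", mods[i], " has < 2 genes")
    x <- t(scale(t(expr[rows, , drop = FALSE])))  # standardise genes
    sv <- svd(x)
    v <- sv$v[, 1]
    if (cor(v, colMeans(x)) < 0) v <- -v
    me[, i] <- v
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = me, var_explained = ve)
}

#' Biweight midcorrelation with hybrid fallback
#'
#' Robust correlation based on median/MAD weights `(1 - u^2)^2` for
#' `|u| < 1`, `u = (x - med) / (9 mad)`. A side with too few distinct values
#' (e.g. a binary trait) or zero MAD falls back to Pearson-style mean/sd
#' weights on that side ("hybrid" mode), which is the convention for
#' module-trait correlations against binary condition indicators.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in \[-1, 1\].
#' @export
bicor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  wside <- function(v) {
    med <- median(v)
    m <- mad(v, constant = 1)
    if (m == 0 || length(unique(v)) <= 2)
      return(list(d = v - mean(v), w = rep(1, length(v))))
    u <- (v - med) / (9 * m)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    list(d = v - med, w = w)
  }
  a <- wside(x)
  b <- wside(y)
  xs <- a$d * a$w
  ys <- b$d * b$w
  sum(xs * ys) / sqrt(sum(xs^2) * sum(ys^2))
}

#' Correlate module eigengenes with binary condition traits
#'
#' Hybrid biweight midcorrelation (Pearson on the binary side) of each
#' eigengene with each 0/1 trait indicator, with an unadjusted Student
#' t p-value on n - 2 degrees of freedom. Constant traits are flagged
#' (NA) rather than fatal.
#'
#' @param eigengenes samples x modules matrix (from [module_eigengene()]).
#' @param traits samples x traits 0/1 matrix or data.frame.
#' @return list of matrices `correlation` and `p` (modules x traits).
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  traits <- as.matrix(traits)
  if (nrow(traits) != nrow(eigengenes))
    stop("traits must have one row per sample")
  if (nrow(traits) < 3) stop("need >= 3 samples")
  if (!all(traits %in% c(0, 1))) stop("traits must be binary 0/1")
  cn <- colnames(traits) %||% paste0("trait", seq_len(ncol(traits)))
  rn <- colnames(eigengenes)
  co <- matrix(NA_real_, length(rn), ncol(traits), dimnames = list(rn, cn))
  pv <- co
  n <- nrow(traits)
  for (i in seq_along(rn)) for (j in seq_len(ncol(traits))) {
    tr <- traits[, j]
    if (length(unique(tr)) < 2) {
      warning("constant trait: ", cn[j])
      next
    }
    r <- bicor(eigengenes[, i], tr)
    co[i, j] <- r
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    pv[i, j] <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(correlation = co, p = pv)
}

#' Cross-network module overlap
#'
#' Cross-tabulates module co-membership of ortholog-linked genes in two
#' networks, computes a Fisher exact p-value per cell, and emits a
#' Sankey-ready node/link structure whose link weights sum to the number of
#' shared orthologs.
#'
#' @param labels_a,labels_b named integer module labels in each network.
#' @param ortho data.frame whose first two columns map network-A gene ids to
#'   network-B gene ids.
#' @return list with `table` (contingency matrix), `fisher_p` (same shape),
#'   and `sankey` (list of `nodes` and `links` data.frames).
#' @export
module_overlap <- function(labels_a, labels_b, ortho) {
  from <- as.character(ortho[[1]])
  to <- as.character(ortho[[2]])
  keep <- from %in% names(labels_a) & to %in% names(labels_b)
  if (!any(keep)) stop("no ortholog pair links the two labelings")
  la <- labels_a[from[keep]]
  lb <- labels_b[to[keep]]
  tab <- table(factor(la), factor(lb))
  n <- sum(tab)
  fp <- tab
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    a <- tab[i, j]
    m2 <- matrix(c(a, sum(tab[i, ]) - a, sum(tab[, j]) - a,
                   n - sum(tab[i, ]) - sum(tab[, j]) + a), 2)
    fp[i, j] <- fisher.test(m2, alternative = "greater")$p.value
  }
  nodes <- data.frame(
    id = c(paste0("A", rownames(tab)), paste0("B", colnames(tab))),
    network = rep(c("A", "B"), c(nrow(tab), ncol(tab))),
    stringsAsFactors = FALSE)
  links <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    data.frame(source = paste0("A", rownames(tab)[i]),
               target = paste0("B", colnames(tab)),
               value = as.vector(tab[i, ]), stringsAsFactors = FALSE)))
  links <- links[links$value > 0, ]
  rownames(links) <- NULL
  list(table = unclass(tab), fisher_p = unclass(fp),
       sankey = list(nodes = nodes, links = links))
}

#' Build a network and detect modules in one call
#'
#' Connectivity filter, signed adjacency, TOM, dynamic-hybrid cut, and
#' eigengenes.
#'
#' @param expr genes x samples matrix.
#' @param params a [network_params()].
#' @param filter apply the connectivity filter first.
#' @return list with `labels`, `sizes`, `eigengenes`, `var_explained`,
#'   `tom`, `expr` (the filtered matrix), and `tree`.
#' @export
build_network <- function(expr, params = network_params(), filter = TRUE) {
  if (filter) expr <- connectivity_filter(expr, params)
  a <- signed_adjacency(expr, params$soft_power)
  tom <- topological_overlap(a)
  mods <- cut_modules(1 - tom, params)
  me <- if (any(mods$labels > 0)) module_eigengene(expr, mods$labels)
        else list(eigengenes = NULL, var_explained = NULL)
  list(labels = mods$labels, sizes = mods$sizes,
       eigengenes = me$eigengenes, var_explained = me$var_explained,
       tom = tom, expr = expr, tree = mods$tree, params = params)
}
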