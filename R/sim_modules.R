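#' Simulate correlated gene modules in two species
#'
#' Builds a species-A expression matrix whose modules are latent-factor
#' blocks: gene `g` in module `m` is `lambda_g * f_m + sqrt(1-lambda_g^2) *
#' noise`, with per-gene loadings drawn around `sqrt(module_cor)` so the mean
#' pairwise within-module correlation is approximately `module_cor`
#' (`cor(g,h) = lambda_g * lambda_h`). A `preserved_fraction` of modules are
#' replicated in species B with the same membership, the same loadings and
#' the same latent factor values (fresh noise), so their density and
#' connectivity structure carries over; the remaining modules have their
#' gene memberships scrambled in species B and receive fresh factors and
#' loadings, so species B retains global module structure but those species-A
#' modules are not preserved. Genes outside modules are independent noise.
#'
#' @param config a [sim_config()]; uses `n_genes`, `n_reps_per_condition`
#'   (samples = 4 x reps per species), `n_modules`, `module_size_range`,
#'   `module_cor`, `preserved_fraction`, `seed`.
#' @param n_samples number of samples per species (default `4 * reps`).
#' @return list with `expr_a`, `expr_b` (genes x samples, unit-variance
#'   log-expression scale), `ortholog_map` (data.frame `gene_a`, `gene_b`,
#'   one-to-one), and `truth` with per-species module labels (0 =
#'   background), loadings, and the preserved module ids.
#' @export
simulate_module_expression <- function(config,
                                       n_samples = 4 * config$n_reps_per_condition) {
  validate_sim_config(config)
  set.seed(sub_seed(config$seed, 10000L))
  ng <- config$n_genes
  nm <- config$n_modules
  size_choices <- seq.int(config$module_size_range[1],
                          config$module_size_range[2])
  sizes <- if (nm > 0)
    size_choices[sample.int(length(size_choices), nm, replace = TRUE)]
  else integer(0)
  if (nm > 0 && nm * max(sizes) > ng)
    stop("configuration error: modules cannot exceed n_genes")
  if (sum(sizes) > ng)
    stop("configuration error: total module genes exceed n_genes")

  gene_a <- sprintf("zfA%05d", seq_len(ng))
  gene_b <- sprintf("hsB%05d", seq_len(ng))
  labels_a <- integer(ng)
  idx <- 1L
  for (m in seq_len(nm)) {
    labels_a[idx:(idx + sizes[m] - 1L)] <- m
    idx <- idx + sizes[m]
  }

  lam_centre <- sqrt(config$module_cor)
  draw_loadings <- function(n)
    pmin(0.995, pmax(0.05, runif(n, lam_centre - 0.1, lam_centre + 0.1)))

  expr_block <- function(lambda, f) {
    noise <- matrix(rnorm(length(lambda) * length(f)), length(lambda))
    lambda %o% f + sqrt(1 - lambda^2) * noise
  }

  # module factors are drawn orthogonal across samples so that distinct
  # modules are distinguishable at small sample sizes (chance correlation
  # between raw Gaussian factors at n = 12 would merge planted modules)
  draw_factors <- function(k, n) {
    if (k == 0) return(matrix(0, 0, n))
    m <- matrix(rnorm(max(k, 1) * n), nrow = n)
    if (k <= n) {
      q <- qr.Q(qr(m))[, seq_len(k), drop = FALSE]
      t(q) * sqrt(n)
    } else t(m)[seq_len(k), , drop = FALSE]
  }

  expr_a <- matrix(rnorm(ng * n_samples), ng, n_samples,
                   dimnames = list(gene_a, sprintf("A_s%02d", seq_len(n_samples))))
  loadings <- setNames(numeric(ng), gene_a)
  factors_a <- draw_factors(max(nm, 1), n_samples)
  for (m in seq_len(nm)) {
    rows <- which(labels_a == m)
    lam <- draw_loadings(length(rows))
    loadings[rows] <- lam
    expr_a[rows, ] <- expr_block(lam, factors_a[m, ])
  }

  n_pres <- round(config$preserved_fraction * nm)
  preserved <- seq_len(n_pres)
  labels_b <- labels_a
  expr_b <- matrix(rnorm(ng * n_samples), ng, n_samples,
                   dimnames = list(gene_b, sprintf("B_s%02d", seq_len(n_samples))))
  loadings_b <- setNames(numeric(ng), gene_b)
  for (m in preserved) {
    rows <- which(labels_a == m)
    lam <- loadings[rows]
    loadings_b[rows] <- lam
    expr_b[rows, ] <- expr_block(lam, factors_a[m, ])
  }
  not_pres <- setdiff(seq_len(nm), preserved)
  if (length(not_pres)) {
    # non-preserved module genes scatter over the whole non-preserved +
    # background pool, so a dispersed reference module is a uniform random
    # set with respect to the test network's structure
    pool <- which(labels_a %in% c(not_pres, 0L))
    shuffled <- sample(pool)
    labels_b[pool] <- 0L
    factors_b <- draw_factors(length(not_pres), n_samples)
    at <- 1L
    for (j in seq_along(not_pres)) {
      m <- not_pres[j]
      rows <- shuffled[at:(at + sizes[m] - 1L)]
      at <- at + sizes[m]
      labels_b[rows] <- m
      lam <- draw_loadings(length(rows))
      loadings_b[rows] <- lam
      expr_b[rows, ] <- expr_block(lam, factors_b[j, ])
    }
  }

  truth <- list(labels_a = setNames(labels_a, gene_a),
                labels_b = setNames(labels_b, gene_b),
                loadings_a = loadings, loadings_b = loadings_b,
                module_sizes = sizes, preserved_modules = preserved)
  class(truth) <- "planted_truth"
  list(expr_a = expr_a, expr_b = expr_b,
       ortholog_map = data.frame(gene_a = gene_a, gene_b = gene_b,
                                 stringsAsFactors = FALSE),
       truth = truth)
}
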