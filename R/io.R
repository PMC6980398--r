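#' Read a genes x samples count matrix from TSV
#'
#' Tab-separated with a header row of sample ids and gene ids in the first
#' column. Duplicate gene or sample ids and negative or non-finite counts are
#' rejected.
#'
#' @param path TSV file.
#' @return integer matrix.
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   row.names = 1)
  m <- as.matrix(df)
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("duplicate gene or sample ids in ", path)
  if (any(!is.finite(m)) || any(m < 0))
    stop("counts must be finite and >= 0")
  m
}

#' Write a genes x samples matrix as TSV
#' @param mat matrix with dimnames.
#' @param path output path.
#' @param id_column name of the first (row-id) column.
#' @export
write_matrix_tsv <- function(mat, path, id_column = "gene_id") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a sample metadata table (TSV)
#'
#' Needs at least sample_id and condition columns; genotype/age/
#' replicate_group are kept when present.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_study_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(df)))
    stop("metadata needs sample_id and condition columns")
  df
}

#' Read a two-column ortholog map (TSV)
#' @param path TSV with or without header; first two columns are used.
#' @param header logical.
#' @return data.frame with columns gene_a, gene_b.
#' @export
read_ortholog_tsv <- function(path, header = TRUE) {
  df <- read.table(path, header = header, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("ortholog map needs two columns")
  out <- df[, 1:2]
  names(out) <- c("gene_a", "gene_b")
  out
}

#' Read a long peptide intensity CSV
#'
#' Columns peptide_id, protein_id, sample_id, intensity; an empty intensity
#' field denotes a censored (missing) measurement.
#'
#' @param path CSV file.
#' @return data.frame suitable for [normalize_peptides()].
#' @export
read_peptides_csv <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  need <- c("peptide_id", "protein_id", "sample_id", "intensity")
  if (!all(need %in% names(df)))
    stop("peptide CSV needs columns: ", paste(need, collapse = ", "))
  df
}

#' Write a simulated study to a directory
#'
#' Emits counts TSV, metadata TSV, truth TSV, and (when present) peptide CSV
#' and ortholog TSV, matching the formats the readers above consume.
#'
#' @param sim result of [simulate_counts()].
#' @param dir output directory (created).
#' @param peptides optional result of [simulate_peptides()].
#' @param modules optional result of [simulate_module_expression()].
#' @return the directory, invisibly.
#' @export
write_simulated_study <- function(sim, dir, peptides = NULL, modules = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(sim$counts, file.path(dir, "counts.tsv"))
  write.table(sim$design, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- data.frame(gene_id = names(sim$truth$pattern),
                      pattern = unname(sim$truth$pattern),
                      stringsAsFactors = FALSE)
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(peptides)) {
    pep <- peptides$peptides
    pep$intensity[is.na(pep$intensity)] <- ""
    write.table(pep, file.path(dir, "peptides.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(modules)) {
    write.table(modules$ortholog_map, file.path(dir, "orthologs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(modules$expr_a, file.path(dir, "expr_speciesA.tsv"))
    write_matrix_tsv(modules$expr_b, file.path(dir, "expr_speciesB.tsv"))
  }
  invisible(dir)
}

#' Write per-contrast DE tables as TSV
#' @param de a `de_result`.
#' @param dir output directory.
#' @return paths written, invisibly.
#' @export
write_de_tables <- function(de, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(de$tables), function(cn) {
    p <- file.path(dir, paste0("de_", cn, ".tsv"))
    write.table(de$tables[[cn]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
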