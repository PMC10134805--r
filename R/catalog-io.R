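#' @importFrom Matrix rowSums colSums t tcrossprod Diagonal sparseMatrix readMM writeMM
#' @importFrom methods as is new
#' @importFrom rlang .data abort
#' @importFrom tibble tibble as_tibble
NULL

# Orientation contract, used everywhere in the package: samples are rows,
# genes are columns. Row/column ids are kept in dimnames and are sorted with
# locale-independent (C radix) order at construction time.

lex_sort <- function(x) sort(unique(x), method = "radix")

#' Build a sparse presence (and optionally abundance) matrix from a membership table
#'
#' Collapses a long membership table of `(sample_id, gene_id[, abundance])`
#' records into a binary samples-by-genes incidence matrix. Duplicate
#' `(sample, gene)` pairs collapse to a single presence entry; their abundances,
#' if given, are summed. Rows and columns are ordered lexicographically
#' (C locale) so that downstream seeded analyses are reproducible across
#' platforms.
#'
#' @param df A data frame with columns `sample_id`, `gene_id` and optionally
#'   `abundance` (numeric, non-negative).
#' @return A list with elements `presence` (a binary `dgCMatrix`) and
#'   `abundance` (a `dgCMatrix` with the same support, or `NULL` when the
#'   input has no abundance column).
#' @export
as_presence_matrix <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("sample_id", "gene_id")
  if (!all(need %in% names(df))) {
    abort(paste0("membership table must have columns ", paste(need, collapse = ", ")))
  }
  samp <- as.character(df$sample_id)
  gene <- as.character(df$gene_id)
  if (anyNA(samp) || anyNA(gene)) abort("sample_id / gene_id may not be missing")
  has_ab <- "abundance" %in% names(df)
  if (has_ab) {
    ab <- as.numeric(df$abundance)
    if (anyNA(ab)) abort("abundance values must be numeric and non-missing")
    if (any(ab < 0)) abort("negative abundance values are not allowed")
  }
  rows <- lex_sort(samp)
  cols <- lex_sort(gene)
  i <- match(samp, rows)
  j <- match(gene, cols)
  pm <- sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(length(rows), length(cols)),
    dimnames = list(rows, cols)
  )
  pm@x[] <- 1 # duplicates collapse to presence
  pm <- methods::as(methods::as(pm, "generalMatrix"), "CsparseMatrix")
  pm@x[] <- 1
  am <- NULL
  if (has_ab) {
    am <- sparseMatrix(
      i = i, j = j, x = ab,
      dims = c(length(rows), length(cols)),
      dimnames = list(rows, cols)
    ) # duplicate abundances summed
    am <- methods::as(methods::as(am, "generalMatrix"), "CsparseMatrix")
  }
  list(presence = pm, abundance = am)
}

#' Read a gene membership TSV into sparse matrices
#'
#' The file must be tab-separated with a header containing `sample_id`,
#' `gene_id` and optionally `abundance`. See [as_presence_matrix()] for the
#' collapsing and ordering rules.
#'
#' @param path Path to the membership TSV.
#' @return As [as_presence_matrix()].
#' @export
read_membership <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(paste0(
      "malformed membership file ", path, ": parse problem at line ",
      probs$row[1], " (", probs$expected[1], " expected, got ", probs$actual[1], ")"
    ))
  }
  as_presence_matrix(df)
}

#' Read a sample metadata TSV
#'
#' Expects header columns `sample_id`, `ecology`, `ecology_group` and
#' optionally `disease_status`, `westernized`, `age_category`. Checks that
#' sample ids are unique and that each ecology maps to exactly one ecology
#' group.
#'
#' @param path Path to the metadata TSV.
#' @return A tibble, one row per sample.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  st <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_table(st)
  st
}

validate_sample_table <- function(st) {
  need <- c("sample_id", "ecology", "ecology_group")
  if (!all(need %in% names(st))) {
    abort(paste0("sample table must have columns ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(st$sample_id)) abort("sample_id values must be unique")
  map <- unique(st[, c("ecology", "ecology_group")])
  if (anyDuplicated(map$ecology)) {
    abort("each ecology must map to exactly one ecology_group")
  }
  invisible(st)
}

#' Read a gene annotation TSV
#'
#' Header columns: `gene_id`, `protein_product`, `cog_category`,
#' `taxon_label`; any annotation may be missing (novel genes carry no
#' annotation at all).
#'
#' @param path Path to the annotation TSV.
#' @return A tibble, one row per gene.
#' @export
read_gene_annotations <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Remove samples with too few genes
#'
#' Drops samples whose presence row sum is below `min_genes` (catalog default
#' 100, the threshold used when assembling the underlying gene catalog), then
#' prunes genes that are no longer present in any retained sample, and
#' recomputes the `n_genes` metadata column.
#'
#' @param pm Binary presence matrix (samples x genes).
#' @param st Sample table; must contain every row of `pm`.
#' @param min_genes Minimum number of genes per retained sample.
#' @return A list with the filtered `presence` matrix and `samples` tibble.
#' @export
apply_sample_filter <- function(pm, st, min_genes = 100) {
  stopifnot(min_genes >= 1)
  if (!all(rownames(pm) %in% st$sample_id)) {
    abort("presence matrix contains samples missing from the sample table")
  }
  keep <- rowSums(pm) >= min_genes
  if (!any(keep)) abort("sample filter removed every sample")
  pm2 <- pm[keep, , drop = FALSE]
  gkeep <- colSums(pm2) > 0
  pm2 <- pm2[, gkeep, drop = FALSE]
  st2 <- st[match(rownames(pm2), st$sample_id), , drop = FALSE]
  st2$n_genes <- as.integer(rowSums(pm2))
  list(presence = pm2, samples = as_tibble(st2))
}

#' Count singleton genes
#'
#' A singleton is a gene present in exactly one sample (column sum 1). In real
#' catalogs singletons dominate: about two thirds of all nonredundant genes
#' assemble in a single sample.
#'
#' @param pm Binary presence matrix.
#' @return A one-row tibble with `n_singleton`, `n_nonsingleton` and
#'   `fraction` = singletons / total genes.
#' @export
singleton_counts <- function(pm) {
  if (length(pm) == 0 || nrow(pm) == 0 || ncol(pm) == 0) abort("empty presence matrix")
  cs <- colSums(pm > 0)
  n1 <- sum(cs == 1)
  n2 <- sum(cs > 1)
  tibble(
    n_singleton = as.integer(n1),
    n_nonsingleton = as.integer(n2),
    fraction = n1 / (n1 + n2)
  )
}

#' Write / read a catalog matrix as Matrix Market plus index sidecars
#'
#' `write_catalog_matrix()` stores the sparse matrix in Matrix Market
#' coordinate format as `<name>.mtx` together with `<name>.rows` and
#' `<name>.cols` (one id per line, in matrix order). `read_catalog_matrix()`
#' reverses this bit-exactly, including row/column ordering.
#'
#' @param m A sparse samples-by-genes matrix with dimnames.
#' @param dir Directory to write into (created if needed).
#' @param name File stem, default `"matrix"`.
#' @return `write_catalog_matrix()` returns the three paths invisibly;
#'   `read_catalog_matrix()` returns a `dgCMatrix`.
#' @export
write_catalog_matrix <- function(m, dir, name = "matrix") {
  if (any(colSums(abs(m)) == 0)) {
    abort("matrix has an all-zero gene column; prune before writing")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) abort("matrix must carry dimnames")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(name, c(".mtx", ".rows", ".cols")))
  writeMM(methods::as(m, "CsparseMatrix"), paths[1])
  writeLines(rownames(m), paths[2])
  writeLines(colnames(m), paths[3])
  invisible(paths)
}

#' @rdname write_catalog_matrix
#' @export
read_catalog_matrix <- function(dir, name = "matrix") {
  paths <- file.path(dir, paste0(name, c(".mtx", ".rows", ".cols")))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) abort(paste0("missing matrix files: ", paste(missing, collapse = ", ")))
  m <- readMM(paths[1])
  # binary matrices round-trip through the Matrix Market pattern type, and
  # incidentally symmetric ones through the symmetric type; normalise both
  m <- methods::as(
    methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
    "CsparseMatrix"
  )
  rows <- readLines(paths[2])
  cols <- readLines(paths[3])
  if (length(rows) != nrow(m) || length(cols) != ncol(m)) {
    abort("index/matrix dimension mismatch in Matrix Market directory")
  }
  dimnames(m) <- list(rows, cols)
  m
}

# internal: validate a binary presence matrix
check_presence <- function(pm, require_no_zero_cols = TRUE) {
  if (!all(pm@x %in% c(0, 1))) abort("presence matrix entries must be 0/1")
  if (require_no_zero_cols && any(colSums(pm) == 0)) {
    abort("presence matrix has an all-zero gene column")
  }
  invisible(pm)
}
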