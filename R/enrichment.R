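#' Benjamini-Yekutieli adjusted p values
#'
#' Step-up false-discovery-rate control valid under arbitrary dependence:
#' `adj(i) = min over j >= rank(i) of min(1, p(j) * n * c(n) / j)` with
#' `c(n) = sum(1/k, k = 1..n)`. Input order is preserved in the output.
#'
#' @param pvals Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same length and order.
#' @export
by_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BY")
}

#' Genes contributing to each cluster
#'
#' Lists, per non-noise cluster of a sample clustering, the genes present in
#' at least one member sample -- the gene universe the per-cluster
#' enrichment tests are run on.
#'
#' @param pm Binary presence matrix.
#' @param clustering An `lsi_clustering` object, or a tibble with
#'   `sample_id` and `cluster` columns.
#' @return A tibble `(cluster, gene_id)`.
#' @export
cluster_gene_membership <- function(pm, clustering) {
  cl <- if (inherits(clustering, "lsi_clustering")) clustering$samples else clustering
  cl <- cl[cl$cluster != 0L, c("sample_id", "cluster")]
  out <- list()
  for (cid in sort(unique(cl$cluster))) {
    rows <- cl$sample_id[cl$cluster == cid]
    genes <- colnames(pm)[colSums(pm[rows, , drop = FALSE]) > 0]
    out[[length(out) + 1L]] <- tibble(cluster = cid, gene_id = genes)
  }
  dplyr::bind_rows(out)
}

#' Per-cluster functional enrichment of gene annotations
#'
#' For every (cluster, annotation value) pair, builds the 2x2 contingency
#' table of annotated genes with that value inside/outside the cluster
#' against all other annotated genes inside/outside, and applies a 1-df
#' chi-square test without continuity correction, switching to a two-sided
#' Fisher exact test whenever any observed cell is below
#' `fisher_cell_threshold`. P values are Benjamini-Yekutieli adjusted within
#' the feature family; rows are flagged enriched at `p_adj < alpha` with
#' fold change above 1.
#'
#' @param gene_clusters Tibble `(cluster, gene_id)` as from
#'   [cluster_gene_membership()].
#' @param annotations Gene annotation tibble (`gene_id` plus the feature
#'   column).
#' @param feature Which annotation column to test: `"protein_product"`,
#'   `"cog_category"` or `"taxon_label"`.
#' @param alpha Significance level on adjusted p values.
#' @param fisher_cell_threshold Cell count below which the Fisher exact test
#'   replaces the chi-square test.
#' @return A tibble with one row per (cluster, feature value): counts,
#'   `statistic`, `p`, `p_adj_by`, `fold_change`, `test_used`, `enriched`.
#'   Features skipped for degenerate margins are recorded in the
#'   `"skipped"` attribute.
#' @export
functional_enrichment <- function(gene_clusters, annotations,
                                  feature = c("protein_product", "cog_category", "taxon_label"),
                                  alpha = 0.05, fisher_cell_threshold = 6) {
  feature <- match.arg(feature)
  stopifnot(alpha > 0, alpha < 1)
  ann <- annotations[!is.na(annotations[[feature]]), c("gene_id", feature)]
  names(ann)[2] <- "feature"
  df <- dplyr::inner_join(gene_clusters, ann, by = "gene_id")
  total_by_feature <- table(ann$feature)
  n_ann_total <- nrow(ann)
  rows <- list()
  skipped <- list()
  for (cid in sort(unique(df$cluster))) {
    in_cl <- df[df$cluster == cid, ]
    n_in <- nrow(in_cl) # annotated genes inside the cluster
    feats <- sort(unique(in_cl$feature))
    cnt_in <- table(in_cl$feature)
    for (f in feats) {
      a <- as.integer(cnt_in[[f]])
      b <- as.integer(total_by_feature[[f]]) - a
      c_ <- n_in - a
      d <- (n_ann_total - as.integer(total_by_feature[[f]])) - c_
      tab <- matrix(c(a, c_, b, d), 2, 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        skipped[[length(skipped) + 1L]] <- tibble(
          cluster = cid, feature = f, reason = "degenerate margin"
        )
        next
      }
      small <- any(tab < fisher_cell_threshold)
      if (small) {
        ft <- stats::fisher.test(tab)
        stat <- NA_real_
        p <- ft$p.value
        test_used <- "fisher"
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        stat <- unname(ct$statistic)
        p <- ct$p.value
        test_used <- "chisq"
      }
      fold <- (a / (a + c_)) / (b / (b + d))
      rows[[length(rows) + 1L]] <- tibble(
        cluster = cid, feature = f,
        n_in = a, n_out = b, other_in = c_, other_out = d,
        statistic = stat, p = p, fold_change = fold, test_used = test_used
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out$p_adj_by <- by_adjust(out$p)
    out$enriched <- out$p_adj_by < alpha & out$fold_change > 1
    out <- dplyr::arrange(out, .data$p_adj_by, .data$p)
  }
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  out
}

# Welch one-sided (greater) t test that tolerates zero variance
welch_greater <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  vx <- stats::var(x)
  vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  delta <- mean(x) - mean(y)
  if (se2 == 0) {
    # both sides constant: identical means give p = 0.5 by symmetry,
    # otherwise the direction decides
    p <- if (delta > 0) 0 else if (delta < 0) 1 else 0.5
    return(list(t = 0, df = NA_real_, p = p))
  }
  t <- delta / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = stats::pt(t, df, lower.tail = FALSE))
}

#' Per-sample counts of genes annotated to each taxon
#'
#' @param pm Binary presence matrix.
#' @param annotations Gene annotation tibble with `taxon_label`.
#' @return A dense samples-by-taxa count matrix.
#' @export
per_sample_taxon_counts <- function(pm, annotations) {
  ann <- annotations[!is.na(annotations$taxon_label), c("gene_id", "taxon_label")]
  ann <- ann[ann$gene_id %in% colnames(pm), ]
  taxa <- lex_sort(ann$taxon_label)
  ind <- sparseMatrix(
    i = match(ann$gene_id, colnames(pm)),
    j = match(ann$taxon_label, taxa),
    x = 1, dims = c(ncol(pm), length(taxa)),
    dimnames = list(colnames(pm), taxa)
  )
  as.matrix(pm %*% ind)
}

#' Per-cluster taxonomic enrichment
#'
#' For every (cluster, taxon) pair, a one-sided Welch t test compares the
#' per-sample count of genes annotated to the taxon inside the cluster
#' against all other clustered samples (alternative: greater inside).
#' Benjamini-Yekutieli adjustment is applied across all pairs.
#'
#' @param taxon_counts Samples-by-taxa count matrix, see
#'   [per_sample_taxon_counts()].
#' @param clustering An `lsi_clustering` object or tibble with `sample_id`
#'   and `cluster`.
#' @param alpha Significance level on adjusted p values.
#' @return A tibble with `cluster`, `taxon`, group means, `statistic` (t),
#'   `p`, `p_adj_by`, `fold_change`, `enriched`.
#' @export
taxonomic_enrichment <- function(taxon_counts, clustering, alpha = 0.05) {
  cl <- if (inherits(clustering, "lsi_clustering")) clustering$samples else clustering
  cl <- cl[cl$cluster != 0L, c("sample_id", "cluster")]
  counts <- taxon_counts[cl$sample_id, , drop = FALSE]
  rows <- list()
  for (cid in sort(unique(cl$cluster))) {
    inside <- cl$cluster == cid
    if (sum(inside) < 2 || sum(!inside) < 2) next
    for (tx in colnames(counts)) {
      x <- counts[inside, tx]
      y <- counts[!inside, tx]
      w <- welch_greater(x, y)
      rows[[length(rows) + 1L]] <- tibble(
        cluster = cid, taxon = tx,
        mean_in = mean(x), mean_out = mean(y),
        statistic = w$t, p = w$p,
        fold_change = if (mean(y) > 0) mean(x) / mean(y) else NA_real_
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out$p_adj_by <- by_adjust(out$p)
    out$enriched <- out$p_adj_by < alpha
    out <- dplyr::arrange(out, .data$p_adj_by, .data$p)
  }
  out
}
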