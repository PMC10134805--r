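#' Pan-ecologically conserved genes
#'
#' A gene is conserved when it is present in at least one sample of every
#' ecology -- found in every type of metagenome, though not necessarily in
#' every genome.
#'
#' @param pm Binary presence matrix.
#' @param st Sample table with `ecology`.
#' @return Character vector of conserved gene ids (matrix column order).
#' @export
conserved_genes <- function(pm, st) {
  st <- st[match(rownames(pm), st$sample_id), , drop = FALSE]
  eco_f <- factor(st$ecology)
  E <- nlevels(eco_f)
  ind <- sparseMatrix(
    i = as.integer(eco_f), j = seq_len(nrow(pm)), x = 1,
    dims = c(E, nrow(pm))
  )
  M <- ind %*% pm
  B <- methods::as(M, "CsparseMatrix")
  B@x[] <- 1
  colnames(pm)[colSums(B) == E]
}

#' Prevalence and abundance profile of a gene set on held-out samples
#'
#' Per ecology: the fraction of that ecology's held-out samples containing
#' each gene, and the median and IQR of its abundance over the samples where
#' it is present. Genes absent from the held-out matrix get prevalence 0 and
#' no abundance summary. Also reports each gene's overall prevalence across
#' all held-out samples, and the median of those per-gene prevalences.
#'
#' @param genes Character vector of gene ids.
#' @param heldout_pm Held-out presence matrix.
#' @param heldout_am Held-out abundance matrix (same support), or `NULL`.
#' @param heldout_st Held-out sample table with `ecology`.
#' @return A `gene_set_profile` object: `per_ecology` (long tibble),
#'   `overall` (per-gene tibble), `median_prevalence`.
#' @export
prevalence_profile <- function(genes, heldout_pm, heldout_am = NULL, heldout_st) {
  st <- heldout_st[match(rownames(heldout_pm), heldout_st$sample_id), , drop = FALSE]
  ecos <- lex_sort(st$ecology)
  present_cols <- intersect(genes, colnames(heldout_pm))
  per_eco <- list()
  for (e in ecos) {
    rows <- which(st$ecology == e)
    if (length(rows) == 0) {
      per_eco[[e]] <- tibble(
        gene_id = genes, ecology = e, prevalence = NA_real_,
        abundance_median = NA_real_, abundance_iqr = NA_real_
      )
      next
    }
    prev <- stats::setNames(rep(0, length(genes)), genes)
    med <- iqr <- stats::setNames(rep(NA_real_, length(genes)), genes)
    if (length(present_cols)) {
      sub <- heldout_pm[rows, present_cols, drop = FALSE]
      prev[present_cols] <- colSums(sub > 0) / length(rows)
      if (!is.null(heldout_am)) {
        asub <- heldout_am[rows, present_cols, drop = FALSE]
        for (g in present_cols) {
          v <- asub[, g]
          v <- v[v > 0]
          if (length(v)) {
            med[g] <- stats::median(v)
            iqr[g] <- stats::IQR(v)
          }
        }
      }
    }
    per_eco[[e]] <- tibble(
      gene_id = genes, ecology = e, prevalence = unname(prev),
      abundance_median = unname(med), abundance_iqr = unname(iqr)
    )
  }
  overall_prev <- stats::setNames(rep(0, length(genes)), genes)
  if (length(present_cols)) {
    overall_prev[present_cols] <-
      colSums(heldout_pm[, present_cols, drop = FALSE] > 0) / nrow(heldout_pm)
  }
  overall <- tibble(gene_id = genes, prevalence = unname(overall_prev))
  out <- list(
    per_ecology = dplyr::bind_rows(per_eco),
    overall = overall,
    median_prevalence = stats::median(overall$prevalence)
  )
  class(out) <- "gene_set_profile"
  out
}

#' Ecology-set-specific differentially abundant genes
#'
#' Candidate genes are present in the training catalog within the target
#' ecologies only: under the default `"each"` rule, in at least one sample of
#' every target ecology (the `"any"` rule requires one sample of any of
#' them), and in no sample outside the target set. Each candidate is then
#' tested for higher abundance in the target ecologies' held-out samples
#' (one-sided Mann-Whitney by default, Welch t as an option), adjusted with
#' Benjamini-Yekutieli across candidates, and selected at
#' `p_adj < alpha`. Candidates missing from the held-out matrix are never
#' selected.
#'
#' @param pm Training presence matrix.
#' @param st Training sample table.
#' @param heldout_am Held-out abundance matrix.
#' @param heldout_st Held-out sample table.
#' @param target_ecologies Character vector: the ecology set of interest
#'   (proper, nonempty subset of all ecologies).
#' @param alpha Significance level on adjusted p values.
#' @param prevalence_rule `"each"` (default, presence required in every
#'   target ecology) or `"any"`.
#' @param test `"wilcoxon"` (default) or `"welch"`.
#' @param name Label for the contrast.
#' @return A `gene_set_result`: `table` (per-candidate tibble with `p`,
#'   `p_adj`, `selected`), `gene_ids` (the selected set), `name`,
#'   `target_ecologies`.
#' @export
ecology_set_genes <- function(pm, st, heldout_am, heldout_st, target_ecologies,
                              alpha = 0.05,
                              prevalence_rule = c("each", "any"),
                              test = c("wilcoxon", "welch"),
                              name = paste(target_ecologies, collapse = "+")) {
  prevalence_rule <- match.arg(prevalence_rule)
  test <- match.arg(test)
  all_ecos <- unique(st$ecology)
  if (!length(target_ecologies) || !all(target_ecologies %in% all_ecos)) {
    abort("target_ecologies must be a nonempty subset of the catalog ecologies")
  }
  if (setequal(target_ecologies, all_ecos)) {
    abort("target_ecologies must be a proper subset of the catalog ecologies")
  }
  st <- st[match(rownames(pm), st$sample_id), , drop = FALSE]
  tgt_rows <- which(st$ecology %in% target_ecologies)
  bg_rows <- setdiff(seq_len(nrow(pm)), tgt_rows)
  # exclusivity: absent from every background sample
  bg_occ <- colSums(pm[bg_rows, , drop = FALSE])
  exclusive <- bg_occ == 0
  if (prevalence_rule == "each") {
    in_all <- rep(TRUE, ncol(pm))
    for (e in target_ecologies) {
      rows <- which(st$ecology == e)
      in_all <- in_all & (colSums(pm[rows, , drop = FALSE]) > 0)
    }
    candidates <- colnames(pm)[exclusive & in_all]
  } else {
    tgt_occ <- colSums(pm[tgt_rows, , drop = FALSE])
    candidates <- colnames(pm)[exclusive & tgt_occ > 0]
  }
  if (!length(candidates)) {
    out <- list(
      table = tibble(
        gene_id = character(), p = numeric(), p_adj = numeric(),
        selected = logical()
      ),
      gene_ids = character(), name = name,
      target_ecologies = target_ecologies
    )
    class(out) <- "gene_set_result"
    return(out)
  }
  h_st <- heldout_st[match(rownames(heldout_am), heldout_st$sample_id), , drop = FALSE]
  h_tgt <- which(h_st$ecology %in% target_ecologies)
  h_bg <- setdiff(seq_len(nrow(heldout_am)), h_tgt)
  p <- med_t <- med_b <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    g <- candidates[i]
    if (!(g %in% colnames(heldout_am))) next # absent from validation: no claim
    x <- as.numeric(heldout_am[h_tgt, g])
    y <- as.numeric(heldout_am[h_bg, g])
    med_t[i] <- stats::median(x)
    med_b[i] <- stats::median(y)
    if (test == "wilcoxon") {
      p[i] <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "greater", exact = FALSE)$p.value
      )
    } else {
      p[i] <- welch_greater(x, y)$p
    }
  }
  p_adj <- rep(NA_real_, length(candidates))
  tested <- !is.na(p)
  if (any(tested)) p_adj[tested] <- by_adjust(p[tested])
  selected <- !is.na(p_adj) & p_adj < alpha
  out <- list(
    table = tibble(
      gene_id = candidates, p = p, p_adj = p_adj,
      median_target = med_t, median_background = med_b,
      selected = selected
    ),
    gene_ids = candidates[selected], name = name,
    target_ecologies = target_ecologies
  )
  class(out) <- "gene_set_result"
  out
}

#' Exact-membership overlap counts across gene set results
#'
#' For every subset of result sets realized in the data, counts the genes
#' belonging to exactly that subset (upset-style exact intersections). The
#' counts over all realized subsets partition the union of the input sets.
#'
#' @param results A named list of character gene-id vectors or
#'   `gene_set_result` objects.
#' @return A tibble `(subset, n_genes)`, `subset` being the member set names
#'   joined with `"+"`.
#' @export
overlap_report <- function(results) {
  sets <- lapply(results, function(r) {
    if (inherits(r, "gene_set_result")) r$gene_ids else as.character(r)
  })
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  universe <- lex_sort(unlist(sets))
  if (!length(universe)) {
    return(tibble(subset = character(), n_genes = integer()))
  }
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(row) paste(names(sets)[row], collapse = "+"))
  tab <- table(key)
  tibble(
    subset = names(tab),
    n_genes = as.integer(tab)
  ) |> dplyr::arrange(dplyr::desc(.data$n_genes))
}
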