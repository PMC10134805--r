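#' Subsampled between-ecology Jaccard distances
#'
#' Controls for unequal ecology sample sizes by drawing, in each of
#' `iterations` rounds, `m` samples without replacement from every ecology,
#' forming each ecology's gene set as the union of its drawn samples' genes,
#' and computing all pairwise Jaccard distances plus, per ecology, the number
#' of genes found only in that ecology's subsample. Distances and unique-gene
#' counts are averaged over iterations.
#'
#' @param pm Binary presence matrix (samples x genes).
#' @param st Sample table with `sample_id` and `ecology` columns.
#' @param m Samples drawn per ecology per iteration (default 4).
#' @param iterations Number of subsampling rounds (default 50).
#' @param seed Integer seed; a fixed seed gives bit-identical results.
#' @param keep_iterations Retain per-iteration distance matrices.
#' @return An `ecology_distance` object: `distances` (E x E symmetric matrix),
#'   `unique_counts` (tibble of per-ecology means), and optionally
#'   `per_iteration`.
#' @export
subsample_jaccard <- function(pm, st, m = 4, iterations = 50, seed = 1L,
                              keep_iterations = FALSE) {
  stopifnot(m >= 1, iterations >= 1)
  st <- st[match(rownames(pm), st$sample_id), , drop = FALSE]
  ecos <- lex_sort(st$ecology)
  sizes <- table(st$ecology)
  small <- names(sizes)[sizes < m]
  if (length(small)) {
    abort(paste0(
      "ecology with fewer than m = ", m, " samples: ",
      paste(small, collapse = ", ")
    ))
  }
  rows_by_eco <- split(seq_len(nrow(pm)), st$ecology)[ecos]
  E <- length(ecos)
  acc_d <- matrix(0, E, E, dimnames = list(ecos, ecos))
  acc_u <- stats::setNames(numeric(E), ecos)
  per_iter <- if (keep_iterations) vector("list", iterations) else NULL
  withr::with_seed(child_seed(seed, 11L), {
    for (it in seq_len(iterations)) {
      drawn <- unlist(lapply(rows_by_eco, function(r) {
        if (length(r) == 1) r else sample(r, m)
      }), use.names = FALSE)
      d <- iteration_jaccard(pm, drawn, rep(seq_len(E), each = m))
      acc_d <- acc_d + d$dist
      acc_u <- acc_u + d$unique
      if (keep_iterations) {
        dm <- d$dist
        dimnames(dm) <- list(ecos, ecos)
        per_iter[[it]] <- dm
      }
    }
  })
  out <- list(
    distances = acc_d / iterations,
    unique_counts = tibble(ecology = ecos, mean_unique = unname(acc_u / iterations)),
    m = m, iterations = iterations, seed = seed,
    per_iteration = per_iter
  )
  class(out) <- "ecology_distance"
  out
}

# one subsampling round: drawn rows grouped into E ecologies of m rows each
iteration_jaccard <- function(pm, drawn, eco_index) {
  E <- max(eco_index)
  P <- pm[drawn, , drop = FALSE]
  ind <- sparseMatrix(
    i = eco_index, j = seq_along(drawn), x = 1,
    dims = c(E, length(drawn))
  )
  M <- ind %*% P
  B <- methods::as(M, "CsparseMatrix")
  B@x[] <- 1 # ecology-level incidence
  inter <- as.matrix(tcrossprod(B))
  sizes <- diag(inter)
  un <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / pmax(un, 1)
  diag(d) <- 0
  occ <- colSums(B)
  uniq <- numeric(E)
  # genes present in exactly one ecology's subsample
  one <- occ == 1
  if (any(one)) {
    B1 <- B[, one, drop = FALSE]
    uniq <- rowSums(B1)
  }
  list(dist = d, unique = uniq)
}

#' Permutation null for the between-ecology comparison
#'
#' Randomly permutes the sample-to-ecology assignment (sample gene content is
#' kept intact), recomputes the subsampled distance analysis for each
#' permutation, and summarises each as the gap between mean between-group and
#' mean within-group ecology distance. Under the null of exchangeable labels
#' the gap distribution is centred at zero; the observed gap measures how
#' strongly ecology groups structure gene content.
#'
#' @inheritParams subsample_jaccard
#' @param n_perm Number of label permutations.
#' @param keep_matrices Retain per-permutation distance matrices.
#' @return A `permutation_null` object: `observed` (gap of the unpermuted
#'   data), `perm` (tibble with per-permutation gaps), and optionally
#'   `matrices`.
#' @export
permutation_null <- function(pm, st, m = 4, iterations = 50, n_perm = 100,
                             seed = 1L, keep_matrices = FALSE) {
  stopifnot(n_perm >= 1)
  st <- st[match(rownames(pm), st$sample_id), , drop = FALSE]
  group_of <- stats::setNames(st$ecology_group, st$ecology)
  obs <- subsample_jaccard(pm, st, m = m, iterations = iterations, seed = seed)
  obs_gap <- distance_gap(obs$distances, group_of)
  gaps <- numeric(n_perm)
  mats <- if (keep_matrices) vector("list", n_perm) else NULL
  withr::with_seed(child_seed(seed, 12L), {
    perm_seeds <- sample.int(2147483646L, n_perm)
  })
  for (p in seq_len(n_perm)) {
    withr::with_seed(perm_seeds[p], {
      st_p <- st
      st_p$ecology <- sample(st$ecology)
    })
    r <- subsample_jaccard(pm, st_p,
      m = m, iterations = iterations,
      seed = perm_seeds[p]
    )
    gaps[p] <- distance_gap(r$distances, group_of)
    if (keep_matrices) mats[[p]] <- r$distances
  }
  out <- list(
    observed = obs_gap,
    observed_result = obs,
    perm = tibble(perm = seq_len(n_perm), gap = gaps),
    matrices = mats
  )
  class(out) <- "permutation_null"
  out
}

# gap = mean between-group distance - mean within-group distance
distance_gap <- function(D, group_of) {
  ecos <- rownames(D)
  g <- group_of[ecos]
  same <- outer(g, g, "==")
  ut <- upper.tri(D)
  between <- mean(D[ut & !same])
  within <- mean(D[ut & same])
  between - within
}

#' Order a between-ecology distance matrix by hierarchical clustering
#'
#' Agglomerative clustering on the averaged ecology distances, for heatmap
#' display and block-structure inspection.
#'
#' @param result An `ecology_distance` object or a symmetric distance matrix.
#' @param linkage Agglomeration method: `"average"` (default), `"complete"`
#'   or `"single"`.
#' @return A list with the `hclust` tree, the `leaf_order` (ecology labels)
#'   and the tree in `newick` text form.
#' @export
order_distance_matrix <- function(result, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  D <- if (inherits(result, "ecology_distance")) result$distances else result
  if (!isSymmetric(unname(D), tol = 1e-10)) abort("distance matrix must be symmetric")
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  list(
    hclust = hc,
    leaf_order = hc$labels[hc$order],
    newick = ape::write.tree(ape::as.phylo(hc))
  )
}

#' Write an ecology distance result as TSV
#'
#' @param result An `ecology_distance` object.
#' @param path Output TSV path (matrix with ecology names as header row and
#'   first column).
#' @export
write_distance_matrix <- function(result, path) {
  D <- if (inherits(result, "ecology_distance")) result$distances else result
  df <- data.frame(ecology = rownames(D), D, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}
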