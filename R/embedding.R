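#' TF-IDF weighting of a binary presence matrix
#'
#' Term frequency: each presence entry divided by its sample's total gene
#' count. Inverse document frequency: the natural log of
#' `(n_samples + 1) / colsum(gene)`. The output entry is TF x IDF and the
#' sparsity pattern of the input is preserved. Rare genes, which best
#' distinguish samples, receive the largest weights.
#'
#' @param pm Binary presence matrix with no all-zero rows or columns.
#' @return A sparse `dgCMatrix` of TF-IDF weights.
#' @export
tfidf_transform <- function(pm) {
  rs <- rowSums(pm)
  cs <- colSums(pm)
  if (any(rs == 0)) abort("presence matrix has an all-zero sample row")
  if (any(cs == 0)) abort("presence matrix has an all-zero gene column")
  n <- nrow(pm)
  tf <- Diagonal(x = 1 / rs) %*% pm
  idf <- log((n + 1) / cs)
  out <- tf %*% Diagonal(x = idf)
  dimnames(out) <- dimnames(pm)
  methods::as(out, "CsparseMatrix")
}

#' Truncated SVD factor scores (latent semantic indexing)
#'
#' Returns the left singular vectors scaled by the singular values, truncated
#' to rank `k` -- the sample coordinates in LSI space. Computed exactly via
#' the eigendecomposition of the sample-by-sample cross-product, with a fixed
#' sign convention (the largest-magnitude loading of each component is made
#' positive), so the result is deterministic with no randomized solver.
#'
#' @param x Weighted (TF-IDF) sparse matrix, samples by genes.
#' @param k Number of components; must not exceed `min(dim(x))`.
#' @return A dense `n_samples x k` matrix of factor scores.
#' @export
lsi_embed <- function(x, k) {
  if (k < 1 || k > min(dim(x))) {
    abort(paste0("k = ", k, " exceeds the rank bound min(dim) = ", min(dim(x))))
  }
  K <- as.matrix(tcrossprod(x))
  ee <- eigen(K, symmetric = TRUE)
  d <- sqrt(pmax(ee$values[seq_len(k)], 0))
  U <- ee$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  scores <- U * rep(d, each = nrow(U))
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("LSI", seq_len(k))
  scores
}

#' Two-dimensional UMAP embedding of LSI scores
#'
#' Wraps the UMAP algorithm (via the uwot package) with a fixed seed for
#' reproducibility on a fixed platform. Exact duplicate rows are collapsed
#' before embedding and re-expanded afterwards, so identical samples receive
#' identical coordinates.
#'
#' @param scores Numeric matrix of factor scores (samples x k).
#' @param n_neighbors UMAP neighbourhood size.
#' @param min_dist UMAP minimum embedding distance.
#' @param seed Integer seed.
#' @param n_epochs Optimisation epochs (default 200).
#' @param nn Optional precomputed exact k-nearest-neighbour graph for the
#'   distinct rows (a list with `idx` and `dist` matrices, the point itself in
#'   the first column), as produced by [exact_knn()]. Grid runs reuse one
#'   graph across the `min_dist` values.
#' @param init Optional initial coordinate matrix for the distinct rows
#'   (defaults to uwot's spectral initialisation).
#' @return An `n x 2` matrix of coordinates.
#' @export
embed_2d <- function(scores, n_neighbors, min_dist, seed = 1L, n_epochs = 200,
                     nn = NULL, init = NULL) {
  scores <- as.matrix(scores)
  key <- apply(scores, 1, paste, collapse = "\r")
  uniq <- !duplicated(key)
  su <- scores[uniq, , drop = FALSE]
  if (nrow(su) < n_neighbors + 1) {
    abort(paste0(
      "too few distinct samples (", nrow(su), ") for n_neighbors = ", n_neighbors
    ))
  }
  if (!all(uniq)) nn <- init <- NULL # precomputed graph indexes the full set
  co_u <- withr::with_seed(child_seed(seed, 21L), {
    uwot::umap(su,
      n_neighbors = n_neighbors, min_dist = min_dist,
      n_components = 2, n_epochs = n_epochs,
      n_threads = 1, n_sgd_threads = 1, batch = FALSE,
      nn_method = nn %||% "annoy",
      init = init %||% "spectral",
      verbose = FALSE
    )
  })
  co <- co_u[match(key, key[uniq]), , drop = FALSE]
  rownames(co) <- rownames(scores)
  colnames(co) <- c("x", "y")
  co
}

# Fuzzy simplicial-set weights from an exact kNN graph: the standard UMAP
# construction (local connectivity 1, bandwidth 1) -- per-point smooth kNN
# calibration by binary search so each point's effective neighbourhood mass
# is log2(n_neighbors), then fuzzy-union symmetrisation.
fuzzy_knn_graph <- function(knn) {
  idx <- knn$idx
  dd <- knn$dist
  n <- nrow(idx)
  k <- ncol(idx)
  dnn <- dd[, -1, drop = FALSE] # neighbours beyond the point itself
  rho <- dnn[, 1]
  target <- log2(k)
  lo <- rep(0, n)
  hi <- rep(Inf, n)
  sigma <- rep(1, n)
  for (it in 1:100) {
    val <- rowSums(exp(-pmax(dnn - rho, 0) / sigma))
    too_big <- val > target
    hi[too_big] <- sigma[too_big]
    lo[!too_big] <- sigma[!too_big]
    sigma <- ifelse(is.finite(hi), (lo + hi) / 2, sigma * 2)
  }
  w <- exp(-pmax(dnn - rho, 0) / sigma)
  P <- sparseMatrix(
    i = rep(seq_len(n), k - 1), j = as.vector(idx[, -1]),
    x = as.vector(w), dims = c(n, n)
  )
  V <- P + Matrix::t(P) - P * Matrix::t(P)
  methods::as(V, "CsparseMatrix")
}

# Run the UMAP stochastic gradient layout on a prepared fuzzy graph with a
# fixed initialisation. Calls the same optimizer uwot::umap() uses, with the
# standard settings (single thread, 5 negative samples, learning rate 1), so
# grid cells sharing a neighbour graph pay only the layout cost.
umap_sgd <- function(graph, init, min_dist, n_epochs, seed) {
  fab <- utils::getFromNamespace("find_ab_params", "uwot")
  mes <- utils::getFromNamespace("make_epochs_per_sample", "uwot")
  goa <- utils::getFromNamespace("get_opt_args", "uwot")
  olr <- utils::getFromNamespace("optimize_layout_r", "uwot")
  ab <- fab(spread = 1, min_dist = min_dist)
  V <- graph
  V@x[V@x < max(V@x) / n_epochs] <- 0
  V <- Matrix::drop0(V)
  positive_head <- V@i
  positive_tail <- Matrix::which(V != 0, arr.ind = TRUE)[, 2] - 1
  positive_ptr <- V@p
  eps <- mes(V@x, n_epochs)
  emb <- t(init)
  out <- withr::with_seed(seed, olr(
    head_embedding = emb, tail_embedding = NULL,
    positive_head = positive_head, positive_tail = positive_tail,
    positive_ptr = positive_ptr, n_epochs = n_epochs,
    n_head_vertices = ncol(emb), n_tail_vertices = ncol(emb),
    epochs_per_sample = eps, method = "umap",
    method_args = list(a = ab[[1]], b = ab[[2]], gamma = 1, approx_pow = FALSE),
    initial_alpha = 1, opt_args = goa(NULL, 1),
    negative_sample_rate = 5, rng_type = "pcg", batch = FALSE,
    n_threads = 1, grain_size = 1, move_other = TRUE,
    epoch_callback = NULL, verbose = FALSE
  ))
  t(out)
}

# deterministic spectral initialisation of a fuzzy graph, centred and scaled
# to unit column standard deviation (the optimizer's expected starting spread)
spectral_init_scaled <- function(graph, seed) {
  si <- utils::getFromNamespace("spectral_init", "uwot")
  emb <- withr::with_seed(seed, si(graph, ndim = 2, verbose = FALSE))
  emb <- sweep(emb, 2, colMeans(emb))
  sweep(emb, 2, pmax(apply(emb, 2, stats::sd), .Machine$double.eps), "/")
}

#' Exact k-nearest-neighbour graph
#'
#' Deterministic exact neighbours by full pairwise distances (fine at the
#' sample counts this package targets); the point itself occupies the first
#' column, as UMAP expects.
#'
#' @param x Numeric matrix (rows = points).
#' @param k Number of neighbours including self.
#' @return A list with `idx` and `dist` matrices of dimension `n x k`.
#' @export
exact_knn <- function(x, k) {
  D <- as.matrix(stats::dist(x))
  n <- nrow(D)
  idx <- matrix(0L, n, k)
  dd <- matrix(0, n, k)
  for (i in seq_len(n)) {
    o <- order(D[i, ], method = "radix")[seq_len(k)]
    # self first (distance 0)
    o <- c(i, setdiff(o, i))[seq_len(k)]
    idx[i, ] <- o
    dd[i, ] <- D[i, o]
  }
  list(idx = idx, dist = dd)
}

#' Mean silhouette of a clustering over non-noise points
#'
#' Euclidean silhouette on the 2-D coordinates, computed only over points
#' assigned to a cluster. Returns `NA` (undefined) when fewer than two
#' clusters are present, so degenerate cells can never win model selection.
#'
#' @param coords `n x 2` coordinate matrix.
#' @param labels Integer labels, `0` = noise.
#' @return Mean silhouette width in `[-1, 1]`, or `NA`.
#' @export
clustering_silhouette <- function(coords, labels) {
  keep <- labels != 0L
  if (length(unique(labels[keep])) < 2) {
    return(NA_real_)
  }
  sil <- cluster::silhouette(labels[keep], stats::dist(coords[keep, , drop = FALSE]))
  mean(sil[, "sil_width"])
}

#' Embedding pipeline configuration
#'
#' Parameter grids for the LSI clustering pipeline: SVD component counts,
#' UMAP neighbourhood sizes and minimum distances, and HDBSCAN minimum
#' cluster sizes, plus the noise-fraction constraint used in model selection.
#'
#' @param k_grid SVD component counts.
#' @param n_neighbors_grid UMAP `n_neighbors` values.
#' @param min_dist_grid UMAP `min_dist` values.
#' @param min_cluster_grid HDBSCAN minimum cluster sizes (`minPts`).
#' @param noise_fraction_max Maximum tolerated fraction of unclustered
#'   samples during model selection.
#' @param n_epochs UMAP optimisation epochs.
#' @param normalize_scores L2-normalise each sample's factor-score vector
#'   before embedding (default `TRUE`). The leading LSI component tracks
#'   per-sample gene count; unit-normalising removes that depth axis so
#'   clusters reflect gene content composition, the standard practice when
#'   LSI feeds a neighbourhood embedding.
#' @return An `embedding_config` object.
#' @export
embedding_config <- function(k_grid = c(10, 50, 100),
                             n_neighbors_grid = c(10, 15, 20, 30),
                             min_dist_grid = c(0.1, 0.25, 0.5),
                             min_cluster_grid = c(25, 50, 75, 100),
                             noise_fraction_max = 0.10,
                             n_epochs = 200,
                             normalize_scores = TRUE) {
  stopifnot(
    length(k_grid) >= 1, length(n_neighbors_grid) >= 1,
    length(min_dist_grid) >= 1, length(min_cluster_grid) >= 1,
    noise_fraction_max >= 0, noise_fraction_max <= 1
  )
  structure(
    list(
      k_grid = as.integer(sort(k_grid)),
      n_neighbors_grid = as.integer(sort(n_neighbors_grid)),
      min_dist_grid = sort(min_dist_grid),
      min_cluster_grid = as.integer(sort(min_cluster_grid)),
      noise_fraction_max = noise_fraction_max,
      n_epochs = n_epochs,
      normalize_scores = normalize_scores
    ),
    class = "embedding_config"
  )
}

#' Select the best grid cell
#'
#' Restricts the grid to cells whose noise fraction is at most
#' `noise_fraction_max` (relaxing to the minimum achieved noise fraction if
#' no cell qualifies), then picks the maximum silhouette; ties break to fewer
#' unclustered samples, then smaller `min_cluster_size`, `k`, `n_neighbors`
#' and `min_dist`. Cells with undefined silhouette (fewer than two clusters)
#' can only be chosen if no cell anywhere has a defined silhouette, in which
#' case the fewest-unclustered cell wins.
#'
#' @param grid_report Tibble with columns `k`, `n_neighbors`, `min_dist`,
#'   `min_cluster_size`, `n_clusters`, `silhouette`, `n_unclustered`, `n`.
#' @param noise_fraction_max Noise constraint, see above.
#' @return The chosen row of `grid_report` (one-row tibble).
#' @export
select_model <- function(grid_report, noise_fraction_max = 0.10) {
  if (nrow(grid_report) == 0) abort("empty grid report")
  g <- grid_report
  nf <- g$n_unclustered / g$n
  ok <- nf <= noise_fraction_max
  if (!any(ok)) ok <- nf <= min(nf)
  g <- g[ok, , drop = FALSE]
  if (all(is.na(g$silhouette))) {
    ord <- order(g$n_unclustered, g$min_cluster_size, g$k, g$n_neighbors, g$min_dist)
    return(g[ord[1], , drop = FALSE])
  }
  g <- g[!is.na(g$silhouette), , drop = FALSE]
  ord <- order(-g$silhouette, g$n_unclustered, g$min_cluster_size, g$k,
    g$n_neighbors, g$min_dist,
    method = "radix"
  )
  g[ord[1], , drop = FALSE]
}

#' Run the full LSI clustering pipeline over the parameter grid
#'
#' TF-IDF, truncated SVD at each `k`, UMAP embedding at each
#' `(n_neighbors, min_dist)`, HDBSCAN at each minimum cluster size, then
#' silhouette-based model selection under the noise constraint.
#'
#' @param pm Filtered binary presence matrix.
#' @param cfg An [embedding_config()].
#' @param st Optional sample table; when given, its metadata columns are
#'   carried into the per-sample output for plotting overlays.
#' @param seed Integer master seed for the UMAP stages.
#' @return An `lsi_clustering` object with elements `samples` (tibble:
#'   `sample_id`, `x`, `y`, `cluster`, plus metadata), `silhouette`,
#'   `n_unclustered`, `chosen_params`, `grid_report`.
#' @export
run_lsi_pipeline <- function(pm, cfg = embedding_config(), st = NULL, seed = 1L) {
  stopifnot(inherits(cfg, "embedding_config"))
  kmax <- max(cfg$k_grid)
  if (kmax >= min(dim(pm))) {
    abort(paste0("largest k in grid (", kmax, ") must be < min(dim) = ", min(dim(pm))))
  }
  X <- tfidf_transform(pm)
  scores_full <- lsi_embed(X, kmax)
  report <- list()
  coords_store <- list()
  labels_store <- list()
  cell <- 0L
  for (k in cfg$k_grid) {
    S <- scores_full[, seq_len(k), drop = FALSE]
    if (isTRUE(cfg$normalize_scores)) {
      nrm <- sqrt(rowSums(S^2))
      S <- S / pmax(nrm, .Machine$double.eps)
    }
    for (nn in cfg$n_neighbors_grid) {
      no_dup <- anyDuplicated(S) == 0
      # the fuzzy neighbour graph and its spectral initialisation depend only
      # on (k, n_neighbors), so one graph serves every min_dist value
      graph <- if (no_dup) fuzzy_knn_graph(exact_knn(S, nn)) else NULL
      init0 <- if (no_dup) {
        withr::with_seed(
          child_seed(seed, 95L + cell),
          uwot::optimize_graph_layout(graph,
            X = S, n_epochs = 0,
            n_sgd_threads = 1, batch = FALSE, verbose = FALSE
          )
        )
      } else {
        NULL
      }
      for (md in cfg$min_dist_grid) {
        cell <- cell + 1L
        co <- if (no_dup) {
          co_md <- umap_sgd(graph, init0, md, cfg$n_epochs,
            seed = child_seed(seed, 100L + cell)
          )
          dimnames(co_md) <- list(rownames(pm), c("x", "y"))
          co_md
        } else {
          embed_2d(S, nn, md,
            seed = child_seed(seed, 100L + cell),
            n_epochs = cfg$n_epochs
          )
        }
        ckey <- paste(k, nn, md, sep = "|")
        coords_store[[ckey]] <- co
        for (mc in cfg$min_cluster_grid) {
          lab <- density_cluster(co, mc)
          lkey <- paste(ckey, mc, sep = "|")
          labels_store[[lkey]] <- lab
          report[[lkey]] <- tibble(
            k = k, n_neighbors = nn, min_dist = md, min_cluster_size = mc,
            n_clusters = length(setdiff(unique(lab), 0L)),
            silhouette = clustering_silhouette(co, lab),
            n_unclustered = sum(lab == 0L),
            n = nrow(co)
          )
        }
      }
    }
  }
  grid_report <- dplyr::bind_rows(report)
  chosen <- select_model(grid_report, cfg$noise_fraction_max)
  ckey <- paste(chosen$k, chosen$n_neighbors, chosen$min_dist, sep = "|")
  lkey <- paste(ckey, chosen$min_cluster_size, sep = "|")
  co <- coords_store[[ckey]]
  lab <- labels_store[[lkey]]
  samples <- tibble(
    sample_id = rownames(pm),
    x = co[, 1], y = co[, 2], cluster = lab
  )
  if (!is.null(st)) {
    samples <- dplyr::left_join(samples, st, by = "sample_id")
  }
  out <- list(
    samples = samples,
    silhouette = chosen$silhouette,
    n_unclustered = chosen$n_unclustered,
    chosen_params = list(
      k = chosen$k, n_neighbors = chosen$n_neighbors,
      min_dist = chosen$min_dist, min_cluster_size = chosen$min_cluster_size
    ),
    grid_report = grid_report,
    seed = seed
  )
  class(out) <- "lsi_clustering"
  out
}

#' Re-embed and re-cluster the samples of chosen clusters
#'
#' Restricts the presence matrix to the member samples of each requested
#' cluster, prunes genes absent from the subset, and reruns the LSI pipeline
#' with fixed subclustering parameters (defaults: k = 50, n_neighbors = 10,
#' min_dist = 0.1, min cluster size = 50).
#'
#' @param pm The full presence matrix.
#' @param st Sample table (metadata overlay for the subcluster output).
#' @param parent The `lsi_clustering` result to subcluster.
#' @param cluster_ids Integer cluster labels to re-analyse.
#' @param cfg Optional [embedding_config()]; defaults to the single fixed
#'   parameter cell above.
#' @param seed Integer seed.
#' @return A named list of `lsi_clustering` objects, one per cluster id.
#' @export
subcluster <- function(pm, st, parent, cluster_ids, cfg = NULL, seed = 1L) {
  stopifnot(inherits(parent, "lsi_clustering"))
  known <- setdiff(unique(parent$samples$cluster), 0L)
  bad <- setdiff(cluster_ids, known)
  if (length(bad)) {
    abort(paste0("unknown cluster id(s): ", paste(bad, collapse = ", ")))
  }
  out <- list()
  for (cid in cluster_ids) {
    ids <- parent$samples$sample_id[parent$samples$cluster == cid]
    sub_cfg <- cfg %||% embedding_config(
      k_grid = min(50L, length(ids) - 1L),
      n_neighbors_grid = 10L, min_dist_grid = 0.1,
      min_cluster_grid = 50L
    )
    if (length(ids) < max(sub_cfg$min_cluster_grid)) {
      abort(paste0(
        "cluster ", cid, " has ", length(ids),
        " samples, fewer than the minimum cluster size ",
        max(sub_cfg$min_cluster_grid)
      ))
    }
    sub_pm <- pm[ids, , drop = FALSE]
    sub_pm <- sub_pm[, colSums(sub_pm) > 0, drop = FALSE]
    out[[as.character(cid)]] <- run_lsi_pipeline(
      sub_pm, sub_cfg,
      st = st, seed = child_seed(seed, 200L + cid)
    )
  }
  out
}
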