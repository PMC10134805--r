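#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy an ecology distance result into long form
#'
#' @param x An `ecology_distance` object.
#' @param ... Unused.
#' @return A tibble `(ecology_a, ecology_b, distance)` over unordered pairs.
#' @method tidy ecology_distance
#' @export
tidy.ecology_distance <- function(x, ...) {
  D <- x$distances
  idx <- which(upper.tri(D), arr.ind = TRUE)
  tibble(
    ecology_a = rownames(D)[idx[, 1]],
    ecology_b = colnames(D)[idx[, 2]],
    distance = D[idx]
  )
}

#' @method glance ecology_distance
#' @export
glance.ecology_distance <- function(x, ...) {
  d <- x$distances[upper.tri(x$distances)]
  tibble(
    n_ecologies = nrow(x$distances), m = x$m, iterations = x$iterations,
    mean_distance = mean(d), min_distance = min(d), max_distance = max(d)
  )
}

#' @method tidy permutation_null
#' @export
tidy.permutation_null <- function(x, ...) x$perm

#' @method glance permutation_null
#' @export
glance.permutation_null <- function(x, ...) {
  tibble(
    observed_gap = x$observed,
    n_perm = nrow(x$perm),
    perm_mean = mean(x$perm$gap),
    perm_q025 = stats::quantile(x$perm$gap, 0.025, names = FALSE),
    perm_q975 = stats::quantile(x$perm$gap, 0.975, names = FALSE),
    perm_q99 = stats::quantile(x$perm$gap, 0.99, names = FALSE),
    p_value = (1 + sum(x$perm$gap >= x$observed)) / (1 + nrow(x$perm))
  )
}

#' @method tidy lsi_clustering
#' @export
tidy.lsi_clustering <- function(x, ...) x$samples

#' @method glance lsi_clustering
#' @export
glance.lsi_clustering <- function(x, ...) {
  tibble(
    n_samples = nrow(x$samples),
    n_clusters = length(setdiff(unique(x$samples$cluster), 0L)),
    silhouette = x$silhouette,
    n_unclustered = x$n_unclustered,
    k = x$chosen_params$k,
    n_neighbors = x$chosen_params$n_neighbors,
    min_dist = x$chosen_params$min_dist,
    min_cluster_size = x$chosen_params$min_cluster_size
  )
}

#' @method tidy gene_set_result
#' @export
tidy.gene_set_result <- function(x, ...) x$table

#' @method glance gene_set_result
#' @export
glance.gene_set_result <- function(x, ...) {
  tibble(
    name = x$name,
    n_candidates = nrow(x$table),
    n_selected = length(x$gene_ids)
  )
}

#' @method tidy gene_set_profile
#' @export
tidy.gene_set_profile <- function(x, ...) x$per_ecology

#' @method glance gene_set_profile
#' @export
glance.gene_set_profile <- function(x, ...) {
  tibble(
    n_genes = nrow(x$overall),
    median_prevalence = x$median_prevalence
  )
}

#' @export
print.ecology_distance <- function(x, ...) {
  cat(
    "Subsampled ecology distances:", nrow(x$distances), "ecologies,",
    x$m, "samples/ecology x", x$iterations, "iterations\n"
  )
  invisible(x)
}

#' @export
print.lsi_clustering <- function(x, ...) {
  g <- glance(x)
  cat(
    "LSI clustering:", g$n_samples, "samples ->", g$n_clusters,
    "clusters (", g$n_unclustered, "unclustered ), silhouette",
    format(g$silhouette, digits = 3), "\n"
  )
  cat(
    "  chosen: k =", g$k, ", n_neighbors =", g$n_neighbors,
    ", min_dist =", g$min_dist, ", min cluster size =", g$min_cluster_size, "\n"
  )
  invisible(x)
}

#' @export
print.gene_set_result <- function(x, ...) {
  cat(
    "Gene set '", x$name, "': ", nrow(x$table), " candidates, ",
    length(x$gene_ids), " selected\n",
    sep = ""
  )
  invisible(x)
}

#' Heatmap of between-ecology distances
#'
#' Ecologies are ordered by average-linkage hierarchical clustering of the
#' distance matrix.
#'
#' @param object An `ecology_distance` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecology_distance
#' @export
autoplot.ecology_distance <- function(object, ...) {
  ord <- order_distance_matrix(object)$leaf_order
  df <- tidy(object)
  df2 <- dplyr::bind_rows(
    df,
    dplyr::rename(df, ecology_a = "ecology_b", ecology_b = "ecology_a"),
    tibble(
      ecology_a = rownames(object$distances),
      ecology_b = rownames(object$distances), distance = 0
    )
  )
  df2$ecology_a <- factor(df2$ecology_a, levels = ord)
  df2$ecology_b <- factor(df2$ecology_b, levels = ord)
  ggplot2::ggplot(df2, ggplot2::aes(.data$ecology_a, .data$ecology_b,
    fill = .data$distance
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard\ndistance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' Scatter plot of the chosen 2-D embedding, coloured by cluster
#'
#' @param object An `lsi_clustering` object.
#' @param colour Column of the sample tibble to colour by (default
#'   `"cluster"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lsi_clustering
#' @export
autoplot.lsi_clustering <- function(object, colour = "cluster", ...) {
  df <- object$samples
  df$.col <- factor(df[[colour]])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$.col)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2", colour = colour) +
    ggplot2::theme_minimal()
}

#' Boxplots of within-ecology diversity metrics
#'
#' @param diversity Long tibble from [within_ecology_diversity()].
#' @return A ggplot object, one facet per metric.
#' @export
plot_diversity <- function(diversity) {
  ggplot2::ggplot(diversity, ggplot2::aes(.data$ecology, .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' Prevalence-by-ecology plot for a gene set profile
#'
#' @param profile A `gene_set_profile` object.
#' @return A ggplot object.
#' @export
plot_prevalence <- function(profile) {
  ggplot2::ggplot(
    profile$per_ecology,
    ggplot2::aes(.data$ecology, .data$prevalence)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::labs(x = NULL, y = "Prevalence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}
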