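#' Jaccard distance between two gene sets
#'
#' `1 - |a intersect b| / |a union b|`.
#'
#' @param a,b Character vectors of gene ids (treated as sets).
#' @return A number in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 && length(b) == 0) {
    abort("Jaccard distance of two empty sets is undefined")
  }
  inter <- length(intersect(a, b))
  1 - inter / (length(a) + length(b) - inter)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`. Note this is not invariant
#' to rescaling one vector alone; when comparing samples of unequal depth,
#' scale each to relative abundance first (as [within_ecology_diversity()]
#' does).
#'
#' @param x,y Non-negative numeric vectors of equal length.
#' @return A number in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort("abundance vectors must have equal length")
  if (any(x < 0) || any(y < 0)) abort("abundances must be non-negative")
  sx <- sum(x)
  sy <- sum(y)
  if (sx == 0 || sy == 0) abort("zero-sum abundance vector")
  1 - 2 * sum(pmin(x, y)) / (sx + sy)
}

#' Chao1 richness estimate from integer abundance counts
#'
#' With `f1` species observed exactly once and `f2` exactly twice:
#' `S_obs + f1^2 / (2 f2)` when `f2 > 0`, otherwise the bias-corrected form
#' `S_obs + f1 (f1 - 1) / 2`.
#'
#' @param counts Non-negative integer abundance vector (one entry per
#'   species; zeros are allowed and ignored).
#' @return A one-row tibble: `s_obs`, `estimate`, `variant`, `f1`, `f2`.
#' @export
chao1 <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    abort("Chao1 requires integer counts (singletons/doubletons undefined otherwise)")
  }
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) {
    est <- s_obs + f1^2 / (2 * f2)
    variant <- "chao1"
  } else {
    est <- s_obs + f1 * (f1 - 1) / 2
    variant <- "chao1_bias_corrected"
  }
  tibble(
    s_obs = as.integer(s_obs), estimate = est, variant = variant,
    f1 = as.integer(f1), f2 = as.integer(f2)
  )
}

#' Chao2 richness estimate from an incidence matrix
#'
#' Incidence-based analogue of Chao1: with `q1` species found in exactly one
#' sampling unit and `q2` in exactly two, the estimate is
#' `S_obs + q1^2 / (2 q2)` when `q2 > 0`, else the bias-corrected
#' `S_obs + q1 (q1 - 1) / 2`.
#'
#' @param incidence Binary units-by-species matrix (at least 2 units).
#' @return A one-row tibble: `s_obs`, `estimate`, `variant`, `q1`, `q2`.
#' @export
chao2 <- function(incidence) {
  if (nrow(incidence) < 2) {
    abort("Chao2 requires at least 2 incidence units")
  }
  inc <- incidence > 0
  freq <- colSums(inc)
  s_obs <- sum(freq > 0)
  q1 <- sum(freq == 1)
  q2 <- sum(freq == 2)
  if (q2 > 0) {
    est <- s_obs + q1^2 / (2 * q2)
    variant <- "chao2"
  } else {
    est <- s_obs + q1 * (q1 - 1) / 2
    variant <- "chao2_bias_corrected"
  }
  tibble(
    s_obs = as.integer(s_obs), estimate = est, variant = variant,
    q1 = as.integer(q1), q2 = as.integer(q2)
  )
}

#' Within-ecology diversity under equal-depth subsampling
#'
#' Per subsampling round and ecology: all pairwise gene-level Jaccard
#' distances between the `m` drawn samples, the Chao2 richness of the
#' ecology's m-sample gene-incidence block, and -- when a species count
#' matrix is supplied -- pairwise Bray-Curtis dissimilarities on per-sample
#' relative species abundances plus a per-sample Chao1 richness from the raw
#' integer counts. Results are pooled over iterations in long format.
#'
#' @inheritParams subsample_jaccard
#' @param species_counts Optional sparse integer samples-by-species count
#'   matrix sharing `pm`'s sample ids.
#' @return A long tibble `(ecology, iteration, metric, value)`; metrics are
#'   `jaccard`, `chao2`, and with species counts also `bray_curtis` and
#'   `chao1`.
#' @export
within_ecology_diversity <- function(pm, st, m = 4, iterations = 50, seed = 1L,
                                     species_counts = NULL) {
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
  if (!is.null(species_counts)) {
    species_counts <- species_counts[rownames(pm), , drop = FALSE]
  }
  rows_by_eco <- split(seq_len(nrow(pm)), st$ecology)[ecos]
  recs <- list()
  withr::with_seed(child_seed(seed, 13L), {
    for (it in seq_len(iterations)) {
      for (e in ecos) {
        r <- rows_by_eco[[e]]
        drawn <- if (length(r) == 1) r else sample(r, m)
        block <- pm[drawn, , drop = FALSE]
        block <- block[, colSums(block) > 0, drop = FALSE]
        # pairwise gene Jaccard within the ecology
        inter <- as.matrix(tcrossprod(block))
        sz <- diag(inter)
        un <- outer(sz, sz, "+") - inter
        jd <- (1 - inter / pmax(un, 1))[upper.tri(inter)]
        recs[[length(recs) + 1L]] <- tibble(
          ecology = e, iteration = it, metric = "jaccard", value = jd
        )
        if (m >= 2) {
          recs[[length(recs) + 1L]] <- tibble(
            ecology = e, iteration = it, metric = "chao2",
            value = chao2(block)$estimate
          )
        }
        if (!is.null(species_counts)) {
          sc <- as.matrix(species_counts[drawn, , drop = FALSE])
          rel <- sc / rowSums(sc)
          bc <- numeric()
          for (i in seq_len(nrow(rel) - 1)) {
            for (j in seq((i + 1), nrow(rel))) {
              bc <- c(bc, bray_curtis(rel[i, ], rel[j, ]))
            }
          }
          recs[[length(recs) + 1L]] <- tibble(
            ecology = e, iteration = it, metric = "bray_curtis", value = bc
          )
          recs[[length(recs) + 1L]] <- tibble(
            ecology = e, iteration = it, metric = "chao1",
            value = vapply(seq_len(nrow(sc)), function(i) chao1(sc[i, ])$estimate, 0)
          )
        }
      }
    }
  })
  dplyr::bind_rows(recs)
}
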