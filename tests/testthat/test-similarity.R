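test_that("ecologies with identical gene content are at distance zero", {
  df <- tidyr::expand_grid(
    sample_id = sprintf("s%02d", 1:8),
    gene_id = sprintf("g%02d", 1:20)
  )
  pm <- as_presence_matrix(df)$presence
  st <- simple_sample_table(pm, c("a", "b"))
  res <- subsample_jaccard(pm, st, m = 4, iterations = 5, seed = 1)
  expect_equal(unname(res$distances["a", "b"]), 0)
  expect_equal(res$unique_counts$mean_unique, c(0, 0))
})

test_that("disjoint gene pools are at distance one with full unique counts", {
  df <- dplyr::bind_rows(
    tidyr::expand_grid(sample_id = sprintf("a%d", 1:4), gene_id = sprintf("ga%02d", 1:15)),
    tidyr::expand_grid(sample_id = sprintf("b%d", 1:4), gene_id = sprintf("gb%02d", 1:25))
  )
  pm <- as_presence_matrix(df)$presence
  st <- simple_sample_table(pm, c("a", "a", "a", "a", "b", "b", "b", "b"))
  st$ecology <- ifelse(startsWith(st$sample_id, "a"), "a", "b")
  res <- subsample_jaccard(pm, st, m = 4, iterations = 3, seed = 1)
  expect_equal(unname(res$distances["a", "b"]), 1)
  uc <- res$unique_counts
  expect_equal(uc$mean_unique[uc$ecology == "a"], 15)
  expect_equal(uc$mean_unique[uc$ecology == "b"], 25)
})

test_that("exhaustive draws equal a set-algebra oracle", {
  # 3 ecologies x 4 samples, m = 4: the draw is deterministic
  withr::with_seed(5, {
    genes <- sprintf("g%03d", 1:60)
    members <- lapply(1:12, function(i) sample(genes, 25))
  })
  df <- tibble::tibble(
    sample_id = rep(sprintf("s%02d", 1:12), lengths(members)),
    gene_id = unlist(members)
  )
  pm <- as_presence_matrix(df)$presence
  st <- simple_sample_table(pm, rep(c("x", "y", "z"), each = 1))
  st$ecology <- rep(c("x", "y", "z"), 4)[match(st$sample_id, sprintf("s%02d", 1:12))]
  res <- subsample_jaccard(pm, st, m = 4, iterations = 2, seed = 9)
  # oracle on plain sets
  eco_sets <- lapply(split(st$sample_id, st$ecology), function(ids) {
    unique(unlist(lapply(ids, function(s) df$gene_id[df$sample_id == s])))
  })
  for (a in names(eco_sets)) {
    for (b in names(eco_sets)) {
      if (a == b) next
      expected <- 1 - length(intersect(eco_sets[[a]], eco_sets[[b]])) /
        length(union(eco_sets[[a]], eco_sets[[b]]))
      expect_equal(unname(res$distances[a, b]), expected)
    }
  }
  others <- function(e) unique(unlist(eco_sets[setdiff(names(eco_sets), e)]))
  for (e in names(eco_sets)) {
    expect_equal(
      res$unique_counts$mean_unique[res$unique_counts$ecology == e],
      length(setdiff(eco_sets[[e]], others(e)))
    )
  }
})

test_that("results are seed-deterministic and averaged over kept iterations", {
  cfg <- small_config()
  out <- generate_catalog(cfg, seed = 1)
  r1 <- subsample_jaccard(out$presence, out$samples,
    m = 3, iterations = 8,
    seed = 42, keep_iterations = TRUE
  )
  r2 <- subsample_jaccard(out$presence, out$samples, m = 3, iterations = 8, seed = 42)
  expect_identical(r1$distances, r2$distances)
  avg <- Reduce(`+`, r1$per_iteration) / length(r1$per_iteration)
  expect_lt(max(abs(avg - r1$distances)), 1e-12)
})

test_that("an undersized ecology is reported by name", {
  pm <- random_presence(5, 30)
  st <- simple_sample_table(pm, c("big", "big", "big", "big", "tiny"))
  st$ecology <- c(rep("big", 4), "tiny")
  expect_error(subsample_jaccard(pm, st, m = 4, iterations = 2), "tiny")
})

test_that("distances are invariant to gene column order", {
  cfg <- small_config()
  out <- generate_catalog(cfg, seed = 2)
  perm <- out$presence[, sample(ncol(out$presence))]
  r1 <- subsample_jaccard(out$presence, out$samples, m = 3, iterations = 5, seed = 7)
  r2 <- subsample_jaccard(perm, out$samples, m = 3, iterations = 5, seed = 7)
  expect_equal(r1$distances, r2$distances)
})

test_that("label permutation centres the group gap at zero", {
  cfg <- small_config(n_samples = 8)
  out <- generate_catalog(cfg, seed = 3)
  pn <- permutation_null(out$presence, out$samples,
    m = 4, iterations = 5,
    n_perm = 30, seed = 1
  )
  expect_gt(pn$observed, max(pn$perm$gap)) # structure dominates any permutation
  expect_lt(abs(mean(pn$perm$gap)), 0.05)
  g <- glance(pn)
  expect_lte(g$perm_q025, 0)
  expect_gte(g$perm_q975, 0)
})

test_that("identical sample content gives all-zero distances under any permutation", {
  df <- tidyr::expand_grid(
    sample_id = sprintf("s%02d", 1:12),
    gene_id = sprintf("g%02d", 1:10)
  )
  pm <- as_presence_matrix(df)$presence
  st <- simple_sample_table(pm, c("a", "b", "c"))
  st$ecology <- rep(c("a", "b", "c"), 4)
  st$ecology_group <- ifelse(st$ecology == "a", "g1", "g2")
  pn <- permutation_null(pm, st, m = 4, iterations = 2, n_perm = 5, seed = 1)
  expect_true(all(pn$perm$gap == 0))
  expect_equal(pn$observed, 0)
})

test_that("hierarchical ordering recovers planted blocks and ultrametric heights", {
  D <- matrix(0.9, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D[1:2, 1:2] <- 0.1
  D[3:4, 3:4] <- 0.1
  diag(D) <- 0
  ord <- order_distance_matrix(D, "average")
  lo <- ord$leaf_order
  expect_true(which(lo == "a") %in% c(which(lo == "b") + 1, which(lo == "b") - 1))
  expect_true(which(lo == "c") %in% c(which(lo == "d") + 1, which(lo == "d") - 1))
  # E = 2: a single merge at the pairwise distance
  D2 <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  ord2 <- order_distance_matrix(D2)
  expect_equal(ord2$hclust$height, 0.4)
  # ultrametric 3x3: merge heights equal the matrix entries
  D3 <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3, 3,
    dimnames = list(c("p", "q", "r"), c("p", "q", "r"))
  )
  ord3 <- order_distance_matrix(D3, "average")
  expect_equal(sort(ord3$hclust$height), c(0.2, 0.6))
  expect_true(grepl("^\\(", ord3$newick))
  # non-symmetric input rejected
  D4 <- D3
  D4[1, 2] <- 0.5
  expect_error(order_distance_matrix(D4), "symmetric")
})

test_that("nested pools give monotone distances on exhaustive draws", {
  # C is a subset of A which is a subset of B; more shared content with C
  # means a smaller distance, so d(A, C) <= d(B, C)
  gc <- sprintf("g%02d", 1:10)
  ga <- sprintf("g%02d", 1:20)
  gb <- sprintf("g%02d", 1:40)
  df <- dplyr::bind_rows(
    tidyr::expand_grid(sample_id = c("c1", "c2"), gene_id = gc),
    tidyr::expand_grid(sample_id = c("a1", "a2"), gene_id = ga),
    tidyr::expand_grid(sample_id = c("b1", "b2"), gene_id = gb)
  )
  pm <- as_presence_matrix(df)$presence
  st <- tibble::tibble(
    sample_id = rownames(pm),
    ecology = substr(rownames(pm), 1, 1),
    ecology_group = ecology
  )
  res <- subsample_jaccard(pm, st, m = 2, iterations = 1, seed = 1)
  expect_lte(res$distances["a", "c"], res$distances["b", "c"])
})
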