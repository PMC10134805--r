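test_that("the generator is deterministic in its seed", {
  cfg <- small_config()
  a <- generate_catalog(cfg, seed = 1)
  b <- generate_catalog(cfg, seed = 1)
  c <- generate_catalog(cfg, seed = 2)
  expect_identical(as.matrix(a$presence), as.matrix(b$presence))
  expect_identical(a$samples, b$samples)
  expect_false(identical(dim(a$presence), dim(c$presence)) &&
    identical(as.matrix(a$presence), as.matrix(c$presence)))
})

test_that("singleton_target = 0 with dropout = 0 yields no singleton columns", {
  cfg <- small_config(singleton_target = 0, dropout = 0)
  out <- generate_catalog(cfg, seed = 3)
  expect_equal(singleton_counts(out$presence)$n_singleton, 0L)
})

test_that("with dropout 0 exactly the planted conserved genes span every ecology", {
  cfg <- small_config(dropout = 0)
  out <- generate_catalog(cfg, seed = 4)
  expect_setequal(conserved_genes(out$presence, out$samples), out$truth$conserved_gene_ids)
  expect_length(out$truth$conserved_gene_ids, 12)
})

test_that("realized singleton fraction hits the target and invariants hold", {
  for (target in c(0.5, 0.66)) {
    cfg <- small_config(n_samples = 10, singleton_target = target)
    out <- generate_catalog(cfg, seed = 5)
    expect_lt(abs(out$truth$singleton_fraction_realized - target), 0.02)
    expect_true(check_ground_truth(out$truth, out$presence, out$samples))
  }
})

test_that("abundance is positive exactly on the presence support", {
  cfg <- small_config()
  out <- generate_catalog(cfg, seed = 6)
  am <- generate_abundance(out$presence, out$samples, cfg, out$truth, seed = 6)
  expect_identical(dimnames(am), dimnames(out$presence))
  expect_equal(as.matrix(am > 0), as.matrix(out$presence > 0))
  counts <- generate_abundance(out$presence, out$samples, cfg, out$truth,
    seed = 6, mode = "counts"
  )
  expect_true(all(counts@x >= 1 & counts@x == round(counts@x)))
})

test_that("planted contrast shifts raise target-ecology abundances", {
  cfg <- small_config()
  out <- generate_catalog(cfg, seed = 7)
  am <- generate_abundance(out$presence, out$samples, cfg, out$truth, seed = 7)
  ct <- out$truth$contrasts[[1]]
  tgt <- out$samples$sample_id[out$samples$ecology %in% ct$target_ecologies]
  shifted <- am[tgt, ct$gene_ids, drop = FALSE]
  base_genes <- setdiff(colnames(am), ct$gene_ids)[1:50]
  base <- am[tgt, base_genes, drop = FALSE]
  expect_gt(median(shifted@x), 4 * median(base@x))
})

test_that("a planted 8x abundance shift is detectable by a rank test across seeds", {
  # Monte-Carlo over seeds on a minimal two-ecology layout, 20 samples per side
  hits <- 0L
  n_rep <- 200L
  pm <- methods::as(Matrix::Matrix(1, 40, 1,
    dimnames = list(sprintf("s%02d", 1:40), "gene"), sparse = TRUE
  ), "CsparseMatrix")
  st <- tibble::tibble(
    sample_id = rownames(pm),
    ecology = rep(c("target", "background"), each = 20),
    ecology_group = ecology
  )
  truth <- structure(
    list(contrasts = list(list(
      name = "t", target_ecologies = "target",
      gene_ids = "gene", shift = 8
    ))),
    class = "ground_truth"
  )
  cfg <- small_config()
  for (s in seq_len(n_rep)) {
    am <- generate_abundance(pm, st, cfg, truth, seed = s)
    p <- stats::wilcox.test(am[1:20, 1], am[21:40, 1],
      alternative = "greater", exact = FALSE
    )$p.value
    hits <- hits + (p < 0.01)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("a unit shift leaves target and background exchangeable", {
  pm <- methods::as(Matrix::Matrix(1, 40, 1,
    dimnames = list(sprintf("s%02d", 1:40), "gene"), sparse = TRUE
  ), "CsparseMatrix")
  st <- tibble::tibble(
    sample_id = rownames(pm),
    ecology = rep(c("target", "background"), each = 20),
    ecology_group = ecology
  )
  truth <- structure(
    list(contrasts = list(list(
      name = "t", target_ecologies = "target",
      gene_ids = "gene", shift = 1
    ))),
    class = "ground_truth"
  )
  cfg <- small_config()
  pvals <- vapply(1:100, function(s) {
    am <- generate_abundance(pm, st, cfg, truth, seed = s)
    stats::wilcox.test(am[1:20, 1], am[21:40, 1],
      alternative = "greater", exact = FALSE
    )$p.value
  }, 0)
  expect_gt(mean(pvals < 0.05), 0.0 - 1e-9) # null: roughly alpha-level hits
  expect_lt(mean(pvals < 0.05), 0.15)
})

test_that("held-out generation is reproducible, disjoint, and prevalence tracks dropout", {
  cfg <- small_config(n_samples = 4, dropout = 0.2, heldout_per_ecology = 30)
  out <- generate_catalog(cfg, seed = 8)
  h1 <- generate_heldout(cfg, out$truth, seed = 8)
  h2 <- generate_heldout(cfg, out$truth, seed = 8)
  expect_identical(as.matrix(h1$presence), as.matrix(h2$presence))
  expect_length(intersect(rownames(h1$presence), rownames(out$presence)), 0)
  # binomial oracle: conserved genes present with probability 1 - dropout
  cons <- intersect(out$truth$conserved_gene_ids, colnames(h1$presence))
  prev <- mean(Matrix::colSums(h1$presence[, cons, drop = FALSE] > 0) / nrow(h1$presence))
  n_bin <- nrow(h1$presence) * length(cons)
  ci <- 4 * sqrt(0.8 * 0.2 / n_bin)
  expect_lt(abs(prev - 0.8), ci + 0.01)
})

test_that("heldout_per_ecology = 0 gives empty tables", {
  cfg <- small_config(heldout_per_ecology = 0)
  out <- generate_catalog(cfg, seed = 9)
  h <- generate_heldout(cfg, out$truth, seed = 9)
  expect_equal(nrow(h$samples), 0)
  expect_equal(dim(h$presence), c(0L, 0L))
})

test_that("group structure separates within from between distances", {
  cfg <- small_config(n_samples = 8)
  out <- generate_catalog(cfg, seed = 10)
  res <- subsample_jaccard(out$presence, out$samples, m = 4, iterations = 10, seed = 1)
  g <- out$samples$ecology_group[match(rownames(res$distances), out$samples$ecology)]
  same <- outer(g, g, "==")
  ut <- upper.tri(res$distances)
  expect_lt(mean(res$distances[ut & same]), mean(res$distances[ut & !same]))
})

test_that("ground truth round-trips through the plain-text format", {
  cfg <- small_config()
  out <- generate_catalog(cfg, seed = 11)
  path <- tempfile()
  write_ground_truth(out$truth, path)
  back <- read_ground_truth(path)
  expect_setequal(back$conserved_gene_ids, out$truth$conserved_gene_ids)
  expect_equal(back$singleton_fraction_realized, out$truth$singleton_fraction_realized)
  expect_equal(back$core_gene_ids, out$truth$core_gene_ids)
  expect_equal(back$group_labels, out$truth$group_labels)
  expect_equal(
    lapply(back$contrasts, `[[`, "gene_ids"),
    lapply(out$truth$contrasts, `[[`, "gene_ids")
  )
})

test_that("species counts are integer, seeded, and within the configured range", {
  cfg <- small_config()
  out <- generate_catalog(cfg, seed = 12)
  sp1 <- generate_species_counts(out$samples, cfg, seed = 1)
  sp2 <- generate_species_counts(out$samples, cfg, seed = 1)
  expect_identical(as.matrix(sp1), as.matrix(sp2))
  expect_true(all(sp1@x == round(sp1@x) & sp1@x >= 1))
  per_sample <- Matrix::rowSums(sp1 > 0)
  expect_true(all(per_sample >= 10 & per_sample <= 18))
})
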