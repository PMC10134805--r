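test_that("tfidf matches the closed-form 2x2 example and a dense naive oracle", {
  pm <- as_presence_matrix(tibble::tibble(
    sample_id = c("s1", "s1", "s2"), gene_id = c("g1", "g2", "g1")
  ))$presence
  w <- as.matrix(tfidf_transform(pm))
  expect_equal(w["s1", "g1"], 0.5 * log(1.5), tolerance = 1e-6)
  expect_equal(w["s1", "g2"], 0.5 * log(3), tolerance = 1e-6)
  expect_equal(w["s2", "g1"], 1 * log(1.5), tolerance = 1e-6)
  expect_equal(w["s2", "g2"], 0)
  expect_equal(unname(w), matrix(c(0.202733, 0.549306, 0.405465, 0), 2, 2, byrow = TRUE),
    tolerance = 1e-6
  )
  # single sample, single gene
  one <- as_presence_matrix(tibble::tibble(sample_id = "s", gene_id = "g"))$presence
  expect_equal(as.numeric(tfidf_transform(one)), log(2), tolerance = 1e-12)
  # dense naive implementation on random matrices
  withr::with_seed(61, {
    for (i in 1:20) {
      pm2 <- random_presence(20, 50, density = 0.3, seed = i)
      dense <- as.matrix(pm2)
      tf <- dense / rowSums(dense)
      idf <- log((nrow(dense) + 1) / colSums(dense))
      naive <- tf * rep(idf, each = nrow(dense))
      expect_equal(as.matrix(tfidf_transform(pm2)), naive, tolerance = 1e-12)
    }
  })
})

test_that("tfidf rejects zero rows and columns, and TF is local to each row", {
  m <- methods::as(Matrix::Matrix(c(1, 0, 0, 0), 2, 2,
    dimnames = list(c("s1", "s2"), c("g1", "g2")), sparse = TRUE
  ), "CsparseMatrix")
  expect_error(tfidf_transform(m), "all-zero")
  # duplicating a row changes IDF of its genes but not TF of other rows
  pm <- random_presence(5, 12, density = 0.5, seed = 2)
  w1 <- tfidf_transform(pm)
  pm2 <- rbind(pm, pm[5, , drop = FALSE])
  rownames(pm2)[6] <- "dup"
  tf1 <- as.matrix(pm / Matrix::rowSums(pm))
  tf2_first5 <- as.matrix(pm2[1:5, ] / Matrix::rowSums(pm2[1:5, ]))
  expect_equal(tf1, tf2_first5, tolerance = 1e-12)
})

test_that("lsi recovers exact low-rank structure", {
  u <- matrix(1:6 / 10, 6, 1)
  v <- matrix(seq(0.1, 1, length.out = 10), 1, 10)
  x <- Matrix::Matrix(u %*% v, sparse = TRUE)
  dimnames(x) <- list(paste0("s", 1:6), paste0("g", 1:10))
  s1 <- lsi_embed(x, 1)
  recon <- norm(as.matrix(x) - s1 %*% (t(s1) %*% as.matrix(x)) / sum(s1^2), "F")
  expect_lt(recon, 1e-8)
  # full rank: reconstruction via scores' norms matches the matrix norm
  pm <- random_presence(8, 30, density = 0.4, seed = 3)
  w <- tfidf_transform(pm)
  sc <- lsi_embed(w, 8)
  expect_equal(sum(sc^2), sum(w^2), tolerance = 1e-8)
  expect_error(lsi_embed(w, 9), "rank bound")
})

test_that("lsi separates orthogonal blocks", {
  blk <- matrix(0, 20, 40)
  blk[1:10, 1:20] <- 1
  blk[11:20, 21:40] <- 1
  blk <- blk * matrix(runif(800, 0.5, 1), 20, 40)
  x <- Matrix::Matrix(blk, sparse = TRUE)
  dimnames(x) <- list(paste0("s", 1:20), paste0("g", 1:40))
  sc <- lsi_embed(x, 2)
  d <- as.matrix(dist(sc))
  within <- mean(d[1:10, 1:10][upper.tri(diag(10))])
  between <- mean(d[1:10, 11:20])
  expect_gt(between, 3 * within)
})

test_that("reconstruction error is non-increasing in k", {
  pm <- random_presence(15, 60, density = 0.3, seed = 4)
  w <- tfidf_transform(pm)
  tot <- sum(w^2)
  errs <- vapply(c(2, 5, 10, 15), function(k) tot - sum(lsi_embed(w, k)^2), 0)
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("the 2-D embedding separates planted blobs and is deterministic", {
  withr::with_seed(5, {
    S <- rbind(matrix(rnorm(300), ncol = 3), matrix(rnorm(300, 8), ncol = 3))
  })
  co1 <- embed_2d(S, 10, 0.1, seed = 6, n_epochs = 150)
  co2 <- embed_2d(S, 10, 0.1, seed = 6, n_epochs = 150)
  expect_identical(co1, co2)
  lab <- rep(1:2, each = 100)
  cent <- rbind(colMeans(co1[lab == 1, ]), colMeans(co1[lab == 2, ]))
  spread <- mean(c(
    sqrt(rowSums((co1[lab == 1, ] - rep(cent[1, ], each = 100))^2)),
    sqrt(rowSums((co1[lab == 2, ] - rep(cent[2, ], each = 100))^2))
  ))
  expect_gt(sqrt(sum((cent[1, ] - cent[2, ])^2)), 2 * spread)
})

test_that("duplicated points are embedded at identical coordinates", {
  withr::with_seed(7, S <- matrix(rnorm(200), ncol = 2))
  S2 <- rbind(S, S[1:10, ])
  co <- embed_2d(S2, 8, 0.1, seed = 1, n_epochs = 100)
  expect_equal(co[101:110, ], co[1:10, ], ignore_attr = TRUE)
  expect_error(embed_2d(S[1:5, ], 10, 0.1), "too few distinct samples")
})

test_that("density clustering recovers planted blobs exactly and flags sparse noise", {
  withr::with_seed(8, {
    X <- rbind(matrix(rnorm(1000), ncol = 2), matrix(rnorm(1000, 12), ncol = 2))
  })
  lab <- density_cluster(X, 50)
  expect_equal(length(setdiff(unique(lab), 0L)), 2)
  truth <- rep(1:2, each = 500)
  tab <- table(lab[lab != 0], truth[lab != 0])
  expect_true(all(apply(tab, 1, function(r) min(r) == 0))) # pure clusters
  withr::with_seed(9, Y <- matrix(runif(60), ncol = 2))
  expect_true(all(density_cluster(Y, 50) == 0L))
})

test_that("density clustering labels are invariant to point order", {
  withr::with_seed(10, {
    X <- rbind(
      matrix(rnorm(300), ncol = 2), matrix(rnorm(300, 9), ncol = 2),
      matrix(rnorm(300, c(0, 18)), ncol = 2)
    )
    perm <- sample(nrow(X))
  })
  l1 <- density_cluster(X, 30)
  l2 <- density_cluster(X[perm, ], 30)
  # same partition up to relabeling
  expect_equal(
    unname(table(paste(l1[perm] != 0, l2 != 0))[["TRUE TRUE"]]),
    sum(l1 != 0)
  )
  keep <- l1[perm] != 0 & l2 != 0
  tab <- table(l1[perm][keep], l2[keep])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("model selection follows the noise constraint and lexicographic ties", {
  grid <- tibble::tibble(
    k = c(10, 10, 50, 50), n_neighbors = 10, min_dist = 0.1,
    min_cluster_size = c(25, 50, 25, 50),
    n_clusters = c(3, 3, 3, 2),
    silhouette = c(0.9, 0.7, 0.7, 0.95),
    n_unclustered = c(5, 10, 50, 300),
    n = 500
  )
  # the 0.95 cell breaches the 10% noise constraint; 0.9 wins
  chosen <- select_model(grid, 0.10)
  expect_equal(chosen$silhouette, 0.9)
  # ties break to fewer unclustered samples
  grid2 <- grid
  grid2$silhouette <- c(0.7, 0.7, 0.7, 0.7)
  grid2$n_unclustered <- c(10, 50, 10, 10)
  chosen2 <- select_model(grid2, 0.5)
  expect_equal(chosen2$n_unclustered, 10)
  expect_equal(chosen2$min_cluster_size, 25) # then smaller minPts
  expect_equal(chosen2$k, 10) # then smaller k
  # if no cell meets the constraint, relax to the minimum achieved noise
  grid3 <- grid
  grid3$n_unclustered <- c(400, 300, 300, 450)
  chosen3 <- select_model(grid3, 0.10)
  expect_equal(chosen3$n_unclustered, 300)
  expect_equal(chosen3$silhouette, 0.7) # max silhouette among the relaxed set
})

test_that("model selection equals a brute-force scan on random grids", {
  oracle <- function(g, nf_max) {
    nf <- g$n_unclustered / g$n
    ok <- if (any(nf <= nf_max)) nf <= nf_max else nf <= min(nf)
    g <- g[ok & !is.na(g$silhouette), ]
    best <- g[g$silhouette == max(g$silhouette), ]
    best <- best[best$n_unclustered == min(best$n_unclustered), ]
    best <- best[best$min_cluster_size == min(best$min_cluster_size), ]
    best <- best[best$k == min(best$k), ]
    best <- best[best$n_neighbors == min(best$n_neighbors), ]
    best[best$min_dist == min(best$min_dist), ][1, ]
  }
  withr::with_seed(11, {
    for (i in 1:20) {
      g <- tidyr::expand_grid(
        k = c(10, 50), n_neighbors = c(10, 20), min_dist = c(0.1, 0.5),
        min_cluster_size = c(25, 50)
      )
      g$n <- 400
      g$n_clusters <- sample(1:6, nrow(g), replace = TRUE)
      g$silhouette <- round(runif(nrow(g)), 2)
      g$n_unclustered <- sample(c(0, 10, 60, 200), nrow(g), replace = TRUE)
      expect_equal(select_model(g, 0.1), oracle(g, 0.1))
    }
  })
})

test_that("silhouette is undefined with fewer than two clusters", {
  co <- matrix(rnorm(40), ncol = 2)
  expect_true(is.na(clustering_silhouette(co, rep(1L, 20))))
  expect_true(is.na(clustering_silhouette(co, rep(0L, 20))))
  sil <- clustering_silhouette(co, rep(c(1L, 2L), each = 10))
  expect_true(sil >= -1 && sil <= 1)
})

test_that("the full pipeline recovers a small planted structure deterministically", {
  eco <- small_ecologies(n_samples = 40)[c(1, 3, 5), ]
  eco$group <- eco$name
  cfg <- catalog_config(
    ecologies = eco, n_conserved = 10,
    core_sizes = stats::setNames(rep(150, 3), eco$name), contrasts = list()
  )
  out <- generate_catalog(cfg, seed = 62)
  ecfg <- embedding_config(
    k_grid = 10, n_neighbors_grid = 15, min_dist_grid = 0.1,
    min_cluster_grid = 20, n_epochs = 150
  )
  res <- run_lsi_pipeline(out$presence, ecfg, st = out$samples, seed = 62)
  res2 <- run_lsi_pipeline(out$presence, ecfg, st = out$samples, seed = 62)
  expect_identical(res$samples, res2$samples)
  gl <- glance(res)
  expect_equal(gl$n_clusters, 3)
  truth <- as.integer(factor(res$samples$ecology))
  agree <- table(res$samples$cluster, truth)
  expect_true(all(rowSums(agree[rownames(agree) != "0", , drop = FALSE] > 0) == 1))
  expect_lte(gl$n_unclustered, 12)
  # grid report silhouettes in range, noise counts consistent
  expect_true(all(is.na(res$grid_report$silhouette) |
    abs(res$grid_report$silhouette) <= 1))
  expect_equal(res$grid_report$n_unclustered[1], sum(res$samples$cluster == 0))
})

test_that("subclustering restricted to all samples matches a fresh pipeline run", {
  eco <- small_ecologies(n_samples = 40)[c(1, 5), ]
  eco$group <- eco$name
  cfg <- catalog_config(
    ecologies = eco, n_conserved = 10,
    core_sizes = stats::setNames(rep(150, 2), eco$name), contrasts = list()
  )
  out <- generate_catalog(cfg, seed = 63)
  ecfg <- embedding_config(
    k_grid = 10, n_neighbors_grid = 10, min_dist_grid = 0.1,
    min_cluster_grid = 25, n_epochs = 100
  )
  res <- run_lsi_pipeline(out$presence, ecfg, st = out$samples, seed = 63)
  expect_gte(max(res$samples$cluster), 1)
  sub <- subcluster(out$presence, out$samples, res,
    cluster_ids = 1L,
    cfg = ecfg, seed = 63
  )
  expect_named(sub, "1")
  expect_s3_class(sub[["1"]], "lsi_clustering")
  # metadata overlay present for plotting
  expect_true(all(c("ecology", "disease_status", "westernized", "age_category")
  %in% names(sub[["1"]]$samples)))
  # an oversized minimum cluster size is reported with the cluster id
  expect_error(
    subcluster(out$presence, out$samples, res,
      cluster_ids = 1L,
      cfg = embedding_config(
        k_grid = 10, n_neighbors_grid = 10,
        min_dist_grid = 0.1, min_cluster_grid = 1000
      )
    ),
    "cluster 1"
  )
  expect_error(subcluster(out$presence, out$samples, res, cluster_ids = 99L), "unknown cluster")
})
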