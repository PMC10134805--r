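#' Default ecology layout for the synthetic catalog generator
#'
#' Seventeen ecologies organised into three higher-level groups (gut
#' associated, environmental, other host), with ecology-dependent per-sample
#' gene-count ranges. Nasal-like ecologies carry few genes per sample drawn
#' from a large ecology-specific pool (high turnover); mouse-like gut
#' ecologies carry many genes dominated by the shared group core (low
#' turnover).
#'
#' @param n_samples Samples per ecology (same for every ecology), default 8.
#' @return A tibble with columns `name`, `group`, `n_samples`, `genes_min`,
#'   `genes_max`, `specific_size`.
#' @export
default_ecologies <- function(n_samples = 8) {
  tibble::tribble(
    ~name, ~group, ~genes_min, ~genes_max, ~specific_size,
    "human_gut", "gut_associated", 500L, 900L, 450L,
    "human_oral", "gut_associated", 400L, 700L, 450L,
    "mouse_gut", "gut_associated", 900L, 1100L, 250L,
    "cow_gut", "gut_associated", 600L, 900L, 450L,
    "pig_gut", "gut_associated", 500L, 800L, 450L,
    "chicken_gut", "gut_associated", 400L, 700L, 450L,
    "moose_gut", "gut_associated", 500L, 800L, 450L,
    "aquatic", "environmental", 400L, 800L, 450L,
    "aquatic_sediment", "environmental", 400L, 800L, 450L,
    "terrestrial_soil", "environmental", 500L, 900L, 450L,
    "plant", "environmental", 300L, 600L, 450L,
    "coral", "environmental", 300L, 600L, 450L,
    "human_nasal", "other_host", 120L, 220L, 700L,
    "human_skin", "other_host", 250L, 450L, 450L,
    "human_vaginal", "other_host", 150L, 300L, 450L,
    "human_airways", "other_host", 200L, 350L, 450L,
    "insect_host", "other_host", 300L, 500L, 450L
  ) |>
    dplyr::mutate(n_samples = as.integer(n_samples), .after = "group")
}

#' Configuration for the synthetic multi-ecology catalog generator
#'
#' The generator plants four kinds of structured genes -- a pan-ecologically
#' conserved set, per-group core pools, per-ecology specific pools and
#' contrast sets exclusive to a target ecology subset with an abundance shift
#' -- and then appends fresh one-sample singleton genes until the realized
#' global singleton fraction reaches `singleton_target` (about two thirds of
#' catalog genes in real data).
#'
#' @param ecologies Ecology layout tibble, see [default_ecologies()].
#' @param n_conserved Number of planted pan-ecological conserved genes.
#' @param core_sizes Named integer vector, group core pool size per group.
#' @param singleton_target Target global fraction of singleton genes, in
#'   `[0, 1)`.
#' @param dropout Per (sample, conserved gene) probability that the gene fails
#'   to assemble in a sample where it would otherwise occur.
#' @param core_frac Fraction of each sample's structured gene budget drawn
#'   from its group core pool (the remainder comes from the ecology-specific
#'   pool).
#' @param contrasts List of planted differential contrasts; each element is a
#'   list with `name`, `target_ecologies` (character), `n_genes`, `shift`
#'   (multiplicative abundance shift in target ecologies) and `inclusion`
#'   (per-target-sample presence probability).
#' @param abundance_meanlog,abundance_sdlog Lognormal parameters of the
#'   per-entry abundance model.
#' @param species_pool,species_range Global species pool size and per-sample
#'   species count range for the species count matrix used by Chao1 and
#'   Bray-Curtis.
#' @param heldout_per_ecology Held-out samples per ecology for validation
#'   (emulating an independent sample set).
#' @return An object of class `catalog_config`.
#' @export
catalog_config <- function(ecologies = default_ecologies(),
                           n_conserved = 60,
                           core_sizes = c(
                             gut_associated = 900, environmental = 900,
                             other_host = 700
                           ),
                           singleton_target = 0.66,
                           dropout = 0.05,
                           core_frac = 0.55,
                           contrasts = default_contrasts(),
                           abundance_meanlog = 1,
                           abundance_sdlog = 1,
                           species_pool = 90,
                           species_range = c(18, 30),
                           heldout_per_ecology = 4) {
  stopifnot(
    is.data.frame(ecologies), nrow(ecologies) >= 1,
    n_conserved >= 0,
    singleton_target >= 0, singleton_target < 1,
    dropout >= 0, dropout < 1,
    core_frac > 0, core_frac < 1,
    heldout_per_ecology >= 0
  )
  if (any(ecologies$n_samples < 2)) {
    abort("every ecology needs at least 2 samples")
  }
  if (any(ecologies$genes_min > ecologies$genes_max) || any(ecologies$genes_min < 1)) {
    abort("invalid genes_per_sample range")
  }
  groups <- unique(ecologies$group)
  if (!all(groups %in% names(core_sizes))) {
    abort("core_sizes must name every ecology group")
  }
  for (ct in contrasts) {
    if (!all(ct$target_ecologies %in% ecologies$name)) {
      abort(paste0("contrast '", ct$name, "' targets unknown ecologies"))
    }
    if (length(ct$target_ecologies) == nrow(ecologies)) {
      abort("contrast target must be a proper subset of the ecologies")
    }
  }
  structure(
    list(
      ecologies = ecologies, n_conserved = as.integer(n_conserved),
      core_sizes = core_sizes, singleton_target = singleton_target,
      dropout = dropout, core_frac = core_frac, contrasts = contrasts,
      abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
      species_pool = as.integer(species_pool),
      species_range = as.integer(species_range),
      heldout_per_ecology = as.integer(heldout_per_ecology)
    ),
    class = "catalog_config"
  )
}

#' Default planted contrasts
#'
#' Three contrasts mirroring ecology subsets of interest in comparative
#' gene-catalog work: genes shared by all gut microbiomes, genes shared by
#' gut and environmental samples, and genes specific to environmental
#' (terrestrial/aquatic) samples.
#'
#' @param shift Multiplicative abundance shift planted in target ecologies.
#' @export
default_contrasts <- function(shift = 8) {
  list(
    list(
      name = "gut_shared",
      target_ecologies = c(
        "human_gut", "mouse_gut", "cow_gut", "pig_gut",
        "chicken_gut", "moose_gut"
      ),
      n_genes = 15L, shift = shift, inclusion = 0.7
    ),
    list(
      name = "gut_environment",
      target_ecologies = c("human_gut", "aquatic_sediment", "terrestrial_soil"),
      n_genes = 15L, shift = shift, inclusion = 0.7
    ),
    list(
      name = "environment_only",
      target_ecologies = c("aquatic", "aquatic_sediment", "terrestrial_soil"),
      n_genes = 15L, shift = shift, inclusion = 0.7
    )
  )
}

# deterministic child-seed rule: one master seed, fixed affine step per stage
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k) %% 2147483647)
}

# largest-remainder integer allocation of `total` over `weights`
alloc_integer <- function(total, weights) {
  n <- length(weights)
  if (total <= 0 || n == 0) {
    return(integer(n))
  }
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  rem <- as.integer(total - sum(base))
  out <- as.integer(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    out[idx] <- out[idx] + 1L
  }
  out
}

# structured gene pools derived from a config (ids are deterministic)
build_pools <- function(cfg) {
  groups <- unique(cfg$ecologies$group)
  conserved <- if (cfg$n_conserved > 0) sprintf("CONS%05d", seq_len(cfg$n_conserved)) else character()
  core <- lapply(groups, function(g) {
    sprintf("CORE_%s_%05d", g, seq_len(cfg$core_sizes[[g]]))
  })
  names(core) <- groups
  specific <- lapply(seq_len(nrow(cfg$ecologies)), function(i) {
    sprintf("SPEC_%s_%05d", cfg$ecologies$name[i], seq_len(cfg$ecologies$specific_size[i]))
  })
  names(specific) <- cfg$ecologies$name
  contrast <- lapply(cfg$contrasts, function(ct) {
    sprintf("CTRST_%s_%04d", ct$name, seq_len(ct$n_genes))
  })
  names(contrast) <- vapply(cfg$contrasts, `[[`, "", "name")
  list(conserved = conserved, core = core, specific = specific, contrast = contrast)
}

# draw the structured gene content of one sample (rng must be active);
# with contrast_everywhere the contrast pools are drawn in every ecology --
# used for held-out samples, whose abundances emulate read-mapping
# quantification rather than assembly presence
draw_structured <- function(eco, group, t_s, cfg, pools,
                            contrast_everywhere = FALSE) {
  cons <- pools$conserved[stats::runif(length(pools$conserved)) >= cfg$dropout]
  ctr <- character()
  for (nm in names(pools$contrast)) {
    ct <- cfg$contrasts[[which(vapply(cfg$contrasts, `[[`, "", "name") == nm)]]
    if (contrast_everywhere || eco %in% ct$target_ecologies) {
      keep <- stats::runif(length(pools$contrast[[nm]])) < ct$inclusion
      ctr <- c(ctr, pools$contrast[[nm]][keep])
    }
  }
  budget <- max(0L, t_s - length(cons) - length(ctr))
  core_pool <- pools$core[[group]]
  spec_pool <- pools$specific[[eco]]
  n_core <- min(round(cfg$core_frac * budget), length(core_pool))
  n_spec <- min(budget - n_core, length(spec_pool))
  c(
    cons, ctr,
    sample(core_pool, n_core),
    sample(spec_pool, n_spec)
  )
}

#' Generate a synthetic multi-ecology gene catalog with planted ground truth
#'
#' Every sample's gene list is built as (conserved genes minus dropout) plus a
#' group-core draw plus an ecology-specific draw plus planted contrast genes,
#' and fresh one-sample singleton genes are appended (or accidental
#' single-sample structured genes trimmed) so the realized global singleton
#' fraction lands on the configured target. After dropout, each conserved
#' gene (and each contrast gene, within its target ecologies) is rescued into
#' one sample of any ecology it would otherwise have vanished from, so the
#' planted ground-truth invariants hold on the emitted matrix.
#'
#' @param cfg A [catalog_config()].
#' @param seed Integer master seed; identical seeds give bit-identical output.
#' @return A list with `samples` (metadata tibble), `presence` (binary
#'   `dgCMatrix`), `annotations` (gene annotation tibble) and `truth`
#'   (a `ground_truth` object).
#' @export
generate_catalog <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "catalog_config"))
  pools <- build_pools(cfg)
  eco <- cfg$ecologies
  withr::with_seed(child_seed(seed, 1L), {
    sample_ids <- unlist(lapply(seq_len(nrow(eco)), function(i) {
      sprintf("S_%s_%03d", eco$name[i], seq_len(eco$n_samples[i]))
    }))
    sample_eco <- rep(eco$name, eco$n_samples)
    sample_group <- rep(eco$group, eco$n_samples)
    t_s <- unlist(lapply(seq_len(nrow(eco)), function(i) {
      sample(seq(eco$genes_min[i], eco$genes_max[i]), eco$n_samples[i], replace = TRUE)
    }))
    members <- vector("list", length(sample_ids))
    for (s in seq_along(sample_ids)) {
      members[[s]] <- draw_structured(sample_eco[s], sample_group[s], t_s[s], cfg, pools)
    }
    # rescue: conserved genes must survive in >=1 sample of every ecology;
    # contrast genes in >=1 sample of each of their target ecologies
    for (e in eco$name) {
      idx <- which(sample_eco == e)
      present <- unique(unlist(members[idx]))
      need <- setdiff(pools$conserved, present)
      for (nm in names(pools$contrast)) {
        ct <- cfg$contrasts[[which(vapply(cfg$contrasts, `[[`, "", "name") == nm)]]
        if (e %in% ct$target_ecologies) {
          need <- c(need, setdiff(pools$contrast[[nm]], present))
        }
      }
      if (length(need)) {
        host <- sample(idx, length(need), replace = TRUE)
        for (j in seq_along(need)) {
          members[[host[j]]] <- c(members[[host[j]]], need[j])
        }
      }
    }
    # singleton budget: count structured columns by occupancy
    all_genes <- unlist(members)
    occ <- table(all_genes)
    s_r <- sum(occ == 1)
    n_ns <- sum(occ > 1)
    t <- cfg$singleton_target
    s_needed <- round(t / (1 - t) * n_ns)
    s_f <- s_needed - s_r
    n_singleton_total <- s_needed
    if (s_f >= 0) {
      per_sample <- alloc_integer(s_f, t_s)
      next_id <- 1L
      for (s in seq_along(members)) {
        if (per_sample[s] > 0) {
          ids <- sprintf("SING%07d", seq(next_id, next_id + per_sample[s] - 1L))
          next_id <- next_id + per_sample[s]
          members[[s]] <- c(members[[s]], ids)
        }
      }
    } else {
      # too many accidental singletons for the target: trim core/specific ones
      protected <- c(pools$conserved, unlist(pools$contrast))
      trimmable <- setdiff(names(occ)[occ == 1], protected)
      excess <- -s_f
      if (length(trimmable) < excess) {
        abort("singleton_target unreachable: too many structured singleton genes to trim")
      }
      drop <- if (length(trimmable) > excess) sample(trimmable, excess) else trimmable
      drop_set <- drop
      members <- lapply(members, function(g) setdiff(g, drop_set))
    }
    pairs <- tibble(
      sample_id = rep(sample_ids, lengths(members)),
      gene_id = unlist(members)
    )
    pm <- as_presence_matrix(pairs)$presence
    st <- tibble(
      sample_id = sample_ids,
      ecology = sample_eco,
      ecology_group = sample_group,
      disease_status = ifelse(
        grepl("^human", sample_eco),
        sample(c("healthy", "disease"), length(sample_ids), replace = TRUE, prob = c(0.7, 0.3)),
        NA_character_
      ),
      westernized = ifelse(
        sample_eco %in% c("human_gut", "human_oral"),
        stats::runif(length(sample_ids)) < 0.6, NA
      ),
      age_category = ifelse(
        grepl("^human", sample_eco),
        sample(c("adult", "child", "newborn"), length(sample_ids),
          replace = TRUE, prob = c(0.7, 0.2, 0.1)
        ),
        NA_character_
      )
    )
    st <- st[match(rownames(pm), st$sample_id), , drop = FALSE]
    st$n_genes <- as.integer(rowSums(pm))
    gene_ids <- colnames(pm)
    ann <- annotate_genes(gene_ids, cfg, pools)
    realized <- function(ids) intersect(ids, gene_ids)
    cs <- colSums(pm)
    singles <- gene_ids[cs == 1]
    frac <- length(singles) / length(gene_ids)
    truth <- structure(
      list(
        conserved_gene_ids = realized(pools$conserved),
        core_gene_ids = lapply(pools$core, realized),
        specific_gene_ids = lapply(pools$specific, realized),
        contrasts = lapply(cfg$contrasts, function(ct) {
          list(
            name = ct$name, target_ecologies = ct$target_ecologies,
            gene_ids = realized(pools$contrast[[ct$name]]), shift = ct$shift
          )
        }),
        singleton_gene_ids = singles,
        singleton_fraction_realized = frac,
        group_labels = stats::setNames(st$ecology_group, st$sample_id),
        singleton_rate = length(singles) / nrow(pm),
        dropout = cfg$dropout
      ),
      class = "ground_truth"
    )
    list(samples = st, presence = pm, annotations = ann, truth = truth)
  })
}

# annotation signatures per planted pool (rng must be active)
annotate_genes <- function(gene_ids, cfg, pools) {
  n <- length(gene_ids)
  product <- rep(NA_character_, n)
  cog <- rep(NA_character_, n)
  taxon <- rep(NA_character_, n)
  group_taxa <- list(
    gut_associated = c("Bacteroides", "Faecalibacterium", "Ruminococcus", "Prevotella", "Lachnospira"),
    environmental = c("Pseudomonas", "Synechococcus", "Nitrospira", "Sphingomonas"),
    other_host = c("Staphylococcus", "Streptococcus", "Corynebacterium", "Lactobacillus")
  )
  idx <- match(pools$conserved, gene_ids)
  ok <- !is.na(idx)
  product[idx[ok]] <- sprintf("conserved marker protein %d", (which(ok) - 1L) %% 12L + 1L)
  cog[idx[ok]] <- "J"
  taxon[idx[ok]] <- "Bacteria_generic"
  group_cogs <- c(gut_associated = "G", environmental = "C", other_host = "M")
  for (g in names(pools$core)) {
    idx <- match(pools$core[[g]], gene_ids)
    ok <- !is.na(idx)
    product[idx[ok]] <- sprintf("%s core protein %d", g, (which(ok) - 1L) %% 25L + 1L)
    cog[idx[ok]] <- if (g %in% names(group_cogs)) group_cogs[[g]] else "S"
    pool_tx <- group_taxa[[g]] %||% "Bacteria_generic"
    taxon[idx[ok]] <- sample(pool_tx, sum(ok), replace = TRUE)
  }
  eco_groups <- stats::setNames(cfg$ecologies$group, cfg$ecologies$name)
  for (e in names(pools$specific)) {
    idx <- match(pools$specific[[e]], gene_ids)
    ok <- !is.na(idx)
    product[idx[ok]] <- sprintf("%s specific protein %d", e, (which(ok) - 1L) %% 15L + 1L)
    cog[idx[ok]] <- sample(c("K", "L", "E", "P", "T"), sum(ok), replace = TRUE)
    taxon[idx[ok]] <- sprintf("%s_specialist", e)
  }
  for (nm in names(pools$contrast)) {
    idx <- match(pools$contrast[[nm]], gene_ids)
    ok <- !is.na(idx)
    product[idx[ok]] <- sprintf("%s associated protein %d", nm, (which(ok) - 1L) %% 8L + 1L)
    cog[idx[ok]] <- "P"
    taxon[idx[ok]] <- "Vibrio"
  }
  rest <- is.na(product)
  if (any(rest)) {
    novel <- stats::runif(sum(rest)) < 0.61 # most singleton genes are novel
    product[rest][!novel] <- "hypothetical protein"
  }
  tibble(
    gene_id = gene_ids, protein_product = product,
    cog_category = cog, taxon_label = taxon
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate abundances on the support of a presence matrix
#'
#' Draws per-entry abundances from a lognormal model; planted contrast genes
#' receive their configured multiplicative shift in their target ecologies.
#' Abundance is strictly positive exactly where presence is 1. In `"counts"`
#' mode values are rounded up to positive integers (species-count style, as
#' Chao1 requires).
#'
#' @param pm Presence matrix from [generate_catalog()] or
#'   [generate_heldout()].
#' @param st Matching sample table.
#' @param cfg The generator configuration.
#' @param truth The recorded ground truth (for planted shifts).
#' @param seed Integer seed.
#' @param mode `"continuous"` or `"counts"`.
#' @return A sparse `dgCMatrix` with the same dimnames as `pm`.
#' @export
generate_abundance <- function(pm, st, cfg, truth, seed = 1L,
                               mode = c("continuous", "counts")) {
  mode <- match.arg(mode)
  withr::with_seed(child_seed(seed, 2L), {
    am <- methods::as(pm, "CsparseMatrix")
    am@x <- stats::rlnorm(length(am@x), cfg$abundance_meanlog, cfg$abundance_sdlog)
    eco_of <- stats::setNames(st$ecology, st$sample_id)
    for (ct in truth$contrasts) {
      gs <- intersect(ct$gene_ids, colnames(am))
      if (!length(gs)) next
      tgt_rows <- which(eco_of[rownames(am)] %in% ct$target_ecologies)
      if (!length(tgt_rows)) next
      sub <- am[, gs, drop = FALSE]
      # scale entries of target samples in contrast columns
      ji <- rep(seq_along(gs), diff(sub@p))
      ii <- sub@i + 1L
      hit <- ii %in% tgt_rows
      if (any(hit)) {
        sub@x[hit] <- sub@x[hit] * ct$shift
        am[, gs] <- sub
      }
    }
    if (mode == "counts") am@x <- ceiling(am@x)
    am
  })
}

#' Generate a per-sample species count matrix
#'
#' Species-level integer counts for alpha (Chao1) and beta (Bray-Curtis)
#' diversity. Each ecology draws per-sample species subsets from the shared
#' global species pool; counts follow a rounded-up lognormal so that count-1
#' and count-2 species (the Chao1 signal) occur naturally.
#'
#' @inheritParams generate_abundance
#' @return A sparse integer `dgCMatrix`, samples by species.
#' @export
generate_species_counts <- function(st, cfg, seed = 1L) {
  withr::with_seed(child_seed(seed, 3L), {
    species <- sprintf("SP%04d", seq_len(cfg$species_pool))
    lo <- cfg$species_range[1]
    hi <- cfg$species_range[2]
    rows <- integer()
    cols <- integer()
    vals <- numeric()
    for (s in seq_len(nrow(st))) {
      n_sp <- sample(seq(lo, hi), 1)
      n_sp <- min(n_sp, length(species))
      sp <- sample.int(length(species), n_sp)
      rows <- c(rows, rep(s, n_sp))
      cols <- c(cols, sp)
      vals <- c(vals, ceiling(stats::rlnorm(n_sp, 1.2, 1)))
    }
    sparseMatrix(
      i = rows, j = cols, x = vals,
      dims = c(nrow(st), length(species)),
      dimnames = list(st$sample_id, species)
    )
  })
}

#' Generate an independent held-out sample set
#'
#' Draws `heldout_per_ecology` fresh samples per ecology from the same
#' generative process (no rescue step, so conserved-gene prevalence reflects
#' the raw dropout rate) with sample ids disjoint from the training catalog,
#' plus abundances on their support. Unlike the training catalog, held-out
#' samples emulate read-mapping abundance quantification: planted contrast
#' genes occur (at background abundance) in every ecology, and only their
#' target ecologies receive the multiplicative shift.
#'
#' @inheritParams generate_abundance
#' @return A list with `samples`, `presence`, `abundance`.
#' @export
generate_heldout <- function(cfg, truth, seed = 1L) {
  stopifnot(inherits(cfg, "catalog_config"), inherits(truth, "ground_truth"))
  eco <- cfg$ecologies
  h <- cfg$heldout_per_ecology
  if (h == 0) {
    empty <- sparseMatrix(
      i = integer(), j = integer(), x = numeric(), dims = c(0, 0),
      dimnames = list(character(), character())
    )
    return(list(
      samples = tibble(
        sample_id = character(), ecology = character(),
        ecology_group = character(), n_genes = integer()
      ),
      presence = empty, abundance = empty
    ))
  }
  pools <- build_pools(cfg)
  withr::with_seed(child_seed(seed, 4L), {
    sample_ids <- unlist(lapply(seq_len(nrow(eco)), function(i) {
      sprintf("H_%s_%03d", eco$name[i], seq_len(h))
    }))
    sample_eco <- rep(eco$name, each = h)
    sample_group <- rep(eco$group, each = h)
    t_s <- unlist(lapply(seq_len(nrow(eco)), function(i) {
      sample(seq(eco$genes_min[i], eco$genes_max[i]), h, replace = TRUE)
    }))
    members <- vector("list", length(sample_ids))
    next_sing <- 1L
    for (s in seq_along(sample_ids)) {
      g <- draw_structured(sample_eco[s], sample_group[s], t_s[s], cfg, pools,
        contrast_everywhere = TRUE
      )
      n_sing <- round(truth$singleton_rate)
      if (n_sing > 0) {
        ids <- sprintf("HSING%07d", seq(next_sing, next_sing + n_sing - 1L))
        next_sing <- next_sing + n_sing
        g <- c(g, ids)
      }
      members[[s]] <- g
    }
    pairs <- tibble(
      sample_id = rep(sample_ids, lengths(members)),
      gene_id = unlist(members)
    )
    pm <- as_presence_matrix(pairs)$presence
    st <- tibble(
      sample_id = sample_ids, ecology = sample_eco,
      ecology_group = sample_group
    )
    st <- st[match(rownames(pm), st$sample_id), , drop = FALSE]
    st$n_genes <- as.integer(rowSums(pm))
    am <- generate_abundance(pm, st, cfg, truth, seed = child_seed(seed, 5L))
    list(samples = st, presence = pm, abundance = am)
  })
}

#' Verify ground-truth invariants on an emitted catalog
#'
#' Checks that the planted gene sets are pairwise disjoint, that every
#' conserved gene occurs in at least one sample of every ecology, that
#' contrast genes never occur outside their target ecologies, and that the
#' recorded singleton fraction matches the matrix.
#'
#' @param truth A `ground_truth` object.
#' @param pm The presence matrix it was emitted with.
#' @param st The matching sample table.
#' @return `TRUE` invisibly; errors on any violation.
#' @export
check_ground_truth <- function(truth, pm, st) {
  sets <- c(
    list(conserved = truth$conserved_gene_ids),
    truth$core_gene_ids, truth$specific_gene_ids,
    lapply(truth$contrasts, `[[`, "gene_ids")
  )
  all_ids <- unlist(sets)
  if (anyDuplicated(all_ids)) abort("planted gene sets are not pairwise disjoint")
  eco_of <- stats::setNames(st$ecology, st$sample_id)
  for (e in unique(st$ecology)) {
    rows <- which(eco_of[rownames(pm)] == e)
    present <- colSums(pm[rows, truth$conserved_gene_ids, drop = FALSE]) > 0
    if (!all(present)) {
      abort(paste0("conserved gene absent from ecology ", e))
    }
  }
  for (ct in truth$contrasts) {
    out_rows <- which(!(eco_of[rownames(pm)] %in% ct$target_ecologies))
    gs <- intersect(ct$gene_ids, colnames(pm))
    if (length(gs) && length(out_rows)) {
      leak <- colSums(pm[out_rows, gs, drop = FALSE]) > 0
      if (any(leak)) abort(paste0("contrast gene leaked outside targets in ", ct$name))
    }
  }
  frac <- singleton_counts(pm)$fraction
  if (abs(frac - truth$singleton_fraction_realized) > 1e-12) {
    abort("recorded singleton fraction does not match the matrix")
  }
  invisible(TRUE)
}

#' Serialize / read ground truth as plain text
#'
#' A simple sectioned key-value and set-listing format: scalar fields first,
#' then one `[section]` per planted gene set, one id per line.
#'
#' @param truth A `ground_truth` object.
#' @param path File path.
#' @export
write_ground_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# ecocatalog ground truth v1")
  wl("singleton_fraction_realized\t", format(truth$singleton_fraction_realized, digits = 17))
  wl("singleton_rate\t", format(truth$singleton_rate, digits = 17))
  wl("dropout\t", format(truth$dropout, digits = 17))
  wl("[conserved]")
  writeLines(truth$conserved_gene_ids, con)
  for (g in names(truth$core_gene_ids)) {
    wl("[core ", g, "]")
    writeLines(truth$core_gene_ids[[g]], con)
  }
  for (e in names(truth$specific_gene_ids)) {
    wl("[specific ", e, "]")
    writeLines(truth$specific_gene_ids[[e]], con)
  }
  for (ct in truth$contrasts) {
    wl(
      "[contrast ", ct$name, "\t", format(ct$shift, digits = 17), "\t",
      paste(ct$target_ecologies, collapse = ","), "]"
    )
    writeLines(ct$gene_ids, con)
  }
  wl("[singletons]")
  writeLines(truth$singleton_gene_ids, con)
  wl("[group_labels]")
  writeLines(paste0(names(truth$group_labels), "\t", truth$group_labels), con)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  is_hdr <- startsWith(lines, "[")
  scalars <- lines[!is_hdr & !grepl("^\\[", lines) & cumsum(is_hdr) == 0]
  kv <- strsplit(scalars, "\t", fixed = TRUE)
  vals <- stats::setNames(
    vapply(kv, function(x) as.numeric(x[2]), 0),
    vapply(kv, `[[`, "", 1)
  )
  hdr_idx <- which(is_hdr)
  bounds <- c(hdr_idx, length(lines) + 1L)
  sections <- list()
  for (i in seq_along(hdr_idx)) {
    hdr <- sub("^\\[(.*)\\]$", "\\1", lines[hdr_idx[i]])
    body <- lines[seq(hdr_idx[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[nzchar(body)]
    sections[[hdr]] <- body
  }
  core <- sections[grepl("^core ", names(sections))]
  names(core) <- sub("^core ", "", names(core))
  spec <- sections[grepl("^specific ", names(sections))]
  names(spec) <- sub("^specific ", "", names(spec))
  ctr_names <- names(sections)[grepl("^contrast ", names(sections))]
  contrasts <- lapply(ctr_names, function(h) {
    parts <- strsplit(sub("^contrast ", "", h), "\t", fixed = TRUE)[[1]]
    list(
      name = parts[1], shift = as.numeric(parts[2]),
      target_ecologies = strsplit(parts[3], ",", fixed = TRUE)[[1]],
      gene_ids = sections[[h]]
    )
  })
  gl <- strsplit(sections[["group_labels"]], "\t", fixed = TRUE)
  structure(
    list(
      conserved_gene_ids = sections[["conserved"]] %||% character(),
      core_gene_ids = core,
      specific_gene_ids = spec,
      contrasts = contrasts,
      singleton_gene_ids = sections[["singletons"]] %||% character(),
      singleton_fraction_realized = unname(vals["singleton_fraction_realized"]),
      group_labels = stats::setNames(
        vapply(gl, `[[`, "", 2),
        vapply(gl, `[[`, "", 1)
      ),
      singleton_rate = unname(vals["singleton_rate"]),
      dropout = unname(vals["dropout"])
    ),
    class = "ground_truth"
  )
}
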