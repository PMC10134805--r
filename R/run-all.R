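#' Default run configuration
#'
#' All parameters of the end-to-end pipeline in one plain list, pre-filled
#' with the canonical analysis settings (4 samples per ecology over 50
#' subsampling iterations; SVD components 10/50/100; UMAP neighbours
#' 10/15/20/30 and minimum distances 0.1/0.25/0.5; minimum cluster sizes
#' 25/50/75/100; enrichment alpha 0.05 with the Fisher switch below 6
#' observations). Serialize with [yaml::write_yaml()] and read back with
#' [read_run_config()].
#'
#' @param outdir Output directory for artifacts.
#' @param seed Master seed; every stage derives its own child seed from it.
#' @return A `run_config` list.
#' @export
default_run_config <- function(outdir = "ecocatalog_run", seed = 1L) {
  structure(
    list(
      outdir = outdir,
      seed = as.integer(seed),
      generator = list(
        n_samples = 8L, n_conserved = 60L, singleton_target = 0.66,
        dropout = 0.05, heldout_per_ecology = 4L
      ),
      similarity = list(m = 4L, iterations = 50L, n_perm = 20L),
      embedding = list(
        k_grid = c(10L, 50L, 100L),
        n_neighbors_grid = c(10L, 15L, 20L, 30L),
        min_dist_grid = c(0.1, 0.25, 0.5),
        min_cluster_grid = c(25L, 50L, 75L, 100L),
        noise_fraction_max = 0.10,
        n_epochs = 200L
      ),
      enrichment = list(alpha = 0.05, fisher_cell_threshold = 6L)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Fields missing from the file fall back to [default_run_config()] values;
#' unknown fields raise an error naming the field.
#'
#' @param path YAML file path.
#' @param outdir,seed Optional overrides.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path, outdir = NULL, seed = NULL) {
  if (!file.exists(path)) abort(paste0("no such config file: ", path))
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_run_config())
  for (nm in names(user)) {
    if (!nm %in% names(cfg)) abort(paste0("unknown config field: ", nm))
    if (is.list(cfg[[nm]])) {
      for (sub in names(user[[nm]])) {
        if (!sub %in% names(cfg[[nm]])) {
          abort(paste0("unknown config field: ", nm, ".", sub))
        }
        cfg[[nm]][[sub]] <- user[[nm]][[sub]]
      }
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  structure(cfg, class = "run_config")
}

run_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the end-to-end pipeline
#'
#' Chains the pipeline stages -- `generate`, `similarity`, `diversity`,
#' `embed`, `enrich`, `genesets` -- on a synthetic catalog, writing TSV /
#' Matrix Market / Newick artifacts to `config$outdir` plus a
#' `manifest.json` recording the configuration, seed, package version,
#' per-stage wall time and every file written. Rerunning with the same
#' configuration and seed reproduces the TSV artifacts byte for byte.
#'
#' @param config A `run_config` list (see [default_run_config()] /
#'   [read_run_config()]).
#' @param stages Stage names to run, or `"all"`.
#' @param verbose Emit progress messages.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), stages = "all",
                         verbose = FALSE) {
  all_stages <- c("generate", "similarity", "diversity", "embed", "enrich", "genesets")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- list(
    config = unclass(config), seed = seed,
    package_version = as.character(utils::packageVersion("ecocatalog")),
    stages = list()
  )
  outputs <- character()
  state <- new.env(parent = emptyenv())

  load_catalog <- function() {
    if (!is.null(state$cat)) {
      return(state$cat)
    }
    pm <- read_catalog_matrix(file.path(outdir, "catalog"), "presence")
    st <- read_sample_table(file.path(outdir, "samples.tsv"))
    ann <- read_gene_annotations(file.path(outdir, "annotations.tsv"))
    truth <- read_ground_truth(file.path(outdir, "truth.txt"))
    state$cat <- list(presence = pm, samples = st, annotations = ann, truth = truth)
    state$cat
  }

  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    files <- character()
    run_log(verbose, stage, "starting (seed ", seed, ")")
    if (stage == "generate") {
      g <- config$generator
      cfg <- catalog_config(
        ecologies = default_ecologies(n_samples = g$n_samples),
        n_conserved = g$n_conserved, singleton_target = g$singleton_target,
        dropout = g$dropout, heldout_per_ecology = g$heldout_per_ecology
      )
      cat <- generate_catalog(cfg, seed = seed)
      held <- generate_heldout(cfg, cat$truth, seed = seed)
      species <- generate_species_counts(cat$samples, cfg, seed = seed)
      state$cat <- c(cat, list(cfg = cfg, held = held, species = species))
      files <- c(
        write_catalog_matrix(cat$presence, file.path(outdir, "catalog"), "presence"),
        write_catalog_matrix(held$presence, file.path(outdir, "heldout"), "presence"),
        write_catalog_matrix(held$abundance, file.path(outdir, "heldout"), "abundance"),
        write_catalog_matrix(species, file.path(outdir, "catalog"), "species_counts")
      )
      p <- file.path(outdir, "samples.tsv")
      readr::write_tsv(cat$samples, p)
      files <- c(files, p)
      p <- file.path(outdir, "heldout_samples.tsv")
      readr::write_tsv(held$samples, p)
      files <- c(files, p)
      p <- file.path(outdir, "annotations.tsv")
      readr::write_tsv(cat$annotations, p)
      files <- c(files, p)
      p <- file.path(outdir, "truth.txt")
      write_ground_truth(cat$truth, p)
      files <- c(files, p)
      run_log(
        verbose, stage, nrow(cat$presence), " samples, ",
        ncol(cat$presence), " genes"
      )
    } else if (stage == "similarity") {
      cat <- load_catalog()
      s <- config$similarity
      res <- subsample_jaccard(cat$presence, cat$samples,
        m = s$m,
        iterations = s$iterations, seed = seed
      )
      files <- c(files, write_distance_matrix(res, file.path(outdir, "ecology_distances.tsv")))
      p <- file.path(outdir, "unique_gene_counts.tsv")
      readr::write_tsv(res$unique_counts, p)
      files <- c(files, p)
      ord <- order_distance_matrix(res)
      p <- file.path(outdir, "ecology_dendrogram.nwk")
      writeLines(ord$newick, p)
      files <- c(files, p)
      if (s$n_perm > 0) {
        pn <- permutation_null(cat$presence, cat$samples,
          m = s$m,
          iterations = s$iterations, n_perm = s$n_perm, seed = seed
        )
        p <- file.path(outdir, "permutation_gaps.tsv")
        readr::write_tsv(
          dplyr::bind_rows(
            tibble(perm = 0L, gap = pn$observed),
            pn$perm
          ), p
        )
        files <- c(files, p)
      }
    } else if (stage == "diversity") {
      cat <- load_catalog()
      s <- config$similarity
      species <- state$cat$species
      if (is.null(species)) {
        species <- read_catalog_matrix(file.path(outdir, "catalog"), "species_counts")
      }
      div <- within_ecology_diversity(cat$presence, cat$samples,
        m = s$m, iterations = s$iterations, seed = seed,
        species_counts = species
      )
      p <- file.path(outdir, "diversity.tsv")
      readr::write_tsv(div, p)
      files <- c(files, p)
    } else if (stage == "embed") {
      cat <- load_catalog()
      e <- config$embedding
      ecfg <- embedding_config(
        k_grid = e$k_grid, n_neighbors_grid = e$n_neighbors_grid,
        min_dist_grid = e$min_dist_grid, min_cluster_grid = e$min_cluster_grid,
        noise_fraction_max = e$noise_fraction_max, n_epochs = e$n_epochs
      )
      res <- run_lsi_pipeline(cat$presence, ecfg, st = cat$samples, seed = seed)
      state$clustering <- res
      p <- file.path(outdir, "clusters.tsv")
      readr::write_tsv(res$samples, p)
      files <- c(files, p)
      p <- file.path(outdir, "grid_report.tsv")
      readr::write_tsv(res$grid_report, p)
      files <- c(files, p)
      run_log(
        verbose, stage, max(res$samples$cluster), " clusters, silhouette ",
        round(res$silhouette, 3)
      )
    } else if (stage == "enrich") {
      cat <- load_catalog()
      cl <- state$clustering
      if (is.null(cl)) {
        cl <- readr::read_tsv(file.path(outdir, "clusters.tsv"),
          show_col_types = FALSE, progress = FALSE
        )
      }
      en <- config$enrichment
      membership <- cluster_gene_membership(cat$presence, cl)
      for (feat in c("protein_product", "cog_category")) {
        fe <- functional_enrichment(membership, cat$annotations,
          feature = feat,
          alpha = en$alpha, fisher_cell_threshold = en$fisher_cell_threshold
        )
        p <- file.path(outdir, paste0("enrichment_", feat, ".tsv"))
        readr::write_tsv(fe, p)
        files <- c(files, p)
      }
      counts <- per_sample_taxon_counts(cat$presence, cat$annotations)
      te <- taxonomic_enrichment(counts, cl, alpha = en$alpha)
      p <- file.path(outdir, "enrichment_taxa.tsv")
      readr::write_tsv(te, p)
      files <- c(files, p)
    } else if (stage == "genesets") {
      cat <- load_catalog()
      held <- state$cat$held
      if (is.null(held)) {
        held <- list(
          presence = read_catalog_matrix(file.path(outdir, "heldout"), "presence"),
          abundance = read_catalog_matrix(file.path(outdir, "heldout"), "abundance"),
          samples = read_sample_table(file.path(outdir, "heldout_samples.tsv"))
        )
      }
      cons <- conserved_genes(cat$presence, cat$samples)
      prof <- prevalence_profile(cons, held$presence, held$abundance, held$samples)
      p <- file.path(outdir, "conserved_genes.tsv")
      readr::write_tsv(prof$per_ecology, p)
      files <- c(files, p)
      p <- file.path(outdir, "conserved_overall.tsv")
      readr::write_tsv(prof$overall, p)
      files <- c(files, p)
      results <- list()
      for (ct in default_contrasts()) {
        r <- ecology_set_genes(cat$presence, cat$samples, held$abundance,
          held$samples, ct$target_ecologies,
          alpha = config$enrichment$alpha, name = ct$name
        )
        results[[ct$name]] <- r
        p <- file.path(outdir, paste0("geneset_", ct$name, ".tsv"))
        readr::write_tsv(r$table, p)
        files <- c(files, p)
      }
      p <- file.path(outdir, "overlaps.tsv")
      readr::write_tsv(overlap_report(results), p)
      files <- c(files, p)
    }
    manifest$stages[[stage]] <- list(
      status = "ok",
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = basename_rel(files, outdir)
    )
    outputs <- c(outputs, files)
    run_log(verbose, stage, "done")
  }
  manifest$outputs <- basename_rel(outputs, outdir)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(manifest)
}

basename_rel <- function(paths, root) {
  sub(paste0("^", root, "/?"), "", paths)
}
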