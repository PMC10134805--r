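# Shared fixtures: small configurations and matrix builders used across tests.

# a small, fast 5-ecology layout (2 groups) for unit tests
small_ecologies <- function(n_samples = 6) {
  tibble::tribble(
    ~name, ~group, ~genes_min, ~genes_max, ~specific_size,
    "gut_a", "gut", 80L, 120L, 90L,
    "gut_b", "gut", 80L, 120L, 90L,
    "env_a", "env", 60L, 100L, 90L,
    "env_b", "env", 60L, 100L, 90L,
    "env_c", "env", 60L, 100L, 90L
  ) |>
    dplyr::mutate(n_samples = as.integer(n_samples), .after = "group")
}

small_config <- function(n_samples = 6, heldout_per_ecology = 3,
                         contrasts = list(
                           list(
                             name = "gut_only", target_ecologies = c("gut_a", "gut_b"),
                             n_genes = 6L, shift = 8, inclusion = 0.8
                           )
                         ), ...) {
  catalog_config(
    ecologies = small_ecologies(n_samples),
    n_conserved = 12,
    core_sizes = c(gut = 150, env = 150),
    contrasts = contrasts,
    species_pool = 40, species_range = c(10, 18),
    heldout_per_ecology = heldout_per_ecology,
    ...
  )
}

# a random sparse binary matrix with guaranteed nonzero rows and columns
random_presence <- function(n, g, density = 0.2, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(n * g, 1, density), n, g)
    for (i in which(rowSums(m) == 0)) m[i, sample(g, 1)] <- 1
    for (j in which(colSums(m) == 0)) m[sample(n, 1), j] <- 1
    dimnames(m) <- list(sprintf("s%03d", seq_len(n)), sprintf("g%04d", seq_len(g)))
    methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  })
}

# sample table for a presence matrix, round-robin over given ecologies
simple_sample_table <- function(pm, ecologies, groups = NULL) {
  eco <- rep_len(ecologies, nrow(pm))
  if (is.null(groups)) groups <- stats::setNames(ecologies, ecologies)
  tibble::tibble(
    sample_id = rownames(pm),
    ecology = eco,
    ecology_group = unname(groups[eco]),
    n_genes = as.integer(Matrix::rowSums(pm))
  )
}

# membership tibble -> temporary TSV file
write_membership_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path)
  path
}
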