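# Shared fixtures. Small simulations are built in code; the expensive
# end-to-end coupled run is computed once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

# A small, fast paired multiome with a recoverable coupled signal.
small_sim <- function(seed = 42, coupling = 1.5, ...) {
  key <- paste0("small_", seed, "_", coupling, "_",
                paste(unlist(list(...)), collapse = "_"))
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_multiome(sim_params(
      n_cells = 200, n_peaks = 400, n_genes = 80, n_chromosomes = 2,
      chrom_length = 8e6, fraction_coupled = 0.2,
      coupling_strength = coupling, seed = seed, ...))
  }
  .fixture_cache[[key]]
}

small_cfg <- function(seed = 42, ...) {
  scev_config(min_peaks_per_cell = 10, min_genes_per_cell = 10,
              min_cells_per_gene = 30, n_homogeneous_cells = 1000,
              select_homogeneous = FALSE, K = 16, K1 = 16, K2 = c(16, 40),
              seed = seed, ...)
}

# The reference coupled run used by the end-to-end acceptance checks:
# 600 cells x 3000 peaks x 400 genes, 10% coupled at strength 1.5, seed 1.
coupled_reference_run <- function() {
  if (is.null(.fixture_cache$coupled_run)) {
    sim <- simulate_multiome(sim_params(seed = 1))
    cfg <- scev_config_sim(seed = 1)
    res <- scev_pipeline(sim$multiome, cfg,
                         models = c("knn", "lasso", "gs", "locreg"))
    .fixture_cache$coupled_run <- list(sim = sim, res = res)
  }
  .fixture_cache$coupled_run
}

# Hand-built tiny multiome for boundary-case tests.
toy_multiome <- function() {
  cells <- paste0("c", 1:4)
  peaks <- data.frame(chrom = c("chr1", "chr1", "chrM"),
                      start = c(100L, 5000L, 10L),
                      end = c(700L, 5400L, 300L), strand = ".",
                      stringsAsFactors = FALSE)
  atac <- count_matrix(matrix(c(2, 1, 0, 5,
                                1, 3, 0, 0,
                                0, 1, 0, 2), 4, 3),
                       cells, paste0("p", 1:3))
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(1000L, 2000L), end = c(4000L, 3000L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  genes$size <- genes$end - genes$start
  rna <- count_matrix(matrix(c(3, 2, 1, 4,
                               0, 0, 1, 1), 4, 2),
                      cells, genes$gene_id)
  paired_multiome(atac, rna, peaks, genes)
}
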