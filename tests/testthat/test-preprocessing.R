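# QC filtering, TF-IDF, RNA normalization, homogeneous-cell selection.

test_that("qc_filter applies the documented rules in order", {
  pm <- toy_multiome()
  cfg <- scev_config(min_peaks_per_cell = 1, min_genes_per_cell = 1,
                     min_cells_per_gene = 2, min_mean_expression = 0.5)
  out <- qc_filter(pm, cfg)
  # chrM peak removed regardless of counts
  expect_false("chrM" %in% out$multiome$peaks$chrom)
  expect_equal(out$report$peaks_removed_region, 1)
  # cell c3 has no nonzero peak -> removed from both modalities
  expect_false("c3" %in% rownames(out$multiome$atac))
  expect_false("c3" %in% rownames(out$multiome$rna))
  # gene gB has counts (0,0,1) over the three retained cells: 1 cell < 2 -> dropped
  expect_false("gB" %in% colnames(out$multiome$rna))
  expect_equal(out$report$n_cells, 3)
})

test_that("the gene expression filter keeps the documented boundary case", {
  # gene with counts (0,0,1,1) over 4 retained cells: 2 expressing cells and
  # mean 0.5 meet the >= thresholds exactly
  cells <- paste0("c", 1:4)
  atac <- count_matrix(matrix(1, 4, 2), cells, c("p1", "p2"))
  peaks <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                      end = c(500L, 1500L), strand = ".")
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(0L, 5000L), end = c(2000L, 7000L),
                      strand = "+", size = c(2000L, 2000L))
  rna <- count_matrix(cbind(c(0, 0, 1, 1), c(2, 2, 2, 2)), cells,
                      genes$gene_id)
  pm <- paired_multiome(atac, rna, peaks, genes)
  cfg <- scev_config(min_peaks_per_cell = 1, min_genes_per_cell = 1,
                     min_cells_per_gene = 2, min_mean_expression = 0.5)
  out <- qc_filter(pm, cfg)
  expect_true("g1" %in% colnames(out$multiome$rna))
  # raising the mean threshold just above 0.5 drops it
  cfg2 <- scev_config(min_peaks_per_cell = 1, min_genes_per_cell = 1,
                      min_cells_per_gene = 2, min_mean_expression = 0.51)
  expect_false("g1" %in% colnames(qc_filter(pm, cfg2)$multiome$rna))
})

test_that("blacklist overlap of at least one bp removes features", {
  pm <- toy_multiome()
  cfg <- scev_config(min_peaks_per_cell = 1, min_genes_per_cell = 1,
                     min_cells_per_gene = 1, min_mean_expression = 0)
  # half-open [699, 800) overlaps peak [100, 700) in exactly 1 bp
  bl <- data.frame(chrom = "chr1", start = 699L, end = 800L)
  out <- qc_filter(pm, cfg, blacklist = bl)
  expect_false(any(out$multiome$peaks$start == 100))
  # [700, 800) touches but does not overlap the half-open peak
  bl2 <- data.frame(chrom = "chr1", start = 700L, end = 800L)
  out2 <- qc_filter(pm, cfg, blacklist = bl2)
  expect_true(any(out2$multiome$peaks$start == 100))
})

test_that("qc_filter is idempotent", {
  s <- small_sim(seed = 31)
  cfg <- small_cfg()
  once <- qc_filter(s$multiome, cfg)
  twice <- qc_filter(once$multiome, cfg)
  expect_identical(as.matrix(once$multiome$atac), as.matrix(twice$multiome$atac))
  expect_identical(as.matrix(once$multiome$rna), as.matrix(twice$multiome$rna))
})

test_that("TF-IDF matches the closed form and preserves zeros", {
  m <- count_matrix(matrix(3, 1, 1), "c1", "p1")
  expect_equal(as.numeric(tfidf_transform(m)), log(10001))
  s <- small_sim(seed = 31)
  tf <- tfidf_transform(s$multiome$atac[Matrix::rowSums(s$multiome$atac) > 0, ])
  expect_equal(as.matrix(tf) == 0, as.matrix(s$multiome$atac[Matrix::rowSums(s$multiome$atac) > 0, ]) == 0)
  expect_true(all(tf@x >= 0))
  # equal counts with equal library sizes transform symmetrically
  eq <- count_matrix(matrix(c(2, 2, 1, 1), 2, 2), c("c1", "c2"), c("p1", "p2"))
  tfe <- as.matrix(tfidf_transform(eq))
  expect_equal(tfe[1, ], tfe[2, ])
})

test_that("TF-IDF is monotone in an entry holding the rest of the row fixed", {
  base <- matrix(c(4, 1, 2,
                   1, 3, 2), 2, 3, byrow = TRUE)
  bumped <- base; bumped[1, 1] <- 7
  t1 <- as.matrix(tfidf_transform(count_matrix(base, c("a", "b"), c("p1", "p2", "p3"))))
  t2 <- as.matrix(tfidf_transform(count_matrix(bumped, c("a", "b"), c("p1", "p2", "p3"))))
  expect_gt(t2[1, 1], t1[1, 1])
})

test_that("RNA normalization matches the closed form and is scale invariant", {
  cells <- c("c1", "c2")
  m <- count_matrix(rbind(c(10, 90), c(20, 180)), cells, c("g1", "g2"))
  norm <- as.matrix(normalize_rna(m))
  expect_equal(norm["c1", "g1"], log(1e4 * 10 / 100 + 1))  # log(1001)
  # doubling all counts of a cell leaves its normalized vector unchanged
  expect_equal(norm["c1", ], norm["c2", ])
  z <- count_matrix(rbind(c(0, 5), c(1, 1)), cells, c("g1", "g2"))
  expect_equal(as.matrix(normalize_rna(z))["c1", "g1"], 0)
  bad <- count_matrix(rbind(c(0, 0), c(1, 1)), cells, c("g1", "g2"))
  expect_error(normalize_rna(bad), "c1")
})

test_that("homogeneous-cell selection is deterministic and exhaustive at target = N", {
  s <- small_sim(seed = 31)
  tf <- tfidf_transform(s$multiome$atac)
  a <- select_homogeneous_cells(tf, 150, seed = 5)
  b <- select_homogeneous_cells(tf, 150, seed = 5)
  expect_identical(a$selected, b$selected)
  expect_identical(a$embedding, b$embedding)
  all_cells <- select_homogeneous_cells(tf, nrow(tf), seed = 5)
  expect_setequal(all_cells$selected, rownames(tf))
})

test_that("selected cells form a contiguous disc around the core", {
  s <- small_sim(seed = 31)
  tf <- tfidf_transform(s$multiome$atac)
  sel <- select_homogeneous_cells(tf, 120, seed = 5)
  d_in <- sel$embedding$dist_to_core[sel$embedding$selected]
  d_out <- sel$embedding$dist_to_core[!sel$embedding$selected]
  expect_lte(max(d_in), min(d_out) + 1e-9)
})

test_that("selection recovers the majority population after a cluster injection", {
  s <- simulate_multiome(sim_params(n_cells = 250, n_peaks = 600, n_genes = 60,
                                    n_chromosomes = 2, chrom_length = 8e6,
                                    seed = 21))
  pm <- inject_heterogeneous_cluster(s$multiome, fraction = 0.2, shift = 5, seed = 22)
  shifted <- attr(pm, "shifted_cells")
  tf <- tfidf_transform(pm$atac)
  sel <- select_homogeneous_cells(tf, n_cells_target = 200, seed = 23)
  expect_gte(mean(!sel$selected %in% shifted), 0.95)
})

test_that("an explicit core cell overrides the medoid rule", {
  s <- small_sim(seed = 31)
  tf <- tfidf_transform(s$multiome$atac)
  sel <- select_homogeneous_cells(tf, 50, seed = 5, core_cell = "cell_0007")
  expect_equal(sel$core_cell, "cell_0007")
  expect_true("cell_0007" %in% sel$selected)
  expect_error(select_homogeneous_cells(tf, 50, seed = 5, core_cell = "nope"),
               "not found")
})
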