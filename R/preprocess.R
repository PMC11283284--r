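# Quality control, TF-IDF, RNA normalization, homogeneous-cell selection.

#' Quality-control filtering of a paired multiome
#'
#' Filters are applied in a fixed order: (1) peaks and genes on excluded
#' chromosomes or overlapping (>= 1 bp) a blacklist interval are dropped;
#' (2) cells with fewer than `min_peaks_per_cell` nonzero peaks are dropped;
#' (3) cells with fewer than `min_genes_per_cell` expressed genes are
#' dropped; (4) genes expressed in fewer than `min_cells_per_gene` retained
#' cells, or with mean raw count below `min_mean_expression` over retained
#' cells, are dropped. A cell removed by either modality's criterion is
#' removed from both, so the ATAC and RNA cell sets stay identical.
#'
#' @param pm a [paired_multiome()].
#' @param cfg an [scev_config()] providing the thresholds.
#' @param excluded_chroms chromosome names whose features are removed.
#' @param blacklist optional interval data frame (0-based half-open, as from
#'   `read_interval_table(kind = "blacklist")`).
#' @return list with `multiome` (filtered) and `report` (a `qc_report` with
#'   the per-stage accounting and final dimensions).
#' @export
qc_filter <- function(pm, cfg = scev_config(),
                      excluded_chroms = cfg$excluded_chroms, blacklist = NULL) {
  stopifnot(inherits(pm, "paired_multiome"))
  atac <- pm$atac; rna <- pm$rna; peaks <- pm$peaks; genes <- pm$genes

  drop_by_region <- function(feat) {
    drop <- feat$chrom %in% excluded_chroms
    if (!is.null(blacklist) && nrow(blacklist) > 0 && nrow(feat) > 0) {
      # 0-based half-open -> 1-based closed for GRanges
      f <- GenomicRanges::GRanges(feat$chrom,
                                  IRanges::IRanges(feat$start + 1L, feat$end))
      b <- GenomicRanges::GRanges(blacklist$chrom,
                                  IRanges::IRanges(blacklist$start + 1L, blacklist$end))
      hits <- GenomicRanges::findOverlaps(f, b, minoverlap = 1L)
      drop[unique(S4Vectors::queryHits(hits))] <- TRUE
    }
    drop
  }
  pk_drop <- drop_by_region(peaks)
  gn_drop_region <- drop_by_region(genes)
  atac <- atac[, !pk_drop, drop = FALSE]; peaks <- peaks[!pk_drop, , drop = FALSE]
  rna <- rna[, !gn_drop_region, drop = FALSE]; genes <- genes[!gn_drop_region, , drop = FALSE]
  sl_log("qc_filter: removed %d peaks and %d genes by chromosome/blacklist",
         sum(pk_drop), sum(gn_drop_region))

  npeaks_per_cell <- Matrix::rowSums(atac > 0)
  cell_drop_atac <- npeaks_per_cell < cfg$min_peaks_per_cell
  if (all(cell_drop_atac)) {
    sl_stop("qc_filter: all cells removed at the min-peaks-per-cell stage")
  }
  ngenes_per_cell <- Matrix::rowSums(rna > 0)
  cell_drop_rna <- ngenes_per_cell < cfg$min_genes_per_cell
  cell_drop <- cell_drop_atac | cell_drop_rna
  if (all(cell_drop)) {
    sl_stop("qc_filter: all cells removed at the min-genes-per-cell stage")
  }
  atac <- atac[!cell_drop, , drop = FALSE]
  rna <- rna[!cell_drop, , drop = FALSE]
  sl_log("qc_filter: removed %d cells (%d by ATAC, %d by RNA criterion)",
         sum(cell_drop), sum(cell_drop_atac), sum(cell_drop_rna))

  cells_per_gene <- Matrix::colSums(rna > 0)
  mean_expr <- Matrix::colMeans(rna)
  gene_keep <- cells_per_gene >= cfg$min_cells_per_gene &
    mean_expr >= cfg$min_mean_expression
  rna <- rna[, gene_keep, drop = FALSE]
  genes <- genes[gene_keep, , drop = FALSE]
  sl_log("qc_filter: removed %d genes by expression criteria", sum(!gene_keep))

  out <- paired_multiome(atac, rna, peaks, genes)
  report <- structure(
    list(cells_removed_atac = sum(cell_drop_atac),
         cells_removed_rna = sum(cell_drop_rna),
         cells_removed = sum(cell_drop),
         genes_removed_region = sum(gn_drop_region),
         genes_removed_expression = sum(!gene_keep),
         peaks_removed_region = sum(pk_drop),
         n_cells = nrow(out$atac), n_peaks = ncol(out$atac),
         n_genes = ncol(out$rna)),
    class = "qc_report")
  list(multiome = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:\n")
  cat(sprintf("  peaks removed (chrom/blacklist): %d\n", x$peaks_removed_region))
  cat(sprintf("  genes removed (chrom/blacklist): %d\n", x$genes_removed_region))
  cat(sprintf("  cells removed: %d (ATAC criterion %d, RNA criterion %d)\n",
              x$cells_removed, x$cells_removed_atac, x$cells_removed_rna))
  cat(sprintf("  genes removed (expression): %d\n", x$genes_removed_expression))
  cat(sprintf("  final: %d cells, %d peaks, %d genes\n",
              x$n_cells, x$n_peaks, x$n_genes))
  invisible(x)
}

#' TF-IDF transform of an ATAC count matrix
#'
#' Computes `log(1 + scale * TF * IDF)` where TF is the cell-wise count
#' fraction `x / rowSums(x)` and IDF is `N / n_cells_with_peak`. Zeros stay
#' zero and the transform is monotone in each entry holding the rest of the
#' cell's row fixed. Peaks open in no cell have undefined IDF and are
#' dropped with a warning.
#'
#' @param atac cell-by-peak count `dgCMatrix`; every cell needs at least one
#'   nonzero entry.
#' @param scale scaling constant, default `1e4`.
#' @return a real-valued `dgCMatrix` of the same shape (minus dropped peaks).
#' @export
tfidf_transform <- function(atac, scale = 1e4) {
  rs <- Matrix::rowSums(atac)
  if (any(rs == 0)) {
    sl_stop("tfidf_transform: cell '%s' has no nonzero peak",
            rownames(atac)[which(rs == 0)[1]])
  }
  open_cells <- Matrix::colSums(atac > 0)
  if (any(open_cells == 0)) {
    sl_warn("tfidf_transform: dropping %d peak(s) open in no cell", sum(open_cells == 0))
    atac <- atac[, open_cells > 0, drop = FALSE]
    open_cells <- open_cells[open_cells > 0]
  }
  N <- nrow(atac)
  out <- Matrix::Diagonal(x = 1 / rs) %*% atac %*%
    Matrix::Diagonal(x = N / open_cells)
  out <- as(out, "CsparseMatrix")
  out@x <- log1p(scale * out@x)
  dimnames(out) <- dimnames(atac)
  out
}

#' Library-size normalization and log transform of RNA counts
#'
#' Computes `log(scale * a / cell_total + 1)` (natural log) for each count
#' `a`; invariant to rescaling all counts of a cell.
#'
#' @param rna cell-by-gene count `dgCMatrix`; every cell needs total > 0.
#' @param scale scaling constant, default `1e4`.
#' @return a real-valued `dgCMatrix` of the same shape.
#' @export
normalize_rna <- function(rna, scale = 1e4) {
  totals <- Matrix::rowSums(rna)
  if (any(totals == 0)) {
    sl_stop("normalize_rna: cell '%s' has zero total count",
            rownames(rna)[which(totals == 0)[1]])
  }
  out <- Matrix::Diagonal(x = scale / totals) %*% rna
  out <- as(out, "CsparseMatrix")
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(rna)
  out
}

#' Select a homogeneous cell subpopulation from the accessibility embedding
#'
#' Features present in fewer than `min_feature_fraction` of cells are
#' removed; a truncated PCA reduces the TF-IDF matrix to `n_dims` dimensions
#' (optionally dropping the first component, as in the LSI convention); a
#' 2-D UMAP embedding is computed with a fixed seed; the core cell is the
#' cell nearest (Euclidean) to the coordinate-wise median of the embedding
#' (or an explicitly supplied cell id); and the `n_cells_target` cells
#' nearest to the core cell — including the core itself — are returned, ties
#' broken by cell-id order.
#'
#' @param atac_tfidf transformed cell-by-peak matrix.
#' @param n_cells_target number of cells to select (<= number of cells).
#' @param min_feature_fraction minimum fraction of cells a feature must be
#'   present in, default 0.01.
#' @param seed integer seed controlling PCA initialisation and UMAP.
#' @param core_cell optional explicit core cell id (`NULL` = automatic).
#' @param n_dims target dimensionality of the linear reduction, default 50
#'   (reduced with a warning when fewer usable features exist).
#' @param drop_first_component drop the first component of the reduction.
#' @return list with `selected` (cell ids), `embedding` (data frame of
#'   cell id, UMAP coordinates and distance to core), and `core_cell`.
#' @export
select_homogeneous_cells <- function(atac_tfidf, n_cells_target,
                                     min_feature_fraction = 0.01, seed = 1,
                                     core_cell = NULL, n_dims = 50,
                                     drop_first_component = FALSE) {
  N <- nrow(atac_tfidf)
  if (n_cells_target > N) {
    sl_stop("n_cells_target (%d) exceeds the number of cells (%d)", n_cells_target, N)
  }
  frac <- Matrix::colSums(atac_tfidf > 0) / N
  keep <- frac >= min_feature_fraction
  x <- atac_tfidf[, keep, drop = FALSE]
  sl_log("select_homogeneous_cells: %d/%d features retained", ncol(x), ncol(atac_tfidf))
  max_dims <- ncol(x) - 1L
  if (max_dims < n_dims) {
    sl_warn("only %d usable features; reducing dimension from %d to %d",
            ncol(x), n_dims, max_dims)
    n_dims <- max_dims
  }
  set.seed(seed)
  pca <- irlba::irlba(x, nv = n_dims, center = Matrix::colMeans(x))
  scores <- pca$u %*% diag(pca$d, n_dims, n_dims)
  if (drop_first_component) scores <- scores[, -1, drop = FALSE]
  emb <- uwot::umap(scores, n_neighbors = min(15, N - 1), n_threads = 1,
                    seed = seed)
  ids <- rownames(atac_tfidf)
  if (is.null(core_cell)) {
    ctr <- apply(emb, 2, median)
    core_i <- which.min(sqrt(colSums((t(emb) - ctr)^2)))
  } else {
    core_i <- match(core_cell, ids)
    if (is.na(core_i)) sl_stop("core cell '%s' not found", core_cell)
  }
  d <- sqrt(colSums((t(emb) - emb[core_i, ])^2))
  ord <- order(d, ids)
  selected <- sort(ids[ord[seq_len(n_cells_target)]])
  embedding <- data.frame(cell_id = ids, umap_1 = emb[, 1], umap_2 = emb[, 2],
                          dist_to_core = d, selected = ids %in% selected,
                          stringsAsFactors = FALSE)
  list(selected = selected, embedding = embedding, core_cell = ids[core_i])
}

#' Run the full preprocessing stage on a paired multiome
#'
#' QC filtering, TF-IDF, RNA normalization and (optionally) homogeneous-cell
#' selection, returning everything downstream stages need.
#'
#' @param pm a [paired_multiome()].
#' @param cfg an [scev_config()].
#' @param blacklist optional blacklist interval data frame.
#' @return an object of class `scev_prep`: the filtered multiome plus
#'   `atac_tfidf`, `rna_norm`, the QC report, and the selection output.
#' @export
preprocess_multiome <- function(pm, cfg = scev_config(), blacklist = NULL) {
  qc <- qc_filter(pm, cfg, blacklist = blacklist)
  pmf <- qc$multiome
  # peaks open in no retained cell have undefined IDF; drop them here so the
  # annotation table stays aligned with the transformed matrix
  open <- Matrix::colSums(pmf$atac > 0) > 0
  if (any(!open)) {
    sl_log("preprocess_multiome: dropping %d peak(s) open in no retained cell",
           sum(!open))
    pmf <- paired_multiome(pmf$atac[, open, drop = FALSE], pmf$rna,
                           pmf$peaks[open, , drop = FALSE], pmf$genes)
  }
  atac_tfidf <- tfidf_transform(pmf$atac, scale = cfg$tfidf_scale)
  selection <- NULL
  if (isTRUE(cfg$select_homogeneous) && cfg$n_homogeneous_cells < nrow(pmf$atac)) {
    selection <- select_homogeneous_cells(
      atac_tfidf, cfg$n_homogeneous_cells,
      min_feature_fraction = cfg$min_feature_fraction, seed = cfg$seed,
      core_cell = cfg$core_cell, n_dims = cfg$n_reduced_dims,
      drop_first_component = cfg$drop_first_component)
    keep <- rownames(pmf$atac) %in% selection$selected
    pmf <- paired_multiome(pmf$atac[keep, , drop = FALSE],
                           pmf$rna[keep, , drop = FALSE], pmf$peaks, pmf$genes)
    atac_tfidf <- atac_tfidf[keep, , drop = FALSE]
    sl_log("preprocess_multiome: %d homogeneous cells selected", sum(keep))
  }
  rna_norm <- normalize_rna(pmf$rna, scale = cfg$rna_scale)
  structure(list(multiome = pmf, atac_tfidf = atac_tfidf, rna_norm = rna_norm,
                 qc_report = qc$report, selection = selection, config = cfg),
            class = "scev_prep")
}
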