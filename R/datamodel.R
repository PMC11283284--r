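# Core data containers and readers/writers.
#
# Count matrices are stored as Matrix::dgCMatrix with cells as rows and
# features as columns; dimnames carry the cell and feature identifiers.
# Genomic intervals are plain data frames in 0-based half-open coordinates
# (BED convention) throughout the package; the on-disk MatrixMarket triplets
# are 1-based and converted on read.

#' Construct a validated cell-by-feature count matrix
#'
#' @param values numeric matrix or sparse Matrix, cells in rows, features in
#'   columns. Entries must be finite and non-negative.
#' @param cell_ids character vector of unique cell identifiers (rows).
#' @param feature_ids character vector of unique feature identifiers (columns).
#' @return a `dgCMatrix` with `cell_ids` as rownames and `feature_ids` as
#'   colnames.
#' @export
count_matrix <- function(values, cell_ids, feature_ids) {
  m <- as(as(as(values, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(m) != length(cell_ids)) {
    sl_stop("count matrix has %d rows but %d cell ids", nrow(m), length(cell_ids))
  }
  if (ncol(m) != length(feature_ids)) {
    sl_stop("count matrix has %d columns but %d feature ids", ncol(m), length(feature_ids))
  }
  if (anyDuplicated(cell_ids)) sl_stop("cell ids are not unique")
  if (anyDuplicated(feature_ids)) sl_stop("feature ids are not unique")
  if (length(m@x) && (anyNA(m@x) || any(m@x < 0))) {
    sl_stop("count matrix entries must be non-negative and non-missing")
  }
  dimnames(m) <- list(as.character(cell_ids), as.character(feature_ids))
  m
}

#' Read a sparse count matrix from MatrixMarket triplets plus id files
#'
#' The triplet file follows the MatrixMarket coordinate convention (1-based
#' indices, a size header line); `cells_path` and `features_path` list one
#' identifier per line, in row and column order respectively.
#'
#' @param triplet_path path to the MatrixMarket `.mtx` file.
#' @param cells_path path to the cell id file (one id per line).
#' @param features_path path to the feature id file (one id per line).
#' @return a `dgCMatrix`, see [count_matrix()].
#' @export
read_count_matrix <- function(triplet_path, cells_path, features_path) {
  tm <- tryCatch(Matrix::readMM(triplet_path),
                 error = function(e) sl_stop("malformed MatrixMarket file '%s': %s",
                                             triplet_path, conditionMessage(e)))
  tm <- as(tm, "TsparseMatrix")
  cells <- readLines(cells_path)
  feats <- readLines(features_path)
  if (nrow(tm) != length(cells) || ncol(tm) != length(feats)) {
    sl_stop("declared matrix shape %dx%d does not match %d cell ids and %d feature ids",
            nrow(tm), ncol(tm), length(cells), length(feats))
  }
  if (length(tm@x)) {
    if (any(tm@x < 0)) sl_stop("negative entries in '%s'", triplet_path)
    if (anyDuplicated(cbind(tm@i, tm@j))) {
      sl_stop("duplicate (row, col) triplet entries in '%s'", triplet_path)
    }
  }
  out <- count_matrix(tm, cells, feats)
  sl_log("read_count_matrix: %d cells x %d features, %d nonzeros",
         nrow(out), ncol(out), length(out@x))
  out
}

#' Write a count matrix as MatrixMarket triplets plus id files
#'
#' Inverse of [read_count_matrix()]; integer counts round-trip exactly.
#'
#' @inheritParams read_count_matrix
#' @param mat a cell-by-feature `dgCMatrix` with dimnames.
#' @return invisibly, `triplet_path`.
#' @export
write_count_matrix <- function(mat, triplet_path, cells_path, features_path) {
  Matrix::writeMM(mat, triplet_path)
  writeLines(rownames(mat), cells_path)
  writeLines(colnames(mat), features_path)
  invisible(triplet_path)
}

validate_intervals <- function(df, what) {
  if (nrow(df) == 0) return(df)
  if (anyNA(df$start) || anyNA(df$end)) sl_stop("%s: missing coordinates", what)
  if (any(df$start < 0)) sl_stop("%s: negative start coordinate", what)
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    sl_stop("%s: start >= end at row %d (%s:%d-%d)", what, bad[1],
            df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]])
  }
  if (any(!nzchar(df$chrom))) sl_stop("%s: empty chromosome name", what)
  df
}

#' Read a table of genomic intervals
#'
#' Peak and gene tables are tab-separated with a header line (`chrom`,
#' `start`, `end`, plus `gene_id` and `strand` for genes); the blacklist is
#' headerless BED. All coordinates are 0-based half-open.
#'
#' @param path file path.
#' @param kind one of `"peak"`, `"gene"`, `"blacklist"`.
#' @return a data frame with columns `chrom`, `start`, `end`, `strand` (and
#'   `gene_id`, `size` for genes), rows in file order.
#' @export
read_interval_table <- function(path, kind = c("peak", "gene", "blacklist")) {
  kind <- match.arg(kind)
  if (kind == "blacklist") {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    df <- df[, 1:3]
    names(df) <- c("chrom", "start", "end")
    df$strand <- "."
  } else {
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", if (kind == "gene") "gene_id")
    miss <- setdiff(need, names(df))
    if (length(miss)) sl_stop("'%s' lacks required column(s): %s", path,
                              paste(miss, collapse = ", "))
    if (is.null(df$strand)) {
      if (kind == "gene") sl_warn("'%s': no strand column; defaulting to '.'", path)
      df$strand <- "."
    }
    df$strand[is.na(df$strand) | !df$strand %in% c("+", "-", ".")] <- "."
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df <- validate_intervals(df, kind)
  if (kind == "gene") {
    df$size <- df$end - df$start
    df <- df[, c("gene_id", "chrom", "start", "end", "strand", "size")]
  } else {
    df <- df[, c("chrom", "start", "end", "strand")]
  }
  sl_log("read_interval_table: %d %s record(s) from '%s'", nrow(df), kind, path)
  df
}

#' Write a table of genomic intervals
#'
#' @param df interval data frame as returned by [read_interval_table()].
#' @param path output file path.
#' @param kind `"peak"`/`"gene"` (TSV with header) or `"blacklist"` (BED).
#' @return invisibly, `path`.
#' @export
write_interval_table <- function(df, path, kind = c("peak", "gene", "blacklist")) {
  kind <- match.arg(kind)
  header <- kind != "blacklist"
  cols <- if (kind == "blacklist") c("chrom", "start", "end") else names(df)
  write.table(df[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = header)
  invisible(path)
}

#' Bundle paired ATAC and RNA count matrices with their annotations
#'
#' Construction fails loudly on any mismatch between the two modalities: the
#' cell sets must be identical and in the same order, and annotation tables
#' must align one-to-one with the matrix columns.
#'
#' @param atac cell-by-peak count `dgCMatrix`.
#' @param rna cell-by-gene count `dgCMatrix` over the same cells.
#' @param peaks peak interval data frame aligned to `colnames(atac)`.
#' @param genes gene annotation data frame (with `gene_id`, `size`) aligned to
#'   `colnames(rna)`.
#' @return an object of class `paired_multiome`.
#' @export
paired_multiome <- function(atac, rna, peaks, genes) {
  if (!identical(rownames(atac), rownames(rna))) {
    sl_stop("ATAC and RNA cell ids differ (or are ordered differently)")
  }
  if (nrow(peaks) != ncol(atac)) {
    sl_stop("%d peak annotations for %d ATAC features", nrow(peaks), ncol(atac))
  }
  if (nrow(genes) != ncol(rna)) {
    sl_stop("%d gene annotations for %d RNA features", nrow(genes), ncol(rna))
  }
  if (!identical(as.character(genes$gene_id), colnames(rna))) {
    sl_stop("gene annotation ids do not match RNA feature ids")
  }
  validate_intervals(peaks, "peaks")
  validate_intervals(genes, "genes")
  if (any(genes$size != genes$end - genes$start) || any(genes$size < 1)) {
    sl_stop("gene sizes inconsistent with coordinates")
  }
  structure(list(atac = atac, rna = rna, peaks = peaks, genes = genes),
            class = "paired_multiome")
}

#' @export
print.paired_multiome <- function(x, ...) {
  cat(sprintf("paired_multiome: %d cells, %d peaks, %d genes\n",
              nrow(x$atac), ncol(x$atac), ncol(x$rna)))
  cat(sprintf("  ATAC nonzero fraction: %.3f; RNA nonzero fraction: %.3f\n",
              length(x$atac@x) / prod(dim(x$atac)),
              length(x$rna@x) / prod(dim(x$rna))))
  invisible(x)
}

#' Write a paired multiome to disk in the package's plain-text formats
#'
#' @param pm a `paired_multiome`.
#' @param dir output directory (created if missing).
#' @return invisibly, `dir`.
#' @export
write_paired_multiome <- function(pm, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_count_matrix(pm$atac, fp("atac.mtx"), fp("cells.txt"), fp("peaks.txt"))
  write_count_matrix(pm$rna, fp("rna.mtx"), fp("cells.txt"), fp("genes.txt"))
  write_interval_table(pm$peaks, fp("peak_annotations.tsv"), "peak")
  write_interval_table(pm$genes, fp("gene_annotations.tsv"), "gene")
  invisible(dir)
}

#' Read a paired multiome written by [write_paired_multiome()]
#'
#' @param dir directory containing the matrix and annotation files.
#' @return a `paired_multiome`.
#' @export
read_paired_multiome <- function(dir) {
  fp <- function(f) file.path(dir, f)
  atac <- read_count_matrix(fp("atac.mtx"), fp("cells.txt"), fp("peaks.txt"))
  rna <- read_count_matrix(fp("rna.mtx"), fp("cells.txt"), fp("genes.txt"))
  peaks <- read_interval_table(fp("peak_annotations.tsv"), "peak")
  genes <- read_interval_table(fp("gene_annotations.tsv"), "gene")
  paired_multiome(atac, rna, peaks, genes)
}
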