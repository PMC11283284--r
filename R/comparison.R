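# The three statistical tests linking prediction performance to scEV, the
# matched-mean sensitivity control, and report assembly. All tests are
# one-sided in the asserted direction (HVGs better predicted; enrichment);
# fully tied comparisons return p = 1 by convention.

#' One-sided Wilcoxon rank-sum test: HVGs better predicted than non-HVGs
#'
#' Mann-Whitney test of whether the prediction performance of HVGs is
#' stochastically greater than that of non-HVGs; exact enumeration for
#' groups of at most 20 without ties, tie-corrected normal approximation
#' otherwise.
#'
#' @param perf named numeric vector of per-gene average correlations.
#' @param hvg character vector of HVG gene ids (a subset of `names(perf)`).
#' @return list with `statistic` (the rank-sum U), `p_value`, and the two
#'   group medians.
#' @export
wilcoxon_hvg_test <- function(perf, hvg) {
  ids <- names(perf)
  if (is.null(ids)) sl_stop("wilcoxon_hvg_test: perf must be named by gene id")
  a <- perf[ids %in% hvg]
  b <- perf[!ids %in% hvg]
  if (!length(a) || !length(b)) sl_stop("wilcoxon_hvg_test: a group is empty")
  if (length(unique(c(a, b))) == 1) {
    return(list(statistic = length(a) * length(b) / 2, p_value = 1,
                median_hvg = median(a), median_non_hvg = median(b)))
  }
  use_exact <- length(a) <= 20 && length(b) <= 20 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "greater",
                                     exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_hvg = median(a), median_non_hvg = median(b))
}

#' One-sided Spearman correlation between performance and scEV
#'
#' Spearman's rho with average ranks for ties; the one-sided p-value (for
#' positive association) comes from the t approximation on rho. Constant
#' input gives rho = 0, p = 1, flagged.
#'
#' @param perf named numeric per-gene average correlations.
#' @param scev named numeric per-gene scEV scores (same genes).
#' @return list with `rho`, `p_value` and a `degenerate` flag.
#' @export
spearman_perf_scev <- function(perf, scev) {
  ids <- names(perf)
  if (!is.null(ids) && !is.null(names(scev))) {
    if (!setequal(ids, names(scev))) {
      sl_stop("spearman_perf_scev: gene universes differ")
    }
    scev <- scev[ids]
  }
  n <- length(perf)
  if (n < 10) sl_stop("spearman_perf_scev: need at least 10 genes")
  if (sd(perf) == 0 || sd(scev) == 0) {
    return(list(rho = 0, p_value = 1, degenerate = TRUE))
  }
  rho <- cor(rank(perf), rank(scev))
  if (abs(rho) >= 1) {
    p <- if (rho > 0) .Machine$double.xmin else 1
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- pt(tstat, df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_value = max(p, .Machine$double.xmin), degenerate = FALSE)
}

#' Fisher enrichment test of well-predicted genes among HVGs
#'
#' One-sided (enrichment) p-value by the hypergeometric tail for the overlap
#' of two gene sets within a universe of `q` genes, plus the sample odds
#' ratio of the 2x2 table.
#'
#' @param well_predicted character vector (top-K1 well-predicted genes).
#' @param hvgs character vector (top-K2 HVGs).
#' @param q size of the gene universe containing both sets.
#' @return list with `overlap`, `odds_ratio` and `p_value`.
#' @export
overlap_fisher <- function(well_predicted, hvgs, q) {
  a <- length(intersect(well_predicted, hvgs))
  k1 <- length(well_predicted); k2 <- length(hvgs)
  if (q < length(union(well_predicted, hvgs))) {
    sl_stop("overlap_fisher: universe (%d) smaller than the union of the sets", q)
  }
  b <- k1 - a; cc <- k2 - a; d <- q - k1 - k2 + a
  p <- phyper(a - 1, k1, q - k1, k2, lower.tail = FALSE)
  orat <- if (b * cc == 0) Inf else (a * d) / (b * cc)
  list(overlap = a, odds_ratio = orat, p_value = min(max(p, .Machine$double.xmin), 1))
}

#' Matched-mean sensitivity control
#'
#' Each HVG is paired with the non-HVG of most similar mean expression
#' (greedy in descending HVG scEV order, without replacement, ties broken by
#' gene id); a one-sided paired signed-rank test then asks whether HVG
#' performance exceeds the matched non-HVG performance, controlling for mean
#' expression level.
#'
#' @param perf named numeric per-gene average correlations.
#' @param hvg character vector of HVG ids.
#' @param scev named numeric scEV scores (orders the greedy matching).
#' @param gene_means named numeric per-gene mean expression.
#' @return list with `pairs` (data frame of matched ids, their means and
#'   performances) and `p_value`.
#' @export
matched_mean_sensitivity <- function(perf, hvg, scev, gene_means) {
  ids <- names(perf)
  non <- setdiff(ids, hvg)
  if (length(non) < length(hvg)) {
    sl_stop("matched_mean_sensitivity: non-HVG pool (%d) smaller than the HVG set (%d)",
            length(non), length(hvg))
  }
  hvg_ord <- hvg[order(-scev[hvg], hvg)]
  avail <- non
  match_id <- character(length(hvg_ord))
  for (i in seq_along(hvg_ord)) {
    dm <- abs(gene_means[avail] - gene_means[hvg_ord[i]])
    j <- order(dm, avail)[1]
    match_id[i] <- avail[j]
    avail <- avail[-j]
  }
  pairs <- data.frame(hvg = hvg_ord, non_hvg = match_id,
                      hvg_mean = unname(gene_means[hvg_ord]),
                      non_hvg_mean = unname(gene_means[match_id]),
                      hvg_r = unname(perf[hvg_ord]),
                      non_hvg_r = unname(perf[match_id]),
                      stringsAsFactors = FALSE)
  diffs <- pairs$hvg_r - pairs$non_hvg_r
  p <- if (all(diffs == 0)) 1 else {
    suppressWarnings(wilcox.test(pairs$hvg_r, pairs$non_hvg_r, paired = TRUE,
                                 alternative = "greater", exact = FALSE,
                                 correct = TRUE))$p.value
  }
  list(pairs = pairs, p_value = p)
}

#' Assemble the full comparison report
#'
#' For every (predictor, detector) pair: the one-sided Wilcoxon test of HVG
#' versus non-HVG performance (at `K1` HVGs), the Spearman correlation of
#' performance with the scEV score over all genes, the matched-mean paired
#' control, and — for every `K2` in the configured list that fits the gene
#' universe — the overlap of the top-`K1` well-predicted genes with the
#' top-`K2` HVGs and its Fisher enrichment p-value. Raw p-values are
#' reported with a Bonferroni column for transparency; no correction is
#' applied to the headline values.
#'
#' @param perf a `performance_table`.
#' @param scev a [scev_table()] on the same gene universe.
#' @param K1 number of well-predicted genes per predictor.
#' @param K2 vector of HVG set sizes for the overlap tests.
#' @return an object of class `comparison_report`: data frames `tests` and
#'   `overlaps`, plus the exported `gene_lists`.
#' @export
build_report <- function(perf, scev, K1 = 200, K2 = c(200, 500, 1000, 2000)) {
  genes <- sort(unique(perf$gene_id))
  miss <- union(setdiff(genes, scev$gene_id), setdiff(scev$gene_id, genes))
  if (length(miss)) {
    sl_stop("build_report: gene universes differ (e.g. %s)",
            paste(head(miss, 3), collapse = ", "))
  }
  q <- length(genes)
  predictors <- unique(perf$predictor)
  detectors <- c(vst = "vst_score", splinefit = "splinefit_score")
  scev_scores <- lapply(detectors, function(col) setNames(scev[[col]], scev$gene_id))
  gene_means <- setNames(scev$mean_expression, scev$gene_id)
  K2 <- K2[K2 <= q]
  if (K1 > q) sl_stop("build_report: K1 (%d) exceeds the gene universe (%d)", K1, q)

  tests <- list(); overlaps <- list()
  gene_lists <- list(well_predicted = list(), hvg = list(), overlap = list())
  for (pr in predictors) {
    pv <- setNames(perf$mean_r[perf$predictor == pr], perf$gene_id[perf$predictor == pr])
    wp <- rank_well_predicted(perf, pr, K1)
    gene_lists$well_predicted[[pr]] <- wp
    for (dt in names(detectors)) {
      sc <- scev_scores[[dt]]
      hv <- select_hvgs(sc, K1)$hvg
      gene_lists$hvg[[dt]] <- hv
      wil <- wilcoxon_hvg_test(pv, hv)
      spr <- spearman_perf_scev(pv, sc)
      mm <- matched_mean_sensitivity(pv, hv, sc, gene_means)
      tests[[paste(pr, dt)]] <- data.frame(
        predictor = pr, detector = dt,
        wilcoxon_U = wil$statistic, wilcoxon_p = wil$p_value,
        median_r_hvg = wil$median_hvg, median_r_non_hvg = wil$median_non_hvg,
        spearman_rho = spr$rho, spearman_p = spr$p_value,
        matched_mean_p = mm$p_value, stringsAsFactors = FALSE)
      for (k2 in K2) {
        hv2 <- select_hvgs(sc, k2)$hvg
        fi <- overlap_fisher(wp, hv2, q)
        overlaps[[paste(pr, dt, k2)]] <- data.frame(
          predictor = pr, detector = dt, K1 = K1, K2 = k2,
          overlap = fi$overlap, overlap_pct = 100 * fi$overlap / min(K1, k2),
          odds_ratio = fi$odds_ratio, fisher_p = fi$p_value,
          stringsAsFactors = FALSE)
      }
      gene_lists$overlap[[paste(pr, dt, sep = "_")]] <-
        intersect(wp, select_hvgs(sc, K1)$hvg)
    }
  }
  tests <- do.call(rbind, tests); rownames(tests) <- NULL
  overlaps <- do.call(rbind, overlaps); rownames(overlaps) <- NULL
  ntest <- nrow(tests) * 3 + nrow(overlaps)
  tests$wilcoxon_p_bonferroni <- pmin(tests$wilcoxon_p * ntest, 1)
  overlaps$fisher_p_bonferroni <- pmin(overlaps$fisher_p * ntest, 1)
  structure(list(tests = tests, overlaps = overlaps, gene_lists = gene_lists,
                 K1 = K1, K2 = K2, q = q),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 3, ...) {
  cat(sprintf("comparison_report: %d genes, K1 = %d well-predicted\n", x$q, x$K1))
  cat("\nHVG vs non-HVG performance (one-sided):\n")
  print(format(x$tests, digits = digits), row.names = FALSE)
  cat("\nOverlap of well-predicted genes with HVGs:\n")
  print(format(x$overlaps, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write a comparison report to TSV files and a text summary
#'
#' @param report a `comparison_report`.
#' @param dir output directory (created if missing).
#' @return invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(report$tests, file.path(dir, "comparison_tests.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$overlaps, file.path(dir, "comparison_overlaps.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (pr in names(report$gene_lists$well_predicted)) {
    writeLines(report$gene_lists$well_predicted[[pr]],
               file.path(dir, sprintf("well_predicted_%s.txt", pr)))
  }
  for (dt in names(report$gene_lists$hvg)) {
    writeLines(report$gene_lists$hvg[[dt]],
               file.path(dir, sprintf("hvg_%s.txt", dt)))
  }
  con <- file.path(dir, "summary.txt")
  txt <- utils::capture.output(print(report))
  writeLines(txt, con)
  invisible(dir)
}
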