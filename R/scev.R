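# Per-gene single-cell expression variability (scEV) scoring and HVG
# selection: the standardized-variance (vst) detector and the 3-D
# spline-distance detector.

#' Standardized-variance (vst) scEV score
#'
#' A loess curve (span 0.3, degree 2) is fitted to log10 variance versus
#' log10 mean of the raw counts across genes; each gene's counts are
#' standardized with its observed mean and the curve-predicted standard
#' deviation, standardized values are clipped at `sqrt(N)`, and the score is
#' the variance of the clipped values — the variance the gene retains after
#' the mean-variance trend is removed. Genes with zero variance score 0.
#'
#' @param counts raw cell-by-gene count matrix of the retained homogeneous
#'   cells (dense or sparse).
#' @param span,degree loess settings, defaults 0.3 and 2.
#' @return named numeric score per gene (higher = more variable).
#' @export
vst_scev <- function(counts, span = 0.3, degree = 2) {
  x <- as.matrix(counts)
  N <- nrow(x)
  m <- colMeans(x)
  v <- apply(x, 2, var)
  ok <- v > 0 & m > 0
  if (sum(ok) < 10) sl_stop("vst_scev: need at least 10 genes with positive variance")
  fit <- loess(log10(v[ok]) ~ log10(m[ok]), span = span, degree = degree)
  sd_hat <- sqrt(10^predict(fit, log10(m[ok])))
  z <- sweep(x[, ok, drop = FALSE], 2, m[ok], "-")
  z <- sweep(z, 2, sd_hat, "/")
  z <- pmin(z, sqrt(N))
  score <- numeric(ncol(x))
  score[ok] <- colSums(z^2) / (N - 1)
  setNames(score, colnames(x))
}

#' Spline-distance scEV score (dropout rate, log mean, log CV)
#'
#' Each gene is placed in a 3-D space of dropout rate (fraction of zero
#' counts), log mean expression and log coefficient of variation; the three
#' coordinates are z-scored across genes, a cubic smoothing spline of each
#' coordinate is fitted against the normalized log-mean rank, and the score
#' is the Euclidean distance of the gene to its fitted curve point, signed
#' by whether the gene lies above (+) or below (-) the curve in the
#' variability coordinate — so only genes more variable than the trend rank
#' as HVGs. Genes with zero variance score 0 and are excluded from the fit.
#'
#' @param counts raw cell-by-gene count matrix of the retained cells.
#' @param variability_coord third coordinate: `"log_cv"` (default) or
#'   `"log_variance"`.
#' @param spar optional smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` (default) selects stiffness by
#'   generalized cross-validation. `df` offers a fixed-stiffness fallback.
#' @param df optional fixed equivalent degrees of freedom for the spline.
#' @return named numeric signed score per gene.
#' @export
splinefit_scev <- function(counts, variability_coord = c("log_cv", "log_variance"),
                           spar = NULL, df = NULL) {
  variability_coord <- match.arg(variability_coord)
  x <- as.matrix(counts)
  m <- colMeans(x)
  v <- apply(x, 2, var)
  drop_rate <- colMeans(x == 0)
  ok <- v > 0 & m > 0
  if (sum(ok) < 10) sl_stop("splinefit_scev: need at least 10 genes with positive variance")
  vc <- if (variability_coord == "log_cv") log(sqrt(v[ok]) / m[ok]) else log(v[ok])
  coords <- cbind(dropout = drop_rate[ok], log_mean = log(m[ok]), variability = vc)
  zc <- scale(coords)
  zc[, attr(zc, "scaled:scale") == 0] <- 0
  rk <- rank(coords[, "log_mean"], ties.method = "average")
  tt <- (rk - 1) / (length(rk) - 1)
  fitted <- sapply(colnames(coords), function(j) {
    sp <- if (!is.null(df)) smooth.spline(tt, zc[, j], df = df)
          else if (!is.null(spar)) smooth.spline(tt, zc[, j], spar = spar)
          else smooth.spline(tt, zc[, j])
    predict(sp, tt)$y
  })
  dist <- sqrt(rowSums((zc - fitted)^2))
  sgn <- sign(zc[, "variability"] - fitted[, "variability"])
  sgn[sgn == 0] <- 1
  score <- numeric(ncol(x))
  score[ok] <- sgn * dist
  setNames(score, colnames(x))
}

#' Select highly variable genes from scEV scores
#'
#' Genes are ordered by score, descending, ties broken by gene id ascending;
#' exactly `K` genes are flagged HVG, the complement is non-HVG.
#'
#' @param scores named numeric scEV scores.
#' @param K number of HVGs (0 <= K <= number of genes).
#' @return list with character vectors `hvg` and `non_hvg`.
#' @export
select_hvgs <- function(scores, K) {
  ids <- names(scores)
  if (is.null(ids)) sl_stop("select_hvgs: scores must be named by gene id")
  if (K > length(scores)) sl_stop("K (%d) exceeds the number of genes (%d)", K, length(scores))
  ord <- order(-scores, ids)
  hvg <- ids[ord][seq_len(K)]
  list(hvg = hvg, non_hvg = setdiff(ids, hvg))
}

#' Assemble the per-gene scEV table
#'
#' Runs both detectors on the raw counts and flags HVGs at the configured
#' `K` for each.
#'
#' @param counts raw cell-by-gene count matrix of the retained cells.
#' @param K number of HVGs to flag per detector.
#' @param variability_coord see [splinefit_scev()].
#' @return a `scev_table` data frame: per gene, mean expression, dropout
#'   rate, both scores, per-detector rank (1 = most variable) and HVG flag.
#' @export
scev_table <- function(counts, K = 200, variability_coord = "log_cv") {
  x <- as.matrix(counts)
  vst <- vst_scev(x)
  spl <- splinefit_scev(x, variability_coord = variability_coord)
  ids <- colnames(x)
  vr <- match(ids, ids[order(-vst, ids)])
  sr <- match(ids, ids[order(-spl, ids)])
  out <- data.frame(
    gene_id = ids,
    mean_expression = colMeans(x),
    dropout_rate = colMeans(x == 0),
    vst_score = unname(vst),
    splinefit_score = unname(spl),
    vst_rank = vr,
    splinefit_rank = sr,
    vst_hvg = vr <= K,
    splinefit_hvg = sr <= K,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("scev_table", "data.frame")
  attr(out, "K") <- K
  out
}

#' @export
print.scev_table <- function(x, ...) {
  cat(sprintf("scev_table: %d genes, K = %d HVGs per detector\n",
              nrow(x), attr(x, "K")))
  cat(sprintf("  detector agreement (Spearman of scores): %.3f\n",
              cor(x$vst_score, x$splinefit_score, method = "spearman")))
  cat(sprintf("  HVG overlap between detectors: %d/%d\n",
              sum(x$vst_hvg & x$splinefit_hvg), attr(x, "K")))
  invisible(x)
}
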