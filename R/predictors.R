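# Seven per-gene models predicting normalized expression from transformed
# accessibility: five global (KNN, lasso, peak-fusion lasso, boosted trees,
# feed-forward net) and two local (gene activity score, local-window lasso).

#' Pearson correlation with a defined degenerate value
#'
#' Returns the Pearson correlation of `truth` and `pred`; when either vector
#' is constant the value is defined as 0 and flagged via the `"degenerate"`
#' attribute, so no NaN ever escapes the evaluation harness.
#'
#' @param truth,pred numeric vectors of equal length.
#' @return a single number in \[-1, 1\] with attribute `degenerate`.
#' @export
pearson_r <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (sd(truth) == 0 || sd(pred) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(cor(truth, pred), degenerate = FALSE)
}

#' Support-overlap similarity between two cells' peak vectors
#'
#' With `a1` the number of peaks nonzero in both cells, `a2` nonzero only in
#' the first and `a3` nonzero only in the second, the similarity is
#' `a1 / (a1 + a2 + a3)` (the Jaccard index of the nonzero supports). Two
#' all-zero cells have similarity 0 by convention (with a warning).
#'
#' @param cell_a,cell_b numeric peak vectors over the same peak set.
#' @return similarity in \[0, 1\].
#' @export
knn_similarity <- function(cell_a, cell_b) {
  stopifnot(length(cell_a) == length(cell_b))
  na <- cell_a > 0; nb <- cell_b > 0
  a1 <- sum(na & nb)
  denom <- a1 + sum(na & !nb) + sum(!na & nb)
  if (denom == 0) {
    sl_warn("knn_similarity: both cells are all-zero; similarity defined as 0")
    return(0)
  }
  a1 / denom
}

# Jaccard similarities of all test cells against all training cells, and the
# k nearest training cells per test cell (ties broken by training-cell order).
knn_neighbors <- function(train_atac, test_atac, k) {
  tb <- as(train_atac > 0, "CsparseMatrix") * 1
  qb <- as(test_atac > 0, "CsparseMatrix") * 1
  inter <- as.matrix(qb %*% Matrix::t(tb))
  uni <- outer(Matrix::rowSums(qb), Matrix::rowSums(tb), "+") - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  if (any(uni == 0)) sl_warn("knn_neighbors: all-zero cell pair; similarity set to 0")
  t(apply(sim, 1, function(s) order(-s)[seq_len(k)]))
}

#' KNN prediction of one gene's expression in test cells
#'
#' Each test cell's prediction is the unweighted mean of the gene's
#' normalized expression over its `k` most similar training cells (by
#' [knn_similarity()] on the nonzero peak supports), ties broken by
#' training-cell order.
#'
#' @param train_atac,test_atac transformed cell-by-peak matrices.
#' @param train_rna_col numeric vector of the gene's normalized expression
#'   in the training cells.
#' @param k number of neighbours (`0 < k <=` number of training cells).
#' @return numeric vector of predictions, one per test cell.
#' @export
knn_predict <- function(train_atac, train_rna_col, test_atac, k) {
  if (k <= 0) sl_stop("knn_predict: k must be positive")
  if (k > nrow(train_atac)) {
    sl_stop("knn_predict: k (%d) exceeds the number of training cells (%d)",
            k, nrow(train_atac))
  }
  nb <- knn_neighbors(train_atac, test_atac, k)
  unname(apply(nb, 1, function(idx) mean(train_rna_col[idx])))
}

# Predict all genes at once: sparse averaging operator over the neighbour sets.
knn_predict_all <- function(train_atac, train_rna, test_atac, k) {
  nb <- knn_neighbors(train_atac, test_atac, k)
  W <- sparseMatrix(i = rep(seq_len(nrow(nb)), each = k), j = as.vector(t(nb)),
                    x = 1 / k, dims = c(nrow(nb), nrow(train_atac)))
  as.matrix(W %*% train_rna)
}

#' Lasso regression with BIC model selection
#'
#' Fits a descending lasso path (`nlambda` values, log-spaced from the
#' smallest penalty that zeroes every coefficient down to
#' `lambda_min_ratio` times it) on internally standardized predictors
#' (constant columns dropped) and picks the penalty minimizing the Gaussian
#' BIC `n*log(RSS/n) + df*log(n)` (df = number of nonzero coefficients)
#' among path models with at least `min_selected` and at most `n/2` selected
#' predictors. The upper bound guards against the near-interpolating tail of
#' the path where the Gaussian BIC degenerates when predictors far outnumber
#' cells. If no path model reaches `min_selected`, the smallest-penalty
#' model is returned with a warning.
#'
#' @param x predictor matrix (cells x predictors), dense or sparse.
#' @param y response vector (one gene's normalized expression).
#' @param min_selected minimum number of selected predictors, default 5.
#' @param nlambda path length, default 50.
#' @param lambda_min_ratio smallest penalty as a fraction of the largest.
#' @return an object of class `lasso_bic` with elements `intercept`, `beta`
#'   (length `ncol(x)`, original scale), `selected` (column indices of
#'   nonzero coefficients), `lambda`, `path` (per-penalty df and BIC),
#'   `degenerate` and `constraint_met`; supports `predict()` and `coef()`.
#' @export
fit_lasso_bic <- function(x, y, min_selected = 5, nlambda = 50,
                          lambda_min_ratio = 1e-3) {
  n <- nrow(x)
  if (n < 2) sl_stop("fit_lasso_bic: need at least 2 training cells")
  p <- ncol(x)
  degenerate_fit <- function(flagged) {
    structure(list(intercept = mean(y), beta = numeric(p), selected = integer(0),
                   lambda = NA_real_, path = NULL, degenerate = flagged,
                   constraint_met = FALSE), class = "lasso_bic")
  }
  if (sd(y) == 0) return(degenerate_fit(TRUE))
  cm <- Matrix::colMeans(x)
  csd <- sqrt(pmax(Matrix::colMeans(x^2) - cm^2, 0) * n / (n - 1))
  keep <- which(csd > 1e-12)
  if (length(keep) == 0) return(degenerate_fit(TRUE))
  if (length(keep) == 1) {
    xx <- as.numeric(x[, keep]); b <- cov(xx, y) / var(xx)
    beta <- numeric(p); beta[keep] <- b
    return(structure(list(intercept = mean(y) - b * mean(xx), beta = beta,
                          selected = keep, lambda = NA_real_, path = NULL,
                          degenerate = FALSE, constraint_met = min_selected <= 1),
                     class = "lasso_bic"))
  }
  xk <- x[, keep, drop = FALSE]
  yc <- y - mean(y)
  lmax <- max(abs(as.vector(Matrix::crossprod(xk, yc))) / csd[keep]) / n
  lam <- exp(seq(log(lmax), log(lambda_min_ratio * lmax), length.out = nlambda))
  fit <- glmnet::glmnet(xk, y, family = "gaussian", lambda = lam,
                        standardize = TRUE)
  pred <- predict(fit, xk)
  rss <- colSums((y - pred)^2)
  df <- fit$df
  bic <- n * log(pmax(rss, 1e-12) / n) + df * log(n)
  min_sel <- min(min_selected, length(keep))
  cand <- which(df >= min_sel & df <= n / 2)
  if (!length(cand)) cand <- which(df >= min_sel)
  constraint_met <- length(cand) > 0
  if (!constraint_met) {
    sl_warn("fit_lasso_bic: no path model selects >= %d predictors; using the smallest penalty",
            min_sel)
    j <- length(fit$lambda)
  } else {
    j <- cand[which.min(bic[cand])]
  }
  beta <- numeric(p)
  beta[keep] <- as.numeric(fit$beta[, j])
  structure(list(intercept = unname(fit$a0[j]), beta = beta,
                 selected = which(beta != 0), lambda = fit$lambda[j],
                 path = data.frame(lambda = fit$lambda, df = df, bic = bic),
                 degenerate = FALSE, constraint_met = constraint_met),
            class = "lasso_bic")
}

#' @export
predict.lasso_bic <- function(object, newx, ...) {
  nz <- object$selected
  out <- rep(object$intercept, nrow(newx))
  if (length(nz)) {
    out <- out + as.vector(newx[, nz, drop = FALSE] %*% object$beta[nz])
  }
  out
}

#' @export
coef.lasso_bic <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta)
}

#' @export
print.lasso_bic <- function(x, ...) {
  cat(sprintf("lasso_bic fit: %d selected predictor(s), lambda = %s%s\n",
              length(x$selected),
              if (is.na(x$lambda)) "NA" else format(x$lambda, digits = 3),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Aggregate peak counts into fixed genomic windows
#'
#' Each peak is assigned to the bin `(chrom, floor(start / window_bp))`
#' (half-open windows); the fused value of a bin in a cell is the sum of the
#' cell's values over the bin's peaks. Bins containing no peak are omitted.
#' Per-cell total signal is conserved.
#'
#' @param atac cell-by-peak matrix.
#' @param peaks peak interval data frame aligned to `colnames(atac)`.
#' @param window_bp bin width in bp, default 100 kb.
#' @return list with `matrix` (cells x bins), `bins` (data frame of chrom,
#'   start, end), and `peak_bin` (bin index of every peak).
#' @export
peak_fusion <- function(atac, peaks, window_bp = 1e5) {
  if (window_bp <= 0) sl_stop("peak_fusion: window_bp must be positive")
  stopifnot(nrow(peaks) == ncol(atac))
  bin <- floor(peaks$start / window_bp)
  key <- paste(peaks$chrom, bin, sep = ":")
  ub <- unique(data.frame(chrom = peaks$chrom, bin = bin, key = key,
                          stringsAsFactors = FALSE))
  ub <- ub[order(ub$chrom, ub$bin), , drop = FALSE]
  j <- match(key, ub$key)
  M <- sparseMatrix(i = seq_along(j), j = j, x = 1,
                    dims = c(ncol(atac), nrow(ub)))
  fused <- atac %*% M
  fused <- as(fused, "CsparseMatrix")
  colnames(fused) <- ub$key
  rownames(fused) <- rownames(atac)
  bins <- data.frame(chrom = ub$chrom, start = ub$bin * window_bp,
                     end = (ub$bin + 1) * window_bp, stringsAsFactors = FALSE)
  list(matrix = fused, bins = bins, peak_bin = j)
}

#' Lasso with BIC selection on peak-fusion predictors
#'
#' Applies [peak_fusion()] and fits [fit_lasso_bic()] on the fused matrix.
#'
#' @inheritParams peak_fusion
#' @inheritParams fit_lasso_bic
#' @return an object of class `peakfusion_lasso` wrapping the `lasso_bic`
#'   fit and the fusion map; `predict()` fuses new data with the same bins.
#' @export
fit_peakfusion_lasso <- function(atac, peaks, y, window_bp = 1e5,
                                 min_selected = 5, ...) {
  fus <- peak_fusion(atac, peaks, window_bp)
  fit <- fit_lasso_bic(fus$matrix, y, min_selected = min_selected, ...)
  structure(list(fit = fit, bins = fus$bins, window_bp = window_bp,
                 peak_bin = fus$peak_bin, n_peaks = ncol(atac)),
            class = "peakfusion_lasso")
}

#' @export
predict.peakfusion_lasso <- function(object, newatac, ...) {
  M <- sparseMatrix(i = seq_along(object$peak_bin), j = object$peak_bin, x = 1,
                    dims = c(object$n_peaks, nrow(object$bins)))
  predict(object$fit, newatac %*% M)
}

#' Gradient-boosted regression trees
#'
#' A boosted-tree ensemble with `n_trees` rounds, squared-error loss and
#' library defaults otherwise; deterministic given the seed.
#'
#' @param x predictor matrix.
#' @param y response vector.
#' @param n_trees number of boosting rounds, default 10.
#' @param seed integer seed.
#' @return an object of class `gbt_model` supporting `predict()`.
#' @export
fit_gbt <- function(x, y, n_trees = 10, seed = 1) {
  if (n_trees < 1) sl_stop("fit_gbt: n_trees must be >= 1")
  set.seed(seed)
  booster <- xgboost::xgboost(
    x = as.matrix(x), y = y, nrounds = n_trees,
    objective = "reg:squarederror", nthreads = 1, verbosity = 0)
  structure(list(booster = booster), class = "gbt_model")
}

#' @export
predict.gbt_model <- function(object, newx, ...) {
  as.numeric(predict(object$booster, as.matrix(newx)))
}

relu <- function(z) pmax(z, 0)

#' Feed-forward neural network predictor
#'
#' A fully connected net `p -> 128 -> 64 -> 1` (configurable hidden sizes)
#' with ReLU activations, inverted dropout after each hidden layer during
#' training, mean-squared-error loss, and Adam updates on shuffled
#' mini-batches. Inputs are min-max scaled to \[0, 1\] with training-set
#' ranges; at prediction time new values are clipped into \[0, 1\].
#' Deterministic given the seed. Intended for fused-peak predictors.
#'
#' @param x training predictor matrix.
#' @param y response vector.
#' @param hidden hidden layer sizes, default `c(128, 64)`.
#' @param dropout dropout rate after each hidden layer, default 0.2.
#' @param epochs,batch_size,lr optimisation settings (30, 64, 1e-3).
#' @param seed integer seed (weights, dropout, shuffling).
#' @return an object of class `mnn_model` supporting `predict()`.
#' @export
fit_mnn <- function(x, y, hidden = c(128, 64), dropout = 0.2, epochs = 30,
                    batch_size = 64, lr = 1e-3, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) sl_stop("fit_mnn: need at least 2 training cells")
  set.seed(seed)
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  rng <- hi - lo; rng[rng == 0] <- 1
  xs <- sweep(sweep(x, 2, lo), 2, rng, "/")

  sizes <- c(ncol(x), hidden, 1)
  L <- length(sizes) - 1
  W <- lapply(seq_len(L), function(l) {
    matrix(rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1])
  })
  b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
  # start at the bias-only solution: zero output weights, output bias mean(y)
  W[[L]][] <- 0
  b[[L]][] <- mean(y)
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(z) z * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0

  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1, n)]
      xb <- xs[idx, , drop = FALSE]; yb <- y[idx]; m <- length(idx)
      # forward
      a <- vector("list", L + 1); a[[1]] <- xb
      masks <- vector("list", L)
      for (l in seq_len(L)) {
        z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
        if (l < L) {
          h <- relu(z)
          mask <- matrix(runif(length(h)) >= dropout, nrow(h), ncol(h)) / (1 - dropout)
          masks[[l]] <- mask * (z > 0)   # combined ReLU + dropout derivative factor
          a[[l + 1]] <- h * mask
        } else {
          a[[l + 1]] <- z
        }
      }
      # backward (MSE)
      delta <- 2 * (a[[L + 1]] - yb) / m
      for (l in rev(seq_len(L))) {
        gW <- crossprod(a[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) delta <- (delta %*% t(W[[l]])) * masks[[l - 1]]
        t_step <- t_step + 1
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        cor1 <- 1 - beta1^t_step; cor2 <- 1 - beta2^t_step
        W[[l]] <- W[[l]] - lr * (mW[[l]] / cor1) / (sqrt(vW[[l]] / cor2) + eps)
        b[[l]] <- b[[l]] - lr * (mb[[l]] / cor1) / (sqrt(vb[[l]] / cor2) + eps)
      }
    }
  }
  structure(list(W = W, b = b, lo = lo, rng = rng, hidden = hidden),
            class = "mnn_model")
}

#' @export
predict.mnn_model <- function(object, newx, ...) {
  xs <- sweep(sweep(as.matrix(newx), 2, object$lo), 2, object$rng, "/")
  xs <- pmin(pmax(xs, 0), 1)
  a <- xs
  L <- length(object$W)
  for (l in seq_len(L)) {
    a <- sweep(a %*% object$W[[l]], 2, object$b[[l]], "+")
    if (l < L) a <- relu(a)
  }
  as.numeric(a)
}

#' Exponential distance weight of the gene activity score
#'
#' `exp(-|distance| / 5000) + exp(-1)`, where distance is measured between
#' the start of the target gene and the start of the peak. Equals
#' `1 + exp(-1)` at distance 0 and decays towards `exp(-1)`.
#'
#' @param distance numeric distance(s) in bp (sign ignored).
#' @return numeric weight(s).
#' @export
distance_weight <- function(distance) {
  exp(-abs(distance) / 5000) + exp(-1)
}

#' Inverse-gene-size factors rescaled to \[1, 5\]
#'
#' The reciprocal of each gene's size, linearly rescaled across all genes so
#' the smallest gene maps to 5 and the largest to 1. When all genes have the
#' same size the scale collapses and every factor is 3 (the midpoint).
#'
#' @param genes gene annotation data frame with `gene_id` and `size`.
#' @return named numeric vector of factors.
#' @export
gene_size_factors <- function(genes) {
  inv <- 1 / genes$size
  rng <- range(inv)
  f <- if (diff(rng) == 0) rep(3, length(inv)) else 1 + 4 * (inv - rng[1]) / diff(rng)
  setNames(f, genes$gene_id)
}

#' Gene activity score from nearby accessibility peaks
#'
#' For each peak on the gene's chromosome whose start lies within
#' `window_bp` of the gene start, the distance weight [distance_weight()] is
#' multiplied by the gene's inverse-size factor (see [gene_size_factors()])
#' and by the cell's transformed peak value; the score is the sum over those
#' peaks. Unsupervised: no training, evaluated directly on any cells. A gene
#' with no peak in its window gets all-zero scores, flagged via the
#' `"empty_window"` attribute (its Pearson correlation then degenerates
#' to 0).
#'
#' @param atac transformed cell-by-peak matrix.
#' @param peaks peak interval data frame aligned to `colnames(atac)`.
#' @param gene one gene's annotation (single-row data frame or list with
#'   `chrom`, `start`).
#' @param size_factor the gene's rescaled inverse-size factor.
#' @param window_bp locality window, default 1.2 Mbp (start-to-start).
#' @return numeric score per cell.
#' @export
gene_score <- function(atac, peaks, gene, size_factor, window_bp = 1.2e6) {
  d <- gene$start - peaks$start
  idx <- which(peaks$chrom == gene$chrom & abs(d) <= window_bp)
  if (!length(idx)) {
    return(structure(numeric(nrow(atac)), empty_window = TRUE))
  }
  w <- distance_weight(d[idx]) * size_factor
  structure(as.vector(atac[, idx, drop = FALSE] %*% w), empty_window = FALSE)
}

# Sparse peaks-by-genes weight operator so all gene scores come from one
# matrix product.
gene_score_operator <- function(peaks, genes, window_bp = 1.2e6) {
  sf <- gene_size_factors(genes)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (g in seq_len(nrow(genes))) {
    d <- genes$start[g] - peaks$start
    idx <- which(peaks$chrom == genes$chrom[g] & abs(d) <= window_bp)
    if (!length(idx)) next
    ii <- c(ii, idx); jj <- c(jj, rep(g, length(idx)))
    xx <- c(xx, distance_weight(d[idx]) * sf[g])
  }
  sparseMatrix(i = ii, j = jj, x = xx, dims = c(nrow(peaks), nrow(genes)),
               dimnames = list(NULL, genes$gene_id))
}

#' Local-window lasso (LocReg)
#'
#' Fits [fit_lasso_bic()] restricted to peaks whose start lies within
#' `window_bp` of the gene start on the same chromosome; the
#' minimum-selection constraint is relaxed to `min(min_selected, number of
#' window peaks)`. With no window peaks the fit degenerates to the training
#' mean (test correlation then 0 by the degeneracy rule).
#'
#' @param atac_train transformed training cell-by-peak matrix.
#' @param peaks peak interval data frame aligned to `colnames(atac_train)`.
#' @param gene one gene's annotation.
#' @param y training response vector.
#' @param window_bp locality window, default 1.2 Mbp.
#' @param min_selected see [fit_lasso_bic()].
#' @param ... passed on to [fit_lasso_bic()].
#' @return an object of class `locreg_fit` supporting `predict()` (which
#'   expects the full peak matrix and subsets the window internally).
#' @export
fit_locreg <- function(atac_train, peaks, gene, y, window_bp = 1.2e6,
                       min_selected = 5, ...) {
  idx <- which(peaks$chrom == gene$chrom &
                 abs(gene$start - peaks$start) <= window_bp)
  if (!length(idx)) {
    fit <- structure(list(intercept = mean(y), beta = numeric(0),
                          selected = integer(0), lambda = NA_real_, path = NULL,
                          degenerate = TRUE, constraint_met = FALSE),
                     class = "lasso_bic")
    return(structure(list(fit = fit, window_idx = integer(0)),
                     class = "locreg_fit"))
  }
  fit <- fit_lasso_bic(atac_train[, idx, drop = FALSE], y,
                       min_selected = min(min_selected, length(idx)), ...)
  structure(list(fit = fit, window_idx = idx), class = "locreg_fit")
}

#' @export
predict.locreg_fit <- function(object, newatac, ...) {
  if (!length(object$window_idx)) {
    return(rep(object$fit$intercept, nrow(newatac)))
  }
  predict(object$fit, newatac[, object$window_idx, drop = FALSE])
}
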