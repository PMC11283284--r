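# Train/test split plan, per-gene evaluation, performance table, ranking.

#' Build a reproducible train/test split plan
#'
#' Cells are randomly divided into a `train_fraction` training set and the
#' complementary test set, `n_splits` times with distinct derived seeds. The
#' same plan is reused for every gene and every predictor within a run so
#' model comparisons are paired.
#'
#' @param n_cells number of cells.
#' @param n_splits number of repeated splits, default 5.
#' @param train_fraction training fraction, default 0.7.
#' @param seed base seed; split `i` uses `seed + i - 1`.
#' @return an object of class `split_plan`: lists `train` and `test` of cell
#'   index vectors plus the settings.
#' @export
make_split_plan <- function(n_cells, n_splits = 5, train_fraction = 0.7,
                            seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    sl_stop("train_fraction must lie strictly between 0 and 1")
  }
  seeds <- seed + seq_len(n_splits) - 1L
  train <- test <- vector("list", n_splits)
  for (i in seq_len(n_splits)) {
    set.seed(seeds[i])
    tr <- sort(sample.int(n_cells, round(train_fraction * n_cells)))
    te <- setdiff(seq_len(n_cells), tr)
    if (length(te) < 3) sl_stop("split %d leaves fewer than 3 test cells", i)
    train[[i]] <- tr; test[[i]] <- te
  }
  structure(list(train = train, test = test, seeds = seeds,
                 n_splits = n_splits, train_fraction = train_fraction),
            class = "split_plan")
}

model_names <- function() c("knn", "lasso", "peakfusion", "gbt", "mnn", "gs", "locreg")

#' Evaluate predictors over the split plan
#'
#' For every requested model, gene and split: fit on the training cells
#' (no-op for the unsupervised gene score), predict the test cells, and
#' record the Pearson correlation of true and predicted expression (0 when
#' either vector is constant). Supervised models never see test-cell
#' expression; scalers and paths are computed on training cells only.
#'
#' @param prep an `scev_prep` from [preprocess_multiome()].
#' @param models character vector of model names among `knn`, `lasso`,
#'   `peakfusion`, `gbt`, `mnn`, `gs`, `locreg`.
#' @param plan a [make_split_plan()]; defaults to the plan implied by `cfg`.
#' @param cfg an [scev_config()] providing hyperparameters.
#' @param genes optional subset of gene ids to evaluate.
#' @return a `performance_table` data frame: one row per (gene, predictor)
#'   with per-split correlations `split_1..n`, their `mean_r`, and the
#'   number of degenerate folds.
#' @export
evaluate_predictors <- function(prep, models = c("knn", "lasso", "gs", "locreg"),
                                plan = NULL, cfg = prep$config, genes = NULL) {
  stopifnot(inherits(prep, "scev_prep"))
  bad <- setdiff(models, model_names())
  if (length(bad)) sl_stop("unknown model(s): %s", paste(bad, collapse = ", "))
  X <- prep$atac_tfidf
  Y <- as.matrix(prep$rna_norm)
  peaks <- prep$multiome$peaks
  gtab <- prep$multiome$genes
  if (is.null(genes)) genes <- gtab$gene_id
  gidx <- match(genes, gtab$gene_id)
  if (anyNA(gidx)) sl_stop("unknown gene id(s): %s",
                           paste(genes[is.na(gidx)], collapse = ", "))
  N <- nrow(X)
  if (is.null(plan)) {
    plan <- make_split_plan(N, cfg$n_splits, cfg$train_fraction, cfg$seed)
  }
  S <- plan$n_splits

  fus <- NULL
  if (any(c("peakfusion", "mnn") %in% models)) {
    fus <- peak_fusion(X, peaks, cfg$fusion_window_bp)
  }
  gs_all <- NULL
  if ("gs" %in% models) {
    op <- gene_score_operator(peaks, gtab, cfg$local_window_bp)
    gs_all <- as.matrix(X %*% op)
  }
  locreg_windows <- NULL
  if ("locreg" %in% models) {
    locreg_windows <- lapply(gidx, function(g) {
      which(peaks$chrom == gtab$chrom[g] &
              abs(gtab$start[g] - peaks$start) <= cfg$local_window_bp)
    })
  }

  r <- array(NA_real_, c(length(gidx), length(models), S),
             dimnames = list(genes, models, NULL))
  for (s in seq_len(S)) {
    tr <- plan$train[[s]]; te <- plan$test[[s]]
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    Ftr <- if (!is.null(fus)) fus$matrix[tr, , drop = FALSE]
    Fte <- if (!is.null(fus)) fus$matrix[te, , drop = FALSE]
    for (mod in models) {
      preds <- switch(
        mod,
        knn = knn_predict_all(Xtr, Y[tr, gidx, drop = FALSE], Xte,
                              min(cfg$knn_k, length(tr))),
        gs = gs_all[te, gidx, drop = FALSE],
        {
          out <- matrix(NA_real_, length(te), length(gidx))
          for (j in seq_along(gidx)) {
            g <- gidx[j]; ytr <- Y[tr, g]
            out[, j] <- switch(
              mod,
              lasso = predict(fit_lasso_bic(Xtr, ytr,
                                            min_selected = cfg$min_selected_peaks,
                                            nlambda = cfg$lasso_nlambda,
                                            lambda_min_ratio = cfg$lasso_lambda_min_ratio),
                              Xte),
              peakfusion = predict(fit_lasso_bic(Ftr, ytr,
                                                 min_selected = cfg$min_selected_peaks,
                                                 nlambda = cfg$lasso_nlambda,
                                                 lambda_min_ratio = cfg$lasso_lambda_min_ratio),
                                   Fte),
              gbt = predict(fit_gbt(Xtr, ytr, n_trees = cfg$n_trees,
                                    seed = cfg$seed + 7919L * s + g),
                            Xte),
              mnn = predict(fit_mnn(Ftr, ytr, hidden = cfg$mnn_hidden,
                                    dropout = cfg$mnn_dropout,
                                    epochs = cfg$mnn_epochs,
                                    batch_size = cfg$mnn_batch_size,
                                    lr = cfg$mnn_learning_rate,
                                    seed = cfg$seed + 7919L * s + g),
                            Fte),
              locreg = {
                idx <- locreg_windows[[j]]
                if (!length(idx)) rep(mean(ytr), length(te))
                else predict(fit_lasso_bic(Xtr[, idx, drop = FALSE], ytr,
                                           min_selected = min(cfg$min_selected_peaks, length(idx)),
                                           nlambda = cfg$lasso_nlambda,
                                           lambda_min_ratio = cfg$lasso_lambda_min_ratio),
                             Xte[, idx, drop = FALSE])
              })
          }
          out
        })
      for (j in seq_along(gidx)) {
        r[j, mod, s] <- as.numeric(pearson_r(Y[te, gidx[j]], preds[, j]))
      }
    }
    sl_log("evaluate_predictors: split %d/%d done", s, S)
  }

  rows <- vector("list", length(models))
  for (m in seq_along(models)) {
    rs <- matrix(r[, m, ], nrow = length(gidx))
    df <- data.frame(gene_id = genes, predictor = models[m],
                     stringsAsFactors = FALSE)
    colnames(rs) <- paste0("split_", seq_len(S))
    df <- cbind(df, rs)
    df$mean_r <- rowMeans(rs)
    df$n_degenerate <- rowSums(rs == 0)
    rows[[m]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("performance_table", "data.frame")
  attr(out, "plan") <- plan
  out
}

#' Evaluate a single gene under one predictor
#'
#' @inheritParams evaluate_predictors
#' @param gene_id the gene to evaluate.
#' @param model one model name.
#' @return list with `per_split` correlations and their `mean`.
#' @export
evaluate_gene <- function(prep, gene_id, model, plan = NULL, cfg = prep$config) {
  pt <- evaluate_predictors(prep, models = model, plan = plan, cfg = cfg,
                            genes = gene_id)
  per <- as.numeric(pt[1, grep("^split_", names(pt))])
  list(per_split = per, mean = pt$mean_r[1])
}

#' Rank genes by average prediction performance
#'
#' Genes are sorted by average test-set Pearson correlation, descending,
#' ties broken by gene id ascending; the top `K1` are the well-predicted
#' genes for that predictor.
#'
#' @param perf a `performance_table`.
#' @param predictor which predictor's column to rank on.
#' @param K1 list length (<= number of genes).
#' @return character vector of `K1` gene ids, best first.
#' @export
rank_well_predicted <- function(perf, predictor, K1) {
  sub <- perf[perf$predictor == predictor, , drop = FALSE]
  if (!nrow(sub)) sl_stop("no rows for predictor '%s'", predictor)
  if (K1 > nrow(sub)) sl_stop("K1 (%d) exceeds the number of genes (%d)", K1, nrow(sub))
  ord <- order(-sub$mean_r, sub$gene_id)
  sub$gene_id[ord][seq_len(K1)]
}

#' @export
print.performance_table <- function(x, ...) {
  cat(sprintf("performance_table: %d genes x %d predictor(s), %d splits\n",
              length(unique(x$gene_id)), length(unique(x$predictor)),
              sum(grepl("^split_", names(x)))))
  for (m in unique(x$predictor)) {
    mr <- x$mean_r[x$predictor == m]
    cat(sprintf("  %-10s mean r: median %.3f, max %.3f\n", m, median(mr), max(mr)))
  }
  invisible(x)
}
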