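# The seven predictors and the evaluation harness.

test_that("support-overlap similarity follows the a1/(a1+a2+a3) definition", {
  a <- c(1, 1, 1, 0, 0); b <- c(0, 2, 3, 4, 0)
  expect_equal(knn_similarity(a, b), 0.5)        # {1,2,3} vs {2,3,4}
  expect_equal(knn_similarity(a, a), 1)
  expect_equal(knn_similarity(c(1, 0), c(0, 2)), 0)
  expect_warning(z <- knn_similarity(c(0, 0), c(0, 0)), "all-zero")
  expect_equal(z, 0)
})

test_that("KNN neighbour sets match an all-pairs brute force on 30 cells", {
  s <- small_sim(seed = 3)
  X <- tfidf_transform(s$multiome$atac[Matrix::rowSums(s$multiome$atac) > 0, ])
  tr <- X[1:20, ]; te <- X[21:30, ]
  k <- 4
  nb <- scevlink:::knn_neighbors(tr, te, k)
  for (i in 1:10) {
    sims <- vapply(1:20, function(j) {
      knn_similarity(as.numeric(te[i, ]), as.numeric(tr[j, ]))
    }, numeric(1))
    expect_equal(sort(nb[i, ]), sort(order(-sims)[1:k]))
  }
})

test_that("KNN prediction degenerates correctly at the k boundaries", {
  s <- small_sim(seed = 3)
  X <- tfidf_transform(s$multiome$atac[Matrix::rowSums(s$multiome$atac) > 0, ])
  y <- as.numeric(normalize_rna(s$multiome$rna)[1:30, 1])
  tr <- X[1:30, ]; te <- X[31:35, ]
  # k = n_train: every prediction is the global training mean
  p_all <- knn_predict(tr, y, te, k = 30)
  expect_equal(p_all, rep(mean(y), 5))
  # a test cell identical to a training cell with k = 1 copies its expression
  p_self <- knn_predict(tr, y, tr[7, , drop = FALSE], k = 1)
  expect_equal(p_self, y[7])
  expect_error(knn_predict(tr, y, te, k = 0), "positive")
  expect_error(knn_predict(tr, y, te, k = 31), "exceeds")
})

test_that("lasso-BIC recovers a noiseless linear signal", {
  set.seed(5)
  x <- matrix(rnorm(100 * 20), 100, 20)
  y <- 3 * x[, 5] + 1
  fit <- suppressWarnings(fit_lasso_bic(x, y))  # exact fit: path never reaches 5
  expect_true(5 %in% fit$selected)
  xnew <- matrix(rnorm(50 * 20), 50, 20)
  r <- cor(predict(fit, xnew), 3 * xnew[, 5] + 1)
  expect_gt(r, 0.999)
})

test_that("the minimum-selection constraint binds for pure-noise responses", {
  set.seed(6)
  x <- matrix(rnorm(80 * 30), 80, 30)
  y <- rnorm(80)
  fit <- fit_lasso_bic(x, y, min_selected = 5)
  expect_gte(length(fit$selected), 5)
  expect_true(fit$constraint_met)
})

test_that("degenerate lasso inputs give flagged mean-only fits", {
  set.seed(6)
  x <- matrix(rnorm(40 * 6), 40, 6)
  fit <- fit_lasso_bic(x, rep(2, 40))
  expect_true(fit$degenerate)
  expect_equal(fit$intercept, 2)
  expect_equal(predict(fit, x[1:3, ]), rep(2, 3))
  # all-constant predictors
  fit2 <- fit_lasso_bic(matrix(1, 40, 3), rnorm(40))
  expect_true(fit2$degenerate)
})

test_that("peak fusion bins by floor(start/window) and conserves signal", {
  peaks <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                      start = c(50000L, 90000L, 100000L, 30000L),
                      end = c(50500L, 90500L, 100500L, 30500L), strand = ".")
  set.seed(8)
  m <- count_matrix(matrix(rpois(20, 2), 5, 4), paste0("c", 1:5), paste0("p", 1:4))
  fus <- peak_fusion(m, peaks, window_bp = 1e5)
  # peaks at 50k and 90k share bin [0, 100000); 100000 starts its own bin
  expect_equal(ncol(fus$matrix), 3)
  expect_equal(as.numeric(fus$matrix[, "chr1:0"]),
               as.numeric(m[, 1] + m[, 2]))
  expect_true("chr1:1" %in% colnames(fus$matrix))
  expect_equal(fus$bins$start[fus$bins$chrom == "chr1"], c(0, 100000))
  expect_equal(Matrix::rowSums(fus$matrix), Matrix::rowSums(m))
  # bin count equals the number of distinct (chrom, floor(start/window)) keys
  expect_equal(ncol(fus$matrix),
               nrow(unique(data.frame(peaks$chrom, floor(peaks$start / 1e5)))))
})

test_that("peak-fusion lasso reduces to plain lasso when every peak has its own bin", {
  s <- small_sim(seed = 17)
  X <- tfidf_transform(s$multiome$atac[Matrix::rowSums(s$multiome$atac) > 0, ])
  y <- as.numeric(normalize_rna(s$multiome$rna)[seq_len(nrow(X)), 3])
  peaks <- s$multiome$peaks
  # a 1-bp window puts every peak alone in its bin
  pf <- fit_peakfusion_lasso(X, peaks, y, window_bp = 1)
  plain <- fit_lasso_bic(X, y)
  expect_equal(sort(pf$fit$selected), sort(plain$selected))
  expect_equal(predict(pf, X[1:5, ]), predict(plain, X[1:5, ]), tolerance = 1e-8)
})

test_that("drivers concentrated in one bin dominate the fused fit", {
  set.seed(9)
  n <- 200
  peaks <- data.frame(chrom = "chr1",
                      start = as.integer(c(10000, 20000, 30000, 500000, 700000, 900000)),
                      end = as.integer(c(10500, 20500, 30500, 500500, 700500, 900500)),
                      strand = ".")
  x <- matrix(rpois(n * 6, 3), n, 6) * 1.0
  y <- rowSums(x[, 1:3]) + rnorm(n, 0, 0.5)   # drivers all in bin [0, 100000)
  m <- count_matrix(x, sprintf("c%03d", 1:n), paste0("p", 1:6))
  pf <- fit_peakfusion_lasso(m, peaks, y, window_bp = 1e5, min_selected = 1)
  beta <- pf$fit$beta
  expect_equal(which.max(abs(beta)), 1L)   # first bin is chr1:0
})

test_that("boosted trees honour constant targets, signal and determinism", {
  set.seed(10)
  x <- matrix(runif(150 * 8), 150, 8)
  expect_equal(predict(fit_gbt(x, rep(1.5, 150), seed = 2), x[1:4, ]),
               rep(1.5, 4), tolerance = 1e-6)
  y <- ifelse(x[, 2] > 0.5, 3, 0)
  fit <- fit_gbt(x, y, n_trees = 10, seed = 2)
  expect_gt(cor(predict(fit, x), y), 0.9)
  fit2 <- fit_gbt(x, y, n_trees = 10, seed = 2)
  expect_identical(predict(fit, x), predict(fit2, x))
  expect_error(fit_gbt(x, y, n_trees = 0), "n_trees")
})

test_that("the neural predictor fits constants exactly and linear signals well", {
  set.seed(11)
  x <- matrix(runif(300 * 5), 300, 5)
  m_const <- fit_mnn(x, rep(2.5, 300), seed = 3)
  expect_lt(max(abs(predict(m_const, x[1:10, ]) - 2.5)), 1e-2)
  beta <- c(3, -2, 1, 0.5, -1)
  xtr <- matrix(runif(400 * 5), 400, 5)
  m_lin <- fit_mnn(xtr, as.numeric(xtr %*% beta), seed = 3)
  xte <- matrix(runif(100 * 5), 100, 5)
  expect_gt(cor(predict(m_lin, xte), as.numeric(xte %*% beta)), 0.95)
  m_lin2 <- fit_mnn(xtr, as.numeric(xtr %*% beta), seed = 3)
  expect_identical(predict(m_lin, xte), predict(m_lin2, xte))
})

test_that("gene-score distance weights match their closed forms", {
  expect_equal(distance_weight(0), 1 + exp(-1))
  expect_equal(distance_weight(1.2e6), exp(-1), tolerance = 1e-9)
  # strictly decreasing where the decay term is representable next to e^-1;
  # non-increasing everywhere (the decay is absorbed by e^-1 past ~40 decay
  # lengths in double precision)
  d_near <- seq(0, 1e5, length.out = 200)
  expect_true(all(diff(distance_weight(d_near)) < 0))
  d_far <- seq(0, 1.2e6, length.out = 500)
  expect_true(all(diff(distance_weight(d_far)) <= 0))
})

test_that("gene size factors rescale inverse size to [1, 5]", {
  genes <- data.frame(gene_id = c("small", "mid", "big"),
                      size = c(1000L, 2000L, 10000L))
  f <- gene_size_factors(genes)
  expect_equal(unname(f["small"]), 5)
  expect_equal(unname(f["big"]), 1)
  expect_true(f["mid"] > 1 && f["mid"] < 5)
  same <- data.frame(gene_id = c("a", "b"), size = c(100L, 100L))
  expect_equal(unname(gene_size_factors(same)), c(3, 3))
})

test_that("a one-peak gene score matches hand arithmetic", {
  # one cell, one peak of value v at distance 5000 from the gene start,
  # gene rescaled size factor 5 -> score = (e^-1 + e^-1) * 5 * v
  v <- 2.7
  atac <- count_matrix(matrix(v, 1, 1), "c1", "p1")
  peaks <- data.frame(chrom = "chr1", start = 10000L, end = 10400L, strand = ".")
  genes <- data.frame(gene_id = c("target", "other"), chrom = "chr1",
                      start = c(15000L, 100000L), end = c(16000L, 200000L),
                      strand = "+", size = c(1000L, 100000L))
  f <- gene_size_factors(genes)
  sc <- gene_score(atac, peaks, genes[1, ], f["target"])
  expect_equal(as.numeric(sc), (exp(-1) + exp(-1)) * 5 * v)
})

test_that("empty gene-score windows are flagged and yield zero scores", {
  atac <- count_matrix(matrix(1, 2, 1), c("c1", "c2"), "p1")
  peaks <- data.frame(chrom = "chr1", start = 0L, end = 400L, strand = ".")
  far_gene <- list(chrom = "chr2", start = 100L)
  sc <- gene_score(atac, peaks, far_gene, 3)
  expect_equal(as.numeric(sc), c(0, 0))
  expect_true(attr(sc, "empty_window"))
})

test_that("local regression reduces to global lasso when the window covers all peaks", {
  s <- small_sim(seed = 17)
  keep <- Matrix::rowSums(s$multiome$atac) > 0
  X <- tfidf_transform(s$multiome$atac[keep, ])
  y <- as.numeric(normalize_rna(s$multiome$rna)[keep, 5])
  peaks <- s$multiome$peaks
  gene <- s$multiome$genes[5, ]
  # single-chromosome peaks within a huge window == global predictor set
  on_chrom <- peaks$chrom == gene$chrom
  lr <- fit_locreg(X[, on_chrom], peaks[on_chrom, ], gene, y, window_bp = 1e9)
  gl <- fit_lasso_bic(X[, on_chrom], y)
  expect_equal(sort(lr$fit$selected), sort(gl$selected))
  # empty window: no peaks on the gene's chromosome
  lr0 <- fit_locreg(X[, on_chrom], peaks[on_chrom, ],
                    list(chrom = "chr99", start = 0L), y)
  expect_equal(predict(lr0, X[1:4, on_chrom]), rep(mean(y), 4))
})

test_that("pearson_r applies the degeneracy convention", {
  expect_equal(as.numeric(pearson_r(c(1, 2, 3), c(1, 2, 3))), 1)
  d <- pearson_r(c(1, 2, 3), c(2, 2, 2))
  expect_equal(as.numeric(d), 0)
  expect_true(attr(d, "degenerate"))
})

test_that("harness per-split correlations equal a direct Pearson formula", {
  s <- small_sim(seed = 19)
  cfg <- small_cfg(seed = 19, n_splits = 2)
  prep <- preprocess_multiome(s$multiome, cfg)
  plan <- make_split_plan(nrow(prep$atac_tfidf), 2, 0.7, 19)
  g <- prep$multiome$genes$gene_id[4]
  res <- evaluate_gene(prep, g, "knn", plan = plan, cfg = cfg)
  # straight-line reimplementation of Pearson's formula on the same folds
  Y <- as.matrix(prep$rna_norm)
  for (si in 1:2) {
    tr <- plan$train[[si]]; te <- plan$test[[si]]
    pred <- knn_predict(prep$atac_tfidf[tr, ], Y[tr, g],
                        prep$atac_tfidf[te, ], cfg$knn_k)
    truth <- Y[te, g]
    n <- length(truth)
    num <- sum(truth * pred) - n * mean(truth) * mean(pred)
    den <- sqrt((sum(truth^2) - n * mean(truth)^2) * (sum(pred^2) - n * mean(pred)^2))
    expect_equal(res$per_split[si], num / den, tolerance = 1e-12)
  }
  expect_equal(res$mean, mean(res$per_split))
})

test_that("the same split plan is reused across genes and predictors", {
  plan1 <- make_split_plan(100, 3, 0.7, 5)
  plan2 <- make_split_plan(100, 3, 0.7, 5)
  expect_identical(plan1, plan2)
  expect_equal(length(unique(plan1$seeds)), 3)
  expect_error(make_split_plan(8, 2, 0.9, 1), "test cells")
})

test_that("well-predicted ranking orders by mean r then gene id", {
  perf <- data.frame(gene_id = c("gB", "gA", "gC"), predictor = "knn",
                     split_1 = c(0.5, 0.5, 0.1), mean_r = c(0.5, 0.5, 0.1))
  class(perf) <- c("performance_table", "data.frame")
  expect_equal(rank_well_predicted(perf, "knn", 3), c("gA", "gB", "gC"))
  expect_equal(rank_well_predicted(perf, "knn", 1), "gA")
  expect_error(rank_well_predicted(perf, "knn", 4), "exceeds")
})
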