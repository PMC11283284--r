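# End-to-end orchestration: preprocess -> predict -> scEV -> compare.

#' Run the accessibility-variability testing pipeline
#'
#' Applies the full analysis to a paired multiome: quality control, TF-IDF
#' and RNA normalization, optional homogeneous-cell selection, per-gene
#' prediction of expression from accessibility over repeated train/test
#' splits, scEV scoring by both detectors, and the comparison layer linking
#' prediction performance to expression variability. Everything is
#' deterministic given `cfg$seed`.
#'
#' @param pm a [paired_multiome()].
#' @param cfg an [scev_config()].
#' @param blacklist optional blacklist interval data frame.
#' @param models predictors to run, default from `cfg`.
#' @return an object of class `scev_analysis` bundling the config, QC
#'   report, preprocessed data, `performance_table`, `scev_table` and
#'   `comparison_report`; supports `print()` and `summary()`.
#' @export
scev_pipeline <- function(pm, cfg = scev_config(), blacklist = NULL,
                          models = cfg$models) {
  prep <- preprocess_multiome(pm, cfg, blacklist = blacklist)
  plan <- make_split_plan(nrow(prep$atac_tfidf), cfg$n_splits,
                          cfg$train_fraction, cfg$seed)
  perf <- evaluate_predictors(prep, models = models, plan = plan, cfg = cfg)
  scev <- scev_table(prep$multiome$rna, K = min(cfg$K, ncol(prep$multiome$rna)))
  K1 <- min(cfg$K1, ncol(prep$multiome$rna))
  report <- build_report(perf, scev, K1 = K1, K2 = cfg$K2)
  structure(list(config = cfg, prep = prep, qc_report = prep$qc_report,
                 plan = plan, performance = perf, scev = scev,
                 report = report, models = models),
            class = "scev_analysis")
}

#' @export
print.scev_analysis <- function(x, ...) {
  cat("scev_analysis\n")
  cat(sprintf("  %d cells, %d peaks, %d genes after preprocessing\n",
              x$qc_report$n_cells, x$qc_report$n_peaks,
              ncol(x$prep$multiome$rna)))
  cat(sprintf("  predictors: %s; %d splits at %.0f%% training\n",
              paste(x$models, collapse = ", "), x$plan$n_splits,
              100 * x$plan$train_fraction))
  cat(sprintf("  K1 = %d well-predicted genes per predictor\n", x$report$K1))
  cat("\n")
  print(x$report)
  invisible(x)
}

#' @export
summary.scev_analysis <- function(object, ...) {
  t <- object$report$tests
  cat("Accessibility vs expression variability: test summary\n")
  for (i in seq_len(nrow(t))) {
    cat(sprintf(
      "  %-10s x %-9s Wilcoxon p = %.3g (median r %.3f vs %.3f), Spearman rho = %.3f (p = %.3g)\n",
      t$predictor[i], t$detector[i], t$wilcoxon_p[i], t$median_r_hvg[i],
      t$median_r_non_hvg[i], t$spearman_rho[i], t$spearman_p[i]))
  }
  invisible(object$report$tests)
}
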