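# Analysis configuration: paper-scale defaults, YAML loading, validation.

config_defaults <- function() {
  list(
    # QC thresholds
    min_peaks_per_cell    = 1000,
    min_genes_per_cell    = 200,
    min_cells_per_gene    = 200,
    min_mean_expression   = 0.5,
    excluded_chroms       = c("chrX", "chrY", "chrM"),
    # homogeneous-cell selection
    n_homogeneous_cells   = 3000,
    min_feature_fraction  = 0.01,
    n_reduced_dims        = 50,
    drop_first_component  = FALSE,
    select_homogeneous    = TRUE,
    core_cell             = NULL,
    # transforms
    tfidf_scale           = 1e4,
    rna_scale             = 1e4,
    # predictors
    models                = c("knn", "lasso", "peakfusion", "gbt", "mnn", "gs", "locreg"),
    knn_k                 = 10,
    n_trees               = 10,
    mnn_hidden            = c(128, 64),
    mnn_dropout           = 0.2,
    mnn_epochs            = 30,
    mnn_batch_size        = 64,
    mnn_learning_rate     = 1e-3,
    local_window_bp       = 1200000,
    fusion_window_bp      = 100000,
    min_selected_peaks    = 5,
    lasso_nlambda         = 50,
    lasso_lambda_min_ratio = 1e-3,
    # evaluation / selection
    n_splits              = 5,
    train_fraction        = 0.7,
    K                     = 200,
    K1                    = 200,
    K2                    = c(200, 500, 1000, 2000),
    seed                  = 1
  )
}

numeric_keys <- function() {
  c("min_peaks_per_cell", "min_genes_per_cell", "min_cells_per_gene",
    "min_mean_expression", "n_homogeneous_cells", "min_feature_fraction",
    "n_reduced_dims", "tfidf_scale", "rna_scale", "knn_k", "n_trees",
    "mnn_hidden", "mnn_dropout", "mnn_epochs", "mnn_batch_size",
    "mnn_learning_rate", "local_window_bp", "fusion_window_bp",
    "min_selected_peaks", "lasso_nlambda", "lasso_lambda_min_ratio",
    "n_splits", "train_fraction", "K", "K1", "K2", "seed")
}

#' Build an analysis configuration
#'
#' Unset keys take the pipeline defaults: minimum 1000 peaks per cell, 200
#' expressed genes per cell, genes expressed in at least 200 cells with mean
#' raw count at least 0.5, 3000 homogeneous cells, k = 10 neighbours, 10
#' boosted trees, a 1.2 Mbp local window, 100 kb fusion bins, K = 200 HVGs,
#' five 70/30 train/test splits.
#'
#' @param ... named settings overriding the defaults; see
#'   [load_config()] for the full key list.
#' @return an object of class `scev_config` (a named list).
#' @export
scev_config <- function(...) {
  over <- list(...)
  cfg <- config_defaults()
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over)))) {
      sl_stop("configuration overrides must be named")
    }
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      sl_stop("unknown configuration key(s): %s\nvalid keys: %s",
              paste(unknown, collapse = ", "),
              paste(names(cfg), collapse = ", "))
    }
    for (k in names(over)) cfg[[k]] <- over[[k]]
  }
  for (k in intersect(numeric_keys(), names(cfg))) {
    v <- cfg[[k]]
    if (is.null(v)) next
    if (!is.numeric(v) || anyNA(v)) {
      sl_stop("configuration key '%s' must be numeric, got '%s'", k, paste(v, collapse = ","))
    }
  }
  pos <- c("min_peaks_per_cell", "min_genes_per_cell", "min_cells_per_gene",
           "n_homogeneous_cells", "knn_k", "n_trees", "mnn_epochs",
           "mnn_batch_size", "local_window_bp", "fusion_window_bp",
           "min_selected_peaks", "lasso_nlambda", "n_splits", "K", "K1", "K2")
  for (k in pos) {
    if (any(cfg[[k]] <= 0)) sl_stop("configuration key '%s' must be positive", k)
  }
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1) {
    sl_stop("train_fraction must lie strictly between 0 and 1 (got %g)", cfg$train_fraction)
  }
  if (cfg$min_feature_fraction < 0 || cfg$min_feature_fraction > 1) {
    sl_stop("min_feature_fraction must lie in [0, 1]")
  }
  bad <- setdiff(cfg$models, c("knn", "lasso", "peakfusion", "gbt", "mnn", "gs", "locreg"))
  if (length(bad)) sl_stop("unknown model(s): %s", paste(bad, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "scev_config")
}

#' Load an analysis configuration from a YAML file
#'
#' Missing keys take the defaults of [scev_config()]; unknown keys and
#' non-numeric values where numbers are expected are configuration errors.
#'
#' @param path path to a YAML file (may be empty).
#' @return an `scev_config`.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(scev_config, vals)
}

#' @export
print.scev_config <- function(x, ...) {
  cat("scev_config:\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-22s %s\n", k,
                if (is.null(v)) "NULL" else paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Configuration scaled to the simulator's reference dimensions
#'
#' The default thresholds of [scev_config()] are sized for real multiome
#' experiments (thousands of cells, hundreds of thousands of peaks). This
#' variant scales them to the reference conditions of [sim_params()] (600
#' cells, 3000 peaks, 400 genes): minimum 50 nonzero peaks and 50 expressed
#' genes per cell, genes expressed in at least 100 cells, 500 homogeneous
#' cells, and HVG/well-predicted list sizes of K = 40 (10% of genes, the
#' simulated coupled fraction).
#'
#' @param seed integer seed.
#' @param ... further overrides passed to [scev_config()].
#' @return an `scev_config`.
#' @export
scev_config_sim <- function(seed = 1, ...) {
  scev_config(min_peaks_per_cell = 50, min_genes_per_cell = 50,
              min_cells_per_gene = 100, n_homogeneous_cells = 500,
              K = 40, K1 = 40, K2 = c(40, 100, 200), seed = seed, ...)
}
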