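# Synthetic paired-multiome generator with known ground truth.
#
# The generator emulates the statistical character of droplet multiome data:
# extreme ATAC sparsity (>90% zeros), peak widths of 200-1000 bp, log-normal
# RNA library sizes, overdispersed counts with dropout — and plants a known
# subset of "coupled" genes whose cross-cell expression variability is driven
# by the latent accessibility of a few nearby and distal driver peaks, so
# that every downstream stage has a recoverable signal.

#' Simulation parameters
#'
#' Defaults define the package's reference study conditions: 600 cells, 3000
#' peaks and 400 genes on four 20-Mb model chromosomes, 10% of genes
#' accessibility-coupled through 5 driver peaks each (3 within the 1.2 Mbp
#' local window, 2 anywhere on the genome), a target ATAC zero fraction of
#' 0.92 and negative-binomial RNA counts (size 8) with 5% dropout.
#'
#' Driver peaks of one gene share a per-gene latent activity factor
#' (`driver_cor` is the share of their latent variance carried by the common
#' factor); driver sets are disjoint across genes and drawn from the
#' more-accessible half of peaks. `coupling_strength` multiplies the
#' standardized summed driver latent accessibility on the log-mean scale of
#' the coupled gene's expression; 0 gives the null model in which
#' coupled-labelled genes are exchangeable with the rest.
#'
#' @param n_cells,n_peaks,n_genes problem dimensions.
#' @param n_chromosomes,chrom_length model genome: number of chromosomes and
#'   their common length in bp.
#' @param fraction_coupled fraction of genes that are accessibility-driven.
#' @param n_driver_peaks driver peaks per coupled gene.
#' @param n_local_drivers how many drivers fall within `local_window_bp` of
#'   the gene start (the rest are placed anywhere on the genome).
#' @param local_window_bp window defining "local" drivers (start-to-start).
#' @param coupling_strength log-scale effect size (>= 0; 0 = null model).
#' @param atac_sparsity target zero fraction of the ATAC matrix.
#' @param rna_dispersion negative-binomial size parameter of RNA counts.
#' @param dropout_rate independent zeroing probability of RNA counts.
#' @param atac_dropout independent zeroing probability of ATAC counts.
#' @param library_size_spread sdlog of the log-normal RNA library factors.
#' @param atac_depth_spread sdlog of the log-normal ATAC cell depths.
#' @param peak_base_spread sd of per-peak baseline log accessibility.
#' @param latent_sd sd of cell-level latent log-accessibility noise.
#' @param driver_cor correlation of a gene's driver-peak latents through the
#'   shared activity factor.
#' @param gene_mean_log,gene_mean_spread meanlog/sdlog of the log-normal
#'   distribution of gene base mean counts.
#' @param seed integer seed; all output is deterministic given the seed.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_cells = 600, n_peaks = 3000, n_genes = 400,
                       n_chromosomes = 4, chrom_length = 2e7,
                       fraction_coupled = 0.1, n_driver_peaks = 5,
                       n_local_drivers = 3, local_window_bp = 1200000,
                       coupling_strength = 1.5, atac_sparsity = 0.92,
                       rna_dispersion = 8, dropout_rate = 0.05,
                       atac_dropout = 0.05, library_size_spread = 0.3,
                       atac_depth_spread = 0.3, peak_base_spread = 0.5,
                       latent_sd = 1.8, driver_cor = 0.6,
                       gene_mean_log = log(2), gene_mean_spread = 0.8,
                       seed = 1) {
  p <- as.list(environment())
  if (p$fraction_coupled < 0 || p$fraction_coupled > 1) {
    sl_stop("fraction_coupled must lie in [0, 1]")
  }
  if (p$coupling_strength < 0) sl_stop("coupling_strength must be >= 0")
  if (p$atac_sparsity <= 0 || p$atac_sparsity >= 1) {
    sl_stop("atac_sparsity must lie strictly between 0 and 1")
  }
  if (p$n_local_drivers > p$n_driver_peaks) {
    sl_stop("n_local_drivers cannot exceed n_driver_peaks")
  }
  if (p$driver_cor < 0 || p$driver_cor > 1) sl_stop("driver_cor must lie in [0, 1]")
  if (p$dropout_rate < 0 || p$dropout_rate >= 1) sl_stop("dropout_rate must lie in [0, 1)")
  p$seed <- as.integer(p$seed)
  structure(p, class = "sim_params")
}

place_features <- function(n, widths, n_chrom, chrom_length, prefix) {
  if (n == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  per <- diff(floor(seq(0, n, length.out = n_chrom + 1)))
  out <- vector("list", n_chrom)
  k <- 0
  for (ch in seq_len(n_chrom)) {
    m <- per[ch]
    if (m == 0) next
    w <- widths[(k + 1):(k + m)]
    slack <- chrom_length - sum(w)
    if (slack <= 0) {
      sl_stop("capacity error: %d %s features of total width %d exceed chromosome length %d",
              m, prefix, sum(w), chrom_length)
    }
    gaps <- sort(runif(m, 0, slack))
    starts <- as.integer(floor(gaps + cumsum(c(0, w[-m]))))
    out[[ch]] <- data.frame(chrom = sprintf("chr%d", ch), start = starts,
                            end = starts + w, strand = ".",
                            stringsAsFactors = FALSE)
    k <- k + m
  }
  do.call(rbind, out)
}

#' Simulate the genomic layout of peaks and genes
#'
#' Peak widths are uniform on \[200, 1000\] bp; gene sizes are log-uniform on
#' \[1 kb, 100 kb\]. Features are placed without overlap within each feature
#' class and returned sorted by (chromosome, start). Deterministic given
#' `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return list with elements `peaks` and `genes` (interval data frames; the
#'   gene table carries `gene_id` and `size`).
#' @export
simulate_genome_layout <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  peak_w <- as.integer(round(runif(params$n_peaks, 200, 1000)))
  gene_w <- as.integer(round(exp(runif(params$n_genes, log(1e3), log(1e5)))))
  peaks <- place_features(params$n_peaks, peak_w, params$n_chromosomes,
                          params$chrom_length, "peak")
  genes <- place_features(params$n_genes, gene_w, params$n_chromosomes,
                          params$chrom_length, "gene")
  if (nrow(genes)) {
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
    genes$size <- genes$end - genes$start
    genes <- genes[, c("gene_id", "chrom", "start", "end", "strand", "size")]
  } else {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), size = integer(),
                        stringsAsFactors = FALSE)
  }
  list(peaks = peaks, genes = genes)
}

# Pick driver peaks for each coupled gene: n_local from the accessible,
# still-unused peaks within the local window of the gene start, the rest from
# accessible unused peaks anywhere else. Falls back to less accessible peaks
# when the preferred pool is exhausted. Driver sets are globally disjoint.
assign_drivers <- function(params, peaks, genes, coupled_idx, mu_p) {
  n_pk <- nrow(peaks)
  accessible <- mu_p >= stats::median(mu_p)
  used <- logical(n_pk)
  drivers <- vector("list", length(coupled_idx))
  names(drivers) <- genes$gene_id[coupled_idx]
  for (i in seq_along(coupled_idx)) {
    g <- coupled_idx[i]
    local_ok <- peaks$chrom == genes$chrom[g] &
      abs(peaks$start - genes$start[g]) <= params$local_window_bp
    pick <- integer(0)
    for (tier in list(which(local_ok & accessible & !used),
                      which(local_ok & !used))) {
      need <- params$n_local_drivers - length(pick)
      if (need <= 0) break
      pick <- c(pick, tier[sample.int(length(tier), min(need, length(tier)))])
      used[pick] <- TRUE
    }
    for (tier in list(which(!local_ok & accessible & !used),
                      which(!used))) {
      need <- params$n_driver_peaks - length(pick)
      if (need <= 0) break
      pick <- c(pick, tier[sample.int(length(tier), min(need, length(tier)))])
      used[pick] <- TRUE
    }
    if (length(pick) < params$n_driver_peaks) {
      sl_stop("cannot assign %d disjoint driver peaks per coupled gene with %d peaks",
              params$n_driver_peaks, n_pk)
    }
    drivers[[i]] <- sort(pick)
  }
  drivers
}

#' Simulate a paired multiome with known accessibility-expression coupling
#'
#' ATAC counts are Poisson draws from per-cell, per-peak latent accessibility
#' propensities (log-normal across cells and peaks, times a log-normal cell
#' depth), with the global rate calibrated numerically so the realized zero
#' fraction matches `atac_sparsity`, plus independent zeroing at
#' `atac_dropout`. RNA counts are negative-binomial with log-normal gene base
#' means and cell library factors; for coupled genes the per-cell log mean is
#' shifted by `coupling_strength` times the standardized sum of the gene's
#' driver-peak latent log-accessibility (variance-centred so the mean
#' expression is unchanged), then dropout is applied. Fully deterministic
#' given `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return list with `multiome` (a [paired_multiome()]) and `truth`, a
#'   `scev_ground_truth` carrying `coupled_gene_ids`, `driver_peaks` (named
#'   list of ATAC column indices per coupled gene), and `latent_activity`
#'   (cells x coupled genes matrix of the standardized driver signal).
#' @export
simulate_multiome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_driver_peaks > params$n_peaks && params$fraction_coupled > 0) {
    sl_stop("n_driver_peaks (%d) exceeds n_peaks (%d)",
            params$n_driver_peaks, params$n_peaks)
  }
  layout <- simulate_genome_layout(params)  # seeds the RNG stream
  peaks <- layout$peaks
  genes <- layout$genes
  N <- params$n_cells; n_pk <- params$n_peaks; n_gn <- params$n_genes

  mu_p <- rnorm(n_pk, 0, params$peak_base_spread)
  depth <- exp(rnorm(N, 0, params$atac_depth_spread))
  n_coup <- round(params$fraction_coupled * n_gn)
  coupled_idx <- sort(sample.int(n_gn, n_coup))
  drivers <- if (n_coup > 0) {
    assign_drivers(params, peaks, genes, coupled_idx, mu_p)
  } else {
    structure(list(), names = character())
  }

  eta <- matrix(rnorm(N * n_pk, 0, params$latent_sd), N, n_pk)
  U <- if (n_coup > 0) matrix(rnorm(N * n_coup), N, n_coup) else NULL
  for (i in seq_len(n_coup)) {
    for (p in drivers[[i]]) {
      eta[, p] <- params$latent_sd * (sqrt(params$driver_cor) * U[, i] +
                                        sqrt(1 - params$driver_cor) * rnorm(N))
    }
  }
  loglat <- sweep(eta, 2, mu_p, "+")
  lam0 <- depth * exp(loglat)

  # calibrate the global rate so the expected zero fraction hits the target
  d0 <- params$atac_dropout
  froot <- function(cc) mean((1 - d0) * exp(-cc * lam0) + d0) - params$atac_sparsity
  cc <- uniroot(froot, c(1e-12, 1e3), extendInt = "downX", tol = 1e-10)$root
  X <- matrix(rpois(N * n_pk, cc * lam0), N, n_pk)
  if (d0 > 0) X[matrix(runif(N * n_pk) < d0, N, n_pk)] <- 0L

  base_mean <- exp(rnorm(n_gn, params$gene_mean_log, params$gene_mean_spread))
  libf <- exp(rnorm(N, 0, params$library_size_spread))
  mu <- outer(libf, base_mean)
  k <- params$coupling_strength
  Z <- if (n_coup > 0) matrix(0, N, n_coup,
                              dimnames = list(NULL, genes$gene_id[coupled_idx])) else NULL
  for (i in seq_len(n_coup)) {
    z <- rowSums(loglat[, drivers[[i]], drop = FALSE])
    z <- (z - mean(z)) / sd(z)
    Z[, i] <- z
    mu[, coupled_idx[i]] <- mu[, coupled_idx[i]] * exp(k * z - k^2 / 2)
  }
  Y <- matrix(rnbinom(N * n_gn, mu = mu, size = params$rna_dispersion), N, n_gn)
  if (params$dropout_rate > 0) {
    Y[matrix(runif(N * n_gn) < params$dropout_rate, N, n_gn)] <- 0L
  }

  cells <- sprintf("cell_%04d", seq_len(N))
  peak_ids <- sprintf("peak_%05d", seq_len(n_pk))
  atac <- count_matrix(X, cells, peak_ids)
  rna <- count_matrix(Y, cells, genes$gene_id)
  pm <- paired_multiome(atac, rna, peaks, genes)
  truth <- structure(
    list(coupled_gene_ids = genes$gene_id[coupled_idx],
         coupled_idx = coupled_idx,
         driver_peaks = drivers,
         latent_activity = Z,
         params = params),
    class = "scev_ground_truth")
  sl_log("simulate_multiome: %d cells, %d peaks (zero fraction %.3f), %d genes (%d coupled)",
         N, n_pk, mean(X == 0), n_gn, n_coup)
  list(multiome = pm, truth = truth)
}

#' Inject a shifted cell subpopulation into a simulated multiome
#'
#' A random subset of cells receives extra accessibility counts on a random
#' subset of peaks, creating a separable cluster in any reasonable embedding;
#' used to exercise homogeneous-cell selection. Cell ids are unchanged; the
#' shifted cell ids are recorded in the `"shifted_cells"` attribute.
#'
#' @param pm a [paired_multiome()].
#' @param fraction fraction of cells to shift (0 < fraction < 0.5).
#' @param shift effect size in units of the per-peak count standard
#'   deviation; 0 returns the input unchanged.
#' @param seed integer seed.
#' @param peak_fraction fraction of peaks that receive the shift.
#' @return the modified `paired_multiome`.
#' @export
inject_heterogeneous_cluster <- function(pm, fraction, shift, seed,
                                         peak_fraction = 0.1) {
  stopifnot(inherits(pm, "paired_multiome"))
  if (fraction <= 0 || fraction >= 0.5) {
    sl_stop("fraction must lie strictly between 0 and 0.5")
  }
  if (shift < 0) sl_stop("shift must be >= 0")
  set.seed(seed)
  N <- nrow(pm$atac); n_pk <- ncol(pm$atac)
  cells <- sort(sample.int(N, round(fraction * N)))
  ids <- rownames(pm$atac)[cells]
  if (shift > 0) {
    pk <- sort(sample.int(n_pk, max(1L, round(peak_fraction * n_pk))))
    m <- Matrix::colMeans(pm$atac[, pk, drop = FALSE])
    v <- Matrix::colMeans(pm$atac[, pk, drop = FALSE]^2) - m^2
    sds <- pmax(sqrt(pmax(v, 0)), 0.05)
    extra <- matrix(rpois(length(cells) * length(pk),
                          rep(shift * sds, each = length(cells))),
                    length(cells), length(pk))
    block <- as.matrix(pm$atac[cells, pk, drop = FALSE]) + extra
    atac <- as(pm$atac, "TsparseMatrix")
    dense <- as.matrix(atac)
    dense[cells, pk] <- block
    pm$atac <- count_matrix(dense, rownames(pm$atac), colnames(pm$atac))
  }
  attr(pm, "shifted_cells") <- ids
  pm
}
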