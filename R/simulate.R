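#' Simulation configuration
#'
#' Describes a two-group bulk RNA-seq experiment generated from the same
#' statistical family the pipeline assumes: negative-binomial counts with
#' a decreasing mean-dispersion trend `phi(mu) = a / mu + b`, log-normal
#' baseline means and library-size factors, a planted fraction of genes
#' with symmetric log2 fold changes bounded away from zero, and optional
#' hidden (unwanted-variation) factors. Defaults mirror a mouse brain
#' bulk RNA-seq study arm: 6 animals per group and a transcriptome-scale
#' gene count; see the methods vignette for the rationale behind every
#' number.
#'
#' @param n_genes Number of genes (default 15000).
#' @param n_per_group Samples per condition (default 6).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   baseline mean counts (default meanlog 4, sdlog 1.5).
#' @param dispersion_a,dispersion_b Trend parameters of
#'   `phi(mu) = a / mu + b` (default a = 2, b = 0.05).
#' @param dispersion_jitter_sd Log-normal gene-to-gene jitter around the
#'   trend (default 0.2; 0 for exact trend dispersions).
#' @param frac_de Fraction of genes with a planted effect, in `[0, 1]`
#'   (default 0.1). The planted count is `round(frac_de * n_genes)`.
#' @param lfc_magnitude,lfc_sd Center and Gaussian jitter of the planted
#'   |log2 fold change| (default 1.5 and 0.4).
#' @param lfc_min Lower bound on planted |log2 fold change| (default 0.5),
#'   so "differentially expressed" is well defined for power computations.
#' @param libsize_sdlog Log-normal sd of the per-sample depth factors
#'   (default 0.3).
#' @param mean_libsize Target mean library size used to scale baseline
#'   means into realistic totals; `NULL` keeps the raw baseline scale.
#' @param n_unwanted_factors,unwanted_sd Number of hidden factors and the
#'   sd of their gene loadings (default 0 and 0.5).
#' @param length_meanlog,length_sdlog Log-normal parameters of gene
#'   lengths in bp (default log(2000) and 0.7; floored at 200 bp).
#' @param seed Integer seed threading through all randomness (default 1).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 15000, n_per_group = 6,
                       baseline_meanlog = 4, baseline_sdlog = 1.5,
                       dispersion_a = 2, dispersion_b = 0.05,
                       dispersion_jitter_sd = 0.2,
                       frac_de = 0.1, lfc_magnitude = 1.5, lfc_sd = 0.4,
                       lfc_min = 0.5, libsize_sdlog = 0.3,
                       mean_libsize = NULL,
                       n_unwanted_factors = 0, unwanted_sd = 0.5,
                       length_meanlog = log(2000), length_sdlog = 0.7,
                       seed = 1) {
  cfg <- list(
    n_genes = n_genes, n_per_group = n_per_group,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    dispersion_a = dispersion_a, dispersion_b = dispersion_b,
    dispersion_jitter_sd = dispersion_jitter_sd,
    frac_de = frac_de, lfc_magnitude = lfc_magnitude, lfc_sd = lfc_sd,
    lfc_min = lfc_min, libsize_sdlog = libsize_sdlog,
    mean_libsize = mean_libsize,
    n_unwanted_factors = n_unwanted_factors, unwanted_sd = unwanted_sd,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    seed = seed
  )
  if (n_genes < 1 || n_per_group < 2) {
    stop("need n_genes >= 1 and n_per_group >= 2", call. = FALSE)
  }
  if (!is.numeric(frac_de) || frac_de < 0 || frac_de > 1) {
    stop("`frac_de` must lie in [0, 1]", call. = FALSE)
  }
  positive <- c("baseline_sdlog", "dispersion_a", "dispersion_b",
                "lfc_magnitude", "lfc_min")
  for (p in positive) {
    if (cfg[[p]] < 0) stop("`", p, "` must be nonnegative", call. = FALSE)
  }
  if (dispersion_jitter_sd < 0 || lfc_sd < 0 || libsize_sdlog < 0 || unwanted_sd < 0) {
    stop("scale parameters must be nonnegative", call. = FALSE)
  }
  if (n_unwanted_factors < 0 || n_unwanted_factors != round(n_unwanted_factors)) {
    stop("`n_unwanted_factors` must be a nonnegative integer", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a two-group NB count dataset with planted effects
#'
#' Counts are drawn as
#' `counts[g, j] ~ NB(mean = mu_g * 2^(x_j * lfc_g) * depth_j * exp(u[g, j]),
#' dispersion = phi_g)` where `x_j` is the 0/1 treatment indicator,
#' `depth_j` the sample depth factor, `u` the hidden-factor component and
#' the NB variance is `mu + phi * mu^2`. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `sim_dataset` list: `counts` (a [count_matrix()] with gene
#'   lengths), `design` (a [study_design()]), `truth` (per-gene tibble
#'   with `is_de`, `true_log2fc`, `true_mean`, `true_dispersion`),
#'   `depth_factors`, `unwanted` (sample scores and gene loadings, or
#'   NULL) and the echoed `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- config$n_genes
  n <- 2 * config$n_per_group
  gene_id <- sprintf("gene%05d", seq_len(g))
  sample_id <- c(sprintf("control_%d", seq_len(config$n_per_group)),
                 sprintf("treatment_%d", seq_len(config$n_per_group)))
  x <- rep(c(0, 1), each = config$n_per_group)

  baseline <- stats::rlnorm(g, config$baseline_meanlog, config$baseline_sdlog)
  if (!is.null(config$mean_libsize)) {
    baseline <- baseline * config$mean_libsize / sum(baseline)
  }
  n_de <- round(config$frac_de * g)
  is_de <- rep(FALSE, g)
  is_de[sample.int(g, n_de)] <- TRUE
  lfc <- rep(0, g)
  if (n_de > 0) {
    mag <- pmax(config$lfc_min,
                stats::rnorm(n_de, config$lfc_magnitude, config$lfc_sd))
    lfc[is_de] <- sample(c(-1, 1), n_de, replace = TRUE) * mag
  }
  depth <- exp(stats::rnorm(n, 0, config$libsize_sdlog))
  depth <- depth / exp(mean(log(depth)))
  phi <- (config$dispersion_a / baseline + config$dispersion_b)
  if (config$dispersion_jitter_sd > 0) {
    phi <- phi * exp(stats::rnorm(g, 0, config$dispersion_jitter_sd))
  }

  mu <- baseline %o% (depth) * 2^(lfc %o% x)
  unwanted <- NULL
  if (config$n_unwanted_factors > 0) {
    k <- config$n_unwanted_factors
    w <- matrix(stats::rnorm(n * k), n, k)
    alpha <- matrix(stats::rnorm(g * k, 0, config$unwanted_sd), g, k)
    mu <- mu * exp(alpha %*% t(w))
    unwanted <- list(scores = w, loadings = alpha)
  }

  counts <- matrix(0, g, n)
  poislike <- phi < 1e-12
  if (any(poislike)) {
    counts[poislike, ] <- stats::rpois(sum(poislike) * n, mu[poislike, ])
  }
  if (any(!poislike)) {
    counts[!poislike, ] <- stats::rnbinom(sum(!poislike) * n,
                                          mu = mu[!poislike, ],
                                          size = rep(1 / phi[!poislike], n))
  }
  dimnames(counts) <- list(gene_id, sample_id)
  lens <- pmax(round(stats::rlnorm(g, config$length_meanlog, config$length_sdlog)), 200)
  names(lens) <- gene_id

  structure(list(
    counts = count_matrix(counts, gene_lengths = lens),
    design = study_design(sample_id, rep(c("control", "treatment"),
                                         each = config$n_per_group)),
    truth = tibble::tibble(gene_id = gene_id, is_de = is_de,
                           true_log2fc = lfc, true_mean = baseline,
                           true_dispersion = phi),
    depth_factors = stats::setNames(depth, sample_id),
    unwanted = unwanted,
    config = config
  ), class = "sim_dataset")
}

#' @exportS3Method base::print
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d genes x %d samples, %d planted DE genes (seed %s)\n",
              nrow(x$counts), ncol(x$counts), sum(x$truth$is_de),
              format(x$config$seed)))
  invisible(x)
}

#' Simulate a fully null dataset
#'
#' Same generator as [simulate_dataset()] but refuses any configuration
#' with planted effects — the calibration harness for type-I error and
#' p-value uniformity checks.
#'
#' @param config A [sim_config()] with `frac_de = 0`.
#' @return A `sim_dataset` with an all-null truth table.
#' @export
simulate_null <- function(config = sim_config(frac_de = 0)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$frac_de != 0) {
    stop("simulate_null requires frac_de = 0 (got ", config$frac_de, ")", call. = FALSE)
  }
  simulate_dataset(config)
}

#' Confusion counts and rates for a call set against the planted truth
#'
#' `empirical_fdr = FP / max(1, FP + TP)` (so an empty call set has FDR
#' 0) and `power = TP / n_de` (0 when nothing was planted).
#'
#' @param calls Character vector of called gene ids (subset of the truth
#'   universe).
#' @param truth The `truth` tibble of a `sim_dataset` (or the dataset
#'   itself).
#' @return A one-row tibble with `tp`, `fp`, `fn`, `tn`,
#'   `empirical_fdr`, `power`.
#' @export
evaluate_calls <- function(calls, truth) {
  if (inherits(truth, "sim_dataset")) truth <- truth$truth
  calls <- unique(as.character(calls))
  unknown <- setdiff(calls, truth$gene_id)
  if (length(unknown)) {
    stop("called gene '", unknown[1], "' is not in the truth universe", call. = FALSE)
  }
  called <- truth$gene_id %in% calls
  tp <- sum(called & truth$is_de)
  fp <- sum(called & !truth$is_de)
  fn <- sum(!called & truth$is_de)
  tn <- sum(!called & !truth$is_de)
  n_de <- sum(truth$is_de)
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    empirical_fdr = fp / max(1, fp + tp),
    power = if (n_de > 0) tp / n_de else 0
  )
}

#' Truth-aware recovery report for a grid
#'
#' For each model (and the consensus), effect-size recovery — bias and
#' RMSE of the per-gene median log2 fold change across that model's
#' cells, over planted genes with true baseline mean at least
#' `min_mean` — plus empirical FDR and power of its target set under the
#' mean-q rule.
#'
#' @param grid A `consensus_grid` run on a simulated dataset.
#' @param truth The matching truth tibble (or `sim_dataset`).
#' @param threshold,k_required Consensus-rule parameters (see
#'   [call_consensus()]).
#' @param min_mean Baseline-mean floor for the lfc recovery rows
#'   (default 20 counts).
#' @return A tibble with one row per model plus one `consensus` row:
#'   `lfc_bias`, `lfc_rmse`, `n_lfc_genes`, `n_called`,
#'   `empirical_fdr`, `power`.
#' @export
recovery_report <- function(grid, truth, threshold = 0.25, k_required = NULL,
                            min_mean = 20) {
  if (inherits(truth, "sim_dataset")) truth <- truth$truth
  if (!identical(sort(grid$gene_ids), sort(truth$gene_id))) {
    stop("grid and truth cover different gene universes", call. = FALSE)
  }
  truth <- truth[match(grid$gene_ids, truth$gene_id), ]
  calls <- call_consensus(grid, threshold = threshold, k_required = k_required)
  hi <- truth$is_de & truth$true_mean >= min_mean

  model_row <- function(md) {
    lfc_cells <- vapply(grid$normalizations, function(nm) {
      grid_cell(grid, nm, md)$log2_fc
    }, numeric(length(grid$gene_ids)))
    est <- apply(matrix(lfc_cells, ncol = length(grid$normalizations)), 1, stats::median)
    err <- est[hi] - truth$true_log2fc[hi]
    ev <- evaluate_calls(calls$targets[[md]], truth)
    tibble::tibble(
      set = md,
      lfc_bias = mean(err), lfc_rmse = sqrt(mean(err^2)),
      n_lfc_genes = sum(hi),
      n_called = length(calls$targets[[md]]),
      empirical_fdr = ev$empirical_fdr, power = ev$power
    )
  }
  rows <- purrr::map_dfr(grid$models, model_row)
  med <- calls$calls$median_lfc
  err_c <- med[hi] - truth$true_log2fc[hi]
  ev_c <- evaluate_calls(consensus_degs(calls), truth)
  dplyr::bind_rows(rows, tibble::tibble(
    set = "consensus",
    lfc_bias = mean(err_c), lfc_rmse = sqrt(mean(err_c^2)),
    n_lfc_genes = sum(hi),
    n_called = sum(calls$calls$called),
    empirical_fdr = ev_c$empirical_fdr, power = ev_c$power
  ))
}
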