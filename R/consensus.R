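#' Run the normalization-by-model grid
#'
#' Applies every registered normalization, then every model on top of it,
#' over one shared gene universe. Each factor-kind normalization enters
#' the count models as natural-log offsets and the rank/t tests as
#' divided-through values; each matrix-kind normalization enters the
#' count models rounded to integers (cell flagged `rounded_matrix`) and
#' the rank/t tests directly. One dispersion fit per normalization is
#' shared between the two NB models. Any cell failure aborts the run
#' with the failing cell named — no partial grids.
#'
#' @param counts A [count_matrix()] (with gene lengths if RPKM is in the
#'   grid).
#' @param design A [study_design()].
#' @param normalizations Character vector of normalization tags; default
#'   the eight built-ins (see [default_normalizations()]), plus any tags
#'   added with [register_normalization()] that you list here.
#' @param models Character vector of model tags (see [default_models()]).
#' @param ruv_k,ruv_control_genes Forwarded to [norm_ruv()].
#' @param verbose Print per-cell progress.
#' @return A `consensus_grid` object: per-cell [de_result()]s plus the
#'   grid geometry. Use [mean_q_aggregate()], [call_consensus()],
#'   [generics::tidy()] and [generics::glance()] on it.
#' @export
run_grid <- function(counts, design,
                     normalizations = default_normalizations(),
                     models = default_models(),
                     ruv_k = 1, ruv_control_genes = "empirical",
                     verbose = FALSE) {
  stopifnot(length(normalizations) >= 1, length(models) >= 1)
  counts <- if (inherits(counts, "count_matrix")) counts else count_matrix(counts)
  design <- align_design(counts, design)
  cells <- list()
  notes <- list()

  for (nm in normalizations) {
    norm <- tryCatch(
      normalize_counts(counts, nm, design, ruv_k = ruv_k,
                       ruv_control_genes = ruv_control_genes),
      error = function(e) stop("normalization '", nm, "' failed: ",
                               conditionMessage(e), call. = FALSE)
    )
    prep <- prepare_model_inputs(counts, norm)
    dispersion <- NULL
    for (md in models) {
      if (verbose) message("cell ", nm, " x ", md)
      if (md %in% c("nb_wald", "nb_lrt_robust") && is.null(dispersion)) {
        dispersion <- fit_dispersion(prep$count_input, design, prep$offsets)
      }
      res <- tryCatch(
        run_model_cell(md, prep, design, dispersion, nm),
        error = function(e) stop("grid cell (", nm, ", ", md, ") failed: ",
                                 conditionMessage(e), call. = FALSE)
      )
      cells[[paste(nm, md, sep = "|")]] <- res
      notes[[paste(nm, md, sep = "|")]] <- prep$note
    }
  }

  structure(
    list(cells = cells, normalizations = normalizations, models = models,
         gene_ids = gene_ids(counts), design = design,
         cell_notes = notes),
    class = "consensus_grid"
  )
}

# how one normalization feeds the five models
prepare_model_inputs <- function(counts, norm) {
  y <- count_values(counts)
  if (norm$kind == "factor") {
    depths <- effective_depth(norm)
    list(
      count_input = y,
      offsets = log(depths),
      depths = depths,
      rank_input = sweep(y, 2, norm$factors, "/"),
      note = ""
    )
  } else {
    rounded <- round(norm$normalized)
    list(
      count_input = rounded,
      offsets = NULL,
      depths = pmax(colSums(rounded), 1),
      rank_input = norm$normalized,
      note = "rounded_matrix"
    )
  }
}

run_model_cell <- function(model, prep, design, dispersion, norm_tag) {
  switch(model,
    nb_wald = nb_wald_test(prep$count_input, design, dispersion,
                           prep$offsets, normalization = norm_tag),
    nb_lrt_robust = nb_lrt_robust_test(prep$count_input, design, dispersion,
                                       prep$offsets, normalization = norm_tag),
    voom = voom_moderated_t_test(prep$count_input, design, prep$depths,
                                 normalization = norm_tag),
    mann_whitney = mann_whitney_test(prep$rank_input, design,
                                     normalization = norm_tag),
    welch_t = welch_t_test(prep$rank_input, design, normalization = norm_tag),
    stop("unknown model '", model, "'", call. = FALSE)
  )
}

#' @exportS3Method base::print
print.consensus_grid <- function(x, ...) {
  cat(sprintf("<consensus_grid> %d genes, %d normalizations x %d models = %d cells\n",
              length(x$gene_ids), length(x$normalizations), length(x$models),
              length(x$cells)))
  invisible(x)
}

#' Extract one grid cell
#' @param grid A `consensus_grid`.
#' @param normalization,model Cell coordinates.
#' @return The cell's [de_result()].
#' @export
grid_cell <- function(grid, normalization, model) {
  key <- paste(normalization, model, sep = "|")
  if (!key %in% names(grid$cells)) {
    stop("no grid cell (", normalization, ", ", model, ")", call. = FALSE)
  }
  grid$cells[[key]]
}

#' Mean q-value per gene per model
#'
#' For each model, the arithmetic mean of a gene's q-values across all of
#' that model's normalizations — the quantity thresholded by the
#' consensus rule.
#'
#' @param grid A `consensus_grid` from [run_grid()].
#' @return A tibble with columns `gene_id`, `model`, `mean_q`.
#' @export
mean_q_aggregate <- function(grid) {
  purrr::map_dfr(grid$models, function(md) {
    qs <- vapply(grid$normalizations, function(nm) {
      cell <- grid_cell(grid, nm, md)
      if (!identical(cell$gene_id, grid$gene_ids)) {
        stop("grid cell (", nm, ", ", md, ") has a mismatched gene universe",
             call. = FALSE)
      }
      cell$q_value
    }, numeric(length(grid$gene_ids)))
    tibble::tibble(gene_id = grid$gene_ids, model = md,
                   mean_q = rowMeans(matrix(qs, ncol = length(grid$normalizations))))
  })
}

#' Consensus DEG calls
#'
#' A gene is a *target* of a model when that model's mean q-value (across
#' normalizations) is strictly below `threshold`; it is called a
#' consensus DEG when it is a target of at least `k_required` models
#' (default: all of them). Direction is the sign of the median log2 fold
#' change across every grid cell; a zero median is labeled "ambiguous".
#'
#' @param grid A `consensus_grid`.
#' @param threshold Mean-q cutoff (default 0.25, strict `<`).
#' @param k_required Number of models that must detect a gene (default:
#'   all models in the grid).
#' @return A `consensus_calls` object; its `$calls` tibble has one row
#'   per gene with `n_models_detected`, `median_lfc`, `direction` and
#'   `called`, and `$targets` holds the per-model target gene sets.
#' @export
call_consensus <- function(grid, threshold = 0.25, k_required = NULL) {
  if (is.null(k_required)) k_required <- length(grid$models)
  if (k_required > length(grid$models)) {
    stop("k_required (", k_required, ") exceeds the number of models (",
         length(grid$models), ")", call. = FALSE)
  }
  mq <- mean_q_aggregate(grid)
  wide <- tidyr::pivot_wider(mq, names_from = "model", values_from = "mean_q")
  detected <- rowSums(as.matrix(wide[, grid$models, drop = FALSE]) < threshold)
  lfc_mat <- vapply(grid$cells, function(cell) cell$log2_fc,
                    numeric(length(grid$gene_ids)))
  med_lfc <- apply(matrix(lfc_mat, ncol = length(grid$cells)), 1, stats::median)
  direction <- dplyr::case_when(
    med_lfc > 0 ~ "up",
    med_lfc < 0 ~ "down",
    TRUE ~ "ambiguous"
  )
  calls <- tibble::tibble(
    gene_id = wide$gene_id,
    n_models_detected = as.integer(detected),
    median_lfc = med_lfc,
    direction = direction,
    called = detected >= k_required
  )
  targets <- purrr::map(grid$models, function(md) {
    wide$gene_id[wide[[md]] < threshold]
  })
  names(targets) <- grid$models
  structure(
    list(calls = calls, targets = targets, mean_q = wide,
         threshold = threshold, k_required = k_required,
         models = grid$models),
    class = "consensus_calls"
  )
}

#' @exportS3Method base::print
print.consensus_calls <- function(x, ...) {
  n <- sum(x$calls$called)
  cat(sprintf("<consensus_calls> %d DEGs of %d genes (mean q < %g in >= %d of %d models)\n",
              n, nrow(x$calls), x$threshold, x$k_required, length(x$models)))
  invisible(x)
}

#' Consensus DEG identifiers
#' @param calls A `consensus_calls` object.
#' @return Character vector of called gene ids.
#' @export
consensus_degs <- function(calls) calls$calls$gene_id[calls$calls$called]

#' Volcano classification of one grid cell
#'
#' Labels each gene up (q below cutoff, positive lfc), down (q below
#' cutoff, negative lfc) or ns, and returns a plot-ready table.
#'
#' @param cell A [de_result()].
#' @param q_cutoff Significance cutoff on the q-value (default 0.01).
#' @return A tibble with `gene_id`, `log2_fc`, `neg_log10_q`, `label`.
#' @export
classify_volcano <- function(cell, q_cutoff = 0.01) {
  if (!all(c("gene_id", "log2_fc", "q_value") %in% names(cell))) {
    stop("`cell` must be a de_result with gene_id, log2_fc and q_value", call. = FALSE)
  }
  if (anyNA(cell$q_value) || anyNA(cell$log2_fc)) {
    stop("missing q-value or log2 fold change in DE result", call. = FALSE)
  }
  tibble::tibble(
    gene_id = cell$gene_id,
    log2_fc = cell$log2_fc,
    neg_log10_q = -log10(pmax(cell$q_value, 1e-300)),
    label = factor(
      dplyr::case_when(
        cell$q_value < q_cutoff & cell$log2_fc > 0 ~ "up",
        cell$q_value < q_cutoff & cell$log2_fc < 0 ~ "down",
        TRUE ~ "ns"
      ),
      levels = c("down", "ns", "up")
    )
  )
}

#' Compare two DEG sets
#'
#' Overlap summary for DEG sets from, e.g., two abstinence timepoints.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return A list with counts `n_a_only`, `n_b_only`, `n_both` and the
#'   corresponding membership vectors.
#' @export
compare_deg_sets <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  both <- intersect(set_a, set_b)
  a_only <- setdiff(set_a, set_b)
  b_only <- setdiff(set_b, set_a)
  list(n_a_only = length(a_only), n_b_only = length(b_only),
       n_both = length(both),
       a_only = a_only, b_only = b_only, both = both)
}
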