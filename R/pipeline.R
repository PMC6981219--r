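#' Run the full consensus pipeline and write a report directory
#'
#' Read -> normalize -> test -> aggregate -> call -> report. Inputs are
#' never mutated; everything lands in `out_dir`:
#' `de_<normalization>_<model>.tsv` per grid cell,
#' `consensus_degs.tsv`, `volcano_<normalization>_<model>.tsv` for the
#' requested volcano cells, and `summary.json` echoing every parameter,
#' cell count, DEG count, per-cell caveats, package version and seed —
#' enough to reconstruct the run.
#'
#' @param counts A [count_matrix()] or a path to a counts TSV.
#' @param design A [study_design()] or a path to a design TSV.
#' @param gtf Optional GTF path; collapsed gene lengths are attached to
#'   the counts (needed for RPKM when lengths are not already present).
#' @param normalizations,models Grid axes (defaults: the eight built-in
#'   normalizations and five models).
#' @param mean_q_threshold Consensus mean-q cutoff (default 0.25).
#' @param k_required Models required for a consensus call (default all).
#' @param volcano_q Volcano classification cutoff (default 0.01).
#' @param volcano_cells `"all"`, `"none"`, or a character vector of
#'   `"<normalization>|<model>"` keys to classify.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed recorded in the summary and set before the
#'   run (the analysis itself is deterministic; the seed guards any
#'   registered method that draws random numbers).
#' @param verbose Print per-cell progress.
#' @return The `consensus_calls` object, invisibly; side effect is the
#'   populated `out_dir`.
#' @export
run_pipeline <- function(counts, design, gtf = NULL,
                         normalizations = default_normalizations(),
                         models = default_models(),
                         mean_q_threshold = 0.25, k_required = NULL,
                         volcano_q = 0.01, volcano_cells = "all",
                         out_dir = "consensusde_run", seed = 1,
                         verbose = FALSE) {
  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(design)) design <- read_design(design)
  if (!is.null(gtf)) {
    lens <- gene_lengths_from_gtf(gtf)
    counts <- count_matrix(count_values(counts),
                           gene_lengths = stats::setNames(lens$length_bp, lens$gene_id))
  }
  design <- align_design(counts, design)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  grid <- run_grid(counts, design, normalizations = normalizations,
                   models = models, verbose = verbose)
  calls <- call_consensus(grid, threshold = mean_q_threshold,
                          k_required = k_required)

  for (key in names(grid$cells)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    write_de_table(grid$cells[[key]],
                   file.path(out_dir, sprintf("de_%s_%s.tsv", parts[1], parts[2])))
  }
  keys <- switch(volcano_cells[1],
                 all = names(grid$cells),
                 none = character(),
                 intersect(volcano_cells, names(grid$cells)))
  for (key in keys) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    tab <- classify_volcano(grid$cells[[key]], q_cutoff = volcano_q)
    utils::write.table(tab, file.path(out_dir, sprintf("volcano_%s_%s.tsv",
                                                       parts[1], parts[2])),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  deg_tab <- tidy(calls)
  utils::write.table(deg_tab[deg_tab$called, ],
                     file.path(out_dir, "consensus_degs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(deg_tab, file.path(out_dir, "consensus_all_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    package = "consensusde",
    version = as.character(utils::packageVersion("consensusde")),
    seed = seed,
    n_genes = length(grid$gene_ids),
    n_samples = nrow(design),
    condition_levels = design_levels(design),
    normalizations = normalizations,
    models = models,
    n_cells = length(grid$cells),
    mean_q_threshold = mean_q_threshold,
    k_required = calls$k_required,
    volcano_q = volcano_q,
    n_deg = sum(calls$calls$called),
    n_up = sum(calls$calls$called & calls$calls$direction == "up"),
    n_down = sum(calls$calls$called & calls$calls$direction == "down"),
    cell_notes = grid$cell_notes[vapply(grid$cell_notes, nzchar, logical(1))]
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(calls)
}

#' Simulate a dataset and write it to files
#'
#' Emits `counts.tsv`, `design.tsv`, `truth.tsv`, `gene_lengths.tsv` and
#' a `config.json` echo into `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return The `sim_dataset`, invisibly.
#' @export
simulate_to_files <- function(config = sim_config(), out_dir = "consensusde_sim") {
  sim <- simulate_dataset(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, file.path(out_dir, "counts.tsv"))
  write_design(sim$design, file.path(out_dir, "design.tsv"))
  utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = gene_ids(sim$counts),
               length_bp = unname(gene_lengths(sim$counts))),
    file.path(out_dir, "gene_lengths.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(sim)
}

#' Evaluate a completed run directory against a truth table
#'
#' Reads `consensus_all_genes.tsv` from a [run_pipeline()] output
#' directory and the matching `truth.tsv`, and writes
#' `evaluation.tsv`/`evaluation.json` with confusion counts, empirical
#' FDR and power of the consensus call set.
#'
#' @param run_dir A completed [run_pipeline()] output directory.
#' @param truth_path Path to the matching truth TSV (from
#'   [simulate_to_files()]).
#' @return The evaluation tibble, invisibly.
#' @export
evaluate_run <- function(run_dir, truth_path) {
  degs_path <- file.path(run_dir, "consensus_all_genes.tsv")
  if (!file.exists(degs_path)) {
    stop("not a completed run directory (missing consensus_all_genes.tsv): ",
         run_dir, call. = FALSE)
  }
  tab <- utils::read.delim(degs_path, stringsAsFactors = FALSE,
                           colClasses = c(gene_id = "character"))
  truth <- tibble::as_tibble(
    utils::read.delim(truth_path, stringsAsFactors = FALSE,
                      colClasses = c(gene_id = "character"))
  )
  if (!setequal(tab$gene_id, truth$gene_id)) {
    stop("run and truth cover different gene universes", call. = FALSE)
  }
  ev <- evaluate_calls(tab$gene_id[tab$called], truth)
  utils::write.table(ev, file.path(run_dir, "evaluation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(ev), file.path(run_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(ev)
}
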