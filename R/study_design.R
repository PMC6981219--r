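#' Two-group study design
#'
#' Assigns each sample to one of exactly two condition levels (e.g. saline
#' vs cocaine). The first declared level is the reference (control): every
#' log2 fold change in the package is treatment minus control.
#'
#' @param sample_ids Character vector of sample ids.
#' @param condition Per-sample condition labels (exactly two distinct values,
#'   each with at least two samples).
#' @param levels Optional length-2 character vector fixing the level order,
#'   control first. Defaults to order of first appearance.
#' @return A tibble of class `study_design` with columns `sample_id` and
#'   `condition` (a factor, control level first).
#' @examples
#' study_design(paste0("s", 1:6), rep(c("saline", "cocaine"), each = 3))
#' @export
study_design <- function(sample_ids, condition, levels = NULL) {
  sample_ids <- as.character(sample_ids)
  condition <- as.character(condition)
  if (length(sample_ids) != length(condition)) {
    stop("`sample_ids` and `condition` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id in design: '",
         sample_ids[duplicated(sample_ids)][1], "'", call. = FALSE)
  }
  if (is.null(levels)) levels <- unique(condition)
  if (length(levels) != 2 || !setequal(levels, unique(condition))) {
    stop("design must have exactly two condition levels, got: ",
         paste(unique(condition), collapse = ", "), call. = FALSE)
  }
  n_per <- table(factor(condition, levels = levels))
  if (any(n_per < 2)) {
    stop("each condition level needs at least 2 samples (",
         paste(sprintf("%s: %d", names(n_per), n_per), collapse = ", "), ")",
         call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = sample_ids,
    condition = factor(condition, levels = levels)
  )
  class(out) <- c("study_design", class(out))
  out
}

#' Read a two-column (sample_id, condition) design table
#'
#' @param path TSV path with a header row; first column sample ids, second
#'   column condition labels. Level order is order of first appearance
#'   (control first).
#' @param levels Optional explicit level order passed to [study_design()].
#' @return A [study_design()] tibble.
#' @export
read_design <- function(path, levels = NULL) {
  if (!file.exists(path)) stop("design file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("design table needs columns (sample_id, condition)", call. = FALSE)
  study_design(df[[1]], df[[2]], levels = levels)
}

#' Write a design table
#' @param design A [study_design()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(
    data.frame(sample_id = design$sample_id, condition = as.character(design$condition)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Check that a design and a count matrix describe the same samples
#'
#' @param counts A [count_matrix()].
#' @param design A [study_design()].
#' @return The design reordered to match the column order of `counts`.
#' @export
align_design <- function(counts, design) {
  missing <- setdiff(design$sample_id, sample_ids(counts))
  if (length(missing)) {
    stop("design sample '", missing[1], "' is absent from the count matrix", call. = FALSE)
  }
  extra <- setdiff(sample_ids(counts), design$sample_id)
  if (length(extra)) {
    stop("count matrix sample '", extra[1], "' is absent from the design", call. = FALSE)
  }
  out <- design[match(sample_ids(counts), design$sample_id), ]
  class(out) <- class(design)
  out
}

design_levels <- function(design) levels(design$condition)

# logical treatment indicator in count-matrix column order
treatment_indicator <- function(design) {
  as.integer(design$condition == design_levels(design)[2])
}
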