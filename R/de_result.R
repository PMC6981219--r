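#' Differential-expression result for one (normalization, model) cell
#'
#' A tibble with one row per gene and columns `gene_id`, `log2_fc`
#' (treatment over control), `stat`, `p_value`, `q_value`, `flag`
#' (empty string, or a short note such as "all_zero" / "zero_group"),
#' carrying `normalization` and `model` attributes. All constructors in the
#' package preserve the input gene order; nothing is re-sorted.
#'
#' @param gene_id Character vector of gene ids.
#' @param log2_fc,stat,p_value Numeric vectors, one value per gene.
#' @param normalization,model Method tags for the grid cell.
#' @param flag Optional character vector of per-gene flags.
#' @param q_value Optional; computed by [bh_adjust()] from `p_value` when
#'   missing.
#' @return A `de_result` tibble.
#' @export
de_result <- function(gene_id, log2_fc, stat, p_value,
                      normalization = NA_character_, model = NA_character_,
                      flag = NULL, q_value = NULL) {
  n <- length(gene_id)
  stopifnot(length(log2_fc) == n, length(stat) == n, length(p_value) == n)
  if (any(!is.na(p_value) & (p_value < 0 | p_value > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(q_value)) q_value <- bh_adjust(p_value)
  if (is.null(flag)) flag <- rep("", n)
  out <- tibble::tibble(
    gene_id = as.character(gene_id),
    log2_fc = as.numeric(log2_fc),
    stat = as.numeric(stat),
    p_value = as.numeric(p_value),
    q_value = as.numeric(q_value),
    flag = as.character(flag)
  )
  attr(out, "normalization") <- normalization
  attr(out, "model") <- model
  class(out) <- c("de_result", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: with p-values sorted ascending,
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1 and mapped back to the
#' input order. Thin wrapper over [stats::p.adjust()] with input validation;
#' q-values within each grid cell are computed independently over all tested
#' genes in that cell.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NA allowed,
#'   propagated).
#' @return Numeric vector of q-values in input order.
#' @examples
#' bh_adjust(c(0.005, 0.01, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("p-values must be numeric", call. = FALSE)
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Write / read a per-cell DE table
#'
#' Tab-separated with columns `gene_id`, `log2FC`, `stat`, `pvalue`,
#' `qvalue`, `flag`, in the input gene order.
#'
#' @param result A [de_result()].
#' @param path Output TSV path.
#' @return `path` (write) or a `de_result` (read), invisibly for write.
#' @export
write_de_table <- function(result, path) {
  df <- data.frame(
    gene_id = result$gene_id,
    log2FC = format_full(result$log2_fc),
    stat = format_full(result$stat),
    pvalue = format_full(result$p_value),
    qvalue = format_full(result$q_value),
    flag = result$flag,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @param normalization,model Tags restored onto the read object.
#' @export
read_de_table <- function(path, normalization = NA_character_, model = NA_character_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character"))
  if (nrow(df) == 0) {
    return(de_result(character(), numeric(), numeric(), numeric(),
                     normalization = normalization, model = model,
                     q_value = numeric(), flag = character()))
  }
  de_result(df$gene_id, df$log2FC, df$stat, df$pvalue,
            q_value = df$qvalue,
            flag = if ("flag" %in% names(df)) ifelse(is.na(df$flag), "", df$flag) else NULL,
            normalization = normalization, model = model)
}

# full-precision decimal serialization so round-trips are lossless to 1e-12
format_full <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 17))
}
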