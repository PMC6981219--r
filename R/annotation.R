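#' Collapsed gene lengths from a GTF annotation
#'
#' For RPKM the pipeline needs a single length per gene. Genes with multiple
#' isoforms are collapsed: the exons of all isoforms are merged (union of
#' intervals, strand ignored) and the length is the number of bases the
#' merged exon model covers.
#'
#' @param path Path to a GTF file (1-based inclusive coordinates, attribute
#'   field carrying `gene_id`).
#' @return A tibble with columns `gene_id` and `length_bp`, one row per gene
#'   that has at least one exon. Genes without exon features are dropped with
#'   a warning.
#' @export
gene_lengths_from_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  if (!"type" %in% names(S4Vectors::mcols(gr))) {
    stop("GTF has no feature type column", call. = FALSE)
  }
  all_genes <- unique(stats::na.omit(S4Vectors::mcols(gr)$gene_id))
  ex <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(ex) == 0) stop("GTF contains no exon features", call. = FALSE)
  ids <- S4Vectors::mcols(ex)$gene_id
  if (is.null(ids) || anyNA(ids)) {
    stop("exon feature without a gene_id attribute", call. = FALSE)
  }
  merged <- GenomicRanges::reduce(
    S4Vectors::split(ex, factor(ids, levels = unique(ids))),
    ignore.strand = TRUE
  )
  lens <- BiocGenerics::sapply(GenomicRanges::width(merged), sum)
  dropped <- setdiff(all_genes, names(lens))
  if (length(dropped)) {
    warning(length(dropped), " gene(s) without exon features dropped: ",
            paste(utils::head(dropped, 3), collapse = ", "),
            if (length(dropped) > 3) ", ..." else "")
  }
  tibble::tibble(gene_id = names(lens), length_bp = as.numeric(lens))
}
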