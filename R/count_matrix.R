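#' Construct a validated gene-by-sample count matrix
#'
#' The central input object of the pipeline: a matrix of nonnegative integer
#' read counts with genes in rows and samples in columns, optionally carrying
#' per-gene lengths (base pairs of the merged exon model) needed for RPKM.
#'
#' Counts must be raw integers. Expected-count matrices with fractional
#' entries are rejected rather than rounded, so that the count-model
#' assumptions stay explicit; round upstream if you really mean to.
#'
#' @param counts Numeric matrix of nonnegative integers with unique rownames
#'   (gene ids) and colnames (sample ids), or a data frame whose first column
#'   holds gene ids and remaining columns hold per-sample counts.
#' @param gene_lengths Optional named numeric vector of positive gene lengths
#'   in base pairs; names must cover every gene id.
#' @return A `count_matrix` object (matrix-backed, with a `gene_lengths`
#'   attribute when provided).
#' @examples
#' m <- matrix(rpois(12, 50), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' cm <- count_matrix(m)
#' dim(cm)
#' @export
count_matrix <- function(counts, gene_lengths = NULL) {
  if (is.data.frame(counts)) {
    ids <- as.character(counts[[1]])
    counts <- as.matrix(counts[, -1, drop = FALSE])
    rownames(counts) <- ids
  }
  if (!is.matrix(counts)) {
    stop("`counts` must be a matrix or a data frame with a gene-id first column", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` needs rownames (gene ids) and colnames (sample ids)", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1]
    stop("duplicate gene id: '", dup, "'", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))][1]
    stop("duplicate sample id: '", dup, "'", call. = FALSE)
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    stop(sprintf(
      "invalid count %s at gene '%s', sample '%s': counts must be nonnegative integers",
      format(counts[bad[1]]), rownames(counts)[i[1]], colnames(counts)[i[2]]
    ), call. = FALSE)
  }
  if (!is.null(gene_lengths)) {
    gene_lengths <- validate_gene_lengths(gene_lengths, rownames(counts))
  }
  structure(counts, gene_lengths = gene_lengths,
            class = c("count_matrix", "matrix", "array"))
}

validate_gene_lengths <- function(gene_lengths, gene_ids) {
  if (is.null(names(gene_lengths))) {
    if (length(gene_lengths) != length(gene_ids)) {
      stop("unnamed `gene_lengths` must have one value per gene", call. = FALSE)
    }
    names(gene_lengths) <- gene_ids
  }
  missing <- setdiff(gene_ids, names(gene_lengths))
  if (length(missing)) {
    stop("missing gene length for gene '", missing[1], "'", call. = FALSE)
  }
  gene_lengths <- gene_lengths[gene_ids]
  if (any(!is.finite(gene_lengths) | gene_lengths <= 0)) {
    bad <- names(gene_lengths)[which(!is.finite(gene_lengths) | gene_lengths <= 0)[1]]
    stop("gene length for '", bad, "' must be a positive number", call. = FALSE)
  }
  gene_lengths
}

#' @exportS3Method base::print
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples\n", nrow(x), ncol(x)))
  cat(sprintf("  library sizes: %s\n",
              paste(format(colSums(unclass(x)), big.mark = ","), collapse = ", ")))
  if (!is.null(attr(x, "gene_lengths"))) cat("  gene lengths: present\n")
  invisible(x)
}

#' Gene ids, sample ids, and gene lengths of a count matrix
#' @param x A `count_matrix`.
#' @return Character vector of ids, or a named numeric vector of lengths
#'   (`NULL` when absent).
#' @export
gene_ids <- function(x) rownames(x)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x)

#' @rdname gene_ids
#' @export
gene_lengths <- function(x) attr(x, "gene_lengths")

# plain numeric matrix view (drops class and attributes)
count_values <- function(x) {
  y <- unclass(x)
  attr(y, "gene_lengths") <- NULL
  y
}

#' Read a count matrix from TSV or MatrixMarket files
#'
#' TSV layout: a header row of sample ids and a first column of gene ids.
#' MatrixMarket layout: a coordinate `.mtx` file plus sidecar id files
#' `<path>.genes.txt` and `<path>.samples.txt`, one id per line.
#'
#' @param path File path (for `mtx`, the path of the `.mtx` file).
#' @param format `"tsv"` or `"mtx"`.
#' @param gene_lengths Optional named vector of gene lengths attached to the
#'   returned object (see [count_matrix()]).
#' @return A validated [count_matrix()].
#' @export
read_counts <- function(path, format = c("tsv", "mtx"), gene_lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- count_matrix(df, gene_lengths = gene_lengths)
  } else {
    genes <- readLines(paste0(path, ".genes.txt"))
    samples <- readLines(paste0(path, ".samples.txt"))
    mm <- as.matrix(Matrix::readMM(path))
    if (nrow(mm) != length(genes) || ncol(mm) != length(samples)) {
      stop("MatrixMarket dimensions do not match sidecar id files", call. = FALSE)
    }
    dimnames(mm) <- list(genes, samples)
    m <- count_matrix(mm, gene_lengths = gene_lengths)
  }
  m
}

#' Write a count matrix to TSV or MatrixMarket files
#'
#' @param x A [count_matrix()].
#' @param path Output path; for `mtx`, sidecar files `<path>.genes.txt` and
#'   `<path>.samples.txt` are written alongside.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  x <- if (inherits(x, "count_matrix")) x else count_matrix(x)
  if (format == "tsv") {
    df <- data.frame(gene_id = gene_ids(x), count_values(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(count_values(x), sparse = TRUE), path)
    writeLines(gene_ids(x), paste0(path, ".genes.txt"))
    writeLines(sample_ids(x), paste0(path, ".samples.txt"))
  }
  invisible(path)
}
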