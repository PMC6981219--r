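#' Normalization results
#'
#' Every normalization in the grid returns a `normalization_result`, one of
#' two kinds:
#'
#' * **factor** methods (TMM, UQ, Median, PoissonSeq) estimate one positive
#'   scale factor per sample — a relative effective sequencing depth,
#'   rescaled to geometric mean 1. The effective depth of sample *j* is
#'   `factor_j * geometric-mean library size`, and count models receive it
#'   as a natural-log offset.
#' * **matrix** methods (TMM_CPM, RPKM, FullQuantile, RUV) return a
#'   transformed gene-by-sample matrix. Rank and t tests consume it
#'   directly; count models receive it rounded to integers, with the cell
#'   flagged.
#'
#' @param method Method tag.
#' @param kind `"factor"` or `"matrix"`.
#' @param factors Named per-sample factors (geometric mean 1) for
#'   factor-kind results.
#' @param normalized Transformed matrix for matrix-kind results.
#' @param lib_sizes Raw per-sample library sizes (column sums).
#' @param params Method parameters echoed into run summaries.
#' @param notes Character vector of warnings/caveats attached to the result.
#' @return A `normalization_result` object.
#' @name normalization_result
NULL

new_normalization_result <- function(method, kind, lib_sizes,
                                     factors = NULL, normalized = NULL,
                                     params = list(), notes = character()) {
  stopifnot(kind %in% c("factor", "matrix"))
  if (is.null(factors) && is.null(normalized)) {
    stop("normalization must produce factors and/or a normalized matrix", call. = FALSE)
  }
  if (!is.null(factors)) {
    if (any(!is.finite(factors) | factors <= 0)) {
      stop("normalization factors must be strictly positive", call. = FALSE)
    }
    factors <- rescale_geomean(factors)
  }
  structure(
    list(method = method, kind = kind, factors = factors,
         normalized = normalized, lib_sizes = lib_sizes,
         params = params, notes = notes),
    class = "normalization_result"
  )
}

#' @exportS3Method base::print
print.normalization_result <- function(x, ...) {
  cat(sprintf("<normalization_result> %s (%s-kind)\n", x$method, x$kind))
  if (!is.null(x$factors)) {
    cat("  factors:", paste(sprintf("%.3f", x$factors), collapse = " "), "\n")
  }
  if (!is.null(x$normalized)) {
    cat(sprintf("  normalized matrix: %d x %d\n", nrow(x$normalized), ncol(x$normalized)))
  }
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

rescale_geomean <- function(x) x / exp(mean(log(x)))

#' Effective per-sample depths of a normalization result
#'
#' For factor-kind results, `factor_j` times the geometric-mean library
#' size (so depths stay on the library-size scale); for matrix-kind
#' results, the column sums of the normalized matrix.
#'
#' @param norm A `normalization_result`.
#' @return Named numeric vector of positive effective depths.
#' @export
effective_depth <- function(norm) {
  if (!is.null(norm$factors)) {
    norm$factors * exp(mean(log(norm$lib_sizes)))
  } else {
    depths <- colSums(norm$normalized)
    if (any(depths <= 0)) stop("normalized matrix has a nonpositive column sum", call. = FALSE)
    depths
  }
}

#' TMM scale factors (trimmed mean of M-values)
#'
#' Pairwise against a reference sample (the one whose 75th count/depth
#' percentile is closest to the mean), log2 ratios of depth-scaled counts
#' are doubly trimmed — `trim_m` on the M (ratio) scale, `trim_a` on the A
#' (abundance) scale — and averaged with inverse asymptotic-variance
#' weights. The per-sample factor is the library size times 2^(trimmed
#' mean), rescaled to geometric mean 1, i.e. a relative effective depth.
#'
#' @param counts A [count_matrix()].
#' @param trim_m Fraction trimmed from each tail of the M-values (default 0.30).
#' @param trim_a Fraction trimmed from each tail of the A-values (default 0.05).
#' @return A factor-kind `normalization_result`.
#' @export
norm_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  y <- count_values(counts)
  n_samp <- ncol(y)
  if (n_samp < 2) stop("TMM needs at least two samples", call. = FALSE)
  lib <- colSums(y)
  if (any(lib == 0)) {
    stop("sample '", colnames(y)[which(lib == 0)[1]], "' has zero total count", call. = FALSE)
  }
  f75 <- vapply(seq_len(n_samp), function(j) {
    stats::quantile(y[, j] / lib[j], 0.75, names = FALSE)
  }, numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  notes <- character()
  log2f <- vapply(seq_len(n_samp), function(j) {
    if (j == ref) return(0)
    m <- tmm_trimmed_mean(y[, j], y[, ref], lib[j], lib[ref], trim_m, trim_a)
    if (is.na(m)) {
      notes <<- c(notes, sprintf("sample '%s': all genes trimmed, factor fell back to 1",
                                 colnames(y)[j]))
      m <- 0
    }
    m
  }, numeric(1))
  if (length(notes)) warning(paste(notes, collapse = "; "))
  factors <- rescale_geomean(lib * 2^log2f)
  names(factors) <- colnames(y)
  new_normalization_result("TMM", "factor", lib, factors = factors,
                           params = list(trim_m = trim_m, trim_a = trim_a,
                                         reference = colnames(y)[ref]),
                           notes = notes)
}

# trimmed, variance-weighted mean of M-values for one sample vs the reference;
# NA when the double trim removes every usable gene
tmm_trimmed_mean <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a) & a > -1e10
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (length(m) == 0) return(NA_real_)
  if (max(abs(m)) < 1e-6) return(0)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep)) return(NA_real_)
  v <- pmax(v, 1e-12)
  sum(m[keep] / v[keep]) / sum(1 / v[keep])
}

#' Counts per million on effective depths
#'
#' `cpm[g, j] = counts[g, j] / effective_depth_j * 1e6`. With the default
#' depths (raw library sizes) every column of the result sums to one
#' million.
#'
#' @param counts A [count_matrix()].
#' @param depths Per-sample positive effective depths; defaults to the raw
#'   library sizes.
#' @return Numeric matrix of the same shape as `counts`.
#' @export
cpm_transform <- function(counts, depths = NULL) {
  y <- count_values(counts)
  if (is.null(depths)) depths <- colSums(y)
  if (length(depths) != ncol(y)) stop("one depth per sample required", call. = FALSE)
  if (any(!is.finite(depths) | depths <= 0)) {
    stop("effective depths must be positive", call. = FALSE)
  }
  sweep(y, 2, depths, "/") * 1e6
}

#' TMM-CPM normalization (matrix-kind)
#'
#' Counts per million computed on TMM effective depths.
#'
#' @inheritParams norm_tmm
#' @return A matrix-kind `normalization_result`.
#' @export
norm_tmm_cpm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  tmm <- norm_tmm(counts, trim_m = trim_m, trim_a = trim_a)
  mat <- cpm_transform(counts, depths = effective_depth(tmm))
  new_normalization_result("TMM_CPM", "matrix", tmm$lib_sizes, normalized = mat,
                           params = tmm$params, notes = tmm$notes)
}

#' RPKM normalization (matrix-kind)
#'
#' Reads per kilobase of merged exon model per million library reads:
#' `counts[g, j] / (length_kb(g) * libsize_millions(j))`. Gene lengths come
#' from the count matrix (see [count_matrix()] and
#' [gene_lengths_from_gtf()]).
#'
#' @param counts A [count_matrix()] carrying gene lengths.
#' @return A matrix-kind `normalization_result`.
#' @export
norm_rpkm <- function(counts) {
  len <- gene_lengths(counts)
  if (is.null(len)) {
    stop("RPKM requires gene lengths; attach them with count_matrix(..., gene_lengths=)",
         call. = FALSE)
  }
  y <- count_values(counts)
  lib <- colSums(y)
  mat <- y / (len / 1e3) %o% (lib / 1e6)
  new_normalization_result("RPKM", "matrix", lib, normalized = mat)
}

#' Upper-quartile scale factors
#'
#' Per-sample factor proportional to the 75th percentile of that sample's
#' nonzero counts (linear-interpolation percentile, index `0.75 * (n - 1)`),
#' rescaled to geometric mean 1.
#'
#' @param counts A [count_matrix()].
#' @return A factor-kind `normalization_result`.
#' @export
norm_uq <- function(counts) {
  y <- count_values(counts)
  uq <- vapply(seq_len(ncol(y)), function(j) {
    nz <- y[y[, j] > 0, j]
    if (length(nz) < 4) {
      stop("sample '", colnames(y)[j],
           "' has fewer than 4 genes with nonzero counts", call. = FALSE)
    }
    stats::quantile(nz, 0.75, names = FALSE, type = 7)
  }, numeric(1))
  factors <- rescale_geomean(uq)
  names(factors) <- colnames(y)
  new_normalization_result("UQ", "factor", colSums(y), factors = factors)
}

#' Median scale factors
#'
#' Per-sample factor proportional to the median of that sample's nonzero
#' counts, rescaled to geometric mean 1. (This is the median of nonzero
#' counts, not DESeq-style median-of-ratios.)
#'
#' @param counts A [count_matrix()].
#' @return A factor-kind `normalization_result`.
#' @export
norm_median <- function(counts) {
  y <- count_values(counts)
  med <- vapply(seq_len(ncol(y)), function(j) {
    nz <- y[y[, j] > 0, j]
    if (length(nz) == 0) {
      stop("sample '", colnames(y)[j], "' has no nonzero counts", call. = FALSE)
    }
    stats::median(nz)
  }, numeric(1))
  factors <- rescale_geomean(med)
  names(factors) <- colnames(y)
  new_normalization_result("Median", "factor", colSums(y), factors = factors)
}

#' Full-quantile normalization (matrix-kind)
#'
#' Forces every sample onto one common empirical distribution: each
#' sample's values are replaced rank-wise by the mean of the sorted
#' columns, with ties broken deterministically by input order. After the
#' transform every column holds the same sorted value multiset, and the
#' transform is idempotent. (Count matrices tie heavily at zero; averaging
#' tied positions instead would destroy both properties, so the
#' order-based convention is used.)
#'
#' @param counts A [count_matrix()].
#' @return A matrix-kind `normalization_result`.
#' @export
norm_full_quantile <- function(counts) {
  y <- count_values(counts)
  if (ncol(y) < 2) stop("full-quantile normalization needs at least two samples", call. = FALSE)
  new_normalization_result("FullQuantile", "matrix", colSums(y),
                           normalized = full_quantile_map(y))
}

# rank-wise substitution by the mean of the sorted columns. Ties are broken
# deterministically by input order (stable sort), which keeps every output
# column an exact permutation of the common reference vector and makes the
# transform idempotent; averaging tied positions instead would break both.
full_quantile_map <- function(y) {
  target <- rowMeans(apply(y, 2, sort))
  out <- y
  for (j in seq_len(ncol(y))) {
    out[order(y[, j]), j] <- target
  }
  out
}

#' PoissonSeq-style iterative depth factors
#'
#' Iterates between (1) scoring every gene with a Poisson goodness-of-fit
#' statistic against the current depth estimates and (2) re-estimating
#' depths from the least-variable half of genes (the presumed null set),
#' starting from library-size proportions. Stops when depths change by
#' less than `tol` or after `max_iter` sweeps.
#'
#' @param counts A [count_matrix()].
#' @param design A [study_design()] (two-group; kept for interface symmetry —
#'   the depth estimate itself is unsupervised).
#' @param max_iter,tol Iteration controls.
#' @return A factor-kind `normalization_result`; `params$converged` records
#'   whether the fixed point was reached (a warning is raised otherwise).
#' @export
norm_poissonseq <- function(counts, design = NULL, max_iter = 20, tol = 1e-8) {
  y <- count_values(counts)
  lib <- colSums(y)
  if (any(lib == 0)) {
    stop("sample '", colnames(y)[which(lib == 0)[1]], "' has zero total count", call. = FALSE)
  }
  d <- lib / sum(lib)
  total <- rowSums(y)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    expected <- total %o% d
    gof <- rowSums((y - expected)^2 / pmax(expected, 1e-12))
    null_set <- rank(gof, ties.method = "first") <= ceiling(nrow(y) / 2)
    d_new <- colSums(y[null_set, , drop = FALSE]) / sum(y[null_set, ])
    delta <- max(abs(d_new - d))
    d <- d_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("PoissonSeq depth estimation did not converge in ",
                          max_iter, " iterations; returning last iterate")
  factors <- rescale_geomean(d)
  names(factors) <- colnames(y)
  new_normalization_result("PoissonSeq", "factor", lib, factors = factors,
                           params = list(converged = converged, iterations = it))
}

#' RUV-style removal of unwanted variation (matrix-kind)
#'
#' On the log(count + 0.5) scale, condition means are removed per gene and
#' `k` unwanted factors are estimated by singular value decomposition of
#' the control-gene residual rows. All genes are then regressed on the
#' estimated factors and the fitted unwanted component is subtracted; the
#' adjusted matrix is returned on the linear scale, clipped at zero.
#'
#' @param counts A [count_matrix()].
#' @param design A [study_design()] aligned with `counts`.
#' @param k Number of unwanted factors (`1 <= k < n_samples - 2`).
#' @param control_genes `"empirical"` (the half of genes with the largest
#'   first-pass Welch-t p-values) or a character vector of gene ids assumed
#'   unaffected by the condition.
#' @return A matrix-kind `normalization_result`; the estimated factors are
#'   in `params$unwanted_factors` (samples x k).
#' @export
norm_ruv <- function(counts, design, k = 1, control_genes = "empirical") {
  y <- count_values(counts)
  design <- align_design(counts, design)
  n_samp <- ncol(y)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  if (k >= n_samp - 2) {
    stop("`k` must be smaller than n_samples - 2 (got k = ", k,
         " with ", n_samp, " samples)", call. = FALSE)
  }
  lmat <- log(y + 0.5)
  grp <- design$condition
  resid <- lmat
  for (lev in levels(grp)) {
    idx <- which(grp == lev)
    resid[, idx] <- lmat[, idx] - rowMeans(lmat[, idx, drop = FALSE])
  }
  if (identical(control_genes, "empirical")) {
    p1 <- welch_stats(lmat, grp == levels(grp)[2])$p_value
    p1[is.na(p1)] <- 1
    ctrl <- rank(-p1, ties.method = "first") <= ceiling(nrow(y) / 2)
  } else {
    ctrl <- rownames(y) %in% control_genes
  }
  if (sum(ctrl) < k + 1) {
    stop("need at least k + 1 = ", k + 1, " control genes, got ", sum(ctrl), call. = FALSE)
  }
  sv <- svd(resid[ctrl, , drop = FALSE], nu = 0, nv = k)
  w <- sv$v[, seq_len(k), drop = FALSE]
  rownames(w) <- colnames(y)
  alpha <- resid %*% w          # w has orthonormal columns
  adjusted <- lmat - alpha %*% t(w)
  mat <- pmax(exp(adjusted) - 0.5, 0)
  dimnames(mat) <- dimnames(y)
  new_normalization_result("RUV", "matrix", colSums(y), normalized = mat,
                           params = list(k = k,
                                         control = if (identical(control_genes, "empirical"))
                                           "empirical" else "user",
                                         unwanted_factors = w))
}

# ---- registry -------------------------------------------------------------

.norm_registry <- new.env(parent = emptyenv())

#' The normalization grid axis
#'
#' `default_normalizations()` lists the eight built-in methods.
#' `register_normalization()` adds a user-supplied method (for example to
#' restore a ninth, externally computed normalization and run a
#' 9-by-5 = 45-cell grid); `registered_normalizations()` lists additions.
#'
#' @param name Method tag (must not clash with a built-in).
#' @param fn Function `(counts, design) -> normalization_result`.
#' @return Character vector of method names, or (for the registration)
#'   `name` invisibly.
#' @export
default_normalizations <- function() {
  c("TMM", "TMM_CPM", "RPKM", "UQ", "FullQuantile", "Median", "PoissonSeq", "RUV")
}

#' @rdname default_normalizations
#' @export
register_normalization <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  if (name %in% default_normalizations()) {
    stop("'", name, "' is a built-in normalization", call. = FALSE)
  }
  assign(name, fn, envir = .norm_registry)
  invisible(name)
}

#' @rdname default_normalizations
#' @export
registered_normalizations <- function() ls(.norm_registry)

#' @rdname default_normalizations
#' @export
clear_registered_normalizations <- function() {
  rm(list = ls(.norm_registry), envir = .norm_registry)
  invisible(NULL)
}

#' Apply one normalization by name
#'
#' @param counts A [count_matrix()].
#' @param method A name from [default_normalizations()] or a registered one.
#' @param design A [study_design()] (needed by PoissonSeq, RUV and possibly
#'   registered methods).
#' @param ruv_k,ruv_control_genes Parameters forwarded to [norm_ruv()].
#' @return A `normalization_result`.
#' @export
normalize_counts <- function(counts, method, design = NULL,
                             ruv_k = 1, ruv_control_genes = "empirical") {
  switch(method,
    TMM = norm_tmm(counts),
    TMM_CPM = norm_tmm_cpm(counts),
    RPKM = norm_rpkm(counts),
    UQ = norm_uq(counts),
    FullQuantile = norm_full_quantile(counts),
    Median = norm_median(counts),
    PoissonSeq = norm_poissonseq(counts, design),
    RUV = norm_ruv(counts, design, k = ruv_k, control_genes = ruv_control_genes),
    {
      if (!exists(method, envir = .norm_registry)) {
        stop("unknown normalization method '", method, "'", call. = FALSE)
      }
      get(method, envir = .norm_registry)(counts, design)
    }
  )
}
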