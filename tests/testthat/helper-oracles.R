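# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (loops, enumeration, per-base bitmaps) so they share no
# code path with the package implementation they check.

rnb_counts <- function(n_genes, n_samples, mu = 100, phi = 0.2, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnbinom(n_genes * n_samples, mu = mu, size = 1 / phi),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  count_matrix(m)
}

two_group_design <- function(n_per_group, ids = NULL) {
  ids <- ids %||% c(sprintf("c%d", seq_len(n_per_group)),
                    sprintf("t%d", seq_len(n_per_group)))
  study_design(ids, rep(c("control", "treatment"), each = n_per_group))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Benjamini-Hochberg step-up, written literally from the definition
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, p[ord[j]] * m / j)
    q_sorted[i] <- min(c(vals, 1))
  }
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  u_stat <- function(a, b) sum(outer(a, b, ">"))
  u_obs <- u_stat(x, y)
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) u_stat(pool[idx], pool[-idx]))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# per-base bitmap length of a union of 1-based inclusive intervals
coverage_length <- function(starts, ends) {
  covered <- logical(max(ends))
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  sum(covered)
}

# write a GTF for a list of genes; each element is a list of isoforms, each
# isoform a 2-column matrix of (start, end) exon intervals
write_gtf <- function(genes, path) {
  lines <- character(0)
  for (g in names(genes)) {
    for (ti in seq_along(genes[[g]])) {
      ex <- genes[[g]][[ti]]
      for (r in seq_len(nrow(ex))) {
        lines <- c(lines, sprintf(
          "chr1\ttest\texon\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; transcript_id \"%s.t%d\";",
          ex[r, 1], ex[r, 2], g, g, ti))
      }
    }
  }
  writeLines(lines, path)
  path
}

# --- straight-line transcriptions of the normalization formulas -----------

manual_quantile75 <- function(v) {
  s <- sort(v)
  h <- 0.75 * (length(s) - 1)
  lo <- floor(h)
  if (lo + 2 > length(s)) return(s[lo + 1])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

oracle_uq_factors <- function(y) {
  uq <- apply(y, 2, function(col) manual_quantile75(col[col > 0]))
  uq / exp(mean(log(uq)))
}

oracle_median_factors <- function(y) {
  med <- apply(y, 2, function(col) {
    nz <- sort(col[col > 0])
    n <- length(nz)
    if (n %% 2 == 1) nz[(n + 1) / 2] else (nz[n / 2] + nz[n / 2 + 1]) / 2
  })
  med / exp(mean(log(med)))
}

oracle_rpkm <- function(y, len) {
  lib <- colSums(y)
  out <- y
  for (g in seq_len(nrow(y))) for (j in seq_len(ncol(y))) {
    out[g, j] <- y[g, j] / ((len[g] / 1000) * (lib[j] / 1e6))
  }
  out
}

oracle_cpm <- function(y, depths) {
  out <- y
  for (j in seq_len(ncol(y))) out[, j] <- y[, j] / depths[j] * 1e6
  out
}

oracle_full_quantile <- function(y) {
  # mean of sorted columns, computed entry by entry
  n <- nrow(y)
  target <- numeric(n)
  for (i in seq_len(n)) {
    vals <- numeric(ncol(y))
    for (j in seq_len(ncol(y))) vals[j] <- sort(y[, j])[i]
    target[i] <- mean(vals)
  }
  out <- y
  for (j in seq_len(ncol(y))) {
    o <- order(y[, j])            # stable: ties keep input order
    for (i in seq_len(n)) out[o[i], j] <- target[i]
  }
  out
}

# doubly trimmed variance-weighted TMM, written from the formula
oracle_tmm_factors <- function(y, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(y)
  f75 <- vapply(seq_len(ncol(y)), function(j) manual_quantile75_all(y[, j] / lib[j]),
                numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  log2f <- vapply(seq_len(ncol(y)), function(j) {
    if (j == ref) return(0)
    obs <- y[, j]; rf <- y[, ref]
    keep0 <- obs > 0 & rf > 0
    obs <- obs[keep0]; rf <- rf[keep0]
    m <- log2((obs / lib[j]) / (rf / lib[ref]))
    a <- 0.5 * (log2(obs / lib[j]) + log2(rf / lib[ref]))
    v <- (lib[j] - obs) / (lib[j] * obs) + (lib[ref] - rf) / (lib[ref] * rf)
    if (max(abs(m)) < 1e-6) return(0)
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    sel <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
    v <- pmax(v, 1e-12)
    sum((m / v)[sel]) / sum((1 / v)[sel])
  }, numeric(1))
  f <- lib * 2^log2f
  f / exp(mean(log(f)))
}

manual_quantile75_all <- function(v) {
  s <- sort(v)
  h <- 0.75 * (length(s) - 1)
  lo <- floor(h)
  if (lo + 2 > length(s)) return(s[lo + 1])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

# PoissonSeq-style iterative depths, written with explicit loops
oracle_poissonseq_factors <- function(y, max_iter = 20, tol = 1e-8) {
  d <- colSums(y) / sum(y)
  for (it in seq_len(max_iter)) {
    gof <- numeric(nrow(y))
    for (g in seq_len(nrow(y))) {
      tot <- sum(y[g, ])
      for (j in seq_len(ncol(y))) {
        e <- tot * d[j]
        gof[g] <- gof[g] + (y[g, j] - e)^2 / max(e, 1e-12)
      }
    }
    keep <- order(gof)[seq_len(ceiling(nrow(y) / 2))]
    d_new <- colSums(y[keep, , drop = FALSE]) / sum(y[keep, ])
    if (max(abs(d_new - d)) < tol) { d <- d_new; break }
    d <- d_new
  }
  d / exp(mean(log(d)))
}

# RUV adjustment via eigen decomposition and per-gene lm(), instead of the
# package's svd + matrix algebra
oracle_ruv <- function(y, treat, k = 1) {
  lmat <- log(y + 0.5)
  resid <- lmat
  for (g in seq_len(nrow(y))) {
    resid[g, !treat] <- lmat[g, !treat] - mean(lmat[g, !treat])
    resid[g, treat] <- lmat[g, treat] - mean(lmat[g, treat])
  }
  pvals <- apply(lmat, 1, function(v) {
    if (stats::sd(v[treat]) == 0 && stats::sd(v[!treat]) == 0) return(1)
    tryCatch(stats::t.test(v[treat], v[!treat])$p.value, error = function(e) 1)
  })
  ctrl <- order(-pvals)[seq_len(ceiling(nrow(y) / 2))]
  ev <- eigen(crossprod(resid[ctrl, , drop = FALSE]), symmetric = TRUE)
  w <- ev$vectors[, seq_len(k), drop = FALSE]
  adj <- lmat
  for (g in seq_len(nrow(y))) {
    fit <- stats::lm(resid[g, ] ~ 0 + w)
    adj[g, ] <- lmat[g, ] - as.vector(w %*% stats::coef(fit))
  }
  pmax(exp(adj) - 0.5, 0)
}

# one-sided anti-conservatism distance of p-values from Uniform(0,1):
# sup_t ( ecdf(t) - t ). A valid (possibly discrete) test keeps this small.
dplus_uniform <- function(p) {
  p <- sort(p)
  max(seq_along(p) / length(p) - p)
}

# fabricate a consensus_grid with prescribed q-values/lfc for rule tests
fake_grid <- function(q_array, lfc_array = NULL, gene_ids = NULL) {
  norms <- dimnames(q_array)[[2]]
  models <- dimnames(q_array)[[3]]
  gene_ids <- gene_ids %||% sprintf("g%d", seq_len(dim(q_array)[1]))
  if (is.null(lfc_array)) {
    lfc_array <- array(1, dim(q_array), dimnames = dimnames(q_array))
  }
  cells <- list()
  for (nm in norms) for (md in models) {
    cells[[paste(nm, md, sep = "|")]] <- de_result(
      gene_ids, lfc_array[, nm, md], stat = rep(0, length(gene_ids)),
      p_value = q_array[, nm, md], q_value = q_array[, nm, md],
      normalization = nm, model = md
    )
  }
  structure(list(cells = cells, normalizations = norms, models = models,
                 gene_ids = gene_ids, design = NULL,
                 cell_notes = stats::setNames(as.list(rep("", length(cells))),
                                              names(cells))),
            class = "consensus_grid")
}
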