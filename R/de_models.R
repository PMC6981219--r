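#' @name de_models
#' @title The five differential-expression models
#' @description
#' Each model consumes a two-group design and returns a [de_result()] with
#' Benjamini-Hochberg q-values over all tested genes. Count models
#' (`nb_wald_test`, `nb_lrt_robust_test`) work on raw counts with
#' per-sample log offsets; `voom_moderated_t_test` works on counts with
#' effective depths; rank and t tests work on any normalized matrix.
#' Genes with zero counts in every sample are never dropped — they get
#' `log2_fc = 0`, `p = q = 1` and the flag `"all_zero"`, so the gene
#' universe is identical in every grid cell.
NULL

#' Negative-binomial Wald test
#'
#' Fits group-specific NB means by maximum likelihood at fixed gene-wise
#' dispersion (vectorised Newton iterations on the log mean), with the
#' per-sample depth entering as an offset. The log2 fold change is the
#' (unshrunken) log2 ratio of fitted treatment over control means — under
#' equal offsets these are the group sample means. The Wald statistic is
#' lfc over its standard error from observed Fisher information, with a
#' two-sided normal p-value.
#'
#' A group with all-zero counts for a gene is given a pseudo-mean
#' equivalent to half a read over the group (flag `"zero_group"`).
#'
#' @param counts A [count_matrix()] or integer matrix.
#' @param design A [study_design()].
#' @param dispersion A `dispersion_fit` from [fit_dispersion()]; fitted
#'   internally when missing.
#' @param offsets Per-sample natural-log offsets (default: equal depths).
#' @param normalization Tag recorded on the result.
#' @return A [de_result()].
#' @export
nb_wald_test <- function(counts, design, dispersion = NULL, offsets = NULL,
                         normalization = NA_character_) {
  y <- if (inherits(counts, "count_matrix")) count_values(counts) else as.matrix(counts)
  design <- if (inherits(counts, "count_matrix")) align_design(counts, design) else design
  if (is.null(dispersion)) dispersion <- fit_dispersion(y, design, offsets)
  phi <- dispersion$final
  s <- depth_scale(offsets, ncol(y))
  treat <- treatment_indicator(design) == 1

  fit_c <- nb_group_fit(y[, !treat, drop = FALSE], s[!treat], phi)
  fit_t <- nb_group_fit(y[, treat, drop = FALSE], s[treat], phi)

  lfc <- log2(fit_t$beta / fit_c$beta)
  se <- sqrt(1 / fit_t$info + 1 / fit_c$info) / log(2)
  stat <- ifelse(fit_t$beta == fit_c$beta, 0, lfc / se)
  p <- 2 * stats::pnorm(-abs(stat))

  flag <- ifelse(fit_c$zero | fit_t$zero, "zero_group", "")
  res <- finalize_de(y, lfc, stat, p, flag, normalization, "nb_wald")
  res
}

#' Robust negative-binomial likelihood-ratio test
#'
#' Compares group-specific versus common NB means at fixed gene-wise
#' dispersion. Observation weights make the test resistant to outliers:
#' after an unweighted full fit, any observation whose Pearson residual
#' `r` exceeds 2.5 in absolute value is down-weighted to `2.5 / |r|`, and
#' both the full and the null model are refit under those fixed weights.
#' The statistic `2 * (l_full - l_null)` is referred to chi-square with
#' one degree of freedom. The reported log2 fold change is the unweighted
#' group-mean ratio, as in [nb_wald_test()].
#'
#' @inheritParams nb_wald_test
#' @param outlier_c Pearson-residual threshold above which observations
#'   are down-weighted (default 2.5).
#' @return A [de_result()].
#' @export
nb_lrt_robust_test <- function(counts, design, dispersion = NULL, offsets = NULL,
                               normalization = NA_character_, outlier_c = 2.5) {
  y <- if (inherits(counts, "count_matrix")) count_values(counts) else as.matrix(counts)
  design <- if (inherits(counts, "count_matrix")) align_design(counts, design) else design
  if (is.null(dispersion)) dispersion <- fit_dispersion(y, design, offsets)
  phi <- dispersion$final
  s <- depth_scale(offsets, ncol(y))
  treat <- treatment_indicator(design) == 1

  # unweighted full fit -> lfc and robustness weights
  fit_c <- nb_group_fit(y[, !treat, drop = FALSE], s[!treat], phi)
  fit_t <- nb_group_fit(y[, treat, drop = FALSE], s[treat], phi)
  mu <- matrix(0, nrow(y), ncol(y))
  mu[, !treat] <- fit_c$beta %o% s[!treat]
  mu[, treat] <- fit_t$beta %o% s[treat]
  r <- (y - mu) / sqrt(pmax(mu + phi * mu^2, 1e-12))
  w <- pmin(outlier_c / pmax(abs(r), 1e-12), 1)   # pmin(matrix, 1) keeps dims

  llw_full <- nb_group_fit(y[, !treat, drop = FALSE], s[!treat], phi,
                           weights = w[, !treat, drop = FALSE])$loglik +
              nb_group_fit(y[, treat, drop = FALSE], s[treat], phi,
                           weights = w[, treat, drop = FALSE])$loglik
  llw_null <- nb_group_fit(y, s, phi, weights = w)$loglik

  stat <- pmax(2 * (llw_full - llw_null), 0)
  stat[fit_c$beta == fit_t$beta] <- 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  lfc <- log2(fit_t$beta / fit_c$beta)
  flag <- ifelse(fit_c$zero | fit_t$zero, "zero_group", "")
  finalize_de(y, lfc, stat, p, flag, normalization, "nb_lrt_robust")
}

# MLE of a common NB mean (per gene) over a set of samples with fixed
# dispersion phi, depth scales s and optional observation weights.
# Solves sum_j w_j (y_j - beta * s_j) / (1 + phi * beta * s_j) = 0 by
# Newton iteration on log(beta), vectorised over genes.
nb_group_fit <- function(y, s, phi, weights = NULL) {
  g <- nrow(y)
  if (is.null(weights)) weights <- matrix(1, g, length(s))
  sw <- weights * rep(s, each = g)
  tot <- rowSums(weights * y)
  zero <- tot == 0
  beta <- tot / rowSums(sw)
  beta[zero] <- 0.5 / sum(s)           # pseudo-mean: half a read over the group
  u <- log(beta)
  for (it in 1:50) {
    mu <- exp(u) * rep(s, each = g); dim(mu) <- dim(y)
    denom <- 1 + phi * mu
    score <- rowSums(weights * (y - mu) / denom)
    info <- rowSums(weights * mu / denom)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    step[zero] <- 0
    u <- u + step
    if (max(abs(step)) < 1e-12) break
  }
  beta <- exp(u)
  mu <- beta * rep(s, each = g); dim(mu) <- dim(y)
  denom <- 1 + phi * mu
  info <- rowSums(weights * mu / denom)
  ll <- rowSums(weights * nb_loglik_terms(y, mu, phi))
  list(beta = beta, info = pmax(info, 1e-12), zero = zero, loglik = ll)
}

# per-observation NB log-likelihood terms without the phi-only constants
# (which cancel in likelihood ratios at fixed phi and fixed weights)
nb_loglik_terms <- function(y, mu, phi) {
  phim <- matrix(phi, nrow(y), ncol(y))
  small <- phim < 1e-8
  out <- y * log(pmax(mu, 1e-300)) - (y + 1 / pmax(phim, 1e-8)) * log1p(phim * mu)
  if (any(small)) {
    pois <- y * log(pmax(mu, 1e-300)) - mu
    out[small] <- pois[small]
  }
  out
}

#' Voom moderated t-test
#'
#' Log-CPM transform `log2((count + 0.5) / (depth + 1) * 1e6)`, a locally
#' weighted mean-variance trend giving each observation a precision
#' weight, a weighted two-group linear fit, and empirical-Bayes moderation
#' of the residual variances toward a common prior, yielding a moderated t
#' with augmented degrees of freedom. Implemented with
#' [limma::voom()] / [limma::lmFit()] / [limma::eBayes()].
#'
#' With fewer than 10 genes the mean-variance trend is unreliable and the
#' function falls back to an unweighted Welch t on the log-CPM values,
#' with a warning.
#'
#' @inheritParams nb_wald_test
#' @param depths Per-sample effective depths (default: column sums).
#' @return A [de_result()].
#' @export
voom_moderated_t_test <- function(counts, design, depths = NULL,
                                  normalization = NA_character_) {
  y <- if (inherits(counts, "count_matrix")) count_values(counts) else as.matrix(counts)
  design <- if (inherits(counts, "count_matrix")) align_design(counts, design) else design
  if (is.null(depths)) depths <- colSums(y)
  treat <- treatment_indicator(design)
  if (nrow(y) < 10) {
    warning("fewer than 10 genes: mean-variance trend unreliable, ",
            "falling back to unweighted Welch t on log-CPM")
    lcpm <- log2((y + 0.5) / rep(depths + 1, each = nrow(y)) * 1e6)
    st <- welch_stats(lcpm, treat == 1)
    return(finalize_de(y, st$mean_diff, st$t, st$p_value,
                       ifelse(st$degenerate, "degenerate", ""),
                       normalization, "voom"))
  }
  mm <- stats::model.matrix(~treat)
  v <- limma::voom(y, design = mm, lib.size = depths)
  fit <- limma::eBayes(limma::lmFit(v, mm))
  lfc <- fit$coefficients[, 2]
  stat <- fit$t[, 2]
  p <- fit$p.value[, 2]
  # a zero effect with (numerically) zero residuals is a 0/0 of rounding
  # errors — the mean-variance trend has no signal to fit there and the
  # precision weights blow up; that is "no evidence", not a statistic
  resid <- v$E - fit$coefficients %*% t(mm)
  degen <- abs(lfc) < 1e-8 & apply(abs(resid), 1, max) < 1e-8
  lfc[degen] <- 0
  stat[degen] <- 0
  p[degen] <- 1
  finalize_de(y, lfc, stat, p, rep("", nrow(y)), normalization, "voom")
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Per gene, the rank-sum U statistic of control versus treatment values.
#' The p-value is exact (full enumeration of orderings) when the combined
#' sample size is at most 10 and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections is used (via
#' [stats::wilcox.test()]). Genes whose values are identical across all
#' samples get `p = 1`. The reported log2 fold change,
#' `log2((mean_t + 0.5) / (mean_c + 0.5))`, is for display only — the test
#' itself is rank-based.
#'
#' @param normalized Numeric gene-by-sample matrix from any normalization.
#' @param design A [study_design()].
#' @param normalization Tag recorded on the result.
#' @param exact_max Combined sample size at or below which the exact
#'   enumeration p-value is used for tie-free genes (default 10).
#' @return A [de_result()].
#' @export
mann_whitney_test <- function(normalized, design, normalization = NA_character_,
                              exact_max = 10) {
  y <- as.matrix(normalized)
  treat <- treatment_indicator(design) == 1
  x1 <- y[, !treat, drop = FALSE]
  x2 <- y[, treat, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  stat <- numeric(nrow(y)); p <- numeric(nrow(y))
  for (g in seq_len(nrow(y))) {
    a <- x1[g, ]; b <- x2[g, ]
    if (max(c(a, b)) == min(c(a, b))) {
      stat[g] <- n1 * n2 / 2; p[g] <- 1
      next
    }
    use_exact <- (n1 + n2 <= exact_max) && !anyDuplicated(c(a, b))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact, correct = TRUE))
    stat[g] <- unname(wt$statistic)
    p[g] <- min(wt$p.value, 1)
  }
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  lfc <- log2((m2 + 0.5) / (m1 + 0.5))
  finalize_de(y, lfc, stat, p, rep("", nrow(y)), normalization, "mann_whitney")
}

#' Welch two-sample t-test
#'
#' Per gene, the unequal-variance t statistic with Satterthwaite degrees
#' of freedom and a two-sided p-value, computed on `log2(x + 0.5)` values
#' by default. Degenerate genes (zero variance in both groups) get `p = 1`
#' when the means agree and `p = 0` with flag `"degenerate"` otherwise.
#'
#' @inheritParams mann_whitney_test
#' @param log_scale Log2-transform with pseudo-count 0.5 first (default TRUE).
#' @return A [de_result()]; `log2_fc` is the difference of group means of
#'   the log2 values (or the log2 ratio of group means when
#'   `log_scale = FALSE`).
#' @export
welch_t_test <- function(normalized, design, log_scale = TRUE,
                         normalization = NA_character_) {
  y <- as.matrix(normalized)
  treat <- treatment_indicator(design) == 1
  x <- if (log_scale) log2(y + 0.5) else y
  st <- welch_stats(x, treat)
  lfc <- if (log_scale) st$mean_diff else {
    log2((rowMeans(y[, treat, drop = FALSE]) + 0.5) /
         (rowMeans(y[, !treat, drop = FALSE]) + 0.5))
  }
  finalize_de(y, lfc, st$t, st$p_value,
              ifelse(st$degenerate, "degenerate", ""), normalization, "welch_t")
}

# vectorised Welch statistics on a transformed matrix
welch_stats <- function(x, treat) {
  x1 <- x[, !treat, drop = FALSE]; x2 <- x[, treat, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, (m2 - m1) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
               1)
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se2 == 0 & m1 != m2
  p[degen] <- 0
  tstat[degen] <- sign(m2 - m1)[degen] * Inf
  p[se2 == 0 & m1 == m2] <- 1
  tibble::tibble(mean_diff = m2 - m1, t = tstat, df = df,
                 p_value = pmin(pmax(p, 0), 1), degenerate = degen)
}

# Uniform handling of all-zero genes and assembly into a de_result.
# `raw` is the matrix the model ran on; genes that are zero in every
# sample are neutralised so every grid cell shares one gene universe.
finalize_de <- function(raw, lfc, stat, p, flag, normalization, model) {
  all_zero <- rowSums(abs(raw)) == 0
  lfc[all_zero] <- 0
  stat[all_zero] <- 0
  p[all_zero] <- 1
  flag[all_zero] <- "all_zero"
  p[is.na(p)] <- 1
  de_result(rownames(raw) %||% as.character(seq_len(nrow(raw))),
            lfc, stat, p, flag = flag,
            normalization = normalization, model = model)
}

#' The model grid axis
#' @return Character vector of the five model tags.
#' @export
default_models <- function() {
  c("nb_wald", "nb_lrt_robust", "voom", "mann_whitney", "welch_t")
}
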