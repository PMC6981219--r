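#' Gene-wise negative-binomial dispersion with trend shrinkage
#'
#' Dispersion is parameterised so that the NB variance is
#' `mu + phi * mu^2`. The estimator has three stages shared by both NB
#' models of the grid:
#'
#' 1. **raw**: method-of-moments within each condition group on
#'    depth-adjusted counts, pooled across groups with df weights and
#'    clipped at zero;
#' 2. **trend**: `phi(mu) = a / mu + b` fitted by robust (M-estimation)
#'    least squares over genes with positive raw dispersion, with `a, b`
#'    clamped nonnegative;
#' 3. **final**: the geometric mean of raw and trend values (equal
#'    log-weights), which always lies between the two; genes whose raw
#'    estimate is zero or undefined take the trend value.
#'
#' @param counts A [count_matrix()] (or plain integer matrix).
#' @param design A [study_design()] aligned with the columns of `counts`.
#' @param offsets Optional per-sample natural-log offsets (e.g.
#'   `log(effective_depth(norm))`); default zero (equal depths).
#' @return A `dispersion_fit`: a tibble with columns `gene_id`, `mean`,
#'   `raw`, `trend`, `final` and attributes `trend_a`, `trend_b`.
#' @export
fit_dispersion <- function(counts, design, offsets = NULL) {
  y <- if (inherits(counts, "count_matrix")) count_values(counts) else as.matrix(counts)
  design <- if (inherits(counts, "count_matrix")) align_design(counts, design) else design
  s <- depth_scale(offsets, ncol(y))
  z <- sweep(y, 2, s, "/")
  grp <- design$condition
  num <- rep(0, nrow(y)); den <- rep(0, nrow(y)); mean_sq <- rep(0, nrow(y))
  for (lev in levels(grp)) {
    idx <- which(grp == lev)
    zk <- z[, idx, drop = FALSE]
    m <- rowMeans(zk)
    v <- apply(zk, 1, stats::var)
    ck <- mean(1 / s[idx])
    df <- length(idx) - 1
    ok <- m > 0
    # (v - m * ck) / m^2 estimates phi within a group; df-weighted pooling
    num[ok] <- num[ok] + df * (v[ok] - m[ok] * ck)
    den[ok] <- den[ok] + df * m[ok]^2
  }
  raw <- ifelse(den > 0, pmax(num / den, 0), NA_real_)
  mu <- rowMeans(z)

  # Log-scale consistency correction for the small-sample skew of the
  # moment estimator: its sampling distribution is approximately
  # chi2_df / df (df = n - 2 residual degrees of freedom), whose log is
  # centred at digamma(df/2) - log(df/2) < 0. Multiplying by the inverse
  # makes the geometric mean of raw estimates — and, because log chi2 is
  # near-symmetric, also their median, the target of the robust trend
  # fit — line up with the true dispersion. Without this the final
  # dispersions sit ~8% low at n = 6/group and the NB tests run visibly
  # anti-conservative.
  df_resid <- max(ncol(y) - 2, 1)
  log_bias <- digamma(df_resid / 2) - log(df_resid / 2)
  raw <- raw * exp(-log_bias)

  fit_genes <- which(!is.na(raw) & raw > 0 & mu > 0)
  if (length(fit_genes) < 3) {
    fallback <- stats::median(raw[!is.na(raw) & raw > 0])
    if (!is.finite(fallback)) fallback <- 0.1
    warning("too few genes with positive raw dispersion; ",
            "trend replaced by global median ", signif(fallback, 3))
    a <- 0; b <- fallback
  } else {
    cf <- tryCatch(
      stats::coef(MASS::rlm(raw[fit_genes] ~ I(1 / mu[fit_genes]), maxit = 50)),
      error = function(e) stats::coef(stats::lm(raw[fit_genes] ~ I(1 / mu[fit_genes])))
    )
    b <- max(cf[1], 0); a <- max(cf[2], 0)
    if (a == 0 && b == 0) b <- stats::median(raw[fit_genes])
  }
  trend <- pmax(a / pmax(mu, 1e-8) + b, 1e-8)
  final <- ifelse(!is.na(raw) & raw > 0, sqrt(raw * trend), trend)

  out <- tibble::tibble(
    gene_id = rownames(y) %||% as.character(seq_len(nrow(y))),
    mean = mu, raw = raw, trend = trend, final = final
  )
  attr(out, "trend_a") <- unname(a)
  attr(out, "trend_b") <- unname(b)
  class(out) <- c("dispersion_fit", class(out))
  out
}

# per-sample depth scale with geometric mean 1, from natural-log offsets
depth_scale <- function(offsets, n_samples) {
  if (is.null(offsets)) return(rep(1, n_samples))
  stopifnot(length(offsets) == n_samples)
  exp(offsets - mean(offsets))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
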