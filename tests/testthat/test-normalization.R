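test_that("factor methods return 1 for identical columns and geometric mean 1", {
  base <- rnb_counts(60, 1, mu = 200, seed = 5)
  y <- matrix(rep(unclass(base)[, 1], 5), ncol = 5,
              dimnames = list(gene_ids(base), paste0("s", 1:5)))
  cm <- count_matrix(y)
  d <- two_group_design(2, ids = colnames(y)[1:4])
  for (res in list(norm_tmm(cm), norm_uq(cm), norm_median(cm),
                   norm_poissonseq(cm))) {
    expect_equal(unname(res$factors), rep(1, 5), tolerance = 1e-12,
                 label = res$method)
  }
})

test_that("factors track per-sample depth: doubling a column doubles its factor", {
  base <- rnb_counts(200, 1, mu = 150, seed = 6)
  v <- unclass(base)[, 1]
  y <- cbind(s1 = v, s2 = v, s3 = 2 * v, s4 = v)
  rownames(y) <- gene_ids(base)
  cm <- count_matrix(y)
  tmm <- norm_tmm(cm)
  expect_equal(unname(tmm$factors[3] / tmm$factors[1]), 2, tolerance = 1e-6)
  uq <- norm_uq(cm)
  expect_equal(unname(uq$factors[3] / uq$factors[1]), 2, tolerance = 1e-12)
  med <- norm_median(cm)
  expect_equal(unname(med$factors[3] / med$factors[1]), 2, tolerance = 1e-12)

  # factor vectors always have geometric mean 1
  for (res in list(tmm, uq, med)) {
    expect_equal(exp(mean(log(res$factors))), 1, tolerance = 1e-12)
  }
})

test_that("TMM matches an independent transcription of the trimmed weighted mean", {
  cm <- rnb_counts(50, 6, mu = 120, phi = 0.15, seed = 7)
  got <- norm_tmm(cm)$factors
  expect_equal(unname(got), unname(oracle_tmm_factors(unclass(cm))),
               tolerance = 1e-10)
})

test_that("TMM agrees with edgeR's effective library sizes", {
  cm <- rnb_counts(300, 6, mu = 90, phi = 0.2, seed = 8)
  y <- unclass(cm)
  fe <- edgeR::calcNormFactors(y, method = "TMM")
  eff <- colSums(y) * fe
  expect_equal(unname(norm_tmm(cm)$factors),
               unname(eff / exp(mean(log(eff)))), tolerance = 1e-10)
})

test_that("upper-quartile factor uses the interpolated 75th percentile of nonzero counts", {
  y <- cbind(s1 = c(4, 8, 12, 16, 0, 0),
             s2 = c(8, 16, 24, 32, 0, 0))
  rownames(y) <- paste0("g", 1:6)
  res <- norm_uq(count_matrix(y))
  # hand percentile: index 0.75*(4-1) = 2.25 -> 12 + 0.25*(16-12) = 13
  expect_equal(unname(res$factors), c(13, 26) / sqrt(13 * 26), tolerance = 1e-12)
  sparse <- cbind(a = c(1, 2, 3, 0), b = c(1, 1, 1, 1))
  rownames(sparse) <- paste0("g", 1:4)
  expect_error(norm_uq(count_matrix(sparse)), "fewer than 4")
})

test_that("UQ and median factors match straight-line oracles on random matrices", {
  cm <- rnb_counts(50, 6, mu = 60, seed = 9)
  y <- unclass(cm)
  expect_equal(unname(norm_uq(cm)$factors), unname(oracle_uq_factors(y)),
               tolerance = 1e-12)
  expect_equal(unname(norm_median(cm)$factors), unname(oracle_median_factors(y)),
               tolerance = 1e-12)
  # median of nonzero counts on a tiny literal column
  y2 <- cbind(s1 = c(2, 4, 6, 0), s2 = c(2, 4, 6, 0) * 3)
  rownames(y2) <- paste0("g", 1:4)
  med <- norm_median(count_matrix(y2))
  expect_equal(unname(med$factors[2] / med$factors[1]), 3, tolerance = 1e-12)
})

test_that("CPM and RPKM are the unit-definition transforms", {
  y <- cbind(s1 = c(10, 999990), s2 = c(50, 999950))
  rownames(y) <- c("gA", "gB")
  cm <- count_matrix(y, gene_lengths = c(gA = 1000, gB = 500))
  # 10 reads, 1e6 depth -> CPM 10; column sums 1e6 on raw library sizes
  cpm <- cpm_transform(cm)
  expect_equal(cpm["gA", "s1"], 10)
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6), tolerance = 1e-9)
  # 10 reads, 1 kb gene, 1e6 library -> RPKM 10; doubling length halves it
  rp <- norm_rpkm(cm)$normalized
  expect_equal(rp["gA", "s1"], 10)
  cm2 <- count_matrix(y, gene_lengths = c(gA = 2000, gB = 500))
  expect_equal(norm_rpkm(cm2)$normalized["gA", "s1"], 5)
  expect_error(norm_rpkm(count_matrix(y)), "requires gene lengths")

  cm3 <- rnb_counts(40, 5, seed = 10)
  lens <- setNames(sample(200:5000, 40), gene_ids(cm3))
  cm3 <- count_matrix(unclass(cm3), gene_lengths = lens)
  expect_equal(norm_rpkm(cm3)$normalized,
               oracle_rpkm(unclass(cm3)[, ], lens), tolerance = 1e-12)
  expect_equal(cpm_transform(cm3, depths = colSums(unclass(cm3))),
               oracle_cpm(unclass(cm3)[, ], colSums(unclass(cm3))),
               tolerance = 1e-12)
})

test_that("full-quantile forces one common distribution and is idempotent", {
  # hand example: columns (1,5) and (3,7) -> both become (2,6)
  y <- cbind(s1 = c(1, 5), s2 = c(3, 7)); rownames(y) <- c("g1", "g2")
  fq <- norm_full_quantile(count_matrix(y))$normalized
  expect_equal(unname(fq), cbind(c(2, 6), c(2, 6)))

  cm <- rnb_counts(80, 6, mu = 40, seed = 11)
  out <- norm_full_quantile(cm)$normalized
  sorted <- apply(out, 2, sort)
  for (j in 2:ncol(sorted)) {
    expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)
  }
  # idempotence and agreement with the position-averaging oracle
  expect_equal(consensusde:::full_quantile_map(out), out, tolerance = 1e-12)
  expect_equal(oracle_full_quantile(unclass(cm)[, ]), out, tolerance = 1e-12)
})

test_that("PoissonSeq depth estimation recovers planted depths", {
  # all genes null with equal library sizes -> factors 1 (symmetry)
  base <- rnb_counts(100, 1, mu = 80, seed = 12)
  y <- matrix(rep(unclass(base)[, 1], 4), ncol = 4,
              dimnames = list(gene_ids(base), paste0("s", 1:4)))
  ps <- norm_poissonseq(count_matrix(y))
  expect_equal(unname(ps$factors), rep(1, 4), tolerance = 1e-12)
  expect_true(ps$params$converged)

  # Poisson counts at depths (1, 2): recovered ratio ~2 up to Monte-Carlo noise
  set.seed(13)
  mu_g <- stats::rlnorm(3000, 4, 1)
  yp <- cbind(s1 = stats::rpois(3000, mu_g), s2 = stats::rpois(3000, 2 * mu_g))
  rownames(yp) <- sprintf("g%04d", 1:3000)
  psd <- norm_poissonseq(count_matrix(yp))
  expect_equal(unname(psd$factors[2] / psd$factors[1]), 2, tolerance = 0.02)

  # strong planted DE perturbs depth estimates less than naive totals do
  set.seed(14)
  mu2 <- stats::rlnorm(2000, 4, 1)
  de <- seq_len(200)                      # 10% of genes, all upregulated in s2
  mu_s2 <- mu2; mu_s2[de] <- mu_s2[de] * 8
  y2 <- cbind(s1 = stats::rpois(2000, mu2), s2 = stats::rpois(2000, mu_s2))
  rownames(y2) <- sprintf("g%04d", 1:2000)
  ps2 <- suppressWarnings(norm_poissonseq(count_matrix(y2)))
  naive <- colSums(y2) / exp(mean(log(colSums(y2))))
  truth <- c(1, 1) # equal true depths
  rmse <- function(f) sqrt(mean((f - truth)^2))
  expect_lt(rmse(unname(ps2$factors)), rmse(unname(naive)))
})

test_that("RUV leaves clean data intact and recovers a planted hidden factor", {
  # equal depths and no hidden factor: removing k = 1 estimated factor can
  # only eat noise, so per-gene log-expression stays close to the input
  # (one direction out of the 2(n-1) residual dimensions)
  sim <- simulate_dataset(sim_config(n_genes = 400, n_per_group = 6,
                                     frac_de = 0.1, n_unwanted_factors = 0,
                                     libsize_sdlog = 0, seed = 15))
  ruv <- norm_ruv(sim$counts, sim$design, k = 1)
  y <- unclass(sim$counts)
  keep <- apply(y, 1, stats::sd) > 0
  cors <- vapply(which(keep), function(g) {
    suppressWarnings(stats::cor(log(y[g, ] + 0.5), log(ruv$normalized[g, ] + 0.5)))
  }, numeric(1))
  expect_gt(stats::median(cors, na.rm = TRUE), 0.95)

  simb <- simulate_dataset(sim_config(n_genes = 800, n_per_group = 6,
                                      frac_de = 0.05, n_unwanted_factors = 1,
                                      unwanted_sd = 0.8, seed = 16))
  ruvb <- norm_ruv(simb$counts, simb$design, k = 1)
  r <- stats::cor(ruvb$params$unwanted_factors[, 1], simb$unwanted$scores[, 1])
  expect_gt(abs(r), 0.9)

  expect_error(norm_ruv(sim$counts, sim$design, k = 0), "positive integer")
  expect_error(norm_ruv(sim$counts, sim$design, k = 10), "n_samples - 2")
  expect_error(norm_ruv(sim$counts, sim$design, k = 1,
                        control_genes = c("gene00001")), "control genes")
})

test_that("scale equivariance: scaling one sample scales its factor", {
  cm <- rnb_counts(150, 5, mu = 70, phi = 0.1, seed = 17)
  y <- unclass(cm)
  y2 <- y; y2[, 2] <- y2[, 2] * 3
  cm2 <- count_matrix(y2)
  d <- two_group_design(2, ids = colnames(y)[1:4])
  # TMM is only approximately equivariant: its inverse-variance weights
  # depend on the library size being rescaled
  pairs <- list(
    UQ = list(norm_uq(cm), norm_uq(cm2), 1e-12),
    Median = list(norm_median(cm), norm_median(cm2), 1e-12),
    TMM = list(norm_tmm(cm), norm_tmm(cm2), 0.02)
  )
  for (nm in names(pairs)) {
    f1 <- pairs[[nm]][[1]]$factors
    f2 <- pairs[[nm]][[2]]$factors
    ratio <- (f2[2] / f1[2]) / (f2[1] / f1[1])  # cancel the geomean rescale
    expect_equal(unname(ratio), 3, tolerance = pairs[[nm]][[3]], label = nm)
  }
})
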