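make_matrix <- function(rows, ids = NULL) {
  m <- do.call(rbind, rows)
  rownames(m) <- ids %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- c(sprintf("c%d", seq_len(ncol(m) / 2)),
                   sprintf("t%d", seq_len(ncol(m) / 2)))
  m
}

test_that("NB Wald lfc equals the log2 ratio of group sample means under equal offsets", {
  d <- two_group_design(3)
  y <- make_matrix(list(c(18, 20, 22, 78, 80, 82),
                        c(50, 50, 50, 50, 50, 50)))
  res <- suppressWarnings(nb_wald_test(count_matrix(y), d))  # 2-gene trend fallback
  expect_equal(res$log2_fc[1], 2, tolerance = 1e-9)   # log2(80/20)
  # identical groups: statistic 0, p = 1
  expect_identical(res$stat[2], 0)
  expect_identical(res$p_value[2], 1)
})

test_that("NB group-mean MLE matches glm.nb-style fits at fixed dispersion", {
  # oracle: stats::glm with MASS negative.binomial family, gene by gene
  set.seed(41)
  d <- two_group_design(4)
  y <- matrix(rnbinom(20 * 8, mu = 60, size = 4), 20, 8,
              dimnames = list(sprintf("g%02d", 1:20), d$sample_id))
  off <- log(c(0.8, 1.1, 1.0, 0.9, 1.2, 1.0, 1.3, 0.85))
  phi <- rep(0.25, 20)
  disp <- fit_dispersion(y, d, off)
  disp$final <- phi
  res <- nb_wald_test(y, d, disp, off)
  grp <- factor(rep(c("c", "t"), each = 4), levels = c("c", "t"))
  s <- exp(off - mean(off))
  for (g in c(1, 7, 13)) {
    fit <- suppressWarnings(stats::glm(
      y[g, ] ~ grp + offset(log(s)),
      family = MASS::negative.binomial(theta = 1 / 0.25)
    ))
    lfc_oracle <- unname(stats::coef(fit)[2]) / log(2)
    expect_equal(res$log2_fc[g], lfc_oracle, tolerance = 1e-6)
  }
})

test_that("robust LRT downweights outliers and matches the plain LRT without them", {
  d <- two_group_design(3)
  clean <- c(10, 11, 9, 10, 10, 12)
  dirty <- c(10, 11, 9, 10, 10, 200)
  y <- make_matrix(list(dirty, clean))
  disp <- suppressWarnings(fit_dispersion(make_matrix(list(clean, clean)), d))
  disp$final <- rep(0.1, 2)
  robust <- nb_lrt_robust_test(y, d, disp)
  plain <- nb_lrt_robust_test(y, d, disp, outlier_c = Inf)
  # the outlier makes the non-robust test look significant; robust resists
  expect_gt(robust$p_value[1], plain$p_value[1])
  # identical groups: statistic 0, p = 1
  yid <- make_matrix(list(c(30, 31, 29, 30, 31, 29)))
  rid <- suppressWarnings(nb_lrt_robust_test(yid, d, NULL))
  expect_identical(rid$stat[1], 0)
  expect_identical(rid$p_value[1], 1)
})

test_that("Mann-Whitney exact p equals full-permutation enumeration", {
  d <- two_group_design(3)
  y <- make_matrix(list(c(1, 2, 3, 4, 5, 6)))
  res <- mann_whitney_test(y, d)
  expect_identical(unname(res$stat[1]), 0)   # U: control beats treatment 0 times
  expect_equal(res$p_value[1], 0.1)          # 2 of C(6,3)=20 orderings as extreme

  set.seed(42)
  for (sizes in list(c(2, 2), c(3, 2), c(3, 3), c(4, 3), c(4, 4), c(5, 5))) {
    n1 <- sizes[1]; n2 <- sizes[2]
    des <- study_design(c(sprintf("c%d", 1:n1), sprintf("t%d", 1:n2)),
                        rep(c("control", "treatment"), c(n1, n2)))
    for (rep in 1:10) {
      vals <- sample(1:1000, n1 + n2)    # tie-free
      m <- matrix(vals, 1, dimnames = list("g1", des$sample_id))
      got <- mann_whitney_test(m, des)$p_value[1]
      expect_equal(got, mw_enum_p(vals[1:n1], vals[-(1:n1)]), tolerance = 1e-12)
    }
  }
})

test_that("Mann-Whitney handles constants and identical groups", {
  d <- two_group_design(3)
  y <- make_matrix(list(rep(7, 6), c(1, 2, 3, 1, 2, 3)))
  res <- mann_whitney_test(y, d)
  expect_identical(res$p_value[1], 1)
  expect_equal(res$p_value[2], 1, tolerance = 1e-9)
})

test_that("Welch t matches stats::t.test gene by gene", {
  d <- two_group_design(3)
  # classic shifted example, equal variances
  y <- make_matrix(list(c(1, 2, 3, 11, 12, 13)))
  res <- welch_t_test(y, d, log_scale = FALSE)
  oracle <- stats::t.test(c(11, 12, 13), c(1, 2, 3))
  expect_equal(res$p_value[1], oracle$p.value, tolerance = 1e-12)
  expect_equal(unname(res$stat[1]), unname(oracle$statistic), tolerance = 1e-12)

  set.seed(43)
  m <- matrix(stats::rlnorm(25 * 6, 3, 1), 25, 6,
              dimnames = list(sprintf("g%02d", 1:25), d$sample_id))
  res2 <- welch_t_test(m, d)   # log2(x + 0.5) by default
  lm2 <- log2(m + 0.5)
  for (g in c(2, 11, 24)) {
    o <- stats::t.test(lm2[g, 4:6], lm2[g, 1:3])
    expect_equal(res2$p_value[g], o$p.value, tolerance = 1e-12)
  }
  # degenerate genes
  yd <- make_matrix(list(rep(4, 6), c(2, 2, 2, 8, 8, 8)))
  resd <- welch_t_test(yd, d, log_scale = FALSE)
  expect_identical(resd$p_value[1], 1)
  expect_identical(resd$p_value[2], 0)
  expect_identical(resd$flag[2], "degenerate")
})

test_that("voom moderated t is null-centred and falls back gracefully", {
  d <- two_group_design(3)
  # identical groups -> coefficient and moderated t exactly 0, p = 1
  set.seed(44)
  base <- rnbinom(50, mu = 100, size = 5)
  y <- matrix(rep(base, 6), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), d$sample_id))
  res <- voom_moderated_t_test(y, d)
  expect_equal(res$stat, rep(0, 50))
  expect_equal(res$p_value, rep(1, 50))

  # tiny gene set: Welch fallback with a warning
  expect_warning(res2 <- voom_moderated_t_test(y[1:5, ], d), "fewer than 10 genes")
  expect_equal(nrow(res2), 5L)

  # near-constant log-variance data: precision weights flatten
  set.seed(45)
  flat <- matrix(round(2^matrix(stats::rnorm(200 * 6, 10, 0.2), 200, 6)), 200, 6,
                 dimnames = list(sprintf("g%03d", 1:200), d$sample_id))
  v <- limma::voom(flat, stats::model.matrix(~rep(0:1, each = 3)),
                   lib.size = colSums(flat))
  expect_lt(max(v$weights) / min(v$weights), 2)
})

test_that("all-zero genes are retained with p = q = 1 in every model", {
  d <- two_group_design(3)
  y <- make_matrix(list(c(12, 15, 9, 30, 28, 33), rep(0, 6)))
  checks <- list(
    suppressWarnings(nb_wald_test(count_matrix(y), d)),   # 2-gene trend fallback
    suppressWarnings(nb_lrt_robust_test(count_matrix(y), d)),
    mann_whitney_test(y, d),
    welch_t_test(y, d)
  )
  for (res in checks) {
    expect_identical(res$gene_id, c("g1", "g2"))
    expect_identical(res$p_value[2], 1)
    expect_identical(res$q_value[2], 1)
    expect_identical(res$log2_fc[2], 0)
    expect_identical(res$flag[2], "all_zero")
  }
})

test_that("Benjamini-Hochberg adjustment matches the hand step-up and brute force", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  p_flat <- rep(0.2, 7)
  expect_equal(bh_adjust(p_flat), p_flat)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(46)
  for (i in 1:25) {
    p <- stats::runif(sample(3:60, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-12)
    expect_true(all(q >= p))                      # BH only increases
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))        # monotone in p order
  }
})
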