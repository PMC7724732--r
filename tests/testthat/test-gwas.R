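test_that("adjusted phenotypes are orthogonal to the covariate design", {
  cfg <- sim_config(n_samples = 90, n_snps = 100, seed = 12)
  g <- simulate_genotypes(cfg)
  tt <- simulate_phenotypes(g, cfg)
  adj <- adjust_phenotypes(tt)
  M <- model.matrix(~ farm + season_year + age, tt)
  for (tr in c("MT_5", "VIAB_5", "R_VIAB")) {
    expect_lt(max(abs(crossprod(M, adj[[tr]]))), 1e-8)
  }
})

test_that("single-level covariates reduce adjustment to centering", {
  df <- data.frame(sample_id = sprintf("S%d", 1:20),
                   farm = "F1", season_year = "SY1", age = "A1",
                   MT_5 = rnorm(20, 70, 10))
  class(df) <- c("trait_table", "data.frame")
  adj <- adjust_phenotypes(df)
  expect_equal(adj$MT_5, df$MT_5 - mean(df$MT_5))
})

test_that("aliased covariates raise an informative error", {
  df <- data.frame(sample_id = sprintf("S%d", 1:20),
                   farm = rep(c("F1", "F2"), 10),
                   season_year = rep(c("SY1", "SY2"), 10),  # aliased
                   age = rep(c("A1", "A2"), each = 10),
                   MT_5 = rnorm(20))
  class(df) <- c("trait_table", "data.frame")
  expect_error(adjust_phenotypes(df), "aliased")
})

test_that("ratio traits are the raw 90/5 quotient before adjustment", {
  df <- data.frame(sample_id = c("a", "b", "c", "d"), farm = "F1",
                   season_year = "S1", age = "A1",
                   VIAB_5 = c(80, 90, 100, 50),
                   VIAB_90 = c(80, 45, 50, 50))
  class(df) <- c("trait_table", "data.frame")
  adj <- adjust_phenotypes(df)
  ratio <- c(1, 0.5, 0.5, 1)
  # single-level covariates -> adjusted ratio is the centered raw quotient
  expect_equal(adj$R_VIAB, ratio - mean(ratio))
})

test_that("bh_fdr matches hand-applied step-up rules", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "p-values")
})

test_that("bh_fdr equals the brute-force step-up definition", {
  set.seed(13)
  for (i in 1:200) {
    p <- runif(sample(1:8, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("with an identity GRM the MLM reduces to OLS t-tests", {
  set.seed(14)
  n <- 80
  X <- matrix(rbinom(n * 12, 2, 0.4), n, 12)
  g <- make_geno(X)
  y <- rnorm(n)
  res <- mlm_assoc(g, y, G = diag(n))
  for (j in c(1, 5, 12)) {
    fit <- summary(lm(y ~ X[, j]))$coefficients
    expect_equal(res$beta[j], fit[2, 1], tolerance = 1e-6)
    expect_equal(res$p[j], fit[2, 4], tolerance = 1e-5)
  }
})

test_that("mlm betas are invariant to adding a constant to the trait", {
  set.seed(15)
  cfg <- sim_config(n_samples = 100, n_snps = 150, seed = 15)
  g <- simulate_genotypes(cfg)
  G <- compute_grm(g)
  y <- rnorm(100)
  r1 <- mlm_assoc(g, y, G = G)
  r2 <- mlm_assoc(g, y + 100, G = G)
  expect_equal(r1$beta, r2$beta, tolerance = 1e-8)
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
})

test_that("a planted QTL effect is recovered within 2 SE", {
  cfg <- sim_config(n_samples = 300, n_snps = 400, missing_rate = 0,
                    qtl_map = data.frame(snp = 200, trait = "MT_5",
                                         effect = 0.5),
                    seed = 16)
  g <- simulate_genotypes(cfg)
  tt <- simulate_phenotypes(g, cfg)
  truth <- attr(tt, "qtl_truth")
  Xf <- model.matrix(~ farm + season_year + age, tt)
  res <- mlm_assoc(g, tt$MT_5, Xf, G = compute_grm(g))
  expect_lt(abs(res$beta[200] - truth$beta_raw[truth$snp == 200 &
                                                 truth$trait == "MT_5"]),
            2 * res$se[200])
  expect_lt(res$q[200], 0.05)
})

test_that("interval clustering follows the 5-Mbp gap rule", {
  hits <- data.frame(
    snp_id = c("s1", "s2", "s3"), chrom = "1",
    bp = c(1e6, 3e6, 10e6), trait = "HABN",
    p = c(1e-8, 1e-6, 1e-7), q = 0.01
  )
  iv <- cluster_intervals(hits)
  expect_equal(nrow(iv), 2)
  expect_equal(iv$n_snps, c(2L, 1L))
  expect_equal(iv$lead_snp[1], "s1")  # minimum p among members
  expect_true(iv$singleton[2])

  # gap of exactly 5 Mbp starts a new interval
  hits2 <- data.frame(snp_id = c("a", "b"), chrom = "2",
                      bp = c(1e6, 6e6), trait = "MT_5",
                      p = c(1e-5, 1e-6), q = 0.01)
  expect_equal(nrow(cluster_intervals(hits2)), 2)
  hits2$bp <- c(1e6, 6e6 - 1)
  expect_equal(nrow(cluster_intervals(hits2)), 1)

  expect_equal(nrow(cluster_intervals(hits[0, ])), 0)
})

test_that("unplaced-scaffold hits are excluded from intervals", {
  hits <- data.frame(snp_id = c("s1", "s2"), chrom = c("1", "AEMK02"),
                     bp = c(1e6, 2e6), trait = "HABN",
                     p = c(1e-8, 1e-9), q = 0.01)
  iv <- cluster_intervals(hits)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$lead_snp, "s1")
})

test_that("interval clustering matches a single-pass oracle", {
  set.seed(17)
  for (i in 1:30) {
    bp <- sort(sample.int(5e7, sample(2:15, 1)))
    hits <- data.frame(snp_id = sprintf("s%d", seq_along(bp)),
                       chrom = "3", bp = bp, trait = "T",
                       p = runif(length(bp)), q = 0.01)
    iv <- cluster_intervals(hits)
    grp <- oracle_intervals(bp)
    expect_equal(nrow(iv), length(grp))
    expect_equal(sort(iv$n_snps), sort(lengths(grp)))
  }
})
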