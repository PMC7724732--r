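test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(n_snps = 100,
                          qtl_map = data.frame(snp = 101, trait = "HABN",
                                               effect = 0.5)),
               "out of bounds")
  expect_error(sim_config(expr_trait_corr = data.frame(gene = 1,
                                                       trait = "HABN",
                                                       r = 1)),
               "target r")
  expect_error(sim_config(mirna_target_map = data.frame(mirna = 1,
                                                        gene = 1,
                                                        r = 0.5)),
               "miRNA-target")
})

test_that("fixed-MAF genotypes hit the target allele frequency", {
  cfg <- sim_config(n_samples = 5000, n_snps = 40, n_mirnas = 0,
                    maf_range = c(0.5, 0.5), ld_rho = 0,
                    missing_rate = 0, qtl_map = data.frame(
                      snp = integer(0), trait = character(0),
                      effect = numeric(0)),
                    expr_trait_corr = data.frame(gene = integer(0),
                                                 trait = character(0),
                                                 r = numeric(0)),
                    seed = 101)
  g <- simulate_genotypes(cfg)
  freq <- colMeans(g$geno) / 2
  # binomial SE on 2n draws = sqrt(.25 / 1e4) = 0.005; allow 4 SE
  expect_true(all(abs(freq - 0.5) < 4 * sqrt(0.25 / 1e4)))
})

test_that("ld_rho = 0 gives independent SNPs, high ld_rho gives LD", {
  cfg0 <- sim_config(n_samples = 2000, n_snps = 40, ld_rho = 0,
                     missing_rate = 0, seed = 5)
  g0 <- simulate_genotypes(cfg0)
  r2_adj <- vapply(seq_len(39), function(j)
    ld_r2(g0$geno[, j], g0$geno[, j + 1]), numeric(1))
  expect_lt(mean(r2_adj), 3 / 2000 * 3)

  cfg9 <- sim_config(n_samples = 2000, n_snps = 40, ld_rho = 0.9,
                     ld_block_size = 40, missing_rate = 0, seed = 5)
  g9 <- simulate_genotypes(cfg9)
  r2_adj9 <- vapply(seq_len(39), function(j)
    ld_r2(g9$geno[, j], g9$geno[, j + 1]), numeric(1))
  expect_gt(mean(r2_adj9), 0.3)
})

test_that("generation is deterministic under the seed", {
  cfg <- sim_config(n_samples = 60, n_snps = 100, n_genes = 40,
                    n_mirnas = 10, seed = 9)
  g1 <- simulate_genotypes(cfg); g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  t1 <- simulate_phenotypes(g1, cfg); t2 <- simulate_phenotypes(g2, cfg)
  expect_identical(t1, t2)
  a1 <- simulate_abundances(cfg, t1, g1)
  a2 <- simulate_abundances(cfg, t2, g2)
  expect_identical(a1, a2)
})

test_that("trait table carries the full 25-trait panel with ratios", {
  cfg <- sim_config(n_samples = 80, n_snps = 200, seed = 2)
  g <- simulate_genotypes(cfg)
  tt <- simulate_phenotypes(g, cfg)
  expect_true(all(trait_names() %in% names(tt)))
  expect_equal(tt$R_VIAB, tt$VIAB_90 / tt$VIAB_5)
  expect_s3_class(tt, "trait_table")
  expect_equal(nrow(attr(tt, "qtl_truth")), nrow(cfg$qtl_map))
})

test_that("planted expression-trait correlations are realized", {
  cfg <- sim_config(n_samples = 300, n_snps = 200, n_genes = 60,
                    n_mirnas = 10, n_rna_samples = 300,
                    expr_trait_corr = data.frame(
                      gene = c(31, 32), trait = c("MT_5", "ORT"),
                      r = c(0.6, -0.5)),
                    eqtl_map = data.frame(snp = integer(0),
                                          gene = integer(0),
                                          r = numeric(0)),
                    seed = 33)
  g <- simulate_genotypes(cfg)
  tt <- simulate_phenotypes(g, cfg)
  ab <- simulate_abundances(cfg, tt, g)
  core <- attr(tt, "trait_core")
  lg <- log2(unclass(ab$mrna) + 1)
  r1 <- cor(lg["gene0031", ], core[, "MT_5"])
  r2 <- cor(lg["gene0032", ], core[, "ORT"])
  expect_lt(abs(r1 - 0.6), 0.1)
  expect_lt(abs(r2 + 0.5), 0.1)
})

test_that("planted null pairs are retained at about the nominal rate", {
  # gene 40 has no planted loading on any trait: across many traits the
  # correlation screen should flag ~5% of pairs
  cfg <- sim_config(n_samples = 250, n_snps = 100, n_genes = 50,
                    n_mirnas = 0, n_rna_samples = 250,
                    expr_trait_corr = data.frame(gene = integer(0),
                                                 trait = character(0),
                                                 r = numeric(0)),
                    eqtl_map = data.frame(snp = integer(0),
                                          gene = integer(0),
                                          r = numeric(0)),
                    mirna_target_map = data.frame(mirna = integer(0),
                                                  gene = integer(0),
                                                  r = numeric(0)),
                    frac_low_expr = 0, seed = 77)
  g <- simulate_genotypes(cfg)
  tt <- simulate_phenotypes(g, cfg)
  ab <- simulate_abundances(cfg, tt, g)
  m <- filter_abundances(ab$mrna)
  adj <- adjust_phenotypes(tt)
  tc <- correlate_traits(m, adj)
  rate <- mean(tc$significant)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("low-expression genes fall below the FPKM screen", {
  cfg <- sim_config(n_samples = 80, n_snps = 100, n_genes = 100,
                    n_mirnas = 20, frac_low_expr = 0.3, seed = 4)
  g <- simulate_genotypes(cfg)
  tt <- simulate_phenotypes(g, cfg)
  ab <- simulate_abundances(cfg, tt, g)
  filt <- filter_abundances(ab$mrna)
  dropped <- attr(filt, "dropped")
  expect_gt(length(dropped), 0)
  expect_true(all(rowMeans(unclass(ab$mrna)[dropped, , drop = FALSE]) < 10))
})
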