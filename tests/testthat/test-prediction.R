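mk_tc <- function(feature, k, r = 0.5) {
  data.frame(feature = rep(feature, k),
             trait = trait_names()[seq_len(k)], r = r, p = 0.01, n = 40,
             significant = TRUE, stringsAsFactors = FALSE)
}

test_that("candidate pool applies the three automatic filters", {
  tc <- rbind(mk_tc("g1", 5), mk_tc("g2", 4), mk_tc("g3", 3),
              mk_tc("g4", 6), mk_tc("g5", 4))
  class(tc) <- c("trait_correlations", "data.frame")
  net <- new_network(
    data.frame(id = c("g1", "g2", "g3", "g4", "g5"), type = "gene"),
    data.frame(a = "g1", b = "g4", weight = 0.9, provenance = "rna")
  )
  vals <- matrix(5, 5, 8, dimnames = list(sprintf("g%d", 1:5),
                                          sprintf("S%d", 1:8)))
  vals["g5", 3] <- 0   # zero-FPKM sample -> excluded
  ab <- abundance_matrix(vals, kind = "mRNA")
  pool <- candidate_gene_pool(net, tc, ab)
  expect_false("g3" %in% pool)   # only 3 correlated traits
  expect_false("g5" %in% pool)   # zero-abundance sample
  # g4 ranks first (6 traits); g1 is adjacent to g4 -> skipped
  expect_true("g4" %in% pool)
  expect_false("g1" %in% pool)
  expect_true("g2" %in% pool)
  expect_error(candidate_gene_pool(net, tc[tc$feature == "g3", ], ab),
               "eligible")
})

test_that("manual ranking takes precedence in the pool", {
  tc <- rbind(mk_tc("g1", 5), mk_tc("g4", 6))
  class(tc) <- c("trait_correlations", "data.frame")
  net <- new_network(
    data.frame(id = c("g1", "g4"), type = "gene"),
    data.frame(a = "g1", b = "g4", weight = 0.9, provenance = "rna")
  )
  ab <- abundance_matrix(
    matrix(5, 2, 6, dimnames = list(c("g1", "g4"), sprintf("S%d", 1:6))),
    kind = "mRNA")
  pool <- candidate_gene_pool(net, tc, ab, manual_list = "g1")
  expect_equal(pool, "g1")
})

test_that("all-subsets R2 enumerates 2^p - 1 models correctly", {
  set.seed(51)
  n <- 50
  vals <- matrix(2^rnorm(3 * n, 5), 3, n,
                 dimnames = list(c("gA", "gB", "gC"),
                                 sprintf("S%03d", 1:n)))
  ab <- abundance_matrix(vals, kind = "mRNA")
  tt <- data.frame(sample_id = colnames(vals),
                   MT_5 = 2 * vals["gA", ] + rnorm(n, 0, 3))
  class(tt) <- c("trait_table", "data.frame")
  tab <- all_subsets_r2(ab, c("gA", "gB", "gC"), tt, "MT_5")
  expect_equal(nrow(tab), 7)
  # single-gene subset R2 equals the squared Pearson correlation
  r_gA <- cor(vals["gA", ], tt$MT_5)
  expect_equal(tab$r2[tab$subset == "gA"], r_gA^2, tolerance = 1e-10)
  # monotone: any superset R2 >= subset R2
  for (i in seq_len(nrow(tab))) {
    gi <- strsplit(tab$subset[i], ",")[[1]]
    for (j in seq_len(nrow(tab))) {
      gj <- strsplit(tab$subset[j], ",")[[1]]
      if (all(gi %in% gj)) expect_gte(tab$r2[j], tab$r2[i] - 1e-10)
    }
  }
  expect_error(all_subsets_r2(ab, sprintf("g%d", 1:21), tt, "MT_5"),
               "20")
})

test_that("best subset per size matches a brute-force lm oracle", {
  set.seed(52)
  n <- 40
  vals <- matrix(2^rnorm(4 * n, 5), 4, n,
                 dimnames = list(sprintf("g%d", 1:4),
                                 sprintf("S%03d", 1:n)))
  ab <- abundance_matrix(vals, kind = "mRNA")
  y <- 1.5 * vals["g2", ] - 0.8 * vals["g4", ] + rnorm(n, 0, 5)
  tt <- data.frame(sample_id = colnames(vals), HABN = y)
  class(tt) <- c("trait_table", "data.frame")
  tab <- all_subsets_r2(ab, rownames(vals), tt, "HABN")
  for (sz in 1:4) {
    cand <- combn(rownames(vals), sz, simplify = FALSE)
    oracle_best <- max(vapply(cand, function(s)
      summary(lm(y ~ t(vals[s, , drop = FALSE])))$r.squared, numeric(1)))
    got <- max(tab$r2[tab$size == sz])
    expect_equal(got, oracle_best, tolerance = 1e-10)
  }
})

test_that("common-gene tally follows the per-size best-model rule", {
  tabA <- data.frame(subset = c("g1", "g2", "g1,g2", "g1,g3"),
                     size = c(1, 1, 2, 2), r2 = c(0.5, 0.3, 0.7, 0.6))
  tabB <- data.frame(subset = c("g1", "g3", "g2,g3"),
                     size = c(1, 1, 2), r2 = c(0.2, 0.4, 0.5))
  sel <- select_common_genes(list(A = tabA, B = tabB), k = 2)
  # best models: A size1 g1, A size2 {g1,g2}; B size1 g3, B size2 {g2,g3}
  # tally: g1 = 2, g2 = 2, g3 = 2 -> ties lexicographic -> g1, g2
  expect_equal(as.character(sel[1:2]), c("g1", "g2"))
  expect_warning(select_common_genes(list(A = tabA), k = 10), "larger")
})

test_that("stepwise recovers a planted single strong predictor", {
  set.seed(53)
  n <- 120
  vals <- matrix(2^rnorm(10 * n, 4), 10, n,
                 dimnames = list(sprintf("g%02d", 1:10),
                                 sprintf("S%03d", 1:n)))
  ab <- abundance_matrix(vals, kind = "mRNA")
  y <- 2 * vals["g04", ] + rnorm(n, 0, 0.1 * sd(vals["g04", ]))
  tt <- data.frame(sample_id = colnames(vals), VCL_5 = y)
  class(tt) <- c("trait_table", "data.frame")
  fit <- stepwise_fit(ab, rownames(vals), tt, "VCL_5")
  expect_true("g04" %in% fit$selected)
  expect_gt(fit$r2, 0.95)
  expect_lt(fit$p_value, 1e-10)
  # stepwise solution equals the best single-gene subset choice
  tab <- all_subsets_r2(ab, rownames(vals)[1:4], tt, "VCL_5")
  best1 <- tab$subset[tab$size == 1][which.max(tab$r2[tab$size == 1])]
  expect_equal(best1, "g04")
})

test_that("stepwise returns the intercept-only model when nothing enters", {
  set.seed(54)
  n <- 30
  vals <- matrix(2^rnorm(3 * n, 4), 3, n,
                 dimnames = list(c("gA", "gB", "gC"),
                                 sprintf("S%03d", 1:n)))
  ab <- abundance_matrix(vals, kind = "mRNA")
  tt <- data.frame(sample_id = colnames(vals), CON = rnorm(n))
  class(tt) <- c("trait_table", "data.frame")
  fit <- stepwise_fit(ab, rownames(vals), tt, "CON", p_enter = 1e-8)
  expect_equal(fit$selected, character(0))
  expect_equal(fit$r2, 0)
  expect_equal(fit$p_value, 1)
})

test_that("panel assembly de-duplicates and applies the gene rules", {
  B <- matrix(0.5, 8, 3,
              dimnames = list(sprintf("s%d", 1:8),
                              c("VIAB_5", "HABN", "MT_5")))
  P <- matrix(0.5, 8, 3, dimnames = dimnames(B))
  P["s1", "HABN"] <- 1e-8   # most significant SNP near gShared
  scan <- make_scan(B, P, chrom = "1",
                    bp = c(1000, 2000, 3000, 50000, 60000, 70000,
                           80000, 90000))
  intervals <- data.frame(trait = c("HABN", "MT_5", "MT_5"),
                          chrom = "1", start_bp = 1, end_bp = 2,
                          n_snps = 2, snp_ids = "x",
                          lead_snp = c("s1", "s4", "s5"),
                          lead_p = 1e-7, singleton = FALSE)
  eg <- structure(data.frame(snp_id = c("s6", "s6"),
                             gene_id = c("gE", "gE"),
                             beta = 1, p = c(1e-6, 1e-5), q = 0.01,
                             cis_trans = "trans",
                             linked_trait = "HABN",
                             stringsAsFactors = FALSE),
                  class = c("eqtl_records", "data.frame"))
  shared <- new_network(
    data.frame(id = c("gShared", "gPoor"), type = "gene",
               in_shared = TRUE),
    data.frame(a = "gShared", b = "gPoor", weight = 0.5,
               provenance = "shared"))
  tc <- rbind(mk_tc("gShared", 5), mk_tc("gPoor", 3))
  class(tc) <- c("trait_correlations", "data.frame")
  ann <- data.frame(gene_id = c("gShared", "gPoor"), chrom = "1",
                    start = c(900, 85000), end = c(2500, 95000))
  panel <- build_snp_panel(intervals, eg, shared, tc, scan, ann)
  # 3 interval leads + 1 eGWAS lead + 1 network-gene SNP (s1, dual tag)
  expect_setequal(panel$snp_id, c("s1", "s4", "s5", "s6"))
  expect_equal(panel$sources[panel$snp_id == "s1"],
               "gwas_lead,network_gene")
  # gPoor correlates with only 3 traits -> contributes no SNP
  expect_false(any(grepl("network_gene",
                         panel$sources[panel$snp_id %in%
                                         c("s7", "s8")])))
})

test_that("panel variance explained recovers a planted causal fraction", {
  cfg <- sim_config(n_samples = 400, n_snps = 300, missing_rate = 0,
                    qtl_map = data.frame(snp = 150, trait = "MT_90",
                                         effect = sqrt(0.3 / 0.7)),
                    h2_per_trait = setNames(rep(0, 19),
                                            spermnet:::.trait_panel()$trait),
                    seed = 55)
  g <- simulate_genotypes(cfg)
  tt <- simulate_phenotypes(g, cfg)
  # planted fraction: beta^2 / (1 + beta^2) = 0.3 of the total variance
  panel <- structure(data.frame(snp_id = c("snp00150", "snp00149"),
                                chrom = "1", bp = c(1, 2),
                                sources = "gwas_lead",
                                stringsAsFactors = FALSE),
                     class = c("snp_panel", "data.frame"))
  # non-convergence can occur on the 2-SNP GRM's flat likelihood; the
  # boundary answer is still the quantity under test
  pv <- suppressWarnings(
    panel_variance_explained(panel, g, tt, trait_cols = "MT_90"))
  expect_lt(abs(pv$var_explained - 0.3), 2 * pv$se)
  expect_true(all(pv$var_explained >= 0 & pv$var_explained <= 1))
  # a noise trait against the same panel sits near the boundary
  pv0 <- suppressWarnings(
    panel_variance_explained(panel, g, tt, trait_cols = "CON"))
  expect_lt(pv0$var_explained, 2 * pv0$se + 0.05)
})
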