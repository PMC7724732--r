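# End-to-end orchestration of the synthetic study: generation -> QC ->
# GWAS -> expression -> eGWAS -> AWM -> PCIT networks -> prediction.

#' Run the full pipeline on a synthetic study
#'
#' Generates a cohort from `cfg`, then runs every stage in order: genotype
#' QC, GRM + multi-trait mixed-model GWAS with per-trait GREML h2, QTL
#' interval clustering, abundance filtering and trait-correlation screens,
#' eGWAS with the phenotype-anchored double filter, AWM construction
#' around the key phenotype, PCIT SNP and RNA networks, shared and final
#' network assembly, and the RNA-model / SNP-panel prediction layer.
#'
#' @param cfg A [sim_config()].
#' @param key_trait AWM key phenotype (default `"VIAB_5"`).
#' @param awm_p Key/non-key association threshold for AWM selection.
#' @param pool_size Gene-pool cap for the all-subsets RNA model
#'   (default 12; the operation allows up to 20).
#' @param n_model_genes Genes kept for the stepwise models (default 10).
#' @param quiet Suppress progress messages.
#' @return A list of class `spermnet_run` with every intermediate object:
#'   `cfg`, `geno_raw`, `qc`, `geno`, `traits`, `traits_adj`, `grm`,
#'   `scan`, `hits`, `intervals`, `abund` (raw), `mrna`, `mirna`
#'   (filtered log2), `corr_mrna`, `corr_mirna`, `eqtl`, `eqtl_filtered`,
#'   `awm_sel`, `awm`, `snp_net`, `rna_net`, `shared_net`, `mirna_edges`,
#'   `final_net`, `pool`, `subset_tables`, `model_genes`, `rna_models`,
#'   `panel`, `panel_var`, `summary`.
#' @export
run_pipeline <- function(cfg, key_trait = "VIAB_5", awm_p = 0.01,
                         pool_size = 12, n_model_genes = 10,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  say("simulating cohort ...")
  geno_raw <- simulate_genotypes(cfg)
  traits <- simulate_phenotypes(geno_raw, cfg)
  ab <- simulate_abundances(cfg, traits, geno_raw)

  say("genotype QC ...")
  qc <- apply_qc(geno_raw)
  geno <- qc$genotypes
  traits_use <- traits[traits$sample_id %in% rownames(geno$geno), ,
                       drop = FALSE]

  say("GWAS (", ncol(geno$geno), " SNPs x 25 traits) ...")
  G <- compute_grm(geno)
  scan <- gwas_scan(geno, traits_use, G = G)
  hits <- scan_hits(scan, 0.05)
  intervals <- cluster_intervals(hits)

  say("expression screens ...")
  traits_adj <- adjust_phenotypes(traits_use)
  mrna <- filter_abundances(ab$mrna)
  mirna <- filter_abundances(ab$mirna)
  corr_mrna <- correlate_traits(mrna, traits_adj)
  corr_mirna <- correlate_traits(mirna, traits_adj)

  say("eGWAS ...")
  eqtl <- egwas_scan(geno, mrna, annotation = ab$annotation)
  eqtl_filtered <- filter_egwas(eqtl, hits, corr_mrna)

  say("AWM + networks ...")
  awm_sel <- select_awm_snps(scan, ab$annotation, key_trait = key_trait,
                             p_thr = awm_p)
  awm <- build_awm(awm_sel, scan, key_trait = key_trait)
  snp_net <- build_snp_network(awm)
  rna_net <- build_rna_network(mrna)
  shared_net <- intersect_networks(snp_net, rna_net)
  me <- mirna_gene_edges(mirna, mrna)
  corr_all <- rbind(as.data.frame(corr_mrna), as.data.frame(corr_mirna))
  corr_all$significant <- corr_all$p <= 0.05
  class(corr_all) <- class(corr_mrna)
  tf_table <- ab$annotation[, c("gene_id", "tf_class")]
  final_net <- build_final_network(shared_net, rna_net, corr_all,
                                   mirna_edges = me, tf_table = tf_table)

  say("prediction layer ...")
  pool <- candidate_gene_pool(final_net, corr_mrna, ab$mrna,
                              max_genes = pool_size)
  subset_tables <- lapply(setNames(nm = trait_names()), function(tr)
    all_subsets_r2(ab$mrna, pool, traits_use, tr))
  model_genes <- select_common_genes(subset_tables, k = n_model_genes)
  rna_models <- lapply(setNames(nm = trait_names()), function(tr)
    stepwise_fit(ab$mrna, model_genes, traits_use, tr))
  panel <- build_snp_panel(intervals, eqtl_filtered, shared_net,
                           corr_mrna, scan, ab$annotation)
  panel_var <- panel_variance_explained(panel, geno, traits_use)

  summary_df <- network_summary(snp = snp_net, rna = rna_net,
                                shared = shared_net, final = final_net)
  structure(list(
    cfg = cfg, geno_raw = geno_raw, qc = qc, geno = geno,
    traits = traits, traits_adj = traits_adj, grm = G, scan = scan,
    hits = hits, intervals = intervals, abund = ab, mrna = mrna,
    mirna = mirna, corr_mrna = corr_mrna, corr_mirna = corr_mirna,
    eqtl = eqtl, eqtl_filtered = eqtl_filtered, awm_sel = awm_sel,
    awm = awm, snp_net = snp_net, rna_net = rna_net,
    shared_net = shared_net, mirna_edges = me, final_net = final_net,
    pool = pool, subset_tables = subset_tables,
    model_genes = model_genes, rna_models = rna_models, panel = panel,
    panel_var = panel_var, summary = summary_df
  ), class = "spermnet_run")
}

#' @export
print.spermnet_run <- function(x, ...) {
  cat("spermnet pipeline run\n")
  cat(sprintf("  %d samples, %d SNPs post-QC, %d GWAS hits in %d intervals\n",
              nrow(x$geno$geno), ncol(x$geno$geno), nrow(x$hits),
              if (is.null(x$intervals)) 0L else nrow(x$intervals)))
  cat(sprintf("  %d significant trait-mRNA correlations; %d filtered eQTL\n",
              sum(x$corr_mrna$significant), nrow(x$eqtl_filtered)))
  print(x$summary)
  cat(sprintf("  panel: %d SNPs; RNA models fit for %d traits\n",
              nrow(x$panel), length(x$rna_models)))
  invisible(x)
}

#' Write the pipeline's tabular outputs to a directory
#'
#' Deterministic text outputs (per-trait association TSVs for traits with
#' hits, intervals, correlations, eQTL, AWM, network edge lists + SIF +
#' GraphML, panel and per-trait report). Two runs with the same seed
#' produce byte-identical files.
#'
#' @param run A `spermnet_run`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_pipeline_outputs <- function(run, dir) {
  stopifnot(inherits(run, "spermnet_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  wt <- function(x, f) write.table(x, fp(f), sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(run$hits, "gwas_hits.tsv")
  if (!is.null(run$intervals)) wt(run$intervals, "gwas_intervals.tsv")
  wt(as.data.frame(run$corr_mrna), "trait_correlations_mrna.tsv")
  wt(as.data.frame(run$corr_mirna), "trait_correlations_mirna.tsv")
  wt(as.data.frame(run$eqtl_filtered), "egwas_filtered.tsv")
  awm_df <- data.frame(gene_id = rownames(run$awm),
                       snp_id = attr(run$awm, "snp_ids"),
                       round(unclass(run$awm), 10),
                       check.names = FALSE)
  wt(awm_df, "awm.tsv")
  write_network_tsv(run$final_net, fp("final_edges.tsv"),
                    fp("final_nodes.tsv"))
  if (nrow(run$final_net$edges)) {
    write_network_sif(run$final_net, fp("final.sif"))
    write_network_graphml(run$final_net, fp("final.graphml"))
  }
  wt(run$panel, "snp_panel.tsv")
  report <- data.frame(
    trait = trait_names(),
    rna_r2 = vapply(run$rna_models, function(m) m$r2, numeric(1)),
    rna_p = vapply(run$rna_models, function(m) m$p_value, numeric(1)),
    panel_var = run$panel_var$var_explained[
      match(trait_names(), run$panel_var$trait)],
    panel_se = run$panel_var$se[match(trait_names(),
                                      run$panel_var$trait)]
  )
  wt(report, "trait_report.tsv")
  invisible(dir)
}
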