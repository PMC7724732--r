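# Synthetic-data generator emulating the study design: LD-blocked genotypes,
# 25 correlated semen traits with farm/season-year/age fixed effects and a
# polygenic background, and sperm mRNA/miRNA abundance matrices with planted
# trait correlations, eQTL effects and negative miRNA-mRNA correlations.

# The fixed 25-trait semen panel: 19 measured traits plus six 90min/5min
# incubation ratios derived from them. Means/SDs/h2 follow the descriptive
# statistics of the boar study the pipeline targets.
.trait_panel <- function() {
  data.frame(
    trait = c("CON", "VIAB_5", "VIAB_90", "ORT", "HABN", "NABN", "TABN",
              "PDROP", "DDROP", "MT_5", "MT_90", "VAP_5", "VAP_90",
              "VCL_5", "VCL_90", "VSL_5", "VSL_90", "ACRO_5", "ACRO_90"),
    mean = c(141.3, 90.1, 77.4, 79.8, 2.1, 3.0, 2.7, 3.5, 4.5, 75.4, 64.1,
             34.0, 30.8, 46.2, 39.7, 27.0, 25.9, 7.0, 16.4),
    sd = c(65.5, 6.3, 17.3, 12.5, 5.9, 4.9, 3.4, 5.1, 4.5, 18.1, 22.0,
           10.2, 9.5, 12.5, 10.2, 8.3, 8.3, 5.6, 12.6),
    h2 = c(0.13, 1e-6, 0.14, 0.13, 0.16, 1e-6, 0.09, 0.12, 0.06, 0.21,
           0.39, 0.17, 0.35, 0.11, 0.35, 0.23, 0.34, 0.08, 0.06),
    stringsAsFactors = FALSE
  )
}

.ratio_pairs <- function() {
  data.frame(
    ratio = c("R_MT", "R_VAP", "R_VCL", "R_VSL", "R_VIAB", "R_ACRO"),
    num = c("MT_90", "VAP_90", "VCL_90", "VSL_90", "VIAB_90", "ACRO_90"),
    den = c("MT_5", "VAP_5", "VCL_5", "VSL_5", "VIAB_5", "ACRO_5"),
    stringsAsFactors = FALSE
  )
}

#' All 25 trait names of the semen-quality panel
#'
#' Nineteen measured traits (concentration, viability, osmotic resistance,
#' morphological abnormalities, droplets, CASA motility and velocities at 5
#' and 90 min) plus six 90/5-min incubation ratios.
#'
#' @return Character vector of length 25.
#' @export
trait_names <- function() c(.trait_panel()$trait, .ratio_pairs()$ratio)

#' Configuration for the synthetic study generator
#'
#' Bundles and validates every knob of the simulated study: cohort and marker
#' sizes, LD structure, the planted genetic architecture (QTL on semen
#' traits, eQTL on gene abundances), planted expression-trait and
#' miRNA-target correlations, and the fixed-effect design (farm,
#' season-year, age).
#'
#' The trait panel itself is fixed: the generator always emits the named
#' 25-trait semen panel (19 measured traits plus 6 incubation ratios) because
#' downstream rules (the VIAB_5 key phenotype, ratio derivation) are defined
#' on those names. All other counts are configurable.
#'
#' @param n_samples Number of boars (genotyped ejaculates).
#' @param n_snps Number of autosomal SNPs.
#' @param n_genes Number of annotated genes with mRNA abundance.
#' @param n_mirnas Number of miRNAs.
#' @param maf_range Length-2 vector of allele-frequency bounds in (0, 0.5].
#' @param ld_block_size SNPs per LD block (adjacent SNPs correlated).
#' @param ld_rho Latent gamete correlation between adjacent SNPs in a block,
#'   in `[0, 1)`.
#' @param h2_per_trait Named or unnamed numeric of length 19 giving the
#'   polygenic heritability of each measured trait; defaults to the study's
#'   published estimates.
#' @param qtl_map `data.frame(snp, trait, effect)`: planted QTL, `effect` in
#'   phenotype-SD units per SD of dosage. `NULL` plants a default
#'   architecture (a handful of moderate QTL on HABN, NABN, MT_5, ACRO_5).
#' @param expr_trait_corr `data.frame(gene, trait, r)`: planted Pearson
#'   correlations between gene log2 abundance and the adjusted trait.
#'   `NULL` plants a default set that includes genes correlated with >= 5
#'   traits (feeding the final-network and panel rules).
#' @param mirna_target_map `data.frame(mirna, gene, r)` with r < 0: planted
#'   negative miRNA-target correlations. `NULL` plants a default set.
#' @param eqtl_map `data.frame(snp, gene, r)`: planted SNP effects on gene
#'   abundance (latent correlation scale). `NULL` plants two strong trans
#'   eQTL whose SNPs are also trait QTL and whose genes correlate with the
#'   same trait, so that the eGWAS double filter has true positives.
#' @param fixed_effect_levels Named integer vector with elements `farm`,
#'   `season_year`, `age` (defaults 3, 9, 3).
#' @param n_rna_samples Number of samples with RNA-seq (first samples of the
#'   cohort; default 40).
#' @param n_runs RNA-seq assay runs (batch factor for the expression
#'   variance-component model; default 4).
#' @param n_chrom Number of autosomes SNPs are spread over.
#' @param missing_rate Genotype missingness rate.
#' @param frac_low_expr Fraction of genes/miRNAs simulated below the
#'   abundance screens (mean FPKM < 10, mean CPM <= 1).
#' @param seed Integer seed; every generator call is reproducible under it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 300, n_snps = 5000, n_genes = 500,
                       n_mirnas = 40, maf_range = c(0.05, 0.5),
                       ld_block_size = 10, ld_rho = 0.8,
                       h2_per_trait = NULL, qtl_map = NULL,
                       expr_trait_corr = NULL, mirna_target_map = NULL,
                       eqtl_map = NULL,
                       fixed_effect_levels = c(farm = 3, season_year = 9,
                                               age = 3),
                       n_rna_samples = min(40, n_samples), n_runs = 4,
                       n_chrom = 18,
                       missing_rate = 0.01, frac_low_expr = 0.2,
                       seed = 1L) {
  panel <- .trait_panel()
  if (is.null(h2_per_trait)) h2_per_trait <- setNames(panel$h2, panel$trait)
  if (length(h2_per_trait) != nrow(panel))
    stop("h2_per_trait must have length ", nrow(panel))
  if (is.null(names(h2_per_trait))) names(h2_per_trait) <- panel$trait
  stopifnot(
    n_samples >= 2, n_snps >= 1, n_genes >= 1, n_mirnas >= 0,
    length(maf_range) == 2, ld_block_size >= 1,
    n_rna_samples >= 3, n_rna_samples <= n_samples,
    n_chrom >= 1, missing_rate >= 0, missing_rate < 1,
    frac_low_expr >= 0, frac_low_expr < 1
  )
  if (any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5] with min <= max")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (any(h2_per_trait < 0) || any(h2_per_trait > 1))
    stop("h2_per_trait values must lie in [0, 1]")
  if (!all(c("farm", "season_year", "age") %in% names(fixed_effect_levels)))
    stop("fixed_effect_levels needs farm, season_year and age entries")

  if (is.null(qtl_map)) qtl_map <- .default_qtl_map(n_snps)
  qtl_map <- .as_planted_df(qtl_map, c("snp", "trait", "effect"))
  if (is.null(expr_trait_corr))
    expr_trait_corr <- .default_expr_trait_corr(n_genes)
  expr_trait_corr <- .as_planted_df(expr_trait_corr, c("gene", "trait", "r"))
  if (is.null(mirna_target_map))
    mirna_target_map <- .default_mirna_targets(n_mirnas, n_genes)
  mirna_target_map <- .as_planted_df(mirna_target_map,
                                     c("mirna", "gene", "r"))
  if (is.null(eqtl_map)) eqtl_map <- .default_eqtl_map(qtl_map,
                                                       expr_trait_corr)
  eqtl_map <- .as_planted_df(eqtl_map, c("snp", "gene", "r"))
  anchor_genes <- .default_anchor_genes(n_snps, n_genes)

  traits25 <- trait_names()
  chk_idx <- function(i, n, what) {
    if (length(i) && (any(i < 1) || any(i > n)))
      stop(what, " index out of bounds")
  }
  chk_trait <- function(tr) {
    if (length(tr) && !all(tr %in% panel$trait))
      stop("planted trait must be one of the 19 measured traits")
  }
  chk_idx(qtl_map$snp, n_snps, "qtl_map snp")
  chk_trait(qtl_map$trait)
  chk_idx(expr_trait_corr$gene, n_genes, "expr_trait_corr gene")
  chk_trait(expr_trait_corr$trait)
  if (nrow(expr_trait_corr) && any(abs(expr_trait_corr$r) >= 1))
    stop("|target r| must be < 1")
  chk_idx(mirna_target_map$mirna, n_mirnas, "mirna_target_map mirna")
  chk_idx(mirna_target_map$gene, n_genes, "mirna_target_map gene")
  if (nrow(mirna_target_map) &&
      (any(mirna_target_map$r >= 0) || any(mirna_target_map$r <= -1)))
    stop("miRNA-target r must lie in (-1, 0)")
  chk_idx(eqtl_map$snp, n_snps, "eqtl_map snp")
  chk_idx(eqtl_map$gene, n_genes, "eqtl_map gene")
  if (nrow(eqtl_map) && any(abs(eqtl_map$r) >= 1))
    stop("|eQTL r| must be < 1")

  cfg <- list(
    n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
    n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
    maf_range = as.numeric(maf_range),
    ld_block_size = as.integer(ld_block_size), ld_rho = as.numeric(ld_rho),
    n_traits = length(traits25), h2_per_trait = h2_per_trait,
    qtl_map = qtl_map, expr_trait_corr = expr_trait_corr,
    mirna_target_map = mirna_target_map, eqtl_map = eqtl_map,
    anchor_genes = anchor_genes,
    fixed_effect_levels = fixed_effect_levels,
    n_rna_samples = as.integer(n_rna_samples), n_runs = as.integer(n_runs),
    n_chrom = as.integer(n_chrom), missing_rate = missing_rate,
    frac_low_expr = frac_low_expr, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

.as_planted_df <- function(x, cols) {
  x <- as.data.frame(x)
  if (nrow(x) == 0) {
    x <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  if (!all(cols %in% names(x)))
    stop("planted map needs columns: ", paste(cols, collapse = ", "))
  x[, cols, drop = FALSE]
}

# Default planted architectures; positions scale with the problem size so a
# small test config still receives in-bounds plants.
.default_snp_pos <- function(f, n_snps)
  max(1L, min(n_snps, as.integer(round(f * n_snps))))

.default_qtl_map <- function(n_snps) {
  pos <- function(f) .default_snp_pos(f, n_snps)
  # six single-trait QTL (clean effect-recovery targets) plus four
  # pleiotropic QTL touching the key phenotype VIAB_5, arranged in two
  # pairs with matching trait profiles so that the genes anchored at them
  # co-associate in the AWM
  single <- data.frame(
    snp = c(pos(0.05), pos(0.35), pos(0.62), pos(0.20), pos(0.80),
            pos(0.47)),
    trait = c("HABN", "HABN", "NABN", "MT_5", "ACRO_5", "MT_90"),
    effect = c(0.55, 0.50, 0.55, 0.50, 0.60, 0.50),
    stringsAsFactors = FALSE
  )
  pleio <- rbind(
    data.frame(snp = pos(0.10), trait = c("VIAB_5", "HABN", "NABN",
                                          "MT_5"),
               effect = c(0.45, 0.40, 0.40, 0.35)),
    data.frame(snp = pos(0.55), trait = c("VIAB_5", "HABN", "NABN",
                                          "MT_5"),
               effect = c(0.40, 0.40, 0.45, 0.35)),
    data.frame(snp = pos(0.25), trait = c("VIAB_5", "MT_5", "MT_90",
                                          "VCL_5"),
               effect = c(0.40, 0.45, 0.40, 0.35)),
    data.frame(snp = pos(0.70), trait = c("VIAB_5", "MT_5", "MT_90",
                                          "VCL_5"),
               effect = c(0.45, 0.40, 0.40, 0.35))
  )
  rbind(single, pleio)
}

# genes anchored at the pleiotropic QTL: gene pairs (1,5) and (2,6) share
# an expression pattern, so the anchored SNP pairs share an AWM profile
# and the pairs appear in both the SNP and the RNA network
.default_anchor_genes <- function(n_snps, n_genes) {
  pos <- function(f) .default_snp_pos(f, n_snps)
  a <- data.frame(gene = c(1L, 5L, 2L, 6L),
                  snp = c(pos(0.10), pos(0.55), pos(0.25), pos(0.70)))
  a[a$gene <= n_genes, , drop = FALSE]
}

.default_expr_trait_corr <- function(n_genes) {
  # genes 1..12: correlated with 5 traits each (candidates for the final
  # network and the gene pool); genes 13..30: one trait each.
  hub_traits <- list(c("HABN", "NABN", "MT_5", "VIAB_5", "ACRO_5"),
                     c("MT_5", "MT_90", "VAP_5", "VAP_90", "VCL_5"),
                     c("VIAB_5", "VIAB_90", "ORT", "CON", "TABN"),
                     c("HABN", "ACRO_5", "ACRO_90", "PDROP", "DDROP"))
  out <- list()
  n_hub <- min(12L, n_genes)
  for (g in seq_len(n_hub)) {
    trs <- hub_traits[[(g - 1L) %% length(hub_traits) + 1L]]
    out[[g]] <- data.frame(gene = g, trait = trs,
                           r = 0.5 * (-1)^(g %% 2),
                           stringsAsFactors = FALSE)
  }
  singles <- .trait_panel()$trait
  for (g in seq(n_hub + 1L, length.out = max(0L, min(38L, n_genes - n_hub)))) {
    out[[g]] <- data.frame(gene = g,
                           trait = singles[(g - 1L) %% length(singles) + 1L],
                           r = 0.45, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.default_mirna_targets <- function(n_mirnas, n_genes) {
  k <- min(8L, n_mirnas, n_genes)
  if (k == 0) return(NULL)
  data.frame(mirna = seq_len(k), gene = seq_len(k), r = -0.6)
}

.default_eqtl_map <- function(qtl_map, expr_trait_corr) {
  # pick QTL whose trait also has a planted correlated gene -> true
  # positives for the eGWAS double filter; prefer genes with the fewest
  # other planted loadings so the planted eQTL correlation is not diluted
  # by the copula variance rescaling
  n_loads <- table(expr_trait_corr$gene)
  out <- list()
  used <- integer(0)
  for (i in seq_len(nrow(qtl_map))) {
    tr <- qtl_map$trait[i]
    g <- setdiff(unique(expr_trait_corr$gene[expr_trait_corr$trait == tr]),
                 used)
    if (!length(g)) next
    # fewest other loadings first, so the planted correlation is not
    # diluted by the copula variance rescaling
    g <- g[order(as.integer(n_loads[as.character(g)]), g)][1]
    used <- c(used, g)
    out[[length(out) + 1L]] <- data.frame(snp = qtl_map$snp[i], gene = g,
                                          r = 0.85)
    if (length(out) >= 2) break
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  samples: %d  SNPs: %d (blocks of %d, rho = %.2f)\n",
              x$n_samples, x$n_snps, x$ld_block_size, x$ld_rho))
  cat(sprintf("  genes: %d  miRNAs: %d  RNA samples: %d\n",
              x$n_genes, x$n_mirnas, x$n_rna_samples))
  cat(sprintf("  planted: %d QTL, %d expr-trait corr, %d miRNA targets, %d eQTL\n",
              nrow(x$qtl_map), nrow(x$expr_trait_corr),
              nrow(x$mirna_target_map), nrow(x$eqtl_map)))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Simulate LD-blocked SNP genotypes
#'
#' Draws per-SNP allele frequencies from `maf_range`, then generates two
#' latent Gaussian gametes per individual with an AR(1) correlation
#' `ld_rho` between adjacent SNPs inside each LD block, thresholds them into
#' alleles and sums to 0/1/2 dosages. Missing genotypes are masked at
#' `missing_rate`. SNPs are laid out along `n_chrom` autosomes with
#' exponential inter-marker spacing (1-based bp).
#'
#' @param cfg A [sim_config()] object.
#' @return A list of class `genotypes` with elements `geno` (samples x SNPs
#'   integer matrix, NA = missing), `map` (data.frame snp_id, chrom, bp, a1,
#'   a2) and `freq` (true simulated alt-allele frequencies).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples; m <- cfg$n_snps
  p <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  thr <- qnorm(p)  # latent < thr -> alt allele

  n_gam <- 2L * n
  z <- matrix(0, n_gam, m)
  blk <- ((seq_len(m) - 1L) %/% cfg$ld_block_size)
  e <- matrix(rnorm(n_gam * m), n_gam, m)
  sq <- sqrt(1 - cfg$ld_rho^2)
  z[, 1] <- e[, 1]
  if (m > 1) {
    for (j in 2:m) {
      if (blk[j] == blk[j - 1L]) {
        z[, j] <- cfg$ld_rho * z[, j - 1L] + sq * e[, j]
      } else {
        z[, j] <- e[, j]
      }
    }
  }
  alle <- sweep(z, 2, thr, "<")  # logical: alt allele
  geno <- alle[seq_len(n), , drop = FALSE] +
    alle[n + seq_len(n), , drop = FALSE]
  storage.mode(geno) <- "integer"
  if (cfg$missing_rate > 0) {
    miss <- matrix(runif(n * m) < cfg$missing_rate, n, m)
    geno[miss] <- NA_integer_
  }
  rownames(geno) <- sprintf("S%04d", seq_len(n))

  # map: spread SNPs over autosomes, exponential spacing, mean 100 kb
  chrom <- rep(seq_len(cfg$n_chrom), length.out = m)
  chrom <- sort(chrom)
  bp <- integer(m)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    bp[idx] <- cumsum(1L + as.integer(round(stats::rexp(length(idx),
                                                        1 / 1e5))))
  }
  map <- data.frame(
    snp_id = sprintf("snp%05d", seq_len(m)),
    chrom = as.character(chrom), bp = bp,
    a1 = "A", a2 = "G", stringsAsFactors = FALSE
  )
  colnames(geno) <- map$snp_id
  structure(list(geno = geno, map = map, freq = p), class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d samples x %d SNPs on %d chromosomes (%.2f%% missing)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom)),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Simulate the 25-trait semen phenotype table
#'
#' Each measured trait is built on a standardized latent scale as the sum of
#' farm, season-year and age effects, the planted QTL contributions
#' (`effect` per SD of dosage), a polygenic term `u ~ N(0, G sigma_u^2)`
#' drawn with the realized genomic relationship matrix of the simulated
#' genotypes, and an i.i.d. residual; `sigma_u^2 = h2`,
#' `sigma_e^2 = 1 - h2`. The latent value is then placed on the trait's
#' published mean/SD scale, and the six 90/5-min ratio traits are derived.
#'
#' @param geno A `genotypes` object from [simulate_genotypes()].
#' @param cfg The same [sim_config()].
#' @return A `data.frame` of class `trait_table` with columns `sample_id`,
#'   `farm`, `season_year`, `age` and the 25 traits. Attributes:
#'   `qtl_truth` (planted QTL with their per-allele effects on the raw
#'   scale), `trait_core` (standardized non-fixed-effect component of each
#'   measured trait, used by the abundance generator), `h2`.
#' @export
simulate_phenotypes <- function(geno, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(geno, "genotypes"))
  if (any(cfg$h2_per_trait > 0) && cfg$n_snps == 0)
    stop("cannot simulate heritable traits without SNPs")
  set.seed(cfg$seed + 1L)
  n <- nrow(geno$geno)
  panel <- .trait_panel()
  h2 <- cfg$h2_per_trait

  lev <- cfg$fixed_effect_levels
  covs <- data.frame(
    sample_id = rownames(geno$geno),
    farm = factor(sprintf("F%d", sample.int(lev["farm"], n, TRUE))),
    season_year = factor(sprintf("SY%d", sample.int(lev["season_year"], n,
                                                    TRUE))),
    age = factor(sprintf("A%d", sample.int(lev["age"], n, TRUE))),
    stringsAsFactors = FALSE
  )

  # polygenic term via the realized GRM
  G <- compute_grm(geno)$grm
  eg <- eigen(G, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  L <- eg$vectors %*% diag(sqrt(ev), n)

  # mean-imputed standardized dosages for QTL contributions
  X <- geno$geno
  cm <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- cm[j]
  X <- scale(X)

  fx <- lapply(c("farm", "season_year", "age"), function(f) {
    eff <- rnorm(nlevels(covs[[f]]), 0, 0.3)
    eff[as.integer(covs[[f]])]
  })
  fixed_part <- fx[[1]] + fx[[2]] + fx[[3]]

  core <- matrix(0, n, nrow(panel), dimnames = list(covs$sample_id,
                                                    panel$trait))
  vals <- core
  truth <- cfg$qtl_map
  truth$beta_raw <- NA_real_
  for (t in seq_len(nrow(panel))) {
    tr <- panel$trait[t]
    u <- as.numeric(L %*% rnorm(n)) * sqrt(h2[tr])
    e <- rnorm(n, 0, sqrt(1 - h2[tr]))
    qtl_part <- numeric(n)
    rows <- which(cfg$qtl_map$trait == tr)
    for (i in rows) {
      zdos <- X[, cfg$qtl_map$snp[i]]
      if (all(is.finite(zdos))) {
        qtl_part <- qtl_part + cfg$qtl_map$effect[i] * zdos
        sd_dos <- sd(geno$geno[, cfg$qtl_map$snp[i]], na.rm = TRUE)
        truth$beta_raw[i] <- cfg$qtl_map$effect[i] * panel$sd[t] / sd_dos
      }
    }
    core[, t] <- u + qtl_part + e
    vals[, t] <- panel$mean[t] + panel$sd[t] * (fixed_part + core[, t])
  }

  out <- cbind(covs, as.data.frame(vals))
  rp <- .ratio_pairs()
  for (i in seq_len(nrow(rp)))
    out[[rp$ratio[i]]] <- out[[rp$num[i]]] / out[[rp$den[i]]]
  rownames(out) <- NULL
  attr(out, "qtl_truth") <- truth
  attr(out, "trait_core") <- core
  attr(out, "h2") <- h2
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Simulate mRNA (FPKM) and miRNA (CPM) abundance matrices
#'
#' Abundances are log-normal: `log2(value) = m + s * z` with a standard
#' normal latent `z` per feature. Planted expression-trait correlations are
#' realized through a Gaussian copula against the standardized non-fixed
#' component of the target trait (so the Pearson correlation on the log2
#' scale is the requested `r` in expectation); planted eQTL add a
#' standardized-dosage component; planted miRNA targets receive a negative
#' loading on their gene's latent. A fraction `frac_low_expr` of features is
#' simulated below the abundance screens (mean FPKM < 10, mean CPM <= 1).
#'
#' @param cfg A [sim_config()].
#' @param traits The `trait_table` from [simulate_phenotypes()].
#' @param geno Optional `genotypes` object; required when `cfg$eqtl_map` is
#'   nonempty.
#' @return List with elements `mrna` and `mirna`, each an
#'   `abundance_matrix` (features x RNA samples, raw FPKM/CPM scale), plus
#'   `annotation`: the gene/miRNA annotation table (chrom, start, end,
#'   1-based inclusive, biotype, tf_class) with genes anchored at SNP
#'   positions so that SNP-to-gene distance rules are exercised.
#' @export
simulate_abundances <- function(cfg, traits, geno = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(traits, "trait_table"))
  if (nrow(cfg$eqtl_map) && is.null(geno))
    stop("eqtl_map planted but no genotypes supplied")
  set.seed(cfg$seed + 2L)
  ns <- cfg$n_rna_samples
  samp <- traits$sample_id[seq_len(ns)]
  core <- attr(traits, "trait_core")[seq_len(ns), , drop = FALSE]
  core_z <- scale(core)

  dos_z <- NULL
  if (!is.null(geno)) {
    Xg <- geno$geno[seq_len(ns), , drop = FALSE]
    cm <- colMeans(Xg, na.rm = TRUE)
    for (j in seq_len(ncol(Xg))) Xg[is.na(Xg[, j]), j] <- cm[j]
    dos_z <- scale(Xg)
  }

  mk_latent <- function(idx_df, n_feat, comp_fun) {
    # comp_fun(row) returns the planted standardized component vector
    z <- matrix(rnorm(n_feat * ns), n_feat, ns)
    for (f in unique(idx_df$feature)) {
      rows <- idx_df[idx_df$feature == f, , drop = FALSE]
      comp <- matrix(0, ns, nrow(rows))
      for (k in seq_len(nrow(rows))) comp[, k] <- comp_fun(rows[k, ])
      w <- rows$r
      s2 <- 1 - sum(w^2)
      if (s2 <= 0.05) {
        w <- w * sqrt(0.95 / sum(w^2))
        s2 <- 0.05
      }
      z[f, ] <- as.numeric(comp %*% w) + sqrt(s2) * rnorm(ns)
    }
    z
  }

  # genes
  plant <- cfg$expr_trait_corr
  plant_df <- data.frame(feature = plant$gene, r = plant$r,
                         trait = plant$trait, stringsAsFactors = FALSE)
  if (nrow(cfg$eqtl_map)) {
    plant_df <- rbind(plant_df,
                      data.frame(feature = cfg$eqtl_map$gene,
                                 r = cfg$eqtl_map$r,
                                 trait = paste0("dos:", cfg$eqtl_map$snp)))
  }
  zg <- mk_latent(plant_df, cfg$n_genes, function(row) {
    if (startsWith(row$trait, "dos:")) {
      dos_z[, as.integer(sub("dos:", "", row$trait))]
    } else {
      core_z[, row$trait]
    }
  })

  n_low <- as.integer(round(cfg$frac_low_expr * cfg$n_genes))
  planted_genes <- unique(plant_df$feature)
  low_pool <- setdiff(seq_len(cfg$n_genes), planted_genes)
  low_genes <- low_pool[seq_len(min(n_low, length(low_pool)))]
  m_g <- runif(cfg$n_genes, 4.5, 9)
  m_g[low_genes] <- runif(length(low_genes), -1, 2)
  s_g <- runif(cfg$n_genes, 0.8, 1.2)
  log2_fpkm <- m_g + s_g * zg
  mrna <- 2^log2_fpkm
  rownames(mrna) <- sprintf("gene%04d", seq_len(cfg$n_genes))
  colnames(mrna) <- samp

  # miRNAs: planted negative loadings on target-gene latents
  if (cfg$n_mirnas > 0) {
    tm <- cfg$mirna_target_map
    tm_df <- data.frame(feature = tm$mirna, r = tm$r, gene = tm$gene)
    zm <- matrix(rnorm(cfg$n_mirnas * ns), cfg$n_mirnas, ns)
    zg_z <- t(scale(t(zg)))
    for (f in unique(tm_df$feature)) {
      rows <- tm_df[tm_df$feature == f, , drop = FALSE]
      w <- rows$r
      s2 <- max(0.05, 1 - sum(w^2))
      comp <- t(zg_z[rows$gene, , drop = FALSE])
      zm[f, ] <- as.numeric(comp %*% w) + sqrt(s2) * rnorm(ns)
    }
    n_low_m <- as.integer(round(cfg$frac_low_expr * cfg$n_mirnas))
    low_m <- setdiff(seq_len(cfg$n_mirnas), unique(tm_df$feature))
    low_m <- low_m[seq_len(min(n_low_m, length(low_m)))]
    m_m <- runif(cfg$n_mirnas, 3, 9)
    m_m[low_m] <- runif(length(low_m), -4, -1.5)
    mirna <- 2^(m_m + runif(cfg$n_mirnas, 0.8, 1.2) * zm)
    rownames(mirna) <- sprintf("mir%03d", seq_len(cfg$n_mirnas))
    colnames(mirna) <- samp
  } else {
    mirna <- matrix(numeric(0), 0, ns, dimnames = list(NULL, samp))
  }

  annotation <- .simulate_annotation(cfg, geno, rownames(mrna),
                                     rownames(mirna))
  list(
    mrna = abundance_matrix(mrna, kind = "mRNA"),
    mirna = abundance_matrix(mirna, kind = "miRNA"),
    annotation = annotation
  )
}

# Genes anchored at randomly chosen SNP positions (guaranteeing in-gene
# SNPs for the AWM distance rule); miRNA loci likewise.
.simulate_annotation <- function(cfg, geno, gene_ids, mirna_ids) {
  if (is.null(geno)) {
    chrom <- as.character(rep(seq_len(cfg$n_chrom),
                              length.out = length(gene_ids)))
    start <- as.integer(runif(length(gene_ids), 1, 5e7))
  } else {
    anchor <- sample.int(nrow(geno$map), length(gene_ids), replace = TRUE)
    ag <- cfg$anchor_genes
    if (!is.null(ag) && nrow(ag))
      anchor[ag$gene] <- ag$snp   # pleiotropic-QTL genes sit on their SNP
    chrom <- geno$map$chrom[anchor]
    start <- pmax(1L, geno$map$bp[anchor] -
                    as.integer(runif(length(gene_ids), 200, 2000)))
  }
  width <- as.integer(runif(length(gene_ids), 2000, 50000))
  ann <- data.frame(
    gene_id = gene_ids, chrom = chrom, start = start,
    end = start + width, biotype = "coding",
    tf_class = sample(c("TF", "TF-cofactor", "none"),
                      length(gene_ids), TRUE, prob = c(0.1, 0.05, 0.85)),
    stringsAsFactors = FALSE
  )
  if (length(mirna_ids)) {
    mstart <- as.integer(runif(length(mirna_ids), 1, 5e7))
    ann <- rbind(ann, data.frame(
      gene_id = mirna_ids,
      chrom = as.character(sample.int(cfg$n_chrom, length(mirna_ids),
                                      TRUE)),
      start = mstart, end = mstart + 100L, biotype = "miRNA",
      tf_class = "none", stringsAsFactors = FALSE
    ))
  }
  ann
}
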