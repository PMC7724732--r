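# Expression GWAS: per-gene simple-regression association of log2
# abundance on SNP dosage, BH-FDR, cis/trans labeling, and the
# phenotype-anchored double filter.

#' Expression GWAS scan
#'
#' For every (SNP, gene) pair, the simple linear regression of the gene's
#' log2 abundance on the dosage (`abundance = mu + SNP + e`), on the
#' samples shared between genotypes and expression. FDR is computed per
#' gene by default (each gene's genome scan is its own family), optionally
#' pooled. A record is labeled `cis` when SNP and gene lie on the same
#' chromosome within `cis_window` bp, `trans` otherwise (requires
#' `annotation`).
#'
#' Only records with q below `report_q` are returned (the full scan is
#' n_snps x n_genes records); set `report_q = 1` to keep everything.
#'
#' @param geno Post-QC `genotypes`.
#' @param abund Log2-scale `abundance_matrix`.
#' @param annotation Optional gene annotation (gene_id, chrom, start, end).
#' @param fdr_scope `"per_gene"` (default) or `"pooled"`.
#' @param report_q Reporting FDR cutoff (default 0.05).
#' @param cis_window bp window for the cis label (default 1 Mbp).
#' @return data.frame of class `eqtl_records`: snp_id, gene_id, beta, se,
#'   p, q, cis_trans; attribute `n_tested` (pairs tested).
#' @export
egwas_scan <- function(geno, abund, annotation = NULL,
                       fdr_scope = c("per_gene", "pooled"),
                       report_q = 0.05, cis_window = 1e6) {
  stopifnot(inherits(geno, "genotypes"),
            inherits(abund, "abundance_matrix"))
  if (!isTRUE(attr(abund, "log2")))
    stop("log2-stabilized abundances required")
  fdr_scope <- match.arg(fdr_scope)
  samp <- intersect(rownames(geno$geno), colnames(abund))
  if (length(samp) < 3) stop("fewer than 3 overlapping samples")
  Z <- .imputed_dosages(geno$geno[samp, , drop = FALSE])
  Y <- t(unclass(abund)[, samp, drop = FALSE])
  n <- length(samp)
  sx <- apply(Z, 2, sd)
  sy <- apply(Y, 2, sd)
  ok_x <- sx > 0; ok_y <- sy > 0
  R <- matrix(NA_real_, ncol(Z), ncol(Y),
              dimnames = list(colnames(Z), colnames(Y)))
  R[ok_x, ok_y] <- cor(Z[, ok_x, drop = FALSE], Y[, ok_y, drop = FALSE])
  tstat <- abs(R) * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  B <- R * rep(sy, each = nrow(R)) / sx
  Q <- P
  if (fdr_scope == "per_gene") {
    for (j in seq_len(ncol(P))) Q[, j] <- bh_fdr(P[, j])
  } else {
    Q[] <- bh_fdr(as.numeric(P))
  }
  idx <- which(Q <= report_q, arr.ind = TRUE)
  out <- data.frame(
    snp_id = rownames(R)[idx[, 1]], gene_id = colnames(R)[idx[, 2]],
    beta = B[idx], p = P[idx], q = Q[idx], stringsAsFactors = FALSE
  )
  out$cis_trans <- NA_character_
  if (!is.null(annotation) && nrow(out)) {
    mi <- match(out$snp_id, geno$map$snp_id)
    gi <- match(out$gene_id, annotation$gene_id)
    same <- !is.na(gi) & geno$map$chrom[mi] == annotation$chrom[gi]
    dist <- pmax(0, pmax(annotation$start[gi] - geno$map$bp[mi],
                         geno$map$bp[mi] - annotation$end[gi]))
    out$cis_trans <- ifelse(same & dist <= cis_window, "cis", "trans")
  }
  out <- out[order(out$gene_id, out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- sum(ok_x) * sum(ok_y)
  class(out) <- c("eqtl_records", "data.frame")
  out
}

#' Double filter tying eQTL to phenotype-relevant SNPs and genes
#'
#' Keeps an eGWAS record only if (i) its SNP is itself a significant GWAS
#' hit (FDR <= 0.05) for some sperm trait, and (ii) the gene's abundance is
#' significantly correlated with that same trait. The matching trait is
#' annotated as `linked_trait` (one output row per qualifying
#' SNP-gene-trait combination).
#'
#' @param eqtl `eqtl_records` from [egwas_scan()].
#' @param gwas_hits data.frame with columns snp_id, trait (e.g.
#'   [scan_hits()] at FDR <= 0.05).
#' @param trait_corr `trait_correlations`; only rows flagged significant
#'   are used.
#' @return Filtered `eqtl_records` with column `linked_trait` added;
#'   always a subset of the input records.
#' @export
filter_egwas <- function(eqtl, gwas_hits, trait_corr) {
  stopifnot(inherits(eqtl, "eqtl_records"))
  sig_corr <- trait_corr[trait_corr$significant, c("feature", "trait")]
  out <- list()
  for (i in seq_len(nrow(eqtl))) {
    snp_traits <- unique(gwas_hits$trait[gwas_hits$snp_id ==
                                           eqtl$snp_id[i]])
    if (!length(snp_traits)) next
    gene_traits <- sig_corr$trait[sig_corr$feature == eqtl$gene_id[i]]
    shared <- intersect(snp_traits, gene_traits)
    for (tr in shared) {
      rec <- eqtl[i, , drop = FALSE]
      rec$linked_trait <- tr
      out[[length(out) + 1L]] <- rec
    }
  }
  if (!length(out)) {
    res <- eqtl[0, , drop = FALSE]
    res$linked_trait <- character(0)
  } else res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("eqtl_records", "data.frame")
  res
}
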