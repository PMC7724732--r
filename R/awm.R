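# Associated weight matrix: SNP selection anchored on a key phenotype,
# gene-distance assignment, one SNP per gene, and column-z-scored additive
# effects across all traits.

#' Select SNPs for the associated weight matrix
#'
#' Four-stage selection around the key phenotype (default VIAB_5):
#' \enumerate{
#'   \item SNPs associated with the key trait at `p <= p_thr`.
#'   \item Trait-dependency stage: Ap is the average number of non-key
#'     traits associated (`p <= p_thr`) over the stage-1 SNPs; SNPs whose
#'     non-key association count is at least `max(2, ceiling(Ap))` qualify.
#'     By default the stage-1 and stage-2 sets are united
#'     (`combine = "union"`); `"sequential"` keeps only stage-1 SNPs that
#'     also meet the Ap rule.
#'   \item Distance rule: keep SNPs lying strictly closer than 2500 bp to,
#'     or strictly farther than 1 Mbp from, the nearest annotated gene on
#'     the same chromosome; each kept SNP is assigned to its nearest gene.
#'     SNPs with no gene on their chromosome are treated as infinitely far
#'     (kept by the far branch) but, having no assignable gene, are dropped
#'     with a warning.
#'   \item One SNP per gene: the SNP with the smallest key-trait P-value.
#' }
#'
#' @param scan An `assoc_scan`.
#' @param annotation Gene annotation (gene_id, chrom, start, end, biotype);
#'   only `biotype == "coding"` rows anchor SNPs (when the column exists).
#' @param key_trait Key phenotype (default `"VIAB_5"`).
#' @param p_thr Association threshold (default 0.01).
#' @param near_bp,far_bp Distance-rule bounds (defaults 2500 and 1e6).
#' @param combine `"union"` or `"sequential"` (see above).
#' @return data.frame: gene_id, snp_id, chrom, bp, key_p, n_nonkey;
#'   attributes `ap` (the realized Ap), `stage_counts`.
#' @export
select_awm_snps <- function(scan, annotation, key_trait = "VIAB_5",
                            p_thr = 0.01, near_bp = 2500, far_bp = 1e6,
                            combine = c("union", "sequential")) {
  stopifnot(inherits(scan, "assoc_scan"))
  combine <- match.arg(combine)
  if (!key_trait %in% scan$traits) stop("key trait absent from scan")
  P <- scan$p
  key_p <- P[, key_trait]
  stage1 <- which(!is.na(key_p) & key_p <= p_thr)
  if (!length(stage1))
    stop("no SNPs pass the key-trait threshold; consider a looser p_thr")
  nonkey <- setdiff(scan$traits, key_trait)
  cnt <- rowSums(P[, nonkey, drop = FALSE] <= p_thr, na.rm = TRUE)
  ap <- mean(cnt[stage1])
  need <- max(2, ceiling(ap))
  stage2 <- which(cnt >= need)
  sel <- if (combine == "union") union(stage1, stage2)
  else intersect(stage1, stage2)
  sel <- sort(sel)

  ann <- annotation
  if ("biotype" %in% names(ann))
    ann <- ann[ann$biotype == "coding", , drop = FALSE]
  map <- scan$map[sel, , drop = FALSE]
  gene_id <- rep(NA_character_, nrow(map))
  dist <- rep(Inf, nrow(map))
  for (i in seq_len(nrow(map))) {
    g <- ann[ann$chrom == map$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    d <- pmax(0, pmax(g$start - map$bp[i], map$bp[i] - g$end))
    j <- which.min(d)
    gene_id[i] <- g$gene_id[j]
    dist[i] <- d[j]
  }
  keep_near <- dist < near_bp
  keep_far <- dist > far_bp    # includes gene-free chromosomes (d = Inf)
  keep <- keep_near | keep_far
  no_gene <- keep & is.na(gene_id)
  if (any(no_gene))
    warning(sum(no_gene), " selected SNP(s) without an assignable gene ",
            "dropped")
  keep <- keep & !is.na(gene_id)

  cand <- data.frame(
    gene_id = gene_id[keep], snp_id = map$snp_id[keep],
    chrom = map$chrom[keep], bp = map$bp[keep],
    key_p = key_p[sel][keep], n_nonkey = cnt[sel][keep],
    stringsAsFactors = FALSE
  )
  if (!nrow(cand)) stop("no SNPs survive the gene-distance rule")
  cand <- cand[order(cand$gene_id, cand$key_p, cand$snp_id), ,
               drop = FALSE]
  cand <- cand[!duplicated(cand$gene_id), , drop = FALSE]
  rownames(cand) <- NULL
  attr(cand, "ap") <- ap
  attr(cand, "stage_counts") <- c(stage1 = length(stage1),
                                  stage2 = length(stage2),
                                  selected = length(sel),
                                  after_distance = sum(keep),
                                  genes = nrow(cand))
  cand
}

#' Build the associated weight matrix
#'
#' One row per selected gene (its selected SNP), one column per trait; each
#' cell is the SNP's additive effect for that trait (significant or not),
#' z-score standardized within the trait column.
#'
#' @param selected Output of [select_awm_snps()].
#' @param scan The `assoc_scan` the selection came from.
#' @param key_trait Key phenotype recorded on the result.
#' @return Object of class `awm`: the genes x traits matrix with
#'   attributes `snp_ids` (named by gene), `key_trait`, `ap`.
#' @export
build_awm <- function(selected, scan, key_trait = "VIAB_5") {
  stopifnot(inherits(scan, "assoc_scan"))
  if (anyDuplicated(selected$gene_id)) stop("duplicate gene rows")
  B <- scan$beta[match(selected$snp_id, rownames(scan$beta)), ,
                 drop = FALSE]
  A <- scale(B)
  A[is.nan(A)] <- 0
  rownames(A) <- selected$gene_id
  structure(as.matrix(A),
            snp_ids = setNames(selected$snp_id, selected$gene_id),
            key_trait = key_trait,
            ap = attr(selected, "ap"),
            class = c("awm", "matrix", "array"))
}

#' @export
print.awm <- function(x, ...) {
  cat(sprintf("AWM: %d genes x %d traits (key trait %s, Ap = %.2f)\n",
              nrow(x), ncol(x), attr(x, "key_trait"),
              attr(x, "ap")))
  invisible(x)
}
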