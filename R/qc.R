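# Genotype quality control: sample call rate, MAF, Hardy-Weinberg exact
# test, SNP missingness, autosome restriction; plus composite (dosage) LD.

#' QC thresholds
#'
#' Defaults reproduce the study filters: samples with call rate lower than
#' 96% excluded; SNPs with minor allele frequency lower than 0.05, HWE
#' exact-test P <= 0.001, or more than 5% missing genotypes excluded; SNPs
#' on sex chromosomes or unplaced scaffolds excluded.
#'
#' @param sample_call_rate_min Minimum sample call rate (exclusive bound:
#'   rates strictly below are removed).
#' @param maf_min Minimum minor allele frequency (exclusive bound).
#' @param hwe_p_max SNPs with HWE exact P <= this are removed.
#' @param snp_missing_max SNPs with missingness strictly above this are
#'   removed.
#' @param autosomes_only Drop sex chromosomes (X/Y/MT) and non-numeric
#'   scaffold labels.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_call_rate_min = 0.96, maf_min = 0.05,
                          hwe_p_max = 0.001, snp_missing_max = 0.05,
                          autosomes_only = TRUE) {
  vals <- c(sample_call_rate_min, maf_min, hwe_p_max, snp_missing_max)
  if (any(vals < 0) || any(vals > 1))
    stop("all thresholds must lie in [0, 1]")
  structure(list(sample_call_rate_min = sample_call_rate_min,
                 maf_min = maf_min, hwe_p_max = hwe_p_max,
                 snp_missing_max = snp_missing_max,
                 autosomes_only = autosomes_only),
            class = "qc_thresholds")
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided P-value from the conditional distribution of the
#' heterozygote count given the allele counts (Wigginton-style): the
#' P-value is the total probability of all heterozygote configurations no
#' more probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return Exact P-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no called genotypes")
  nA <- 2 * n_AA + n_Aa   # rarer allele count decided below
  na <- 2 * n_aa + n_Aa
  n_rare <- min(nA, na)
  # heterozygote count has the parity of the rare allele count
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  # log P(het = h | allele counts) up to a constant:
  # P(h) proportional to n! / (nAA! h! naa!) * 2^h with
  # nAA = (n_rare - h)/2 ... using rare/common split
  n_common <- 2 * n - n_rare
  lp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- (n_common - h) / 2
    h * log(2) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs + 1e-12]))
}

#' Apply the study's genotype QC filters
#'
#' Filter order is fixed: (1) samples by call rate, (2) SNPs by MAF
#' (recomputed on retained samples), (3) HWE exact test, (4) SNP
#' missingness, (5) autosome restriction. The sequence is repeated until it
#' removes nothing, so the result is a fixed point and QC is idempotent.
#' Boundary behavior follows the stated rules: a call rate of exactly the threshold or a MAF of exactly
#' `maf_min` is kept ("lower than" excludes); HWE P equal to `hwe_p_max` is
#' removed; missingness equal to `snp_missing_max` is kept.
#'
#' @param geno A `genotypes` object.
#' @param thr A [qc_thresholds()] object.
#' @return List of class `qc_result`: `genotypes` (filtered), `report`
#'   (counts removed per filter), `kept_samples`, `kept_snps`.
#' @export
apply_qc <- function(geno, thr = qc_thresholds()) {
  stopifnot(inherits(geno, "genotypes"), inherits(thr, "qc_thresholds"))
  X <- geno$geno; map <- geno$map; freq <- geno$freq
  report <- list(samples_low_call_rate = 0L, snps_low_maf = 0L,
                 snps_hwe = 0L, snps_missingness = 0L,
                 snps_non_autosomal = 0L)

  # the filter sequence is repeated until it removes nothing: removing
  # high-missingness SNPs can change sample call rates and vice versa, so
  # a single pass is not a fixed point
  repeat {
    removed <- 0L

    cr <- rowMeans(!is.na(X))
    keep_s <- cr >= thr$sample_call_rate_min
    report$samples_low_call_rate <- report$samples_low_call_rate +
      sum(!keep_s)
    removed <- removed + sum(!keep_s)
    X <- X[keep_s, , drop = FALSE]
    if (nrow(X) == 0) stop("no samples survive QC")

    p <- colMeans(X, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    maf[is.nan(maf)] <- 0
    keep_maf <- maf >= thr$maf_min
    report$snps_low_maf <- report$snps_low_maf + sum(!keep_maf)

    hwe_p <- rep(NA_real_, ncol(X))
    for (j in which(keep_maf)) {
      g <- X[, j]
      hwe_p[j] <- hwe_exact_test(sum(g == 2, na.rm = TRUE),
                                 sum(g == 1, na.rm = TRUE),
                                 sum(g == 0, na.rm = TRUE))
    }
    keep_hwe <- keep_maf & (is.na(hwe_p) | hwe_p > thr$hwe_p_max)
    report$snps_hwe <- report$snps_hwe + sum(keep_maf & !keep_hwe)

    miss <- colMeans(is.na(X))
    keep_miss <- keep_hwe & miss <= thr$snp_missing_max
    report$snps_missingness <- report$snps_missingness +
      sum(keep_hwe & !keep_miss)

    keep_auto <- keep_miss
    if (thr$autosomes_only) {
      autosomal <- grepl("^[0-9]+$", map$chrom)
      keep_auto <- keep_miss & autosomal
      report$snps_non_autosomal <- report$snps_non_autosomal +
        sum(keep_miss & !autosomal)
    }

    if (!any(keep_auto)) stop("no SNPs survive QC")
    removed <- removed + sum(!keep_auto)
    X <- X[, keep_auto, drop = FALSE]
    map <- map[keep_auto, , drop = FALSE]
    freq <- freq[keep_auto]
    if (removed == 0L) break
  }

  out <- structure(list(geno = X, map = map, freq = freq),
                   class = "genotypes")
  structure(list(genotypes = out,
                 report = as.data.frame(report),
                 kept_samples = rownames(X),
                 kept_snps = map$snp_id),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("Genotype QC\n")
  cat(sprintf("  kept: %d samples, %d SNPs\n",
              length(x$kept_samples), length(x$kept_snps)))
  r <- x$report
  for (nm in names(r)) cat(sprintf("  removed (%s): %d\n", nm, r[[nm]]))
  invisible(x)
}

#' Pairwise LD as squared dosage correlation
#'
#' Composite (genotypic) LD: the squared Pearson correlation of the two
#' dosage vectors; no phasing is attempted. Missing dosages are mean-imputed
#' for this computation only.
#'
#' @param snp_a,snp_b Dosage vectors (0/1/2, NA allowed).
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(snp_a, snp_b) {
  stopifnot(length(snp_a) == length(snp_b))
  if (sum(stats::complete.cases(snp_a, snp_b)) < 2)
    stop("need at least 2 complete pairs")
  snp_a[is.na(snp_a)] <- mean(snp_a, na.rm = TRUE)
  snp_b[is.na(snp_b)] <- mean(snp_b, na.rm = TRUE)
  if (sd(snp_a) == 0 || sd(snp_b) == 0)
    stop("LD undefined for a monomorphic SNP")
  cor(snp_a, snp_b)^2
}
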