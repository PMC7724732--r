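# Independent brute-force oracles, deliberately written with naive loops so
# they share no code path with the package implementations.

# PCIT trio elimination, straight from the definition.
oracle_pcit_keep <- function(corr) {
  n <- nrow(corr)
  keep <- matrix(TRUE, n, n)
  diag(keep) <- FALSE
  if (n < 3) return(keep)
  partial <- function(rxy, rxz, ryz) {
    den <- sqrt((1 - rxz^2) * (1 - ryz^2))
    if (den < 1e-12) return(NA_real_)
    (rxy - rxz * ryz) / den
  }
  for (x in 1:(n - 2)) for (y in (x + 1):(n - 1)) for (z in (y + 1):n) {
    rxy <- corr[x, y]; rxz <- corr[x, z]; ryz <- corr[y, z]
    ratios <- c()
    pxy <- partial(rxy, rxz, ryz)
    pxz <- partial(rxz, rxy, ryz)
    pyz <- partial(ryz, rxy, rxz)
    if (abs(rxy) >= 1e-12 && !is.na(pxy)) ratios <- c(ratios, abs(pxy / rxy))
    if (abs(rxz) >= 1e-12 && !is.na(pxz)) ratios <- c(ratios, abs(pxz / rxz))
    if (abs(ryz) >= 1e-12 && !is.na(pyz)) ratios <- c(ratios, abs(pyz / ryz))
    if (!length(ratios)) next
    eps <- mean(ratios)
    if (abs(rxy) <= abs(eps * rxz) && abs(rxy) <= abs(eps * ryz))
      keep[x, y] <- keep[y, x] <- FALSE
    if (abs(rxz) <= abs(eps * rxy) && abs(rxz) <= abs(eps * ryz))
      keep[x, z] <- keep[z, x] <- FALSE
    if (abs(ryz) <= abs(eps * rxy) && abs(ryz) <= abs(eps * rxz))
      keep[y, z] <- keep[z, y] <- FALSE
  }
  keep
}

# Benjamini-Hochberg from the closed-form definition
# q_i = min over { j : p_j >= p_i } of m * p_j / rank(p_j).
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    cand <- which(p >= p[i])
    min(1, min(m * p[cand] / r[cand]))
  }, numeric(1))
}

# HWE exact test by full enumeration of the conditional distribution of the
# heterozygote count given allele counts, using exact log probabilities of
# the full multinomial form.
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  hs <- seq(if (min(nA, na) %% 2 == 0) 0 else 1, min(nA, na), by = 2)
  logp <- vapply(hs, function(h) {
    aa <- (nA - h) / 2
    bb <- (na - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp)
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nAa, hs)] + 1e-12])
}

# Single-pass interval clustering oracle (positions sorted; new interval at
# gap >= gap_bp).
oracle_intervals <- function(bp, gap_bp = 5e6) {
  bp <- sort(bp)
  groups <- list()
  cur <- bp[1]
  if (length(bp) > 1) for (i in 2:length(bp)) {
    if (bp[i] - bp[i - 1] >= gap_bp) {
      groups[[length(groups) + 1]] <- cur
      cur <- bp[i]
    } else cur <- c(cur, bp[i])
  }
  groups[[length(groups) + 1]] <- cur
  groups
}

# Build a minimal genotypes object from a dosage matrix.
make_geno <- function(X, chrom = NULL, bp = NULL) {
  X <- as.matrix(X)
  m <- ncol(X)
  if (is.null(rownames(X))) rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  map <- data.frame(
    snp_id = sprintf("snp%04d", seq_len(m)),
    chrom = if (is.null(chrom)) rep("1", m) else as.character(chrom),
    bp = if (is.null(bp)) seq_len(m) * 1000L else as.integer(bp),
    a1 = "A", a2 = "G", stringsAsFactors = FALSE
  )
  colnames(X) <- map$snp_id
  structure(list(geno = X, map = map,
                 freq = colMeans(X, na.rm = TRUE) / 2),
            class = "genotypes")
}

# Minimal assoc_scan fixture from beta and p matrices.
make_scan <- function(B, P, chrom = NULL, bp = NULL) {
  m <- nrow(B)
  map <- data.frame(
    snp_id = if (is.null(rownames(B))) sprintf("snp%04d", seq_len(m))
             else rownames(B),
    chrom = if (is.null(chrom)) rep("1", m) else as.character(chrom),
    bp = if (is.null(bp)) seq_len(m) * 1000L else as.integer(bp),
    a1 = "A", a2 = "G", stringsAsFactors = FALSE
  )
  rownames(B) <- rownames(P) <- map$snp_id
  Q <- apply(P, 2, function(x) p.adjust(x, "BH"))
  structure(list(beta = B, se = B * 0 + 1, p = P, q = Q, map = map,
                 traits = colnames(B),
                 h2 = data.frame(trait = colnames(B), h2 = NA, se = NA)),
            class = "assoc_scan")
}

# Multivariate normal sample with given correlation, via Cholesky.
rmvn_corr <- function(n, R) {
  p <- nrow(R)
  matrix(rnorm(n * p), n, p) %*% chol(R)
}
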