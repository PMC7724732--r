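# Mixed-linear-model association: phenotype preparation, P3D/EMMAX-style
# single-SNP scan with GREML-estimated variance components, BH-FDR, and
# 5-Mbp QTL interval clustering.

#' Adjust phenotypes for the fixed environmental effects
#'
#' Per trait, returns the residuals of an ordinary least-squares fit on
#' farm, season-year and age (factors). Ratio traits (90/5-min) are
#' computed from the raw values before adjustment if absent. A covariate
#' with a single observed level is dropped (the residuals then equal the
#' centered trait); an aliased (rank-deficient) design is an error naming
#' the aliased columns.
#'
#' @param traits A `trait_table`.
#' @param covariates Covariate column names (default farm, season_year,
#'   age).
#' @return A `trait_table` of residuals (covariate columns retained),
#'   attribute `adjusted = TRUE`.
#' @export
adjust_phenotypes <- function(traits,
                              covariates = c("farm", "season_year",
                                             "age")) {
  stopifnot(is.data.frame(traits))
  tn <- intersect(trait_names(), names(traits))
  if (!length(tn)) stop("no recognized trait columns")
  rp <- .ratio_pairs()
  for (i in seq_len(nrow(rp))) {
    if (!rp$ratio[i] %in% names(traits) &&
        all(c(rp$num[i], rp$den[i]) %in% names(traits))) {
      traits[[rp$ratio[i]]] <- traits[[rp$num[i]]] / traits[[rp$den[i]]]
      tn <- c(tn, rp$ratio[i])
    }
  }
  covariates <- intersect(covariates, names(traits))
  use <- character(0)
  for (cv in covariates) {
    f <- droplevels(factor(traits[[cv]]))
    traits[[cv]] <- f
    if (nlevels(f) >= 2) use <- c(use, cv)
  }
  if (length(use)) {
    fml <- as.formula(paste("~", paste(use, collapse = " + ")))
    M <- model.matrix(fml, traits)
    qrM <- qr(M)
    if (qrM$rank < ncol(M)) {
      aliased <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
      stop("aliased covariate levels: ", paste(aliased, collapse = ", "))
    }
  } else M <- matrix(1, nrow(traits), 1)
  out <- traits
  for (tr in tn) {
    y <- traits[[tr]]
    ok <- is.finite(y)
    res <- rep(NA_real_, length(y))
    fit <- lm.fit(M[ok, , drop = FALSE], y[ok])
    res[ok] <- fit$residuals
    out[[tr]] <- res
  }
  attr(out, "adjusted") <- TRUE
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Benjamini-Hochberg FDR
#'
#' Step-up q-values with monotonicity enforcement; input order preserved.
#' @param p Vector of P-values in (0, 1].
#' @return q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.na(p) & (p <= 0 | p > 1))) stop("p-values must lie in (0,1]")
  p.adjust(p, method = "BH")
}

#' Single-trait mixed-linear-model association scan
#'
#' The model is `y = mu + delta SNP + covariates + u + e` with
#' `u ~ N(0, G sigma_u2)`. Variance components are estimated once under the
#' no-SNP null by [greml()] (P3D/EMMAX approximation), then each SNP is
#' tested by a generalized-least-squares Wald test of `delta` in the
#' eigenbasis of G. Dosages are centered (equivalent to the -1/0/1 coding)
#' and mean-imputed where missing. A trait whose null fit lands at the
#' `sigma_u2` boundary reduces automatically to ordinary least squares.
#'
#' @param geno A `genotypes` object.
#' @param y Trait vector aligned with `rownames(geno$geno)`.
#' @param X Fixed-covariate design matrix (with intercept); default
#'   intercept only.
#' @param G GRM (`grm` object/matrix) or a [grm_eigen()]; computed from
#'   `geno` when NULL.
#' @param eig Optional precomputed [grm_eigen()] (alias for `G`).
#' @param trait Trait name carried into the output.
#' @param exact_reml If TRUE, re-estimate variance components for every SNP
#'   (slow; the P3D approximation is the default).
#' @return data.frame of class `assoc_result`: snp_id, chrom, bp, maf,
#'   beta, se, p, q.
#' @export
mlm_assoc <- function(geno, y, X = NULL, G = NULL, eig = NULL,
                      trait = "trait", exact_reml = FALSE) {
  stopifnot(inherits(geno, "genotypes"))
  n_all <- nrow(geno$geno)
  stopifnot(length(y) == n_all)
  keep <- !is.na(y)
  Xf <- if (is.null(X)) matrix(1, n_all, 1) else as.matrix(X)
  Z <- .imputed_dosages(geno$geno)
  maf <- pmin(colMeans(Z) / 2, 1 - colMeans(Z) / 2)
  y <- y[keep]; Xf <- Xf[keep, , drop = FALSE]
  Z <- Z[keep, , drop = FALSE]
  if (is.null(eig)) {
    if (inherits(G, "grm_eigen")) eig <- G
    else {
      M <- if (is.null(G)) compute_grm(geno)$grm
      else if (inherits(G, "grm")) G$grm else as.matrix(G)
      eig <- grm_eigen(M[keep, keep, drop = FALSE])
    }
  }
  null_fit <- greml(y, Xf, eig)
  res <- .gls_scan(Z, y, Xf, eig, null_fit, exact_reml = exact_reml)
  out <- data.frame(
    snp_id = geno$map$snp_id, chrom = geno$map$chrom, bp = geno$map$bp,
    trait = trait, maf = maf, beta = res$beta, se = res$se, p = res$p,
    stringsAsFactors = FALSE
  )
  out$q <- bh_fdr(out$p)
  attr(out, "null_fit") <- null_fit
  class(out) <- c("assoc_result", "data.frame")
  out
}

.imputed_dosages <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  cm <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- cm[((idx - 1L) %/% n) + 1L]
  X
}

# GLS Wald scan in the eigenbasis of G, vectorized across SNPs.
.gls_scan <- function(Z, y, Xf, eig, null_fit, exact_reml = FALSE) {
  n <- length(y)
  U <- eig$vectors; d <- eig$values
  Zc <- sweep(Z, 2, colMeans(Z), "-")
  Zt <- crossprod(U, Zc)
  yt <- as.numeric(crossprod(U, y))
  Xt <- crossprod(U, Xf)
  # Wald test with per-SNP residual rescaling of the null-model V: the
  # statistic is exactly the OLS t-test when V is proportional to the
  # identity (sigma_u2 = 0), and EMMAX-style otherwise.
  scan_one_weights <- function(su, se) {
    w <- 1 / (su * d + se)
    XtW <- Xt * w
    C <- solve(crossprod(Xt, XtW))
    My <- w * yt - XtW %*% (C %*% crossprod(XtW, yt))
    MZ <- Zt * w - XtW %*% (C %*% crossprod(XtW, Zt))
    gMg <- colSums(Zt * MZ)
    gMy <- as.numeric(crossprod(Zt, My))
    list(gMg = gMg, gMy = gMy, yMy = sum(yt * My))
  }
  df <- n - ncol(Xf) - 1
  wald <- function(sw) {
    gMg <- sw$gMg; gMy <- sw$gMy
    beta <- ifelse(gMg > 0, gMy / gMg, NA_real_)
    scale <- pmax((sw$yMy - beta^2 * gMg) / df, 1e-300)
    se <- ifelse(gMg > 0, sqrt(scale / gMg), NA_real_)
    list(beta = beta, se = se)
  }
  if (!exact_reml) {
    sw <- scan_one_weights(null_fit$sigma_u2, null_fit$sigma_e2)
    res <- wald(sw)
    beta <- res$beta; se <- res$se
  } else {
    m <- ncol(Zt)
    beta <- se <- rep(NA_real_, m)
    for (j in seq_len(m)) {
      fit_j <- greml(y, cbind(Xf, Z[, j]), eig)
      sw <- scan_one_weights(fit_j$sigma_u2, fit_j$sigma_e2)
      res <- wald(sw)
      beta[j] <- res$beta[j]; se[j] <- res$se[j]
    }
  }
  z <- beta / se
  p <- 2 * pt(-abs(z), df = df)
  p[!is.finite(p)] <- NA_real_
  list(beta = beta, se = se, p = p)
}

#' Multi-trait association scan
#'
#' Runs [mlm_assoc()] for every trait, sharing one GRM eigendecomposition
#' across traits with complete phenotypes.
#'
#' @param geno A `genotypes` object (post-QC).
#' @param traits A `trait_table`.
#' @param trait_cols Traits to scan (default: all 25 panel traits present).
#' @param covariates Covariate columns used as fixed effects.
#' @param G Optional precomputed `grm`/matrix.
#' @return Object of class `assoc_scan`: list with matrices `beta`, `se`,
#'   `p`, `q` (SNPs x traits), `map`, `traits` (names), `h2` (per-trait
#'   null-model heritability and SE).
#' @export
gwas_scan <- function(geno, traits,
                      trait_cols = NULL,
                      covariates = c("farm", "season_year", "age"),
                      G = NULL) {
  stopifnot(inherits(geno, "genotypes"), is.data.frame(traits))
  if (is.null(trait_cols))
    trait_cols <- intersect(trait_names(), names(traits))
  samp <- rownames(geno$geno)
  tt <- traits[match(samp, traits$sample_id), , drop = FALSE]
  covariates <- intersect(covariates, names(tt))
  use_cov <- covariates[vapply(covariates, function(cv)
    nlevels(droplevels(factor(tt[[cv]]))) >= 2, logical(1))]
  Xf <- if (length(use_cov)) {
    model.matrix(as.formula(paste("~", paste(use_cov, collapse = "+"))),
                 droplevels(tt))
  } else matrix(1, nrow(tt), 1)
  if (is.null(G)) G <- compute_grm(geno)
  M <- if (inherits(G, "grm")) G$grm else as.matrix(G)
  eig_full <- grm_eigen(M)
  m <- ncol(geno$geno)
  B <- SE <- P <- Q <- matrix(NA_real_, m, length(trait_cols),
                              dimnames = list(geno$map$snp_id, trait_cols))
  h2 <- data.frame(trait = trait_cols, h2 = NA_real_, se = NA_real_)
  for (k in seq_along(trait_cols)) {
    y <- tt[[trait_cols[k]]]
    if (all(is.na(y))) next
    eig_k <- if (any(is.na(y))) NULL else eig_full
    res <- mlm_assoc(geno, y, Xf, G = M, eig = eig_k,
                     trait = trait_cols[k])
    B[, k] <- res$beta; SE[, k] <- res$se; P[, k] <- res$p
    Q[, k] <- res$q
    nf <- attr(res, "null_fit")
    h2$h2[k] <- nf$h2; h2$se[k] <- nf$se_h2
  }
  structure(list(beta = B, se = SE, p = P, q = Q, map = geno$map,
                 traits = trait_cols, h2 = h2),
            class = "assoc_scan")
}

#' @export
print.assoc_scan <- function(x, ...) {
  cat(sprintf("Association scan: %d SNPs x %d traits\n",
              nrow(x$p), length(x$traits)))
  nh <- colSums(x$q <= 0.05, na.rm = TRUE)
  cat(sprintf("  traits with FDR<=0.05 hits: %d (total hits %d)\n",
              sum(nh > 0), sum(nh)))
  invisible(x)
}

#' Significant hits of an association scan
#'
#' @param scan An `assoc_scan`.
#' @param fdr_max FDR threshold (default 0.05).
#' @return data.frame: snp_id, chrom, bp, trait, beta, se, p, q.
#' @export
scan_hits <- function(scan, fdr_max = 0.05) {
  stopifnot(inherits(scan, "assoc_scan"))
  idx <- which(scan$q <= fdr_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(snp_id = character(0), chrom = character(0),
                      bp = integer(0), trait = character(0),
                      beta = numeric(0), se = numeric(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  out <- data.frame(
    snp_id = rownames(scan$p)[idx[, 1]],
    chrom = scan$map$chrom[idx[, 1]], bp = scan$map$bp[idx[, 1]],
    trait = scan$traits[idx[, 2]],
    beta = scan$beta[idx], se = scan$se[idx], p = scan$p[idx],
    q = scan$q[idx], stringsAsFactors = FALSE
  )
  out[order(out$trait, out$chrom, out$bp), , drop = FALSE]
}

#' Cluster significant SNPs into QTL intervals
#'
#' Per trait and chromosome, positions sorted ascending are chained into an
#' interval while the gap to the previous SNP is shorter than `gap_bp`; a
#' gap of `gap_bp` or more starts a new interval. Single-SNP intervals are
#' kept in the output but flagged `singleton` (they are excluded from
#' candidate lists downstream). SNPs on non-numeric (unplaced) chromosome
#' labels are excluded from clustering.
#'
#' @param hits data.frame from [scan_hits()].
#' @param gap_bp Gap threshold in bp (default 5 Mbp).
#' @return data.frame: trait, chrom, start_bp, end_bp, n_snps, snp_ids
#'   (comma-joined, position-sorted), lead_snp, lead_p, singleton.
#' @export
cluster_intervals <- function(hits, gap_bp = 5e6) {
  if (nrow(hits) == 0)
    return(data.frame(trait = character(0), chrom = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), snp_ids = character(0),
                      lead_snp = character(0), lead_p = numeric(0),
                      singleton = logical(0), stringsAsFactors = FALSE))
  hits <- hits[grepl("^[0-9]+$", hits$chrom), , drop = FALSE]
  out <- list()
  for (tr in unique(hits$trait)) {
    for (cc in unique(hits$chrom[hits$trait == tr])) {
      h <- hits[hits$trait == tr & hits$chrom == cc, , drop = FALSE]
      h <- h[order(h$bp), , drop = FALSE]
      grp <- cumsum(c(1, diff(h$bp) >= gap_bp))
      for (g in unique(grp)) {
        hh <- h[grp == g, , drop = FALSE]
        lead <- which.min(hh$p)
        out[[length(out) + 1L]] <- data.frame(
          trait = tr, chrom = cc, start_bp = min(hh$bp),
          end_bp = max(hh$bp), n_snps = nrow(hh),
          snp_ids = paste(hh$snp_id, collapse = ","),
          lead_snp = hh$snp_id[lead], lead_p = hh$p[lead],
          singleton = nrow(hh) == 1L, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}
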