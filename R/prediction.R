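# Phenotype-prediction layer: candidate gene pool, all-subsets R^2,
# common-gene selection, stepwise per-trait RNA models, and the SNP-panel
# GREML variance-explained estimator.

#' Candidate gene pool for the RNA model
#'
#' Applies the automatic filters: (i) the gene correlates with at least
#' `min_traits` phenotypes, (ii) the picked genes share no edge in the
#' final network (greedy, in ranking order), (iii) every RNA sample has
#' abundance strictly greater than 0 FPKM. Relevance ranking (the manual,
#' literature-driven criterion) is supplied as `manual_list`; genes listed
#' there are considered first, the rest are ranked by number of correlated
#' traits (descending), ties lexicographic.
#'
#' @param final_net The final `spermnet_network`.
#' @param trait_corr `trait_correlations`.
#' @param abundances Raw-scale mRNA `abundance_matrix`.
#' @param manual_list Optional character vector of prioritized gene ids.
#' @param max_genes Pool cap (default 20).
#' @param min_traits Minimum correlated phenotypes (default 4).
#' @return Character vector of gene ids (length >= 2, <= `max_genes`).
#' @export
candidate_gene_pool <- function(final_net, trait_corr, abundances,
                                manual_list = NULL, max_genes = 20,
                                min_traits = 4) {
  stopifnot(inherits(final_net, "spermnet_network"),
            inherits(abundances, "abundance_matrix"))
  sig <- trait_corr[trait_corr$significant, , drop = FALSE]
  cnt <- table(sig$feature)
  elig <- names(cnt)[cnt >= min_traits]
  elig <- intersect(elig, final_net$nodes$id[final_net$nodes$type ==
                                               "gene"])
  elig <- intersect(elig, rownames(abundances))
  pos <- rownames(abundances)[apply(unclass(abundances) > 0, 1, all)]
  elig <- intersect(elig, pos)
  if (length(elig) < 2) stop("fewer than 2 eligible genes for the pool")
  rank_order <- c(
    intersect(manual_list, elig),
    setdiff(elig[order(-as.integer(cnt[elig]), elig)], manual_list)
  )
  adj <- final_net$edges
  picked <- character(0)
  for (g in rank_order) {
    touches <- any(c(adj$b[adj$a == g], adj$a[adj$b == g]) %in% picked)
    if (touches) next
    picked <- c(picked, g)
    if (length(picked) >= max_genes) break
  }
  picked
}

#' All-subsets regression R^2
#'
#' Ordinary least-squares R^2 of every nonempty subset of the pool genes
#' (unadjusted raw abundances as predictors) against one trait. Refuses
#' pools larger than 20 predictors (2^p - 1 fits).
#'
#' @param abundances Raw-scale mRNA `abundance_matrix`.
#' @param pool Character vector of gene ids (columns of the design).
#' @param traits `trait_table` (raw phenotypes).
#' @param trait Trait name.
#' @return data.frame: subset (comma-joined gene ids, lexicographic
#'   within), size, r2; attribute `n` (samples used).
#' @export
all_subsets_r2 <- function(abundances, pool, traits, trait) {
  p <- length(pool)
  if (p > 20) stop("pool larger than 20 genes: refusing 2^p fits")
  if (p < 1) stop("empty pool")
  samp <- intersect(colnames(abundances), traits$sample_id)
  X <- t(unclass(abundances)[pool, samp, drop = FALSE])
  y <- traits[[trait]][match(samp, traits$sample_id)]
  ok <- is.finite(y) & rowSums(!is.finite(X)) == 0
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X), "-")
  XtX <- crossprod(Xc); Xty <- crossprod(Xc, yc)
  tss <- sum(yc^2)
  subs <- unlist(lapply(seq_len(p), function(k)
    combn(p, k, simplify = FALSE)), recursive = FALSE)
  r2 <- vapply(subs, function(s) {
    b <- tryCatch(solve(XtX[s, s, drop = FALSE],
                        Xty[s, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(b)) return(NA_real_)
    as.numeric(crossprod(Xty[s, ], b)) / tss
  }, numeric(1))
  out <- data.frame(
    subset = vapply(subs, function(s) paste(sort(pool[s]),
                                            collapse = ","),
                    character(1)),
    size = vapply(subs, length, integer(1)),
    r2 = pmin(1, pmax(0, r2)), stringsAsFactors = FALSE
  )
  attr(out, "n") <- n
  out
}

#' Select the genes most common across traits' best subsets
#'
#' For each trait, the best-R^2 subset of every model size is taken (ties:
#' lexicographically smallest subset string); gene occurrences across all
#' traits' best models are tallied and the `k` most frequent genes are
#' returned (ties lexicographic).
#'
#' @param subset_tables Named list (per trait) of [all_subsets_r2()]
#'   tables.
#' @param k Number of genes (default 10).
#' @return Character vector of gene ids; attribute `tally` (named counts).
#' @export
select_common_genes <- function(subset_tables, k = 10) {
  tally <- integer(0)
  for (tab in subset_tables) {
    for (sz in sort(unique(tab$size))) {
      sub <- tab[tab$size == sz & is.finite(tab$r2), , drop = FALSE]
      if (!nrow(sub)) next
      best <- sub[sub$r2 == max(sub$r2), , drop = FALSE]
      pick <- sort(best$subset)[1]
      for (g in strsplit(pick, ",")[[1]])
        tally[g] <- if (g %in% names(tally)) tally[[g]] + 1L else 1L
    }
  }
  ord <- order(-unlist(tally), names(tally))
  genes <- names(tally)[ord]
  if (k > length(genes)) {
    warning("k larger than the pool; returning all ", length(genes),
            " genes")
    k <- length(genes)
  }
  out <- genes[seq_len(k)]
  attr(out, "tally") <- tally[ord]
  out
}

#' Stepwise RNA regression model for one trait
#'
#' Forward-backward stepwise ordinary least squares on the selected genes'
#' unadjusted abundances, with entry/stay F-test P-value thresholds
#' (defaults 0.15/0.15). If no predictor enters, the intercept-only model
#' (R^2 = 0) is returned.
#'
#' @param abundances Raw-scale mRNA `abundance_matrix`.
#' @param genes Candidate predictors (<= 10 by construction upstream).
#' @param traits `trait_table`.
#' @param trait Trait name.
#' @param p_enter,p_stay Entry/stay thresholds (default 0.15).
#' @return Object of class `rna_model`: trait, selected (genes),
#'   coefficients (incl. intercept), r2, p_value (overall F), n.
#' @export
stepwise_fit <- function(abundances, genes, traits, trait,
                         p_enter = 0.15, p_stay = 0.15) {
  samp <- intersect(colnames(abundances), traits$sample_id)
  X <- t(unclass(abundances)[genes, samp, drop = FALSE])
  y <- traits[[trait]][match(samp, traits$sample_id)]
  ok <- is.finite(y) & rowSums(!is.finite(X)) == 0
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  current <- character(0)
  repeat {
    changed <- FALSE
    # forward step: best entry P-value
    cand <- setdiff(genes, current)
    if (length(cand)) {
      pvals <- vapply(cand, function(g) {
        .partial_f_p(X, y, current, g)
      }, numeric(1))
      if (any(is.finite(pvals)) && min(pvals, na.rm = TRUE) <= p_enter) {
        current <- c(current, cand[which.min(pvals)])
        changed <- TRUE
      }
    }
    # backward step: drop worst stayer
    if (length(current) > 0) {
      pstay <- vapply(current, function(g) {
        .partial_f_p(X, y, setdiff(current, g), g)
      }, numeric(1))
      worst <- which.max(pstay)
      if (is.finite(pstay[worst]) && pstay[worst] > p_stay) {
        current <- current[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(current)) {
    fit <- lm(y ~ ., data = data.frame(y = y, X[, current,
                                                drop = FALSE]))
    sm <- summary(fit)
    r2 <- sm$r.squared
    fs <- sm$fstatistic
    pv <- pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
    cf <- coef(fit)
  } else {
    r2 <- 0; pv <- 1; cf <- c(`(Intercept)` = mean(y))
  }
  structure(list(trait = trait, selected = current,
                 coefficients = cf, r2 = unname(r2),
                 p_value = unname(pv), n = n),
            class = "rna_model")
}

# P-value of the partial F test for adding `g` on top of `base`.
.partial_f_p <- function(X, y, base, g) {
  d0 <- if (length(base))
    data.frame(y = y, X[, base, drop = FALSE]) else data.frame(y = y)
  d1 <- data.frame(y = y, X[, c(base, g), drop = FALSE])
  f0 <- lm(y ~ ., data = d0)
  f1 <- lm(y ~ ., data = d1)
  a <- anova(f0, f1)
  p <- a$`Pr(>F)`[2]
  if (is.null(p) || !is.finite(p)) NA_real_ else p
}

#' @export
print.rna_model <- function(x, ...) {
  cat(sprintf("RNA model for %s: R2 = %.3f (P = %.3g), %d gene(s)\n",
              x$trait, x$r2, x$p_value, length(x$selected)))
  if (length(x$selected))
    cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.rna_model <- function(object, abundances, ...) {
  cf <- object$coefficients
  if (!length(object$selected))
    return(rep(unname(cf[1]), ncol(abundances)))
  X <- t(unclass(abundances)[object$selected, , drop = FALSE])
  as.numeric(cf[1] + X %*% cf[-1])
}

#' Assemble the SNP prediction panel
#'
#' De-duplicated union of: the lead SNPs of the GWAS QTL intervals, the
#' lead SNPs of the (double-filtered) eGWAS hits, and, for every gene that
#' is in the shared network and correlates with at least `min_traits`
#' phenotypes, that gene's most significant GWAS SNP (minimum P over all
#' traits among SNPs nearest to the gene). Only autosomal SNPs enter;
#' source tags are retained (a SNP qualifying through several routes
#' carries all its tags).
#'
#' @param intervals Output of [cluster_intervals()].
#' @param egwas_records Filtered `eqtl_records` (may be empty).
#' @param shared_net The shared network.
#' @param trait_corr `trait_correlations`.
#' @param scan The `assoc_scan` (for per-gene minimum-P SNP lookup).
#' @param annotation Gene annotation (gene_id, chrom, start, end).
#' @param min_traits Phenotype-correlation requirement (default 4).
#' @param max_gene_dist SNP-to-gene assignment window for the network-gene
#'   route (default 1 Mbp).
#' @return data.frame of class `snp_panel`: snp_id, chrom, bp, sources
#'   (comma-joined tags).
#' @export
build_snp_panel <- function(intervals, egwas_records, shared_net,
                            trait_corr, scan, annotation,
                            min_traits = 4, max_gene_dist = 1e6) {
  stopifnot(inherits(scan, "assoc_scan"))
  tags <- list()
  add <- function(tags, snp, tag) {
    tags[[snp]] <- union(tags[[snp]], tag); tags
  }
  if (!is.null(intervals) && nrow(intervals))
    for (s in unique(intervals$lead_snp)) tags <- add(tags, s,
                                                      "gwas_lead")
  if (!is.null(egwas_records) && nrow(egwas_records)) {
    eg <- egwas_records[order(egwas_records$p), , drop = FALSE]
    for (g in unique(eg$gene_id))
      tags <- add(tags, eg$snp_id[eg$gene_id == g][1], "egwas_lead")
  }
  sig <- trait_corr[trait_corr$significant, , drop = FALSE]
  cnt <- table(sig$feature)
  qual <- names(cnt)[cnt >= min_traits]
  qual <- intersect(qual, shared_net$nodes$id)
  minp <- apply(scan$p, 1, function(z) suppressWarnings(min(z,
                                                            na.rm = TRUE)))
  for (g in qual) {
    gi <- match(g, annotation$gene_id)
    if (is.na(gi)) next
    on_chr <- which(scan$map$chrom == annotation$chrom[gi])
    if (!length(on_chr)) next
    d <- pmax(0, pmax(annotation$start[gi] - scan$map$bp[on_chr],
                      scan$map$bp[on_chr] - annotation$end[gi]))
    near <- on_chr[d <= max_gene_dist]
    if (!length(near)) next
    best <- near[which.min(minp[near])]
    tags <- add(tags, scan$map$snp_id[best], "network_gene")
  }
  if (!length(tags)) stop("empty SNP panel")
  ids <- names(tags)
  mi <- match(ids, scan$map$snp_id)
  out <- data.frame(
    snp_id = ids, chrom = scan$map$chrom[mi], bp = scan$map$bp[mi],
    sources = vapply(tags, function(x) paste(sort(x), collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE
  )
  out <- out[grepl("^[0-9]+$", out$chrom), , drop = FALSE]
  if (!nrow(out)) stop("empty SNP panel after autosome restriction")
  out <- out[order(out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_panel", "data.frame")
  out
}

#' Phenotypic variance explained by a SNP panel
#'
#' Restricts the genotypes to the panel SNPs, computes their GRM, and runs
#' [greml()] per trait (with the same fixed covariates as the GWAS). The
#' returned fraction is the panel-GRM h2 estimate with its SE.
#'
#' @param panel An `snp_panel`.
#' @param geno Post-QC `genotypes` containing the panel SNPs.
#' @param traits `trait_table`.
#' @param trait_cols Traits to evaluate (default: all panel traits
#'   present).
#' @param covariates Fixed-effect columns.
#' @return data.frame: trait, var_explained, se, converged.
#' @export
panel_variance_explained <- function(panel, geno, traits,
                                     trait_cols = NULL,
                                     covariates = c("farm",
                                                    "season_year",
                                                    "age")) {
  stopifnot(inherits(panel, "snp_panel"), inherits(geno, "genotypes"))
  idx <- match(panel$snp_id, geno$map$snp_id)
  if (any(is.na(idx))) stop("panel SNPs missing from genotypes")
  sub <- structure(list(
    geno = geno$geno[, idx, drop = FALSE],
    map = geno$map[idx, , drop = FALSE],
    freq = geno$freq[idx]
  ), class = "genotypes")
  G <- compute_grm(sub)
  samp <- rownames(geno$geno)
  tt <- traits[match(samp, traits$sample_id), , drop = FALSE]
  if (is.null(trait_cols))
    trait_cols <- intersect(trait_names(), names(tt))
  covariates <- intersect(covariates, names(tt))
  use_cov <- covariates[vapply(covariates, function(cv)
    nlevels(droplevels(factor(tt[[cv]]))) >= 2, logical(1))]
  Xf <- if (length(use_cov))
    model.matrix(as.formula(paste("~", paste(use_cov, collapse = "+"))),
                 droplevels(tt)) else matrix(1, nrow(tt), 1)
  eig <- grm_eigen(G)
  out <- lapply(trait_cols, function(tr) {
    y <- tt[[tr]]
    fit <- if (any(is.na(y))) greml(y, Xf, G) else greml(y, Xf, eig)
    data.frame(trait = tr, var_explained = fit$h2, se = fit$se_h2,
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
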