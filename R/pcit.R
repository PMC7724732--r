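# PCIT: partial-correlation-with-information-theory edge filtering, applied
# identically to SNP-effect (AWM) and RNA-abundance matrices.

#' PCIT edge filtering
#'
#' Computes all pairwise Pearson correlations over the observation columns,
#' then eliminates edges by first-order partial correlation with a
#' data-driven tolerance: for every trio (x, y, z) the three partial
#' correlations are formed, the trio tolerance `eps` is the mean of the
#' absolute ratios |partial / direct|, and edge (x, y) is eliminated when
#' `|r_xy| <= |eps * r_xz|` and `|r_xy| <= |eps * r_yz|` for some z (ties
#' eliminate). Surviving edges whose correlation t-test P-value is at or
#' below `p_max` are flagged significant. With exactly two features there
#' are no trios and all edges survive the elimination step.
#'
#' Constant features are excluded with a warning before the scan.
#'
#' @param data Numeric matrix, features x observations (at least 2
#'   features and 3 observations).
#' @param p_max Correlation significance threshold (default 0.05).
#' @return Object of class `pcit_result`: `nodes` (feature ids), `corr`
#'   (full correlation matrix), `kept` (logical matrix after elimination,
#'   diagonal FALSE), `p` (correlation P-values), `significant`
#'   (`kept & p <= p_max`), `n_obs`.
#' @export
pcit_filter <- function(data, p_max = 0.05) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("need at least 2 features")
  if (ncol(data) < 3) stop("need at least 3 observations")
  if (is.null(rownames(data)))
    rownames(data) <- sprintf("f%d", seq_len(nrow(data)))
  sds <- apply(data, 1, sd)
  if (any(sds == 0)) {
    warning("constant feature(s) excluded: ",
            paste(rownames(data)[sds == 0], collapse = ", "))
    data <- data[sds > 0, , drop = FALSE]
    if (nrow(data) < 2) stop("fewer than 2 non-constant features")
  }
  corr <- cor(t(data))
  n <- ncol(data)
  kept <- .pcit_keep_cpp(corr)
  dimnames(kept) <- dimnames(corr)
  tstat <- abs(corr) * sqrt((n - 2) / pmax(1 - corr^2,
                                           .Machine$double.eps))
  p <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  diag(p) <- 1
  sig <- kept & p <= p_max
  structure(list(nodes = rownames(corr), corr = corr, kept = kept,
                 p = p, significant = sig, n_obs = n),
            class = "pcit_result")
}

#' @export
print.pcit_result <- function(x, ...) {
  nk <- sum(x$kept[upper.tri(x$kept)])
  ns <- sum(x$significant[upper.tri(x$significant)])
  cat(sprintf("PCIT: %d features, %d observations; %d/%d edges kept, %d significant\n",
              length(x$nodes), x$n_obs, nk,
              choose(length(x$nodes), 2), ns))
  invisible(x)
}

#' Edge list of a PCIT result
#'
#' @param x A `pcit_result`.
#' @param significant_only Keep only significant edges (default TRUE).
#' @return data.frame: a, b (a < b), r, p, kept, significant.
#' @export
pcit_edges <- function(x, significant_only = TRUE) {
  stopifnot(inherits(x, "pcit_result"))
  ut <- which(upper.tri(x$corr), arr.ind = TRUE)
  out <- data.frame(
    a = x$nodes[ut[, 1]], b = x$nodes[ut[, 2]],
    r = x$corr[ut], p = x$p[ut], kept = x$kept[ut],
    significant = x$significant[ut], stringsAsFactors = FALSE
  )
  if (significant_only) out <- out[out$significant, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Significant negative miRNA-gene edges by PCIT
#'
#' Stacks the gene and miRNA log2 abundance matrices over their shared
#' samples, runs [pcit_filter()], and returns only the gene-miRNA edges
#' that are kept, significant, and negatively correlated.
#'
#' @param mirna,genes Log2-scale `abundance_matrix` objects.
#' @param p_max Significance threshold (default 0.05).
#' @return data.frame: gene, mirna, r, p.
#' @export
mirna_gene_edges <- function(mirna, genes, p_max = 0.05) {
  stopifnot(inherits(mirna, "abundance_matrix"),
            inherits(genes, "abundance_matrix"))
  samp <- intersect(colnames(genes), colnames(mirna))
  if (length(samp) < 3) stop("fewer than 3 shared samples")
  stacked <- rbind(unclass(genes)[, samp, drop = FALSE],
                   unclass(mirna)[, samp, drop = FALSE])
  res <- pcit_filter(stacked, p_max = p_max)
  ed <- pcit_edges(res, significant_only = TRUE)
  gene_ids <- rownames(genes); mir_ids <- rownames(mirna)
  cross <- (ed$a %in% gene_ids & ed$b %in% mir_ids) |
    (ed$a %in% mir_ids & ed$b %in% gene_ids)
  ed <- ed[cross & ed$r < 0, , drop = FALSE]
  data.frame(
    gene = ifelse(ed$a %in% gene_ids, ed$a, ed$b),
    mirna = ifelse(ed$a %in% mir_ids, ed$a, ed$b),
    r = ed$r, p = ed$p, stringsAsFactors = FALSE
  )
}
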