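# Abundance filtering and log2 stabilization, the external-effect
# variance-component model on long-format expression, and Pearson
# trait-abundance correlation screens.

#' Construct an abundance matrix
#'
#' @param values Numeric matrix, features x samples (FPKM for mRNA, CPM for
#'   miRNA), raw scale unless `log2` is TRUE.
#' @param kind `"mRNA"` or `"miRNA"`.
#' @param log2 Whether values are already log2-stabilized.
#' @return The matrix with class `abundance_matrix` and attributes `kind`,
#'   `log2`.
#' @export
abundance_matrix <- function(values, kind = c("mRNA", "miRNA"),
                             log2 = FALSE) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids")
  if (!log2 && any(values < 0)) stop("raw abundances must be >= 0")
  structure(values, kind = kind, log2 = log2,
            class = c("abundance_matrix", class(values)))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("%s abundance: %d features x %d samples (%s scale)\n",
              attr(x, "kind"), nrow(x), ncol(x),
              if (attr(x, "log2")) "log2" else "raw"))
  invisible(x)
}

#' Filter and log2-stabilize abundances
#'
#' mRNA features are kept iff their mean FPKM is >= `fpkm_min` (boundary
#' kept); miRNA features iff their mean CPM is strictly greater than
#' `cpm_min` (boundary dropped), or, with `strict_per_sample = TRUE`, iff
#' every sample exceeds `cpm_min`. Surviving values are stabilized as
#' `log2(x + pseudo)`.
#'
#' @param m An `abundance_matrix` (raw scale).
#' @param fpkm_min mRNA mean-abundance screen (default 10).
#' @param cpm_min miRNA abundance screen (default 1, strict).
#' @param strict_per_sample For miRNA, require every sample > `cpm_min`
#'   instead of the mean.
#' @param pseudo Pseudo-count added before log2 (default 1).
#' @return A log2-scale `abundance_matrix` of the retained features, with
#'   attribute `dropped` (ids that failed the screen).
#' @export
filter_abundances <- function(m, fpkm_min = 10, cpm_min = 1,
                              strict_per_sample = FALSE, pseudo = 1) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (isTRUE(attr(m, "log2"))) stop("abundances already log2-stabilized")
  if (attr(m, "kind") == "mRNA") {
    keep <- rowMeans(m) >= fpkm_min
  } else if (strict_per_sample) {
    keep <- apply(m > cpm_min, 1, all)
  } else {
    keep <- rowMeans(m) > cpm_min
  }
  if (!any(keep)) stop("no features survive the abundance screen")
  out <- abundance_matrix(log2(unclass(m)[keep, , drop = FALSE] + pseudo),
                          kind = attr(m, "kind"), log2 = TRUE)
  attr(out, "dropped") <- rownames(m)[!keep]
  out
}

#' Variance components of external effects on expression
#'
#' Fits, on the long-format library x gene response, the crossed
#' random-effects model `log2 abundance = mu + library + gene + gene:farm +
#' gene:year_season + gene:age + gene:run + e` (library fixed, the rest
#' random) by REML via lme4, and reports each component's share of the
#' total variance. The result is a report only: following the rationale
#' that most variance is attributable to the gene itself, abundances are
#' not corrected downstream.
#'
#' @param m A log2-scale `abundance_matrix`.
#' @param covariates data.frame with one row per sample (library) giving
#'   `farm`, `year_season`, `age`, `run` (factors); rownames or a
#'   `sample_id` column must match `colnames(m)`.
#' @return Object of class `expr_varcomp`: data.frame of variance `share`s
#'   (gene, gene:farm, gene:year_season, gene:age, gene:run, residual;
#'   shares sum to 1) plus attribute `explained` (1 - residual share).
#' @export
expr_variance_components <- function(m, covariates) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (!isTRUE(attr(m, "log2"))) stop("log2-stabilized abundances required")
  cv <- as.data.frame(covariates)
  if ("sample_id" %in% names(cv)) rownames(cv) <- cv$sample_id
  cv <- cv[colnames(m), , drop = FALSE]
  if (any(is.na(cv)))
    stop("covariates missing for some libraries")
  vals <- unclass(m)
  if (sd(vals) == 0) stop("constant expression response")
  long <- data.frame(
    y = as.numeric(vals),
    gene = factor(rep(rownames(m), times = ncol(m))),
    library = factor(rep(colnames(m), each = nrow(m)))
  )
  terms <- c("(1 | gene)")
  for (f in c("farm", "year_season", "age", "run")) {
    if (!f %in% names(cv)) next
    fac <- droplevels(factor(cv[[f]]))
    if (nlevels(fac) < 2) {
      warning("covariate '", f, "' has fewer than 2 levels; term dropped")
      next
    }
    long[[f]] <- fac[match(long$library, rownames(cv))]
    terms <- c(terms, sprintf("(1 | gene:%s)", f))
  }
  fml <- as.formula(paste("y ~ library +", paste(terms, collapse = " + ")))
  fit <- lme4::lmer(fml, data = long,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- setNames(vc$vcov, vc$grp)
  names(comp)[names(comp) == "Residual"] <- "residual"
  names(comp) <- sub("^gene:(.*)$", "gene:\\1", names(comp))
  shares <- comp / sum(comp)
  out <- data.frame(component = names(shares), variance = unname(comp),
                    share = unname(shares), stringsAsFactors = FALSE)
  stopifnot(abs(sum(out$share) - 1) < 1e-8)
  attr(out, "explained") <- 1 - out$share[out$component == "residual"]
  class(out) <- c("expr_varcomp", "data.frame")
  out
}

#' Pearson correlation screen between abundances and traits
#'
#' For every (feature, trait) pair, the Pearson correlation of the
#' log2-stabilized abundance with the covariate-adjusted trait, with the
#' two-sided t-test P-value `p = 2 P(T_{n-2} > |r| sqrt((n-2)/(1-r^2)))`.
#' Pairs with `p <= p_max` are flagged significant.
#'
#' @param m A log2-scale `abundance_matrix`.
#' @param traits An adjusted `trait_table` (see [adjust_phenotypes()]).
#' @param trait_cols Trait columns to screen (default: all panel traits
#'   present).
#' @param p_max Significance threshold (default 0.05).
#' @return data.frame of class `trait_correlations`: feature, trait, r, p,
#'   n, significant; attribute `n_traits_per_feature` (named count of
#'   significant traits per feature).
#' @export
correlate_traits <- function(m, traits, trait_cols = NULL, p_max = 0.05) {
  stopifnot(inherits(m, "abundance_matrix"), is.data.frame(traits))
  if (!isTRUE(attr(m, "log2")))
    stop("log2-stabilized abundances required")
  if (is.null(trait_cols))
    trait_cols <- intersect(trait_names(), names(traits))
  samp <- intersect(colnames(m), traits$sample_id)
  if (length(samp) < 3) stop("fewer than 3 shared samples")
  vals <- t(unclass(m)[, samp, drop = FALSE])
  T_ <- as.matrix(traits[match(samp, traits$sample_id), trait_cols,
                         drop = FALSE])
  sd_f <- apply(vals, 2, sd)
  sd_t <- apply(T_, 2, sd)
  if (any(sd_f == 0))
    warning("zero-variance feature(s) skipped: ",
            paste(colnames(vals)[sd_f == 0], collapse = ", "))
  if (any(is.na(sd_t)) || any(sd_t == 0, na.rm = TRUE))
    warning("zero-variance or missing trait(s) skipped")
  R <- suppressWarnings(cor(vals, T_, use = "pairwise.complete.obs"))
  n <- length(samp)
  tstat <- abs(R) * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  out <- data.frame(
    feature = rep(rownames(R), times = ncol(R)),
    trait = rep(colnames(R), each = nrow(R)),
    r = as.numeric(R), p = as.numeric(P), n = n,
    stringsAsFactors = FALSE
  )
  out <- out[is.finite(out$r), , drop = FALSE]
  out$significant <- out$p <= p_max
  sig <- out[out$significant, , drop = FALSE]
  cnt <- table(factor(sig$feature, levels = rownames(m)))
  attr(out, "n_traits_per_feature") <- setNames(as.integer(cnt),
                                                names(cnt))
  class(out) <- c("trait_correlations", "data.frame")
  out
}

#' Significant-trait count per feature
#'
#' @param tc A `trait_correlations` object.
#' @return Named integer vector: number of significantly correlated traits
#'   per feature (features with none included as 0).
#' @export
n_traits_correlated <- function(tc) {
  stopifnot(inherits(tc, "trait_correlations"))
  attr(tc, "n_traits_per_feature")
}
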