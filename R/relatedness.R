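# Genomic relationship matrix (Yang/VanRaden standardized-dosage form) and
# single-component GREML via average-information REML with EM safeguarding.

#' Compute the genomic relationship matrix
#'
#' `G[j,k] = (1/N) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' over the N SNPs with 0 < p < 1. Missing dosages are mean-imputed.
#'
#' @param geno A `genotypes` object or a samples x SNPs dosage matrix.
#' @return List of class `grm`: `grm` (n x n), `n_snps_used`.
#' @export
compute_grm <- function(geno) {
  X <- if (inherits(geno, "genotypes")) geno$geno else as.matrix(geno)
  n <- nrow(X)
  cm <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- cm[((idx - 1L) %/% n) + 1L]
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!all(poly))
    warning(sum(!poly), " monomorphic SNP(s) skipped in GRM")
  if (!any(poly)) stop("no polymorphic SNPs for GRM")
  Z <- sweep(X[, poly, drop = FALSE], 2, 2 * p[poly], "-")
  Z <- sweep(Z, 2, sqrt(2 * p[poly] * (1 - p[poly])), "/")
  G <- tcrossprod(Z) / sum(poly)
  dimnames(G) <- list(rownames(X), rownames(X))
  structure(list(grm = G, n_snps_used = sum(poly)), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("GRM: %d samples, %d SNPs used, mean diagonal %.3f\n",
              nrow(x$grm), x$n_snps_used, mean(diag(x$grm))))
  invisible(x)
}

#' Precompute the eigendecomposition of a GRM
#'
#' GREML and the mixed-model association scan both work in the eigenbasis
#' of G; when many traits share one GRM the decomposition can be done once
#' and passed to [greml()] / [gwas_scan()].
#'
#' @param G A `grm` object or plain symmetric matrix.
#' @return List of class `grm_eigen` with `values`, `vectors`.
#' @export
grm_eigen <- function(G) {
  M <- if (inherits(G, "grm")) G$grm else as.matrix(G)
  ee <- eigen(M, symmetric = TRUE)
  neg <- ee$values < -1e-8 * max(abs(ee$values))
  if (any(neg))
    warning("GRM not PSD; ", sum(neg), " negative eigenvalue(s) clipped")
  ee$values <- pmax(ee$values, 0)
  structure(list(values = ee$values, vectors = ee$vectors,
                 ids = rownames(M)), class = "grm_eigen")
}

#' GREML: REML estimation of the genomic variance fraction
#'
#' Fits `y = X b + u + e` with `u ~ N(0, G sigma_u^2)`,
#' `e ~ N(0, I sigma_e^2)` by average-information REML. Iterations use the
#' AI update with an EM step as fallback whenever the AI step leaves the
#' parameter space or decreases the restricted likelihood. Variance
#' components are floored at `1e-8 * var(y)`; convergence is declared when
#' the relative change in restricted log-likelihood drops below `tol`.
#' Standard errors come from the inverse AI matrix at the optimum, with the
#' delta method for `h2 = sigma_u^2 / (sigma_u^2 + sigma_e^2)`.
#'
#' @param y Numeric response (samples with NA dropped listwise together
#'   with their rows of X/G).
#' @param X Fixed-effect design matrix (default intercept only).
#' @param G A `grm`, plain matrix, or a precomputed [grm_eigen()].
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum AI/EM iterations.
#' @return Object of class `greml_fit`: `sigma_u2`, `sigma_e2`, `h2`,
#'   `se_h2`, `se_sigma` (2-vector), `loglik`, `converged`, `n_iter`.
#' @export
greml <- function(y, X = NULL, G, tol = 1e-8, max_iter = 100L) {
  keep <- !is.na(y)
  if (inherits(G, "grm_eigen")) {
    if (!all(keep)) stop("precomputed eigen requires complete y")
    ee <- G
  } else {
    M <- if (inherits(G, "grm")) G$grm else as.matrix(G)
    y <- y[keep]
    if (!is.null(X)) X <- X[keep, , drop = FALSE]
    ee <- grm_eigen(M[keep, keep, drop = FALSE])
  }
  n <- length(ee$values)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design X is rank deficient")
  stopifnot(length(y) == n, nrow(X) == n)

  U <- ee$vectors; d <- ee$values
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  vy <- var(y)
  floor_v <- 1e-8 * vy
  th <- c(u = vy / 2, e = vy / 2)

  reml_parts <- function(th) {
    V <- th[1] * d + th[2]
    w <- 1 / V
    XtW <- Xt * w
    XtWX <- crossprod(Xt, XtW)
    C <- solve(XtWX)
    XtWy <- crossprod(XtW, yt)
    Py <- w * yt - (XtW %*% (C %*% XtWy))
    Py <- as.numeric(Py)
    ll <- -0.5 * (sum(log(V)) + determinant(XtWX)$modulus[1] +
                    sum(yt * Py))
    list(w = w, C = C, XtW = XtW, Py = Py, ll = ll)
  }
  tr_PV <- function(parts, dv) {
    # tr(P diag(dv)) = sum(w*dv) - tr(C Xt' W diag(dv) W Xt)
    sum(parts$w * dv) -
      sum(parts$C * crossprod(parts$XtW, parts$XtW * dv))
  }
  P_times <- function(parts, v) {
    as.numeric(parts$w * v -
                 parts$XtW %*% (parts$C %*% crossprod(parts$XtW, v)))
  }

  parts <- reml_parts(th)
  ll <- parts$ll
  converged <- FALSE
  AI <- diag(2)
  for (it in seq_len(max_iter)) {
    Py <- parts$Py
    GPy <- d * Py
    PGPy <- P_times(parts, GPy)
    PPy <- P_times(parts, Py)
    score <- c(
      -0.5 * (tr_PV(parts, d) - sum(Py * GPy)),
      -0.5 * (tr_PV(parts, rep(1, n)) - sum(Py * Py))
    )
    AI <- 0.5 * matrix(c(
      sum(GPy * PGPy), sum(GPy * PPy),
      sum(GPy * PPy), sum(Py * PPy)
    ), 2, 2)
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    # AI step, projected to the boundary when it leaves the space
    th_new <- if (!is.null(step)) pmax(th + step, floor_v) else NULL
    use_em <- is.null(th_new) || any(!is.finite(th_new))
    if (!use_em) {
      parts_new <- reml_parts(th_new)
      if (!is.finite(parts_new$ll) || parts_new$ll < ll - 1e-6)
        use_em <- TRUE
    }
    if (use_em) {
      th_new <- c(
        th[1] + th[1]^2 * (sum(Py * GPy) - tr_PV(parts, d)) / n,
        th[2] + th[2]^2 * (sum(Py * Py) - tr_PV(parts, rep(1, n))) / n
      )
      th_new <- pmax(th_new, floor_v)
      parts_new <- reml_parts(th_new)
    }
    ll_new <- parts_new$ll
    done <- abs(ll_new - ll) < tol * (abs(ll) + 1) ||
      max(abs(th_new - th) / (th + floor_v)) < 1e-8
    th <- th_new; parts <- parts_new; ll <- ll_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GREML did not converge in ", max_iter, " iterations")

  Vc <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  s <- sum(th)
  grad <- c(th[2], -th[1]) / s^2
  se_h2 <- sqrt(max(0, as.numeric(t(grad) %*% Vc %*% grad)))
  structure(list(
    sigma_u2 = unname(th[1]), sigma_e2 = unname(th[2]),
    h2 = unname(th[1] / s), se_h2 = se_h2,
    se_sigma = sqrt(pmax(0, diag(Vc))), loglik = ll,
    converged = converged, n_iter = it
  ), class = "greml_fit")
}

#' @export
print.greml_fit <- function(x, ...) {
  cat(sprintf("GREML fit: h2 = %.4f (SE %.4f)\n", x$h2, x$se_h2))
  cat(sprintf("  sigma_u2 = %.4g, sigma_e2 = %.4g, logLik = %.3f\n",
              x$sigma_u2, x$sigma_e2, x$loglik))
  cat(sprintf("  %s in %d iterations\n",
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' @export
summary.greml_fit <- function(object, ...) {
  out <- data.frame(
    component = c("sigma_u2", "sigma_e2", "h2"),
    estimate = c(object$sigma_u2, object$sigma_e2, object$h2),
    se = c(object$se_sigma, object$se_h2)
  )
  attr(out, "loglik") <- object$loglik
  out
}
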