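# Eigen-rotated single-component REML (EMMA-style).
#
# Model: y = X b + g + e, g ~ N(0, K sg2), e ~ N(0, I se2).
# With K = U diag(lambda) U', rotating by U' gives independent
# observations with variances sg2 * lambda + se2; the REML likelihood is
# profiled over the ratio delta = se2 / sg2 and maximised by 1-D search
# on log(delta).

reml_fit <- function(y, X, K = NULL, eig = NULL) {
  n <- length(y)
  if (is.null(dim(X))) X <- matrix(X, nrow = n)
  if (is.null(eig)) {
    stopifnot(nrow(K) == n)
    eig <- eigen(K, symmetric = TRUE)
  }
  lambda <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  q <- ncol(X)

  neg_restricted_ll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (lambda + delta)           # proportional precision
    sw <- sqrt(w)
    Xw <- Xs * sw
    yw <- ys * sw
    XtX <- crossprod(Xw)
    b <- solve(XtX, crossprod(Xw, yw))
    r <- yw - Xw %*% b
    rss <- sum(r^2)
    sg2 <- rss / (n - q)
    # restricted log-likelihood up to a constant
    ll <- -0.5 * ((n - q) * log(sg2) - sum(log(w)) +
                    determinant(XtX, logarithm = TRUE)$modulus + (n - q))
    -as.numeric(ll)
  }
  opt <- optimize(neg_restricted_ll, interval = c(-12, 12), tol = 1e-10)
  delta <- exp(opt$minimum)
  w <- 1 / (lambda + delta)
  sw <- sqrt(w)
  Xw <- Xs * sw
  yw <- ys * sw
  XtX <- crossprod(Xw)
  b <- solve(XtX, crossprod(Xw, yw))
  r <- yw - Xw %*% b
  sg2 <- sum(r^2) / (n - q)
  se2 <- sg2 * delta
  # marginal residuals and BLUP of g
  fitted_fixed <- as.numeric(X %*% b)
  marg <- y - fitted_fixed
  # BLUP: g_hat = sg2 K V^{-1} (y - Xb); in rotated space
  Vinv_marg <- U %*% (w / sg2 * crossprod(U, marg))
  g_hat <- sg2 * (U %*% (lambda * crossprod(U, as.numeric(Vinv_marg))))
  list(beta = as.numeric(b), sg2 = sg2, se2 = se2, delta = delta,
       eig = eig, U = U, lambda = lambda, w = w,
       blup = as.numeric(g_hat),
       resid_marginal = marg,
       resid_conditional = marg - as.numeric(g_hat),
       loglik = -opt$objective, n = n, q = q)
}

# Build a covariate design matrix with intercept.
build_design <- function(n, covariates = NULL) {
  X <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    X <- cbind(X, covariates)
  }
  X
}

#' Genomic relationship matrix (VanRaden)
#'
#' \eqn{G = Z Z' / \sum_j 2 p_j (1 - p_j)} with Z the column-centred
#' dosage matrix; monomorphic sites are skipped. Injected singleton
#' sites, when flagged in the variant table, are excluded (the GRM is a
#' pruned-set quantity).
#'
#' @param g a \code{\link{phased_genotypes}} object.
#' @return an N x N symmetric matrix of class \code{grm} with attribute
#'   \code{"kind" = "snp"}.
#' @export
compute_grm <- function(g) {
  if (!is.null(g$variants$is_singleton))
    g <- subset_variants(g, !g$variants$is_singleton)
  dos <- hap_to_dosage(g$hap)
  p <- colMeans(dos) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("empty GRM: all sites monomorphic")
  dos <- dos[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(dos, 2L, 2 * p)
  G <- tcrossprod(Z) / sum(2 * p * (1 - p))
  dimnames(G) <- list(g$samples, g$samples)
  structure(G, class = c("grm", "matrix"), kind = "snp")
}

#' Top principal components of a relationship matrix
#'
#' Eigenvectors of the (centred) GRM with a deterministic sign
#' convention: in each PC the loading with the largest magnitude is made
#' positive.
#'
#' @param grm an N x N relationship matrix.
#' @param k number of components (default 10; must be < N).
#' @return N x k matrix of principal components (columns \code{PC1..PCk}).
#' @export
compute_pcs <- function(grm, k = 10) {
  n <- nrow(grm)
  if (k >= n) stop("invalid k: must be smaller than the number of individuals")
  if (k == 0) return(matrix(numeric(0), nrow = n, ncol = 0))
  eig <- eigen(grm, symmetric = TRUE)
  pcs <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(pcs[, j]))
    if (pcs[i, j] < 0) pcs[, j] <- -pcs[, j]
  }
  colnames(pcs) <- paste0("PC", seq_len(k))
  rownames(pcs) <- rownames(grm)
  pcs
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH q-values with the usual monotonicity enforcement.
#'
#' @param pvalues vector of p-values in (0, 1]; NAs pass through.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  p.adjust(pvalues, method = "BH")
}

#' Single-SNP mixed-linear-model association scan
#'
#' Fits the null mixed model y = Q a + g + e once by REML with the GRM
#' as the genetic covariance (EMMA eigen rotation), then tests every SNP
#' by generalized least squares with the variance components held fixed
#' — the standard one-null-fit approximation used by fastGWA/EMMAX.
#' With an identity GRM the test reduces exactly to the OLS t-test.
#'
#' @param y numeric trait vector (NAs dropped with their rows).
#' @param g a \code{\link{phased_genotypes}}; singleton-flagged sites are
#'   excluded from testing.
#' @param grm relationship matrix from \code{\link{compute_grm}}.
#' @param covariates optional numeric matrix of covariates (e.g. top PCs
#'   from \code{\link{compute_pcs}} and a batch indicator); an intercept
#'   is always added.
#' @return data.frame of class \code{assoc_result}: chrom, pos, id, af,
#'   beta, se, p, q (BH-FDR). Variance components are attached as the
#'   \code{"varcomp"} attribute.
#' @export
snp_scan <- function(y, g, grm, covariates = NULL) {
  stopifnot(inherits(g, "phased_genotypes"))
  keep <- !is.na(y)
  if (!is.null(g$variants$is_singleton)) {
    g_test <- subset_variants(g, !g$variants$is_singleton)
  } else g_test <- g
  y <- y[keep]
  if (length(unique(y)) < 2) stop("degenerate trait: y is constant")
  dos <- hap_to_dosage(g_test$hap)[keep, , drop = FALSE]
  K <- grm[keep, keep]
  X <- build_design(length(y), if (is.null(covariates)) NULL else
    as.matrix(covariates)[keep, , drop = FALSE])

  null <- reml_fit(y, X, K)
  # whiten: S = diag(1/sqrt(lambda + delta)) U'
  sw <- sqrt(null$w)
  yw <- as.numeric(crossprod(null$U, y)) * sw
  Xw <- crossprod(null$U, X) * sw
  Gw <- crossprod(null$U, dos) * sw
  # residualize on covariates under the GLS metric
  qrX <- qr(Xw)
  yr <- qr.resid(qrX, yw)
  Gr <- qr.resid(qrX, Gw)
  sxx <- colSums(Gr^2)
  ok <- sxx > 1e-12
  beta <- se <- p <- rep(NA_real_, ncol(dos))
  df <- length(y) - ncol(X) - 1L
  ssy <- sum(yr^2)
  bj <- as.numeric(crossprod(Gr[, ok, drop = FALSE], yr)) / sxx[ok]
  rss <- pmax(ssy - bj^2 * sxx[ok], 0)
  sej <- sqrt(rss / df / sxx[ok])
  tj <- bj / sej
  beta[ok] <- bj
  se[ok] <- sej
  p[ok] <- 2 * pt(-abs(tj), df)
  out <- data.frame(chrom = g_test$variants$chrom, pos = g_test$variants$pos,
                    id = g_test$variants$id, af = g_test$af,
                    beta = beta, se = se, p = p, q = bh_fdr(p),
                    stringsAsFactors = FALSE)
  attr(out, "varcomp") <- c(sg2 = null$sg2, se2 = null$se2)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' @export
#' @method print assoc_result
print.assoc_result <- function(x, ...) {
  cat("Association scan:", nrow(x), "tests;",
      sum(x$q <= 0.05, na.rm = TRUE), "significant at FDR 0.05\n")
  top <- x[order(x$p), ][seq_len(min(5L, nrow(x))), ]
  print.data.frame(top, row.names = FALSE, digits = 4)
  invisible(x)
}
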