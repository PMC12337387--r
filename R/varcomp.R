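#' Two-component EM-REML for variance explained by locus sets
#'
#' Fits y = X b + u1 + u2 + e with u_i ~ N(0, K_i s2_i): K1 the
#' relationship matrix built from the significant loci, K2 from the
#' insignificant loci. EM-REML iterates
#' \eqn{\sigma_i^2 \leftarrow \sigma_i^2 + \sigma_i^4 (y'P K_i P y -
#' tr(P K_i)) / n} until the relative change of every component is
#' below \code{tol} (components are floored at zero; if a component is
#' floored the fit is restarted once from a jittered start and the
#' higher-likelihood solution kept). The proportion of variance
#' explained by the significant loci is
#' \eqn{\sigma_1^2 / (\sigma_1^2 + \sigma_2^2 + \sigma_e^2)} and the
#' genome-wide PVE is
#' \eqn{(\sigma_1^2 + \sigma_2^2) / (\sigma_1^2 + \sigma_2^2 +
#' \sigma_e^2)}.
#'
#' @param y trait vector (NAs dropped with their rows).
#' @param K1 GRM of significant loci (or NULL when there are none: the
#'   model falls back to a single genetic component and PVE_sig = 0).
#' @param K2 GRM of insignificant loci.
#' @param covariates optional covariate matrix.
#' @param tol relative-change convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 500).
#' @return object of class \code{variance_components}: \code{sigma2}
#'   (named: sig, insig, e), \code{pve_sig}, \code{pve_genomewide},
#'   \code{loglik} (REML log-likelihood trace), \code{iterations},
#'   \code{converged}.
#' @export
emreml_two_grm <- function(y, K1, K2, covariates = NULL,
                           tol = 1e-6, max_iter = 500) {
  keep <- !is.na(y)
  y <- y[keep]
  if (length(unique(y)) < 2) stop("degenerate trait: y is constant")
  n <- length(y)
  X <- build_design(n, if (is.null(covariates)) NULL else
    as.matrix(covariates)[keep, , drop = FALSE])
  # an all-zero matrix contributes nothing to the covariance: treat it
  # as an absent component (its variance is identically zero)
  drop1 <- is.null(K1) || all(K1 == 0)
  drop2 <- all(K2 == 0)
  if (drop1 && drop2) stop("both relationship matrices are zero")
  Ks <- list()
  if (!drop1) Ks <- c(Ks, list(K1[keep, keep]))
  if (!drop2) Ks <- c(Ks, list(K2[keep, keep]))
  single <- length(Ks) == 1L
  fit <- em_reml_run(y, X, Ks, start = rep(var(y) / (length(Ks) + 1),
                                           length(Ks) + 1),
                     tol = tol, max_iter = max_iter)
  if (fit$floored) {
    jit <- fit$start0 * stats::runif(length(fit$start0), 0.3, 1.7)
    fit2 <- em_reml_run(y, X, Ks, start = jit, tol = tol,
                        max_iter = max_iter)
    if (tail(fit2$loglik, 1) > tail(fit$loglik, 1)) fit <- fit2
  }
  s <- fit$sigma2
  if (single) s <- if (drop1) c(0, s) else c(s[1], 0, s[2])
  tot <- sum(s)
  out <- list(sigma2 = setNames(s, c("sig", "insig", "e")),
              pve_sig = s[1] / tot,
              pve_genomewide = (s[1] + s[2]) / tot,
              loglik = fit$loglik, iterations = fit$iterations,
              converged = fit$converged)
  class(out) <- "variance_components"
  out
}

# EM-REML core over an arbitrary list of covariance matrices (residual
# component appended implicitly with K = I).
em_reml_run <- function(y, X, Ks, start, tol, max_iter) {
  n <- length(y)
  nk <- length(Ks)
  s <- pmax(start, 1e-8)
  ll_trace <- numeric(0)
  floored <- FALSE
  converged <- FALSE
  it <- 0
  repeat {
    it <- it + 1
    V <- diag(rep(s[nk + 1], n))
    for (i in seq_len(nk)) V <- V + s[i] * Ks[[i]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) { V <- V + diag(1e-8 * mean(diag(V)), n); ch <- chol(V) }
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    P <- Vi - ViX %*% solve(XtViX, t(ViX))
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) +
                    determinant(XtViX, logarithm = TRUE)$modulus +
                    sum(y * Py))
    ll_trace <- c(ll_trace, as.numeric(ll))
    s_new <- s
    for (i in seq_len(nk)) {
      KPy <- Ks[[i]] %*% Py
      s_new[i] <- s[i] + s[i]^2 * (sum(Py * KPy) - sum(P * Ks[[i]])) / n
    }
    s_new[nk + 1] <- s[nk + 1] + s[nk + 1]^2 *
      (sum(Py^2) - sum(diag(P))) / n
    if (any(s_new < 0)) floored <- TRUE
    s_new <- pmax(s_new, 0)
    rel <- abs(s_new - s) / pmax(abs(s), 1e-12)
    s <- s_new
    if (all(rel < tol)) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged && it >= max_iter && max(abs(diff(tail(ll_trace, 2)))) > 1e-3)
    warning("EM-REML did not converge in ", max_iter,
            " iterations (last relative change ", signif(max(rel), 3), ")")
  list(sigma2 = s, loglik = ll_trace, iterations = it,
       converged = converged, floored = floored, start0 = start)
}

#' @export
#' @method print variance_components
print.variance_components <- function(x, ...) {
  cat("Two-component variance decomposition (EM-REML,",
      x$iterations, "iterations)\n")
  cat(sprintf("  sigma2_sig = %.4g, sigma2_insig = %.4g, sigma2_e = %.4g\n",
              x$sigma2["sig"], x$sigma2["insig"], x$sigma2["e"]))
  cat(sprintf("  PVE(significant loci) = %.1f%%, genome-wide PVE = %.1f%%\n",
              100 * x$pve_sig, 100 * x$pve_genomewide))
  invisible(x)
}

#' GRM from an explicit subset of variant columns
#'
#' Convenience wrapper for the two-component PVE model: VanRaden GRM
#' computed from the given variant columns only.
#'
#' @param g a \code{\link{phased_genotypes}}.
#' @param cols variant column indices.
#' @return a \code{grm} matrix.
#' @export
grm_from_loci <- function(g, cols) {
  compute_grm(subset_variants(g, cols))
}
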