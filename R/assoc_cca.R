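#' Canonical-correlation multi-trait association scan
#'
#' For each SNP the first canonical correlation between the genotype
#' dosage (a single variable) and the stage's trait matrix equals the
#' multiple correlation of regressing dosage on the traits:
#' \eqn{\rho^2 = S_{xy}' S_{yy}^{-1} S_{xy} / S_{xx}}. Significance uses
#' Bartlett's chi-square approximation
#' \eqn{\chi^2 = -(n - 1 - (q + 2)/2)\,\ln(1 - \rho^2)} on q degrees of
#' freedom (q traits), BH-FDR adjusted across SNPs. Canonical trait
#' coefficients are returned standardized to unit trait variance, with
#' the first trait's coefficient made non-negative.
#'
#' @param g a \code{\link{phased_genotypes}} (singleton-flagged sites
#'   excluded from testing).
#' @param traits numeric matrix or data.frame of the stage's traits
#'   (individuals x traits); rows with any missing value are dropped
#'   listwise.
#' @return data.frame of class \code{cca_result}: chrom, pos, id, rho,
#'   chisq, p, q; the trait-coefficient matrix (SNPs x traits) is the
#'   \code{"coefficients"} attribute and the post-deletion sample size
#'   the \code{"n_used"} attribute.
#' @export
cca_scan <- function(g, traits) {
  stopifnot(inherits(g, "phased_genotypes"))
  traits <- as.matrix(traits)
  if (ncol(traits) < 1) stop("invalid input: need at least one trait")
  if (!is.null(g$variants$is_singleton))
    g <- subset_variants(g, !g$variants$is_singleton)
  keep <- complete.cases(traits)
  Y <- traits[keep, , drop = FALSE]
  if (any(apply(Y, 2L, sd) == 0)) stop("constant trait column in CCA input")
  # linearly dependent trait columns (e.g. a variance recorded on two
  # proportional scales) make S_yy singular: keep a maximal independent set
  qy <- qr(scale(Y))
  if (qy$rank < ncol(Y)) {
    kept <- sort(qy$pivot[seq_len(qy$rank)])
    warning("dropping ", ncol(Y) - qy$rank,
            " linearly dependent trait column(s): ",
            paste(colnames(Y)[-kept], collapse = ", "))
    Y <- Y[, kept, drop = FALSE]
  }
  n <- nrow(Y)
  q <- ncol(Y)
  if (n <= q + 2) stop("too few complete rows for ", q, " traits")
  dos <- hap_to_dosage(g$hap)[keep, , drop = FALSE]
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sdY <- apply(Y, 2L, sd)
  Syy <- crossprod(Yc) / (n - 1)
  Syy_inv <- solve(Syy)
  Xc <- scale(dos, center = TRUE, scale = FALSE)
  Sxx <- colSums(Xc^2) / (n - 1)
  Sxy <- crossprod(Yc, Xc) / (n - 1)          # q x M
  A <- Syy_inv %*% Sxy                        # q x M raw coefficients
  rho2 <- colSums(Sxy * A) / Sxx
  rho2[Sxx <= 1e-12] <- NA
  rho2 <- pmin(pmax(rho2, 0), 1 - 1e-12)
  chisq <- -(n - 1 - (q + 2) / 2) * log(1 - rho2)
  p <- stats::pchisq(chisq, df = q, lower.tail = FALSE)
  p[is.na(rho2)] <- 1                          # constant genotype sentinel
  coefs <- t(A) * rep(sdY, each = ncol(dos))   # standardized to unit trait SD
  # sign convention: first trait coefficient non-negative
  flip <- !is.na(coefs[, 1L]) & coefs[, 1L] < 0
  coefs[flip, ] <- -coefs[flip, ]
  # scale so that the coefficient vector has unit norm (direction only)
  nrm <- sqrt(rowSums(coefs^2))
  coefs <- coefs / ifelse(nrm > 0, nrm, 1)
  colnames(coefs) <- colnames(Y)
  out <- data.frame(chrom = g$variants$chrom, pos = g$variants$pos,
                    id = g$variants$id,
                    rho = sqrt(ifelse(is.na(rho2), NA, rho2)),
                    chisq = chisq, p = p, q = bh_fdr(p),
                    stringsAsFactors = FALSE)
  attr(out, "coefficients") <- coefs
  attr(out, "n_used") <- n
  class(out) <- c("cca_result", "assoc_result", "data.frame")
  out
}

#' Per-trait canonical coefficients of significant SNPs
#'
#' Extracts the standardized trait-side canonical coefficients for the
#' SNPs significant at the given FDR, for cross-stage comparison of a
#' SNP's trait contributions.
#'
#' @param result a \code{cca_result} from \code{\link{cca_scan}}.
#' @param fdr significance threshold on the q-value (default 0.05).
#' @return data.frame: chrom, pos, id, q, then one signed coefficient
#'   column per trait.
#' @export
canonical_coefficients <- function(result, fdr = 0.05) {
  co <- attr(result, "coefficients")
  sig <- which(!is.na(result$q) & result$q <= fdr)
  cbind(result[sig, c("chrom", "pos", "id", "q")],
        as.data.frame(co[sig, , drop = FALSE]))
}

#' Genotype-by-stage interaction test with post-hoc contrasts
#'
#' Two-way fixed-effect linear model of a trait measured in the up- and
#' sustained-stage on stage, genotype and their interaction; the
#' interaction is assessed by an F-test. When it is significant at
#' \code{alpha}, estimated-marginal-mean contrasts of each genotype
#' against the grand mean within each stage are computed (emmeans
#' "eff" contrasts), Bonferroni-adjusted.
#'
#' @param data data.frame with columns \code{individual}, \code{stage}
#'   (factor with two levels), \code{value}.
#' @param genotype factor of genotype levels (aa/Aa/AA), one entry per
#'   row of \code{data} or one per individual.
#' @param alpha significance gate for running the post-hoc contrasts.
#' @return list of class \code{interaction_result}: \code{p_interaction},
#'   \code{anova}, \code{posthoc} (NULL unless the interaction is
#'   significant), \code{model}.
#' @export
stage_interaction_test <- function(data, genotype, alpha = 0.05) {
  stopifnot(all(c("individual", "stage", "value") %in% names(data)))
  if (length(genotype) == length(unique(data$individual)) &&
      length(genotype) != nrow(data))
    genotype <- genotype[match(data$individual, unique(data$individual))]
  d <- data.frame(stage = factor(data$stage), value = data$value,
                  genotype = factor(genotype))
  d <- d[complete.cases(d), ]
  empty <- names(which(table(d$genotype) == 0))
  d$genotype <- droplevels(d$genotype)
  tab <- table(d$genotype, d$stage)
  bad <- rownames(tab)[apply(tab == 0, 1L, any)]
  if (length(bad)) {
    warning("dropping genotype level(s) with an empty stage cell: ",
            paste(bad, collapse = ", "))
    d <- droplevels(d[!d$genotype %in% bad, ])
  }
  if (nlevels(d$stage) != 2) stop("need exactly two stages")
  if (nlevels(d$genotype) < 2) stop("need at least two genotype levels")
  fit <- lm(value ~ stage * genotype, data = d)
  an <- anova(fit)
  p_int <- an["stage:genotype", "Pr(>F)"]
  posthoc <- NULL
  if (!is.na(p_int) && p_int < alpha) {
    em <- emmeans::emmeans(fit, ~ genotype | stage)
    posthoc <- as.data.frame(emmeans::contrast(em, method = "eff",
                                               adjust = "bonferroni"))
  }
  structure(list(p_interaction = p_int, anova = an, posthoc = posthoc,
                 model = fit), class = "interaction_result")
}

#' @export
#' @method print interaction_result
print.interaction_result <- function(x, ...) {
  cat("Genotype x stage interaction: F-test p =",
      format.pval(x$p_interaction, digits = 3), "\n")
  if (!is.null(x$posthoc)) {
    cat("Post-hoc genotype-vs-grand-mean contrasts (Bonferroni):\n")
    print.data.frame(x$posthoc, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
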