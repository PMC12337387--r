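#' Build non-overlapping haplotype blocks
#'
#' Cuts each chromosome's SNPs (position order, singleton-flagged sites
#' excluded) into consecutive non-overlapping windows of
#' \code{block_size} SNPs; a trailing remainder shorter than a block is
#' dropped. Within each block the distinct haplotype sequences observed
#' across the 2N haplotypes form the allele catalogue, coded in
#' decreasing frequency order (allele 1 = most frequent).
#'
#' @param g a \code{\link{phased_genotypes}}.
#' @param block_size SNPs per block (default 5).
#' @return list of \code{haplotype_block} objects: fields \code{id},
#'   \code{chrom}, \code{cols} (variant columns), \code{start},
#'   \code{end} (bp), \code{alleles} (sequences), \code{freq},
#'   \code{hap_allele} (allele code per haplotype, 2N),
#'   \code{pair} (N x 2 unordered allele codes per individual).
#' @export
build_blocks <- function(g, block_size = 5) {
  stopifnot(inherits(g, "phased_genotypes"), block_size >= 1)
  keep_idx <- seq_len(nrow(g$variants))
  if (!is.null(g$variants$is_singleton)) {
    keep_idx <- which(!g$variants$is_singleton)
    g <- subset_variants(g, keep_idx)
  }
  n <- n_individuals(g)
  blocks <- list()
  for (ch in unique(g$variants$chrom)) {
    cols <- which(g$variants$chrom == ch)
    nb <- length(cols) %/% block_size
    if (nb == 0L) {
      warning("chromosome ", ch, " has fewer than ", block_size,
              " SNPs; no blocks built")
      next
    }
    for (b in seq_len(nb)) {
      bc <- cols[((b - 1L) * block_size + 1L):(b * block_size)]
      seqs <- apply(g$hap[, bc, drop = FALSE], 1L, paste0, collapse = "")
      tab <- sort(table(seqs), decreasing = TRUE)
      codes <- match(seqs, names(tab))
      odd <- seq(1L, 2L * n, by = 2L)
      pair <- cbind(pmin(codes[odd], codes[odd + 1L]),
                    pmax(codes[odd], codes[odd + 1L]))
      blocks[[length(blocks) + 1L]] <- structure(
        list(id = paste0(ch, "_block", b), chrom = ch, cols = keep_idx[bc],
             start = g$variants$pos[bc[1L]], end = g$variants$pos[bc[block_size]],
             positions = g$variants$pos[bc],
             ref = g$variants$ref[bc], alt = g$variants$alt[bc],
             alleles = names(tab), freq = as.numeric(tab) / (2 * n),
             hap_allele = codes, pair = pair),
        class = "haplotype_block")
    }
  }
  blocks
}

#' Haplotype-allele dosage coding
#'
#' Codes each individual by the number of copies (0/1/2) of every
#' haplotype allele in a block; rows sum to 2.
#'
#' @param block a \code{haplotype_block} from \code{\link{build_blocks}}.
#' @return N x (number of alleles) integer matrix, columns named
#'   \code{<block id>.A<code>}.
#' @export
dosage_code <- function(block) {
  n <- nrow(block$pair)
  k <- length(block$alleles)
  d <- matrix(0L, n, k)
  d[cbind(seq_len(n), block$pair[, 1L])] <- d[cbind(seq_len(n), block$pair[, 1L])] + 1L
  d[cbind(seq_len(n), block$pair[, 2L])] <- d[cbind(seq_len(n), block$pair[, 2L])] + 1L
  colnames(d) <- paste0(block$id, ".A", seq_len(k))
  d
}

#' Haplotype-based relationship matrix
#'
#' Per block i, the haplotype-level relationship matrix \eqn{\Gamma_i}
#' scores 1 when two haplotype alleles are equal and 0 otherwise; the
#' genome-wide \eqn{\Gamma} is the average over blocks, and the
#' individual-level matrix is \eqn{H = K \Gamma K' / 2} with
#' \eqn{K = I_m \otimes [1\,1]} collapsing the two haplotypes of each
#' individual. Computed blockwise as
#' \eqn{H = \sum_i D_i D_i' / (2 n)} with \eqn{D_i} the block's allele
#' dosage matrix, which is algebraically identical.
#'
#' @param blocks list of blocks from \code{\link{build_blocks}}.
#' @param keep_gamma also return the 2N x 2N haplotype-level
#'   \eqn{\Gamma} (memory-hungry; for verification on small data).
#' @return N x N matrix of class \code{grm} with attribute
#'   \code{"kind" = "haplotype"}; diagonal entries lie in [1, 2]. When
#'   \code{keep_gamma} is TRUE the \code{"gamma"} attribute holds
#'   \eqn{\Gamma}.
#' @export
hap_grm <- function(blocks, keep_gamma = FALSE) {
  stopifnot(length(blocks) >= 1)
  n <- nrow(blocks[[1L]]$pair)
  H <- matrix(0, n, n)
  for (b in blocks) {
    D <- dosage_code(b)
    H <- H + tcrossprod(D)
  }
  H <- H / (2 * length(blocks))
  if (keep_gamma) {
    G <- matrix(0, 2L * n, 2L * n)
    for (b in blocks)
      G <- G + outer(b$hap_allele, b$hap_allele, "==")
    attr(H, "gamma") <- G / length(blocks)
  }
  structure(H, class = c("grm", "matrix"), kind = "haplotype")
}

# Haplotype-combination factor for one block: unordered allele pair as a
# categorical level, levels carried by fewer than min_carriers
# individuals merged into "rare".
combination_factor <- function(block, min_carriers = 5) {
  lev <- paste0(block$pair[, 1L], "/", block$pair[, 2L])
  tab <- table(lev)
  rare <- names(tab)[tab < min_carriers]
  if (length(rare)) lev[lev %in% rare] <- "rare"
  factor(lev)
}

#' Haplotype-block association scan (two-step method)
#'
#' Step 1 fits the null mixed model y = Q a + g_h + e once by REML with
#' the haplotype relationship matrix H as the genetic covariance; step 2
#' tests each block's haplotype-combination factor (unordered allele
#' pair; levels with fewer than \code{min_carriers} carriers merged into
#' a "rare" level) by an overall F-test with the null variance
#' components held fixed, BH-FDR adjusted across blocks. The second-step
#' regressions are run on variance-whitened data (generalized least
#' squares under the null covariance) rather than on raw model
#' residuals: raw-residual regressions are miscalibrated under strong
#' relatedness, while the whitened form keeps the one-null-fit two-step
#' economy and exact type-I control.
#'
#' By default the genetic covariance for blocks on a chromosome is built
#' from the other chromosomes' blocks (leave-one-chromosome-out, LOCO),
#' the standard guard against proximal contamination: a strong causal
#' block would otherwise be absorbed into its own polygenic term and
#' shrink its own test signal. With a single chromosome (or
#' \code{loco = FALSE}) the supplied genome-wide H is used for all
#' blocks.
#'
#' @param y numeric trait vector (NAs dropped).
#' @param blocks list from \code{\link{build_blocks}}.
#' @param H haplotype relationship matrix from \code{\link{hap_grm}};
#'   may be NULL when \code{loco = TRUE} (per-chromosome matrices are
#'   built internally).
#' @param covariates optional covariate matrix.
#' @param min_carriers merge threshold for rare combination levels.
#' @param loco leave-one-chromosome-out genetic covariance (default
#'   TRUE; ignored when all blocks share one chromosome).
#' @return data.frame of class \code{assoc_result}: block, chrom, start,
#'   end, n_alleles, p, q.
#' @export
hgwas_scan <- function(y, blocks, H = NULL, covariates = NULL,
                       min_carriers = 5, loco = TRUE) {
  keep <- !is.na(y)
  yk <- y[keep]
  if (length(unique(yk)) < 2) stop("degenerate trait: y is constant")
  X <- build_design(length(yk), if (is.null(covariates)) NULL else
    as.matrix(covariates)[keep, , drop = FALSE])
  chroms <- vapply(blocks, `[[`, character(1), "chrom")
  if (length(unique(chroms)) < 2L) loco <- FALSE
  scan_set <- function(idx, K) {
    null <- reml_fit(yk, X, K[keep, keep])
    sw <- sqrt(null$w)
    yw <- as.numeric(crossprod(null$U, yk)) * sw
    Xw <- crossprod(null$U, X) * sw
    qrX <- qr(Xw)
    yr <- qr.resid(qrX, yw)
    rss0 <- sum(yr^2)
    n <- length(yk)
    pv <- vapply(blocks[idx], function(b) {
      f <- droplevels(combination_factor(b, min_carriers)[keep])
      if (nlevels(f) < 2L) return(1)
      Fm <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
      Fw <- qr.resid(qrX, crossprod(null$U, Fm) * sw)
      qrF <- qr(Fw)
      df1 <- qrF$rank
      if (df1 < 1L) return(1)
      rss1 <- sum(qr.resid(qrF, yr)^2)
      df2 <- n - qrX$rank - df1
      if (df2 < 1L) return(1)
      Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
      stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    }, numeric(1))
    list(p = pv, varcomp = c(sg2 = null$sg2, se2 = null$se2))
  }
  p <- numeric(length(blocks))
  if (loco) {
    vc <- NULL
    for (ch in unique(chroms)) {
      idx <- which(chroms == ch)
      K <- hap_grm(blocks[chroms != ch])
      res <- scan_set(idx, K)
      p[idx] <- res$p
      if (is.null(vc)) vc <- res$varcomp
    }
  } else {
    if (is.null(H)) H <- hap_grm(blocks)
    res <- scan_set(seq_along(blocks), H)
    p <- res$p
    vc <- res$varcomp
  }
  out <- data.frame(block = vapply(blocks, `[[`, character(1), "id"),
                    chrom = vapply(blocks, `[[`, character(1), "chrom"),
                    start = vapply(blocks, `[[`, numeric(1), "start"),
                    end = vapply(blocks, `[[`, numeric(1), "end"),
                    n_alleles = vapply(blocks, function(b) length(b$alleles),
                                       numeric(1)),
                    p = p, q = bh_fdr(p), stringsAsFactors = FALSE)
  attr(out, "varcomp") <- vc
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Estimate haplotype-allele effects and classify BHA/UHA
#'
#' Fixed-effect least squares of the trait on the allele dosages of the
#' significant blocks (jointly by default, or one block at a time),
#' dropping the most frequent allele of each block as the reference for
#' identifiability. Alleles with p < \code{alpha} are classified as
#' beneficial (BHA) when the effect points in the trait's desirable
#' direction and unbeneficial (UHA) when it points against it; the rest
#' are neutral.
#'
#' @param y numeric trait vector.
#' @param blocks list of significant blocks.
#' @param covariates optional covariate matrix.
#' @param joint fit all blocks in one model (TRUE) or per block (FALSE).
#' @param alpha significance level for classification (default 0.05).
#' @param direction +1 if a larger trait value is desirable, -1
#'   otherwise (see \code{\link{trait_directions}}).
#' @return data.frame of class \code{haplotype_effects}: block, allele
#'   code, sequence, frequency, effect, se, p, class.
#' @export
estimate_allele_effects <- function(y, blocks, covariates = NULL,
                                    joint = TRUE, alpha = 0.05,
                                    direction = 1) {
  if (length(blocks) == 0L)
    return(structure(data.frame(block = character(0), allele = integer(0),
                                sequence = character(0), freq = numeric(0),
                                effect = numeric(0), se = numeric(0),
                                p = numeric(0), class = character(0)),
                     class = c("haplotype_effects", "data.frame")))
  keep <- !is.na(y)
  make_cols <- function(b) {
    d <- dosage_code(b)[keep, , drop = FALSE]
    d[, -1L, drop = FALSE]  # drop the most frequent allele (reference)
  }
  meta <- do.call(rbind, lapply(blocks, function(b) {
    k <- length(b$alleles)
    if (k < 2L) return(NULL)
    data.frame(block = b$id, allele = 2:k, sequence = b$alleles[-1L],
               freq = b$freq[-1L], stringsAsFactors = FALSE)
  }))
  if (is.null(meta))
    stop("no block has more than one haplotype allele")
  fit_one <- function(D) {
    X <- build_design(sum(keep), if (is.null(covariates)) NULL else
      as.matrix(covariates)[keep, , drop = FALSE])
    fit <- lm(y[keep] ~ 0 + X + D)
    sm <- coef(summary(fit))
    idx <- paste0("D", colnames(D))
    rn <- rownames(sm)
    res <- matrix(NA_real_, ncol(D), 3,
                  dimnames = list(colnames(D), c("effect", "se", "p")))
    hit <- match(idx, rn)
    found <- !is.na(hit)
    if (any(!found))
      warning("collinear dosage column(s) dropped: ",
              paste(colnames(D)[!found], collapse = ", "))
    res[found, ] <- sm[hit[found], c(1L, 2L, 4L)]
    res
  }
  if (joint) {
    D <- do.call(cbind, lapply(blocks, make_cols))
    est <- fit_one(D)
  } else {
    est <- do.call(rbind, lapply(blocks, function(b) fit_one(make_cols(b))))
  }
  key <- do.call(rbind, lapply(blocks, function(b) {
    k <- length(b$alleles)
    if (k < 2L) return(NULL)
    data.frame(col = paste0(b$id, ".A", 2:k))
  }))
  est <- est[match(key$col, rownames(est)), , drop = FALSE]
  cls <- rep("neutral", nrow(meta))
  sig <- !is.na(est[, "p"]) & est[, "p"] < alpha
  cls[sig & direction * est[, "effect"] > 0] <- "BHA"
  cls[sig & direction * est[, "effect"] < 0] <- "UHA"
  out <- data.frame(meta, effect = est[, "effect"], se = est[, "se"],
                    p = est[, "p"], class = cls, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("haplotype_effects", "data.frame")
  out
}

#' @export
#' @method print haplotype_effects
print.haplotype_effects <- function(x, ...) {
  cat("Haplotype-allele effects:", nrow(x), "non-reference alleles;",
      sum(x$class == "BHA"), "BHA,", sum(x$class == "UHA"), "UHA\n")
  print.data.frame(head(as.data.frame(x), 8), row.names = FALSE, digits = 3)
  invisible(x)
}
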