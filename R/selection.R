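#' Find singleton variants and their carrier haplotypes
#'
#' A singleton is a site whose alternative allele is carried by exactly
#' one of the 2N haplotypes. Run this on the full (unpruned) variant
#' set.
#'
#' @param g a \code{\link{phased_genotypes}}.
#' @return data.frame with columns \code{col} (variant column),
#'   \code{chrom}, \code{pos}, \code{hap} (carrier haplotype row index).
#' @export
find_singletons <- function(g) {
  ac <- colSums(g$hap)
  idx <- which(ac == 1L)
  hap <- vapply(idx, function(j) which(g$hap[, j] == 1L), integer(1))
  data.frame(col = idx, chrom = g$variants$chrom[idx],
             pos = g$variants$pos[idx], hap = hap)
}

# Per-haplotype singleton gap around position P on one chromosome:
# distance to the nearest carried singleton upstream plus downstream;
# a missing side is truncated to the available side, doubled; haplotypes
# with no singleton on the chromosome get NA.
singleton_gap <- function(spos_list, hap_ids, P) {
  vapply(hap_ids, function(h) {
    sp <- spos_list[[h]]
    if (is.null(sp) || length(sp) == 0L) return(NA_real_)
    i <- findInterval(P, sp)
    up <- if (i >= 1L) P - sp[i] else NA_real_
    down <- if (i < length(sp)) sp[i + 1L] - P else NA_real_
    if (is.na(up) && is.na(down)) NA_real_
    else if (is.na(up)) 2 * down
    else if (is.na(down)) 2 * up
    else up + down
  }, numeric(1))
}

#' Raw singleton-density score (gap-ratio form)
#'
#' For each test SNP, every haplotype's singleton gap is the distance
#' from the SNP to its nearest carried singleton upstream plus the
#' nearest downstream (chromosome ends truncate to the available side,
#' doubled). The raw score is
#' \eqn{rSDS = \ln(\overline{gap}_{alt}) - \ln(\overline{gap}_{ref})},
#' so a positive score means alternative-allele haplotypes carry
#' sparser singletons — the footprint of recent positive selection on
#' the alternative allele. This is a deliberately simplified gap-ratio
#' statistic: it preserves the defining singleton-density signal and the
#' frequency-bin standardization, without the full tip-branch-length
#' likelihood machinery.
#'
#' @param g a \code{\link{phased_genotypes}} (full set, singletons
#'   included).
#' @param test_snps variant column indices of the SNPs to score (default:
#'   all non-singleton polymorphic sites).
#' @param singletons optional precomputed \code{\link{find_singletons}}
#'   table.
#' @param min_carriers minimum haplotypes per allele class (default 2);
#'   SNPs failing it get NA.
#' @return data.frame of class \code{sds_result}: chrom, pos, id, af,
#'   rsds.
#' @export
raw_sds <- function(g, test_snps = NULL, singletons = NULL, min_carriers = 2) {
  if (is.null(singletons)) singletons <- find_singletons(g)
  ac <- colSums(g$hap)
  nh <- nrow(g$hap)
  if (is.null(test_snps))
    test_snps <- which(ac > 1L & ac < nh)
  rsds <- rep(NA_real_, length(test_snps))
  for (ch in unique(g$variants$chrom[test_snps])) {
    sch <- singletons[singletons$chrom == ch, , drop = FALSE]
    spos_list <- split(sch$pos, factor(sch$hap, levels = seq_len(nh)))
    spos_list <- lapply(spos_list, sort)
    on_ch <- which(g$variants$chrom[test_snps] == ch)
    for (k in on_ch) {
      j <- test_snps[k]
      P <- g$variants$pos[j]
      alt <- which(g$hap[, j] == 1L)
      ref <- which(g$hap[, j] == 0L)
      ga <- singleton_gap(spos_list, alt, P)
      gr <- singleton_gap(spos_list, ref, P)
      ga <- ga[!is.na(ga)]; gr <- gr[!is.na(gr)]
      if (length(ga) >= min_carriers && length(gr) >= min_carriers)
        rsds[k] <- log(mean(ga)) - log(mean(gr))
    }
  }
  out <- data.frame(chrom = g$variants$chrom[test_snps],
                    pos = g$variants$pos[test_snps],
                    id = g$variants$id[test_snps],
                    af = g$af[test_snps], rsds = rsds,
                    stringsAsFactors = FALSE)
  class(out) <- c("sds_result", "data.frame")
  out
}

#' Standardize raw SDS within allele-frequency bins
#'
#' SNPs with alternative-allele frequency outside [0.05, 0.95] are
#' dropped; the rest are binned at width \code{bin_width} (default
#' 0.005), bins with fewer than \code{min_bin} SNPs are merged with
#' their nearest neighbouring bin, and scores are centred and scaled to
#' unit SD within each bin.
#'
#' @param sds an \code{sds_result} from \code{\link{raw_sds}} (or any
#'   data.frame with \code{rsds} and \code{af}).
#' @param bin_width frequency bin width (default 0.005).
#' @param min_bin minimum SNPs per bin before merging (default 10).
#' @return the input restricted to scored SNPs in frequency range, with
#'   columns \code{bin} and \code{sds} (standardized score) added.
#' @export
standardize_sds <- function(sds, bin_width = 0.005, min_bin = 10) {
  keep <- !is.na(sds$rsds) & sds$af >= 0.05 & sds$af <= 0.95
  out <- sds[keep, , drop = FALSE]
  if (nrow(out) < 2) stop("undefined standardization: fewer than 2 scored SNPs")
  bin <- floor((out$af - 0.05) / bin_width)
  bin[out$af == 0.95] <- max(bin[out$af < 0.95], 0)
  # merge small bins with their nearest occupied neighbour
  repeat {
    tab <- table(bin)
    small <- names(tab)[tab < min_bin]
    if (!length(small) || length(tab) == 1L) break
    b <- as.integer(small[1L])
    others <- as.integer(setdiff(names(tab), small[1L]))
    if (!length(others)) break
    nearest <- others[which.min(abs(others - b))]
    bin[bin == b] <- nearest
  }
  z <- stats::ave(out$rsds, bin, FUN = function(x)
    if (length(x) > 1 && sd(x) > 0) (x - mean(x)) / sd(x) else x * 0)
  out$bin <- bin
  out$sds <- z
  out
}

#' Mean standardized SDS in non-overlapping windows
#'
#' Windows of \code{window} bp per chromosome; a SNP at position P falls
#' in window \code{floor(P / window)} (half-open windows reported with
#' 0-based starts, BED convention). Empty windows are omitted.
#'
#' @param scores data.frame with \code{chrom}, \code{pos}, \code{sds}.
#' @param window window size in bp (default 50 kb).
#' @return data.frame: chrom, start (0-based), end, msds, n_snps.
#' @export
msds_windows <- function(scores, window = 50000) {
  sc <- scores[!is.na(scores$sds), , drop = FALSE]
  win <- floor(sc$pos / window)
  key <- paste(sc$chrom, win)
  agg <- tapply(sc$sds, key, mean)
  cnt <- tapply(sc$sds, key, length)
  parts <- strsplit(names(agg), " ")
  out <- data.frame(chrom = vapply(parts, `[[`, character(1), 1L),
                    start = as.numeric(vapply(parts, `[[`, character(1), 2L)) * window,
                    msds = as.numeric(agg), n_snps = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out$end <- out$start + window
  out <- out[order(out$chrom, out$start), c("chrom", "start", "end", "msds", "n_snps")]
  rownames(out) <- NULL
  out
}

#' Polarize standardized SDS by a trait's GWAS effect direction
#'
#' The trait-SDS is the standardized score when the alternative allele's
#' estimated effect on the trait is positive, and its negative
#' otherwise, so a positive tSDS means the trait-increasing allele shows
#' the selection footprint. SNPs with an exactly zero effect get NA.
#'
#' @param sds standardized scores (output of
#'   \code{\link{standardize_sds}}).
#' @param assoc an \code{assoc_result} from \code{\link{snp_scan}} with
#'   matching chrom/pos.
#' @return the \code{sds} rows that matched the scan, with columns
#'   \code{beta}, \code{assoc_p} and \code{tsds} added.
#' @export
tsds_polarize <- function(sds, assoc) {
  key_s <- paste(sds$chrom, sds$pos)
  key_a <- paste(assoc$chrom, assoc$pos)
  hit <- match(key_s, key_a)
  out <- sds[!is.na(hit), , drop = FALSE]
  a <- assoc[hit[!is.na(hit)], ]
  out$beta <- a$beta
  out$assoc_p <- a$p
  out$tsds <- ifelse(is.na(a$beta) | a$beta == 0, NA_real_,
                     ifelse(a$beta > 0, out$sds, -out$sds))
  out
}

#' Spearman trend of tSDS across association-strength bins
#'
#' SNPs are ranked by -log10(GWAS p) ascending and chunked into
#' consecutive bins of \code{bin_size} SNPs (final partial bin kept);
#' the Spearman correlation between bin rank and mean tSDS is the trend
#' statistic: positive when selection favoured trait-increasing alleles.
#'
#' @param tsds vector of per-SNP trait-polarized scores.
#' @param p matching GWAS p-values.
#' @param bin_size SNPs per bin (default 1000).
#' @return list of class \code{tsds_trend}: \code{rho}, \code{p_value},
#'   \code{n_bins}, \code{bin_means}.
#' @export
tsds_trend <- function(tsds, p, bin_size = 1000) {
  ok <- !is.na(tsds) & !is.na(p)
  tsds <- tsds[ok]; p <- p[ok]
  if (length(tsds) < 2 * bin_size)
    stop("insufficient data: need at least 2 full bins of ", bin_size, " SNPs")
  o <- order(-log10(p))            # ascending -log10(p)
  tsds <- tsds[o]
  bin <- ceiling(seq_along(tsds) / bin_size)
  bm <- tapply(tsds, bin, mean)
  ct <- suppressWarnings(cor.test(seq_along(bm), as.numeric(bm),
                                  method = "spearman"))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value,
                 n_bins = length(bm), bin_means = as.numeric(bm)),
            class = "tsds_trend")
}

#' @export
#' @method print tsds_trend
print.tsds_trend <- function(x, ...) {
  cat("tSDS trend: Spearman rho =", round(x$rho, 3),
      "over", x$n_bins, "bins (p =", format.pval(x$p_value, digits = 3), ")\n")
  invisible(x)
}

# Tajima's D constants for n sequences (textbook a1, a2, b1, b2, c1, c2,
# e1, e2).
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D and nucleotide diversity
#'
#' The genome is divided into non-overlapping windows of \code{window}
#' bp. Per window, the mean pairwise difference is
#' \eqn{\hat{k} = \sum_{sites} 2\hat{p}(1-\hat{p}) \cdot 2N/(2N-1)}, the
#' per-bp diversity is \eqn{\pi = \hat{k} / window}, and Tajima's D is
#' \eqn{(\hat{k} - S/a_1)/\sqrt{e_1 S + e_2 S (S-1)}} with S segregating
#' sites and the textbook constants for 2N sequences. Windows with no
#' segregating site get D = NA and pi = 0; D needs at least 4
#' haplotypes.
#'
#' @param g a \code{\link{phased_genotypes}} (full variant set).
#' @param window window size in bp (default 100 kb).
#' @return data.frame: chrom, start (0-based), end, pi (per bp),
#'   tajima_d, n_sites.
#' @export
tajima_pi_windows <- function(g, window = 100000) {
  nh <- nrow(g$hap)
  af <- g$af
  seg <- af > 0 & af < 1
  win <- floor(g$variants$pos / window)
  lens <- if (!is.null(g$chrom_lengths)) g$chrom_lengths else
    tapply(g$variants$pos, g$variants$chrom, max)
  const <- if (nh >= 4) tajima_constants(nh) else NULL
  out <- list()
  for (ch in unique(g$variants$chrom)) {
    nwin <- ceiling(as.numeric(lens[[ch]]) / window)
    for (w in seq_len(nwin) - 1L) {
      idx <- which(g$variants$chrom == ch & win == w & seg)
      S <- length(idx)
      k_hat <- if (S > 0)
        sum(2 * af[idx] * (1 - af[idx])) * nh / (nh - 1) else 0
      D <- NA_real_
      if (S > 0 && !is.null(const)) {
        denom <- sqrt(const$e1 * S + const$e2 * S * (S - 1))
        if (denom > 0) D <- (k_hat - S / const$a1) / denom
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = w * window, end = (w + 1L) * window,
        pi = k_hat / window, tajima_d = D, n_sites = S,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
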