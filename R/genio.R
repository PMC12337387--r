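#' Phased genotype container
#'
#' Holds a set of phased, biallelic variants: a variant table with 1-based
#' coordinates (VCF dialect), and a haplotype matrix with two consecutive
#' rows per individual (rows 2i-1 and 2i are the two haplotypes of
#' individual i). Alternative-allele frequencies are the column means of
#' the haplotype matrix.
#'
#' @param samples character vector of N sample identifiers.
#' @param variants data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}, \code{id}; positions must be strictly
#'   increasing within each chromosome.
#' @param hap 2N x M matrix of 0/1 haplotype alleles, columns in genome order.
#' @param chrom_lengths optional named vector of chromosome lengths in bp,
#'   used when writing VCF contig headers.
#' @return An object of class \code{phased_genotypes} with elements
#'   \code{samples}, \code{variants}, \code{hap}, \code{af}.
#' @export
phased_genotypes <- function(samples, variants, hap, chrom_lengths = NULL) {
  samples <- as.character(samples)
  n <- length(samples)
  if (nrow(hap) != 2L * n)
    stop("hap must have two rows per sample (", 2L * n, " expected, got ",
         nrow(hap), ")")
  if (ncol(hap) != nrow(variants))
    stop("hap columns (", ncol(hap), ") must match variant rows (",
         nrow(variants), ")")
  if (!all(hap %in% c(0L, 1L)))
    stop("haplotype matrix entries must be 0 or 1")
  need <- c("chrom", "pos", "ref", "alt", "id")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants lacks columns: ", paste(miss, collapse = ", "))
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  storage.mode(hap) <- "integer"
  obj <- list(samples = samples,
              variants = as.data.frame(variants, stringsAsFactors = FALSE),
              hap = hap,
              af = colMeans(hap),
              chrom_lengths = chrom_lengths)
  class(obj) <- "phased_genotypes"
  obj
}

#' @export
#' @method print phased_genotypes
print.phased_genotypes <- function(x, ...) {
  cat("phased_genotypes:", length(x$samples), "individuals,",
      nrow(x$variants), "biallelic sites on",
      length(unique(x$variants$chrom)), "chromosome(s)\n")
  if (!is.null(attr(x, "singletons")))
    cat("  ", nrow(attr(x, "singletons")), "injected singleton sites\n")
  invisible(x)
}

#' Number of individuals in a phased genotype set
#' @param g a \code{phased_genotypes} object.
#' @return integer count of individuals.
#' @export
n_individuals <- function(g) length(g$samples)

#' Subset variants of a phased genotype set
#'
#' @param g a \code{phased_genotypes} object.
#' @param idx integer or logical index over variant columns.
#' @return a \code{phased_genotypes} with the selected variants; the
#'   singleton ground-truth attribute, if present, is re-indexed.
#' @export
subset_variants <- function(g, idx) {
  if (is.logical(idx)) idx <- which(idx)
  idx <- sort(unique(idx))                 # keep genome order
  out <- phased_genotypes(g$samples, g$variants[idx, , drop = FALSE],
                          g$hap[, idx, drop = FALSE], g$chrom_lengths)
  sg <- attr(g, "singletons")
  if (!is.null(sg)) {
    newcol <- match(sg$col, idx)
    sg <- sg[!is.na(newcol), , drop = FALSE]
    sg$col <- newcol[!is.na(newcol)]
    attr(out, "singletons") <- sg
  }
  out
}

#' Drop injected singleton sites (pruned SNP set)
#'
#' Returns the variant set with all sites whose alternative allele is
#' carried by exactly one haplotype removed; the association scans and
#' relationship matrices operate on this pruned set, while the selection
#' statistics need the full set.
#'
#' @param g a \code{phased_genotypes} object.
#' @return a \code{phased_genotypes} without singleton sites.
#' @export
drop_singletons <- function(g) {
  ac <- colSums(g$hap)
  subset_variants(g, ac != 1L)
}

#' Read a phased VCF
#'
#' Parses a VCF (4.x, plain text or gzipped) and keeps phased biallelic
#' records only. Multi-allelic, unphased or incompletely genotyped records
#' are skipped, and the skip counts are attached as the
#' \code{"skipped"} attribute.
#'
#' @param path path to a VCF file.
#' @return a \code{phased_genotypes} object.
#' @export
read_phased_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no records in VCF: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  biallelic <- !grepl(",", fix$ALT) & fix$ALT != "." & !is.na(fix$ALT)
  phased <- apply(gt, 1L, function(r)
    all(!is.na(r)) && all(grepl("^[01]\\|[01]$", r)))
  keep <- biallelic & phased
  n_multi <- sum(!biallelic)
  n_unphased <- sum(biallelic & !phased)
  if (!any(keep)) stop("no phased biallelic records in ", path)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  a1 <- matrix(as.integer(substr(t(gt), 1L, 1L)), ncol = nrow(fix))
  a2 <- matrix(as.integer(substr(t(gt), 3L, 3L)), ncol = nrow(fix))
  hap <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(fix))
  hap[seq(1L, nrow(hap), by = 2L), ] <- a1
  hap[seq(2L, nrow(hap), by = 2L), ] <- a2
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                     paste0(fix$CHROM, "_", fix$POS), fix$ID),
                         stringsAsFactors = FALSE)
  out <- phased_genotypes(samples, variants, hap)
  attr(out, "skipped") <- c(multiallelic = n_multi, unphased = n_unphased)
  if (n_multi + n_unphased > 0L)
    message("read_phased_vcf: skipped ", n_multi, " multi-allelic and ",
            n_unphased, " unphased/incomplete record(s)")
  out
}

#' Write a phased VCF 4.2
#'
#' Writes plain-text VCF with phased GT fields ("|" separator) and contig
#' header lines for every chromosome present.
#'
#' @param g a \code{phased_genotypes} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_phased_vcf <- function(g, path) {
  chroms <- unique(g$variants$chrom)
  lens <- vapply(chroms, function(ch) {
    if (!is.null(g$chrom_lengths) && ch %in% names(g$chrom_lengths))
      as.integer(g$chrom_lengths[[ch]])
    else max(g$variants$pos[g$variants$chrom == ch])
  }, integer(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=layscan",
               sprintf("##contig=<ID=%s,length=%d>", chroms, lens),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples), collapse = "\t")), con)
  if (nrow(g$variants) > 0L) {
    n <- length(g$samples)
    odd <- seq(1L, 2L * n, by = 2L)
    gt <- matrix(paste0(g$hap[odd, , drop = FALSE], "|",
                        g$hap[odd + 1L, , drop = FALSE]), nrow = n)
    lines <- paste(g$variants$chrom, g$variants$pos, g$variants$id,
                   g$variants$ref, g$variants$alt, ".", "PASS", ".", "GT",
                   apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read daily laying records from TSV
#'
#' Expects a rectangular table with a \code{sample} column followed by
#' \code{day_1 ... day_D} binary columns.
#'
#' @param path input TSV.
#' @return a \code{laying_records} object (see \code{\link{laying_records}}).
#' @export
read_laying_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (!"sample" %in% names(d)) stop("laying TSV lacks a 'sample' column")
  m <- as.matrix(d[, setdiff(names(d), "sample"), drop = FALSE])
  storage.mode(m) <- "integer"
  laying_records(d$sample, m)
}

#' Write daily laying records to TSV
#' @param rec a \code{laying_records} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_laying_tsv <- function(rec, path) {
  d <- data.frame(sample = rec$samples, rec$matrix, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an association-result table
#'
#' @param res data.frame with per-variant results (chrom, pos, effect, SE,
#'   p, q, ...).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_assoc_tsv <- function(res, path) {
  write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write windowed statistics BED-style
#'
#' Windows are emitted as 0-based half-open intervals
#' (\code{chrom start end statistic...}), the BED convention; all point
#' coordinates elsewhere in the package stay 1-based (VCF convention).
#'
#' @param wins data.frame with columns \code{chrom}, \code{start}
#'   (0-based), \code{end}, plus statistic columns.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_window_bed <- function(wins, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(wins)))
  wins$start <- format(wins$start, scientific = FALSE, trim = TRUE)
  wins$end <- format(wins$end, scientific = FALSE, trim = TRUE)
  write.table(wins, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a trait table from TSV
#' @param path input TSV with a \code{sample} column and trait columns.
#' @return data.frame with samples as rownames.
#' @export
read_trait_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  rownames(d) <- d$sample
  d$sample <- NULL
  d
}

#' Write a trait table to TSV
#' @param tab data.frame of traits with samples as rownames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trait_tsv <- function(tab, path) {
  d <- data.frame(sample = rownames(tab), tab, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
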