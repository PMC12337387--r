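#' Haplotype-allele frequencies of a block in a population panel
#'
#' Slices the panel's haplotypes at the block's positions (matched by
#' chromosome and position; when a position matches but ref/alt differ,
#' it is treated as absent). Positions absent from the panel are filled
#' with the reference allele for every haplotype, making the discovery
#' cohort's catalogued alleles directly comparable. Sequences not in the
#' catalogue are counted as \code{"other"}.
#'
#' @param block a \code{haplotype_block} from \code{\link{build_blocks}}.
#' @param panel a \code{\link{phased_genotypes}} population panel.
#' @return named numeric vector of frequencies: one entry per catalogued
#'   allele (\code{A1, A2, ...}) plus \code{other}; sums to 1.
#' @export
allele_frequency_in_panel <- function(block, panel) {
  nh <- nrow(panel$hap)
  key_b <- paste(block$chrom, block$positions)
  key_p <- paste(panel$variants$chrom, panel$variants$pos)
  hit <- match(key_b, key_p)
  if (!all(is.na(hit))) {
    ok <- !is.na(hit)
    same <- rep(FALSE, length(hit))
    same[ok] <- panel$variants$ref[hit[ok]] == block$ref[ok] &
      panel$variants$alt[hit[ok]] == block$alt[ok]
    hit[!same] <- NA
  }
  if (all(is.na(hit)))
    warning("no overlapping positions; all-reference fill for block ",
            block$id)
  slice <- matrix(0L, nh, length(key_b))   # reference fill = 0
  for (j in which(!is.na(hit))) slice[, j] <- panel$hap[, hit[j]]
  seqs <- apply(slice, 1L, paste0, collapse = "")
  code <- match(seqs, block$alleles)
  k <- length(block$alleles)
  counts <- tabulate(code, nbins = k)
  freq <- c(counts, sum(is.na(code))) / nh
  names(freq) <- c(paste0("A", seq_len(k)), "other")
  freq
}

#' Enriched score of an allele class in population panels
#'
#' For the BHA (or UHA) of a trait, the enriched score of panel k is
#' \eqn{E_k = \sum_n f_{nk}}, the sum of the class alleles' haplotype
#' frequencies in that panel. Uncatalogued ("other") sequences never
#' contribute.
#'
#' @param effects a \code{haplotype_effects} table from
#'   \code{\link{estimate_allele_effects}}.
#' @param blocks the blocks the effects refer to.
#' @param panels list of \code{\link{phased_genotypes}} panels.
#' @param class \code{"BHA"} or \code{"UHA"}.
#' @return data.frame: population, E, n_alleles. E is NA when the class
#'   is empty.
#' @export
enriched_score <- function(effects, blocks, panels, class = c("BHA", "UHA")) {
  class <- match.arg(class)
  eff <- effects[effects$class == class, , drop = FALSE]
  ids <- vapply(blocks, `[[`, character(1), "id")
  pop_names <- if (!is.null(names(panels))) names(panels) else
    paste0("pop", seq_along(panels))
  if (nrow(eff) == 0L)
    return(data.frame(population = pop_names, E = NA_real_, n_alleles = 0L))
  out <- vapply(panels, function(panel) {
    E <- 0
    for (i in seq_len(nrow(eff))) {
      b <- blocks[[match(eff$block[i], ids)]]
      f <- allele_frequency_in_panel(b, panel)
      E <- E + f[[paste0("A", eff$allele[i])]]
    }
    E
  }, numeric(1))
  data.frame(population = pop_names, E = as.numeric(out),
             n_alleles = nrow(eff))
}
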