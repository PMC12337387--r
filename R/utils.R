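#' @keywords internal
"_PACKAGE"

#' @importFrom stats anova coef cor cor.test lm optimize p.adjust pnorm
#'   predict pt quantile rbinom rnorm rpois runif sd setNames var complete.cases
#' @importFrom utils read.table write.table head tail
NULL

# Clamp numeric values into [lo, hi].
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Derive a stage-specific seed from a master seed so pipeline stages are
# independently reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

# Two consecutive rows per individual: rows of the haplotype matrix that
# belong to individual i.
hap_rows <- function(i) c(2L * i - 1L, 2L * i)

# Dosage matrix (N x M, entries 0/1/2) from a 2N x M haplotype matrix.
hap_to_dosage <- function(hap) {
  n <- nrow(hap) / 2L
  hap[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    hap[seq(2L, 2L * n, by = 2L), , drop = FALSE]
}
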