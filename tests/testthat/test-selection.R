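test_that("singleton finder recovers the simulator's ground truth exactly", {
  fx <- fix_cohort()
  found <- find_singletons(fx$g)
  truth <- attr(fx$g, "singletons")
  expect_equal(found$col, truth$col)
  expect_equal(found$hap, truth$hap)
  # AC = 2 sites are not singletons
  ac <- colSums(fx$g$hap)
  expect_false(any(found$col %in% which(ac == 2)))
})

# Four haplotypes with hand-placed singletons around a test SNP at 100 kb:
# reference carriers have total gaps of 20 kb, alternative carriers 80 kb.
hand_sds_fixture <- function() {
  P <- 100000L
  sing_pos <- c(P - 10000L, P + 10000L,   # hap 1 (ref): gap 20 kb
                P - 9000L,  P + 11000L,   # hap 2 (ref): gap 20 kb
                P - 40000L, P + 40000L,   # hap 3 (alt): gap 80 kb
                P - 39000L, P + 41000L)   # hap 4 (alt): gap 80 kb
  carrier <- c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L)
  pos <- sort(c(sing_pos, P))
  hap <- matrix(0L, 4, length(pos))
  for (i in seq_along(sing_pos))
    hap[carrier[i], which(pos == sing_pos[i])] <- 1L
  hap[c(3, 4), pos == P] <- 1L
  g <- phased_genotypes(c("i1", "i2"),
                        data.frame(chrom = "chr1", pos = pos, ref = "A",
                                   alt = "T",
                                   id = paste0("s", seq_along(pos))),
                        hap, c(chr1 = 200000L))
  list(g = g, test_col = which(pos == P))
}

test_that("raw SDS matches the hand-computed gap ratio", {
  fx <- hand_sds_fixture()
  res <- raw_sds(fx$g, test_snps = fx$test_col)
  expect_equal(res$rsds, log(80000) - log(20000), tolerance = 1e-12)
  expect_equal(res$rsds, log(4), tolerance = 1e-12)
})

test_that("raw SDS is zero under symmetric spacing and antisymmetric under swap", {
  fx <- hand_sds_fixture()
  g <- fx$g
  # symmetric: make alt carriers see the same gaps as ref carriers
  res0 <- raw_sds(g, test_snps = fx$test_col)
  g_swap <- g
  g_swap$hap[, fx$test_col] <- 1L - g_swap$hap[, fx$test_col]
  g_swap$af <- colMeans(g_swap$hap)
  res_swap <- raw_sds(g_swap, test_snps = fx$test_col)
  expect_equal(res_swap$rsds, -res0$rsds, tolerance = 1e-12)
  # identical spacing in both classes: zero score
  P <- 50000L
  pos <- c(P - 5000L, P - 4000L, P, P + 4000L, P + 5000L)
  hap <- matrix(0L, 4, 5)
  hap[1, 1] <- 1L; hap[2, 4] <- 1L; hap[3, 2] <- 1L; hap[4, 5] <- 1L
  hap[c(3, 4), 3] <- 1L
  g2 <- phased_genotypes(c("i1", "i2"),
                         data.frame(chrom = "chr1", pos = pos, ref = "A",
                                    alt = "T", id = paste0("s", 1:5)), hap)
  expect_equal(raw_sds(g2, test_snps = 3L)$rsds, 0, tolerance = 1e-12)
  # an allele class below the carrier minimum gets no score
  expect_true(is.na(raw_sds(g2, test_snps = 3L, min_carriers = 3)$rsds))
})

test_that("simulated sweeps push the raw score positive", {
  mean_rsds <- vapply(1:10, function(s) {
    cfg <- sim_config(n_individuals = 60, n_snps_per_chrom = 120,
                      n_chroms = 1, mutation_density = 2, seed = 900 + s)
    g0 <- simulate_haplotypes(cfg)
    ns <- which(!g0$variants$is_singleton)
    cand <- ns[g0$af[ns] > 0.3 & g0$af[ns] < 0.7]
    swept <- cand[unique(round(seq(1, length(cand), length.out = 5)))]
    g <- sweep_singletons(g0, swept, keep = 0.25, seed = s)
    key <- match(paste(g0$variants$chrom[swept], g0$variants$pos[swept]),
                 paste(g$variants$chrom, g$variants$pos))
    mean(raw_sds(g, test_snps = key)$rsds, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(mean_rsds), 0)
  expect_gt(mean(mean_rsds > 0), 0.7)
})

test_that("frequency-bin standardization centres, scales and preserves order", {
  fx <- fix_cohort()
  sds <- standardize_sds(raw_sds(fx$g), min_bin = 5)
  means <- tapply(sds$sds, sds$bin, mean)
  sds_by <- tapply(sds$sds, sds$bin, sd)
  expect_lt(max(abs(means)), 1e-8)
  expect_lt(max(abs(sds_by[!is.na(sds_by)] - 1)), 1e-8)
  # frequency range rule
  expect_true(all(sds$af >= 0.05 & sds$af <= 0.95))
  # rank order within a bin is preserved (monotone transform)
  b0 <- sds$bin[1]
  inb <- sds[sds$bin == b0, ]
  expect_identical(order(inb$rsds), order(inb$sds))
  # idempotence: standardizing the standardized scores changes nothing
  again <- standardize_sds(transform(sds, rsds = sds), min_bin = 5)
  expect_equal(again$sds, sds$sds, tolerance = 1e-12)
  expect_error(standardize_sds(data.frame(rsds = 1, af = 0.5)), "fewer than 2")
})

test_that("mSDS windows follow the floor(pos/window) convention", {
  sc <- data.frame(chrom = "chr1", pos = c(10, 49999, 50000, 60000),
                   sds = c(1, -1, 2, 4))
  w <- msds_windows(sc, window = 50000)
  expect_equal(w$start, c(0, 50000))
  expect_equal(w$end, c(50000, 100000))
  expect_equal(w$msds, c(0, 3))        # two SNPs at +/-1 average to zero
  expect_equal(w$n_snps, c(2L, 2L))
  one <- msds_windows(data.frame(chrom = "chr1", pos = 10, sds = 1.7))
  expect_equal(one$msds, 1.7)
})

test_that("tSDS polarization follows and flips with the effect sign", {
  fx <- fix_cohort()
  sds <- standardize_sds(raw_sds(fx$g), min_bin = 5)
  scan <- snp_scan(rowMeans(fx$rec$matrix), fx$g, compute_grm(fx$g))
  tp <- tsds_polarize(sds, scan)
  pos_beta <- !is.na(tp$beta) & tp$beta > 0
  expect_equal(tp$tsds[pos_beta], tp$sds[pos_beta])
  scan_flip <- scan
  scan_flip$beta <- -scan_flip$beta
  tp2 <- tsds_polarize(sds, scan_flip)
  ok <- !is.na(tp$tsds)
  expect_equal(tp2$tsds[ok], -tp$tsds[ok])
})

test_that("tSDS trend statistic: monotone construction and degenerate input", {
  tsds <- seq(-1, 1, length.out = 300)
  p <- 10^(-seq_along(tsds) / 30)          # -log10(p) increasing with tsds
  tt <- tsds_trend(tsds, p, bin_size = 30)
  expect_equal(tt$rho, 1)
  expect_equal(tt$n_bins, 10)
  expect_error(tsds_trend(tsds, p, bin_size = 200), "insufficient")
})

test_that("pi and D: identical haplotypes, hand-worked window oracle", {
  hap <- matrix(0L, 4, 3)
  g0 <- phased_genotypes(c("i1", "i2"),
                         data.frame(chrom = "chr1", pos = c(10L, 500L, 900L),
                                    ref = "A", alt = "T",
                                    id = paste0("s", 1:3)), hap,
                         c(chr1 = 1000L))
  w0 <- tajima_pi_windows(g0, window = 1000)
  expect_equal(w0$pi, 0)
  expect_true(is.na(w0$tajima_d))
  # 4 haplotypes, 3 segregating sites: brute-force pairwise oracle
  hap1 <- rbind(c(1L, 0L, 0L),
                c(0L, 1L, 0L),
                c(0L, 1L, 1L),
                c(0L, 0L, 0L))
  g1 <- phased_genotypes(c("i1", "i2"),
                         data.frame(chrom = "chr1", pos = c(10L, 500L, 900L),
                                    ref = "A", alt = "T",
                                    id = paste0("s", 1:3)), hap1,
                         c(chr1 = 1000L))
  w1 <- tajima_pi_windows(g1, window = 1000)
  expect_equal(w1$tajima_d, brute_tajima_d(hap1), tolerance = 1e-10)
  expect_equal(w1$pi * 1000, brute_pairwise_pi(hap1), tolerance = 1e-10)
  expect_equal(w1$n_sites, 3L)
})

test_that("windowed D is centred near zero under a neutral frequency spectrum", {
  ds <- vapply(1:10, function(s) {
    g <- simulate_neutral_sites(40, 600, chrom_length_bp = 6e5, seed = s)
    w <- tajima_pi_windows(g, window = 1e5)
    mean(w$tajima_d, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(ds)), 0.3)
})
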