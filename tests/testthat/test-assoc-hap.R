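test_that("block construction drops remainders and catalogues alleles", {
  set.seed(5)
  hap <- matrix(rbinom(8 * 12, 1, 0.5), nrow = 8)
  hap[, 3] <- c(0, 0, 0, 1, 1, 1, 1, 1)    # keep sites polymorphic
  g <- phased_genotypes(paste0("i", 1:4),
                        data.frame(chrom = "chr1", pos = seq(10, 120, by = 10),
                                   ref = "A", alt = "T",
                                   id = paste0("s", 1:12)), hap)
  blocks <- build_blocks(g, block_size = 5)
  expect_length(blocks, 2)                  # 12 SNPs -> 2 blocks, 2 dropped
  expect_equal(blocks[[1]]$cols, 1:5)
  expect_equal(blocks[[2]]$cols, 6:10)
  # frequency bookkeeping
  for (b in blocks) {
    expect_equal(sum(b$freq), 1)
    expect_true(all(diff(b$freq) <= 0))     # most frequent first
    expect_equal(length(b$alleles), length(unique(
      apply(hap[, b$cols], 1, paste0, collapse = ""))))
  }
  expect_warning(build_blocks(subset_variants(g, 1:3), 5), "fewer than")
})

test_that("identical haplotypes collapse to a single allele", {
  hap <- matrix(rep(c(0L, 1L, 0L, 1L, 1L), each = 6), nrow = 6)
  g <- phased_genotypes(paste0("i", 1:3),
                        data.frame(chrom = "chr1", pos = 1:5 * 10, ref = "A",
                                   alt = "T", id = paste0("s", 1:5)), hap)
  b <- build_blocks(g)[[1]]
  expect_length(b$alleles, 1)
  expect_equal(hap_grm(list(b))[1, 1], 2)   # everyone doubly identical
})

test_that("observed 5-mers give the enumerated allele frequencies", {
  hap <- rbind(c(0, 0, 0, 0, 0),
               c(0, 0, 0, 0, 1),
               c(1, 1, 1, 1, 1),
               c(1, 1, 1, 1, 1))
  g <- phased_genotypes(c("i1", "i2"),
                        data.frame(chrom = "chr1", pos = 1:5 * 10, ref = "A",
                                   alt = "T", id = paste0("s", 1:5)),
                        hap)
  b <- build_blocks(g)[[1]]
  got <- setNames(b$freq, b$alleles)
  expect_equal(got[["11111"]], 0.5)
  expect_equal(got[["00000"]], 0.25)
  expect_equal(got[["00001"]], 0.25)
})

test_that("dosage coding: rows sum to two, hom/het patterns", {
  fx <- fix_cohort()
  blocks <- build_blocks(fx$g)
  for (b in blocks[seq(1, length(blocks), by = 7)]) {
    d <- dosage_code(b)
    expect_true(all(rowSums(d) == 2L))
    expect_true(all(d %in% 0:2))
    hom <- b$pair[, 1] == b$pair[, 2]
    expect_true(all(d[cbind(which(hom), b$pair[hom, 1])] == 2L))
  }
})

test_that("haplotype relationship matrix equals the Gamma/K brute force", {
  # worked 2-individual example: pairs (h1,h2) and (h1,h1)
  hap <- rbind(c(0, 0, 0, 0, 0),
               c(0, 0, 0, 0, 1),
               c(0, 0, 0, 0, 0),
               c(0, 0, 0, 0, 0))
  g <- phased_genotypes(c("i1", "i2"),
                        data.frame(chrom = "chr1", pos = 1:5 * 10, ref = "A",
                                   alt = "T", id = paste0("s", 1:5)), hap)
  blocks <- build_blocks(g)
  H <- hap_grm(blocks, keep_gamma = TRUE)
  expect_equal(unclass(H), matrix(c(1, 1, 1, 2), 2), ignore_attr = TRUE)
  expect_equal(unclass(H), brute_hap_grm(blocks), ignore_attr = TRUE)
  # 20 random small instances against the brute force
  for (s in 1:20) {
    set.seed(100 + s)
    n <- sample(3:8, 1)
    m <- 5 * sample(1:3, 1)
    hap <- matrix(rbinom(2 * n * m, 1, runif(1, 0.2, 0.8)), nrow = 2 * n)
    gg <- phased_genotypes(paste0("i", 1:n),
                           data.frame(chrom = "chr1", pos = seq_len(m) * 10,
                                      ref = "A", alt = "T",
                                      id = paste0("s", seq_len(m))), hap)
    bl <- build_blocks(gg)
    expect_equal(unclass(hap_grm(bl)), brute_hap_grm(bl),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # bounds: diagonal in [1, 2]; disjoint alleles give the identity
  fx <- fix_cohort()
  Hc <- hap_grm(build_blocks(fx$g))
  expect_true(all(diag(Hc) >= 1 - 1e-12 & diag(Hc) <= 2 + 1e-12))
  hap0 <- rbind(diag(5)[1, , drop = FALSE] * 0, c(1, 0, 0, 0, 0),
                c(0, 1, 1, 0, 0), c(1, 1, 1, 1, 1))
  g0 <- phased_genotypes(c("i1", "i2"),
                         data.frame(chrom = "chr1", pos = 1:5 * 10, ref = "A",
                                    alt = "T", id = paste0("s", 1:5)), hap0)
  H0 <- hap_grm(build_blocks(g0))
  expect_equal(unclass(H0), diag(2), ignore_attr = TRUE)
})

test_that("two-step scan finds a planted block-level QTL", {
  fx <- fix_cohort()
  blocks <- build_blocks(fx$g)
  chroms <- vapply(blocks, `[[`, character(1), "chrom")
  target <- which(chroms == "chr2")[4]
  b <- blocks[[target]]
  d <- dosage_code(b)
  k <- which.min(abs(b$freq - 0.3))         # a reasonably common allele
  set.seed(17)
  gv <- d[, k]
  y <- as.numeric(scale(gv) * sqrt(0.25) + rnorm(150) * sqrt(0.75))
  hs <- hgwas_scan(y, blocks)
  expect_equal(which.min(hs$p), target)
  expect_error(hgwas_scan(rep(0, 150), blocks), "degenerate trait")
})

test_that("two-step p-values track the exact one-step mixed-model LRT", {
  fx <- fix_cohort()
  blocks <- build_blocks(fx$g)
  H <- hap_grm(blocks)
  y <- polygenic_trait(H, 0.3, seed = 23)
  two <- hgwas_scan(y, blocks, H, loco = FALSE)
  one <- exact_lmm_lrt(y, blocks, H)
  keep <- two$p < 1 & one < 1
  expect_gte(cor(two$p[keep], one[keep], method = "spearman"), 0.9)
})

test_that("allele effects recover a planted noiseless signal", {
  fx <- fix_cohort()
  blocks <- build_blocks(fx$g)
  b <- blocks[[3]]
  d <- dosage_code(b)
  y <- 1.0 * d[, 2]                          # +1 per copy of allele 2
  eff <- suppressWarnings(estimate_allele_effects(y, blocks[3]))
  est <- eff$effect[eff$allele == 2]
  expect_equal(est, 1.0, tolerance = 1e-8)
  expect_equal(eff$class[eff$allele == 2], "BHA")
  # lower-is-better traits flip the classification
  eff_dn <- suppressWarnings(estimate_allele_effects(y, blocks[3],
                                                     direction = -1))
  expect_equal(eff_dn$class[eff_dn$allele == 2], "UHA")
  # no blocks -> empty result
  expect_equal(nrow(estimate_allele_effects(y, list())), 0)
})

test_that("planted effect signs survive estimation across seeds", {
  fx <- fix_cohort()
  blocks <- build_blocks(fx$g)
  ok <- 0
  for (s in 1:10) {
    set.seed(300 + s)
    b1 <- blocks[[5]]; b2 <- blocks[[40]]
    gv <- dosage_code(b1)[, 2] - dosage_code(b2)[, 2]
    y <- as.numeric(scale(gv) * sqrt(0.4) + rnorm(150) * sqrt(0.6))
    eff <- suppressWarnings(estimate_allele_effects(y, list(b1, b2)))
    e1 <- eff$effect[eff$block == b1$id & eff$allele == 2]
    e2 <- eff$effect[eff$block == b2$id & eff$allele == 2]
    ok <- ok + (e1 > 0 && e2 < 0)
  }
  expect_gte(ok, 9)
})

test_that("rare combination levels are merged and singletons degrade to p = 1", {
  fx <- fix_cohort()
  blocks <- build_blocks(fx$g)
  f <- layscan:::combination_factor(blocks[[1]], min_carriers = 5)
  tab <- table(f)
  expect_true(all(tab[names(tab) != "rare"] >= 5))
  # a block with a single level after merging is untestable
  hap1 <- matrix(0L, 300, 5)
  g1 <- phased_genotypes(paste0("i", 1:150),
                         data.frame(chrom = "chr1", pos = 1:5, ref = "A",
                                    alt = "T", id = paste0("s", 1:5)),
                         hap1)
  b1 <- build_blocks(g1)[[1]]
  y <- rnorm(150)
  hs <- hgwas_scan(y, list(b1), diag(150), loco = FALSE)
  expect_equal(hs$p, 1)
})
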