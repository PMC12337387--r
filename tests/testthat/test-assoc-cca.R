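test_that("a trait equal to the dosage gives canonical correlation one", {
  fx <- fix_cohort()
  g <- fx$g
  dos <- layscan:::hap_to_dosage(subset_variants(
    g, !g$variants$is_singleton)$hap)
  j <- which(g$af[!g$variants$is_singleton] > 0.2 &
               g$af[!g$variants$is_singleton] < 0.8)[7]
  set.seed(1)
  Y <- cbind(t1 = dos[, j], t2 = rnorm(150))
  res <- cca_scan(g, Y)
  expect_equal(res$rho[j], 1, tolerance = 1e-6)
  expect_lt(res$p[j], 1e-20)
  # constant genotype is a p = 1 sentinel
  expect_true(all(res$p[is.na(res$rho)] == 1))
  expect_error(cca_scan(g, matrix(numeric(0), 150, 0)), "at least one trait")
})

test_that("eigen route equals brute-force projection search and cancor", {
  set.seed(7)
  for (i in 1:20) {
    n <- 60
    q <- sample(2:4, 1)
    Y <- matrix(rnorm(n * q), n)
    x <- as.integer(rbinom(n, 2, 0.4))
    if (length(unique(x)) < 2) x[1:2] <- c(0L, 2L)
    # pack the single genotype into a one-site container
    hap <- matrix(0L, 2 * n, 1)
    hap[seq(1, 2 * n, 2), 1] <- as.integer(x >= 1)
    hap[seq(2, 2 * n, 2), 1] <- as.integer(x == 2)
    g <- phased_genotypes(paste0("i", 1:n),
                          data.frame(chrom = "chr1", pos = 1L, ref = "A",
                                     alt = "T", id = "s1"), hap)
    res <- cca_scan(g, Y)
    expect_equal(res$rho[1], brute_cca_rho(x, Y), tolerance = 1e-6)
    expect_equal(res$rho[1], stats::cancor(x, Y)$cor[1], tolerance = 1e-10)
  }
})

test_that("single-trait case matches the Pearson chi-square closely", {
  set.seed(9)
  n <- 120
  rel <- vapply(1:100, function(i) {
    x <- rbinom(n, 2, runif(1, 0.2, 0.8))
    y <- matrix(0.3 * x + rnorm(n), ncol = 1)
    hap <- matrix(0L, 2 * n, 1)
    hap[seq(1, 2 * n, 2), 1] <- as.integer(x >= 1)
    hap[seq(2, 2 * n, 2), 1] <- as.integer(x == 2)
    g <- phased_genotypes(paste0("i", 1:n),
                          data.frame(chrom = "chr1", pos = 1L, ref = "A",
                                     alt = "T", id = "s1"), hap)
    res <- cca_scan(g, y)
    p_pearson <- stats::pchisq(n * res$rho[1]^2, 1, lower.tail = FALSE)
    abs(-log10(res$p[1]) + log10(p_pearson)) / max(-log10(p_pearson), 1e-12)
  }, numeric(1))
  expect_lt(max(rel), 0.1)
})

test_that("canonical coefficients: one-trait unit, orthogonal noise near zero", {
  set.seed(21)
  n <- 500
  x <- rbinom(n, 2, 0.5)
  hap <- matrix(0L, 2 * n, 1)
  hap[seq(1, 2 * n, 2), 1] <- as.integer(x >= 1)
  hap[seq(2, 2 * n, 2), 1] <- as.integer(x == 2)
  g <- phased_genotypes(paste0("i", 1:n),
                        data.frame(chrom = "chr1", pos = 1L, ref = "A",
                                   alt = "T", id = "s1"), hap)
  res1 <- cca_scan(g, matrix(x + rnorm(n, 0, 0.1), ncol = 1,
                             dimnames = list(NULL, "t")))
  expect_equal(abs(attr(res1, "coefficients")[1, 1]), 1, tolerance = 1e-9,
               ignore_attr = TRUE)
  # a trait orthogonal to the association contributes ~ nothing
  Y <- cbind(signal = x + rnorm(n, 0, 0.5), noise = rnorm(n))
  res2 <- cca_scan(g, Y)
  co <- attr(res2, "coefficients")
  expect_gt(co[1, "signal"], 0)              # sign convention: first >= 0
  expect_lt(abs(co[1, "noise"]), 0.1)
  tab <- canonical_coefficients(res2, fdr = 0.5)
  expect_true(all(c("signal", "noise") %in% colnames(tab)))
  # n used by Bartlett equals the post-deletion count
  Y[3, 1] <- NA
  expect_equal(attr(cca_scan(g, Y), "n_used"), n - 1)
})

test_that("CCA p-values are uniform under the global null", {
  fx <- fix_cohort()
  set.seed(13)
  Y <- matrix(rnorm(150 * 3), 150)
  res <- cca_scan(fx$g, Y)
  p <- res$p[!is.na(res$rho)]
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("stage interaction: planted crossover is detected with opposite signs", {
  hits <- 0
  for (s in 1:10) {
    set.seed(40 + s)
    n <- 120
    geno <- factor(sample(c("aa", "Aa", "AA"), n, replace = TRUE,
                          prob = c(0.25, 0.5, 0.25)))
    x <- as.integer(geno) - 1
    up <- 1 * x + rnorm(n)
    sus <- -1 * x + rnorm(n)
    d <- data.frame(individual = rep(seq_len(n), 2),
                    stage = rep(c("up", "sustained"), each = n),
                    value = c(up, sus))
    res <- stage_interaction_test(d, rep(geno, 2))
    ok <- res$p_interaction < 0.05
    if (ok && !is.null(res$posthoc)) {
      ph <- res$posthoc
      aa_up <- ph$estimate[grepl("AA", ph$contrast) & ph$stage == "up"]
      aa_sus <- ph$estimate[grepl("AA", ph$contrast) & ph$stage == "sustained"]
      ok <- length(aa_up) == 1 && sign(aa_up) != sign(aa_sus)
    }
    hits <- hits + ok
  }
  expect_gte(hits, 9)
})

test_that("stage interaction nulls: uniform p and zero gamma", {
  set.seed(77)
  ps <- vapply(1:200, function(i) {
    n <- 60
    geno <- factor(sample(c("aa", "Aa", "AA"), n, replace = TRUE))
    d <- data.frame(individual = rep(seq_len(n), 2),
                    stage = rep(c("up", "sustained"), each = n),
                    value = rnorm(2 * n))
    stage_interaction_test(d, rep(geno, 2))$p_interaction
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # identical stage means per genotype: interaction estimate is zero
  n <- 30
  geno <- factor(rep(c("aa", "Aa", "AA"), each = n / 3))
  base <- as.integer(geno)
  d <- data.frame(individual = rep(seq_len(n), 2),
                  stage = rep(c("up", "sustained"), each = n),
                  value = rep(base, 2))
  res <- suppressWarnings(stage_interaction_test(d, rep(geno, 2)))
  cf <- coef(res$model)
  expect_lt(max(abs(cf[grepl(":", names(cf))])), 1e-10)
})
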