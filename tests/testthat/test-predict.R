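# Small two-chromosome cohort for prediction protocol tests.
fix_pred <- function() fixture("pred", function() {
  cfg <- sim_config(n_individuals = 200, n_snps_per_chrom = 100,
                    n_chroms = 2, mutation_density = 0.3,
                    recombination_prob = 0.02, seed = 5)
  g <- simulate_haplotypes(cfg)
  blocks <- build_blocks(g)
  list(g = g, blocks = blocks)
})

test_that("HPPS sums effect times dosage over the chosen allele class", {
  fx <- fix_pred()
  b <- fx$blocks[[1]]
  eff <- data.frame(block = b$id, allele = 2L, sequence = b$alleles[2],
                    freq = b$freq[2], effect = 1.0, se = 0.1, p = 0.001,
                    class = "BHA", stringsAsFactors = FALSE)
  s <- hpps(eff, fx$blocks[1], "all")
  expect_equal(s, 1.0 * dosage_code(b)[, 2])
  expect_equal(hpps(eff, fx$blocks[1], "bene"), s)
  expect_warning(s0 <- hpps(eff, fx$blocks[1], "unbe"), "no unbe")
  expect_equal(s0, rep(0, 200))
  # zero effects give zero scores
  eff$effect <- 0
  expect_equal(hpps(eff, fx$blocks[1], "all"), rep(0, 200))
})

test_that("HPPS correlates with the true genetic value on simulated data", {
  cfg <- sim_config(n_individuals = 300, n_snps_per_chrom = 100, n_chroms = 2,
                    mutation_density = 0.3,
                    qtl_list = list(qtl_spec("chr1", 20, 1,
                                             kind = "haplotype-allele")),
                    h2_target = 0.4, seed = 31)
  g <- simulate_haplotypes(cfg)
  rec <- simulate_laying_records(g, cfg)
  y <- rowMeans(rec$matrix)
  blocks <- build_blocks(g)
  hs <- hgwas_scan(y, blocks)
  sig <- order(hs$p)[1:3]
  eff <- suppressWarnings(estimate_allele_effects(y, blocks[sig]))
  s <- suppressWarnings(hpps(eff, blocks[sig], "all"))
  ct <- cor.test(s, attr(rec, "genetic_value"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("HBLUP: noiseless recovery and null behaviour", {
  fx <- fix_pred()
  Z <- dosage_code(fx$blocks[[4]])
  y <- as.numeric(Z %*% rnorm(ncol(Z)))
  fit <- hblup_fit(y, Z)
  expect_gt(cor(fit$prediction, y), 0.999)
  # pure-noise phenotype: held-out prediction has no skill
  set.seed(44)
  yn <- rnorm(200)
  cors <- vapply(1:5, function(i) {
    train <- setdiff(1:200, ((i - 1) * 40 + 1):(i * 40))
    f <- hblup_fit(yn, Z, train = train)
    cor(f$prediction[-train], yn[-train])
  }, numeric(1))
  expect_lt(abs(mean(cors)), 2 * sd(cors) / sqrt(5) + 0.2)
})

test_that("GBLUP: identity GRM gives the covariate fit, duplicates predict", {
  set.seed(3)
  y <- rnorm(60)
  fit <- gblup_fit(y, diag(60), train = 1:40)
  # identity GRM: out-of-sample genomic covariance is zero, so held-out
  # predictions collapse to the covariate (intercept) fit
  expect_equal(sd(fit$prediction[41:60]), 0, tolerance = 1e-10)
  expect_equal(fit$prediction[41], mean(y[1:40]), tolerance = 0.05)
  # a duplicated individual in train and validation is predicted well
  fx <- fix_pred()
  g <- fx$g
  G <- compute_grm(g)
  yq <- polygenic_trait(G, 0.8, seed = 12)
  train <- 1:150
  G2 <- G
  G2[151, ] <- G2[1, ]; G2[, 151] <- G2[, 1]; G2[151, 151] <- G2[1, 1]
  yq[151] <- yq[1]
  f <- gblup_fit(yq, G2, train = train)
  expect_lt(abs(f$prediction[151] - f$prediction[1]), 1e-6)
})

test_that("cross-validation: deterministic block signal, null, determinism", {
  fx <- fix_pred()
  y <- 2 * dosage_code(fx$blocks[[10]])[, 2]
  cv <- suppressWarnings(cross_validate("hpps-all", y = y,
                                        blocks = fx$blocks,
                                        n_validation = 50, folds = 5,
                                        repeats = 3, seed = 9))
  expect_gt(cv$mean, 0.9)
  expect_true(all(abs(cv$correlations) <= 1))
  cv2 <- suppressWarnings(cross_validate("hpps-all", y = y,
                                         blocks = fx$blocks,
                                         n_validation = 50, folds = 5,
                                         repeats = 3, seed = 9))
  expect_identical(cv$correlations, cv2$correlations)
  # permuted phenotype: no skill
  set.seed(2)
  yp <- sample(y)
  cvp <- suppressWarnings(cross_validate("hpps-all", y = yp,
                                         blocks = fx$blocks,
                                         n_validation = 50, folds = 5,
                                         repeats = 3, seed = 9))
  expect_lt(abs(cvp$mean),
            2 * sd(cvp$correlations) / sqrt(3) + 0.1)
  expect_error(cross_validate("hpps-all", y = y[1:40], blocks = fx$blocks,
                              n_validation = 50, folds = 5), "more individuals")
})

test_that("amalgamating both allele classes is at least as predictive", {
  fx <- fix_pred()
  wins <- 0
  for (s in 1:6) {
    set.seed(500 + s)
    gv <- dosage_code(fx$blocks[[5]])[, 2] -
      dosage_code(fx$blocks[[25]])[, 2]
    y <- as.numeric(scale(gv) * sqrt(0.5) + rnorm(200) * sqrt(0.5))
    ms <- vapply(c("hpps-all", "hpps-bene", "hpps-unbe"), function(m)
      suppressWarnings(cross_validate(m, y = y, blocks = fx$blocks,
                                      n_validation = 40, folds = 4,
                                      repeats = 2, seed = s))$mean,
      numeric(1))
    wins <- wins + (ms["hpps-all"] >= max(ms["hpps-bene"], ms["hpps-unbe"]) - 0.02)
  }
  expect_gte(wins, 4)
})

test_that("HBLUP beats fixed-effect HPPS under many small effects", {
  fx <- fix_pred()
  wins <- 0
  for (s in 1:6) {
    set.seed(700 + s)
    picks <- sample(length(fx$blocks), 12)
    gv <- rowSums(vapply(picks, function(i) {
      d <- dosage_code(fx$blocks[[i]])
      as.numeric(d %*% rnorm(ncol(d), 0, 0.3))
    }, numeric(200)))
    y <- as.numeric(scale(gv) * sqrt(0.5) + rnorm(200) * sqrt(0.5))
    mh <- suppressWarnings(cross_validate("hblup", y = y, blocks = fx$blocks,
                                          n_validation = 40, folds = 4,
                                          repeats = 2, seed = s))$mean
    mb <- suppressWarnings(cross_validate("hpps-bene", y = y,
                                          blocks = fx$blocks,
                                          n_validation = 40, folds = 4,
                                          repeats = 2, seed = s))$mean
    wins <- wins + (mh >= mb)
  }
  expect_gte(wins, 4)
})
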