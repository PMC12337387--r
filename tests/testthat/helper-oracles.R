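# Independent oracles used across the suite. Each one deliberately takes
# a different computational route from the package implementation.

# Clutch/interval structure by explicit day-by-day walking (no rle).
brute_clutches <- function(v) {
  clutches <- integer(0); run <- 0L
  for (d in v) {
    if (d == 1L) run <- run + 1L
    else if (run > 0L) { clutches <- c(clutches, run); run <- 0L }
  }
  if (run > 0L) clutches <- c(clutches, run)
  ones <- which(v == 1L)
  intervals <- integer(0)
  if (length(ones) >= 2L) {
    run <- 0L
    for (d in v[min(ones):max(ones)]) {
      if (d == 0L) run <- run + 1L
      else if (run > 0L) { intervals <- c(intervals, run); run <- 0L }
    }
  }
  list(clutches = clutches, intervals = intervals)
}

# Haplotype-level relationship by the literal Gamma / K-collapse route:
# Gamma_i from pairwise allele identity, averaged, then H = K Gamma K'/2
# with K = I_m (x) [1 1].
brute_hap_grm <- function(blocks) {
  n <- nrow(blocks[[1]]$pair)
  G <- matrix(0, 2 * n, 2 * n)
  for (b in blocks) {
    a <- b$hap_allele
    Gi <- matrix(0, 2 * n, 2 * n)
    for (i in seq_len(2 * n))
      for (j in seq_len(2 * n))
        Gi[i, j] <- as.numeric(a[i] == a[j])
    G <- G + Gi
  }
  G <- G / length(blocks)
  K <- kronecker(diag(n), matrix(c(1, 1), nrow = 1))
  K %*% G %*% t(K) / 2
}

# Mean pairwise difference and Tajima's D by explicit pairwise Hamming
# counting over haplotypes (frequency formulas never used).
brute_pairwise_pi <- function(hap) {
  nh <- nrow(hap)
  tot <- 0; np <- 0
  for (i in seq_len(nh - 1))
    for (j in (i + 1):nh) {
      tot <- tot + sum(hap[i, ] != hap[j, ])
      np <- np + 1
    }
  tot / np
}

brute_tajima_d <- function(hap) {
  nh <- nrow(hap)
  af <- colMeans(hap)
  S <- sum(af > 0 & af < 1)
  if (S == 0) return(NA_real_)
  k_hat <- brute_pairwise_pi(hap)
  a1 <- sum(1 / seq_len(nh - 1)); a2 <- sum(1 / seq_len(nh - 1)^2)
  b1 <- (nh + 1) / (3 * (nh - 1)); b2 <- 2 * (nh^2 + nh + 3) / (9 * nh * (nh - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (nh + 2) / (a1 * nh) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# First canonical correlation between a single variable x and a trait
# matrix Y by direct maximisation of |cor(x, Y b)| from random restarts.
brute_cca_rho <- function(x, Y, n_starts = 40) {
  q <- ncol(Y)
  best <- 0
  obj <- function(b) {
    v <- as.numeric(Y %*% b)
    if (sd(v) == 0) return(0)
    -abs(cor(x, v))
  }
  for (s in seq_len(n_starts)) {
    b0 <- rnorm(q)
    o <- optim(b0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- max(best, -o$value)
  }
  best
}

# Exact one-step mixed-model association: per-block ML likelihood-ratio
# test with the block factor as fixed effects (delta re-optimised under
# null and alternative). Independent of the package's two-step path.
exact_lmm_lrt <- function(y, blocks, H, min_carriers = 5) {
  n <- length(y)
  eig <- eigen(H, symmetric = TRUE)
  lambda <- pmax(eig$values, 0); U <- eig$vectors
  ys <- crossprod(U, y)
  ml_loglik <- function(Xs) {
    f <- function(log_delta) {
      delta <- exp(log_delta)
      w <- 1 / (lambda + delta)
      sw <- sqrt(w)
      Xw <- Xs * sw; yw <- ys * sw
      b <- qr.coef(qr(Xw), yw)
      r <- yw - Xw %*% b
      s2 <- sum(r^2) / n
      -0.5 * (n * log(s2) - sum(log(w)) + n)
    }
    optimize(function(ld) -f(ld), c(-12, 12))$objective * -1
  }
  X0 <- crossprod(U, matrix(1, n, 1))
  ll0 <- ml_loglik(X0)
  vapply(blocks, function(b) {
    fct <- droplevels(layscan:::combination_factor(b, min_carriers))
    if (nlevels(fct) < 2) return(1)
    Xs <- crossprod(U, cbind(1, stats::model.matrix(~fct)[, -1, drop = FALSE]))
    ll1 <- ml_loglik(Xs)
    stats::pchisq(2 * (ll1 - ll0), df = nlevels(fct) - 1, lower.tail = FALSE)
  }, numeric(1))
}

# Thin singletons around swept SNPs on alternative-allele haplotypes: the
# selection footprint the singleton-density score is built to detect.
sweep_singletons <- function(g, cols, window = 1e6, keep = 0.25, seed = 1) {
  set.seed(seed)
  sg <- attr(g, "singletons")
  drop <- integer(0)
  for (j in cols) {
    P <- g$variants$pos[j]; ch <- g$variants$chrom[j]
    alt_h <- which(g$hap[, j] == 1L)
    cand <- which(sg$chrom == ch & abs(sg$pos - P) <= window & sg$hap %in% alt_h)
    del <- cand[runif(length(cand)) > keep]
    drop <- c(drop, sg$col[del])
  }
  if (length(drop))
    subset_variants(g, setdiff(seq_len(ncol(g$hap)), unique(drop)))
  else g
}

# Background polygenic trait drawn from a given relationship matrix.
polygenic_trait <- function(K, h2, seed) {
  set.seed(seed)
  n <- nrow(K)
  eig <- eigen(K, symmetric = TRUE)
  u <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * rnorm(n))
  as.numeric(sqrt(h2) * u / sd(u) + sqrt(1 - h2) * rnorm(n))
}
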