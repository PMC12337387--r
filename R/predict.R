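#' Haplotype-based polygenic prediction score (HPPS)
#'
#' Sums estimated fixed allele effects times allele dosages over the
#' significant blocks. \code{subset = "all"} uses every significantly
#' classified allele (BHA and UHA), \code{"bene"} only BHA and
#' \code{"unbe"} only UHA.
#'
#' @param effects a \code{haplotype_effects} table from
#'   \code{\link{estimate_allele_effects}}.
#' @param blocks the blocks the effects refer to (same block ids).
#' @param subset \code{"all"}, \code{"bene"} or \code{"unbe"}.
#' @return numeric per-individual score vector.
#' @export
hpps <- function(effects, blocks, subset = c("all", "bene", "unbe")) {
  subset <- match.arg(subset)
  want <- switch(subset, all = c("BHA", "UHA"), bene = "BHA", unbe = "UHA")
  eff <- effects[effects$class %in% want & !is.na(effects$effect), , drop = FALSE]
  n <- nrow(blocks[[1L]]$pair)
  if (nrow(eff) == 0L) {
    warning("no ", subset, " alleles; HPPS is zero for all individuals")
    return(numeric(n))
  }
  score <- numeric(n)
  ids <- vapply(blocks, `[[`, character(1), "id")
  for (i in seq_len(nrow(eff))) {
    b <- blocks[[match(eff$block[i], ids)]]
    d <- dosage_code(b)[, eff$allele[i]]
    score <- score + eff$effect[i] * d
  }
  score
}

#' Haplotype-based BLUP (ridge mixed model on allele dosages)
#'
#' Fits y = Q a + Z mu + e on the training individuals with
#' i.i.d. random allele effects mu ~ N(0, I s2_mu); the variance ratio
#' is estimated by REML through the eigendecomposition of Z Z', and the
#' BLUP of mu gives out-of-sample predictions Q a + Z mu for everyone.
#'
#' @param y trait values (training individuals; others NA or excluded
#'   via \code{train}).
#' @param Z dosage matrix of all alleles of the significant blocks
#'   (all individuals x alleles).
#' @param covariates optional covariate matrix (all individuals).
#' @param train integer/logical index of training individuals (default:
#'   all with non-missing y).
#' @return list with \code{prediction} (all individuals), \code{mu}
#'   (allele BLUPs), \code{alpha} (covariate effects), \code{s2_mu},
#'   \code{s2_e}.
#' @export
hblup_fit <- function(y, Z, covariates = NULL, train = NULL) {
  n <- nrow(Z)
  if (is.null(train)) train <- which(!is.na(y))
  if (is.logical(train)) train <- which(train)
  Xall <- build_design(n, covariates)
  Zt <- Z[train, , drop = FALSE]
  K <- tcrossprod(Zt)
  fit <- reml_fit(y[train], Xall[train, , drop = FALSE], K)
  # mu_hat = s2_mu Z' V^{-1} (y - X b) with V = s2_mu Z Z' + s2_e I;
  # in reml_fit's scale sg2 multiplies K = ZZ', so s2_mu = sg2.
  w <- fit$w / fit$sg2
  Vinv_r <- fit$U %*% (w * crossprod(fit$U, fit$resid_marginal))
  mu <- fit$sg2 * as.numeric(crossprod(Zt, Vinv_r))
  pred <- as.numeric(Xall %*% fit$beta) + as.numeric(Z %*% mu)
  list(prediction = pred, mu = mu, alpha = fit$beta,
       s2_mu = fit$sg2, s2_e = fit$se2)
}

#' Genomic BLUP with an arbitrary relationship matrix
#'
#' Standard GBLUP: variance components by REML on the training set,
#' genetic values for validation individuals predicted through the
#' genomic covariance between validation and training individuals,
#' K[val, train] V^{-1} (y - X b).
#'
#' @param y trait values.
#' @param grm N x N relationship matrix (SNP- or haplotype-based).
#' @param covariates optional covariate matrix.
#' @param train index of training individuals (default: non-missing y).
#' @return list with \code{prediction} (all N individuals),
#'   \code{s2_g}, \code{s2_e}.
#' @export
gblup_fit <- function(y, grm, covariates = NULL, train = NULL) {
  n <- nrow(grm)
  if (is.null(train)) train <- which(!is.na(y))
  if (is.logical(train)) train <- which(train)
  Xall <- build_design(n, covariates)
  K <- grm[train, train]
  fit <- reml_fit(y[train], Xall[train, , drop = FALSE], K)
  w <- fit$w / fit$sg2
  Vinv_r <- as.numeric(fit$U %*% (w * crossprod(fit$U, fit$resid_marginal)))
  ghat <- fit$sg2 * as.numeric(grm[, train, drop = FALSE] %*% Vinv_r)
  pred <- as.numeric(Xall %*% fit$beta) + ghat
  list(prediction = pred, s2_g = fit$sg2, s2_e = fit$se2)
}

#' Fixed-validation-set cross-validation of phenotype prediction
#'
#' Per repeat, a fixed validation set of \code{n_validation} individuals
#' is drawn and excluded from all training; the remainder is split into
#' \code{folds} folds, and each fold's model (discovery of significant
#' blocks, allele-effect estimation and variance components are all
#' re-fit inside the training data only) predicts the validation
#' phenotypes. The per-repeat accuracy is the mean Pearson correlation
#' between prediction and observed phenotype over folds, and the report
#' averages over repeats. A leakage guard raises a hard error if any
#' validation individual enters a training design.
#'
#' @param method one of \code{"hpps-all"}, \code{"hpps-bene"},
#'   \code{"hpps-unbe"}, \code{"hblup"}, \code{"gblup-snp"},
#'   \code{"gblup-hap"}.
#' @param y trait vector.
#' @param blocks haplotype blocks (needed by hpps/hblup/gblup-hap).
#' @param grm SNP GRM (needed by gblup-snp).
#' @param covariates optional covariate matrix.
#' @param n_validation validation-set size (default 100).
#' @param folds training folds per repeat (default 10).
#' @param repeats number of repeats (default 50).
#' @param seed integer seed.
#' @param alpha block-discovery significance level on the HGWAS q-value
#'   (falls back to raw p if no block passes FDR).
#' @param direction trait polarity for BHA/UHA classification.
#' @param reuse_discovery reuse whole-data discovery inside folds
#'   (leaks phenotype information; off by default, available for
#'   comparison).
#' @return object of class \code{cv_report}: per-repeat correlations and
#'   their mean.
#' @export
cross_validate <- function(method = c("hpps-all", "hpps-bene", "hpps-unbe",
                                      "hblup", "gblup-snp", "gblup-hap"),
                           y, blocks = NULL, grm = NULL, covariates = NULL,
                           n_validation = 100, folds = 10, repeats = 50,
                           seed = 1, alpha = 0.05, direction = 1,
                           reuse_discovery = FALSE) {
  method <- match.arg(method)
  n <- length(y)
  if (n <= n_validation + folds)
    stop("need more individuals than n_validation + folds")
  set.seed(derive_seed(seed, paste0("cv-", method)))
  H <- if (method %in% c("hblup", "gblup-hap") ||
           startsWith(method, "hpps")) hap_grm(blocks) else NULL
  if (method == "gblup-hap") grm <- H
  whole_scan <- NULL
  if (reuse_discovery && (startsWith(method, "hpps") || method == "hblup"))
    whole_scan <- hgwas_scan(y, blocks, H, covariates)

  rep_cor <- numeric(repeats)
  for (r in seq_len(repeats)) {
    val <- sample.int(n, n_validation)
    rest <- setdiff(seq_len(n), val)
    fold_id <- sample(rep_len(seq_len(folds), length(rest)))
    fold_cor <- numeric(folds)
    for (f in seq_len(folds)) {
      train <- rest[fold_id != f]
      if (length(intersect(train, val)))
        stop("leakage: validation individual in training design")
      pred <- cv_predict(method, y, train, blocks, grm, H, covariates,
                         alpha, direction, whole_scan)
      obs <- y[val]
      pv <- pred[val]
      fold_cor[f] <- if (sd(pv) == 0 || sd(obs) == 0) 0 else cor(pv, obs)
    }
    rep_cor[r] <- mean(fold_cor)
  }
  structure(list(method = method, correlations = rep_cor,
                 mean = mean(rep_cor), repeats = repeats,
                 n_validation = n_validation, folds = folds),
            class = "cv_report")
}

# One training fit + all-individual prediction for cross_validate.
cv_predict <- function(method, y, train, blocks, grm, H, covariates,
                       alpha, direction, whole_scan = NULL) {
  n <- length(y)
  y_tr <- rep(NA_real_, n)
  y_tr[train] <- y[train]
  cov_tr <- covariates
  if (method == "gblup-snp" || method == "gblup-hap")
    return(gblup_fit(y_tr, grm, covariates, train = train)$prediction)

  # discovery inside the training data only (unless explicitly reused)
  scan <- if (is.null(whole_scan)) {
    sub_blocks <- lapply(blocks, subset_block, idx = train)
    hg <- hap_grm(sub_blocks)
    cv <- if (is.null(covariates)) NULL else
      as.matrix(covariates)[train, , drop = FALSE]
    hgwas_scan(y[train], sub_blocks, hg, cv)
  } else whole_scan
  sig <- which(scan$q <= alpha)
  if (!length(sig)) sig <- which(scan$p <= alpha)
  if (!length(sig)) sig <- which.min(scan$p)
  sig <- sig[order(scan$p[sig])]   # strongest blocks first: they keep
                                   # their alleles if collinearity drops
  # cap the joint design well below n_train so the allele-effect model
  # never saturates inside a fold
  n_par <- cumsum(vapply(blocks[sig], function(b)
    max(length(b$alleles) - 1L, 1L), numeric(1)))
  sig <- sig[n_par <= max(length(train) %/% 3L, n_par[1L])]
  sig_blocks <- blocks[sig]

  if (method == "hblup") {
    Z <- do.call(cbind, lapply(sig_blocks, dosage_code))
    return(hblup_fit(y_tr, Z, covariates, train = train)$prediction)
  }
  # HPPS: effects estimated on training individuals, applied to all
  tr_blocks <- lapply(sig_blocks, subset_block, idx = train)
  cv <- if (is.null(covariates)) NULL else
    as.matrix(covariates)[train, , drop = FALSE]
  eff <- suppressWarnings(
    estimate_allele_effects(y[train], tr_blocks, cv,
                            alpha = alpha, direction = direction))
  subset <- sub("^hpps-", "", method)
  suppressWarnings(hpps(eff, sig_blocks, subset))
}

# Restrict a haplotype block to a subset of individuals (allele codes and
# frequencies are kept from the full catalogue so dosage columns align).
subset_block <- function(block, idx) {
  b <- block
  hr <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  b$hap_allele <- block$hap_allele[hr]
  b$pair <- block$pair[idx, , drop = FALSE]
  b
}

#' @export
#' @method print cv_report
print.cv_report <- function(x, ...) {
  cat("Cross-validation (", x$method, "): mean r = ",
      round(x$mean, 3), " over ", x$repeats, " repeat(s), ",
      "validation n = ", x$n_validation, ", ", x$folds, "-fold\n", sep = "")
  invisible(x)
}
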