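#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. The defaults are
#' the study conditions the rest of the package is validated against:
#' a laying cycle observed weekly from 21 to 43 weeks of age (161 days),
#' a Yang-Ning mean curve with the fitted parameters a = 0.837,
#' b = 0.015, c = 1.182, d = 2.621 (model time t = week - 20), and
#' founder-pool haplotype copying that creates block-scale linkage
#' disequilibrium.
#'
#' @param n_individuals number of diploid individuals.
#' @param n_snps_per_chrom polymorphic sites simulated per chromosome
#'   (before singleton injection).
#' @param n_chroms number of chromosomes.
#' @param chrom_length_bp chromosome length in base pairs.
#' @param mutation_density expected private singleton mutations per
#'   haplotype per megabase.
#' @param recombination_prob per-SNP probability of switching founder
#'   template while copying a haplotype.
#' @param n_founders size of the founder haplotype pool.
#' @param qtl_list list of QTL specifications from \code{\link{qtl_spec}}.
#' @param curve_params named vector \code{c(a, b, c, d)} of the Yang-Ning
#'   mean laying-rate curve; \code{a} is the maximum rate in [0, 1],
#'   \code{b} the weekly decline rate, \code{c} the weekly increase rate
#'   and \code{d} the model-time of first egg in weeks.
#' @param h2_target fraction of individual-level variance in weekly laying
#'   probability that is genetic, in [0, 1].
#' @param ind_sd total standard deviation of individual deviations
#'   (genetic + permanent environment) on the probability scale.
#' @param n_background_loci number of random background SNPs given small
#'   normal effects to create a polygenic term (0 = none).
#' @param seed integer seed; identical configurations and seeds give
#'   bit-identical output.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_individuals = 600, n_snps_per_chrom = 500,
                       n_chroms = 2, chrom_length_bp = 5e6,
                       mutation_density = 2, recombination_prob = 0.05,
                       n_founders = 8, qtl_list = list(),
                       curve_params = c(a = 0.837, b = 0.015,
                                        c = 1.182, d = 2.621),
                       h2_target = 0.4, ind_sd = 0.12,
                       n_background_loci = 0, seed = 1) {
  stopifnot(n_individuals >= 0, n_snps_per_chrom >= 0, n_chroms >= 1,
            chrom_length_bp > 0, mutation_density >= 0,
            recombination_prob >= 0, recombination_prob <= 1,
            n_founders >= 2, h2_target >= 0, h2_target <= 1, ind_sd >= 0)
  cp <- curve_params
  if (is.null(names(cp))) names(cp) <- c("a", "b", "c", "d")
  if (cp[["a"]] < 0 || cp[["a"]] > 1) stop("curve parameter a must be in [0,1]")
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_snps_per_chrom = as.integer(n_snps_per_chrom),
              n_chroms = as.integer(n_chroms),
              chrom_length_bp = as.integer(chrom_length_bp),
              mutation_density = mutation_density,
              recombination_prob = recombination_prob,
              n_founders = as.integer(n_founders),
              qtl_list = qtl_list, curve_params = cp,
              h2_target = h2_target, ind_sd = ind_sd,
              n_background_loci = as.integer(n_background_loci),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' QTL specification
#'
#' @param chrom chromosome label (e.g. \code{"chr1"}).
#' @param index 1-based index of the SNP on that chromosome (among the
#'   non-singleton sites, in position order), or the block index when
#'   \code{kind = "haplotype-allele"}.
#' @param effect additive effect in trait units per allele copy (for
#'   haplotype-allele QTLs, per copy of the chosen block allele).
#' @param kind \code{"snp"} or \code{"haplotype-allele"}.
#' @return an object of class \code{qtl_spec}.
#' @export
qtl_spec <- function(chrom, index, effect, kind = c("snp", "haplotype-allele")) {
  kind <- match.arg(kind)
  structure(list(chrom = chrom, index = as.integer(index),
                 effect = effect, kind = kind), class = "qtl_spec")
}

#' Simulate phased haplotypes with linkage disequilibrium
#'
#' Haplotypes are produced by copying from a small founder pool with
#' per-SNP template switching (probability
#' \code{config$recombination_prob}), which creates block-scale LD
#' without an external coalescent simulator. Private singleton mutations
#' are then injected as separate sites at a Poisson rate of
#' \code{mutation_density} per haplotype per Mb; their ground truth
#' (carrier haplotype and position) is attached as the
#' \code{"singletons"} attribute so the singleton finder can be checked
#' exactly.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{\link{phased_genotypes}} object; the variant table has
#'   an \code{is_singleton} column, and the attribute \code{"singletons"}
#'   records (col, chrom, pos, hap) for every injected singleton.
#' @export
simulate_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_individuals < 1L || config$n_snps_per_chrom < 1L)
    stop("invalid config: need at least one individual and one SNP")
  set.seed(derive_seed(config$seed, "haplotypes"))
  n <- config$n_individuals
  nh <- 2L * n
  per_chrom <- vector("list", config$n_chroms)
  for (ci in seq_len(config$n_chroms)) {
    m <- config$n_snps_per_chrom
    pos <- sort(sample.int(config$chrom_length_bp, m))
    fq <- runif(m, 0.1, 0.9)
    founders <- matrix(rbinom(config$n_founders * m, 1L, rep(fq, each = config$n_founders)),
                       nrow = config$n_founders)
    # copy haplotypes from the founder pool with template switching
    hap <- matrix(0L, nrow = nh, ncol = m)
    for (h in seq_len(nh)) {
      tmpl <- sample.int(config$n_founders, 1L)
      if (config$recombination_prob > 0) {
        sw <- runif(m) < config$recombination_prob
        tmpl_seq <- integer(m)
        cur <- tmpl
        for (j in seq_len(m)) {
          if (sw[j]) cur <- sample.int(config$n_founders, 1L)
          tmpl_seq[j] <- cur
        }
        hap[h, ] <- founders[cbind(tmpl_seq, seq_len(m))]
      } else {
        hap[h, ] <- founders[tmpl, ]
      }
    }
    # private singleton mutations at new sites, never reused
    lambda <- config$mutation_density * config$chrom_length_bp / 1e6
    n_sing <- rpois(nh, lambda)
    tot <- sum(n_sing)
    if (tot > 0L) {
      avail <- setdiff(seq_len(config$chrom_length_bp), pos)
      spos <- sample(avail, tot)
      carrier <- rep(seq_len(nh), n_sing)
      o <- order(spos)
      spos <- spos[o]; carrier <- carrier[o]
      smat <- matrix(0L, nrow = nh, ncol = tot)
      smat[cbind(carrier, seq_len(tot))] <- 1L
      allpos <- c(pos, spos)
      is_sing <- c(rep(FALSE, m), rep(TRUE, tot))
      carr <- c(rep(NA_integer_, m), carrier)
      o <- order(allpos)
      per_chrom[[ci]] <- list(pos = allpos[o],
                              hap = cbind(hap, smat)[, o, drop = FALSE],
                              is_singleton = is_sing[o], carrier = carr[o])
    } else {
      per_chrom[[ci]] <- list(pos = pos, hap = hap,
                              is_singleton = rep(FALSE, m),
                              carrier = rep(NA_integer_, m))
    }
  }
  chroms <- paste0("chr", seq_len(config$n_chroms))
  variants <- do.call(rbind, lapply(seq_along(per_chrom), function(ci) {
    pc <- per_chrom[[ci]]
    data.frame(chrom = chroms[ci], pos = pc$pos,
               ref = "A", alt = "T",
               id = paste0(chroms[ci], "_", pc$pos),
               is_singleton = pc$is_singleton,
               stringsAsFactors = FALSE)
  }))
  hap <- do.call(cbind, lapply(per_chrom, `[[`, "hap"))
  cl <- setNames(rep(config$chrom_length_bp, config$n_chroms), chroms)
  g <- phased_genotypes(paste0("ind", seq_len(n)), variants, hap, cl)
  carrier <- unlist(lapply(per_chrom, `[[`, "carrier"))
  sg <- which(variants$is_singleton)
  attr(g, "singletons") <- data.frame(col = sg, chrom = variants$chrom[sg],
                                      pos = variants$pos[sg],
                                      hap = carrier[sg])
  g
}

# Resolve QTL specs to haplotype-matrix columns / block descriptors and
# compute each individual's raw genetic value.
qtl_genetic_values <- function(g, qtl_list, block_size = 5L) {
  n <- n_individuals(g)
  gv <- numeric(n)
  details <- list()
  ns_idx <- which(!g$variants$is_singleton)  # pruned-set indexing
  for (q in qtl_list) {
    on_chrom <- ns_idx[g$variants$chrom[ns_idx] == q$chrom]
    if (q$kind == "snp") {
      if (q$index < 1L || q$index > length(on_chrom))
        stop("unknown QTL locus: ", q$chrom, " index ", q$index)
      col <- on_chrom[q$index]
      dos <- hap_to_dosage(g$hap[, col, drop = FALSE])[, 1L]
      gv <- gv + q$effect * dos
      details[[length(details) + 1L]] <-
        list(kind = "snp", chrom = q$chrom, col = col,
             pos = g$variants$pos[col], effect = q$effect)
    } else {
      nb <- length(on_chrom) %/% block_size
      if (q$index < 1L || q$index > nb)
        stop("unknown QTL block: ", q$chrom, " block ", q$index)
      cols <- on_chrom[((q$index - 1L) * block_size + 1L):(q$index * block_size)]
      seqs <- apply(g$hap[, cols, drop = FALSE], 1L, paste0, collapse = "")
      tab <- sort(table(seqs), decreasing = TRUE)
      # the most frequent non-majority allele carries the effect
      target <- names(tab)[min(2L, length(tab))]
      carries <- as.integer(seqs == target)
      dos <- carries[seq(1L, 2L * n, 2L)] + carries[seq(2L, 2L * n, 2L)]
      gv <- gv + q$effect * dos
      details[[length(details) + 1L]] <-
        list(kind = "haplotype-allele", chrom = q$chrom, block = q$index,
             cols = cols, allele_seq = target,
             pos = g$variants$pos[cols[1L]], effect = q$effect)
    }
  }
  list(gv = gv, details = details)
}

#' Simulate daily laying records
#'
#' Each individual's weekly laying probability is the Yang-Ning mean
#' curve evaluated at model time t = week - 20, plus an additive
#' individual deviation split into a genetic part (planted QTLs and
#' optional polygenic background, rescaled so its share of the deviation
#' variance is \code{h2_target}) and a normal permanent-environment
#' part, clamped to [0, 1]. Daily records are independent Bernoulli
#' draws at that weekly probability; week w covers days
#' 7(w-21)+1 ... 7(w-21)+7, so weeks 21-43 span 161 days.
#'
#' @param genotypes a \code{\link{phased_genotypes}} from
#'   \code{\link{simulate_haplotypes}}.
#' @param config the same \code{\link{sim_config}}.
#' @return a \code{\link{laying_records}} object with attributes
#'   \code{"genetic_value"} (true scaled genetic values),
#'   \code{"qtl"} (resolved planted-QTL details) and
#'   \code{"weekly_prob"} (N x 23 matrix of true weekly probabilities).
#' @export
simulate_laying_records <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genotypes, "phased_genotypes"))
  set.seed(derive_seed(config$seed, "laying"))
  n <- n_individuals(genotypes)
  cp <- config$curve_params
  weeks <- 21:43
  base <- yangning(weeks - 20, cp[["a"]], cp[["b"]], cp[["c"]], cp[["d"]])

  qd <- qtl_genetic_values(genotypes, config$qtl_list)
  gv <- qd$gv
  if (config$n_background_loci > 0L) {
    ns_idx <- which(!genotypes$variants$is_singleton)
    bg <- sample(ns_idx, min(config$n_background_loci, length(ns_idx)))
    eff <- rnorm(length(bg))
    dos <- hap_to_dosage(genotypes$hap[, bg, drop = FALSE])
    gv <- gv + as.numeric(dos %*% eff)
  }
  sd_g <- sqrt(config$h2_target) * config$ind_sd
  sd_e <- sqrt(1 - config$h2_target) * config$ind_sd
  if (sd(gv) > 0 && sd_g > 0) gv <- (gv - mean(gv)) / sd(gv) * sd_g
  else gv <- rep(0, n)
  ev <- rnorm(n, 0, sd_e)

  p <- clamp(outer(gv + ev, rep(1, length(weeks))) +
               outer(rep(1, n), base))
  rec <- matrix(0L, nrow = n, ncol = 161L)
  for (wi in seq_along(weeks)) {
    days <- (7L * (wi - 1L) + 1L):(7L * wi)
    rec[, days] <- rbinom(n * 7L, 1L, rep(p[, wi], 7L))
  }
  out <- laying_records(genotypes$samples, rec)
  attr(out, "genetic_value") <- gv
  attr(out, "env_value") <- ev
  attr(out, "qtl") <- qd$details
  attr(out, "weekly_prob") <- p
  out
}

#' Simulate drifted population panels
#'
#' Each panel resamples haplotypes from the base cohort (preserving LD),
#' then shifts every site's alternative-allele frequency by an
#' independent bounded random walk step \code{drift * U(-1, 1)} (clamped
#' to [0, 1]) by flipping randomly chosen haplotype entries. With
#' \code{drift = 0} a panel is a plain haplotype resample of the base.
#'
#' @param base a \code{\link{phased_genotypes}} cohort.
#' @param n_pops number of panels.
#' @param drift magnitude of the frequency random walk, in [0, 1]; the
#'   expected absolute frequency shift per locus is \code{drift / 2}
#'   before clamping.
#' @param n_per_pop individuals sampled per panel.
#' @param seed integer seed.
#' @return list of \code{n_pops} \code{phased_genotypes} panels.
#' @export
simulate_population_panel <- function(base, n_pops, drift = 0.1,
                                      n_per_pop = 50, seed = 1) {
  stopifnot(inherits(base, "phased_genotypes"))
  if (n_pops < 1) stop("invalid config: n_pops must be >= 1")
  if (drift < 0 || drift > 1) stop("drift must be in [0, 1]")
  set.seed(derive_seed(seed, "panels"))
  nh_base <- nrow(base$hap)
  m <- ncol(base$hap)
  lapply(seq_len(n_pops), function(k) {
    nh <- 2L * n_per_pop
    hap <- base$hap[sample.int(nh_base, nh, replace = TRUE), , drop = FALSE]
    if (drift > 0) {
      delta <- drift * runif(m, -1, 1)
      cur <- colSums(hap)
      target <- round(clamp(cur / nh + delta) * nh)
      for (j in which(target != cur)) {
        d <- target[j] - cur[j]
        if (d > 0L) {
          z <- which(hap[, j] == 0L)
          hap[z[sample.int(length(z), min(d, length(z)))], j] <- 1L
        } else {
          o <- which(hap[, j] == 1L)
          hap[o[sample.int(length(o), min(-d, length(o)))], j] <- 0L
        }
      }
    }
    phased_genotypes(paste0("pop", k, "_ind", seq_len(n_per_pop)),
                     base$variants, hap, base$chrom_lengths)
  })
}

#' Simulate sites with a neutral frequency spectrum
#'
#' Generates unlinked biallelic sites whose derived-allele counts follow
#' the standard neutral site-frequency spectrum (P(k) proportional to
#' 1/k, k = 1 ... 2N-1), with carriers assigned uniformly at random.
#' Under this spectrum the pairwise-diversity and segregating-site
#' estimators of the population mutation rate agree in expectation, so
#' windowed Tajima's D is centred at zero — the calibration fixture for
#' the diversity statistics. No linkage disequilibrium is generated.
#'
#' @param n_individuals number of diploid individuals.
#' @param n_sites number of segregating sites.
#' @param chrom_length_bp chromosome length; positions are uniform.
#' @param seed integer seed.
#' @return a \code{\link{phased_genotypes}} on one chromosome.
#' @export
simulate_neutral_sites <- function(n_individuals, n_sites,
                                   chrom_length_bp = 1e6, seed = 1) {
  stopifnot(n_individuals >= 2, n_sites >= 1)
  set.seed(derive_seed(seed, "neutral-sfs"))
  nh <- 2L * n_individuals
  pos <- sort(sample.int(chrom_length_bp, n_sites))
  k <- sample(seq_len(nh - 1L), n_sites, replace = TRUE,
              prob = 1 / seq_len(nh - 1L))
  hap <- matrix(0L, nh, n_sites)
  for (j in seq_len(n_sites))
    hap[sample.int(nh, k[j]), j] <- 1L
  variants <- data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T",
                         id = paste0("chr1_", pos),
                         stringsAsFactors = FALSE)
  phased_genotypes(paste0("ind", seq_len(n_individuals)), variants, hap,
                   c(chr1 = chrom_length_bp))
}

#' Write simulation ground truth as JSON
#'
#' @param records a \code{\link{laying_records}} from
#'   \code{\link{simulate_laying_records}}.
#' @param config the \code{\link{sim_config}} used.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_truth_json <- function(records, config, path) {
  truth <- list(seed = config$seed,
                h2_target = config$h2_target,
                curve_params = as.list(config$curve_params),
                qtl = attr(records, "qtl"),
                genetic_value = setNames(as.list(attr(records, "genetic_value")),
                                         records$samples))
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
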