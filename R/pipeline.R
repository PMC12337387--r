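#' End-to-end demonstration pipeline on synthetic data
#'
#' Generates a synthetic cohort, then runs every stage of the analysis:
#' curve fitting and model selection, stage segmentation at the
#' stationary point, derived-trait construction with the 3-sigma filter,
#' SNP- and haplotype-block association scans, canonical-correlation
#' scan, haplotype-allele effect estimation and BHA/UHA classification,
#' cross-validated prediction, two-component variance explained,
#' selection statistics (rSDS/tSDS/Tajima's D/pi) and population
#' enriched scores. Writes a markdown report plus TSV/VCF/BED artefacts
#' into \code{out_dir}. One master seed drives every stage through
#' per-stage derived seeds.
#'
#' @param n_individuals cohort size (default 300 for a quick demo).
#' @param n_snps_per_chrom SNPs per chromosome (default 500).
#' @param seed master seed.
#' @param out_dir output directory (default a tempdir subdirectory).
#' @param cv_repeats cross-validation repeats (default 3 for the demo).
#' @return invisibly, a list with the main result objects; the report
#'   path is the \code{"report"} attribute.
#' @export
run_demo <- function(n_individuals = 300, n_snps_per_chrom = 500, seed = 1,
                     out_dir = file.path(tempdir(), "layscan_demo"),
                     cv_repeats = 3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lines <- c("# layscan demo pipeline", "",
             sprintf("seed %d, %d individuals, %d SNPs/chromosome", seed,
                     n_individuals, n_snps_per_chrom), "")
  say <- function(...) lines <<- c(lines, sprintf(...))

  cfg <- sim_config(n_individuals = n_individuals,
                    n_snps_per_chrom = n_snps_per_chrom,
                    qtl_list = list(qtl_spec("chr1", 100, 0.08),
                                    qtl_spec("chr2", 30, 0.06,
                                             kind = "haplotype-allele")),
                    h2_target = 0.4, seed = seed)
  g <- simulate_haplotypes(cfg)
  rec <- simulate_laying_records(g, cfg)
  write_phased_vcf(g, file.path(out_dir, "genotypes.vcf"))
  write_laying_tsv(rec, file.path(out_dir, "laying.tsv"))
  write_truth_json(rec, cfg, file.path(out_dir, "truth.json"))

  ## curves
  weekly <- colMeans(vapply(21:43, function(w)
    rowMeans(rec$matrix[, stage_days(w), drop = FALSE]), numeric(n_individuals)))
  sel <- select_curve_model(weekly)
  say("## Laying-rate curve\n")
  say("BIC: %s", paste(names(sel$bic), round(sel$bic, 2),
                       sep = " = ", collapse = ", "))
  sp <- stationary_point(sel$fits$yangning)
  say("stationary point: %.1f weeks of age", sp)
  stages <- segment_stages(sp)

  ## traits
  traits <- remove_outliers_3sigma(derive_traits(rec, stages))
  write_trait_tsv(traits, file.path(out_dir, "traits.tsv"))
  say("\n## Derived traits\n")
  say("%d traits x %d individuals; %d outlier values removed",
      ncol(traits), nrow(traits), sum(attr(traits, "n_removed")))

  ## association scans on up-stage ECI
  y <- traits[["up-ECI"]]
  grm <- compute_grm(g)
  pcs <- compute_pcs(grm, k = min(10, n_individuals - 1))
  scan <- snp_scan(y, g, grm, covariates = pcs)
  write_assoc_tsv(scan, file.path(out_dir, "snp_scan_up-ECI.tsv"))
  say("\n## SNP scan (up-ECI)\n")
  say("top SNP: %s p = %.3g (q = %.3g)", scan$id[which.min(scan$p)],
      min(scan$p, na.rm = TRUE), min(scan$q, na.rm = TRUE))

  blocks <- build_blocks(g)
  H <- hap_grm(blocks)
  hscan <- hgwas_scan(y, blocks, H, covariates = pcs)
  write_assoc_tsv(hscan, file.path(out_dir, "hap_scan_up-ECI.tsv"))
  say("\n## Haplotype-block scan (up-ECI)\n")
  say("top block: %s p = %.3g", hscan$block[which.min(hscan$p)],
      min(hscan$p, na.rm = TRUE))

  sig <- which(hscan$q <= 0.05)
  if (!length(sig)) sig <- order(hscan$p)[1:3]
  eff <- suppressWarnings(
    estimate_allele_effects(y, blocks[sig], covariates = pcs))
  say("alleles: %d BHA, %d UHA", sum(eff$class == "BHA"),
      sum(eff$class == "UHA"))

  ## CCA on the up-stage traits
  up_traits <- traits[, grep("^up-", colnames(traits))]
  up_traits <- up_traits[, colSums(!is.na(up_traits)) == nrow(up_traits),
                         drop = FALSE]
  cres <- if (ncol(up_traits) >= 2) cca_scan(g, up_traits) else NULL
  if (!is.null(cres)) {
    write_assoc_tsv(cres, file.path(out_dir, "cca_scan_up.tsv"))
    say("\n## CCA scan (up-stage, %d traits)\n", ncol(up_traits))
    say("top SNP rho = %.3f, p = %.3g", cres$rho[which.min(cres$p)],
        min(cres$p, na.rm = TRUE))
  }

  ## prediction
  cv <- cross_validate("hpps-all", y = mean_fill(traits)[["up-ECI"]],
                       blocks = blocks, covariates = pcs,
                       n_validation = max(20, round(n_individuals / 6)),
                       folds = 5, repeats = cv_repeats, seed = seed)
  say("\n## Prediction\n")
  say("HPPS_all mean CV correlation: %.3f", cv$mean)

  ## variance components
  sig_snp <- which(!is.na(scan$q) & scan$q <= 0.05)
  if (!length(sig_snp)) sig_snp <- order(scan$p)[1:20]
  ns <- which(!g$variants$is_singleton)
  vc <- emreml_two_grm(y, grm_from_loci(g, ns[sig_snp]),
                       grm_from_loci(g, ns[-sig_snp]), covariates = pcs)
  say("\n## Variance explained\n")
  say("PVE(sig) = %.1f%%, genome-wide PVE = %.1f%%", 100 * vc$pve_sig,
      100 * vc$pve_genomewide)

  ## selection statistics
  sds <- standardize_sds(raw_sds(g), min_bin = 5)
  msds <- msds_windows(sds)
  write_window_bed(msds, file.path(out_dir, "msds.bed"))
  tp <- tsds_polarize(sds, scan)
  trend <- tryCatch(tsds_trend(tp$tsds, tp$assoc_p,
                               bin_size = max(10, nrow(tp) %/% 20)),
                    error = function(e) NULL)
  dw <- tajima_pi_windows(g)
  write_window_bed(dw, file.path(out_dir, "tajima_pi.bed"))
  say("\n## Selection\n")
  say("%d SNPs scored; mean Tajima's D = %.3f; mean pi = %.3g/bp",
      nrow(sds), mean(dw$tajima_d, na.rm = TRUE), mean(dw$pi))
  if (!is.null(trend)) say("tSDS trend rho = %.3f", trend$rho)

  ## population enriched scores
  panels <- simulate_population_panel(g, n_pops = 5, drift = 0.1,
                                      seed = seed)
  es <- enriched_score(eff, blocks[sig], panels, "BHA")
  say("\n## Enriched scores (BHA)\n")
  say("E by population: %s", paste(round(es$E, 3), collapse = ", "))

  report <- file.path(out_dir, "report.md")
  writeLines(lines, report)
  message("demo report written to ", report)
  out <- list(config = cfg, curve = sel, stages = stages, traits = traits,
              snp_scan = scan, hap_scan = hscan, effects = eff, cv = cv,
              varcomp = vc, sds = sds, trend = trend, windows = dw,
              enriched = es)
  attr(out, "report") <- report
  invisible(out)
}
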