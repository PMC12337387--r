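# layscan

Genetic dissection of egg-production efficiency in laying hens, from
daily laying records and phased genotypes.

Egg production over a laying cycle is not one number: the rate climbs
steeply after onset of lay, peaks, and declines slowly, and hens with
the same total egg count can differ widely in persistency and rhythm.
`layscan` implements an analysis pipeline built around that structure:

* **Laying-curve models** — fits the Wood
  ($y_t = a t^b e^{-ct}$), compartmental
  ($y_t = a(1-e^{-c(t-d)})e^{-bt}$) and Yang–Ning
  ($y_t = a e^{-bt}/(1+e^{-c(t-d)})$) curves to weekly mean rates,
  ranks them by BIC, locates the Yang–Ning stationary point in closed
  form ($t^* = d + \ln((c-b)/b)/c$, model time = week − 20) and splits
  the cycle into up- and sustained-stages at its floor.
* **Derived traits** — 13 production, clutch and interval traits per
  stage from daily 0/1 records (ECI, CPN, TCS, LIT, AILI/TILI/MILI, II,
  EV/WEV/BWEV, WMLR/BWMLR), with a single-pass 3σ outlier filter.
* **Association scans** — single-SNP mixed linear model
  ($y = Q\alpha + x\beta + g + e$, EMMAX-style one-null-fit REML with a
  VanRaden GRM and PC covariates, BH-FDR); haplotype-block scan over
  5-SNP blocks with a Ferdosi-style haplotype relationship matrix
  ($H = K\Gamma K'/2$, $K = I\otimes[1\,1]$) and a calibrated two-step
  test; multi-trait canonical-correlation scan with Bartlett's
  chi-square; genotype×stage interaction tests with emmeans post-hoc
  contrasts.
* **Haplotype-based prediction** — allele-effect estimation with
  BHA/UHA classification, HPPS scores, HBLUP and GBLUP, under a
  leakage-guarded fixed-validation-set cross-validation protocol.
* **Variance explained** — two-component EM-REML
  ($y = Z_1\mu_1 + Z_2\mu_2 + e$) giving the PVE of significant versus
  insignificant loci.
* **Selection statistics** — singleton-density scores (gap-ratio rSDS,
  frequency-bin standardization, 50-kb mSDS windows), trait-polarized
  tSDS with the 1,000-SNP-bin Spearman trend test, and windowed
  Tajima's D and π.
* **Population enriched scores** — $E_k = \sum_n f_{nk}$, the summed
  panel frequencies of a trait's beneficial (or unbeneficial) haplotype
  alleles.
* **A synthetic-data generator** — phased haplotypes with founder-pool
  LD, recorded singleton ground truth, planted SNP/haplotype QTLs and
  Bernoulli daily laying records driven by the Yang–Ning curve, so
  every stage of the pipeline can be validated against known truth.

## Worked example

Simulate a 300-bird cohort with one planted SNP QTL, fit the laying
curve, derive traits, and scan:

```r
library(layscan)

cfg <- sim_config(n_individuals = 300, n_snps_per_chrom = 400,
                  n_chroms = 2,
                  qtl_list = list(qtl_spec("chr1", 200, 1)),
                  h2_target = 0.25, seed = 7)
g   <- simulate_haplotypes(cfg)
rec <- simulate_laying_records(g, cfg)

weekly <- colMeans(sapply(21:43, function(w)
  rowMeans(rec$matrix[, layscan:::stage_days(w)])))
sel <- select_curve_model(weekly)
sel$fits$yangning
#> Laying-rate curve fit (yangning model)
#>   parameters: a = 0.8216, b = 0.01502, c = 1.147, d = 2.63
#>   RSS = 0.001122  BIC = -215.81
#>   stationary point at 26.4 weeks of age
round(sel$bic, 2)
#>      yangning compartmental          wood
#>       -215.81       -155.53       -125.13
```

The Yang–Ning model wins the BIC comparison, and its stationary point
(26.4 weeks in this replicate) splits the cycle into the up-stage
(weeks 21–26) and sustained-stage (27–43). Deriving the stage traits
and scanning up-stage effective clutch intensity (ECI):

```r
stages <- segment_stages(stationary_point(sel$fits$yangning))
traits <- remove_outliers_3sigma(derive_traits(rec, stages))

grm  <- compute_grm(g)
scan <- snp_scan(traits[["up-ECI"]], g, grm,
                 covariates = compute_pcs(grm, 10))
scan
#> Association scan: 800 tests; 0 significant at FDR 0.05
#>  chrom     pos           id     af    beta     se         p      q
#>   chr1 2424542 chr1_2424542 0.1583  0.8043 0.2168 0.0002504 0.1810
#>   chr1 4359629 chr1_4359629 0.1400 -0.5920 0.2011 0.0035117 0.6945
#>   ...
attr(rec, "qtl")[[1]]$pos
#> [1] 2424542
```

The top-ranked SNP is exactly the planted QTL: its positive `beta`
(0.80 ECI units per alternative-allele copy) reflects the planted
laying-probability effect propagating into clutch intensity. At n = 300
with a single derived trait the hit does not clear FDR 0.05 — the
q-value column is doing its job — while the genome-wide rank already
identifies the locus.

`run_demo()` chains every stage (curves → traits → SNP/haplotype/CCA
scans → prediction → variance components → selection → enriched scores)
on synthetic data and writes a markdown report plus VCF/TSV/BED
artefacts.

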