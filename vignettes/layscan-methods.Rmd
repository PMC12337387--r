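---
title: "Models and methods behind layscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind layscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

layscan dissects egg-production efficiency in laying hens from two raw
inputs: daily 0/1 laying records over weeks 21–43 of age and phased
biallelic genotypes. This vignette explains each model in the pipeline,
the assumptions it makes, the tunable parameters, and the design choices
taken where the methodology was genuinely open.

## The laying-rate curve and the stage split

The mean weekly laying rate of a flock rises steeply after onset of lay
and then declines slowly. Three classical models are fitted by bounded
nonlinear least squares (`fit_laying_curve()`), all in model time
$t$ = week of age − 20, so $t = 1 \dots 23$ spans weeks 21–43:

* Wood: $y_t = a\,t^b e^{-ct}$
* compartmental: $y_t = a(1 - e^{-c(t-d)})\,e^{-bt}$
* Yang–Ning: $y_t = a\,e^{-bt} / (1 + e^{-c(t-d)})$

In the Yang–Ning model $a \in [0,1]$ is the maximum potential laying
rate, $b$ the weekly decline rate, $c$ the weekly increase rate and $d$
the model time of first egg (weeks). **The time offset matters**: with
the published parameter estimates ($a=0.837$, $b=0.015$, $c=1.182$,
$d=2.621$) the stationary point
$t^* = d + \ln((c-b)/b)/c$ equals 6.30, which is a biologically sensible
26.3 weeks of age only when $t$ counts weeks since week 20. `layscan`
therefore fixes $t$ = week − 20 everywhere.

The optimiser is Levenberg–Marquardt (`minpack.lm::nls.lm`) from a fixed
multi-start grid ($a \in \{0.5, 0.8, 1.0\}$, $b \in \{0.005, 0.02,
0.05\}$, $c \in \{0.5, 1, 2\}$, $d \in \{1, 3, 5\}$), with box bounds
keeping $a \le 1.5$, $b \ge 0$ and $c > 0$; the best start by residual
sum of squares wins, and a fit that lands on a bound is flagged
(`boundary = TRUE`) rather than silently accepted. Model selection uses
the standard least-squares (Gaussian-residual) form
$\mathrm{BIC} = n\ln(\mathrm{RSS}/n) + k\ln n$ with $k$ parameters.

`stationary_point()` uses the closed form above (returning `NA` for
monotone curves, i.e. $b \le 0$ or $b \ge c$), and `segment_stages()`
splits the cycle at its floor: up-stage = weeks 21…⌊$t^*+20$⌋,
sustained-stage = the remainder through week 43. The 26.3-week optimum
thus reproduces the canonical 21–26 / 27–43 / 21–43 stage split.

## Derived traits

Thirteen traits are computed per stage (`derive_traits()`), in three
families:

* **production** — EV (variance of weekly egg counts), WMLR (max weekly
  eggs / 7), WEV (variance of weekly laying rate), BWMLR and BWEV
  (bi-weekly analogues over consecutive week pairs; a trailing odd week
  is dropped);
* **clutch** — CPN (number of clutches; a clutch is a maximal run of
  laying days), TCS (total eggs in clutches — equal to the stage's total
  eggs), ECI (eggs in clutches of length ≥ 2 divided by the number of
  such clutches);
* **interval** — LIT (days from first to last egg, inclusive), AILI /
  TILI / MILI (mean / total / maximum interval length, where intervals
  are non-laying runs strictly between the first and last egg), and II
  (number of intervals divided by the number of eligible clutches).

Two conventions are deliberate interpretations, since the original
supplementary definitions are not part of the inputs this package was
built from: EV-family traits operate on weekly (bi-weekly) counts and
rates, and LIT is the first-to-last-egg span. Pre-onset and post-cessation
zeros are excluded from intervals because they reflect sexual maturity
and moult, not laying rhythm. An individual with no clutch of length
≥ 2 gets missing ECI/II; a bird with no intervals gets AILI = TILI =
MILI = 0. Outlier removal (`remove_outliers_3sigma()`) is a single
pass of the mean ± 3 SD rule per trait column — no iteration, since
iterating would make the retained-sample definition depend on the
removal order.

`trait_directions()` records each trait's desirable direction (e.g.
ECI higher-is-better, TILI lower-is-better; variability traits are
coded lower-is-better). That registry sets the polarity used to call
haplotype alleles beneficial or unbeneficial.

## Association scans

**Single-SNP scan** (`snp_scan()`): the mixed linear model
$y = Q\alpha + x\beta + g + e$ with $g \sim N(0, G\sigma_g^2)$, $G$ the
VanRaden genomic relationship matrix. Variance components are estimated
once by REML under the null on the eigen-rotated model, and every SNP is
then tested by generalized least squares with components fixed — the
one-null-fit approximation popularised by EMMAX/fastGWA. The per-SNP
test rescales by the residual sum of squares, so with an identity GRM it
reduces exactly to the OLS t-test. Covariates default to an intercept;
the top 10 PCs of the GRM (`compute_pcs()`, deterministic sign
convention) and a batch indicator are the intended additions for real
cohorts. Multiplicity is controlled by Benjamini–Hochberg FDR at 0.05.

**Haplotype-block scan** (`hgwas_scan()`): chromosomes are cut into
non-overlapping blocks of five consecutive SNPs (`build_blocks()`;
trailing remainders are dropped), each individual is coded by its
unordered pair of block alleles, and levels carried by fewer than five
individuals are pooled into a "rare" level to keep the design
estimable. The genetic covariance is the Ferdosi-style haplotype
relationship matrix: per block, $\Gamma_i$ scores haplotype-allele
identity 0/1; $\Gamma$ averages over blocks; and
$H = K\Gamma K'/2$ with $K = I_m \otimes [1\,1]$ collapses the two
haplotypes of each individual (computed blockwise as
$\sum_i D_iD_i'/(2n)$ with $D_i$ the allele-dosage matrix, which is
algebraically identical and far cheaper). Diagonal entries of $H$ run
from 1 (heterozygous at every block) to 2 (homozygous everywhere).

The block test is two-step: one null REML fit with $H$, then per-block
F-tests with the null components held fixed. Two implementation
decisions depart from the simplest reading of the recipe, for
statistical reasons established during development:

* step 2 runs on *variance-whitened* data (GLS under the null
  covariance) rather than on raw model residuals — raw-residual
  regressions (the GRAMMAR shortcut) are miscalibrated under strong
  relatedness, while the whitened form keeps exact type-I control at
  the same cost;
* the null covariance is leave-one-chromosome-out (LOCO) by default —
  with a genome-wide $H$, a strong causal block is partially absorbed
  into its own polygenic term and its test signal shrinks, which at
  desk scale can erase a deterministic block effect entirely.
  Single-chromosome inputs fall back to the genome-wide matrix.

**Allele effects** (`estimate_allele_effects()`): dosages of all
non-reference alleles of the significant blocks (reference = most
frequent allele per block, for identifiability) enter one joint least
squares fit with the covariates; collinear columns are dropped with a
warning. Alleles with $p < 0.05$ are classified BHA (effect in the
trait's desirable direction) or UHA (against it). A per-block mode
(`joint = FALSE`) is available because the alternative reading — one
model per block — is also defensible; the joint fit is the default
since it avoids double-counting alleles shared through linkage.

**Multi-trait CCA scan** (`cca_scan()`): with a single genotype variable
against $q$ traits, the first canonical correlation reduces to the
multiple correlation of regressing dosage on the traits,
$\rho^2 = S_{xy}'S_{yy}^{-1}S_{xy}/S_{xx}$, tested with Bartlett's
chi-square $-(n - 1 - (q+2)/2)\ln(1-\rho^2)$ on $q$ degrees of freedom.
Rows with any missing trait are removed listwise and the post-deletion
$n$ enters the statistic. Trait-side coefficients are standardized to
unit trait SD, scaled to unit norm, and signed so the first trait's
coefficient is non-negative — making coefficients comparable across
stages and runs. Linearly dependent trait columns (EV and WEV differ
only by a 1/49 scale, for instance) are dropped with a warning before
inversion. The genotype-by-stage interaction model
(`stage_interaction_test()`) is an ordinary two-way fixed-effect fit
with an interaction F-test, followed (when significant) by
estimated-marginal-mean contrasts of each genotype against the grand
mean within each stage, Bonferroni-adjusted, via emmeans.

## Prediction

Three predictors are built from the significant blocks: HPPS (sum of
estimated fixed allele effects × dosages; variants using all classified
alleles, only BHA, or only UHA), HBLUP (ridge-type mixed model with
i.i.d. random allele effects, variance ratio by REML on the
eigendecomposition of $ZZ'$), and GBLUP (individual-level BLUP through
a SNP- or haplotype-based relationship matrix, with out-of-sample
prediction through the genomic covariance between validation and
training individuals).

`cross_validate()` implements the fixed-validation-set protocol: per
repeat, a validation set (default 100 individuals) is drawn once and
excluded from *all* training; the remainder is split into 10 folds, and
each fold's model re-runs block discovery, effect estimation and
variance-component fitting inside its training data only. Accuracy is
the Pearson correlation between prediction and observed phenotype on
the validation set, averaged over folds and then over repeats (default
50). Two guards are built in: a hard error if any validation individual
reaches a training design, and a cap on the joint allele-effect design
(total non-reference alleles ≤ a third of the training size, strongest
blocks first) so the fixed-effect model can never saturate inside a
fold. Whole-data discovery can be reused inside folds only behind the
explicit `reuse_discovery = TRUE` flag; it leaks phenotype information
and exists for comparison, not for reporting.

## Variance explained

`emreml_two_grm()` fits $y = Z_1\mu_1 + Z_2\mu_2 + e$ with
$\mu_i \sim N(0, K_i\sigma_i^2)$, $K_1$ built from the significant loci
and $K_2$ from the rest, by EM-REML: monotone in the restricted
likelihood, components floored at zero with one jittered restart, and
convergence declared when every component's relative change drops below
10⁻⁶ (cap 500 iterations). PVE of the significant loci is
$\sigma_1^2/(\sigma_1^2+\sigma_2^2+\sigma_e^2)$; genome-wide PVE adds
$\sigma_2^2$ to the numerator, so PVE$_\text{sig}$ ≤ PVE$_\text{gw}$ by
construction. EM was chosen over faster average-information updates
because its monotonicity makes every run self-verifying; an all-zero
relationship matrix is treated as an absent component.

## Selection statistics

`find_singletons()` lists sites whose alternative allele occurs on
exactly one haplotype. The raw singleton-density score of a test SNP
(`raw_sds()`) is the log ratio of the mean singleton gap (nearest
carried singleton upstream + downstream; a chromosome end truncates to
the available side, doubled) between alternative- and reference-allele
haplotypes: haplotypes carrying a recently selected allele descend from
few recent ancestors and carry sparser singletons, so a positive score
marks selection on the alternative allele. This is deliberately a
*gap-ratio surrogate* for the full tip-branch-length likelihood with
per-frequency-bin gamma shapes: it preserves the defining signal and
the standardization step, and only its sign and rank behaviour are
relied on anywhere in the package. Reference/alternative polarity is
used instead of ancestral/derived, matching the empirical finding that
the two give equivalent results in this system.

Scores are standardized to zero mean and unit SD within
alternative-allele-frequency bins of width 0.005 spanning [0.05, 0.95]
(`standardize_sds()`; bins under 10 SNPs merge with their nearest
neighbour), averaged in 50-kb windows (`msds_windows()`), and polarized
per trait (`tsds_polarize()`): tSDS = +score when the alternative
allele's GWAS effect is positive, −score otherwise. The trend test
(`tsds_trend()`) ranks SNPs by −log₁₀(GWAS p), chunks them into
consecutive bins of 1,000 SNPs, and reports the Spearman correlation of
bin rank with mean tSDS — positive when selection favoured
trait-increasing alleles. Windowed Tajima's D and per-bp π
(`tajima_pi_windows()`, 100-kb windows) use the textbook constants with
$\hat{k} = \sum 2\hat{p}(1-\hat{p}) \cdot 2N/(2N-1)$; windows with no
segregating sites report π = 0 and missing D.

Window membership throughout follows `floor(pos / window)`, reported as
0-based half-open intervals (BED convention); every point coordinate in
the package stays 1-based (VCF convention), with this single conversion
at the window boundary.

## Population enriched scores

For a trait's BHA (or UHA) set, the enriched score of panel $k$ is
$E_k = \sum_n f_{nk}$, the sum of the class alleles' haplotype
frequencies in that panel (`enriched_score()`). Panel haplotypes are
sliced at the block's positions; positions missing from a panel are
filled with the discovery cohort's reference allele so the catalogued
alleles stay comparable, and sequences outside the catalogue count as
"other" and never contribute. $E$ ranges from 0 (alleles absent) to the
number of alleles (all fixed).

## The synthetic-data generator

`simulate_haplotypes()` creates linkage disequilibrium by copying each
haplotype from a small founder pool (default 8 founders) with a
per-SNP template-switch probability (default 0.05); this produces
block-scale LD and is exactly reproducible from a seed, which a
coalescent simulator would not give without an external dependency.
Private singleton mutations are injected as separate sites at a Poisson
rate (default 2 per haplotype per Mb) and their carriers recorded, so
the singleton finder has unambiguous ground truth. Planted QTLs are
single SNPs or block alleles (for block QTLs, the second-most-frequent
allele carries the effect, so it is never the dropped reference).

`simulate_laying_records()` drives daily Bernoulli draws with a weekly
probability: the Yang–Ning mean curve at the published parameter values
(the package's defaults) plus an individual deviation split into a
genetic part (planted QTLs and optional polygenic background, rescaled
so its share of the deviation variance equals `h2_target`, default 0.4)
and a Gaussian permanent-environment part, clamped to [0, 1]. The total
deviation SD defaults to 0.12 on the probability scale — large enough
for trait heritabilities in the realistic 0.2–0.4 band once
binomial day-to-day noise is added, small enough that clamping at the
curve's ≈ 0.82 peak stays rare. Week $w$ maps to days
$7(w-21)+1 \dots 7(w-21)+7$, so 23 weeks give 161 days.

`simulate_population_panel()` resamples haplotypes from the base cohort
(preserving LD) and shifts each site's allele frequency by an
independent bounded step `drift · U(−1, 1)` implemented as random
entry flips, so the expected absolute shift has the closed form
drift/2. `simulate_neutral_sites()` generates unlinked sites with
derived-allele counts drawn from the neutral frequency spectrum
(P(k) ∝ 1/k); under that spectrum the diversity and segregating-sites
estimators of θ agree in expectation, making it the calibration fixture
for Tajima's D.

What the generator does *not* emulate: demographic history, sex
chromosomes, genotyping error, pedigree structure, non-equilibrium LD
decay, or selection acting during the simulation (selection footprints
are imposed post hoc by thinning singletons around chosen SNPs in the
test suite). Passing tests on this generator therefore demonstrate
correctness of the statistical machinery under the stated generative
assumptions, not robustness to every pathology of real resequencing
data.

## Problem sizes and numerical choices

The test suite and examples run at desk scale, chosen as the smallest
sizes at which each property is statistically sharp: null calibration
at 500 individuals × 2,000 SNPs, planted-QTL recovery at 600
individuals with a QTL explaining ~10 % of trait variance,
variance-component recovery at 800 individuals with a 2:3:5 split,
cross-validation at 200 individuals with a 50-bird validation set.
REML fits go through a single eigendecomposition with the variance
ratio profiled on log δ ∈ [−12, 12] (tolerance 10⁻¹⁰); EM-REML floors
components at zero and restarts once from a jittered start if a floor
was hit; Cholesky factorizations add 10⁻⁸ · mean diagonal jitter only
on failure. Ties in the multi-start curve grid resolve to the first
best start, and the PC sign convention (largest-magnitude loading
positive) makes eigenvector output reproducible across BLAS
implementations.

## Known limitations

* The gap-ratio SDS is scale-incompatible with the full likelihood
  score; only signs, ranks and bin-standardized values are meaningful.
* The two-step block test with LOCO refits the null once per
  chromosome; with very few chromosomes the polygenic correction is
  correspondingly coarse.
* Trait definitions in the EV family are proportional across scales
  (EV ∝ WEV), which is why the CCA drops dependent columns; a future
  revision could redefine WEV on daily rates within weeks.
* The 3σ filter is single-pass by design; heavy-tailed traits retain
  moderate outliers.
* `mean_fill()` is a convenience completion, not an imputation model;
  analyses sensitive to missingness should handle it explicitly.
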