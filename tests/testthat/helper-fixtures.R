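# Shared simulated fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Mid-sized cohort reused by several suites.
fix_cohort <- function() fixture("cohort", function() {
  cfg <- sim_config(n_individuals = 150, n_snps_per_chrom = 150,
                    n_chroms = 2, mutation_density = 0.5,
                    qtl_list = list(qtl_spec("chr1", 60, 1)),
                    h2_target = 0.3, seed = 42)
  g <- simulate_haplotypes(cfg)
  rec <- simulate_laying_records(g, cfg)
  list(cfg = cfg, g = g, rec = rec)
})

# Hand-written phased genotype set: 3 individuals, 4 sites, one chromosome.
fix_tiny <- function() fixture("tiny", function() {
  hap <- rbind(c(0, 1, 0, 1),
               c(0, 0, 1, 1),
               c(1, 1, 0, 0),
               c(0, 1, 1, 0),
               c(1, 0, 0, 1),
               c(1, 1, 1, 1))
  variants <- data.frame(chrom = "chr1", pos = c(100L, 250L, 300L, 900L),
                         ref = c("A", "C", "G", "T"),
                         alt = c("T", "G", "A", "C"),
                         id = paste0("s", 1:4), stringsAsFactors = FALSE)
  phased_genotypes(c("i1", "i2", "i3"), variants, hap,
                   chrom_lengths = c(chr1 = 1000L))
})
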