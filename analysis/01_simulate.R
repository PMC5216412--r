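#!/usr/bin/env Rscript
# Simulate the synthetic study data: Y-STR haplotypes from a four-region
# refugium-expansion demography, and two-population SNP genotypes for
# F_ST dating. Writes tables under results/ and the truth records needed
# by the later stages.

library(refugium)

out_dir <- file.path("results")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

seed <- 20170106L

# Four populations descending from two refugium pairs: (North1, North2)
# split 250 generations ago, (South1, South2) split 250 generations ago,
# the two pairs splitting 800 generations ago; constant-then-exponential
# growth from an ancestral size of 1,500 males starting 1,000 generations
# before present.
demography <- demography_model(
  "((North1,North2)north,(South1,South2)south)root;",
  N0 = 8000, N_a = 1500, beta = 1000,
  split_times = c(root = 800, north = 250, south = 250),
  mu = 6.9e-4
)

sim <- simulate_str_sample(
  demography,
  n_per_pop = c(North1 = 25, North2 = 25, South1 = 25, South2 = 25),
  n_loci = 11, seed = seed,
  uep = c(M_NORTH = 0.5)
)

write_haplotype_table(sim$table, file.path(out_dir, "str_haplotypes.tsv"))
truth <- data.frame(
  quantity = c("tmrca", paste0("split_", names(sim$truth$split_times)),
               paste0("uep_tmrca_", names(sim$truth$uep_tmrca))),
  generations = c(sim$truth$tmrca, unname(sim$truth$split_times),
                  unname(sim$truth$uep_tmrca))
)
write.table(truth, file.path(out_dir, "str_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Simulated", nrow(sim$table), "Y chromosomes from 4 populations;",
    "sample TMRCA", round(sim$truth$tmrca), "generations\n")

# SNP genotypes: two populations of diploid size 500 split 0.1 * 2N
# generations ago (expected Hudson F_ST about 1 - exp(-0.1) = 0.095)
geno <- simulate_divergent_genotypes(n_sites = 5000, n_per_pop = c(40, 40),
                                     N = 500, t_split = 100, seed = seed)
write_genotype_matrix(geno, file.path(out_dir, "snp_genotypes.tsv"))
cat("Simulated 5000 SNPs for 2 x 40 diploids, true split 100 generations\n")

pool <- population_pooling(
  c("North1", "North2", "South1", "South2"),
  c("North", "North", "South", "South"))
write_pooling(pool, file.path(out_dir, "pooling.tsv"))
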