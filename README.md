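# refugium

Dating post-glacial population expansions from Y-chromosome STR
haplotypes and autosomal SNP differentiation.

During the Last Glacial Period, human populations persisted in
isolated refugia; post-glacial warming released them into expansions
that shaped modern genetic variation. `refugium` implements the
inference machinery used to reconstruct and date such expansions from
modern samples:

* **Coalescent MCMC for Y-STR data.** A Metropolis-Hastings sampler
  over genealogies and demographic parameters under the single-step
  mutation model — the net repeat change after an expected
  θ = μt mutations is Skellam, P(k) = e^−θ I_|k|(θ) — with a
  constant-then-exponential-growth, splitting demography:
  N(t) = N₀e^(−rt) below the growth onset β, N_a above, and each
  population split dividing the parental effective size among the
  children. Reports posterior medians and 95% credible intervals for
  TMRCAs, split times, μ and N₀.
* **Double-conformation pooled runs.** For a balanced four-group
  history ((A,B),(C,D)), the two splits are estimated in separate runs
  — (AB,(C,D)) and ((A,B),CD) — removing the spurious interaction
  between the sister splits; the two root-split posteriors double as a
  consistency check.
* **Population statistics.** Slatkin-style R_ST from squared
  repeat differences, Hudson F_ST (population pairs and individual
  pairs), hierarchical AMOVA with Φ_CT/Φ_SC/Φ_ST and population-level
  permutation, classical MDS, Mantel tests, Fisher exact geographic
  concordance, neighbor joining, Ward clustering, per-population STR
  variance, and haplogroup-frequency PCA.
* **Median-joining haplotype networks** with population-label
  assortativity against a permutation null.
* **F_ST-based dating.** t = −2·Ne·ln(1 − F_ST) generations with a
  harmonic-mean Ne; e.g. Ne = 8060 (the harmonic mean of 7,000 and
  9,500) maps F_ST = 0.075 to 1260 generations (36.4 ka at 28.96
  years/generation) and 0.057 to 946 generations (27.4 ka), where the
  linear form 2·Ne·F_ST would give 1209 and 919.
* **A structured-coalescent simulator** producing Y-STR haplotype
  tables (with UEP-defined clades) and drifted SNP genotype tables
  with known truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(refugium)

# two populations split 300 generations ago, constant total size 2000
mod <- demography_model("(A,B)root;", N0 = 2000,
                        split_times = c(root = 300))
sim <- simulate_str_sample(mod, c(A = 25, B = 25), n_loci = 11, seed = 11)

# R_ST between the populations
D <- pairwise_rst(sim$table)
round(D["A", "B"], 4)
#> [1] 0.1202

# posterior for the split time and TMRCA
fit <- run_mcmc(sim$table, topology = "(A,B)root;",
                n_iter = 2000, burn_in = 600, thin = 4, seed = 2)
subset(fit$summary, quantity %in% c("split_root", "tmrca"))
#>    quantity    median      q025      q975      ess
#>       tmrca 5669.8655 1707.0582 15380.267  20.8682
#>  split_root  821.3157  251.9242  1449.832 114.6381
```

The simulated truth here is a 300-generation split and a realized
sample TMRCA of 6599 generations; both lie inside their 95% credible
intervals. The `ess` column is the effective sample size of each
posterior trace — increase `n_iter` until it is comfortable.

The four `analysis/` scripts run the full synthetic study in order:
`01_simulate.R` (generate haplotypes, genotypes, pooling, truth),
`02_ystr_structure.R` (R_ST, MDS, AMOVA, variance, network),
`03_mcmc_splits.R` (UEP TMRCA, double-conformation splits, dated split
tree), `04_fst_dating.R` (Hudson F_ST, individual-pair MDS/Ward/NJ,
Mantel, drift dating). Each writes its tables under `results/`.

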