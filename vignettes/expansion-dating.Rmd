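---
title: "Dating population expansions from Y-STR and autosomal data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating population expansions from Y-STR and autosomal data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`refugium` reconstructs and dates population expansions from glacial
refugia using two complementary sources of evidence: Y-chromosome STR
haplotypes (with their haplogroup-defining UEP markers), and autosomal
SNP differentiation summarized as F~ST~. The package provides

* a Bayesian MCMC sampler for TMRCAs and population split times under
  the single-step mutation model (SMM) and a splitting,
  constant-then-exponential-growth coalescent;
* the surrounding population-genetic statistics: Slatkin-style R~ST~,
  Hudson F~ST~ (population pairs and individual pairs), hierarchical
  AMOVA with Φ statistics, classical MDS, Mantel and Fisher exact
  tests, neighbor-joining and Ward clustering, per-population STR
  variance, and haplogroup-frequency PCA;
* median-joining haplotype networks;
* F~ST~-based divergence dating with harmonic-mean effective sizes;
* a structured-coalescent simulator that generates STR haplotype and
  SNP genotype tables with known truth, so every stage is testable
  without access to any sample data.

# The demographic model

Backward in time, the total effective number of males is

$$N(t) = \begin{cases} N_0\,e^{-rt} & t < \beta \\ N_a & t \ge \beta \end{cases}$$

with growth rate $r = \log(N_0/N_a)/\beta$ implied by the present size
$N_0$, the ancestral size $N_a$, and the growth onset $\beta$
(generations before present). Population splits divide the total size
among child populations: a split with proportion $p$ gives the first
child a fraction $p$ of the parent's share, so child sizes always sum
to the parent size. Within each population unit of share $w$, every
lineage pair coalesces at rate $1/(w\,N(t))$ (haploid scaling — the Y
chromosome is carried by one copy per male); lineages from different
populations can only coalesce root-ward of their populations' split.
There is no migration after splits and no selection: admixture after a
split is interpreted, as in this class of models, as biasing split
estimates toward more recent dates.

STR loci mutate under the SMM: mutation counts on a branch of length
$t$ are Poisson with mean $\mu t$, each mutation changing the repeat
count by $\pm 1$ with equal probability. The net change over expected
$\theta = \mu t$ mutations is symmetric Skellam,
$P(k) = e^{-\theta} I_{|k|}(\theta)$ with $I$ the modified Bessel
function of the first kind. Repeat counts are unbounded in the
simulator — no reflecting boundaries — matching the pure SMM the
likelihood assumes.

# The likelihood and the sampler

The likelihood of a genealogy is computed by Felsenstein pruning per
locus over a truncated integer repeat window around the observed range.
The window half-width is at least $6\sqrt{\theta_\max}$ (widened
automatically in the exported `tree_log_likelihood()`, capped at 200
states); inside `run_mcmc()` the window is fixed for the whole run so
every iteration targets the same posterior. Transition kernels are
truncated where the Skellam mass falls below ~1e-9
($|k| > \theta + 6\sqrt\theta + 4$). The root state prior is uniform
over the window. This pruning formulation replaces mutation-augmented
tree sampling: it targets the identical likelihood and is directly
checkable against the two-tip closed form
$P(\text{data}) = P_{\rm SMM}(k;\,\mu t_{\rm path})/W$, which the test
suite does.

`run_mcmc()` is a Metropolis-Hastings sampler alternating:

* **genealogy moves** — uniform node-time slides (multiplicative for
  the root), restricted subtree reattachment at fixed node height
  (uniform over the branches spanning that height; invalid
  cross-population attachments are rejected by the prior), and a
  whole-tree scale move;
* **a ridge move** — the model has an exact scaling symmetry
  ($t \to ft$, $N_0 \to fN_0$, $\beta \to f\beta$, splits $\to fs$,
  $r \to r/f$, $\mu \to \mu/f$ leaves both likelihood and coalescent
  density invariant); a joint rescaling proposal traverses this ridge
  directly;
* **split-time moves** — a random walk; an exact Gibbs draw of a
  single split time from its full conditional where the total size is
  constant over the feasible range (the conditional is piecewise
  exponential in the split: the waiting-time exponent contributes a
  slope from the pair-rate difference between split and merged
  configurations, and each within-population coalescence contributes a
  jump as the split crosses it; sampled by inverse CDF), falling back
  to a uniform Metropolis proposal over the feasible interval
  otherwise; and a translation move with a mixture of step scales that
  shifts a split together with every genealogy node above it. The
  split time and the first post-merge coalescences form a tight ridge,
  and the translation slides the whole block along it;
* **parameter moves** — log-scale random walks for $\mu$, $N_0$, $r$;
  reflected walks for $\beta$, split times and $p$; plus independence
  proposals from the prior, whose prior-density terms cancel so the
  acceptance ratio reduces to the coalescent (and, for $\mu$,
  likelihood) ratio. In a run with zero loci this makes the sampler
  draw essentially independently from the prior — the basis of the
  prior-recovery tests.

Defaults (all overridable through `prior_spec()`): $\mu \sim$
Gamma(shape 2, mean 6.9e-4) per locus per generation, shared across
loci (11 loci carry little per-locus rate information);
$N_0 \sim$ Gamma(shape 1, mean 5000); growth rate $\sim$ Gamma(shape 1,
mean 0.002)/generation; $\beta \sim$ U(0, 5000) generations;
$p \sim$ Beta(1, 1); split times $\sim$ U(0, 1500) generations subject
to root-ward ordering. The split range, roughly 43 ka at the default
generation time, spans post-glacial and Holocene divergence scales —
the regime this package addresses — with a wide margin. The posterior
support additionally enforces the model invariant $N_a \ge 1$: without
it the prior puts mass on demographies whose ancestral size falls
below one individual, where the coalescent degenerates. Time is kept
in generations internally; years appear only at reporting, through the
generation time (default 28.96 years, the unique value under which the
F~ST~-derived dates reproduce both printed year conversions — 1260
generations as 36.4 ka and 946 generations as 27.4 ka; the frequently
used 28.9 yr/gen gives 27.3 ka for the second pair).

The population-tree topology is fixed per run. Exploring topologies is
done the way the pooled analyses do it: separate runs on pooled
designs. `run_double_conformation()` implements the two-conformation
device for a balanced four-group history $((A,B),(C,D))$: estimating
both splits in a single run induces a spurious interaction between the
$(A,B)$ and $(C,D)$ split times, so the sampler is run twice — designs
$(AB,(C,D))$ and $((A,B),CD)$, pooling one sister pair at a time — and
the two root-split posteriors double as a consistency check
(overlapping 95% intervals and a median ratio within $[1/1.75, 1.75]$,
the factor echoing the typical spread of these credible intervals).

# What the tests do and do not show

The simulator is validated against closed forms: mean pair-coalescence
time $N$ and the full exponential distribution under constant size
(KS), variance accumulation $2\mu t$ under the SMM, and the drift
expectation $F_{ST} \approx 1 - e^{-t/2N}$ for the genotype simulator.
The sampler is validated three ways, in increasing strength:

1. **fixed-parameter, no-data runs** reproduce the structured
   coalescent measured by the independent simulator (KS on TMRCA);
2. **free-parameter, no-data runs** recover the priors (the marginal
   of every parameter under the joint prior-times-coalescent target is
   its prior);
3. **simulation-based calibration**: each replicate draws the true
   split time *from its prior*, simulates 25+25 haplotypes at 11 loci
   under the study-scale demography (total size 2000, mutation rate
   6.9e-4, constant size), and fits with the known nuisance parameters
   fixed; the 95% credible interval for the split must cover the drawn
   truth. For a correct sampler this coverage is nominal by
   construction, with binomial fluctuation. (The fully-free variant in
   which every demography parameter is drawn from its prior is also
   exactly nominal in principle, but at desk-scale chain lengths the
   finite-chain noise in interval endpoints undercovers at
   prior-tail demographies; converged spot-checks agree with long
   reference chains.)

A caution that the calibration makes explicit: when the truth is a
*fixed* value in the tail of the prior (rather than drawn from it),
Bayesian interval coverage at 11-locus data strength is not nominal —
the data are too weak to dominate the prior, and the posterior for a
split time leans toward the youngest genealogy node that joins the two
populations. This is a property of Bayesian intervals under weak data,
not an implementation defect; with real studies' larger samples and
more loci the likelihood dominates and the distinction fades. The same
weak-data behaviour is the reason the original analyses treat split
estimates as bounded above by TMRCAs and check them across pooled
conformations.

The synthetic data emulate multi-population samples descended from
refugia with known split times, constant-then-exponential growth, SMM
loci, and clade-defining UEP markers. They do not emulate genotyping
error, locus-specific mutation rates, multi-step mutations, population
migration after splits, or sampling biases of real surveys — passing
tests say the machinery is correct under its model, not that the model
captures every feature of real Y-STR data.

# Distance, variance and ordination conventions

* **R~ST~** uses the pooled-pairs form: per locus, $S_W$ is the mean
  within-group pairwise squared repeat difference with the two groups
  weighted equally (switchable to pair-count weighting), $\bar S$ the
  mean over all pooled pairs; loci combine by summing numerators and
  denominators, $0/0 \equiv 0$. Negative raw estimates are retained in
  an attribute; matrix entries are clamped at zero because MDS needs
  dissimilarities while inference wants the raw value.
* **Hudson F~ST~** is the ratio-of-averages estimator; its
  individual-pair variant treats each diploid as a two-allele
  population, skipping sites missing in either member and flagging
  pairs with fewer than 50 usable sites.
* **AMOVA** partitions squared repeat-score distances (haplotype
  identity switchable) with the standard unequal-size coefficients;
  Φ~CT~ significance permutes whole populations among regions with the
  $+1/+1$ p-value convention, or exhaustively for small designs.
  Missing repeats contribute zero to a pair's squared distance at that
  locus (pairwise-complete deletion).
* **Classical MDS** is Torgerson double-centering; negative
  eigenvalues are reported, never used. **Ward** operates on
  coordinates reconstructed from the top three MDS dimensions,
  mirroring how clustering is applied to reconstructed distances.
  **NJ** clamps negative branch lengths to zero, transferring the
  deficit to the sibling edge so path lengths are preserved.
* **Median-joining networks** are used for STR data (the reduced
  median method is defined for binary characters, so the multistate
  STR case uses median-joining; this divergence is deliberate and
  documented). Links are feasible within `epsilon` of the minimax
  connection distance; component-wise medians of linked triplets are
  added greedily only when they shorten the spanning weight; medians
  of degree < 3 are pruned; ties break lexicographically so input
  order never matters. Loci are equally weighted.

# F~ST~ dating

Under pure drift, differentiation accumulates as
$F_{ST} = 1 - e^{-t/2N_e}$, giving $t = -2N_e\ln(1 - F_{ST})$
generations. With $N_e = 8060$ — the harmonic mean of 7,000 and 9,500
— an ancestral $F_{ST}$ of 0.075 dates to 1260 generations (36.4 ka at
28.96 yr/gen) and 0.057 to 946 generations (27.4 ka). The linear
approximation $t = 2N_eF_{ST}$ gives 1209 and 919 generations instead;
the log form is the one consistent with both printed dates, and
`fst_to_time()` returns both so the comparison is explicit. Reported
values round to 3 significant figures; full precision is kept
internally.

# Problem sizes

The analysis scripts and tests use reduced problem sizes chosen to
exercise every code path at useful precision: chains of 1,000–2,500
sweeps (each sweep makes several genealogy updates plus a parameter
pass), 25 haplotypes per population at 11 loci, 100
calibration replicates, and 5,000-SNP genotype tables. These are the
package's own verification scales; real analyses should use longer
chains (the `ess` column of the posterior summary says when).

# Known limitations

* No topology sampling over population trees, no admixture or
  post-split migration — inherited limits of the splitting model.
* Shared mutation rate across loci by default.
* UEP conditioning is approximated by subset analysis (carrier
  monophyly by construction) rather than joint modelling of the UEP on
  the full genealogy.
* `assemble_split_tree()` requires a one-to-one mapping from reports
  to nodes and flags (rather than resolves) age inversions between
  overlapping pooled runs.
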