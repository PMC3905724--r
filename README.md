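# isoshare

Haplotype sharing and rare-variant association analysis for population
isolates, with a ground-truth cohort simulator.

## The problem

In a genetic isolate — a village founded by a small group and closed for
centuries — a functional allele that is vanishingly rare outside (one in
~3,000 chromosomes) can drift to ~2% frequency. A cohort of ~1,300 villagers
then holds enough heterozygous carriers for a single-variant scan of a
quantitative trait to reach genome-wide significance, where an outbred
design would need tens of thousands of samples. But isolates bring two
analytical obligations: every association test must account for pervasive
kinship, and an elevated allele frequency must be shown to reflect drift
rather than one cluster of close relatives. `isoshare` implements the full
chain for both, aimed at statistical geneticists working with exome-array or
sequence genotypes from founder populations:

* **Simulation** — a forward-in-time diploid isolate with a founder
  bottleneck, Poisson recombination on a genetic map (Haldane model), a
  focal allele carried on exactly one founder haplotype and
  rejection-sampled to a target final frequency, array-style genotype error
  and missingness, and complete ground truth (haplotypes, pedigree, true IBD
  segments around the focal allele).
* **Genotype QC** — the staged filter sequence used for exome arrays: call
  rate, MAF-stratified heterozygosity outliers, exact Hardy–Weinberg tests,
  excess-singleton samples; every stage logged.
* **Traits** — Friedewald LDL, unit conversion, 5-SD outlier removal,
  natural-log and rank-based inverse-normal transforms, HDL dichotomization.
* **Mixed-model association** — centered kinship `K = WW'/p`; maximum
  likelihood for `y = Xα + xβ + u + ε`, `cov(u) = σ_g²K`, with the variance
  ratio profiled on the eigendecomposition of `K`; likelihood-ratio
  p-values; variance explained `2f(1−f)β²/var(y)`; conditional and binary
  fits.
* **Haplotype sharing** — the surrogate-parent hidden Markov model: the
  hidden state is a pair of other cohort members whose genotypes are
  compatible with Mendelian transmission of the target's genotype (1%
  miscall tolerance; per-parent switch probability `1 − exp(−d)` over `d`
  Morgans); Viterbi decoding yields maximal-identity segments, sharing
  profiles, carrier/non-carrier Kolmogorov–Smirnov comparisons, and a
  generations-to-common-ancestor estimator (segment length ~ Gamma(2, 2G)
  in Morgans, so `Ĝ = 1/mean(length)`).
* **Variant statistics** — exact HWE test, EM haplotype-frequency LD
  (D′, r²), method-of-moments pairwise IBD (π̂), Fisher's method,
  power/sample-size (`N = (z_{1−α/2} + z_{power})²/VE`), and the
  Kimura–Ohta frequency-based allele age `−4·Ne·p·log(p)/(1−p)` generations.

## Worked example

Simulate a 1,267-sample isolate in which the focal allele has drifted to
~1.9%, then test an HDL-like trait (variant explains 2.9% of variance on a
30%-heritable polygenic background) with the kinship-aware mixed model
(runs in about a minute):

```r
library(isoshare)
cfg <- isolate_config(n_variants = 2000, seed = 1)
sim <- simulate_isolate(cfg)
sim$genotypes
#> geno_matrix: 1267 samples x 2000 variants
#>  chromosomes: 11
#>  missing calls: 0.51%
round(sim$truth$focal$freq, 4)
#> [1] 0.0193

K  <- kinship_centered(sim$genotypes)
tc <- trait_config("HDL", variance_explained_target = 0.029,
                   polygenic_h2 = 0.3, mean = 1.265, sd = 0.35)
ph  <- simulate_traits(sim$truth, tc, kinship = K, seed = 2)
lmm_fit(ph$HDL, sim$truth$carrier_status, K = K)
#> assoc_result: beta = 0.273 (se 0.07287), LRT p = 0.00019, EAF = 0.01934, VE = 0.0237, n = 1267
```

The fitted per-allele effect (0.27 mmol/l higher HDL per copy, p = 1.9×10⁻⁴
by likelihood-ratio test) recovers the generating model: the variant's
estimated share of trait variance is 2.4% against the 2.9% target, with the
shortfall driven by the ~49 carriers behind the estimate. Dating the
carriers' common ancestor from shared-segment lengths works the same way:

```r
g <- estimate_generations(c(21.1, 9.5, 14.2, 30.8, 12.4, 17.9, 8.3, 25.6))
sprintf("G = %.2f (95%% CI %.2f-%.2f)", g$G, g$ci[1], g$ci[2])
#> [1] "G = 5.72 (95% CI 3.27-8.85)"
```

i.e. segments averaging ~17.5 cM put the nearest common ancestor about six
generations back.

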