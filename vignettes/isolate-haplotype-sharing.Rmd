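---
title: "Rare-variant drift, kinship-aware association and haplotype sharing in population isolates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant drift, kinship-aware association and haplotype sharing in population isolates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoshare)
```

## The scientific setting

Genetic isolates — villages founded by a small number of families and closed
to immigration for centuries — can carry functional variants at frequencies
ten to a hundred times higher than the surrounding outbred population, purely
through drift at the founding bottleneck and in the small early generations.
A lipid-modifying loss-of-function allele that is present on roughly 1 in
3,000 outbred European chromosomes can reach ~2% in such a village, so a
cohort of ~1,300 villagers contains dozens of heterozygous carriers and a
single-variant association scan reaches genome-wide significance where an
outbred design would need tens of thousands of samples.

Working in an isolate has a price: everyone is related to everyone, so naive
regression tests are confounded by kinship, and an apparently drifted allele
could instead reflect a cluster of close relatives. `isoshare` implements the
analysis chain that addresses both concerns, together with a synthetic-cohort
generator so that every stage can be exercised, calibrated and tested with
known ground truth.

The package has six parts: the simulator (`simulate_isolate`,
`simulate_traits`), staged genotype QC (`run_qc_pipeline`), lipid-trait
preparation (`prepare_phenotypes` and friends), the kinship-aware linear
mixed model (`kinship_centered`, `lmm_fit`), the surrogate-parent
haplotype-sharing HMM (`viterbi_surrogate_parents`, `sharing_profile`), and
variant-level statistics (`hwe_exact_test`, `ld_em`, `pairwise_ibd`,
`fisher_meta`, `required_sample_size`, `allele_age_frequency`).

## The simulator: what it emulates

`simulate_isolate` is a forward-in-time diploid simulator over discrete,
non-overlapping generations:

* **Founders.** `n_founders` individuals whose marker alleles are drawn
  independently at intermediate frequencies (uniform on 0.05–0.95), plus a
  single *focal* derived allele placed on exactly one founder haplotype.
  `n_founders` is the *effective* breeding pool at founding, not a census
  count. The default — 100 founders, 15 generations, growth to 1,267 — gives
  the focal allele a 0.5% start and asks drift to carry it to ~1.9%: a tail
  event, which is the point, and one that rejection sampling still accepts
  within a few dozen attempts because runs that lose the allele abort early.
  The pool size also controls background relatedness; at 100 founders most
  carrier pairs are only distantly related genome-wide, matching what real
  isolate cohorts show, whereas a very small pool (20–30 founders) makes the
  whole cohort close kin and visibly costs the mixed model power.
* **Mating and recombination.** Each offspring draws two distinct parents
  uniformly (random union, no selfing, monogamy not enforced). Each gamete
  is a mosaic of the parent's two haplotypes with breakpoints from a Poisson
  process at 1 per Morgan on the genetic-map scale — the Haldane
  no-interference model. The map is either uniform (`cM_per_Mb`) or any
  piecewise map supplied as a `genetic_map`.
* **Frequency targeting.** Whole replicates are rejection-sampled until the
  final focal-allele frequency lands within `freq_tol` of
  `carrier_target_freq`. Conditioning on the outcome keeps the drift
  dynamics unbiased *given survival*; nothing inside a run is nudged. The
  attempt budget is explicit and exceeding it is an error, not a silent
  relaxation.
* **Noise.** Genotyping error (default 1%, the same rate the sharing HMM
  assumes) replaces a call with one of the two wrong values uniformly;
  missingness blanks calls. Both touch only the released genotype matrix —
  the `sim_truth` object keeps clean haplotypes, the pedigree, carrier
  status and the true focal IBD segment of every haplotype, against which
  the detection methods are scored.

What it deliberately does **not** emulate: coalescent history behind the
founders (founder marker genotypes are exchangeable, so background linkage
disequilibrium is weaker than in real data), selection, migration,
non-autosomal inheritance, and array-specific artefacts (intensity-driven
miscalls are uniform here). Passing tests therefore demonstrate correctness
of the algorithms under the stated generative model, not robustness to every
failure mode of real array data.

## Staged genotype QC

`run_qc_pipeline` applies, in order: a 90% call-rate prefilter on both axes,
a 98% sample call-rate filter, heterozygosity-outlier removal computed
separately over rare (MAF < 1%) and common variants, a 95% variant call-rate
filter plus an exact Hardy–Weinberg test at p < 10⁻⁴, a 99% final variant
call-rate filter, removal of samples that are the sole minor-allele carrier
at more than 100 variants, and a final Hardy–Weinberg pass. All comparisons
are strict, filters only delete rows/columns (never edit calls), and every
stage is logged with counts and IDs.

Two rules are this package's own:

* The heterozygosity-outlier cut is numeric — |z| > `het_outlier_sd`
  (default 3) within each MAF stratum — replacing the visual inspection used
  in array practice. Any z-threshold rule will flag the extreme order
  statistic of a large clean cohort occasionally, so the multiplier is
  exposed; cohorts of a few hundred samples are better served by 5–6.
* A stratum with fewer than `min_variants` (20) markers is skipped with a
  warning: heterozygosity fractions over a handful of variants are too
  discrete for z-scores to mean anything.

## Trait preparation

Lipid phenotypes follow a fixed order: unit harmonization to mg/dl
(cholesterol-family factor 38.67, triglycerides 88.57 mg/dl per mmol/l), LDL
derivation by the Friedewald equation (LDL = TC − HDL − TG/5, invalid and
set missing above 400 mg/dl triglycerides), single-pass removal of values
more than 5 SD from the trait mean (strict inequality; the rule is not
iterated, since re-iteration would change results), the per-trait transform
(natural log for triglyceride-like traits, inverse-normal for age), and HDL
dichotomization (high ≥ 60, low < 40 mg/dl). The inverse-normal transform
uses the Blom offset, `qnorm((r − 3/8)/(n + 1/4))`, with ties sharing their
average rank; for `{1, 2, 3}` this gives scores ±0.87, 0.

## The linear mixed model

Association uses `y = Xα + xβ + u + ε` with `cov(u) = σg²K` and
`cov(ε) = σe²I`, where `K` is the centered genetic relationship matrix
`WW'/p` (`W` holds genotypes centered at twice the allele frequency,
missing calls mean-imputed for this computation only). The variance ratio
`λ = σg²/σe²` is profiled on the eigendecomposition of `K` — computed once
per cohort and reused across variants — and maximized by bounded
one-dimensional search of the profiled log-likelihood over `log10 λ ∈
[−5, 5]`, with both boundary values checked explicitly. P-values come from a
likelihood-ratio χ²(1) against the model without the variant.

Numerical and design choices: maximum likelihood rather than REML, so
likelihoods of nested fixed-effect models are directly comparable for the
LRT; weighted least squares inside the profile uses pivoted QR, so an
aliased column (a variant conditioned on itself) gets coefficient zero
instead of an error; rows with missing trait or dosage are dropped, not
imputed; variance explained is reported as `2f(1−f)β²/var(y)`. Binary
traits are analysed by the same linear model on the 0/1 outcome with the
effect also reported on an exponentiated scale — a linear-probability
treatment, chosen over a logistic mixed model for comparability of its LRT
machinery; it is an approximation at extreme case fractions. Kinship
estimation needs a dense marker panel: with only a few hundred markers the
noise in `K` correlates with individual dosages and mildly deflates
standard errors (the package's tests use 2,000 markers for a 2,000-sample
cohort).

The covariate set defaults to an intercept only; age and sex can be passed
explicitly, since which covariates a given analysis warrants is a
study-level decision.

## Surrogate-parent haplotype sharing

The core bespoke computation asks, for a target individual: which two other
cohort members could currently be serving as "surrogate parents", in the
sense that the target's genotype is compatible with Mendelian transmission
from theirs — and over how long a stretch does the best such pair persist?

The hidden state of the HMM is an unordered pair of candidates. The emission
probability at a variant is the chance that the target's observed genotype
arises when each surrogate transmits one allele drawn uniformly from its own
genotype, allowing the observation to be a miscall with probability
`error_rate` (default 1%, uniform over the two wrong values); a missing
target call emits probability 1, and a missing candidate call transmits an
uninformative allele (½/½). Between adjacent variants at genetic distance
`d` Morgans each surrogate independently switches with probability
`1 − exp(−switch_rate·d)` (default rate 1/Morgan) to a uniformly redrawn
candidate — so between any two markers one surrogate can change. The most
probable path is decoded by the Viterbi algorithm in log space.

Because the switch kernel is "stay or redraw uniformly", the transition
probability between two pairs depends only on how many members they share
(2, 1 or 0), and the per-site maximization runs in `O(states + candidates)`
rather than quadratic time; coefficients are ordered so the relaxation is
exact, and ties break deterministically toward staying and then toward the
lowest candidate indices. The decoder is verified against exhaustive path
enumeration on small instances.

Shared segments are reported as the maximal run of variants around a focal
position over which a focal surrogate stays in the decoded pair, with
boundaries at the outermost typed variants (never extrapolated into untyped
gaps), closed 1-based bp coordinates plus cM from the supplied map. BED
export converts to 0-based half-open. The candidate set defaults to all
samples with kinship to the target below `relatedness_cap` (0.2), so that
"nearest neighbour" means distant genealogy, not siblings.

Around the decoded segments sit three analyses. `maximal_identity_pair` is
the model-free cross-check: the longest interval around the focal position
in which a pair has at most `max_mismatch` opposite-homozygote genotypes.
`compare_carriers` is a two-sample Kolmogorov–Smirnov test of carrier vs
non-carrier segment lengths at the focal position. `estimate_generations`
fits the model in which the shared segment extends left and right by
independent exponentials with rate 2G per Morgan — 2G meioses separating
the pair through a common ancestor G generations back — so the total length
is Gamma(2, 2G), the MLE is `G = 1/mean(length in Morgans)` and the CI
comes from the exact Gamma distribution of the total. Whether such a
fit should use means, medians or the whole profile is genuinely open; the
MLE on lengths was chosen for its closed form and testable sampling
distribution. `excess_relatedness_decay` fits an exponential to the decay
of carrier-minus-background sharing with cM distance from the locus.

## Variant-level statistics

* **Hardy–Weinberg**: the exact conditional test; the p-value sums the
  probabilities of all heterozygote configurations no more probable than the
  observed one, computed via log-factorials. Monomorphic variants return
  p = 1 by convention. Verified against an independent recurrence-based
  enumeration for every table with up to 50 individuals.
* **LD**: two-locus haplotype frequencies by EM over the double-heterozygote
  ambiguity, initialized at linkage equilibrium (deterministic, so no seed),
  converging when the largest frequency change drops below 10⁻¹⁰ (cap 1,000
  iterations); the log-likelihood is asserted non-decreasing at every
  iteration. D′ and r² use the standard normalizations.
* **IBD**: PLINK-style method-of-moments estimates of P(IBD = 0, 1, 2) from
  identity-by-state counts and sample allele frequencies, without
  small-sample bias corrections; `pihat = z1/2 + z2`, clamped to [0, 1].
* **Meta-analysis**: Fisher's method, `−2Σ log p ~ χ²(2k)`.
* **Power**: normal approximation, `N = (z_{1−α/2} + z_{power})²/VE` with
  `VE = 2f(1−f)β_std²` and genome-wide α = 5×10⁻⁸ by default. The published
  "67,000 outbred samples" figure does not state its assumptions, so this
  model is held to order-of-magnitude concordance only.
* **Allele age**: the Kimura–Ohta neutral expectation,
  `−4·Ne·p·log(p)/(1−p)` generations (default Ne = 10,000, 25 years per
  generation). This is a deliberate stand-in for likelihood-based
  haplotype-sharing age estimators; it agrees with the published ~3 KYA
  estimate to well within its own uncertainty.
* Reported kb spans use `floor(bp/1000)` — a 571,082 bp interval is "at
  least 571 kb".

## A worked example

```{r, eval = FALSE}
cfg <- isolate_config(seed = 1)            # 100 founders -> 1,267 samples
sim <- simulate_isolate(cfg)
qc <- run_qc_pipeline(sim$genotypes)
K <- kinship_centered(qc$genotypes)
tc <- trait_config("HDL", variance_explained_target = 0.029,
                   polygenic_h2 = 0.3, mean = 1.265, sd = 0.35)
ph <- simulate_traits(sim$truth, tc, kinship = kinship_centered(sim$genotypes))
fit <- lmm_fit(ph$HDL, sim$truth$carrier_status, K = kinship_centered(sim$genotypes))
fit
```

## Problem sizes and test design

The test suite builds all fixtures in code. Exhaustive oracles run at the
sizes where enumeration is feasible (every Hardy–Weinberg table up to 50
individuals; every Viterbi instance up to 5 variants and 4 candidates,
checked on hundreds of randomized draws). Statistical calibration uses 1,000
null replicates at 300 samples for the mixed model's type-I error, 200
replicates at 2,000 samples for effect recovery, and 200 replicates of 500
segment lengths for the generations estimator. The full-cohort demonstration
in `scripts/acceptance.R` simulates 1,267 samples at 2,000 markers and runs
the sharing analysis on a 60-sample subsample — sizes chosen so a complete
run stays in the minutes range on one core while keeping every estimator in
its asymptotic regime.

## Known limitations

Founder haplotypes are exchangeable draws, so the simulator underestimates
baseline LD and therefore overestimates how sharply direct-scan identity
intervals terminate. The sharing HMM's switch model treats surrogates
independently; the published long-range phasing idea constrains one switch
per interval, which matters only at extreme marker densities. The
linear-probability treatment of binary traits and the neutral allele-age
formula are intentionally simple models and are documented as such above.
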