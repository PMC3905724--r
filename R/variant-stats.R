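#' Allele frequency from genotype or allele counts
#'
#' @param n_ref_hom,n_het,n_alt_hom genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return alternate-allele frequency `(2*n_alt_hom + n_het) / (2*N)`.
#' @examples
#' allele_frequency(1219, 48, 0)        # ~0.019
#' allele_frequency_counts(3, 8585)     # ~0.00035
#' @export
allele_frequency <- function(n_ref_hom, n_het, n_alt_hom) {
  total <- n_ref_hom + n_het + n_alt_hom
  stopifnot(total > 0, n_ref_hom >= 0, n_het >= 0, n_alt_hom >= 0)
  (2 * n_alt_hom + n_het) / (2 * total)
}

#' @rdname allele_frequency
#' @param n_alt,n_ref allele (chromosome) counts.
#' @export
allele_frequency_counts <- function(n_alt, n_ref) {
  stopifnot(n_alt + n_ref > 0, n_alt >= 0, n_ref >= 0)
  n_alt / (n_alt + n_ref)
}

#' Heterozygote fraction
#'
#' Fraction of individuals heterozygous at a variant.
#'
#' @inheritParams allele_frequency
#' @export
het_fraction <- function(n_ref_hom, n_het, n_alt_hom) {
  total <- n_ref_hom + n_het + n_alt_hom
  stopifnot(total > 0)
  n_het / total
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditioning on the observed allele counts: the
#' p-value is the sum, over all heterozygote counts compatible with the allele
#' counts, of configuration probabilities no larger than that of the observed
#' configuration. Monomorphic variants return p = 1 by convention.
#'
#' @inheritParams allele_frequency
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_ref_hom, n_het, n_alt_hom) {
  stopifnot(n_ref_hom >= 0, n_het >= 0, n_alt_hom >= 0)
  n <- n_ref_hom + n_het + n_alt_hom
  n_a <- 2 * n_alt_hom + n_het      # minor-or-not; symmetry makes choice free
  n_b <- 2 * n_ref_hom + n_het
  if (n == 0 || n_a == 0 || n_b == 0) return(1)
  rare <- min(n_a, n_b)
  ## P(n_het = h | allele counts) via log-factorials; h has fixed parity
  h <- seq(rare %% 2, rare, by = 2)
  ## counts: het h, rare-hom (rare - h)/2, common-hom n - h - (rare - h)/2
  n_rr <- (rare - h) / 2
  n_cc <- n - h - n_rr
  lp <- lfactorial(n) - lfactorial(n_rr) - lfactorial(h) - lfactorial(n_cc) +
    h * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_het, h)]
  if (is.na(obs)) stop("observed heterozygote count incompatible with allele counts")
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Pairwise identity by descent by method of moments
#'
#' Estimates, for every pair of samples, the probabilities of sharing 0, 1 or
#' 2 alleles identical by descent from identity-by-state counts and sample
#' allele frequencies (the PLINK-style moment estimator), and the summary
#' proportion `pihat = P(IBD=1)/2 + P(IBD=2)`.
#'
#' @param g a [geno_matrix].
#' @param pairs optional 2-column matrix of sample indices; default all pairs.
#' @return data.frame with columns `i`, `j`, `z0`, `z1`, `z2`, `pihat`
#'   (all clamped to [0, 1]).
#' @export
pairwise_ibd <- function(g, pairs = NULL) {
  geno <- g$geno
  n <- nrow(geno)
  f <- alt_freqs(g)
  use <- !is.na(f) & f > 0 & f < 1
  geno <- geno[, use, drop = FALSE]
  f <- f[use]
  q <- 1 - f
  ## expected per-locus P(IBS = i | IBD = j)
  e00 <- 2 * f^2 * q^2
  e10 <- 4 * f^3 * q + 4 * f * q^3
  e20 <- 1 - e00 - e10
  e11 <- 2 * f^2 * q + 2 * f * q^2
  e21 <- 1 - e11
  if (is.null(pairs)) {
    pairs <- t(utils::combn(n, 2))
  }
  res <- apply(pairs, 1, function(pr) {
    a <- geno[pr[1], ]; b <- geno[pr[2], ]
    ok <- !is.na(a) & !is.na(b)
    ibs <- 2 - abs(a[ok] - b[ok])
    L <- sum(ok)
    if (L == 0) return(c(NA, NA, NA, NA))
    z0 <- sum(ibs == 0) / sum(e00[ok])
    z1 <- (sum(ibs == 1) - z0 * sum(e10[ok])) / sum(e11[ok])
    z2 <- (sum(ibs == 2) - z0 * sum(e20[ok]) - z1 * sum(e21[ok])) / L
    z <- pmin(1, pmax(0, c(z0, z1, z2)))
    z <- z / sum(z)
    c(z, z[2] / 2 + z[3])
  })
  data.frame(
    i = pairs[, 1], j = pairs[, 2],
    z0 = res[1, ], z1 = res[2, ], z2 = res[3, ],
    pihat = pmin(1, pmax(0, res[4, ]))
  )
}

#' Two-locus linkage disequilibrium by EM
#'
#' Estimates the four two-locus haplotype frequencies from unphased diploid
#' genotypes by expectation-maximization over the double-heterozygote phase
#' ambiguity, then reports the normalized disequilibrium coefficients D' and
#' r-squared.
#'
#' @param ga,gb genotype vectors (0/1/2, NA allowed) at the two variants, or a
#'   [geno_matrix] plus two variant ids/indices via `g`, `a`, `b`.
#' @param tol convergence tolerance on the max haplotype-frequency change.
#' @param max_iter iteration cap.
#' @return list with `d_prime`, `r2`, `D`, `hap_freqs` (named AB, Ab, aB, ab,
#'   where A/B are the alternate alleles) and the iteration count.
#' @export
ld_em <- function(ga, gb, tol = 1e-10, max_iter = 1000) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  n <- length(ga)
  pA <- mean(ga) / 2
  pB <- mean(gb) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    stop("linkage disequilibrium undefined for monomorphic variants")
  }
  ## 3x3 genotype table; only the double heterozygote is phase-ambiguous
  tab <- table(factor(ga, 0:2), factor(gb, 0:2))
  ## start at linkage equilibrium; frequencies of haplotypes AB, Ab, aB, ab
  ## (A = alt at locus 1, B = alt at locus 2)
  h <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  n_dh <- tab["1", "1"]
  ## haplotype counts fixed by unambiguous genotypes:
  fixed <- c(
    AB = 2 * tab["2", "2"] + tab["2", "1"] + tab["1", "2"],
    Ab = 2 * tab["2", "0"] + tab["2", "1"] + tab["1", "0"],
    aB = 2 * tab["0", "2"] + tab["0", "1"] + tab["1", "2"],
    ab = 2 * tab["0", "0"] + tab["0", "1"] + tab["1", "0"]
  )
  ll_old <- -Inf
  iter <- 0
  repeat {
    iter <- iter + 1
    ## E step: split double heterozygotes between AB/ab and Ab/aB phases
    w <- h["AB"] * h["ab"]
    w <- if (w + h["Ab"] * h["aB"] == 0) 0.5 else w / (w + h["Ab"] * h["aB"])
    counts <- fixed + n_dh * c(w, 1 - w, 1 - w, w)
    h_new <- counts / (2 * n)
    ll <- sum(fixed * log(pmax(h_new, 1e-300))) +
      n_dh * log(max(2 * (h_new["AB"] * h_new["ab"] + h_new["Ab"] * h_new["aB"]), 1e-300))
    if (ll < ll_old - 1e-9) stop("EM log-likelihood decreased")  # invariant
    delta <- max(abs(h_new - h))
    h <- h_new
    ll_old <- ll
    if (delta < tol || iter >= max_iter) break
  }
  D <- h["AB"] - pA * pB
  d_max <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (d_max == 0) 0 else abs(D) / d_max
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(
    d_prime = unname(min(1, d_prime)), r2 = unname(min(1, r2)),
    D = unname(D), hap_freqs = h, n_iter = iter
  )
}

#' @rdname ld_em
#' @param g a [geno_matrix].
#' @param a,b variant ids or column indices.
#' @export
ld_em_variants <- function(g, a, b, tol = 1e-10, max_iter = 1000) {
  if (is.character(a)) a <- match(a, g$variants$id)
  if (is.character(b)) b <- match(b, g$variants$id)
  ld_em(g$geno[, a], g$geno[, b], tol = tol, max_iter = max_iter)
}

#' Haplotype span arithmetic
#'
#' Length of a closed physical interval, with the kb figure reported as
#' `floor(bp / 1000)` (a shared span of 571,082 bp is "at least 571 kb").
#'
#' @param start_bp,end_bp 1-based physical coordinates, `end_bp >= start_bp`.
#' @return list with `bp` and `kb`.
#' @export
haplotype_span <- function(start_bp, end_bp) {
  stopifnot(end_bp >= start_bp)
  bp <- end_bp - start_bp
  list(bp = bp, kb = floor(bp / 1000))
}

#' Maximal interval shared by all carrier haplotypes
#'
#' Given phased haplotypes that each carry the focal derived allele, finds the
#' maximal closed interval around the focal position over which all carrier
#' haplotypes are identical (zero allele mismatches), and per-pair extended
#' matching intervals.
#'
#' @param haps matrix of phased haplotypes (haplotypes x variants, alleles 0/1).
#' @param pos physical positions of the variants (strictly increasing).
#' @param focal_pos position of the focal variant (must be one of `pos`).
#' @return list with `start_bp`, `end_bp`, `span` (from [haplotype_span]) for
#'   the all-carrier interval, and `pairs`: a data.frame of pairwise intervals.
#' @export
shared_carrier_haplotype <- function(haps, pos, focal_pos) {
  stopifnot(nrow(haps) >= 2, ncol(haps) == length(pos))
  k <- match(focal_pos, pos)
  if (is.na(k)) stop("focal position is not a typed variant")
  if (any(haps[, k] != 1)) stop("every carrier haplotype must carry the focal allele")
  span_idx <- function(rows) {
    ident <- apply(haps[rows, , drop = FALSE], 2, function(a) all(a == a[1]))
    l <- k; while (l > 1 && ident[l - 1]) l <- l - 1
    r <- k; while (r < length(pos) && ident[r + 1]) r <- r + 1
    c(l, r)
  }
  all_iv <- span_idx(seq_len(nrow(haps)))
  prs <- t(utils::combn(nrow(haps), 2))
  piv <- t(apply(prs, 1, span_idx))
  list(
    start_bp = pos[all_iv[1]], end_bp = pos[all_iv[2]],
    span = haplotype_span(pos[all_iv[1]], pos[all_iv[2]]),
    pairs = data.frame(
      hap_a = prs[, 1], hap_b = prs[, 2],
      start_bp = pos[piv[, 1]], end_bp = pos[piv[, 2]]
    )
  )
}

#' Fisher's method for combining p-values
#'
#' Combines k independent p-values via `X2 = -2 * sum(log(p))` referred to a
#' chi-square distribution with 2k degrees of freedom.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return list with `statistic`, `df` and the combined `p`.
#' @export
fisher_meta <- function(p_values) {
  stopifnot(length(p_values) >= 1, all(p_values > 0), all(p_values <= 1))
  x2 <- -2 * sum(log(p_values))
  k <- length(p_values)
  list(statistic = x2, df = 2 * k,
       p = stats::pchisq(x2, df = 2 * k, lower.tail = FALSE))
}

#' Sample size required to detect an additive variant
#'
#' Normal-approximation power calculation for a single-variant additive test:
#' the non-centrality per individual equals the fraction of trait variance the
#' variant explains, `VE = 2 f (1-f) beta_std^2`, so
#' `N = (z_{1-alpha/2} + z_{power})^2 / VE`, rounded up.
#'
#' @param ve variance explained (fraction in (0,1)); alternatively supply
#'   `maf` and `beta_std` (standardized per-allele effect).
#' @param maf,beta_std effect-allele frequency and standardized effect, used
#'   when `ve` is missing.
#' @param alpha significance level (default genome-wide 5e-8).
#' @param power target power (default 0.8).
#' @return required sample size (integer; `Inf` when `ve` is 0).
#' @export
required_sample_size <- function(ve = NULL, maf = NULL, beta_std = NULL,
                                 alpha = 5e-8, power = 0.8) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  if (is.null(ve)) {
    stopifnot(!is.null(maf), !is.null(beta_std))
    ve <- 2 * maf * (1 - maf) * beta_std^2
  }
  stopifnot(ve >= 0, ve < 1)
  if (ve == 0) return(Inf)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  ceiling(z^2 / ve)
}

#' Allele age from population frequency
#'
#' Expected age of a neutral derived allele at frequency p in a population of
#' effective size Ne (Kimura-Ohta): `-4 Ne p log(p) / (1 - p)` generations,
#' converted to years with a configurable generation time.
#'
#' @param freq derived-allele frequency in (0, 1).
#' @param effective_size effective population size Ne (default 10,000).
#' @param generation_years years per generation (default 25).
#' @return list with `generations` and `years`.
#' @export
allele_age_frequency <- function(freq, effective_size = 10000,
                                 generation_years = 25) {
  stopifnot(freq > 0, freq < 1, effective_size > 0, generation_years > 0)
  gens <- -4 * effective_size * freq * log(freq) / (1 - freq)
  list(generations = gens, years = gens * generation_years)
}

#' Years to the common ancestor implied by a generation count
#'
#' The mean number of generations back to the genealogical nearest neighbour's
#' common ancestor, times the generation time, is a lower bound on the age of
#' a mutation shared through that ancestor.
#'
#' @param generations mean generations to the common ancestor.
#' @param generation_years years per generation (default 25).
#' @return age lower bound in years.
#' @export
generations_to_years <- function(generations, generation_years = 25) {
  stopifnot(generations > 0, generation_years > 0)
  generations * generation_years
}
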