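## Independent oracles used across test files. These deliberately avoid the
## package's internal code paths: emissions, transitions and maximizations
## are recomputed from the model definition by direct enumeration.

## Brute-force maximum over every surrogate-parent pair path. States are all
## unordered pairs of the m candidates; transitions use the per-parent
## "stay with 1-s, else uniform redraw" kernel, emissions the Mendelian
## transmission model with miscall probability e. Returns the maximal path
## log-probability and one maximizing path.
oracle_viterbi <- function(gt, cand_geno, cM, error_rate, switch_rate) {
  m <- nrow(cand_geno)
  n <- length(gt)
  pairs <- t(combn(m, 2))
  S <- nrow(pairs)
  pa <- cand_geno / 2
  pa[is.na(pa)] <- 0.5
  emit <- function(state, t) {
    if (is.na(gt[t])) return(0)
    a <- pa[pairs[state, 1], t]
    b <- pa[pairs[state, 2], t]
    pt <- c((1 - a) * (1 - b), a * (1 - b) + (1 - a) * b, a * b)[gt[t] + 1]
    log(error_rate / 2 + (1 - 1.5 * error_rate) * pt)
  }
  trans <- function(s1, s2, s) {
    u <- s / m
    Tk <- function(x, y) if (x == y) 1 - s + u else u
    a <- pairs[s1, 1]; b <- pairs[s1, 2]
    c_ <- pairs[s2, 1]; d <- pairs[s2, 2]
    log(Tk(a, c_) * Tk(b, d) + Tk(a, d) * Tk(b, c_))
  }
  sw <- 1 - exp(-switch_rate * diff(cM) / 100)
  ## tabulate emissions and per-interval transitions once, then score every
  ## one of the S^n paths by vectorized lookups (tests keep S^n small)
  E <- outer(seq_len(S), seq_len(n), Vectorize(emit))
  Tlist <- lapply(seq_len(max(n - 1, 0)), function(t) {
    outer(seq_len(S), seq_len(S), Vectorize(function(s1, s2) trans(s1, s2, sw[t])))
  })
  score <- function(p) {
    lp <- E[p[1], 1]
    if (n > 1) {
      for (t in 2:n) lp <- lp + Tlist[[t - 1]][p[t - 1], p[t]] + E[p[t], t]
    }
    lp
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  lp <- E[cbind(paths[, 1], 1)]
  if (n > 1) {
    for (t in 2:n) {
      lp <- lp + Tlist[[t - 1]][cbind(paths[, t - 1], paths[, t])] +
        E[cbind(paths[, t], t)]
    }
  }
  best <- which.max(lp)
  list(log_prob = lp[best], path = paths[best, ], pairs = pairs, score = score)
}

## Exact HWE p-value by the Wigginton-style recurrence over heterozygote
## counts (a different route than the package's log-factorial enumeration).
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  rare <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)
  if (n == 0 || rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  mid <- hets[which.min(abs(hets - rare * (2 * n - rare) / (2 * n)))]
  probs[hets == mid] <- 1
  ## downward recurrence: P(h-2)/P(h) = h(h-1) / (4 (nr+1) (nc+1))
  if (mid >= 2) {
    for (h in seq(mid, 2, by = -2)) {
      nr <- (rare - h) / 2
      nc <- n - h - nr
      probs[hets == h - 2] <- probs[hets == h] * h * (h - 1) /
        (4 * (nr + 1) * (nc + 1))
    }
  }
  ## upward recurrence: P(h+2)/P(h) = 4 nr nc / ((h+2)(h+1))
  if (mid <= rare - 2) {
    for (h in seq(mid, rare - 2, by = 2)) {
      nr <- (rare - h) / 2
      nc <- n - h - nr
      probs[hets == h + 2] <- probs[hets == h] * 4 * nr * nc /
        ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- probs[hets == n_ab]
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

## Direct haplotype counting for LD when phase is unambiguous (no double
## heterozygotes in the data).
oracle_ld_counting <- function(ga, gb) {
  stopifnot(!any(ga == 1 & gb == 1))
  n <- length(ga)
  cnt <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (k in seq_len(n)) {
    a <- ga[k]; b <- gb[k]
    ## each individual contributes two haplotypes; with no double het the
    ## phase split is unique: the alt alleles ride together on haplotype 1
    h1 <- c(min(a, 1), min(b, 1))
    h2 <- c(a, b) - h1
    for (hh in list(h1, h2)) {
      key <- paste0(if (hh[1] == 1) "A" else "a", if (hh[2] == 1) "B" else "b")
      cnt[key] <- cnt[key] + 1
    }
  }
  cnt / (2 * n)
}

## Two-sample KS statistic by double-loop ECDF evaluation.
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(p) abs(mean(x <= p) - mean(y <= p)), 0))
}

## Small genotype-matrix fixture builder.
make_geno <- function(geno, pos = NULL, chrom = "11") {
  geno <- as.matrix(geno)
  if (is.null(pos)) pos <- seq(1e6, by = 1e6, length.out = ncol(geno))
  geno_matrix(geno, chrom = chrom, pos = pos)
}
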