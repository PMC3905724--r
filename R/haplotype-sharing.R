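#' Configuration for surrogate-parent haplotype sharing
#'
#' Parameters of the long-range-phasing-style hidden Markov model that
#' assigns each target individual a pair of "surrogate parents" — two other
#' cohort members whose genotypes are locally compatible with Mendelian
#' transmission of the target's genotype.
#'
#' @param error_rate per-genotype miscall probability allowed when matching
#'   the target's genotype (default 0.01).
#' @param switch_rate intensity, per Morgan, at which a surrogate parent can
#'   change between adjacent variants (default 1; the switch probability over
#'   genetic distance d Morgans is `1 - exp(-switch_rate * d)` per parent).
#' @param candidate_set optional sample IDs eligible as surrogate parents;
#'   default all samples other than the target.
#' @param relatedness_cap when a kinship matrix is supplied, candidates with
#'   kinship to the target at or above this value are excluded (default 0.2),
#'   so that sharing reflects distant genealogy rather than close relatives.
#' @export
lrp_config <- function(error_rate = 0.01, switch_rate = 1,
                       candidate_set = NULL, relatedness_cap = 0.2) {
  stopifnot(error_rate >= 0, error_rate < 0.5, switch_rate > 0,
            relatedness_cap > 0)
  structure(list(error_rate = error_rate, switch_rate = switch_rate,
                 candidate_set = candidate_set,
                 relatedness_cap = relatedness_cap),
            class = "lrp_config")
}

## Emission log-probabilities for every unordered candidate pair at every
## site. paM: candidates x sites matrix of P(transmit alt) = genotype/2
## (0.5 where the candidate call is missing). Target genotype gt; a missing
## target call emits probability 1. Error model: the observed target genotype
## is a miscall with probability e, uniform over the two wrong values, so
## P(obs | pair) = e/2 + (1 - 3e/2) * P(true = obs | pair).
.lrp_emissions <- function(gt, paM, i_idx, j_idx, e) {
  A <- paM[i_idx, , drop = FALSE]
  B <- paM[j_idx, , drop = FALSE]
  S <- length(i_idx); n <- length(gt)
  Pt <- matrix(1, S, n)
  for (t in seq_len(n)) {
    if (is.na(gt[t])) next
    a <- A[, t]; b <- B[, t]
    Pt[, t] <- switch(as.character(gt[t]),
                      "0" = (1 - a) * (1 - b),
                      "1" = a * (1 - b) + (1 - a) * b,
                      "2" = a * b)
  }
  E <- e / 2 + (1 - 1.5 * e) * Pt
  E[, is.na(gt)] <- 1
  log(E)
}

## Viterbi decode over unordered candidate pairs. The per-parent switch
## kernel is "stay with 1-s, else redraw uniformly over the m candidates",
## so the pair-to-pair transition probability depends only on how many
## candidates the two pairs share (2, 1 or 0), which lets the maximization
## over predecessors run in O(S + m) per site instead of O(S^2):
##   overlap 2: v^2 + u^2,  overlap 1: u (v + u),  overlap 0: 2 u^2
## with u = s/m and v = 1 - s + u. Overlap-2 never has the smallest
## coefficient, so relaxed per-candidate maxima cannot overstate the true
## maximum; ties break deterministically toward staying, then toward the
## lowest pair index (pairs are enumerated in lexicographic candidate order).
.lrp_viterbi <- function(logE, s_vec, m, i_idx, j_idx) {
  S <- nrow(logE); n <- ncol(logE)
  rows_by_cand <- lapply(seq_len(m), function(x) which(i_idx == x | j_idx == x))
  delta <- logE[, 1]
  choice <- matrix(0L, S, n)      # 0 stay, 1 via Mc[i], 2 via Mc[j], 3 global
  mc_arg <- matrix(0L, m, n)
  g_arg <- integer(n)
  for (t in 2:n) {
    s <- s_vec[t - 1]
    u <- s / m
    v <- 1 - s + u
    l2 <- log(v^2 + u^2)
    l1 <- log(u * (v + u))
    l0 <- log(2) + 2 * log(u)
    Mc <- numeric(m); McA <- integer(m)
    for (x in seq_len(m)) {
      rows <- rows_by_cand[[x]]
      k <- which.max(delta[rows])
      Mc[x] <- delta[rows[k]]
      McA[x] <- rows[k]
    }
    G <- which.max(delta)
    val2 <- delta + l2
    v1i <- Mc[i_idx] + l1
    v1j <- Mc[j_idx] + l1
    val0 <- delta[G] + l0
    best <- pmax(val2, v1i, v1j, val0)
    ## precedence on ties: stay > via-i > via-j > global
    ch <- ifelse(val2 >= best - 1e-12, 0L,
                 ifelse(v1i >= best - 1e-12, 1L,
                        ifelse(v1j >= best - 1e-12, 2L, 3L)))
    choice[, t] <- ch
    mc_arg[, t] <- McA
    g_arg[t] <- G
    delta <- logE[, t] + best
  }
  ## traceback
  path <- integer(n)
  path[n] <- which.max(delta)
  for (t in n:2) {
    j <- path[t]
    path[t - 1] <- switch(choice[j, t] + 1L,
                          j,                      # stay
                          mc_arg[i_idx[j], t],    # best pair containing i
                          mc_arg[j_idx[j], t],    # best pair containing j
                          g_arg[t])               # global best
  }
  list(path = path, log_prob = max(delta))
}

#' Surrogate-parent path by the Viterbi algorithm
#'
#' For a target individual, decodes the most probable path of surrogate-parent
#' pairs along one chromosome. The hidden state is an unordered pair of other
#' cohort members; the emission probability at each variant is the chance that
#' the target's genotype arises by each pseudo-parent transmitting one allele
#' drawn uniformly from its own genotype, with the observed genotype miscalled
#' with probability `error_rate`; between adjacent variants at genetic
#' distance d Morgans each pseudo-parent independently switches with
#' probability `1 - exp(-switch_rate * d)` to a uniformly redrawn candidate.
#' All arithmetic is in log space. Ties break deterministically toward the
#' lowest candidate indices.
#'
#' @param g a [geno_matrix] restricted to one chromosome.
#' @param target sample ID or index of the target individual.
#' @param map a [genetic_map] covering all variant positions.
#' @param cfg an [lrp_config].
#' @param kinship optional kinship matrix; candidates with kinship to the
#'   target >= `cfg$relatedness_cap` are excluded.
#' @param focal_pos optional vector of focal physical positions at which to
#'   extract shared segments (see Details).
#' @return list with `path` (data.frame: site, pos, cM, parent1, parent2),
#'   `log_prob` of the decoded path, `candidates`, and `segments`: for each
#'   focal position and each of the two surrogates at that position, the
#'   maximal run of variants over which that surrogate stays in the decoded
#'   pair, reported as closed 1-based bp coordinates with cM bounds.
#' @export
viterbi_surrogate_parents <- function(g, target, map, cfg = lrp_config(),
                                      kinship = NULL, focal_pos = NULL) {
  ids <- sample_ids(g)
  if (is.character(target)) target <- match(target, ids)
  stopifnot(!is.na(target), target >= 1, target <= length(ids))
  cand <- if (is.null(cfg$candidate_set)) setdiff(seq_along(ids), target)
          else setdiff(match(cfg$candidate_set, ids), target)
  if (!is.null(kinship)) {
    kin <- kinship[ids[target], ids[cand]]
    cand <- cand[kin < cfg$relatedness_cap]
  }
  cand <- sort(cand)
  if (length(cand) < 2) stop("need at least 2 surrogate-parent candidates")
  m <- length(cand)
  chrom <- g$variants$chrom[1]
  stopifnot(all(g$variants$chrom == chrom))
  cM <- map_cM(map, chrom, g$variants$pos)
  prs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  ord <- order(prs[, 1], prs[, 2])
  i_idx <- prs[ord, 1]; j_idx <- prs[ord, 2]
  paM <- g$geno[cand, , drop = FALSE] / 2
  paM[is.na(paM)] <- 0.5
  logE <- .lrp_emissions(g$geno[target, ], paM, i_idx, j_idx, cfg$error_rate)
  d_morgans <- diff(cM) / 100
  s_vec <- 1 - exp(-cfg$switch_rate * d_morgans)
  if (ncol(logE) == 1) {
    dec <- list(path = which.max(logE[, 1]), log_prob = max(logE[, 1]))
  } else {
    dec <- .lrp_viterbi(logE, s_vec, m, i_idx, j_idx)
  }
  p1 <- cand[i_idx[dec$path]]
  p2 <- cand[j_idx[dec$path]]
  path_df <- data.frame(site = seq_along(dec$path), pos = g$variants$pos,
                        cM = cM, parent1 = ids[p1], parent2 = ids[p2],
                        stringsAsFactors = FALSE)
  segments <- NULL
  if (!is.null(focal_pos)) {
    segments <- do.call(rbind, lapply(focal_pos, function(fp) {
      k <- which.min(abs(g$variants$pos - fp))
      surr <- c(p1[k], p2[k])
      do.call(rbind, lapply(surr, function(sx) {
        inpair <- p1 == sx | p2 == sx
        l <- k; while (l > 1 && inpair[l - 1]) l <- l - 1
        r <- k; while (r < length(inpair) && inpair[r + 1]) r <- r + 1
        data.frame(
          target = ids[target], surrogate = ids[sx], chrom = chrom,
          focal_pos = fp,
          start_bp = g$variants$pos[l], end_bp = g$variants$pos[r],
          start_cM = cM[l], end_cM = cM[r],
          length_bp = g$variants$pos[r] - g$variants$pos[l],
          length_cM = cM[r] - cM[l],
          contains_focal = TRUE, stringsAsFactors = FALSE
        )
      }))
    }))
  }
  list(path = path_df, log_prob = dec$log_prob, candidates = ids[cand],
       segments = segments)
}

#' Maximal haplotype identity between two samples by direct scan
#'
#' The maximal closed interval containing the focal position over which the
#' two samples' genotypes never contradict sharing a haplotype — i.e. contain
#' no opposite homozygotes — allowing up to `max_mismatch` opposite-homozygote
#' sites as genotyping-error tolerance. Boundaries are the outermost
#' compatible variant positions. This direct scan is the model-free
#' cross-check for the HMM-based segments.
#'
#' @param g a [geno_matrix] restricted to one chromosome.
#' @param sample_a,sample_b sample IDs or indices.
#' @param focal_pos physical position inside the typed range.
#' @param map a [genetic_map].
#' @param max_mismatch tolerated opposite-homozygote count (default 0).
#' @return one-row data.frame in the [viterbi_surrogate_parents] segment
#'   format.
#' @export
maximal_identity_pair <- function(g, sample_a, sample_b, focal_pos, map,
                                  max_mismatch = 0) {
  ids <- sample_ids(g)
  if (is.character(sample_a)) sample_a <- match(sample_a, ids)
  if (is.character(sample_b)) sample_b <- match(sample_b, ids)
  pos <- g$variants$pos
  if (focal_pos < pos[1] || focal_pos > pos[length(pos)]) {
    stop("focal position outside the typed variant range")
  }
  chrom <- g$variants$chrom[1]
  k <- which.min(abs(pos - focal_pos))
  a <- g$geno[sample_a, ]; b <- g$geno[sample_b, ]
  opp <- !is.na(a) & !is.na(b) & abs(a - b) == 2
  n <- length(pos)
  ## split the mismatch budget between the two flanks to maximize bp span
  left_mm <- which(opp[seq_len(k)])            # ascending positions
  right_mm <- which(opp[seq(k, n)]) + k - 1
  if (opp[k]) {
    left_mm <- setdiff(left_mm, k); right_mm <- setdiff(right_mm, k)
  }
  budget <- max_mismatch - as.integer(opp[k])
  if (budget < 0) {
    l <- r <- k
  } else {
    best <- c(k, k, -1)
    for (jl in 0:budget) {
      jr <- budget - jl
      ## allowing jl mismatches on the left: extend past the jl nearest ones
      nl <- length(left_mm); nr <- length(right_mm)
      l <- if (nl > jl) left_mm[nl - jl] + 1 else 1
      r <- if (nr > jr) right_mm[jr + 1] - 1 else n
      if (pos[r] - pos[l] > best[3]) best <- c(l, r, pos[r] - pos[l])
    }
    l <- best[1]; r <- best[2]
  }
  cM <- map_cM(map, chrom, pos[c(l, r)])
  data.frame(
    target = ids[sample_a], surrogate = ids[sample_b], chrom = chrom,
    focal_pos = focal_pos,
    start_bp = pos[l], end_bp = pos[r], start_cM = cM[1], end_cM = cM[2],
    length_bp = pos[r] - pos[l], length_cM = cM[2] - cM[1],
    contains_focal = TRUE, stringsAsFactors = FALSE
  )
}

#' Haplotype-sharing profile over a position grid
#'
#' For each target sample and each grid position, the length (bp and cM) of
#' the maximal identity segment between the target and its genealogical
#' nearest neighbour — the Viterbi-selected surrogate parent whose run around
#' the grid point is longest. One Viterbi decode per target serves the whole
#' grid.
#'
#' @param g a [geno_matrix] restricted to one chromosome.
#' @param map a [genetic_map].
#' @param cfg an [lrp_config].
#' @param grid physical positions at which sharing is measured (non-empty).
#' @param targets sample IDs or indices to profile (default all samples).
#' @param carriers sample IDs carrying the focal allele (for downstream
#'   carrier/non-carrier comparisons); default none.
#' @param kinship optional kinship matrix for candidate restriction.
#' @return a `sharing_profile`: list with `grid`, `grid_cM`, matrices
#'   `len_bp` and `len_cM` (targets x grid points), `targets`, `is_carrier`,
#'   and the per-target, per-grid-point `segments` data.frame.
#' @export
sharing_profile <- function(g, map, cfg = lrp_config(), grid,
                            targets = NULL, carriers = character(0),
                            kinship = NULL) {
  stopifnot(length(grid) >= 1)
  ids <- sample_ids(g)
  if (is.null(targets)) targets <- ids
  if (is.numeric(targets)) targets <- ids[targets]
  chrom <- g$variants$chrom[1]
  len_bp <- matrix(NA_real_, length(targets), length(grid),
                   dimnames = list(targets, NULL))
  len_cM <- len_bp
  segs <- vector("list", length(targets))
  for (ti in seq_along(targets)) {
    dec <- viterbi_surrogate_parents(g, targets[ti], map, cfg,
                                     kinship = kinship, focal_pos = grid)
    s <- dec$segments
    ## nearest neighbour at each grid point = surrogate with the longer run
    picked <- do.call(rbind, lapply(seq_along(grid), function(gi) {
      sub <- s[s$focal_pos == grid[gi], ]
      sub[which.max(sub$length_cM), ]
    }))
    len_bp[ti, ] <- picked$length_bp
    len_cM[ti, ] <- picked$length_cM
    segs[[ti]] <- picked
  }
  structure(
    list(grid = grid, grid_cM = map_cM(map, chrom, grid),
         len_bp = len_bp, len_cM = len_cM, targets = targets,
         is_carrier = targets %in% carriers,
         median_len_bp = apply(len_bp, 2, stats::median),
         median_len_cM = apply(len_cM, 2, stats::median),
         segments = do.call(rbind, segs)),
    class = "sharing_profile"
  )
}

#' @export
print.sharing_profile <- function(x, ...) {
  cat("sharing_profile:", length(x$targets), "targets x", length(x$grid),
      "grid positions;", sum(x$is_carrier), "carriers\n",
      sprintf("median nearest-neighbour segment: %.2f cM (%.2f Mb)\n",
              stats::median(x$len_cM), stats::median(x$len_bp) / 1e6))
  invisible(x)
}

#' Compare carrier and non-carrier sharing at a focal position
#'
#' Two-sample Kolmogorov-Smirnov test on maximal-identity segment lengths at
#' the grid point nearest the focal position: extensive recent co-ancestry of
#' carriers would show as a length distribution shifted upward relative to
#' non-carriers.
#'
#' @param profile a [sharing_profile] with at least 2 carriers and 2
#'   non-carriers.
#' @param focal_pos focal physical position.
#' @return list with the KS `D` statistic, `p` value and the group sizes.
#' @export
compare_carriers <- function(profile, focal_pos) {
  gi <- which.min(abs(profile$grid - focal_pos))
  x <- profile$len_cM[profile$is_carrier, gi]
  y <- profile$len_cM[!profile$is_carrier, gi]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least 2 carriers and 2 non-carriers")
  }
  kt <- suppressWarnings(stats::ks.test(x, y))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_carriers = length(x), n_noncarriers = length(y))
}

#' Generations to the common ancestor from shared-segment lengths
#'
#' Model: the shared segment extends left and right of the focal point by
#' independent exponential lengths with rate 2G per Morgan (2G meioses
#' separate the pair through a common ancestor G generations back), so the
#' total length is Gamma(shape 2, rate 2G). The maximum-likelihood estimate
#' is `G = 1 / mean(length in Morgans)`; the CI comes from the exact Gamma
#' sampling distribution of the total.
#'
#' @param lengths_cM positive segment lengths in cM.
#' @param conf confidence level (default 0.95).
#' @return list with `G`, `ci` (lower, upper) and `n`.
#' @export
estimate_generations <- function(lengths_cM, conf = 0.95) {
  stopifnot(length(lengths_cM) >= 1, all(lengths_cM > 0))
  L <- lengths_cM / 100           # Morgans
  n <- length(L)
  G <- 1 / mean(L)
  ## sum(L) * 2G ~ Gamma(shape 2n, rate 1)
  a <- (1 - conf) / 2
  ci <- stats::qgamma(c(a, 1 - a), shape = 2 * n) / (2 * sum(L))
  list(G = G, ci = ci, n = n)
}

#' Decay of excess carrier sharing with distance from the focal locus
#'
#' At each grid point, the excess is the mean sharing length among carriers
#' minus the mean among non-carriers; excess driven by co-ancestry at the
#' focal locus decays with genetic distance from it. An exponential decay
#' rate is fitted by least squares on the log of the positive excess values.
#'
#' @param profile a [sharing_profile] with at least 2 carriers.
#' @param focal_pos focal physical position.
#' @return list with `table` (distance_cM, excess_cM), fitted `rate` per cM
#'   (NA when no positive excess), and `intercept`.
#' @export
excess_relatedness_decay <- function(profile, focal_pos) {
  if (sum(profile$is_carrier) < 2) stop("need at least 2 carriers")
  exc <- colMeans(profile$len_cM[profile$is_carrier, , drop = FALSE]) -
    colMeans(profile$len_cM[!profile$is_carrier, , drop = FALSE])
  gi <- which.min(abs(profile$grid - focal_pos))
  dist <- abs(profile$grid_cM - profile$grid_cM[gi])
  tab <- data.frame(distance_cM = dist, excess_cM = exc)
  pos <- tab$excess_cM > 0
  if (sum(pos) >= 2 && stats::var(tab$distance_cM[pos]) > 0) {
    fit <- stats::lm(log(excess_cM) ~ distance_cM, data = tab[pos, ])
    rate <- -unname(stats::coef(fit)[2])
    icpt <- exp(unname(stats::coef(fit)[1]))
  } else {
    rate <- NA_real_
    icpt <- NA_real_
  }
  list(table = tab[order(tab$distance_cM), ], rate = rate, intercept = icpt)
}

#' Write shared segments as BED-like TSV
#'
#' Internally segments are closed 1-based `[start_bp, end_bp]`; the BED body
#' is 0-based half-open, so `chromStart = start_bp - 1` and
#' `chromEnd = end_bp`. cM columns are appended after the standard fields.
#'
#' @param segments segment data.frame from [viterbi_surrogate_parents] or
#'   [sharing_profile].
#' @param path output path.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(
    chrom = segments$chrom, chromStart = segments$start_bp - 1,
    chromEnd = segments$end_bp,
    name = paste0(segments$target, "|", segments$surrogate),
    score = 0, strand = ".",
    start_cM = segments$start_cM, end_cM = segments$end_cM,
    length_cM = segments$length_cM
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
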