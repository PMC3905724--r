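## Build a trio-plus-strangers cohort: target's genotype is exactly the sum
## of one allele from each true parent, with no recombination and no error.
make_trio_cohort <- function(n_strangers = 8, n_var = 120, seed = 8) {
  set.seed(seed)
  f <- runif(n_var, 0.2, 0.8)
  hap <- function() rbinom(n_var, 1, f)
  p1 <- rbind(hap(), hap())
  p2 <- rbind(hap(), hap())
  child <- p1[1, ] + p2[1, ]
  strangers <- t(replicate(n_strangers, hap() + hap()))
  geno <- rbind(child, colSums(p1), colSums(p2), strangers)
  rownames(geno) <- c("child", "dad", "mum", sprintf("X%02d", 1:n_strangers))
  g <- geno_matrix(geno, chrom = "11",
                   pos = sort(sample(2e5:1.98e7, n_var)))
  rownames(g$geno) <- rownames(geno)
  g
}

test_that("a true trio is decoded as surrogate parents across the chromosome", {
  g <- make_trio_cohort()
  map <- uniform_map("11", 2e7, 1)
  v <- viterbi_surrogate_parents(g, "child", map, lrp_config(error_rate = 0.01),
                                 focal_pos = 1e7)
  expect_true(all(v$path$parent1 %in% c("dad", "mum") &
                    v$path$parent2 %in% c("dad", "mum")))
  seg <- v$segments
  expect_equal(unique(seg$start_bp), g$variants$pos[1])
  expect_equal(unique(seg$end_bp), g$variants$pos[n_variants(g)])
  expect_true(all(seg$contains_focal))
})

test_that("Viterbi decoding equals brute-force path enumeration", {
  set.seed(18)
  for (rep in 1:30) {
    m <- sample(3:4, 1)
    n <- sample(2:5, 1)
    cand <- matrix(sample(0:2, m * n, TRUE), m, n)
    gt <- sample(c(0:2, NA), n, TRUE, prob = c(0.3, 0.3, 0.3, 0.1))
    pos <- sort(sample(1e6:2e7, n))
    g <- geno_matrix(rbind(gt, cand), chrom = "11", pos = pos)
    rownames(g$geno) <- c("T", paste0("C", 1:m))
    map <- uniform_map("11", 2.1e7, sample(c(1, 5), 1))
    e <- runif(1, 0.005, 0.05)
    v <- viterbi_surrogate_parents(g, "T", map, lrp_config(error_rate = e))
    orc <- oracle_viterbi(gt, cand, map_cM(map, "11", pos), e,
                          switch_rate = 1)
    expect_equal(v$log_prob, orc$log_prob, tolerance = 1e-9)
    ## the decoded path itself attains the maximum under the oracle's scorer
    cand_ids <- paste0("C", 1:m)
    states <- apply(
      cbind(match(v$path$parent1, cand_ids), match(v$path$parent2, cand_ids)),
      1, function(pr) which(orc$pairs[, 1] == min(pr) & orc$pairs[, 2] == max(pr)))
    expect_equal(orc$score(states), orc$log_prob, tolerance = 1e-9)
  }
})

test_that("ties between identical candidates break to the lowest indices", {
  same <- rep(1L, 6)
  geno <- rbind(T1 = same, A = same, B = same, C = same)
  g <- geno_matrix(geno, chrom = "11", pos = seq(1e6, 6e6, by = 1e6))
  rownames(g$geno) <- rownames(geno)
  map <- uniform_map("11", 7e6, 1)
  v <- viterbi_surrogate_parents(g, "T1", map, lrp_config())
  expect_true(all(v$path$parent1 == "A"))
  expect_true(all(v$path$parent2 == "B"))
})

test_that("direct-scan maximal identity handles edge and budget cases", {
  map <- uniform_map("11", 2e7, 1)
  pos <- seq(1e6, 1e7, length.out = 10)
  ## identical samples share the whole chromosome
  a <- rbinom(10, 2, 0.5)
  g <- make_geno(rbind(a, a), pos = pos)
  seg <- maximal_identity_pair(g, 1, 2, focal_pos = 5e6, map)
  expect_equal(seg$start_bp, pos[1])
  expect_equal(seg$end_bp, pos[10])
  ## opposite homozygotes immediately flanking the focal site
  x <- c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0)
  y <- c(0, 0, 0, 2, 1, 2, 0, 0, 0, 0)
  g2 <- make_geno(rbind(x, y), pos = pos)
  seg2 <- maximal_identity_pair(g2, 1, 2, focal_pos = pos[5], map,
                                max_mismatch = 0)
  expect_equal(seg2$start_bp, pos[5])
  expect_equal(seg2$end_bp, pos[5])
  expect_equal(seg2$length_bp, 0)
  ## one unit of mismatch budget extends past a single discordance
  seg3 <- maximal_identity_pair(g2, 1, 2, focal_pos = pos[5], map,
                                max_mismatch = 1)
  expect_gt(seg3$length_bp, 0)
  expect_error(maximal_identity_pair(g2, 1, 2, focal_pos = 2e7, map),
               "outside")
})

test_that("detected segments track true IBD segments in an error-free cohort", {
  ## a wide founder pool keeps background IBD low enough that compatible
  ## intervals are dominated by the focal co-ancestry
  cfg <- isolate_config(
    n_founders = 60, n_generations = 4, final_n = 120, n_variants = 800,
    chrom_length_bp = 2e7, carrier_target_freq = 0.05, freq_tol = 0.04,
    genotype_error_rate = 0, missing_rate = 0, max_attempts = 400, seed = 77
  )
  sim <- simulate_isolate(cfg)
  truth <- sim$truth
  carriers <- which(truth$carrier_status > 0)
  expect_gte(length(carriers), 2)
  seg_overlap <- function(a1, a2, b1, b2) {
    inter <- max(0, min(a2, b2) - max(a1, b1))
    min(inter / max(a2 - a1, 1), inter / max(b2 - b1, 1))
  }
  ## direct scan vs truth for carrier pairs
  ov <- apply(truth$ibd_segments, 1, function(r) {
    det <- maximal_identity_pair(sim$genotypes, r[["i"]], r[["j"]],
                                 focal_pos = truth$focal$pos, sim$map,
                                 max_mismatch = 0)
    seg_overlap(det$start_bp, det$end_bp, r[["start_bp"]], r[["end_bp"]])
  })
  expect_gte(mean(ov >= 0.9), 0.9)
  ## HMM segment for the focal-side surrogate vs the direct scan of the
  ## same pair
  hov <- vapply(carriers[seq_len(min(4, length(carriers)))], function(tg) {
    v <- viterbi_surrogate_parents(sim$genotypes, tg, sim$map,
                                   lrp_config(error_rate = 0.01),
                                   focal_pos = truth$focal$pos)
    s <- v$segments[which.max(v$segments$length_cM), ]
    det <- maximal_identity_pair(sim$genotypes, s$target, s$surrogate,
                                 truth$focal$pos, sim$map, max_mismatch = 0)
    seg_overlap(s$start_bp, s$end_bp, det$start_bp, det$end_bp)
  }, 0)
  expect_gte(mean(hov >= 0.9), 0.75)
})

test_that("marker refinement only tightens identity constraints", {
  ## denser typing can only add opposite-homozygote constraints, so the
  ## nearest discordance flanking the focal site moves closer (never away)
  sim <- shared_sim()
  full <- sim$genotypes
  keep <- seq(1, n_variants(full), by = 2)
  half <- subset_geno(full, variants = keep)
  fp <- sim$truth$focal$pos
  nearest_mismatch <- function(g, a, b) {
    pos <- g$variants$pos
    ga <- g$geno[a, ]; gb <- g$geno[b, ]
    opp <- which(!is.na(ga) & !is.na(gb) & abs(ga - gb) == 2)
    left <- opp[pos[opp] < fp]
    right <- opp[pos[opp] > fp]
    c(if (length(left)) max(pos[left]) else -Inf,
      if (length(right)) min(pos[right]) else Inf)
  }
  for (pr in list(c(1, 2), c(3, 9), c(5, 20))) {
    nm_full <- nearest_mismatch(full, pr[1], pr[2])
    nm_half <- nearest_mismatch(half, pr[1], pr[2])
    expect_gte(nm_full[1], nm_half[1])
    expect_lte(nm_full[2], nm_half[2])
  }
})

test_that("sharing profile and carrier comparison behave on a small cohort", {
  sim <- shared_sim()
  g <- subset_geno(sim$genotypes, samples = 1:60)
  carriers <- sample_ids(g)[sim$truth$carrier_status[1:60] > 0]
  grid <- c(5e6, sim$truth$focal$pos, 1.5e7)
  prof <- sharing_profile(g, sim$map, lrp_config(), grid,
                          targets = 1:25, carriers = carriers)
  expect_equal(dim(prof$len_cM), c(25, 3))
  expect_true(all(prof$len_cM >= 0, na.rm = TRUE))
  ## single-point grid equals the single-segment computation
  p1 <- sharing_profile(g, sim$map, lrp_config(), grid[2], targets = 3)
  v <- viterbi_surrogate_parents(g, 3, sim$map, lrp_config(),
                                 focal_pos = grid[2])
  expect_equal(unname(p1$len_cM[1, 1]), max(v$segments$length_cM))
})

test_that("KS comparison of carriers equals a direct ECDF computation", {
  fake_profile <- function(x, y) {
    structure(list(
      grid = 1, grid_cM = 1,
      len_cM = matrix(c(x, y), ncol = 1),
      targets = paste0("S", seq_len(length(x) + length(y))),
      is_carrier = c(rep(TRUE, length(x)), rep(FALSE, length(y)))
    ), class = "sharing_profile")
  }
  ## identical distributions: D = 0, p = 1
  r <- compare_carriers(fake_profile(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r$D, 0)
  expect_equal(r$p, 1)
  ## disjoint supports: D = 1
  r2 <- compare_carriers(fake_profile(c(0, 0, 0), c(1, 1, 1)), 1)
  expect_equal(r2$D, 1)
  ## random inputs match the double-loop oracle
  set.seed(23)
  for (i in 1:10) {
    x <- rexp(sample(5:20, 1)); y <- rexp(sample(5:20, 1), rate = 0.7)
    r3 <- compare_carriers(fake_profile(x, y), 1)
    expect_equal(r3$D, oracle_ks_D(x, y), tolerance = 1e-12)
  }
  expect_error(compare_carriers(fake_profile(1, c(1, 2)), 1), "at least 2")
})

test_that("generation estimator matches its closed form and scales correctly", {
  ## mean length 1 Morgan (100 cM) gives G = 1
  expect_equal(estimate_generations(rep(100, 10))$G, 1)
  ## background sharing scale: mean 15.3 cM implies ~6.54 generations
  expect_equal(round(estimate_generations(rep(15.3, 50))$G, 2), 6.54)
  ## scale consistency: multiplying lengths by c divides G by c
  set.seed(31)
  L <- rexp(100, 1) * 20
  expect_equal(estimate_generations(L * 3)$G,
               estimate_generations(L)$G / 3, tolerance = 1e-12)
  ## CI covers the point estimate
  est <- estimate_generations(L)
  expect_true(est$ci[1] < est$G && est$G < est$ci[2])
  expect_error(estimate_generations(c(10, -1)))
})

test_that("excess carrier relatedness decays at the constructed rate", {
  ## synthetic profile with exact exponential excess, rate r per cM
  r_true <- 0.12
  grid_cM <- seq(0, 40, by = 2)
  n_car <- 10; n_non <- 30
  base <- 5
  excess <- 3 * exp(-r_true * grid_cM)
  len <- rbind(
    matrix(rep(base + excess, each = n_car), n_car),
    matrix(base, n_non, length(grid_cM))
  )
  prof <- structure(list(
    grid = grid_cM * 1e6, grid_cM = grid_cM, len_cM = len,
    targets = paste0("S", 1:(n_car + n_non)),
    is_carrier = c(rep(TRUE, n_car), rep(FALSE, n_non))
  ), class = "sharing_profile")
  fit <- excess_relatedness_decay(prof, focal_pos = 0)
  expect_equal(fit$rate, r_true, tolerance = 0.05 * r_true)
  ## carriers assigned at random: excess ~ 0 and no exponential fit is forced
  set.seed(41)
  len2 <- matrix(rexp(40 * length(grid_cM), 1 / base), 40)
  prof2 <- structure(list(
    grid = grid_cM * 1e6, grid_cM = grid_cM, len_cM = len2,
    targets = paste0("S", 1:40), is_carrier = sample(c(TRUE, FALSE), 40, TRUE)
  ), class = "sharing_profile")
  fit2 <- excess_relatedness_decay(prof2, focal_pos = 0)
  expect_lt(abs(mean(fit2$table$excess_cM)), 2 * base / sqrt(40))
})
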