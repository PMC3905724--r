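test_that("without noise every genotype is the sum of its two haplotypes", {
  cfg <- isolate_config(n_founders = 12, n_generations = 4, final_n = 60,
                        n_variants = 100, chrom_length_bp = 5e6,
                        carrier_target_freq = NULL,
                        genotype_error_rate = 0, missing_rate = 0, seed = 5)
  sim <- simulate_isolate(cfg)
  expect_identical(unname(sim$genotypes$geno),
                   unname(sim$truth$h1 + sim$truth$h2))
  expect_false(anyNA(sim$genotypes$geno))
  ## exactly one founder haplotype carried the derived allele
  expect_equal(sim$truth$focal$freq,
               mean(sim$truth$carrier_status) / 2)
})

test_that("injected error and missingness match their configured rates", {
  cfg <- isolate_config(n_founders = 12, n_generations = 3, final_n = 150,
                        n_variants = 300, chrom_length_bp = 5e6,
                        carrier_target_freq = NULL,
                        genotype_error_rate = 0.05, missing_rate = 0.04,
                        seed = 6)
  sim <- simulate_isolate(cfg)
  true_g <- sim$truth$h1 + sim$truth$h2
  obs <- sim$genotypes$geno
  miss <- mean(is.na(obs))
  err <- mean(obs != true_g, na.rm = TRUE)
  n_calls <- length(obs)
  expect_lt(abs(miss - 0.04), 4 * sqrt(0.04 * 0.96 / n_calls))
  expect_lt(abs(err - 0.05), 4 * sqrt(0.05 * 0.95 / n_calls))
})

test_that("allele frequency is a martingale under pure drift", {
  ## constant population size, no frequency targeting: across replicates the
  ## mean final frequency equals the founder frequency 1/(2 nF)
  freqs <- vapply(1:220, function(s) {
    cfg <- isolate_config(n_founders = 10, n_generations = 3,
                          pop_size_trajectory = c(10, 10, 10),
                          n_variants = 4, chrom_length_bp = 4e6,
                          carrier_target_freq = NULL,
                          genotype_error_rate = 0, missing_rate = 0, seed = s)
    simulate_isolate(cfg)$truth$focal$freq
  }, 0)
  expect_gt(t.test(freqs, mu = 1 / 20)$p.value, 0.01)
})

test_that("recombination breakpoints are Poisson at the map rate", {
  ## 1 cM/Mb over 1 Mb: 0.01 Morgans per meiosis. Use discordant parental
  ## haplotypes so every crossover is visible as a switch in the gamete.
  set.seed(55)
  n_mark <- 200
  map <- uniform_map("11", 1e6, 1)
  var_cM <- map_cM(map, "11", seq(1, 1e6, length.out = n_mark))
  total_cM <- max(map$cM)
  h <- rbind(rep(0L, n_mark), rep(1L, n_mark))
  anc <- cbind(1:2, 0, total_cM)
  counts <- vapply(1:10000, function(i) {
    gam <- isoshare:::.gamete(h, anc, var_cM, total_cM, focal_cM = 0.5)
    sum(diff(gam$hap) != 0)
  }, 0)
  lambda <- total_cM / 100
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 10000))
  ## chi-square of {0, >=1} categories against Poisson probabilities
  obs <- c(sum(counts == 0), sum(counts >= 1))
  expected <- 10000 * c(dpois(0, lambda), 1 - dpois(0, lambda))
  chi2 <- sum((obs - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 1))
})

test_that("true IBD segments around the focal allele shrink over generations", {
  med_len <- function(G, seeds) {
    lens <- unlist(lapply(seeds, function(s) {
      cfg <- isolate_config(n_founders = 10, n_generations = G,
                            pop_size_trajectory = rep(80, G),
                            n_variants = 50, chrom_length_bp = 2e7,
                            carrier_target_freq = 0.15, freq_tol = 0.12,
                            genotype_error_rate = 0, missing_rate = 0,
                            max_attempts = 400, seed = s)
      sim <- simulate_isolate(cfg)
      segs <- sim$truth$ibd_segments
      if (is.null(segs)) return(numeric(0))
      segs$end_cM - segs$start_cM
    }))
    median(lens)
  }
  short_g <- med_len(2, 1:6)
  long_g <- med_len(12, 1:6)
  expect_gt(short_g, long_g)
  ## IBD segments contain the focal position
  cfg <- isolate_config(n_founders = 10, n_generations = 5,
                        pop_size_trajectory = rep(80, 5), n_variants = 50,
                        chrom_length_bp = 2e7, carrier_target_freq = 0.15,
                        freq_tol = 0.12, genotype_error_rate = 0,
                        missing_rate = 0, max_attempts = 400, seed = 3)
  sim <- simulate_isolate(cfg)
  segs <- sim$truth$ibd_segments
  expect_true(all(segs$start_cM <= sim$truth$focal$cM))
  expect_true(all(segs$end_cM >= sim$truth$focal$cM))
})

test_that("an unreachable target frequency fails with a clear message", {
  cfg <- isolate_config(n_founders = 10, n_generations = 2, final_n = 40,
                        n_variants = 10, chrom_length_bp = 1e6,
                        carrier_target_freq = 0.9, freq_tol = 0.01,
                        max_attempts = 3, seed = 1)
  expect_error(simulate_isolate(cfg), "not reached")
})

test_that("trait simulation realizes its variance targets", {
  set.seed(61)
  ## pure noise: regression slope on carrier status ~ 0
  stub <- structure(list(carrier_status = stats::setNames(
    rbinom(2000, 2, 0.019), sprintf("S%04d", 1:2000))), class = "sim_truth")
  tc0 <- trait_config(variance_explained_target = 0, polygenic_h2 = 0,
                      mean = 0, sd = 1)
  ph0 <- simulate_traits(stub, tc0, seed = 2)
  sl <- coef(summary(lm(ph0$HDL ~ stub$carrier_status)))[2, ]
  expect_lt(abs(sl["Estimate"]), 3 * sl["Std. Error"])
  ## implied standardized effect at the drifted frequency
  stub38 <- structure(list(carrier_status = stats::setNames(
    rep(c(1L, 0L), c(38, 962)), sprintf("S%04d", 1:1000))), class = "sim_truth")
  tc <- trait_config(variance_explained_target = 0.029, polygenic_h2 = 0,
                     mean = 0, sd = 1)
  ph <- simulate_traits(stub38, tc, seed = 3)
  beta <- attr(ph, "trait_params")$beta
  expect_equal(beta, sqrt(0.029 / (2 * 0.019 * 0.981)), tolerance = 1e-12)
  expect_equal(round(beta, 3), 0.882)
  ## realized variance fraction close to target (no polygenic term)
  r2 <- summary(lm(ph$HDL ~ stub38$carrier_status))$r.squared
  expect_lt(abs(r2 - 0.029), 0.02)
  ## polygenic component requires a kinship matrix; non-PSD rejected
  expect_error(simulate_traits(stub38, trait_config(polygenic_h2 = 0.3),
                               kinship = NULL), "kinship")
  badK <- matrix(c(1, 2, 2, 1), 2)
  stub2 <- structure(list(carrier_status = c(S1 = 0L, S2 = 1L)),
                     class = "sim_truth")
  expect_error(simulate_traits(stub2, trait_config(polygenic_h2 = 0.3),
                               kinship = badK), "positive semidefinite")
})

test_that("a mixed model on a large simulated cohort recovers the variance explained", {
  set.seed(71)
  copies <- rbinom(5000, 2, 0.019)
  stub <- structure(list(carrier_status = stats::setNames(
    copies, sprintf("S%04d", 1:5000))), class = "sim_truth")
  tc <- trait_config(variance_explained_target = 0.039, polygenic_h2 = 0,
                     mean = 1.265, sd = 0.35)
  ph <- simulate_traits(stub, tc, seed = 4)
  res <- lmm_fit(ph$HDL, copies, K = NULL)
  expect_lt(abs(res$variance_explained - 0.039), 0.01)
})

test_that("ground truth round-trips through TSV files", {
  sim_small <- simulate_isolate(isolate_config(
    n_founders = 10, n_generations = 3, final_n = 50, n_variants = 60,
    chrom_length_bp = 5e6, carrier_target_freq = 0.1, freq_tol = 0.09,
    genotype_error_rate = 0, missing_rate = 0, max_attempts = 300, seed = 13))
  truth <- sim_small$truth
  dir <- tempfile("truth")
  write_truth(truth, dir)
  back <- read_truth(dir)
  expect_identical(back$h1, truth$h1)
  expect_identical(back$h2, truth$h2)
  expect_equal(back$carrier_status, truth$carrier_status)
  expect_equal(back$focal$pos, truth$focal$pos)
  expect_equal(sum(back$carrier_status > 0), sum(truth$carrier_status > 0))
  ## segment file is sorted by start coordinate
  if (!is.null(truth$ibd_segments)) {
    segs <- read.table(file.path(dir, "ibd_segments.tsv"), header = TRUE)
    expect_false(is.unsorted(segs$start_bp))
  }
  unlink(dir, recursive = TRUE)
})
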