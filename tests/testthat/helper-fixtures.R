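## Shared simulated cohort, built once per test run. Moderate size so the
## full suite stays fast; the acceptance tests build their own cohorts at the
## sizes they need.
.fixture_env <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- isolate_config(
      n_founders = 20, n_generations = 8, final_n = 250, n_variants = 400,
      chrom_length_bp = 2e7, carrier_target_freq = 0.019, freq_tol = 0.012,
      genotype_error_rate = 0.005, missing_rate = 0.002,
      max_attempts = 300, seed = 2024
    )
    .fixture_env$sim <- simulate_isolate(cfg)
  }
  .fixture_env$sim
}

shared_kinship <- function() {
  if (is.null(.fixture_env$K)) {
    .fixture_env$K <- kinship_centered(shared_sim()$genotypes)
  }
  .fixture_env$K
}

## Parent-offspring duos with independent founders: rows 1..n_pairs are
## parents, rows n_pairs+1..2*n_pairs their offspring (one transmitted
## allele, one population allele).
make_duos <- function(n_pairs, n_var, seed = 1) {
  set.seed(seed)
  f <- runif(n_var, 0.1, 0.9)
  parent_h1 <- matrix(rbinom(n_pairs * n_var, 1, rep(f, each = n_pairs)), n_pairs)
  parent_h2 <- matrix(rbinom(n_pairs * n_var, 1, rep(f, each = n_pairs)), n_pairs)
  pick <- matrix(runif(n_pairs * n_var) < 0.5, n_pairs)
  transmitted <- ifelse(pick, parent_h1, parent_h2)
  other <- matrix(rbinom(n_pairs * n_var, 1, rep(f, each = n_pairs)), n_pairs)
  geno <- rbind(parent_h1 + parent_h2, transmitted + other)
  make_geno(geno, pos = sort(sample(1e4:1e8, n_var)))
}
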