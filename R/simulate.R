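#' Configuration for the isolate simulator
#'
#' Describes a founder-bottleneck isolate: a small founder pool, discrete
#' non-overlapping generations with random mating, recombination as a Poisson
#' process on the genetic-map (cM) scale, a single founder haplotype carrying
#' a derived focal allele that drifts to a target frequency, and array-style
#' genotyping noise (miscalls and missingness).
#'
#' The defaults emulate a Cretan-style village isolate sampled at around 1,267
#' individuals about 15 generations after founding, in which a focal allele
#' carried on a single founder haplotype (start frequency 0.5%) has drifted to
#' ~1.9%. The founder pool is the *effective* breeding pool at founding, far
#' smaller than the census; it controls both how often rejection sampling
#' accepts a drift trajectory and how related the final cohort is (with 100
#' founders, most carrier pairs are only distantly related genome-wide, as in
#' real isolate cohorts).
#'
#' @param n_founders number of founder individuals (>= 2).
#' @param n_generations number of discrete generations simulated.
#' @param pop_size_trajectory integer vector of population sizes per
#'   generation (length `n_generations`); default geometric growth from
#'   `n_founders` to `final_n`.
#' @param final_n final-generation size used for the default trajectory.
#' @param chrom_length_bp physical chromosome length (bp).
#' @param n_variants number of markers (strictly increasing random positions).
#' @param map a [genetic_map], or `NULL` for a uniform map at `cM_per_Mb`.
#' @param cM_per_Mb rate of the default uniform map.
#' @param chrom chromosome label.
#' @param carrier_target_freq target final derived-allele frequency for the
#'   focal variant, or `NULL` to accept any drift outcome.
#' @param freq_tol absolute tolerance around `carrier_target_freq`.
#' @param genotype_error_rate per-genotype miscall probability (default 0.01,
#'   the error level the haplotype-sharing model also assumes).
#' @param missing_rate per-genotype missingness probability.
#' @param max_attempts rejection-sampling budget for frequency targeting.
#' @param seed integer RNG seed; every stochastic draw derives from it.
#' @return a validated `isolate_config` list.
#' @export
isolate_config <- function(n_founders = 100, n_generations = 15,
                           pop_size_trajectory = NULL, final_n = 1267,
                           chrom_length_bp = 2e7, n_variants = 1000,
                           map = NULL, cM_per_Mb = 1, chrom = "11",
                           carrier_target_freq = 0.019, freq_tol = 0.006,
                           genotype_error_rate = 0.01, missing_rate = 0.005,
                           max_attempts = 200, seed = 1) {
  stopifnot(
    n_founders >= 2, n_generations >= 1, chrom_length_bp > 0,
    n_variants >= 2,
    genotype_error_rate >= 0, genotype_error_rate <= 1,
    missing_rate >= 0, missing_rate <= 1, max_attempts >= 1
  )
  if (!is.null(carrier_target_freq)) {
    stopifnot(carrier_target_freq > 0, carrier_target_freq < 1, freq_tol > 0)
  }
  if (is.null(pop_size_trajectory)) {
    pop_size_trajectory <- round(exp(seq(log(n_founders), log(final_n),
                                         length.out = n_generations + 1)))[-1]
  }
  stopifnot(length(pop_size_trajectory) == n_generations,
            all(pop_size_trajectory >= 2))
  if (is.null(map)) map <- uniform_map(chrom, chrom_length_bp, cM_per_Mb)
  structure(
    list(
      n_founders = n_founders, n_generations = n_generations,
      pop_size_trajectory = as.integer(pop_size_trajectory),
      chrom_length_bp = chrom_length_bp, n_variants = n_variants,
      map = map, chrom = chrom,
      carrier_target_freq = carrier_target_freq, freq_tol = freq_tol,
      genotype_error_rate = genotype_error_rate, missing_rate = missing_rate,
      max_attempts = max_attempts, seed = as.integer(seed)
    ),
    class = "isolate_config"
  )
}

## One meiosis: recombine a parent's two haplotype rows into a gamete.
## Breakpoints are a Poisson process at 1 per Morgan on the cM scale
## (Haldane: no interference); `anc` rows are (founder_hap, lo_cM, hi_cM)
## ancestry of the segment covering the focal cM position.
.gamete <- function(h_parent, anc_parent, var_cM, total_cM, focal_cM) {
  k <- stats::rpois(1, total_cM / 100)
  start <- sample.int(2, 1)
  if (k == 0) {
    return(list(hap = h_parent[start, ], anc = anc_parent[start, ]))
  }
  bks <- sort(stats::runif(k, 0, total_cM))
  seg <- findInterval(var_cM, bks)              # 0..k
  which_hap <- (seg + start) %% 2 + 1           # alternate at each breakpoint
  hap <- ifelse(which_hap == 1, h_parent[1, ], h_parent[2, ])
  fseg <- findInterval(focal_cM, bks)
  fh <- (fseg + start) %% 2 + 1
  lo <- if (fseg == 0) 0 else bks[fseg]
  hi <- if (fseg == k) total_cM else bks[fseg + 1]
  anc <- anc_parent[fh, ]
  anc[2] <- max(anc[2], lo)
  anc[3] <- min(anc[3], hi)
  list(hap = hap, anc = anc)
}

.simulate_once <- function(cfg, var_pos, var_cM, focal_idx, total_cM,
                           abort_if_lost = FALSE) {
  nF <- cfg$n_founders
  m <- cfg$n_variants
  ## founder haplotypes: intermediate-frequency markers, focal allele on
  ## exactly one founder haplotype (haplotype 1 of founder 1)
  f0 <- stats::runif(m, 0.05, 0.95)
  h1 <- matrix(stats::rbinom(nF * m, 1, rep(f0, each = nF)), nF, m)
  h2 <- matrix(stats::rbinom(nF * m, 1, rep(f0, each = nF)), nF, m)
  h1[, focal_idx] <- 0L
  h2[, focal_idx] <- 0L
  h1[1, focal_idx] <- 1L
  ## ancestry of the focal segment: (founder_hap_id, lo_cM, hi_cM)
  anc1 <- cbind(seq_len(nF), 0, total_cM)
  anc2 <- cbind(nF + seq_len(nF), 0, total_cM)
  focal_cM <- var_cM[focal_idx]
  pedigree <- data.frame(gen = 0L, id = seq_len(nF),
                         parent1 = NA_integer_, parent2 = NA_integer_)
  for (g in seq_len(cfg$n_generations)) {
    n_new <- cfg$pop_size_trajectory[g]
    n_old <- nrow(h1)
    nh1 <- matrix(0L, n_new, m); nh2 <- matrix(0L, n_new, m)
    na1 <- matrix(0, n_new, 3); na2 <- matrix(0, n_new, 3)
    p1 <- integer(n_new); p2 <- integer(n_new)
    for (i in seq_len(n_new)) {
      pr <- sample.int(n_old, 2, replace = FALSE)   # two distinct parents
      g1 <- .gamete(rbind(h1[pr[1], ], h2[pr[1], ]),
                    rbind(anc1[pr[1], ], anc2[pr[1], ]),
                    var_cM, total_cM, focal_cM)
      g2 <- .gamete(rbind(h1[pr[2], ], h2[pr[2], ]),
                    rbind(anc1[pr[2], ], anc2[pr[2], ]),
                    var_cM, total_cM, focal_cM)
      nh1[i, ] <- g1$hap; nh2[i, ] <- g2$hap
      na1[i, ] <- g1$anc; na2[i, ] <- g2$anc
      p1[i] <- pr[1]; p2[i] <- pr[2]
    }
    h1 <- nh1; h2 <- nh2; anc1 <- na1; anc2 <- na2
    pedigree <- rbind(pedigree,
                      data.frame(gen = g, id = seq_len(n_new),
                                 parent1 = p1, parent2 = p2))
    ## a lost focal allele can never reach a positive target frequency, so
    ## the attempt can be rejected without simulating the remaining
    ## generations
    if (abort_if_lost && !any(h1[, focal_idx] == 1L) &&
        !any(h2[, focal_idx] == 1L)) {
      return(list(lost = TRUE))
    }
  }
  list(h1 = h1, h2 = h2, anc1 = anc1, anc2 = anc2, pedigree = pedigree)
}

#' Simulate a population isolate with a drifting focal allele
#'
#' Forward-in-time simulation under the configuration from [isolate_config]:
#' founders carry intermediate-frequency marker alleles plus a single derived
#' focal allele on one founder haplotype; each offspring haplotype is a mosaic
#' of one parent's two haplotypes with Poisson recombination breakpoints on
#' the cM scale; the run is rejection-resampled until the final focal-allele
#' frequency lands within `freq_tol` of `carrier_target_freq` (conditioning on
#' the drift outcome without biasing its dynamics). Genotyping error and
#' missingness are injected only into the returned genotype matrix; the truth
#' object keeps the error-free haplotypes.
#'
#' @param config an [isolate_config].
#' @return list with `genotypes` (a [geno_matrix]), `truth` (a `sim_truth`:
#'   error-free haplotypes, pedigree, carrier status, true focal IBD segments,
#'   attempt count) and `map` (the [genetic_map] used).
#' @export
simulate_isolate <- function(config) {
  stopifnot(inherits(config, "isolate_config"))
  set.seed(config$seed)
  var_pos <- sort(sample.int(config$chrom_length_bp - 2, config$n_variants)) + 1
  var_cM <- map_cM(config$map, config$chrom, var_pos)
  total_cM <- max(config$map$cM[config$map$chrom == config$chrom])
  focal_idx <- which.min(abs(var_pos - config$chrom_length_bp / 2))
  run <- NULL
  attempts <- 0
  targeting <- !is.null(config$carrier_target_freq) &&
    config$carrier_target_freq - config$freq_tol > 0
  repeat {
    attempts <- attempts + 1
    cand <- .simulate_once(config, var_pos, var_cM, focal_idx, total_cM,
                           abort_if_lost = targeting)
    if (is.null(cand$lost)) {
      freq <- mean(c(cand$h1[, focal_idx], cand$h2[, focal_idx]))
      if (is.null(config$carrier_target_freq) ||
          abs(freq - config$carrier_target_freq) <= config$freq_tol) {
        run <- cand
        break
      }
    }
    if (attempts >= config$max_attempts) {
      stop("target focal-allele frequency ", config$carrier_target_freq,
           " not reached within ", config$max_attempts,
           " attempts; widen freq_tol or adjust the founder pool")
    }
  }
  n <- nrow(run$h1)
  ids <- sprintf("S%04d", seq_len(n))
  rownames(run$h1) <- ids; rownames(run$h2) <- ids
  geno_true <- run$h1 + run$h2
  geno <- geno_true
  ## error model: miscall with prob e, uniform over the two wrong values
  if (config$genotype_error_rate > 0) {
    hit <- which(stats::runif(length(geno)) < config$genotype_error_rate)
    if (length(hit)) {
      wrong <- vapply(geno[hit], function(x) sample(setdiff(0:2, x), 1), 0L)
      geno[hit] <- wrong
    }
  }
  if (config$missing_rate > 0) {
    geno[stats::runif(length(geno)) < config$missing_rate] <- NA_integer_
  }
  rownames(geno) <- ids
  gm <- geno_matrix(geno, chrom = config$chrom, pos = var_pos)
  carrier_status <- run$h1[, focal_idx] + run$h2[, focal_idx]
  ## true IBD segments around the focal allele, among carrier haplotypes
  ## (all descend from founder haplotype 1)
  carrier_of <- function(i) {
    if (run$h1[i, focal_idx] == 1) run$anc1[i, ] else run$anc2[i, ]
  }
  carriers <- which(carrier_status > 0)
  ibd <- NULL
  if (length(carriers) >= 2) {
    prs <- t(utils::combn(carriers, 2))
    segs <- t(apply(prs, 1, function(pr) {
      a <- carrier_of(pr[1]); b <- carrier_of(pr[2])
      c(max(a[2], b[2]), min(a[3], b[3]))
    }))
    ibd <- data.frame(
      i = prs[, 1], j = prs[, 2],
      start_cM = segs[, 1], end_cM = segs[, 2],
      start_bp = round(map_bp(config$map, config$chrom, segs[, 1])),
      end_bp = round(map_bp(config$map, config$chrom, segs[, 2]))
    )
  }
  truth <- structure(
    list(
      h1 = run$h1, h2 = run$h2,
      pedigree = run$pedigree,
      carrier_status = stats::setNames(carrier_status, ids),
      focal = list(index = focal_idx, pos = var_pos[focal_idx],
                   cM = var_cM[focal_idx], freq = mean(carrier_status) / 2),
      ibd_segments = ibd,
      attempts = attempts
    ),
    class = "sim_truth"
  )
  list(genotypes = gm, truth = truth, map = config$map)
}

#' Trait model configuration
#'
#' An additive quantitative-trait model on a lipid-trait scale: the focal
#' variant contributes a per-allele effect sized to explain a target fraction
#' of trait variance, on top of a kinship-structured polygenic background and
#' independent residual noise. Defaults mirror an HDL-like trait
#' (mean 1.265, sd 0.35 mmol/l) with the focal variant explaining ~2.9% of
#' variance.
#'
#' @param trait_name trait label.
#' @param variance_explained_target fraction of variance from the focal
#'   variant; ignored when `variant_beta` is given.
#' @param variant_beta per-allele effect in trait units (overrides the target).
#' @param polygenic_h2 fraction of variance from the polygenic background.
#' @param mean,sd trait scale.
#' @param units unit tag carried through to the phenotype table.
#' @export
trait_config <- function(trait_name = "HDL", variance_explained_target = 0.029,
                         variant_beta = NULL, polygenic_h2 = 0.3,
                         mean = 1.265, sd = 0.35, units = "mmol/l") {
  stopifnot(polygenic_h2 >= 0, polygenic_h2 <= 1, sd > 0)
  if (is.null(variant_beta)) {
    stopifnot(variance_explained_target >= 0,
              variance_explained_target + polygenic_h2 <= 1)
  }
  structure(
    list(trait_name = trait_name,
         variance_explained_target = variance_explained_target,
         variant_beta = variant_beta, polygenic_h2 = polygenic_h2,
         mean = mean, sd = sd, units = units),
    class = "trait_config"
  )
}

#' Simulate quantitative traits on a simulated cohort
#'
#' Draws `trait = mean + beta * copies + u + e` with `u ~ N(0, sigma_g^2 K)`
#' (kinship-structured polygenic background) and independent residuals. When
#' a variance-explained target is given, beta is derived from the realized
#' focal-allele frequency via `VE = 2 f (1-f) beta_std^2`.
#'
#' @param truth a `sim_truth` from [simulate_isolate] (or any object with a
#'   `carrier_status` vector of 0/1/2 copies).
#' @param config a [trait_config].
#' @param kinship symmetric positive-semidefinite kinship matrix matching the
#'   cohort, or `NULL` for no polygenic structure (requires `polygenic_h2 = 0`).
#' @param seed RNG seed.
#' @return a phenotype data.frame: `sample_id`, `sex`, `age`, and one trait
#'   column named after the trait, with a `units` attribute.
#' @export
simulate_traits <- function(truth, config, kinship = NULL, seed = 1) {
  stopifnot(inherits(config, "trait_config"))
  copies <- truth$carrier_status
  n <- length(copies)
  set.seed(seed)
  f <- mean(copies) / 2
  var_y <- config$sd^2
  if (!is.null(config$variant_beta)) {
    beta <- config$variant_beta
    ve <- min(2 * f * (1 - f) * beta^2 / var_y, 1)
  } else {
    ve <- config$variance_explained_target
    beta <- if (ve == 0) 0 else sqrt(ve * var_y / (2 * f * (1 - f)))
  }
  h2 <- config$polygenic_h2
  stopifnot(ve + h2 <= 1 + 1e-12)
  u <- 0
  if (h2 > 0) {
    if (is.null(kinship)) stop("polygenic_h2 > 0 requires a kinship matrix")
    stopifnot(nrow(kinship) == n, ncol(kinship) == n)
    K <- kinship / mean(diag(kinship))
    L <- tryCatch(chol(K + diag(1e-8, n)),
                  error = function(e) stop("kinship matrix is not positive semidefinite"))
    u <- as.vector(crossprod(L, stats::rnorm(n))) * sqrt(h2 * var_y)
  }
  e <- stats::rnorm(n, 0, sqrt(max(1 - ve - h2, 0) * var_y))
  y <- config$mean + beta * (copies - 2 * f) + u + e
  out <- data.frame(
    sample_id = if (!is.null(names(copies))) names(copies) else sprintf("S%04d", seq_len(n)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    age = pmax(18, round(stats::rnorm(n, 62, 19)))
  )
  out[[config$trait_name]] <- y
  attr(out, "units") <- config$units
  attr(out, "trait_params") <- list(beta = beta, ve = ve, polygenic_h2 = h2,
                                    focal_freq = f)
  out
}

#' Write / read simulator ground truth as TSV files
#'
#' Serializes a `sim_truth` to a directory of plain TSV files (haplotypes,
#' pedigree, carrier status, true IBD segments, focal-variant metadata) and
#' reads it back losslessly.
#'
#' @param truth a `sim_truth`.
#' @param dir output directory (created if needed).
#' @export
write_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(data.frame(sample_id = rownames(truth$h1), truth$h1, check.names = FALSE), "haplotypes1.tsv")
  wt(data.frame(sample_id = rownames(truth$h2), truth$h2, check.names = FALSE), "haplotypes2.tsv")
  wt(truth$pedigree, "pedigree.tsv")
  wt(data.frame(sample_id = names(truth$carrier_status),
                copies = as.integer(truth$carrier_status)), "carriers.tsv")
  if (!is.null(truth$ibd_segments)) {
    segs <- truth$ibd_segments[order(truth$ibd_segments$start_bp), ]
    wt(segs, "ibd_segments.tsv")
  }
  wt(data.frame(field = c("focal_index", "focal_pos", "focal_cM", "focal_freq", "attempts"),
                value = c(truth$focal$index, truth$focal$pos, truth$focal$cM,
                          truth$focal$freq, truth$attempts)), "focal.tsv")
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  rt <- function(f, ...) utils::read.table(file.path(dir, f), header = TRUE,
                                           sep = "\t", ...)
  hp1 <- rt("haplotypes1.tsv", check.names = FALSE)
  hp2 <- rt("haplotypes2.tsv", check.names = FALSE)
  h1 <- as.matrix(hp1[, -1]); dimnames(h1) <- list(hp1$sample_id, NULL)
  h2 <- as.matrix(hp2[, -1]); dimnames(h2) <- list(hp2$sample_id, NULL)
  storage.mode(h1) <- "integer"; storage.mode(h2) <- "integer"
  carr <- rt("carriers.tsv", colClasses = c("character", "integer"))
  foc <- rt("focal.tsv")
  fv <- stats::setNames(foc$value, foc$field)
  ibd_path <- file.path(dir, "ibd_segments.tsv")
  structure(
    list(
      h1 = h1, h2 = h2, pedigree = rt("pedigree.tsv"),
      carrier_status = stats::setNames(carr$copies, carr$sample_id),
      focal = list(index = as.integer(fv[["focal_index"]]),
                   pos = fv[["focal_pos"]], cM = fv[["focal_cM"]],
                   freq = fv[["focal_freq"]]),
      ibd_segments = if (file.exists(ibd_path)) rt("ibd_segments.tsv") else NULL,
      attempts = as.integer(fv[["attempts"]])
    ),
    class = "sim_truth"
  )
}
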