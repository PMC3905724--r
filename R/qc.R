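#' Staged genotype QC thresholds
#'
#' Thresholds for the staged exome-array QC pipeline: a loose prefilter on
#' both axes, sample call rate, heterozygosity outliers stratified by MAF,
#' variant call rate plus an exact Hardy-Weinberg test, a tighter final
#' variant call rate, an excess-singleton sample filter, and a final HWE pass.
#' All comparisons are strict inequalities.
#'
#' @param prefilter_call_rate initial call-rate prefilter on both axes (0.90).
#' @param sample_call_rate sample call-rate threshold (0.98).
#' @param het_outlier_sd SD multiplier for heterozygosity outliers; the
#'   published pipeline removed visual outliers, so the numeric default (3)
#'   is this package's rule.
#' @param het_maf_split MAF boundary between the rare and common strata (0.01).
#' @param variant_call_rate variant call-rate threshold (0.95).
#' @param hwe_p exact-test Hardy-Weinberg p-value threshold (1e-4).
#' @param final_variant_call_rate final variant call-rate threshold (0.99).
#' @param singleton_sample_limit samples that are the sole minor-allele
#'   carrier at more than this many variants are removed (100).
#' @export
qc_thresholds <- function(prefilter_call_rate = 0.90, sample_call_rate = 0.98,
                          het_outlier_sd = 3, het_maf_split = 0.01,
                          variant_call_rate = 0.95, hwe_p = 1e-4,
                          final_variant_call_rate = 0.99,
                          singleton_sample_limit = 100) {
  rates <- c(prefilter_call_rate, sample_call_rate, variant_call_rate,
             final_variant_call_rate)
  stopifnot(all(rates >= 0), all(rates <= 1), hwe_p > 0, hwe_p < 1,
            het_outlier_sd > 0, singleton_sample_limit >= 0)
  structure(
    list(prefilter_call_rate = prefilter_call_rate,
         sample_call_rate = sample_call_rate,
         het_outlier_sd = het_outlier_sd, het_maf_split = het_maf_split,
         variant_call_rate = variant_call_rate, hwe_p = hwe_p,
         final_variant_call_rate = final_variant_call_rate,
         singleton_sample_limit = singleton_sample_limit),
    class = "qc_thresholds"
  )
}

.qc_stage <- function(stage, axis, removed_ids, n_before, n_after, reason) {
  data.frame(stage = stage, axis = axis, n_before = n_before,
             n_removed = n_before - n_after, n_after = n_after,
             removed = paste(removed_ids, collapse = ","),
             reason = reason, stringsAsFactors = FALSE)
}

#' Call-rate filter
#'
#' Removes samples or variants whose call rate is strictly below the
#' threshold. An empty matrix after filtering is reported, not an error.
#'
#' @param g a [geno_matrix].
#' @param axis `"samples"` or `"variants"`.
#' @param threshold minimum call rate in [0, 1].
#' @return list with the filtered `genotypes` and a one-row `report`.
#' @export
call_rate_filter <- function(g, axis = c("samples", "variants"), threshold) {
  axis <- match.arg(axis)
  stopifnot(threshold >= 0, threshold <= 1)
  cr <- call_rate(g, axis)
  drop <- cr < threshold
  ids <- if (axis == "samples") sample_ids(g) else g$variants$id
  out <- if (axis == "samples") subset_geno(g, samples = !drop)
         else subset_geno(g, variants = !drop)
  list(genotypes = out,
       report = .qc_stage(paste0("call_rate_", axis), axis, ids[drop],
                          length(drop), sum(!drop),
                          paste0("call rate < ", threshold)))
}

#' Heterozygosity outlier detection
#'
#' Computes each sample's heterozygous-call fraction separately over rare
#' (MAF < `maf_split`) and common (MAF >= `maf_split`) variants and flags
#' samples more than `sd_mult` standard deviations from the cohort mean in
#' either stratum. A stratum with fewer than `min_variants` variants gives
#' meaninglessly discrete heterozygosity fractions and is skipped with a
#' warning.
#'
#' @param g a [geno_matrix] with at least 3 samples.
#' @param maf_split MAF boundary between strata (default 0.01).
#' @param sd_mult SD multiplier (default 3).
#' @param min_variants minimum stratum size for the z-scores to be usable
#'   (default 20).
#' @return character vector of flagged sample IDs.
#' @export
heterozygosity_outliers <- function(g, maf_split = 0.01, sd_mult = 3,
                                    min_variants = 20) {
  stopifnot(n_samples(g) >= 3)
  mf <- maf(g)
  flagged <- character(0)
  for (stratum in c("rare", "common")) {
    keep <- if (stratum == "rare") mf < maf_split else mf >= maf_split
    keep[is.na(keep)] <- FALSE
    if (sum(keep) < min_variants) {
      warning("fewer than ", min_variants, " variants in the ", stratum,
              " MAF stratum; stratum skipped")
      next
    }
    sub <- g$geno[, keep, drop = FALSE]
    het <- rowMeans(sub == 1, na.rm = TRUE)
    s <- stats::sd(het)
    if (is.na(s) || s == 0) next
    z <- abs(het - mean(het)) / s
    flagged <- union(flagged, sample_ids(g)[z > sd_mult])
  }
  flagged
}

#' Hardy-Weinberg equilibrium filter
#'
#' Removes variants whose exact-test p-value (see [hwe_exact_test]) is
#' strictly below `p_threshold`. Monomorphic variants have p = 1 and are
#' never removed.
#'
#' @param g a [geno_matrix].
#' @param p_threshold p-value threshold (default 1e-4).
#' @return list with filtered `genotypes`, a `report` row, and the vector of
#'   per-variant p-values.
#' @export
hwe_filter <- function(g, p_threshold = 1e-4) {
  p <- apply(g$geno, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(1)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  })
  drop <- p < p_threshold
  list(genotypes = subset_geno(g, variants = !drop),
       report = .qc_stage("hwe", "variants", g$variants$id[drop],
                          length(drop), sum(!drop),
                          paste0("HWE exact p < ", p_threshold)),
       p = p)
}

#' Excess-singleton sample filter
#'
#' Removes samples that are the sole carrier of the minor allele at strictly
#' more than `limit` variants (an excess of private variation indicates
#' sample-level artefacts).
#'
#' @param g a [geno_matrix].
#' @param limit maximum tolerated singleton count (default 100; strict ">").
#' @return list with filtered `genotypes` and a `report` row.
#' @export
singleton_sample_filter <- function(g, limit = 100) {
  geno <- g$geno
  f <- alt_freqs(g)
  ## orient to minor allele per variant
  minor <- sweep(geno, 2, ifelse(!is.na(f) & f > 0.5, 2, 0),
                 function(x, m) abs(x - m))
  mac <- colSums(minor, na.rm = TRUE)
  singleton_var <- which(mac == 1)
  counts <- integer(nrow(geno))
  if (length(singleton_var)) {
    sub <- minor[, singleton_var, drop = FALSE]
    sub[is.na(sub)] <- 0L
    counts <- rowSums(sub >= 1)
  }
  drop <- counts > limit
  list(genotypes = subset_geno(g, samples = !drop),
       report = .qc_stage("singletons", "samples", sample_ids(g)[drop],
                          length(drop), sum(!drop),
                          paste0("sole minor-allele carrier at > ", limit,
                                 " variants")))
}

#' Run the staged QC pipeline
#'
#' Applies, in order: call-rate prefilter on both axes, sample call-rate
#' filter, heterozygosity-outlier removal in two MAF strata, variant
#' call-rate + HWE filters, final variant call-rate filter, excess-singleton
#' sample filter, and a final HWE pass. Genotype values are never modified,
#' only rows/columns removed.
#'
#' @param g a [geno_matrix].
#' @param thresholds a [qc_thresholds].
#' @return list with the surviving `genotypes` and a cumulative `report`
#'   data.frame (one row per stage).
#' @export
run_qc_pipeline <- function(g, thresholds = qc_thresholds()) {
  th <- thresholds
  report <- NULL
  step <- function(res) {
    report <<- rbind(report, res$report)
    res$genotypes
  }
  g <- step(call_rate_filter(g, "samples", th$prefilter_call_rate))
  g <- step(call_rate_filter(g, "variants", th$prefilter_call_rate))
  g <- step(call_rate_filter(g, "samples", th$sample_call_rate))
  if (n_samples(g) >= 3 && n_variants(g) > 0) {
    out <- heterozygosity_outliers(g, th$het_maf_split, th$het_outlier_sd)
    keep <- !(sample_ids(g) %in% out)
    report <- rbind(report, .qc_stage("het_outliers", "samples", out,
                                      n_samples(g), sum(keep),
                                      paste0("heterozygosity > ",
                                             th$het_outlier_sd, " SD")))
    g <- subset_geno(g, samples = keep)
  }
  g <- step(call_rate_filter(g, "variants", th$variant_call_rate))
  g <- step(hwe_filter(g, th$hwe_p)[c("genotypes", "report")])
  g <- step(call_rate_filter(g, "variants", th$final_variant_call_rate))
  g <- step(singleton_sample_filter(g, th$singleton_sample_limit))
  g <- step(hwe_filter(g, th$hwe_p)[c("genotypes", "report")])
  rownames(report) <- NULL
  list(genotypes = g, report = report)
}

#' Write a QC report as TSV
#'
#' @param report the `report` element from [run_qc_pipeline].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
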