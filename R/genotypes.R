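#' Genotype matrix container
#'
#' A `geno_matrix` holds diploid genotype calls for a set of samples at a set
#' of variants, coded as copies of the alternate (derived/effect) allele:
#' 0, 1, 2 or `NA` for a missing call. Variant metadata (chromosome, 1-based
#' physical position, reference and alternate alleles) travels with the calls.
#'
#' @param geno integer matrix, samples in rows, variants in columns; entries
#'   in `{0, 1, 2, NA}`. Row names are sample IDs (generated if absent).
#' @param chrom chromosome label per variant (recycled if length 1).
#' @param pos 1-based physical position per variant; strictly increasing
#'   within each chromosome.
#' @param ref,alt reference / alternate allele per variant.
#' @param id variant identifier; defaults to `chrom:pos`.
#' @return An object of class `geno_matrix`: a list with elements `geno`
#'   (the call matrix) and `variants` (a data.frame of variant metadata).
#' @export
geno_matrix <- function(geno, chrom, pos, ref = "A", alt = "G", id = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  m <- ncol(geno)
  chrom <- rep_len(as.character(chrom), m)
  pos <- as.integer(pos)
  stopifnot(length(pos) == m)
  if (any(!is.na(geno) & !(geno %in% 0:2))) {
    stop("genotype calls must be 0, 1, 2 or NA")
  }
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("variant positions must be strictly increasing within chromosome ", ch)
    }
  }
  ref <- rep_len(as.character(ref), m)
  alt <- rep_len(as.character(alt), m)
  if (is.null(id)) id <- paste0(chrom, ":", pos)
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("S%04d", seq_len(nrow(geno)))
  }
  colnames(geno) <- id
  structure(
    list(
      geno = geno,
      variants = data.frame(
        id = id, chrom = chrom, pos = pos, ref = ref, alt = alt,
        stringsAsFactors = FALSE
      )
    ),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(
    "geno_matrix:", nrow(x$geno), "samples x", ncol(x$geno), "variants\n",
    "chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n",
    sprintf("missing calls: %.2f%%\n", 100 * mean(is.na(x$geno)))
  )
  invisible(x)
}

#' @rdname geno_matrix
#' @param g a `geno_matrix`.
#' @export
n_samples <- function(g) nrow(g$geno)

#' @rdname geno_matrix
#' @export
n_variants <- function(g) ncol(g$geno)

#' @rdname geno_matrix
#' @export
sample_ids <- function(g) rownames(g$geno)

#' Subset a genotype matrix by sample and/or variant
#'
#' @param g a `geno_matrix`.
#' @param samples sample indices, names or logical mask (default: keep all).
#' @param variants variant indices, ids or logical mask (default: keep all).
#' @return a `geno_matrix` restricted to the selection.
#' @export
subset_geno <- function(g, samples = NULL, variants = NULL) {
  keep_s <- if (is.null(samples)) seq_len(nrow(g$geno)) else samples
  keep_v <- if (is.null(variants)) seq_len(ncol(g$geno)) else variants
  if (is.character(keep_v)) keep_v <- match(keep_v, g$variants$id)
  out <- g
  out$geno <- g$geno[keep_s, keep_v, drop = FALSE]
  if (is.logical(keep_v)) keep_v <- which(keep_v)
  out$variants <- g$variants[keep_v, , drop = FALSE]
  rownames(out$variants) <- NULL
  out
}

#' Per-sample or per-variant call rate
#'
#' @param g a `geno_matrix`.
#' @param axis `"samples"` or `"variants"`.
#' @return numeric vector of fractions of non-missing calls.
#' @export
call_rate <- function(g, axis = c("samples", "variants")) {
  axis <- match.arg(axis)
  if (axis == "samples") 1 - rowMeans(is.na(g$geno)) else 1 - colMeans(is.na(g$geno))
}

#' Alternate-allele frequency per variant
#'
#' @param g a `geno_matrix`.
#' @return numeric vector of alt-allele frequencies (missing calls excluded).
#' @export
alt_freqs <- function(g) {
  colMeans(g$geno, na.rm = TRUE) / 2
}

#' Minor-allele frequency per variant
#'
#' @param g a `geno_matrix`.
#' @return numeric vector of minor-allele frequencies.
#' @export
maf <- function(g) {
  f <- alt_freqs(g)
  pmin(f, 1 - f)
}

## ---- genetic map ----------------------------------------------------------

#' Genetic map
#'
#' A monotone mapping from physical position (bp) to cumulative genetic
#' position (cM) per chromosome, as distributed with HapMap-style fine-scale
#' maps: chromosome, position, local recombination rate (cM/Mb) and
#' cumulative cM.
#'
#' @param chrom chromosome label per map point.
#' @param pos physical position (bp), strictly increasing per chromosome.
#' @param rate local recombination rate, cM/Mb.
#' @param cM cumulative genetic position, non-decreasing per chromosome.
#' @return a `genetic_map` data.frame with columns `chrom`, `pos`, `rate`, `cM`.
#' @export
genetic_map <- function(chrom, pos, rate, cM) {
  df <- data.frame(
    chrom = as.character(chrom), pos = as.numeric(pos),
    rate = as.numeric(rate), cM = as.numeric(cM),
    stringsAsFactors = FALSE
  )
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (is.unsorted(sub$pos, strictly = TRUE)) {
      stop("map positions must be strictly increasing on chromosome ", ch)
    }
    if (is.unsorted(sub$cM)) {
      stop("cumulative cM must be non-decreasing on chromosome ", ch)
    }
  }
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Uniform-rate genetic map over one chromosome
#'
#' @param chrom chromosome label.
#' @param length_bp chromosome length in bp.
#' @param cM_per_Mb constant recombination rate (default 1 cM/Mb).
#' @return a `genetic_map` with two anchor points spanning the chromosome.
#' @export
uniform_map <- function(chrom = "11", length_bp, cM_per_Mb = 1) {
  stopifnot(length_bp > 0, cM_per_Mb >= 0)
  genetic_map(
    chrom = c(chrom, chrom), pos = c(1, length_bp),
    rate = c(cM_per_Mb, cM_per_Mb),
    cM = c(0, (length_bp - 1) / 1e6 * cM_per_Mb)
  )
}

#' Interpolate cumulative genetic position
#'
#' Linear interpolation of cumulative cM at arbitrary physical positions.
#' Positions outside the mapped range are an error: the map must cover every
#' queried variant.
#'
#' @param map a `genetic_map`.
#' @param chrom chromosome of the query positions.
#' @param pos physical positions (bp).
#' @return cumulative cM at each position.
#' @export
map_cM <- function(map, chrom, pos) {
  sub <- map[map$chrom == as.character(chrom[1]), ]
  if (nrow(sub) < 2) stop("map has fewer than 2 points on chromosome ", chrom[1])
  if (any(pos < min(sub$pos) | pos > max(sub$pos))) {
    stop("position outside the genetic map range on chromosome ", chrom[1])
  }
  stats::approx(sub$pos, sub$cM, xout = pos, ties = "ordered")$y
}

#' Invert a genetic map: physical position at a cumulative cM
#'
#' @param map a `genetic_map`.
#' @param chrom chromosome label.
#' @param cM cumulative genetic positions.
#' @return physical positions (bp), linearly interpolated.
#' @export
map_bp <- function(map, chrom, cM) {
  sub <- map[map$chrom == as.character(chrom[1]), ]
  ## flat (zero-rate) stretches make the inverse non-unique; take leftmost
  stats::approx(sub$cM, sub$pos, xout = cM, ties = "ordered", rule = 2)$y
}

#' Read / write a genetic map as 4-column TSV
#'
#' Columns: chromosome, position (bp), rate (cM/Mb), cumulative cM.
#'
#' @param path file path.
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric", "numeric", "numeric"))
  names(df) <- c("chrom", "pos", "rate", "cM")
  genetic_map(df$chrom, df$pos, df$rate, df$cM)
}

#' @rdname read_genetic_map
#' @param map a `genetic_map`.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---- VCF I/O --------------------------------------------------------------

#' Read genotypes from a VCF file
#'
#' Parses the GT field of a VCF (plain or bgzipped) into a [geno_matrix].
#' Multi-allelic records are rejected; half-missing calls count as missing.
#'
#' @param path path to a VCF file.
#' @return a `geno_matrix`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE))) {
    stop("multi-allelic records are not supported")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ## gt is variants x samples of "0/0", "0|1", ".", ...
  count_alt <- function(s) {
    al <- strsplit(s, "[/|]")
    vapply(al, function(a) {
      if (length(a) != 2 || any(a == ".")) NA_integer_ else sum(a == "1")
    }, integer(1))
  }
  calls <- apply(gt, 2, count_alt)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1, dimnames = list(NULL, colnames(gt)))
  geno <- t(calls)  # samples x variants
  rownames(geno) <- colnames(gt)
  id <- fix[, "ID"]
  id[is.na(id) | id == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(id) | id == "."]
  geno_matrix(geno, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
              ref = fix[, "REF"], alt = fix[, "ALT"], id = id)
}

#' Write genotypes to a VCF file
#'
#' Writes a minimal VCFv4.2 with a GT field. By default genotypes are written
#' unphased (`0/1`); when `haplotypes` is supplied (a list with matrices `h1`
#' and `h2`, samples x variants, alleles 0/1) phased `h1|h2` genotypes are
#' written instead.
#'
#' @param g a `geno_matrix`.
#' @param path output path (plain-text `.vcf`).
#' @param haplotypes optional list(h1, h2) of phased alleles.
#' @export
write_vcf <- function(g, path, haplotypes = NULL) {
  geno <- g$geno
  n <- nrow(geno); m <- ncol(geno)
  if (is.null(haplotypes)) {
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", n, m)
    ok <- !is.na(geno)
    gt[ok] <- code[as.character(geno[ok])]
  } else {
    stopifnot(all(dim(haplotypes$h1) == dim(geno)))
    gt <- matrix(paste0(haplotypes$h1, "|", haplotypes$h2), n, m)
    gt[is.na(geno)] <- ".|."
  }
  v <- g$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=isoshare",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                sep = "\t")
  body <- paste(body, apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
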