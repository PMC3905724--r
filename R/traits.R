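## Unit conversion factors, mg/dl per mmol/l.
.LIPID_FACTORS <- c(HDL = 38.67, LDL = 38.67, total_cholesterol = 38.67,
                    TC = 38.67, triglycerides = 88.57, TG = 88.57)

#' Convert lipid measurements between mg/dl and mmol/l
#'
#' Cholesterol-family traits (HDL, LDL, total cholesterol) use factor 38.67
#' mg/dl per mmol/l; triglycerides use 88.57. The conversion is bijective.
#'
#' @param values numeric measurements.
#' @param trait one of `"HDL"`, `"LDL"`, `"total_cholesterol"` (`"TC"`),
#'   `"triglycerides"` (`"TG"`).
#' @param from,to `"mg/dl"` or `"mmol/l"`.
#' @export
convert_lipid_units <- function(values, trait, from, to) {
  from <- match.arg(from, c("mg/dl", "mmol/l"))
  to <- match.arg(to, c("mg/dl", "mmol/l"))
  if (from == to) return(values)
  fac <- .LIPID_FACTORS[[trait]]
  if (is.null(fac)) stop("no unit factor known for trait ", trait)
  if (from == "mmol/l") values * fac else values / fac
}

#' LDL cholesterol by the Friedewald equation
#'
#' `LDL = TC - HDL - TG/5` in mg/dl; the equation is invalid at high
#' triglycerides, so LDL is returned missing when TG > 400 mg/dl.
#'
#' @param tc,hdl,tg total cholesterol, HDL and triglycerides in mg/dl.
#' @return LDL in mg/dl (`NA` where TG > 400 mg/dl or any input is missing).
#' @export
friedewald_ldl <- function(tc, hdl, tg) {
  if (any(stats::na.omit(c(tc, hdl, tg)) < 0)) {
    stop("lipid concentrations must be non-negative")
  }
  ldl <- tc - hdl - tg / 5
  ldl[!is.na(tg) & tg > 400] <- NA_real_
  ldl
}

#' Remove extreme trait outliers
#'
#' Sets to missing every value strictly more than `sd_mult` standard
#' deviations from the mean, where mean and SD are computed once over the
#' non-missing input (a single pass; the rule is not re-applied to the
#' cleaned vector).
#'
#' @param values numeric vector; needs at least 2 non-missing values (an
#'   all-missing vector is returned unchanged).
#' @param sd_mult SD multiplier (default 5).
#' @export
remove_outliers <- function(values, sd_mult = 5) {
  ok <- !is.na(values)
  if (!any(ok)) return(values)
  stopifnot(sum(ok) >= 2)
  m <- mean(values[ok])
  s <- stats::sd(values[ok])
  if (is.na(s) || s == 0 || !is.finite(sd_mult)) return(values)
  values[ok & abs(values - m) > sd_mult * s] <- NA_real_
  values
}

#' Trait normalization transforms
#'
#' `natural_log` takes the natural logarithm (all values must be positive);
#' `inverse_normal` maps values to normal scores through their ranks using
#' the Blom offset `qnorm((r - 3/8) / (n + 1/4))`, with ties sharing their
#' average rank. Missing values are preserved in place.
#'
#' @param values numeric vector.
#' @param kind `"natural_log"` or `"inverse_normal"`.
#' @export
transform_trait <- function(values, kind = c("natural_log", "inverse_normal")) {
  kind <- match.arg(kind)
  ok <- !is.na(values)
  out <- rep(NA_real_, length(values))
  if (kind == "natural_log") {
    bad <- which(ok & values <= 0)
    if (length(bad)) {
      stop("natural_log transform requires positive values; offending index ",
           bad[1])
    }
    out[ok] <- log(values[ok])
  } else {
    r <- rank(values[ok], ties.method = "average")
    n <- sum(ok)
    out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  }
  out
}

#' Dichotomize HDL into clinical categories
#'
#' High HDL is defined as >= 60 mg/dl, low HDL as < 40 mg/dl; values in
#' between are neither. Missing values propagate.
#'
#' @param hdl HDL cholesterol in mg/dl.
#' @return factor with levels `low`, `neither`, `high`.
#' @export
dichotomize_hdl <- function(hdl) {
  out <- rep(NA_character_, length(hdl))
  out[!is.na(hdl) & hdl >= 60] <- "high"
  out[!is.na(hdl) & hdl < 40] <- "low"
  out[!is.na(hdl) & hdl >= 40 & hdl < 60] <- "neither"
  factor(out, levels = c("low", "neither", "high"))
}

#' Prepare a lipid phenotype table for association analysis
#'
#' Applies the fixed preparation order: unit harmonization to mg/dl, LDL
#' derivation by [friedewald_ldl] where absent, outlier removal at
#' `outlier_sd` standard deviations per trait, the per-trait normalization
#' transform (natural log for triglycerides-like traits, inverse-normal for
#' age), and HDL dichotomization.
#'
#' @param pheno data.frame with `sample_id` and trait columns; lipid columns
#'   among `HDL`, `LDL`, `total_cholesterol`, `triglycerides`.
#' @param units `"mg/dl"` or `"mmol/l"`, the units of the lipid columns.
#' @param log_traits columns to natural-log transform.
#' @param invnorm_traits columns to inverse-normal transform.
#' @param outlier_sd SD multiplier for outlier removal (default 5).
#' @return the prepared data.frame (lipids in mg/dl) with added `LDL` (if
#'   derivable) and `hdl_class` columns.
#' @export
prepare_phenotypes <- function(pheno, units = "mg/dl",
                               log_traits = "triglycerides",
                               invnorm_traits = "age", outlier_sd = 5) {
  lipids <- intersect(c("HDL", "LDL", "total_cholesterol", "triglycerides"),
                      names(pheno))
  for (tr in lipids) {
    pheno[[tr]] <- convert_lipid_units(pheno[[tr]], tr, units, "mg/dl")
  }
  if (!"LDL" %in% names(pheno) &&
      all(c("total_cholesterol", "HDL", "triglycerides") %in% names(pheno))) {
    pheno$LDL <- friedewald_ldl(pheno$total_cholesterol, pheno$HDL,
                                pheno$triglycerides)
  }
  for (tr in intersect(c(lipids, "LDL"), names(pheno))) {
    pheno[[tr]] <- remove_outliers(pheno[[tr]], outlier_sd)
  }
  for (tr in intersect(log_traits, names(pheno))) {
    pheno[[tr]] <- transform_trait(pheno[[tr]], "natural_log")
  }
  for (tr in intersect(invnorm_traits, names(pheno))) {
    pheno[[tr]] <- transform_trait(pheno[[tr]], "inverse_normal")
  }
  if ("HDL" %in% names(pheno)) pheno$hdl_class <- dichotomize_hdl(pheno$HDL)
  attr(pheno, "units") <- "mg/dl"
  pheno
}
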