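# Mitochondrial somatic-variant filtering against NuMT artifacts, data-driven
# cutoff derivation, heteroplasmy banding and mtDNA copy-number estimation.

#' Control-vs-tumour allele-rate ratio statistic
#'
#' For a candidate mtDNA variant with tumour/control alt read counts and mean
#' depths, computes
#' \deqn{r = \frac{N_{ctrl}/RD_{ctrl}}{N_{ctrl}/RD_{ctrl} + N_{tum}/RD_{tum}}}
#' Nuclear-embedded mitochondrial segments (NuMTs) contaminate tumour and
#' control alike, so artifact calls have r near 0.5 while true somatic
#' mutations (absent from the control) have r near 0. When both alt counts
#' are zero the statistic is undefined and \code{NA} is returned; such a
#' candidate trivially passes the ratio rule downstream.
#'
#' @param n_mut_ctrl,rd_ctrl control alt read count and mean read depth.
#' @param n_mut_tum,rd_tum tumour alt read count and mean read depth.
#' @return numeric in [0, 1], \code{NA} where undefined.
#' @export
ratio_statistic <- function(n_mut_ctrl, rd_ctrl, n_mut_tum, rd_tum) {
  check_number(n_mut_ctrl, "n_mut_ctrl", lower = 0)
  check_number(n_mut_tum, "n_mut_tum", lower = 0)
  if (any(rd_ctrl <= 0) || any(rd_tum <= 0)) {
    stop_input("read depths must be positive")
  }
  rc <- n_mut_ctrl / rd_ctrl
  rt <- n_mut_tum / rd_tum
  out <- rc / (rc + rt)
  out[rc + rt == 0] <- NA_real_
  out
}

#' Data-driven cutoff: median plus twice the interquartile range
#'
#' Reproduces the derivation used to set the artifact-filter cutoffs: the
#' cutoff is the median of the statistic over all mutation candidates plus
#' two times its interquartile range, under the same quantile convention as
#' the burden classifier (\code{\link{cohort_quartiles}}).
#'
#' @param values numeric vector of statistic values (length >= 4).
#' @return single numeric cutoff.
#' @export
derive_cutoff <- function(values) {
  if (!is.numeric(values) || anyNA(values)) {
    stop_input("`values` must be numeric and complete")
  }
  if (length(values) < 4) {
    stop_input("at least 4 values are required to derive a cutoff (got %d)",
               length(values))
  }
  q <- cohort_quartiles(values)
  unname(q["median"] + 2 * (q["q75"] - q["q25"]))
}

#' Filter mtDNA somatic-variant candidates against NuMT artifacts
#'
#' Applies the cohort-level artifact filter to a table of mtDNA variant
#' candidates. A candidate is retained iff all of the following hold:
#' \enumerate{
#'   \item control VAF strictly below \code{ctrl_vaf_cutoff};
#'   \item \code{\link{ratio_statistic}} strictly below \code{ratio_cutoff}
#'     (undefined ratio passes);
#'   \item for low-heteroplasmy candidates (tumour VAF < 0.10) the variant's
#'     cohort carrier frequency is strictly below \code{recurrence_cutoff}
#'     (NuMT artifacts recur across tumours; higher-VAF candidates bypass
#'     this rule so recurrent true hotspots are not deleted);
#'   \item tumour VAF strictly inside the heteroplasmy window
#'     \code{het_window}.
#' }
#' A false-negative guard then re-examines variants whose cohort maximum VAF
#' is below 0.1 and median VAF below 0.05: for these, the recurrence rule is
#' set aside and only carriers with tumour VAF > 0.05 are retained.
#'
#' Variant identity for cohort frequencies is the exact (pos, ref, alt)
#' triple; the frequency denominator is the number of tumours.
#'
#' @param cohort data.frame with columns \code{sample_id}, \code{pos},
#'   \code{ref}, \code{alt}, \code{n_mut_tum}, \code{rd_tum},
#'   \code{n_mut_ctrl}, \code{rd_ctrl}; tumour/control VAFs are computed from
#'   counts unless \code{vaf_tum}/\code{vaf_ctrl} columns are present.
#' @param ctrl_vaf_cutoff control-VAF cutoff, default 0.0034.
#' @param ratio_cutoff ratio-statistic cutoff, default 0.0629.
#' @param recurrence_cutoff cohort-frequency cutoff for low-heteroplasmy
#'   candidates, default 0.023.
#' @param het_window open heteroplasmy window, default \code{c(0.01, 0.95)}.
#' @param n_cohort number of tumours in the cohort (frequency denominator);
#'   defaults to the number of distinct \code{sample_id}s in \code{cohort}.
#' @return data.frame (one row per candidate, input order preserved) with the
#'   input columns plus \code{vaf_tum}, \code{vaf_ctrl}, \code{ratio},
#'   \code{cohort_freq}, per-rule failure flags (\code{fail_ctrl_vaf},
#'   \code{fail_ratio}, \code{fail_recurrence}, \code{fail_het_window},
#'   \code{fail_rescue}), \code{rescued}, \code{retained} and
#'   \code{rules_failed}. The cutoffs used are attached as attribute
#'   \code{"cutoffs"}.
#' @export
filter_candidates <- function(cohort,
                              ctrl_vaf_cutoff = 0.0034,
                              ratio_cutoff = 0.0629,
                              recurrence_cutoff = 0.023,
                              het_window = c(0.01, 0.95),
                              n_cohort = NULL) {
  check_columns(cohort, c("sample_id", "pos", "ref", "alt",
                          "n_mut_tum", "rd_tum", "n_mut_ctrl", "rd_ctrl"),
                "cohort")
  for (nm in c("ctrl_vaf_cutoff", "ratio_cutoff", "recurrence_cutoff")) {
    check_number(get(nm), nm, lower = 0, upper = 1)
  }
  check_number(het_window, "het_window", lower = 0, upper = 1)
  if (length(het_window) != 2 || het_window[1] >= het_window[2]) {
    stop_input("`het_window` must be an increasing pair in [0, 1]")
  }
  out <- cohort
  if (!"vaf_tum" %in% names(out)) out$vaf_tum <- out$n_mut_tum / out$rd_tum
  if (!"vaf_ctrl" %in% names(out)) out$vaf_ctrl <- out$n_mut_ctrl / out$rd_ctrl
  check_number(out$vaf_tum, "vaf_tum", lower = 0, upper = 1)
  check_number(out$vaf_ctrl, "vaf_ctrl", lower = 0, upper = 1)
  n_cohort <- n_cohort %||% length(unique(out$sample_id))
  if (n_cohort <= 0) stop_input("`n_cohort` must be positive")

  key <- paste(out$pos, out$ref, out$alt, sep = ":")
  carriers <- tapply(out$sample_id, key, function(s) length(unique(s)))
  out$cohort_freq <- as.numeric(carriers[key]) / n_cohort
  out$ratio <- ratio_statistic(out$n_mut_ctrl, out$rd_ctrl,
                               out$n_mut_tum, out$rd_tum)

  out$fail_ctrl_vaf <- !(out$vaf_ctrl < ctrl_vaf_cutoff)
  out$fail_ratio <- !is.na(out$ratio) & !(out$ratio < ratio_cutoff)
  out$fail_recurrence <- out$vaf_tum < 0.10 &
    !(out$cohort_freq < recurrence_cutoff)
  out$fail_het_window <- !(out$vaf_tum > het_window[1] &
                             out$vaf_tum < het_window[2])

  vmax <- tapply(out$vaf_tum, key, max)
  vmed <- tapply(out$vaf_tum, key, stats::median)
  rescue_variant <- as.logical(vmax[key] < 0.1 & vmed[key] < 0.05)
  out$rescued <- rescue_variant & out$fail_recurrence & out$vaf_tum > 0.05
  out$fail_recurrence[out$rescued] <- FALSE
  out$fail_rescue <- rescue_variant & !(out$vaf_tum > 0.05)

  flags <- c("fail_ctrl_vaf", "fail_ratio", "fail_recurrence",
             "fail_het_window", "fail_rescue")
  fail_any <- Reduce(`|`, out[flags])
  out$retained <- !fail_any
  out$rules_failed <- apply(out[flags], 1, function(f) {
    if (!any(f)) "" else paste(sub("^fail_", "", flags[f]), collapse = ";")
  })
  attr(out, "cutoffs") <- list(ctrl_vaf_cutoff = ctrl_vaf_cutoff,
                               ratio_cutoff = ratio_cutoff,
                               recurrence_cutoff = recurrence_cutoff,
                               het_window = het_window,
                               n_cohort = n_cohort)
  out
}

#' Heteroplasmy band of an mtDNA variant
#'
#' A variant is near-homoplasmic when its allele fraction exceeds 60%
#' (strictly), heteroplasmic otherwise.
#'
#' @param vaf allele fraction(s) in [0, 1].
#' @return character vector of \code{"near_homoplasmic"} /
#'   \code{"heteroplasmic"}.
#' @export
heteroplasmy_class <- function(vaf) {
  check_number(vaf, "vaf", lower = 0, upper = 1)
  ifelse(vaf > 0.60, "near_homoplasmic", "heteroplasmic")
}

#' Mitochondrial genome copy number from read depths
#'
#' The raw mtDNA copy number of a diploid-nuclear sample is
#' \code{2 * mt_mean_depth / autosomal_mean_depth}. Because only a fraction
#' of the cells in a tumour sample are tumour cells, a purity-adjusted copy
#' number is also reported using the pinned formula
#' \code{(raw_tumour - (1 - purity) * control_raw_cn) / purity} when both the
#' purity and the matched control's raw copy number are available; otherwise
#' the normalized value equals the raw value.
#'
#' @param mt_mean_depth mean read depth over the mitochondrial genome (> 0).
#' @param autosomal_mean_depth mean autosomal read depth (> 0).
#' @param purity tumour cell fraction in (0, 1], optional.
#' @param control_raw_cn raw mtDNA copy number of the matched control,
#'   optional.
#' @return list with \code{raw} and \code{normalized}.
#' @export
mtdna_copy_number <- function(mt_mean_depth, autosomal_mean_depth,
                              purity = NULL, control_raw_cn = NULL) {
  if (any(mt_mean_depth <= 0) || any(autosomal_mean_depth <= 0)) {
    stop_input("depths must be positive")
  }
  raw <- 2 * mt_mean_depth / autosomal_mean_depth
  normalized <- raw
  if (!is.null(purity)) {
    check_number(purity, "purity", lower = 0, upper = 1)
    if (any(purity == 0)) stop_input("`purity` must be positive")
    ctrl <- control_raw_cn %||% 0
    if (is.null(control_raw_cn) && any(purity < 1)) {
      # without a control reference the adjustment is undefined; report raw
      normalized <- raw
    } else {
      normalized <- (raw - (1 - purity) * ctrl) / purity
    }
  }
  list(raw = raw, normalized = normalized)
}
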