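# Allele-specific copy-number state taxonomy, focal thresholds, gene
# annotation and genome-altered density metrics.

cn_state_levels <- c("wild_type", "homozygous_deletion", "loh",
                     "copy_neutral_loh", "gain_loh", "gain",
                     "amp_loh", "amp", "indeterminate")

#' Classify allele-specific copy-number states
#'
#' Maps total copy number (tcn) and minor copy number (lcn) of a segment to
#' one of eight states: wild type (2,1), homozygous deletion (0,0),
#' LOH (1,0), copy-neutral LOH (2,0), gain-LOH (tcn 3-4, lcn 0), gain
#' (tcn 3-4, lcn >= 1), amp-LOH (tcn >= 5, lcn 0) and amp
#' (tcn >= 5, lcn >= 1).
#'
#' Allele-specific callers can fail to resolve the minor allele at low
#' coverage; a missing lcn yields a coarse label from tcn alone
#' (0 homozygous_deletion, 1 loh, 2 wild_type, 3-4 gain, >= 5 amp) with
#' \code{lcn_indeterminate = TRUE}, rather than silently dropping the
#' segment (which would bias genome-altered fractions).
#'
#' @param tcn integer total copy number (>= 0).
#' @param lcn integer minor copy number, \code{NA} when unresolved. Must
#'   satisfy \code{lcn <= tcn - lcn} (the minor allele is the lower one).
#' @return data.frame with columns \code{tcn}, \code{lcn}, \code{state}
#'   (factor over the state vocabulary) and \code{lcn_indeterminate}.
#' @export
classify_state <- function(tcn, lcn = NA_integer_) {
  n <- max(length(tcn), length(lcn))
  tcn <- rep_len(as.numeric(tcn), n)
  lcn <- rep_len(as.numeric(lcn), n)
  if (anyNA(tcn) || any(tcn < 0)) stop_input("`tcn` must be non-negative and known")
  if (any(tcn != floor(tcn)) || any(!is.na(lcn) & lcn != floor(lcn))) {
    stop_input("`tcn` and `lcn` must be integer copy numbers")
  }
  known <- !is.na(lcn)
  if (any(known & lcn < 0)) stop_input("`lcn` must be non-negative")
  if (any(known & lcn > tcn)) stop_input("`lcn` cannot exceed `tcn`")
  if (any(known & 2 * lcn > tcn)) {
    stop_input("`lcn` must be the minor allele copy number (lcn <= tcn - lcn)")
  }
  state <- character(n)
  state[known & tcn == 0] <- "homozygous_deletion"
  state[known & tcn == 1] <- "loh"
  state[known & tcn == 2 & lcn == 0] <- "copy_neutral_loh"
  state[known & tcn == 2 & lcn == 1] <- "wild_type"
  state[known & tcn %in% c(3, 4) & lcn == 0] <- "gain_loh"
  state[known & tcn %in% c(3, 4) & lcn >= 1] <- "gain"
  state[known & tcn >= 5 & lcn == 0] <- "amp_loh"
  state[known & tcn >= 5 & lcn >= 1] <- "amp"
  # coarse mapping when the minor allele is unresolved
  state[!known & tcn == 0] <- "homozygous_deletion"
  state[!known & tcn == 1] <- "loh"
  state[!known & tcn == 2] <- "wild_type"
  state[!known & tcn %in% c(3, 4)] <- "gain"
  state[!known & tcn >= 5] <- "amp"
  data.frame(
    tcn = tcn, lcn = lcn,
    state = factor(state, levels = cn_state_levels),
    lcn_indeterminate = !known,
    stringsAsFactors = FALSE
  )
}

#' Focal amplification/deletion call from the log2 ratio
#'
#' Strict inequalities as printed: amplification when
#' \code{log2_ratio > amp_threshold}, deletion when
#' \code{log2_ratio < del_threshold}, neutral otherwise.
#'
#' @param log2_ratio finite tumour/control log2 ratio(s).
#' @param amp_threshold default 0.9.
#' @param del_threshold default -0.3.
#' @return character vector of \code{"amplification"}, \code{"deletion"},
#'   \code{"neutral"}.
#' @export
classify_focal <- function(log2_ratio, amp_threshold = 0.9,
                           del_threshold = -0.3) {
  if (!is.numeric(log2_ratio) || anyNA(log2_ratio) || any(!is.finite(log2_ratio))) {
    stop_input("`log2_ratio` must be finite")
  }
  if (del_threshold >= amp_threshold) {
    stop_input("`del_threshold` must be below `amp_threshold`")
  }
  ifelse(log2_ratio > amp_threshold, "amplification",
         ifelse(log2_ratio < del_threshold, "deletion", "neutral"))
}

#' Annotate genes with the copy-number state of overlapping segments
#'
#' Each gene interval is assigned the state of the segment it overlaps in
#' each sample; when a gene spans several segments the one with the largest
#' overlap wins. Genes with no overlapping segment are labelled missing
#' (\code{NA}). Coordinates are 1-based inclusive on both inputs.
#'
#' @param segments data.frame with \code{sample_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{tcn}, \code{lcn}.
#' @param genes data.frame with \code{gene}, \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive; convert BED half-open starts on read).
#' @return long data.frame \code{gene}, \code{sample_id}, \code{state},
#'   \code{lcn_indeterminate}.
#' @export
annotate_genes <- function(segments, genes) {
  check_columns(genes, c("gene", "chrom", "start", "end"), "genes")
  check_columns(segments, c("sample_id", "chrom", "start", "end", "tcn"), "segments")
  if (!"lcn" %in% names(segments)) segments$lcn <- NA_integer_
  samples <- unique(segments$sample_id)
  out <- expand.grid(gene = genes$gene, sample_id = samples,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$state <- factor(rep(NA_character_, nrow(out)), levels = cn_state_levels)
  out$lcn_indeterminate <- rep(NA, nrow(out))
  if (nrow(segments) == 0 || nrow(genes) == 0) return(out)
  seg_state <- classify_state(segments$tcn, segments$lcn)
  for (s in samples) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    st <- seg_state[segments$sample_id == s, , drop = FALSE]
    for (ch in unique(genes$chrom)) {
      gi <- which(genes$chrom == ch)
      si <- which(seg$chrom == ch)
      if (length(si) == 0) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(genes$start[gi], genes$end[gi]),
        IRanges::IRanges(seg$start[si], seg$end[si])
      )
      if (length(hits) == 0) next
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      ov <- pmin(genes$end[gi][qh], seg$end[si][sh]) -
        pmax(genes$start[gi][qh], seg$start[si][sh]) + 1
      best <- tapply(seq_along(qh), qh, function(ii) ii[which.max(ov[ii])])
      for (b in best) {
        row <- which(out$gene == genes$gene[gi][qh[b]] & out$sample_id == s)
        out$state[row] <- st$state[si[sh[b]]]
        out$lcn_indeterminate[row] <- st$lcn_indeterminate[si[sh[b]]]
      }
    }
  }
  out
}

#' Copy-number density metrics per sample
#'
#' Computes the eight genome-altered density metrics used for mutational
#' density analyses: the fraction of the genome with total copy-number
#' aberration (\code{pga_total}), the gained and lost fractions
#' (\code{pga_gain}, \code{pga_loss}, relative to the neutral total copy
#' number 2), their ratio, and the average lengths of aberrant, gained and
#' lost segments plus the gain:loss length ratio. Ratios (and average
#' lengths) are reported as \code{NA} when their denominator is zero.
#'
#' @param segments data.frame with \code{sample_id}, \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive), \code{tcn}; segments must
#'   not overlap within a sample.
#' @param genome_size_bp genome length in bp used as the PGA denominator.
#' @param baseline \code{"diploid"} (aberration means tcn != 2) or
#'   \code{"ploidy"} (aberration relative to the sample's length-weighted
#'   modal tcn).
#' @return data.frame, one row per sample, columns \code{sample_id},
#'   \code{pga_total}, \code{pga_gain}, \code{pga_loss},
#'   \code{pga_gain_loss_ratio}, \code{avg_len}, \code{avg_len_gain},
#'   \code{avg_len_loss}, \code{avg_len_gain_loss_ratio}.
#' @export
cnv_density <- function(segments, genome_size_bp,
                        baseline = c("diploid", "ploidy")) {
  baseline <- match.arg(baseline)
  check_columns(segments, c("sample_id", "chrom", "start", "end", "tcn"), "segments")
  if (!is.numeric(genome_size_bp) || length(genome_size_bp) != 1 ||
      genome_size_bp <= 0) {
    stop_input("`genome_size_bp` must be a single positive number")
  }
  if (nrow(segments) > 0 && any(segments$end < segments$start)) {
    stop_input("segments with end < start")
  }
  # overlap check within sample/chromosome
  sp <- split(segments, segments$sample_id)
  for (seg in sp) {
    for (ch in unique(seg$chrom)) {
      s <- seg[seg$chrom == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
        stop_input("overlapping segments for sample %s on %s",
                   s$sample_id[1], ch)
      }
    }
  }
  one <- function(seg) {
    neutral <- 2
    if (baseline == "ploidy" && nrow(seg) > 0) {
      len <- seg$end - seg$start + 1
      neutral <- as.numeric(names(which.max(tapply(len, seg$tcn, sum))))
    }
    len <- seg$end - seg$start + 1
    gain <- seg$tcn > neutral
    loss <- seg$tcn < neutral
    ab <- gain | loss
    ratio <- function(num, den) if (isTRUE(den > 0)) num / den else NA_real_
    mean_or_na <- function(x) if (length(x) > 0) mean(x) else NA_real_
    data.frame(
      sample_id = if (nrow(seg) > 0) seg$sample_id[1] else NA_character_,
      pga_total = sum(len[ab]) / genome_size_bp,
      pga_gain = sum(len[gain]) / genome_size_bp,
      pga_loss = sum(len[loss]) / genome_size_bp,
      pga_gain_loss_ratio = ratio(sum(len[gain]), sum(len[loss])),
      avg_len = mean_or_na(len[ab]),
      avg_len_gain = mean_or_na(len[gain]),
      avg_len_loss = mean_or_na(len[loss]),
      avg_len_gain_loss_ratio = ratio(mean_or_na(len[gain]),
                                      mean_or_na(len[loss])),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(sp, one))
  rownames(out) <- NULL
  out
}
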