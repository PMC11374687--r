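# Cohort-level mutation burden classification and co-mutation testing.

#' Iterative quantile-based hypermutation classification
#'
#' Classifies tumours as hypermutated (HM) or non-hypermutated (nHM) from
#' their total somatic short-variant counts. In each round, samples whose
#' count strictly exceeds \code{median + iqr_factor * IQR} over the current
#' pool are flagged; every flagged pool member is then replaced by two
#' artificial samples carrying half of its count each, and the threshold is
#' recomputed on the updated pool. The procedure repeats until a round flags
#' nothing. A sample is HM iff it, or any artificial descendant of it, was
#' ever flagged; \code{outlier_times} counts the rounds in which that
#' happened. Splitting halves the pool maximum every round, so the procedure
#' terminates after at most \code{ceil(log2(max(counts))) + 1} rounds.
#'
#' For odd counts the two halves are \code{floor(n/2)} and \code{ceiling(n/2)}
#' so the total count is conserved. Quartiles follow the convention of
#' \code{\link{cohort_quartiles}}.
#'
#' @param counts named non-negative numeric vector of per-sample somatic
#'   short-variant counts; names are sample identifiers.
#' @param iqr_factor multiplier of the interquartile range (default 1.5).
#' @return object of class \code{hm_result}: a list with
#'   \describe{
#'     \item{samples}{data.frame with \code{sample_id}, \code{n_snv},
#'       \code{is_hm}, \code{outlier_times}.}
#'     \item{rounds_total}{number of rounds evaluated, including the final
#'       round that flagged nothing.}
#'     \item{threshold_trace}{the threshold used in each round
#'       (length \code{rounds_total}).}
#'   }
#' @export
classify_hypermutation <- function(counts, iqr_factor = 1.5) {
  if (!is.numeric(counts)) stop_input("`counts` must be a numeric vector")
  if (length(counts) < 3) {
    stop_input("at least 3 samples are required to classify hypermutation (got %d)",
               length(counts))
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop_input("`counts` must be non-negative and complete")
  }
  check_number(iqr_factor, "iqr_factor", lower = 0)
  ids <- names(counts) %||% paste0("sample_", seq_along(counts))
  if (anyDuplicated(ids)) stop_input("sample identifiers must be unique")

  pool_count <- as.numeric(counts)
  pool_origin <- ids
  outlier_times <- stats::setNames(integer(length(ids)), ids)
  threshold_trace <- numeric(0)
  max_rounds <- ceiling(log2(max(pool_count) + 1)) + 2L  # safety bound only

  repeat {
    q <- cohort_quartiles(pool_count)
    thr <- q["median"] + iqr_factor * (q["q75"] - q["q25"])
    threshold_trace <- c(threshold_trace, unname(thr))
    flagged <- pool_count > thr
    if (!any(flagged)) break
    hit <- unique(pool_origin[flagged])
    outlier_times[hit] <- outlier_times[hit] + 1L
    lo <- floor(pool_count[flagged] / 2)
    hi <- ceiling(pool_count[flagged] / 2)
    pool_count <- c(pool_count[!flagged], lo, hi)
    pool_origin <- c(pool_origin[!flagged],
                     pool_origin[flagged], pool_origin[flagged])
    if (length(threshold_trace) > max_rounds) {
      stop("hypermutation classification failed to terminate")  # nocov
    }
  }

  structure(list(
    samples = data.frame(
      sample_id = ids,
      n_snv = as.numeric(counts),
      is_hm = outlier_times[ids] > 0L,
      outlier_times = unname(outlier_times[ids]),
      row.names = NULL,
      stringsAsFactors = FALSE
    ),
    rounds_total = length(threshold_trace),
    threshold_trace = threshold_trace
  ), class = "hm_result")
}

#' @export
print.hm_result <- function(x, ...) {
  cat(sprintf("Hypermutation classification: %d/%d samples HM after %d round(s)\n",
              sum(x$samples$is_hm), nrow(x$samples), x$rounds_total))
  invisible(x)
}

#' Tumour mutation burden per sample
#'
#' TMB is the somatic short-variant count divided by the genome size in
#' megabases. When a hypermutation classification is supplied, the observed
#' HM TMB cutoff (the minimum TMB among HM samples) is reported alongside.
#'
#' @param counts named non-negative numeric vector of per-sample counts.
#' @param genome_size_mb callable genome size in megabases (> 0). The default
#'   2859 corresponds to the non-gap GRCh38 autosomes plus X.
#' @param hm optional \code{hm_result} (see
#'   \code{\link{classify_hypermutation}}) or named logical vector of HM
#'   status.
#' @return list with \code{burden} (data.frame \code{sample_id}, \code{n_snv},
#'   \code{tmb}) and \code{hm_tmb_cutoff} (\code{NULL} when no sample is HM or
#'   \code{hm} is missing).
#' @export
compute_tmb <- function(counts, genome_size_mb = 2859, hm = NULL) {
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0)) {
    stop_input("`counts` must be non-negative and complete")
  }
  if (!is.numeric(genome_size_mb) || length(genome_size_mb) != 1 ||
      is.na(genome_size_mb) || genome_size_mb <= 0) {
    stop_input("`genome_size_mb` must be a single positive number")
  }
  ids <- names(counts) %||% paste0("sample_", seq_along(counts))
  burden <- data.frame(
    sample_id = ids,
    n_snv = as.numeric(counts),
    tmb = as.numeric(counts) / genome_size_mb,
    stringsAsFactors = FALSE
  )
  cutoff <- NULL
  if (!is.null(hm)) {
    is_hm <- if (inherits(hm, "hm_result")) {
      stats::setNames(hm$samples$is_hm, hm$samples$sample_id)[ids]
    } else {
      hm[ids]
    }
    if (anyNA(is_hm)) stop_input("`hm` does not cover all samples in `counts`")
    if (any(is_hm)) cutoff <- min(burden$tmb[is_hm])
  }
  list(burden = burden, hm_tmb_cutoff = cutoff)
}

#' Microsatellite instability call from a paired-sample score
#'
#' A tumour is called MSI when its paired-module instability score is greater
#' than or equal to the threshold (boundary inclusive), MSS otherwise.
#'
#' @param msi_score non-negative score(s).
#' @param threshold call threshold, default 3.5.
#' @return character vector of \code{"MSI"} / \code{"MSS"}.
#' @export
classify_msi <- function(msi_score, threshold = 3.5) {
  check_number(msi_score, "msi_score", lower = 0)
  check_number(threshold, "threshold", lower = 0)
  ifelse(msi_score >= threshold, "MSI", "MSS")
}

#' Pairwise co-mutation and mutual-exclusivity testing
#'
#' Two-sided Fisher's exact test for every pair of genes in a binary
#' genes-by-samples mutation matrix, with Benjamini-Hochberg adjustment
#' across all tested pairs. The odds ratio reported is the sample
#' (cross-product) odds ratio \code{both * neither / (a_only * b_only)};
#' pairs with an odds ratio above 1 are labelled co-occurring, at or below 1
#' mutually exclusive. Pairs involving a gene mutated in no or in all samples
#' are skipped with a warning (the test is degenerate there).
#'
#' @param mutation_matrix logical or 0/1 matrix, genes in rows, samples in
#'   columns; rownames are gene names.
#' @param fdr_threshold significance level on the adjusted p-value
#'   (default 0.1).
#' @return data.frame with one row per tested pair: \code{gene_a},
#'   \code{gene_b}, contingency counts (\code{both}, \code{a_only},
#'   \code{b_only}, \code{neither}), \code{odds_ratio}, \code{p_value},
#'   \code{fdr}, \code{direction}, \code{significant}.
#' @export
pairwise_comutation <- function(mutation_matrix, fdr_threshold = 0.1) {
  m <- as.matrix(mutation_matrix)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop_input("`mutation_matrix` needs at least 2 genes and 2 samples")
  }
  if (anyNA(m) || !all(m %in% c(0, 1))) {
    stop_input("`mutation_matrix` must be binary (0/1 or logical) and complete")
  }
  mode(m) <- "logical"
  genes <- rownames(m) %||% paste0("gene_", seq_len(nrow(m)))
  rs <- rowSums(m)
  degenerate <- rs == 0 | rs == ncol(m)
  if (any(degenerate)) {
    warning(sprintf("skipping pairs involving constant gene(s): %s",
                    paste(genes[degenerate], collapse = ", ")),
            call. = FALSE)
  }
  keep <- which(!degenerate)
  if (length(keep) < 2) stop_input("fewer than 2 non-constant genes")
  pairs <- utils::combn(keep, 2)
  n_pairs <- ncol(pairs)
  res <- data.frame(
    gene_a = genes[pairs[1, ]],
    gene_b = genes[pairs[2, ]],
    both = integer(n_pairs), a_only = integer(n_pairs),
    b_only = integer(n_pairs), neither = integer(n_pairs),
    odds_ratio = numeric(n_pairs), p_value = numeric(n_pairs),
    stringsAsFactors = FALSE
  )
  for (k in seq_len(n_pairs)) {
    a <- m[pairs[1, k], ]
    b <- m[pairs[2, k], ]
    tab <- c(both = sum(a & b), a_only = sum(a & !b),
             b_only = sum(!a & b), neither = sum(!a & !b))
    res$both[k] <- tab["both"]; res$a_only[k] <- tab["a_only"]
    res$b_only[k] <- tab["b_only"]; res$neither[k] <- tab["neither"]
    res$odds_ratio[k] <- (tab["both"] * tab["neither"]) /
      (tab["a_only"] * tab["b_only"])
    res$p_value[k] <- stats::fisher.test(
      matrix(tab, nrow = 2, byrow = TRUE))$p.value
  }
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res$direction <- ifelse(res$odds_ratio > 1, "co-occurring", "exclusive")
  res$significant <- res$fdr < fdr_threshold
  res
}
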