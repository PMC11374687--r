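# Mutational signature profile comparison and activity correlation.

align_channels <- function(u, v) {
  if (!is.null(names(u)) && !is.null(names(v))) {
    if (!setequal(names(u), names(v))) {
      stop_input("profiles are defined over different channel sets")
    }
    v <- v[names(u)]
  } else if (length(u) != length(v)) {
    stop_input("profiles have different numbers of channels")
  }
  list(u = as.numeric(u), v = as.numeric(v))
}

#' Cosine similarity between two signature profiles
#'
#' Standard cosine of two non-negative channel-probability vectors. Profiles
#' are aligned by channel label when both are named, never by position, so
#' catalogue files with different channel orderings compare correctly. Scale
#' invariant: \code{cosine_similarity(u, c * v) == cosine_similarity(u, v)}
#' for any c > 0.
#'
#' @param u,v numeric profile vectors over the same channel set (e.g. the 96
#'   trinucleotide substitution channels), named by channel.
#' @return similarity in [0, 1] for non-negative profiles.
#' @export
cosine_similarity <- function(u, v) {
  al <- align_channels(u, v)
  u <- al$u; v <- al$v
  if (anyNA(u) || anyNA(v)) stop_input("profiles must be complete")
  if (any(u < 0) || any(v < 0)) stop_input("profiles must be non-negative")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop_input("cosine similarity undefined for a zero profile")
  sum(u * v) / (nu * nv)
}

#' Novelty assessment of a signature profile against two catalogues
#'
#' A de novo signature is considered novel iff its best cosine similarity to
#' each of two reference catalogues is strictly below the threshold;
#' otherwise the best-matching catalogue signature is reported. Monotone in
#' the threshold: raising it never turns a novel call into a known one.
#'
#' @param profile named channel-probability vector.
#' @param catalogue_a,catalogue_b matrices with channels in rows (rownames =
#'   channel labels) and reference signatures in columns.
#' @param threshold novelty threshold, default 0.85.
#' @return list with \code{novel} (logical), \code{best_match},
#'   \code{best_similarity}, \code{max_sim_a}, \code{max_sim_b}.
#' @export
novelty_flag <- function(profile, catalogue_a, catalogue_b, threshold = 0.85) {
  sims_vs <- function(cat, which) {
    cat <- as.matrix(cat)
    if (ncol(cat) == 0 || nrow(cat) == 0) {
      stop_input("catalogue %s is empty", which)
    }
    sims <- vapply(seq_len(ncol(cat)), function(j) {
      cosine_similarity(profile, stats::setNames(cat[, j], rownames(cat)))
    }, numeric(1))
    stats::setNames(sims, colnames(cat) %||% paste0(which, seq_len(ncol(cat))))
  }
  sa <- sims_vs(catalogue_a, "a")
  sb <- sims_vs(catalogue_b, "b")
  all_sims <- c(sa, sb)
  best <- which.max(all_sims)
  list(
    novel = max(sa) < threshold && max(sb) < threshold,
    best_match = names(all_sims)[best],
    best_similarity = unname(all_sims[best]),
    max_sim_a = max(sa),
    max_sim_b = max(sb)
  )
}

#' Pairwise Spearman correlation of signature activities
#'
#' Spearman's rank correlation over all pairs of signatures in a
#' samples-by-signatures activity matrix, with Benjamini-Hochberg adjustment
#' across pairs; an adjusted p below \code{fdr_threshold} is flagged
#' significant. Ties receive average ranks. The p-value uses exact
#' permutation enumeration for fewer than 10 untied samples and the
#' t-approximation otherwise. Pairs involving a constant activity column are
#' skipped with a warning.
#'
#' @param activities numeric matrix, samples in rows, signatures in columns
#'   (colnames = signature names), entries >= 0.
#' @param fdr_threshold significance level on the adjusted p (default 0.05).
#' @return data.frame with \code{sig_a}, \code{sig_b}, \code{rho},
#'   \code{p_value}, \code{fdr}, \code{significant}.
#' @export
activity_correlation <- function(activities, fdr_threshold = 0.05) {
  m <- as.matrix(activities)
  if (nrow(m) < 5) stop_input("at least 5 samples required")
  if (ncol(m) < 2) stop_input("at least 2 signatures required")
  if (anyNA(m) || any(m < 0)) {
    stop_input("`activities` must be complete and non-negative")
  }
  sigs <- colnames(m) %||% paste0("sig_", seq_len(ncol(m)))
  constant <- apply(m, 2, function(x) length(unique(x)) < 2)
  if (any(constant)) {
    warning(sprintf("skipping pairs involving constant activity column(s): %s",
                    paste(sigs[constant], collapse = ", ")), call. = FALSE)
  }
  keep <- which(!constant)
  if (length(keep) < 2) stop_input("fewer than 2 non-constant signatures")
  pairs <- utils::combn(keep, 2)
  res <- data.frame(sig_a = sigs[pairs[1, ]], sig_b = sigs[pairs[2, ]],
                    rho = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  n <- nrow(m)
  for (k in seq_len(ncol(pairs))) {
    x <- m[, pairs[1, k]]; y <- m[, pairs[2, k]]
    ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
    ct <- suppressWarnings(stats::cor.test(
      x, y, method = "spearman", exact = (n < 10) && !ties))
    res$rho[k] <- unname(ct$estimate)
    res$p_value[k] <- ct$p.value
  }
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$fdr < fdr_threshold
  res
}
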