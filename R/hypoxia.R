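# Buffa hypoxia scoring and nested-linear-model association framework.

#' Buffa hypoxia score
#'
#' For every gene in the hypoxia signature, the reference value is the median
#' abundance over tumour samples only. A scored sample receives +1 for a
#' gene whose abundance is strictly above that tumour median and -1
#' otherwise (ties score -1); the hypoxia score is the sum over signature
#' genes. Both tumour and control columns of the matrix are scored, always
#' against the tumour medians. Because the score only uses ranks relative to
#' a median, it is invariant under any monotone per-gene transformation of
#' the abundances.
#'
#' @param expression numeric matrix, genes in rows (rownames = gene names),
#'   samples in columns (colnames = sample ids); e.g. log2(TPM + 1).
#' @param signature_genes character vector of signature gene names; all must
#'   be present in the matrix.
#' @param tumour_ids column names of the tumour samples used for the
#'   reference medians (>= 2).
#' @return data.frame with \code{sample_id} and integer \code{score} in
#'   [-G, G] for a signature of G genes.
#' @export
buffa_score <- function(expression, signature_genes, tumour_ids) {
  m <- as.matrix(expression)
  missing_genes <- setdiff(signature_genes, rownames(m))
  if (length(missing_genes) > 0) {
    stop_input("signature gene(s) absent from the expression matrix: %s",
               paste(missing_genes, collapse = ", "))
  }
  missing_t <- setdiff(tumour_ids, colnames(m))
  if (length(missing_t) > 0) {
    stop_input("tumour sample(s) absent from the expression matrix: %s",
               paste(utils::head(missing_t, 5), collapse = ", "))
  }
  if (length(tumour_ids) < 2) stop_input("at least 2 tumour samples required")
  sig <- m[signature_genes, , drop = FALSE]
  med <- apply(sig[, tumour_ids, drop = FALSE], 1, stats::median)
  score <- colSums(ifelse(sig > med, 1L, -1L))
  data.frame(sample_id = colnames(m), score = as.integer(score),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample mutational density feature matrix
#'
#' Assembles the 22 mutational density metrics tested against hypoxia:
#' 10 variant-count metrics (all, coding, non-coding, nonsynonymous, SNV,
#' DNV, TNV, DEL, INS, INDEL), the 8 copy-number density metrics of
#' \code{\link{cnv_density}}, and 4 structural-variant counts (deletion,
#' inversion, tandem duplication, translocation), plus clonal/subclonal
#' mutation counts when a clonality annotation is available and the
#' adjustment covariates (age, sex, purity) from the clinical table. Each
#' metric is also binned into cohort deciles (columns suffixed
#' \code{_decile}); metrics that are constant across the cohort cannot be
#' binned and are flagged in the \code{"degenerate_metrics"} attribute.
#' Metrics from a missing input table are \code{NA}, not zero.
#'
#' @param variants somatic variant table (\code{sample_id},
#'   \code{variant_class} in SNV/DNV/TNV/INS/DEL, \code{region} in
#'   coding/noncoding, logical \code{nonsynonymous}, optional
#'   \code{clonality} in clonal/subclonal) or \code{NULL}.
#' @param segments copy-number segment table for \code{\link{cnv_density}}
#'   or \code{NULL}.
#' @param svs structural-variant table (\code{sample_id}, \code{sv_class} in
#'   deletion/inversion/tandem_duplication/translocation) or \code{NULL}.
#' @param clinical clinical table (\code{patient_id} or \code{sample_id},
#'   \code{age}, \code{sex}, \code{purity}) or \code{NULL}.
#' @param genome_size_bp PGA denominator passed to \code{\link{cnv_density}}.
#' @param deciles add decile bins (default TRUE).
#' @return data.frame, one row per sample.
#' @export
feature_matrix <- function(variants = NULL, segments = NULL, svs = NULL,
                           clinical = NULL, genome_size_bp = 2859e6,
                           deciles = TRUE) {
  ids <- character(0)
  if (!is.null(variants)) ids <- union(ids, variants$sample_id)
  if (!is.null(segments)) ids <- union(ids, segments$sample_id)
  if (!is.null(svs)) ids <- union(ids, svs$sample_id)
  if (!is.null(clinical)) {
    idc <- clinical$sample_id %||% clinical$patient_id
    ids <- union(ids, idc)
  }
  if (length(ids) == 0) stop_input("no input tables with samples provided")
  ids <- sort(ids)
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)

  count_by <- function(tab, which_rows) {
    tab <- table(factor(tab$sample_id[which_rows], levels = ids))
    as.numeric(tab)
  }
  snv_metrics <- c("n_all", "n_coding", "n_noncoding", "n_nonsynonymous",
                   "n_snv", "n_dnv", "n_tnv", "n_del", "n_ins", "n_indel")
  cnv_metrics <- c("pga_total", "pga_gain", "pga_loss", "pga_gain_loss_ratio",
                   "avg_len", "avg_len_gain", "avg_len_loss",
                   "avg_len_gain_loss_ratio")
  sv_metrics <- c("sv_deletion", "sv_inversion", "sv_tandem_duplication",
                  "sv_translocation")
  if (!is.null(variants)) {
    check_columns(variants, c("sample_id", "variant_class", "region",
                              "nonsynonymous"), "variants")
    v <- variants
    out$n_all <- count_by(v, rep(TRUE, nrow(v)))
    out$n_coding <- count_by(v, v$region == "coding")
    out$n_noncoding <- count_by(v, v$region == "noncoding")
    out$n_nonsynonymous <- count_by(v, as.logical(v$nonsynonymous))
    for (cl in c("snv", "dnv", "tnv", "del", "ins")) {
      out[[paste0("n_", cl)]] <- count_by(v, v$variant_class == toupper(cl))
    }
    out$n_indel <- out$n_del + out$n_ins
    if ("clonality" %in% names(v)) {
      out$n_clonal <- count_by(v, v$clonality == "clonal")
      out$n_subclonal <- count_by(v, v$clonality == "subclonal")
    }
  } else {
    out[snv_metrics] <- NA_real_
  }
  if (!is.null(segments)) {
    dens <- cnv_density(segments, genome_size_bp)
    out[cnv_metrics] <- dens[match(out$sample_id, dens$sample_id), cnv_metrics]
    # samples without any segment have no aberration
    none <- !(out$sample_id %in% dens$sample_id)
    out[none, c("pga_total", "pga_gain", "pga_loss")] <- 0
  } else {
    out[cnv_metrics] <- NA_real_
  }
  if (!is.null(svs)) {
    check_columns(svs, c("sample_id", "sv_class"), "svs")
    for (cl in c("deletion", "inversion", "tandem_duplication",
                 "translocation")) {
      out[[paste0("sv_", cl)]] <- count_by(svs, svs$sv_class == cl)
    }
  } else {
    out[sv_metrics] <- NA_real_
  }
  if (!is.null(clinical)) {
    cl <- clinical
    cl$sample_id <- cl$sample_id %||% cl$patient_id
    keep <- intersect(c("age", "sex", "purity"), names(cl))
    out[keep] <- cl[match(out$sample_id, cl$sample_id), keep]
  }

  degenerate <- character(0)
  if (deciles) {
    metric_cols <- c(snv_metrics, "n_clonal", "n_subclonal",
                     cnv_metrics, sv_metrics)
    for (col in intersect(metric_cols, names(out))) {
      x <- out[[col]]
      if (all(is.na(x))) next
      br <- unique(stats::quantile(x, probs = 0:10 / 10, na.rm = TRUE,
                                   type = 7))
      if (length(br) < 2) {
        degenerate <- c(degenerate, col)
        out[[paste0(col, "_decile")]] <- NA_integer_
        next
      }
      out[[paste0(col, "_decile")]] <- as.integer(
        cut(x, breaks = br, include.lowest = TRUE, labels = FALSE))
    }
  }
  attr(out, "degenerate_metrics") <- degenerate
  out
}

#' Association between hypoxia score and one mutational feature
#'
#' Fits the nested linear models
#' \code{hypoxia ~ feature + age + sex + purity} (full) and
#' \code{hypoxia ~ age + sex + purity} (null) on complete cases and compares
#' them with an F-test (ANOVA). The direction is the sign of the feature
#' coefficient in the full model. The p-value is raw; adjust across features
#' with \code{\link{adjust_pvalues}}.
#'
#' @param scores numeric hypoxia scores, one per sample.
#' @param feature numeric (or two-level) mutational feature, same order.
#' @param covariates data.frame of adjustment covariates (age, sex, purity),
#'   same order; may be \code{NULL} for an unadjusted comparison.
#' @param feature_name label carried into the result.
#' @return one-row data.frame: \code{feature}, \code{f_statistic},
#'   \code{p_value}, \code{direction} (+1/-1), \code{n_used},
#'   \code{n_excluded}.
#' @export
associate <- function(scores, feature, covariates = NULL,
                      feature_name = "feature") {
  if (length(feature) != length(scores)) {
    stop_input("`scores` and `feature` must have the same length")
  }
  df <- data.frame(hypoxia = as.numeric(scores), feature = feature)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(scores)) {
      stop_input("`covariates` must have one row per sample")
    }
    df <- cbind(df, covariates)
  }
  cc <- stats::complete.cases(df)
  n_excluded <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  if (nrow(df) < 10) {
    stop_input("fewer than 10 complete cases (%d)", nrow(df))
  }
  if (length(unique(df$feature)) < 2) {
    stop_input("feature `%s` is constant on complete cases", feature_name)
  }
  full <- stats::lm(hypoxia ~ ., data = df)
  null <- stats::lm(hypoxia ~ . - feature, data = df)
  if (anyNA(coef(full))) {
    stop_input("rank-deficient full model for feature `%s` (collinear covariates?)",
               feature_name)
  }
  an <- stats::anova(null, full)
  beta <- stats::coef(full)[grep("^feature", names(stats::coef(full)))][1]
  data.frame(
    feature = feature_name,
    f_statistic = an$F[2],
    p_value = an$`Pr(>F)`[2],
    direction = unname(sign(beta)),
    n_used = nrow(df),
    n_excluded = n_excluded,
    stringsAsFactors = FALSE
  )
}

#' Multiple-testing adjustment with the 20-test Bonferroni switch
#'
#' Bonferroni adjustment when fewer than 20 tests were conducted,
#' Benjamini-Hochberg otherwise; significance downstream is assessed at
#' adjusted p < 0.1.
#'
#' @param p numeric p-values in [0, 1].
#' @param n_tests number of tests conducted (default \code{length(p)}).
#' @return list with \code{p_adjusted} and \code{method}
#'   (\code{"bonferroni"} or \code{"BH"}).
#' @export
adjust_pvalues <- function(p, n_tests = length(p)) {
  check_number(p, "p", lower = 0, upper = 1)
  method <- if (n_tests < 20) "bonferroni" else "BH"
  list(p_adjusted = stats::p.adjust(p, method = method, n = n_tests),
       method = method)
}

#' Simulation-based residual uniformity check
#'
#' Verifies the distributional assumptions of a fitted Gaussian linear model
#' by parametric simulation: \code{n_sim} response vectors are drawn from the
#' fitted model, each observation's scaled residual is its quantile among its
#' simulated values, and the scaled residuals are tested against Uniform(0,1)
#' with a Kolmogorov-Smirnov test. Under a correctly specified model the
#' scaled residuals are approximately uniform and the KS test rejects at
#' about its nominal rate.
#'
#' @param fit an \code{lm} fit.
#' @param n_sim number of simulated response vectors (>= 20, default 250).
#' @param seed optional seed for the simulation stream.
#' @return list with \code{statistic}, \code{p_value} and the scaled
#'   residuals \code{quantiles}.
#' @export
residual_uniformity <- function(fit, n_sim = 250, seed = NULL) {
  if (!inherits(fit, "lm")) stop_input("`fit` must be an lm model")
  if (n_sim < 20) stop_input("`n_sim` must be at least 20")
  mu <- stats::fitted(fit)
  sigma <- summary(fit)$sigma
  y <- mu + stats::residuals(fit)
  n <- length(y)
  draw <- function() matrix(stats::rnorm(n * n_sim, mean = mu, sd = sigma),
                            nrow = n)
  sims <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  # ties are assessed with a numerical tolerance so that an (essentially)
  # perfect fit, whose residuals and simulation noise are both at rounding
  # level, degenerates cleanly to scaled residuals of 0.5
  tol <- sqrt(.Machine$double.eps) * max(1, mean(abs(mu)))
  u <- vapply(seq_len(n), function(i) {
    below <- sum(sims[i, ] < y[i] - tol)
    ties <- sum(abs(sims[i, ] - y[i]) <= tol)
    (below + 0.5 * (ties + 1)) / (n_sim + 1)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  list(statistic = unname(ks$statistic), p_value = ks$p.value, quantiles = u)
}
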