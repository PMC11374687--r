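# Seeded synthetic cohort generator. Emulates the statistical structure each
# downstream stage assumes (a hypermutated subpopulation, NuMT-like mtDNA
# artifacts vs true somatic mutations, copy-number gains/losses/LOH, a
# coherently hypoxic expression subgroup, and survival times with a planted
# threshold effect), so the whole pipeline is testable without any download.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a scaled-down population cohort: ~22% hypermutated
#' tumours at a 20-fold multiple of the baseline burden, a bounded
#' multiplicative spread of baseline mutation counts (log-scale sd
#' \code{baseline_log_sigma}, drawn log-uniform so the planted hypermutated
#' class is cleanly identifiable by a quantile rule), a 52-gene hypoxia
#' signature shifted by one standard deviation in a planted high-hypoxia
#' subgroup, and mitochondrial candidate tables mixing private true somatic
#' mutations with recurrent low-VAF control-supported artifacts at depths
#' spanning the 500-30000x regime of deep mtDNA coverage.
#'
#' @param n_samples number of tumours.
#' @param hm_fraction fraction of planted hypermutated tumours in [0, 1].
#' @param baseline_log_mu mean of baseline log mutation counts.
#' @param baseline_log_sigma sd of baseline log mutation counts.
#' @param hm_multiplier burden multiple of the hypermutated class (> 1).
#' @param n_genes genes in the expression matrix.
#' @param n_signature_genes hypoxia signature size.
#' @param hypoxia_effect standardized expression shift of signature genes in
#'   the high-hypoxia subgroup.
#' @param n_mito_sites mtDNA candidate sites.
#' @param numt_fraction fraction of mtDNA sites that are NuMT-like artifacts.
#' @param numt_recurrence fraction of the cohort carrying each artifact.
#' @param genome_size_mb genome size in megabases.
#' @param seed integer seed; identical seed and config give byte-identical
#'   cohorts.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 200, hm_fraction = 0.22,
                       baseline_log_mu = log(200), baseline_log_sigma = 0.3,
                       hm_multiplier = 20, n_genes = 200,
                       n_signature_genes = 52, hypoxia_effect = 1,
                       n_mito_sites = 40, numt_fraction = 0.3,
                       numt_recurrence = 0.15, genome_size_mb = 2859,
                       seed = 1) {
  cfg <- list(n_samples = n_samples, hm_fraction = hm_fraction,
              baseline_log_mu = baseline_log_mu,
              baseline_log_sigma = baseline_log_sigma,
              hm_multiplier = hm_multiplier, n_genes = n_genes,
              n_signature_genes = n_signature_genes,
              hypoxia_effect = hypoxia_effect, n_mito_sites = n_mito_sites,
              numt_fraction = numt_fraction,
              numt_recurrence = numt_recurrence,
              genome_size_mb = genome_size_mb, seed = seed)
  counts <- c("n_samples", "n_genes", "n_signature_genes", "n_mito_sites")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0 ||
        cfg[[nm]] != floor(cfg[[nm]])) {
      stop_input("`%s` must be a positive integer", nm)
    }
  }
  for (nm in c("hm_fraction", "numt_fraction", "numt_recurrence")) {
    check_number(cfg[[nm]], nm, lower = 0, upper = 1)
  }
  if (cfg$hm_multiplier <= 1) stop_input("`hm_multiplier` must exceed 1")
  if (cfg$baseline_log_sigma < 0) stop_input("`baseline_log_sigma` must be >= 0")
  if (cfg$genome_size_mb <= 0) stop_input("`genome_size_mb` must be positive")
  if (cfg$n_signature_genes > cfg$n_genes) {
    stop_input("`n_signature_genes` cannot exceed `n_genes`")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic cohort
#'
#' Draws a complete multi-table cohort under one seeded RNG stream with no
#' global side effects. Baseline log mutation counts are log-uniform around
#' \code{baseline_log_mu} with sd \code{baseline_log_sigma}; planted
#' hypermutated samples are shifted by \code{log(hm_multiplier)}.
#' Mitochondrial candidates mix private true somatics (control alt count
#' near zero) with recurrent NuMT-like artifacts (control-supported, tumour
#' VAF below 0.1, carried by \code{numt_recurrence} of the cohort).
#' Signature genes are shifted by \code{hypoxia_effect} (in units of the
#' residual sd) in a planted high-hypoxia subgroup. Survival times are
#' exponential with a hazard ratio of 3 above the 40th percentile of a
#' continuous marker, censored administratively at the registry data-lock
#' date. All planted labels are returned in \code{truth}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{synthetic_cohort} with elements
#'   \code{variants}, \code{segments}, \code{mito}, \code{expression}
#'   (matrix), \code{clinical}, \code{sv}, \code{truth}, \code{config}.
#' @export
generate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_local_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_samples
  ids <- sprintf("S%04d", seq_len(n))

  ## planted hypermutation labels and per-sample burdens
  n_hm <- round(cfg$hm_fraction * n)
  is_hm <- stats::setNames(rep(FALSE, n), ids)
  if (n_hm > 0) is_hm[sample.int(n, n_hm)] <- TRUE
  half_width <- sqrt(3) * cfg$baseline_log_sigma  # log-uniform, matching sd
  log_counts <- cfg$baseline_log_mu +
    stats::runif(n, -half_width, half_width) +
    ifelse(is_hm, log(cfg$hm_multiplier), 0)
  counts <- pmax(1L, round(exp(log_counts)))

  ## somatic short-variant table (MAF-like)
  total <- sum(counts)
  class_probs <- c(SNV = 0.85, DNV = 0.02, TNV = 0.005, INS = 0.06,
                   DEL = 0.065)
  chrom_len <- round(cfg$genome_size_mb * 1e6 / 22)
  region <- sample(c("coding", "noncoding"), total, replace = TRUE,
                   prob = c(0.02, 0.98))
  bases <- c("A", "C", "G", "T")
  variants <- data.frame(
    sample_id = rep(ids, counts),
    chrom = paste0("chr", sample.int(22, total, replace = TRUE)),
    pos = sample.int(chrom_len, total, replace = TRUE),
    ref = sample(bases, total, replace = TRUE),
    alt = sample(bases, total, replace = TRUE),
    variant_class = sample(names(class_probs), total, replace = TRUE,
                           prob = class_probs),
    region = region,
    nonsynonymous = region == "coding" & stats::runif(total) < 0.7,
    vaf = round(stats::runif(total, 0.05, 0.95), 4),
    clonality = sample(c("clonal", "subclonal"), total, replace = TRUE,
                       prob = c(0.7, 0.3)),
    stringsAsFactors = FALSE
  )
  # indels keep a single-base ref with a longer alt (INS) or vice versa (DEL)
  ins <- variants$variant_class == "INS"
  del <- variants$variant_class == "DEL"
  variants$alt[ins] <- paste0(variants$ref[ins], "A")
  variants$alt[del] <- substr(variants$ref[del], 1, 1)
  variants$ref[del] <- paste0(variants$alt[del], "T")

  ## allele-specific copy-number segments (fewer CNVs in HM tumours)
  seg_states <- data.frame(
    tcn = c(2L, 0L, 1L, 2L, 3L, 4L, 5L, 6L),
    lcn = c(1L, 0L, 0L, 0L, 0L, 1L, 0L, 2L)
  )
  seg_list <- lapply(seq_len(n), function(i) {
    k <- min(22L, stats::rpois(1, if (is_hm[i]) 3 else 10) + 1L)
    chroms <- sample.int(22, k)
    len <- round(stats::runif(k, 1e5, 2e7))
    start <- pmax(1L, sample.int(chrom_len, k) - len)
    st <- seg_states[sample.int(nrow(seg_states), k, replace = TRUE,
                                prob = c(0.35, 0.03, 0.12, 0.1, 0.12, 0.12,
                                         0.08, 0.08)), ]
    data.frame(
      sample_id = ids[i],
      chrom = paste0("chr", chroms),
      start = start,
      end = pmin(start + len, chrom_len),
      tcn = st$tcn,
      lcn = st$lcn,
      log2_ratio = round(log2(pmax(st$tcn, 0.5) / 2) +
                           stats::rnorm(k, 0, 0.05), 4),
      stringsAsFactors = FALSE
    )
  })
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL

  ## mitochondrial candidate table: true somatics vs NuMT-like artifacts
  n_numt <- round(cfg$numt_fraction * cfg$n_mito_sites)
  site_pos <- sample.int(16569, cfg$n_mito_sites)
  site_ref <- sample(bases, cfg$n_mito_sites, replace = TRUE)
  site_alt <- unname(vapply(site_ref, function(r) sample(setdiff(bases, r), 1), ""))
  site_class <- c(rep("numt", n_numt),
                  rep("somatic", cfg$n_mito_sites - n_numt))
  mito_list <- lapply(seq_len(cfg$n_mito_sites), function(j) {
    if (site_class[j] == "numt") {
      carriers <- sample(ids, max(2L, round(cfg$numt_recurrence * n)))
      vt <- stats::runif(length(carriers), 0.012, 0.08)
      vc <- stats::runif(length(carriers), 0.004, 0.02)
    } else {
      carriers <- sample(ids, 1)
      vt <- stats::runif(1, 0.06, 0.90)
      vc <- 0
    }
    rd_t <- round(stats::runif(length(carriers), 500, 30000))
    rd_c <- round(stats::runif(length(carriers), 500, 30000))
    n_t <- pmax(1L, round(vt * rd_t))
    n_c <- if (site_class[j] == "numt") {
      pmax(2L, ceiling(vc * rd_c))
    } else {
      stats::rbinom(length(carriers), 1, 0.2)
    }
    data.frame(
      sample_id = carriers, pos = site_pos[j], ref = site_ref[j],
      alt = site_alt[j], n_mut_tum = n_t, rd_tum = rd_t,
      n_mut_ctrl = n_c, rd_ctrl = rd_c,
      truth_class = site_class[j], stringsAsFactors = FALSE
    )
  })
  mito <- do.call(rbind, mito_list)
  rownames(mito) <- NULL
  mito$vaf_tum <- mito$n_mut_tum / mito$rd_tum
  mito$vaf_ctrl <- mito$n_mut_ctrl / mito$rd_ctrl
  truth_mito <- mito[, c("sample_id", "pos", "ref", "alt", "truth_class")]
  mito$truth_class <- NULL

  ## expression matrix with a planted high-hypoxia subgroup
  n_ctrl <- max(2L, round(n * 0.1))
  ctrl_ids <- sprintf("C%04d", seq_len(n_ctrl))
  genes <- c(sprintf("SIG%03d", seq_len(cfg$n_signature_genes)),
             sprintf("G%04d", seq_len(cfg$n_genes - cfg$n_signature_genes)))
  hypoxia_group <- stats::setNames(
    sample(c("high", "low"), n, replace = TRUE, prob = c(0.3, 0.7)), ids)
  base_mu <- stats::runif(cfg$n_genes, 2, 8)
  expr <- matrix(stats::rnorm(cfg$n_genes * (n + n_ctrl), mean = base_mu),
                 nrow = cfg$n_genes,
                 dimnames = list(genes, c(ids, ctrl_ids)))
  sig_rows <- seq_len(cfg$n_signature_genes)
  expr[sig_rows, ids[hypoxia_group == "high"]] <-
    expr[sig_rows, ids[hypoxia_group == "high"]] + cfg$hypoxia_effect
  expr[sig_rows, ctrl_ids] <- expr[sig_rows, ctrl_ids] - 0.5
  expr <- round(expr, 4)

  ## clinical table with a planted survival threshold effect
  data_lock <- as.Date("2023-06-14")
  diagnosis <- as.Date("2004-01-01") + sample.int(4500, n, replace = TRUE)
  surgery <- diagnosis + sample.int(60, n, replace = TRUE) + 6L
  marker <- stats::rnorm(n)
  cutpoint <- if (n > 1) {
    unname(stats::quantile(marker, 0.4, type = 7))
  } else {
    marker
  }
  surv_group <- ifelse(marker > cutpoint, "high_risk", "low_risk")
  rate <- 0.08 * ifelse(surv_group == "high_risk", 3, 1)
  t_death <- stats::rexp(n) / rate
  censor_years <- as.numeric(data_lock - surgery) / DAYS_PER_YEAR
  died <- t_death < censor_years
  death_date <- as.Date(ifelse(died, surgery + round(t_death * DAYS_PER_YEAR),
                               NA), origin = "1970-01-01")
  recur_frac <- stats::runif(n, 0.3, 0.9)
  has_recur <- (died & stats::runif(n) < 0.6) | (!died & stats::runif(n) < 0.1)
  recur_years <- ifelse(died, recur_frac * t_death, recur_frac * censor_years)
  recurrence_date <- as.Date(
    ifelse(has_recur, surgery + pmax(1, round(recur_years * DAYS_PER_YEAR)),
           NA), origin = "1970-01-01")
  clinical <- data.frame(
    patient_id = ids,
    age = pmin(95L, pmax(30L, round(stats::rnorm(n, 72, 10)))),
    sex = sample(c("female", "male"), n, replace = TRUE),
    purity = round(stats::runif(n, 0.2, 0.95), 3),
    site = sample(c("right_colon", "left_colon", "rectum"), n,
                  replace = TRUE, prob = c(0.47, 0.25, 0.28)),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.2, 0.3, 0.35, 0.15)),
    grade = sample(c("low", "high"), n, replace = TRUE, prob = c(0.75, 0.25)),
    pretreated = stats::runif(n) < 0.12,
    diagnosis_date = diagnosis,
    surgery_date = surgery,
    recurrence_date = recurrence_date,
    death_date = death_date,
    last_followup_date = data_lock,
    marker = round(marker, 4),
    stringsAsFactors = FALSE
  )

  ## structural variants: deletions most common; inversions and tandem
  ## duplications rarer in HM tumours
  sv_classes <- c("deletion", "inversion", "tandem_duplication",
                  "translocation")
  sv_lambda <- function(hm) if (hm) c(18, 2, 1, 6) else c(22, 8, 5, 4)
  sv_list <- lapply(seq_len(n), function(i) {
    k <- stats::rpois(4, sv_lambda(is_hm[i]))
    if (sum(k) == 0) return(NULL)
    data.frame(sample_id = ids[i], sv_class = rep(sv_classes, k),
               stringsAsFactors = FALSE)
  })
  sv <- do.call(rbind, sv_list)
  if (is.null(sv)) {
    sv <- data.frame(sample_id = character(0), sv_class = character(0))
  }
  rownames(sv) <- NULL

  structure(list(
    variants = variants, segments = segments, mito = mito,
    expression = expr, clinical = clinical, sv = sv,
    truth = list(
      is_hm = is_hm,
      n_snv = stats::setNames(as.integer(counts), ids),
      hypoxia_group = hypoxia_group,
      mito = truth_mito,
      survival_group = stats::setNames(surv_group, ids),
      survival_cutpoint = cutpoint,
      signature_genes = genes[sig_rows]
    ),
    config = cfg
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort: %d tumours (%d HM), %d variants, ",
                     "%d CN segments, %d mtDNA candidates, %d x %d expression\n"),
              x$config$n_samples, sum(x$truth$is_hm), nrow(x$variants),
              nrow(x$segments), nrow(x$mito), nrow(x$expression),
              ncol(x$expression)))
  invisible(x)
}

#' Simulate a survival cohort with a planted marker threshold effect
#'
#' Standalone generator for cutpoint-recovery studies: exponential survival
#' with hazard \code{baseline_rate} below and \code{hr * baseline_rate}
#' above the \code{marker_quantile} quantile of a standard normal marker,
#' administratively censored at \code{horizon} years.
#'
#' @param n subjects.
#' @param hr hazard ratio above the threshold (default 3).
#' @param marker_quantile quantile of the marker at which the effect is
#'   planted (default 0.4).
#' @param baseline_rate events per year below the threshold (default 0.1).
#' @param horizon administrative censoring horizon in years (default 10).
#' @param seed optional seed.
#' @return data.frame with \code{marker}, \code{time}, \code{event}, plus
#'   the planted \code{cutpoint} as an attribute.
#' @export
simulate_survival_cohort <- function(n, hr = 3, marker_quantile = 0.4,
                                     baseline_rate = 0.1, horizon = 10,
                                     seed = NULL) {
  gen <- function() {
    marker <- stats::rnorm(n)
    cut <- unname(stats::quantile(marker, marker_quantile, type = 7))
    rate <- baseline_rate * ifelse(marker > cut, hr, 1)
    t <- stats::rexp(n) / rate
    out <- data.frame(marker = marker, time = pmin(t, horizon),
                      event = as.integer(t <= horizon))
    attr(out, "cutpoint") <- cut
    out
  }
  if (is.null(seed)) gen() else with_local_seed(seed, gen())
}

#' Write a synthetic cohort to plain-text files
#'
#' Serializes the cohort tables to a directory: MAF-like variant TSV, SEG
#' TSV, mitochondrial candidate TSV plus a VCF 4.2 rendering, expression
#' TSV (genes by samples), clinical TSV, SV TSV, a signature gene list and
#' the truth labels. A manifest of files with md5 checksums and row counts
#' is returned and written as \code{manifest.tsv}; the checksum of any file
#' changes iff its table changes. Output is byte-deterministic for a given
#' cohort.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param directory output directory (created if absent).
#' @return data.frame manifest: \code{file}, \code{md5}, \code{n_rows}.
#' @export
write_cohort <- function(cohort, directory) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stop_input("`cohort` must be a synthetic_cohort")
  }
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok || file.access(directory, mode = 2) != 0) {
    stop_input("cannot write to directory `%s`", directory)
  }
  tsv <- function(df, file) {
    utils::write.table(df, file.path(directory, file), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    file
  }
  files <- c(
    tsv(cohort$variants, "variants.maf.tsv"),
    tsv(cohort$segments, "segments.seg.tsv"),
    tsv(cohort$mito, "mito_counts.tsv"),
    tsv(data.frame(gene = rownames(cohort$expression),
                   cohort$expression, check.names = FALSE),
        "expression.tsv"),
    tsv(cohort$clinical, "clinical.tsv"),
    tsv(cohort$sv, "sv.tsv"),
    tsv(cohort$truth$mito, "truth_mito.tsv"),
    tsv(data.frame(sample_id = names(cohort$truth$is_hm),
                   is_hm = unname(cohort$truth$is_hm),
                   n_snv = unname(cohort$truth$n_snv),
                   hypoxia_group = unname(cohort$truth$hypoxia_group),
                   survival_group = unname(cohort$truth$survival_group)),
        "truth_samples.tsv")
  )
  writeLines(cohort$truth$signature_genes,
             file.path(directory, "signature_genes.txt"))
  files <- c(files, "signature_genes.txt")

  ## VCF 4.2 rendering of the mitochondrial candidates
  vcf <- file.path(directory, "mito.vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrM,length=16569>",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Tumour sample\">",
    "##INFO=<ID=NMT,Number=1,Type=Integer,Description=\"Tumour alt reads\">",
    "##INFO=<ID=RDT,Number=1,Type=Integer,Description=\"Tumour mean depth\">",
    "##INFO=<ID=NMC,Number=1,Type=Integer,Description=\"Control alt reads\">",
    "##INFO=<ID=RDC,Number=1,Type=Integer,Description=\"Control mean depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (nrow(cohort$mito) > 0) {
    with(cohort$mito, sprintf(
      "chrM\t%d\t.\t%s\t%s\t.\t.\tSAMPLE=%s;NMT=%d;RDT=%d;NMC=%d;RDC=%d",
      pos, ref, alt, sample_id, n_mut_tum, rd_tum, n_mut_ctrl, rd_ctrl))
  } else {
    character(0)
  }
  writeLines(c(header, body), vcf)
  files <- c(files, "mito.vcf")

  n_rows <- c(nrow(cohort$variants), nrow(cohort$segments),
              nrow(cohort$mito), nrow(cohort$expression),
              nrow(cohort$clinical), nrow(cohort$sv),
              nrow(cohort$truth$mito), length(cohort$truth$is_hm),
              length(cohort$truth$signature_genes), nrow(cohort$mito))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(directory, files))),
    n_rows = n_rows,
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(directory, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

#' Read a cohort directory written by \code{write_cohort}
#'
#' @param directory directory containing the TSV files.
#' @return list with the cohort tables (\code{variants}, \code{segments},
#'   \code{mito}, \code{expression} matrix, \code{clinical}, \code{sv}).
#' @export
read_cohort <- function(directory) {
  rd <- function(file, ...) {
    utils::read.delim(file.path(directory, file), stringsAsFactors = FALSE,
                      ...)
  }
  expr_df <- rd("expression.tsv", check.names = FALSE)
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expr) <- expr_df$gene
  clin <- rd("clinical.tsv", na.strings = "")
  for (col in grep("_date$", names(clin), value = TRUE)) {
    clin[[col]] <- as.Date(clin[[col]])
  }
  list(
    variants = rd("variants.maf.tsv"),
    segments = rd("segments.seg.tsv"),
    mito = rd("mito_counts.tsv"),
    expression = expr,
    clinical = clin,
    sv = rd("sv.tsv")
  )
}
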