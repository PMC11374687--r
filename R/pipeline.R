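# End-to-end orchestration: simulate (optional) -> landscape -> copy number
# -> mito -> hypoxia -> signatures -> prognostics, with a reproducible run
# manifest. Every procedure-derived constant is surfaced as a named
# configuration key, never hard-coded at a call site.

#' Default pipeline configuration
#'
#' Returns the full default configuration tree. User configurations (lists
#' or YAML files) are merged over these defaults; unknown keys are rejected.
#'
#' @return nested named list.
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1,
    simulate = list(enabled = TRUE, n_samples = 200, hm_fraction = 0.22,
                    baseline_log_mu = log(200), baseline_log_sigma = 0.3,
                    hm_multiplier = 20, n_genes = 200,
                    n_signature_genes = 52, hypoxia_effect = 1,
                    n_mito_sites = 40, numt_fraction = 0.3,
                    numt_recurrence = 0.15, genome_size_mb = 2859),
    inputs = list(variants = NULL, segments = NULL, mito = NULL,
                  expression = NULL, clinical = NULL, sv = NULL,
                  signature_genes = NULL),
    landscape = list(iqr_factor = 1.5, genome_size_mb = 2859,
                     msi_threshold = 3.5, comutation_fdr = 0.1),
    copy_number = list(amp_threshold = 0.9, del_threshold = -0.3),
    mito = list(ctrl_vaf_cutoff = 0.0034, ratio_cutoff = 0.0629,
                recurrence_cutoff = 0.023, het_window = c(0.01, 0.95),
                near_homoplasmy_vaf = 0.6),
    hypoxia = list(adjusted_p_threshold = 0.1, bonferroni_below_n_tests = 20),
    signatures = list(novelty_threshold = 0.85, correlation_fdr = 0.05),
    prognostics = list(min_group_fraction = 0.1, univariable_p = 0.05,
                       min_carriers = 5)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop_input("unknown configuration key(s): %s",
               paste0(path, unknown, collapse = ", "))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Validate pipeline input files
#'
#' Schema and sanity checks per table format: required columns, coordinate
#' ordering, copy-number consistency, VAF ranges. Failures are reported per
#' file with offending row numbers; the function itself never errors on bad
#' content.
#'
#' @param paths named list of file paths; recognized names are
#'   \code{variants}, \code{segments}, \code{mito}, \code{expression},
#'   \code{clinical}.
#' @return data.frame with \code{input}, \code{file}, \code{pass},
#'   \code{issues}.
#' @export
validate_inputs <- function(paths) {
  checks <- list(
    variants = function(df) {
      issues <- character(0)
      need <- c("sample_id", "chrom", "pos", "ref", "alt", "variant_class",
                "region", "nonsynonymous", "vaf")
      miss <- setdiff(need, names(df))
      if (length(miss) > 0) {
        return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
      }
      bad <- which(df$vaf < 0 | df$vaf > 1)
      if (length(bad) > 0) {
        issues <- c(issues, sprintf("VAF outside [0,1] at row(s): %s",
                                    paste(utils::head(bad, 5), collapse = ", ")))
      }
      bad <- which(!df$variant_class %in% c("SNV", "DNV", "TNV", "INS", "DEL"))
      if (length(bad) > 0) {
        issues <- c(issues, sprintf("unknown variant_class at row(s): %s",
                                    paste(utils::head(bad, 5), collapse = ", ")))
      }
      issues
    },
    segments = function(df) {
      issues <- character(0)
      need <- c("sample_id", "chrom", "start", "end", "tcn")
      miss <- setdiff(need, names(df))
      if (length(miss) > 0) {
        return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
      }
      bad <- which(df$end < df$start)
      if (length(bad) > 0) {
        issues <- c(issues, sprintf("end < start at row(s): %s",
                                    paste(utils::head(bad, 5), collapse = ", ")))
      }
      bad <- which(df$end == df$start - 1)
      if (length(bad) > 0) {
        issues <- c(issues, sprintf("zero-length segment at row(s): %s",
                                    paste(utils::head(bad, 5), collapse = ", ")))
      }
      bad <- which(df$tcn < 0)
      if (length(bad) > 0) {
        issues <- c(issues, sprintf("negative tcn at row(s): %s",
                                    paste(utils::head(bad, 5), collapse = ", ")))
      }
      if ("lcn" %in% names(df)) {
        bad <- which(!is.na(df$lcn) & df$lcn > df$tcn)
        if (length(bad) > 0) {
          issues <- c(issues, sprintf("lcn > tcn at row(s): %s",
                                      paste(utils::head(bad, 5), collapse = ", ")))
        }
      }
      issues
    },
    mito = function(df) {
      issues <- character(0)
      need <- c("sample_id", "pos", "ref", "alt", "n_mut_tum", "rd_tum",
                "n_mut_ctrl", "rd_ctrl")
      miss <- setdiff(need, names(df))
      if (length(miss) > 0) {
        return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
      }
      bad <- which(df$n_mut_tum > df$rd_tum | df$n_mut_ctrl > df$rd_ctrl)
      if (length(bad) > 0) {
        issues <- c(issues, sprintf("alt count exceeds depth at row(s): %s",
                                    paste(utils::head(bad, 5), collapse = ", ")))
      }
      bad <- which(df$pos < 1 | df$pos > 16569)
      if (length(bad) > 0) {
        issues <- c(issues, sprintf("position outside mtDNA at row(s): %s",
                                    paste(utils::head(bad, 5), collapse = ", ")))
      }
      issues
    },
    expression = function(df) {
      if (ncol(df) < 2) return("expression table needs gene + sample columns")
      if (anyNA(df[, -1])) return("missing expression values")
      character(0)
    },
    clinical = function(df) {
      need <- c("patient_id", "diagnosis_date", "surgery_date",
                "recurrence_date", "death_date", "last_followup_date",
                "stage")
      miss <- setdiff(need, names(df))
      if (length(miss) > 0) {
        return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
      }
      character(0)
    }
  )
  rows <- lapply(names(paths), function(nm) {
    path <- paths[[nm]]
    if (is.null(path)) return(NULL)
    if (!file.exists(path)) {
      return(data.frame(input = nm, file = path, pass = FALSE,
                        issues = "file not found", stringsAsFactors = FALSE))
    }
    df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
    issues <- if (nm %in% names(checks)) checks[[nm]](df) else character(0)
    data.frame(input = nm, file = path, pass = length(issues) == 0,
               issues = paste(issues, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(input = character(0), file = character(0),
                      pass = logical(0), issues = character(0))
  }
  out
}

#' Run the full cohort analysis pipeline
#'
#' Executes simulate (optional) -> landscape -> copy_number -> mito ->
#' hypoxia -> signatures -> prognostics on synthetic or user-supplied
#' tables, writing every stage result as TSV into \code{out_dir} along with
#' a JSON run manifest (seed, configuration hash, per-stage row counts and
#' file checksums). Runs are byte-deterministic for a fixed configuration
#' and seed.
#'
#' @param config nested list overriding \code{\link{pipeline_defaults}}, or
#'   the path of a YAML file with the same structure.
#' @param out_dir output directory.
#' @param seed overrides \code{config$seed} when given.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(pipeline_defaults(), config)
  if (!is.null(seed)) cfg$seed <- seed
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop_input("cannot create output directory `%s`", out_dir)

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))

  stages <- list()
  outputs <- character(0)
  tsv <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    outputs <<- c(outputs, file)
    file
  }
  log_stage <- function(name, n_rows) {
    message(sprintf("[%s] %d rows", name, n_rows))
    stages[[length(stages) + 1]] <<- list(stage = name, n_rows = n_rows)
  }

  ## stage 1: inputs (simulated or read from disk)
  sig_genes <- NULL
  if (isTRUE(cfg$simulate$enabled)) {
    sim <- cfg$simulate
    sim$enabled <- NULL
    cohort <- generate_cohort(do.call(sim_config, c(sim, list(seed = cfg$seed))))
    tables <- cohort[c("variants", "segments", "mito", "expression",
                       "clinical", "sv")]
    sig_genes <- cohort$truth$signature_genes
    sim_dir <- file.path(out_dir, "simulated")
    write_cohort(cohort, sim_dir)
    log_stage("simulate", cfg$simulate$n_samples)
  } else {
    needed <- c("variants", "segments", "mito", "expression", "clinical")
    for (nm in needed) {
      if (is.null(cfg$inputs[[nm]])) {
        stop_input("stage inputs: no `%s` file configured and simulation disabled", nm)
      }
      if (!file.exists(cfg$inputs[[nm]])) {
        stop_input("stage inputs: file `%s` (%s) not found",
                   cfg$inputs[[nm]], nm)
      }
    }
    report <- validate_inputs(cfg$inputs[!vapply(cfg$inputs, is.null, TRUE)])
    if (any(!report$pass)) {
      bad <- report[!report$pass, ]
      stop_input("stage inputs: validation failed for %s (%s)",
                 paste(bad$input, collapse = ", "),
                 paste(bad$issues, collapse = " | "))
    }
    tables <- list(
      variants = utils::read.delim(cfg$inputs$variants, stringsAsFactors = FALSE),
      segments = utils::read.delim(cfg$inputs$segments, stringsAsFactors = FALSE),
      mito = utils::read.delim(cfg$inputs$mito, stringsAsFactors = FALSE),
      clinical = utils::read.delim(cfg$inputs$clinical, na.strings = "",
                                   stringsAsFactors = FALSE)
    )
    for (col in grep("_date$", names(tables$clinical), value = TRUE)) {
      tables$clinical[[col]] <- as.Date(tables$clinical[[col]])
    }
    expr_df <- utils::read.delim(cfg$inputs$expression, check.names = FALSE,
                                 stringsAsFactors = FALSE)
    tables$expression <- as.matrix(expr_df[, -1, drop = FALSE])
    rownames(tables$expression) <- expr_df[[1]]
    tables$sv <- if (!is.null(cfg$inputs$sv)) {
      utils::read.delim(cfg$inputs$sv, stringsAsFactors = FALSE)
    } else {
      NULL
    }
    if (!is.null(cfg$inputs$signature_genes)) {
      sig_genes <- readLines(cfg$inputs$signature_genes)
    }
    log_stage("inputs", nrow(tables$variants))
  }

  ## stage 2: landscape
  counts_tab <- table(tables$variants$sample_id)
  counts <- stats::setNames(as.numeric(counts_tab), names(counts_tab))
  hm <- classify_hypermutation(counts, iqr_factor = cfg$landscape$iqr_factor)
  tmb <- compute_tmb(counts, genome_size_mb = cfg$landscape$genome_size_mb,
                     hm = hm)
  burden <- merge(hm$samples, tmb$burden[, c("sample_id", "tmb")],
                  by = "sample_id")
  tsv(burden, "burden.tsv")
  log_stage("landscape", nrow(burden))

  ## stage 3: copy number
  seg <- tables$segments
  if (!"lcn" %in% names(seg)) seg$lcn <- NA_integer_
  seg_states <- classify_state(seg$tcn, seg$lcn)
  seg$state <- as.character(seg_states$state)
  if ("log2_ratio" %in% names(seg)) {
    seg$focal <- classify_focal(seg$log2_ratio,
                                amp_threshold = cfg$copy_number$amp_threshold,
                                del_threshold = cfg$copy_number$del_threshold)
  }
  tsv(seg, "segments_annotated.tsv")
  dens <- cnv_density(tables$segments,
                      genome_size_bp = cfg$landscape$genome_size_mb * 1e6)
  tsv(dens, "cnv_density.tsv")
  log_stage("copy_number", nrow(seg))

  ## stage 4: mitochondrial filter
  mito_report <- filter_candidates(
    tables$mito,
    ctrl_vaf_cutoff = cfg$mito$ctrl_vaf_cutoff,
    ratio_cutoff = cfg$mito$ratio_cutoff,
    recurrence_cutoff = cfg$mito$recurrence_cutoff,
    het_window = cfg$mito$het_window
  )
  mito_report$heteroplasmy <- heteroplasmy_class(mito_report$vaf_tum)
  tsv(mito_report, "mito_filter.tsv")
  log_stage("mito", nrow(mito_report))

  ## stage 5: hypoxia
  if (is.null(sig_genes)) {
    stop_input("stage hypoxia: no signature gene list available")
  }
  tumour_ids <- intersect(colnames(tables$expression),
                          tables$clinical$patient_id)
  scores <- buffa_score(tables$expression, sig_genes, tumour_ids)
  tsv(scores, "hypoxia_scores.tsv")
  fm <- feature_matrix(variants = tables$variants, segments = tables$segments,
                       svs = tables$sv, clinical = tables$clinical,
                       genome_size_bp = cfg$landscape$genome_size_mb * 1e6)
  tsv(fm, "feature_matrix.tsv")
  test_features <- c("n_all", "n_snv", "n_indel", "pga_total", "pga_gain",
                     "pga_loss", "sv_deletion", "sv_inversion",
                     "sv_tandem_duplication", "sv_translocation")
  test_features <- test_features[vapply(test_features, function(f) {
    f %in% names(fm) && !all(is.na(fm[[f]])) &&
      length(unique(fm[[f]][!is.na(fm[[f]])])) > 1
  }, logical(1))]
  sc <- scores$score[match(fm$sample_id, scores$sample_id)]
  covars <- fm[, intersect(c("age", "sex", "purity"), names(fm)), drop = FALSE]
  assoc <- do.call(rbind, lapply(test_features, function(f) {
    associate(sc, fm[[f]], covars, feature_name = f)
  }))
  adj <- adjust_pvalues(assoc$p_value, n_tests = nrow(assoc))
  assoc$p_adjusted <- adj$p_adjusted
  assoc$adjust_method <- adj$method
  assoc$significant <- assoc$p_adjusted < cfg$hypoxia$adjusted_p_threshold
  tsv(assoc, "hypoxia_associations.tsv")
  log_stage("hypoxia", nrow(assoc))

  ## stage 6: signatures (variant-class activities as per-sample exposures)
  act <- as.matrix(table(tables$variants$sample_id,
                         tables$variants$variant_class))
  act_cor <- activity_correlation(act,
                                  fdr_threshold = cfg$signatures$correlation_fdr)
  tsv(act_cor, "activity_correlations.tsv")
  log_stage("signatures", nrow(act_cor))

  ## stage 7: prognostics
  endpoints <- derive_endpoints(tables$clinical)
  tsv(endpoints, "endpoints.tsv")
  os <- endpoints[endpoints$endpoint == "OS" & endpoints$eligible, ]
  cut_res <- NULL
  if ("marker" %in% names(tables$clinical) && nrow(os) >= 20 &&
      sum(os$event) > 0) {
    marker <- tables$clinical$marker[match(os$patient_id,
                                           tables$clinical$patient_id)]
    cut_res <- maxstat_cutpoint(marker, os$time, os$event,
                                min_group_fraction = cfg$prognostics$min_group_fraction)
    tsv(data.frame(variable = "marker", cutpoint = cut_res$cutpoint,
                   statistic = cut_res$statistic, n_low = cut_res$n_low,
                   n_high = cut_res$n_high),
        "maxstat_cutpoint.tsv")
  }
  feats <- data.frame(patient_id = hm$samples$sample_id,
                      hypermutated = as.integer(hm$samples$is_hm))
  covs <- tables$clinical[, intersect(c("patient_id", "site", "stage",
                                        "grade", "pretreated"),
                                      names(tables$clinical)), drop = FALSE]
  cox <- cox_workflow(os, feats, covs,
                      p_screen = cfg$prognostics$univariable_p,
                      min_carriers = cfg$prognostics$min_carriers)
  tsv(cox, "cox_results.tsv")
  log_stage("prognostics", nrow(endpoints))

  manifest <- list(
    package = "crcmetrics",
    version = as.character(utils::packageVersion("crcmetrics")),
    seed = cfg$seed,
    config_hash = config_hash,
    stages = stages,
    files = lapply(outputs, function(f) {
      list(file = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
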