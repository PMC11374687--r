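small_cfg <- function(seed = 1, ...) {
  sim_config(n_samples = 30, n_genes = 40, n_signature_genes = 10,
             n_mito_sites = 15, seed = seed, ...)
}

test_that("identical config and seed give identical cohorts", {
  a <- generate_cohort(small_cfg(seed = 4))
  b <- generate_cohort(small_cfg(seed = 4))
  expect_identical(a, b)
  c <- generate_cohort(small_cfg(seed = 5))
  expect_false(identical(a$variants, c$variants))
})

test_that("the generator leaves the global RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_cohort(small_cfg(seed = 9)))
  expect_identical(.Random.seed, before)
})

test_that("degenerate fractions behave as configured", {
  none <- generate_cohort(small_cfg(seed = 2, hm_fraction = 0))
  expect_false(any(none$truth$is_hm))
  all_hm <- generate_cohort(small_cfg(seed = 2, hm_fraction = 1))
  expect_true(all(all_hm$truth$is_hm))
})

test_that("config validation rejects non-positive counts and bad fractions", {
  expect_error(sim_config(n_samples = 0), "positive integer")
  expect_error(sim_config(n_samples = -5), "positive integer")
  expect_error(sim_config(hm_fraction = 1.2), "\\[0")
  expect_error(sim_config(hm_multiplier = 1), "exceed 1")
  expect_error(sim_config(n_signature_genes = 99, n_genes = 50), "exceed")
})

test_that("generated tables satisfy the plausibility invariants", {
  ch <- generate_cohort(small_cfg(seed = 6))
  ids <- names(ch$truth$is_hm)

  expect_true(all(ch$variants$vaf >= 0 & ch$variants$vaf <= 1))
  expect_true(all(ch$segments$tcn >= 0))
  expect_true(all(ch$segments$lcn >= 0 & ch$segments$lcn <= ch$segments$tcn))
  expect_true(all(ch$segments$end >= ch$segments$start))
  expect_true(all(ch$mito$n_mut_tum <= ch$mito$rd_tum))
  expect_true(all(ch$mito$vaf_tum >= 0 & ch$mito$vaf_tum <= 1))

  cl <- ch$clinical
  expect_true(all(cl$diagnosis_date <= cl$surgery_date))
  ok_rec <- is.na(cl$recurrence_date) | cl$recurrence_date >= cl$surgery_date
  expect_true(all(ok_rec))
  end_date <- pmin(cl$death_date, cl$last_followup_date, na.rm = TRUE)
  expect_true(all(cl$surgery_date <= end_date))

  # every sample id appears in every per-sample table and in the truth
  expect_setequal(unique(ch$variants$sample_id), ids)
  expect_setequal(cl$patient_id, ids)
  expect_true(all(ch$mito$sample_id %in% ids))
  expect_true(all(ids %in% colnames(ch$expression)))
  expect_setequal(names(ch$truth$hypoxia_group), ids)
  expect_setequal(names(ch$truth$survival_group), ids)
})

test_that("planted HM burdens exceed the quantile threshold in every seed", {
  for (seed in 1:20) {
    ch <- generate_cohort(sim_config(n_samples = 200, hm_fraction = 0.1,
                                     hm_multiplier = 20, seed = seed))
    counts <- ch$truth$n_snv
    q <- quantile(counts, c(0.25, 0.5, 0.75), type = 7)
    thr <- q[2] + 1.5 * (q[3] - q[1])
    expect_true(all(counts[ch$truth$is_hm] > thr))
  }
})

test_that("write/read round-trips the cohort tables exactly", {
  ch <- generate_cohort(small_cfg(seed = 8))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(ch, dir)
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))

  back <- read_cohort(dir)
  expect_equal(back$variants, ch$variants)
  expect_equal(back$segments, ch$segments)
  expect_equal(back$mito, ch$mito, tolerance = 1e-12)
  expect_equal(back$expression, ch$expression)
  expect_equal(back$sv, ch$sv)
  expect_equal(back$clinical$stage, ch$clinical$stage)
  expect_equal(back$clinical$death_date, ch$clinical$death_date)

  # the VCF rendering is well-formed
  vcf <- readLines(file.path(dir, "mito.vcf"))
  expect_equal(vcf[1], "##fileformat=VCFv4.2")
  expect_equal(sum(!startsWith(vcf, "#")), nrow(ch$mito))
})

test_that("manifest checksums change iff a table changes", {
  ch <- generate_cohort(small_cfg(seed = 10))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_cohort(ch, d1)
  m2 <- write_cohort(ch, d2)
  expect_equal(m1$md5, m2$md5)

  ch$segments$tcn[1] <- ch$segments$tcn[1] + 1
  d3 <- withr::local_tempdir()
  m3 <- write_cohort(ch, d3)
  changed <- m1$md5 != m3$md5
  expect_identical(m1$file[changed], "segments.seg.tsv")
})

test_that("a zero-sample cohort writes headers-only files with a valid manifest", {
  ch <- generate_cohort(small_cfg(seed = 3))
  empty <- ch
  for (nm in c("variants", "segments", "mito", "clinical", "sv")) {
    empty[[nm]] <- ch[[nm]][0, , drop = FALSE]
  }
  empty$truth$mito <- ch$truth$mito[0, , drop = FALSE]
  dir <- withr::local_tempdir()
  manifest <- write_cohort(empty, dir)
  expect_equal(manifest$n_rows[manifest$file == "variants.maf.tsv"], 0)
  lines <- readLines(file.path(dir, "variants.maf.tsv"))
  expect_equal(length(lines), 1)  # header only
})

test_that("survival simulation plants the advertised threshold effect", {
  d <- simulate_survival_cohort(2000, hr = 3, seed = 1)
  cut <- attr(d, "cutpoint")
  high <- d$marker > cut
  rate_high <- sum(d$event[high]) / sum(d$time[high])
  rate_low <- sum(d$event[!high]) / sum(d$time[!high])
  expect_equal(rate_high / rate_low, 3, tolerance = 0.25)
  expect_equal(mean(high), 0.6, tolerance = 0.01)
})
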