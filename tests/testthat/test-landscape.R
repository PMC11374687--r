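test_that("iterative HM classification resolves the hand-derived cohorts", {
  # one extreme sample: flagged once, its halves pass the round-2 threshold
  res <- classify_hypermutation(c(s1 = 100, s2 = 110, s3 = 120, s4 = 130,
                                  s5 = 5000))
  expect_equal(res$samples$is_hm, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(res$samples$outlier_times, c(0, 0, 0, 0, 1))
  expect_equal(res$rounds_total, 2)
  expect_equal(res$threshold_trace, c(150, 2817.5))

  # extreme sample re-flagged as a descendant once: halves at 5000 are
  # flagged in round 2, quarters at 2500 pass in round 3
  res2 <- classify_hypermutation(c(setNames(rep(10, 7), paste0("s", 1:7)),
                                   s8 = 10000))
  expect_equal(res2$samples$is_hm[8], TRUE)
  expect_equal(res2$samples$outlier_times[8], 2)
  expect_equal(sum(res2$samples$is_hm), 1)
  expect_equal(res2$rounds_total, 3)
})

test_that("equal counts give a zero IQR and no HM call (strict >)", {
  res <- classify_hypermutation(setNames(rep(50, 6), paste0("s", 1:6)))
  expect_false(any(res$samples$is_hm))
  expect_equal(res$rounds_total, 1)
})

test_that("HM classification validates its inputs", {
  expect_error(classify_hypermutation(c(a = 1, b = 2)), "at least 3")
  expect_error(classify_hypermutation(c(a = 1, b = 2, c = -1)),
               "non-negative")
})

test_that("HM procedure terminates within the halving bound and is
           invariant to sample order", {
  set.seed(42)
  for (rep in 1:10) {
    counts <- setNames(round(exp(rnorm(30, log(300), 1.5))) + 1,
                       paste0("s", 1:30))
    res <- classify_hypermutation(counts)
    expect_lte(res$rounds_total, ceiling(log2(max(counts))) + 1)
    perm <- sample(length(counts))
    res_p <- classify_hypermutation(counts[perm])
    ord <- match(res$samples$sample_id, res_p$samples$sample_id)
    expect_equal(res$samples$is_hm, res_p$samples$is_hm[ord])
    expect_equal(res$samples$outlier_times, res_p$samples$outlier_times[ord])
  }
})

test_that("adding mutations to a sample never turns HM into nHM", {
  set.seed(7)
  for (rep in 1:10) {
    counts <- setNames(round(exp(rnorm(20, log(200), 1))) + 1,
                       paste0("s", 1:20))
    res <- classify_hypermutation(counts)
    target <- sample(names(counts), 1)
    bumped <- counts
    bumped[target] <- bumped[target] + sample(1:5000, 1)
    res_b <- classify_hypermutation(bumped)
    if (res$samples$is_hm[res$samples$sample_id == target]) {
      expect_true(res_b$samples$is_hm[res_b$samples$sample_id == target])
    }
  }
})

test_that("TMB is count over genome megabases with an HM-derived cutoff", {
  tmb <- compute_tmb(c(a = 2316), genome_size_mb = 100)
  expect_equal(tmb$burden$tmb, 23.16)
  expect_null(tmb$hm_tmb_cutoff)

  counts <- c(s1 = 100, s2 = 120, s3 = 110, s4 = 5000)
  hm <- c(s1 = FALSE, s2 = FALSE, s3 = FALSE, s4 = TRUE)
  tmb2 <- compute_tmb(counts, genome_size_mb = 50, hm = hm)
  expect_equal(tmb2$hm_tmb_cutoff, 100)
  tmb3 <- compute_tmb(counts, genome_size_mb = 50,
                      hm = setNames(rep(FALSE, 4), names(counts)))
  expect_null(tmb3$hm_tmb_cutoff)
  expect_error(compute_tmb(c(a = 1), genome_size_mb = 0), "positive")
})

test_that("MSI calls are boundary-inclusive at the score threshold", {
  expect_equal(classify_msi(3.5), "MSI")
  expect_equal(classify_msi(0), "MSS")
  expect_equal(classify_msi(3.4999), "MSS")
  expect_equal(classify_msi(c(10, 1)), c("MSI", "MSS"))
  expect_error(classify_msi(-1), "\\[0")
})

test_that("pairwise Fisher matches the hypergeometric enumeration oracle", {
  # worked 2x2: cross-product odds ratio 72
  a <- rep(c(1, 1, 0, 0), c(30, 5, 5, 60))
  b <- rep(c(1, 0, 1, 0), c(30, 5, 5, 60))
  res <- pairwise_comutation(rbind(A = a, B = b))
  expect_equal(res$odds_ratio, 72)
  expect_equal(res$p_value, oracle_fisher_p(30, 5, 5, 60), tolerance = 1e-12)
  expect_equal(res$direction, "co-occurring")

  # random tables with margins <= 30 agree with full enumeration
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(8:30, 1)
    a <- rbinom(n, 1, runif(1, 0.2, 0.8))
    b <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    res <- pairwise_comutation(rbind(A = a, B = b))
    expect_equal(res$p_value,
                 oracle_fisher_p(res$both, res$a_only, res$b_only,
                                 res$neither),
                 tolerance = 1e-12)
  }
})

test_that("independence and exclusivity patterns are labelled correctly", {
  # checkerboard: a and b independent with OR = 1
  a <- rep(c(1, 1, 0, 0), 10)
  b <- rep(c(1, 0, 1, 0), 10)
  res <- pairwise_comutation(rbind(A = a, B = b))
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_value, 1)

  # perfectly exclusive pair
  a <- rep(c(1, 0, 0), c(20, 20, 60))
  b <- rep(c(0, 1, 0), c(20, 20, 60))
  res <- pairwise_comutation(rbind(A = a, B = b))
  expect_equal(res$odds_ratio, 0)
  expect_equal(res$direction, "exclusive")
})

test_that("constant genes are skipped with a warning, not an error", {
  m <- rbind(A = c(1, 0, 1, 0), B = c(1, 1, 1, 1), C = c(0, 1, 1, 0))
  expect_warning(res <- pairwise_comutation(m), "constant")
  expect_equal(nrow(res), 1)
  expect_setequal(c(res$gene_a, res$gene_b), c("A", "C"))
})
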