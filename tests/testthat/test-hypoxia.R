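random_expression <- function(n_genes, n_samples, prefix = "s") {
  matrix(rnorm(n_genes * n_samples, mean = 5),
         nrow = n_genes,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         paste0(prefix, seq_len(n_samples))))
}

test_that("Buffa score equals the brute-force sign-sum oracle", {
  set.seed(21)
  for (rep in 1:20) {
    m <- random_expression(10, 12)
    tum <- sample(colnames(m), 8)
    sig <- sample(rownames(m), 6)
    expect_equal(buffa_score(m, sig, tum), oracle_buffa(m, sig, tum))
  }
})

test_that("Buffa score is a rank statistic: monotone transforms preserve it", {
  set.seed(22)
  m <- random_expression(8, 10)
  sig <- rownames(m)
  tum <- colnames(m)[1:8]
  base <- buffa_score(m, sig, tum)
  expect_equal(buffa_score(exp(m), sig, tum), base)       # strictly monotone
  expect_equal(buffa_score(m * 3 - 1, sig, tum), base)    # affine
})

test_that("Buffa extremes and ties behave as pinned", {
  # 4 tumours, 1 gene, abundances 2,4,6,8: median 5 splits the cohort
  m <- matrix(c(2, 4, 6, 8), nrow = 1,
              dimnames = list("g1", paste0("t", 1:4)))
  expect_equal(buffa_score(m, "g1", colnames(m))$score, c(-1, -1, 1, 1))

  # sample above the tumour median on all G genes scores +G
  m2 <- random_expression(10, 6)
  m2[, "s6"] <- apply(m2[, 1:5], 1, max) + 1
  expect_equal(buffa_score(m2, rownames(m2), paste0("s", 1:5))$score[6], 10)

  # exact ties at the median score -1 (strictly-above rule)
  m3 <- matrix(5, nrow = 2, ncol = 4,
               dimnames = list(c("g1", "g2"), paste0("t", 1:4)))
  expect_equal(buffa_score(m3, c("g1", "g2"), colnames(m3))$score,
               rep(-2L, 4))
})

test_that("Buffa scoring reports missing signature genes by name", {
  m <- random_expression(4, 5)
  expect_error(buffa_score(m, c("g01", "nope"), colnames(m)), "nope")
})

test_that("the feature matrix counts variants per class and region", {
  variants <- data.frame(
    sample_id = "s1",
    variant_class = c("SNV", "SNV", "SNV", "SNV", "SNV", "INS"),
    region = c("coding", "coding", "coding", "noncoding", "noncoding",
               "noncoding"),
    nonsynonymous = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  fm <- feature_matrix(variants = variants, deciles = FALSE)
  expect_equal(fm$n_all, 6)
  expect_equal(fm$n_coding, 3)
  expect_equal(fm$n_nonsynonymous, 2)
  expect_equal(fm$n_ins, 1)
  expect_equal(fm$n_indel, 1)
  # variants supplied but no SV table: SV metrics are missing, not zero
  expect_true(is.na(fm$sv_deletion))
})

test_that("SV-free samples count zero SVs once an SV table exists", {
  variants <- data.frame(sample_id = c("s1", "s2"), variant_class = "SNV",
                         region = "coding", nonsynonymous = TRUE)
  svs <- data.frame(sample_id = "s1", sv_class = "deletion")
  fm <- feature_matrix(variants = variants, svs = svs, deciles = FALSE)
  expect_equal(fm$sv_deletion[fm$sample_id == "s2"], 0)
  expect_equal(fm$sv_inversion, c(0, 0))
})

test_that("constant metrics are flagged as decile-degenerate", {
  variants <- data.frame(sample_id = paste0("s", 1:12),
                         variant_class = "SNV", region = "coding",
                         nonsynonymous = FALSE)
  fm <- feature_matrix(variants = variants)
  expect_true("n_all" %in% attr(fm, "degenerate_metrics"))
  expect_true(all(is.na(fm$n_all_decile)))
  expect_false(all(is.na(fm$n_nonsynonymous)))
})

test_that("a perfect predictor is detected with positive direction", {
  set.seed(23)
  f <- rnorm(50)
  cov <- data.frame(age = rnorm(50, 70, 8), sex = rbinom(50, 1, 0.5),
                    purity = runif(50))
  res <- associate(f, f, cov)
  expect_lt(res$p_value, 1e-20)
  expect_equal(res$direction, 1)
})

test_that("associations are invariant to affine rescaling of the feature", {
  set.seed(24)
  s <- rnorm(80); f <- rnorm(80)
  cov <- data.frame(age = rnorm(80), sex = rbinom(80, 1, 0.5),
                    purity = runif(80))
  p1 <- associate(s, f, cov)$p_value
  p2 <- associate(s, 1000 * f - 3, cov)$p_value
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("degenerate association inputs raise errors", {
  s <- rnorm(30)
  expect_error(associate(s, rep(1, 30), NULL), "constant")
  expect_error(associate(rnorm(5), rnorm(5), NULL), "complete cases")
})

test_that("p adjustment switches from Bonferroni to BH at 20 tests", {
  expect_equal(adjust_pvalues(0.01, n_tests = 5)$p_adjusted, 0.05)
  expect_equal(adjust_pvalues(0.01, n_tests = 5)$method, "bonferroni")
  expect_equal(adjust_pvalues(rep(0.03, 25))$method, "BH")
  expect_equal(adjust_pvalues(rep(0.03, 25))$p_adjusted, rep(0.03, 25))
  expect_equal(adjust_pvalues(runif(19))$method, "bonferroni")
  expect_equal(adjust_pvalues(runif(20))$method, "BH")

  p <- c(0.01, 0.02, 0.03, 0.04)
  got <- adjust_pvalues(p, n_tests = 30)$p_adjusted
  # direct step-up computation over 30 tests
  oracle <- rev(cummin(rev(p * 30 / seq_along(p))))
  expect_equal(got, pmin(1, oracle))
})

test_that("simulation-based residual check rejects a degenerate fit and a
           misspecified variance model", {
  # all residuals identical (an exact fit): scaled residuals pile at 0.5
  y <- rep(5, 40)
  fit0 <- lm(y ~ 1)
  r0 <- suppressWarnings(residual_uniformity(fit0, n_sim = 200, seed = 1))
  expect_true(all(abs(r0$quantiles - 0.5) < 0.05))
  expect_lt(r0$p_value, 1e-6)

  # grossly heteroscedastic truth fit homoscedastically: mostly rejected
  set.seed(25)
  rejected <- 0
  for (i in 1:20) {
    x <- runif(150)
    y <- x + rnorm(150, sd = 0.05 + 3 * x^3)
    fit <- lm(y ~ x)
    if (residual_uniformity(fit, n_sim = 120, seed = i)$p_value < 0.05) {
      rejected <- rejected + 1
    }
  }
  expect_gt(rejected, 10)
  expect_error(residual_uniformity(fit0, n_sim = 10), "at least 20")
})
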