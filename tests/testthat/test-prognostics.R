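clinical_fixture <- function() {
  data.frame(
    patient_id = c("P1", "P2", "P3", "P4"),
    diagnosis_date = as.Date(c("2010-01-01", "2012-03-01", "2011-06-01",
                               "2013-01-01")),
    surgery_date = as.Date(c("2010-02-01", "2012-03-20", "2011-06-15",
                             "2013-02-01")),
    recurrence_date = as.Date(c(NA, "2014-03-20", NA, NA)),
    death_date = as.Date(c("2015-01-01", "2016-03-20", NA, NA)),
    last_followup_date = as.Date("2020-06-01"),
    stage = c("II", "III", "I", "IV"),
    stringsAsFactors = FALSE
  )
}

test_that("survival endpoints follow the registry definitions", {
  ep <- derive_endpoints(clinical_fixture())
  get <- function(p, e) ep[ep$patient_id == p & ep$endpoint == e, ]

  # OS: diagnosis to death, 2010-01-01 .. 2015-01-01 is 5 years (one leap day)
  expect_equal(get("P1", "OS")$time, as.numeric(
    as.Date("2015-01-01") - as.Date("2010-01-01")) / 365.25)
  expect_equal(round(get("P1", "OS")$time, 2), 5)
  expect_true(get("P1", "OS")$event)

  # alive with no recurrence: OS and RFS censored at last follow-up
  expect_false(get("P3", "OS")$event)
  expect_false(get("P3", "RFS")$event)
  expect_equal(get("P3", "RFS")$time, as.numeric(
    as.Date("2020-06-01") - as.Date("2011-06-15")) / 365.25)

  # RFS: surgery to earliest of recurrence or death
  expect_true(get("P2", "RFS")$event)
  expect_equal(get("P2", "RFS")$time, as.numeric(
    as.Date("2014-03-20") - as.Date("2012-03-20")) / 365.25)

  # stage IV at diagnosis is excluded from RFS but not OS
  expect_false(get("P4", "RFS")$eligible)
  expect_equal(get("P4", "RFS")$reason, "stage IV at diagnosis")
  expect_true(get("P4", "OS")$eligible)

  # SAR only for patients with a recurrence
  expect_true(get("P2", "SAR")$eligible)
  expect_false(get("P1", "SAR")$eligible)

  # totality: every patient has every endpoint row
  expect_equal(nrow(ep), 3 * 4)
  # idempotence on the same input
  expect_identical(ep, derive_endpoints(clinical_fixture()))
})

test_that("recurrence before surgery is a record-level error", {
  cl <- clinical_fixture()
  cl$recurrence_date[2] <- cl$surgery_date[2] - 10
  expect_error(derive_endpoints(cl), "P2")
})

test_that("maxstat equals the exhaustive-scan oracle on small cohorts", {
  set.seed(41)
  for (rep in 1:4) {
    n <- sample(25:50, 1)
    d <- simulate_survival_cohort(n, hr = 2, seed = 100 + rep)
    got <- maxstat_cutpoint(d$marker, d$time, d$event)
    orc <- oracle_maxstat(d$marker, d$time, d$event)
    expect_equal(got$statistic, orc$stat, tolerance = 1e-10)
    expect_equal(got$cutpoint, orc$cutpoint, tolerance = 1e-10)
  }
})

test_that("maxstat separates an immediate-death group from a long-lived one", {
  marker <- c(rep(0, 15), rep(10, 15))
  time <- c(runif(15, 0.1, 0.5), rep(20, 15))
  event <- c(rep(1, 15), rep(0, 15))
  res <- maxstat_cutpoint(marker, time, event)
  expect_equal(res$cutpoint, 5)
  expect_equal(res$n_low, 15)
})

test_that("maxstat is invariant under monotone marker transformations", {
  d <- simulate_survival_cohort(80, seed = 5)
  base <- maxstat_cutpoint(d$marker, d$time, d$event)
  trans <- maxstat_cutpoint(exp(d$marker), d$time, d$event)
  expect_equal(trans$statistic, base$statistic, tolerance = 1e-10)
  expect_equal(trans$n_low, base$n_low)
})

test_that("maxstat rejects degenerate inputs", {
  d <- simulate_survival_cohort(30, seed = 6)
  expect_error(maxstat_cutpoint(rep(1, 30), d$time, d$event), "constant")
  expect_error(maxstat_cutpoint(d$marker, d$time, rep(0, 30)), "no events")
  expect_error(maxstat_cutpoint(d$marker[1:10], d$time[1:10], d$event[1:10]),
               "at least 20")
})

simulate_cox_cohort <- function(n, beta, seed) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  age_group <- rbinom(n, 1, 0.5)
  rate <- 0.1 * exp(beta * x + 0.3 * age_group)
  t <- rexp(n) / rate
  list(
    endpoints = data.frame(patient_id = paste0("P", 1:n),
                           time = pmin(t, 10),
                           event = as.integer(t <= 10)),
    features = data.frame(patient_id = paste0("P", 1:n), mut = x),
    covariates = data.frame(patient_id = paste0("P", 1:n),
                            age_group = age_group)
  )
}

test_that("the Cox workflow recovers a planted hazard ratio", {
  ok <- 0
  for (i in 1:60) {
    d <- simulate_cox_cohort(500, log(2), seed = 500 + i)
    res <- cox_workflow(d$endpoints, d$features, d$covariates)
    hr <- res$hr[res$stage == "multivariable"]
    if (length(hr) == 1 && hr > 1.5 && hr < 2.7) ok <- ok + 1
  }
  expect_gte(ok, 54)  # >= 90% of simulations
})

test_that("a null feature passes the univariable screen at about 5%", {
  passed <- 0
  for (i in 1:200) {
    d <- simulate_cox_cohort(300, 0, seed = 2000 + i)
    res <- cox_workflow(d$endpoints, d$features, d$covariates)
    if (any(res$stage == "multivariable")) passed <- passed + 1
  }
  # binomial 95% interval around 0.05 for 200 draws is (0.02, 0.08)
  expect_gte(passed / 200, 0.015)
  expect_lte(passed / 200, 0.095)
})

test_that("features collinear with a covariate are dropped with a warning", {
  set.seed(77)
  n <- 200
  grp <- rbinom(n, 1, 0.5)
  t <- rexp(n) / (0.1 * exp(0.9 * grp))  # strong covariate effect
  endpoints <- data.frame(patient_id = paste0("P", 1:n),
                          time = pmin(t, 10), event = as.integer(t <= 10))
  features <- data.frame(patient_id = paste0("P", 1:n), mut = grp)
  covariates <- data.frame(patient_id = paste0("P", 1:n), age_group = grp)
  expect_warning(res <- cox_workflow(endpoints, features, covariates),
                 "rank deficiency")
  expect_false(any(res$stage == "multivariable"))
})

test_that("rare binary features are skipped with a warning", {
  d <- simulate_cox_cohort(100, 0, seed = 88)
  d$features$mut <- c(1, 1, rep(0, 98))
  expect_warning(res <- cox_workflow(d$endpoints, d$features, d$covariates),
                 "fewer than 5")
  expect_equal(nrow(res), 0)
})
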