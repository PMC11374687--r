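# Survival endpoint derivation, maximally selected rank statistic cutpoints
# and the univariable-to-multivariable Cox workflow.

DAYS_PER_YEAR <- 365.25

as_date <- function(x, name) {
  d <- tryCatch(as.Date(x), error = function(e) NULL)
  if (is.null(d)) stop_input("column `%s` is not parseable as dates", name)
  d
}

#' Derive survival endpoints from a clinical table
#'
#' Computes, per patient, the three registry endpoints:
#' \describe{
#'   \item{OS}{overall survival: time from diagnosis of the primary tumour to
#'     death, censored at last follow-up if alive; all stages eligible.}
#'   \item{RFS}{recurrence-free survival: time from surgery to the earliest
#'     of local/distant recurrence or death, censored at last follow-up if
#'     neither; patients with stage IV at diagnosis are excluded, as are
#'     patients without a surgery date.}
#'   \item{SAR}{survival after recurrence: time from recurrence to death,
#'     censored at last follow-up; only patients with a recurrence are
#'     eligible.}
#' }
#' Times are reported in years (365.25 days). Every patient receives a row
#' for every endpoint with an eligibility flag and reason, so the derivation
#' is total and idempotent.
#'
#' @param clinical data.frame with \code{patient_id},
#'   \code{diagnosis_date}, \code{surgery_date}, \code{recurrence_date},
#'   \code{death_date}, \code{last_followup_date} (missing dates NA) and
#'   \code{stage} (I-IV).
#' @return data.frame with \code{patient_id}, \code{endpoint}, \code{time}
#'   (years), \code{event} (logical), \code{eligible}, \code{reason}.
#' @export
derive_endpoints <- function(clinical) {
  check_columns(clinical, c("patient_id", "diagnosis_date", "surgery_date",
                            "recurrence_date", "death_date",
                            "last_followup_date", "stage"), "clinical")
  dg <- as_date(clinical$diagnosis_date, "diagnosis_date")
  su <- as_date(clinical$surgery_date, "surgery_date")
  re <- as_date(clinical$recurrence_date, "recurrence_date")
  de <- as_date(clinical$death_date, "death_date")
  fu <- as_date(clinical$last_followup_date, "last_followup_date")
  end_anchor <- ifelse(!is.na(de), de, fu)  # numeric days
  if (any(!is.na(de) & de < dg)) stop_input("death before diagnosis")
  bad <- !is.na(re) & !is.na(su) & re < su
  if (any(bad)) {
    stop_input("recurrence before surgery for patient(s): %s",
               paste(clinical$patient_id[bad], collapse = ", "))
  }
  years <- function(from, to) as.numeric(to - from) / DAYS_PER_YEAR
  n <- nrow(clinical)
  mk <- function(endpoint, time, event, eligible, reason) {
    data.frame(patient_id = clinical$patient_id, endpoint = endpoint,
               time = time, event = event, eligible = eligible,
               reason = reason, stringsAsFactors = FALSE)
  }
  os <- mk("OS", years(as.numeric(dg), end_anchor), !is.na(de),
           !is.na(dg) & !is.na(end_anchor), "")
  os$reason[!os$eligible] <- "missing dates"

  rfs_event_day <- pmin(ifelse(is.na(re), Inf, as.numeric(re)),
                        ifelse(is.na(de), Inf, as.numeric(de)))
  rfs_event <- is.finite(rfs_event_day)
  rfs_end <- ifelse(rfs_event, rfs_event_day, as.numeric(fu))
  rfs_eligible <- clinical$stage != "IV" & !is.na(su)
  rfs_reason <- rep("", n)
  rfs_reason[clinical$stage == "IV"] <- "stage IV at diagnosis"
  rfs_reason[is.na(su)] <- "no surgery date"
  rfs <- mk("RFS", years(as.numeric(su), rfs_end), rfs_event,
            rfs_eligible, rfs_reason)

  sar_eligible <- !is.na(re)
  sar <- mk("SAR", years(as.numeric(re), end_anchor), !is.na(de),
            sar_eligible, ifelse(sar_eligible, "", "no recurrence"))

  out <- rbind(os, rfs, sar)
  out$time[!out$eligible] <- NA_real_
  rownames(out) <- NULL
  out
}

# Log-rank (Peto) scores: a_i = delta_i - Lambda_hat(t_i) with the
# Nelson-Aalen cumulative hazard evaluated at each subject's time.
logrank_scores <- function(time, event) {
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]
  n <- length(t_s)
  ut <- unique(t_s)
  d <- vapply(ut, function(t) sum(e_s[t_s == t]), numeric(1))
  r <- vapply(ut, function(t) sum(t_s >= t), numeric(1))
  cumhaz <- cumsum(d / r)
  a <- numeric(n)
  a[ord] <- e_s - cumhaz[match(t_s, ut)]
  a
}

#' Maximally selected rank statistic cutpoint
#'
#' Scans all admissible dichotomizations of a continuous marker and returns
#' the one maximizing the standardized two-group log-rank statistic,
#' computed as a linear rank statistic with log-rank (Peto) scores and the
#' permutation variance: for a split putting m of N subjects below the
#' cutpoint, \eqn{T = |S - m \bar a| / \sqrt{m (N - m) / (N (N-1)) \sum_i
#' (a_i - \bar a)^2}} where S is the sum of the scores below the cutpoint.
#' Candidate cutpoints are the midpoints between consecutive distinct marker
#' values whose induced groups both hold at least
#' \code{min_group_fraction} of the cohort. Because the statistic only uses
#' the ranks of the marker, it is invariant under strictly monotone
#' transformations of the marker.
#'
#' No small-sample correction of the selected statistic's p-value is
#' applied; the operation returns the cutpoint and the statistic, not an
#' inference on it.
#'
#' @param values continuous marker, one value per subject.
#' @param time,event follow-up time and event indicator (1 = event).
#' @param min_group_fraction minimum fraction of subjects on each side of an
#'   admissible cutpoint (default 0.1).
#' @return list of class \code{cutpoint_result}: \code{cutpoint},
#'   \code{statistic}, \code{n_low}, \code{n_high}, and a data.frame
#'   \code{scan} of all candidate cutpoints with their statistics.
#' @export
maxstat_cutpoint <- function(values, time, event, min_group_fraction = 0.1) {
  n <- length(values)
  if (length(time) != n || length(event) != n) {
    stop_input("`values`, `time` and `event` must have the same length")
  }
  if (n < 20) stop_input("at least 20 subjects required (got %d)", n)
  if (sum(event) == 0) stop_input("no events observed")
  if (length(unique(values)) < 2) stop_input("`values` is constant")
  check_number(min_group_fraction, "min_group_fraction", lower = 0, upper = 0.5)

  a <- logrank_scores(time, event)
  ord <- order(values)
  v_s <- values[ord]; a_s <- a[ord]
  abar <- mean(a)
  ss <- sum((a - abar)^2)
  min_m <- max(1, ceiling(min_group_fraction * n))

  cum <- cumsum(a_s)
  # split after position m puts subjects 1..m in the low group; admissible
  # only between distinct marker values
  m_all <- seq_len(n - 1)
  distinct <- v_s[m_all] < v_s[m_all + 1]
  adm <- distinct & m_all >= min_m & (n - m_all) >= min_m
  if (!any(adm)) stop_input("no admissible cutpoint under `min_group_fraction`")
  m_adm <- m_all[adm]
  S <- cum[m_adm]
  var_s <- m_adm * (n - m_adm) / (n * (n - 1)) * ss
  stat <- abs(S - m_adm * abar) / sqrt(var_s)
  cutpoints <- (v_s[m_adm] + v_s[m_adm + 1]) / 2
  best <- which.max(stat)
  structure(list(
    cutpoint = cutpoints[best],
    statistic = stat[best],
    n_low = m_adm[best],
    n_high = n - m_adm[best],
    scan = data.frame(cutpoint = cutpoints, statistic = stat,
                      n_low = m_adm, n_high = n - m_adm)
  ), class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("Maxstat cutpoint %.4g (standardized log-rank %.3f; %d vs %d)\n",
              x$cutpoint, x$statistic, x$n_low, x$n_high))
  invisible(x)
}

#' Univariable-to-multivariable Cox association workflow
#'
#' For each candidate feature, fits a univariable Cox proportional-hazards
#' model on the endpoint; features significant at \code{p_screen} are refit
#' in a multivariable model adjusted for the supplied covariates. Binary
#' features with fewer than \code{min_carriers} carriers are skipped with a
#' warning. A feature whose multivariable coefficient cannot be estimated
#' (rank deficiency, e.g. a feature identical to a covariate) is dropped
#' with a warning.
#'
#' @param endpoints data.frame with \code{patient_id}, \code{time},
#'   \code{event} (a single endpoint, already filtered to eligible
#'   patients).
#' @param features data.frame with \code{patient_id} plus one column per
#'   candidate feature (binary 0/1 or continuous).
#' @param covariates data.frame with \code{patient_id} plus adjustment
#'   columns (e.g. site, pretreatment, stage, age group, grade).
#' @param p_screen univariable screening threshold, default 0.05.
#' @param min_carriers minimum carriers for a binary feature, default 5.
#' @return data.frame with one row per feature and analysis stage
#'   (\code{"univariable"}, \code{"multivariable"}): \code{feature},
#'   \code{stage}, \code{hr}, \code{ci_lower}, \code{ci_upper},
#'   \code{p_value}, \code{n}, \code{n_events}.
#' @export
cox_workflow <- function(endpoints, features, covariates = NULL,
                         p_screen = 0.05, min_carriers = 5) {
  check_columns(endpoints, c("patient_id", "time", "event"), "endpoints")
  check_columns(features, "patient_id", "features")
  feature_names <- setdiff(names(features), "patient_id")
  if (length(feature_names) == 0) stop_input("no feature columns supplied")
  base <- endpoints[, c("patient_id", "time", "event")]
  if (!is.null(covariates)) {
    check_columns(covariates, "patient_id", "covariates")
    base <- merge(base, covariates, by = "patient_id")
  }
  cov_names <- setdiff(names(base), c("patient_id", "time", "event"))
  rows <- list()
  extract <- function(fit, stage, feat, n, n_events) {
    s <- summary(fit)
    i <- which(startsWith(rownames(s$coefficients), ".feature"))[1]
    data.frame(feature = feat, stage = stage,
               hr = s$conf.int[i, "exp(coef)"],
               ci_lower = s$conf.int[i, "lower .95"],
               ci_upper = s$conf.int[i, "upper .95"],
               p_value = s$coefficients[i, "Pr(>|z|)"],
               n = n, n_events = n_events, stringsAsFactors = FALSE)
  }
  for (feat in feature_names) {
    df <- merge(base, features[, c("patient_id", feat)], by = "patient_id")
    names(df)[names(df) == feat] <- ".feature"
    df <- df[stats::complete.cases(df), , drop = FALSE]
    x <- df$.feature
    if (length(unique(x)) == 2 && min(table(x)) < min_carriers) {
      warning(sprintf("feature `%s` has fewer than %d carriers; skipped",
                      feat, min_carriers), call. = FALSE)
      next
    }
    if (length(unique(x)) < 2) {
      warning(sprintf("feature `%s` is constant; skipped", feat),
              call. = FALSE)
      next
    }
    uni <- survival::coxph(survival::Surv(time, event) ~ .feature, data = df)
    rows[[length(rows) + 1]] <- extract(uni, "univariable", feat,
                                        nrow(df), sum(df$event))
    p_uni <- rows[[length(rows)]]$p_value
    if (is.na(p_uni) || p_uni >= p_screen || length(cov_names) == 0) next
    form <- stats::as.formula(paste(
      "survival::Surv(time, event) ~ .feature +",
      paste(cov_names, collapse = " + ")))
    multi <- suppressWarnings(survival::coxph(form, data = df))
    cf <- stats::coef(multi)
    if (!any(startsWith(names(cf), ".feature")) || anyNA(cf)) {
      warning(sprintf("feature `%s` dropped from multivariable model (rank deficiency)",
                      feat), call. = FALSE)
      next
    }
    rows[[length(rows) + 1]] <- extract(multi, "multivariable",
                                        feat, nrow(df), sum(df$event))
  }
  if (length(rows) == 0) {
    return(data.frame(feature = character(0), stage = character(0),
                      hr = numeric(0), ci_lower = numeric(0),
                      ci_upper = numeric(0), p_value = numeric(0),
                      n = integer(0), n_events = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
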