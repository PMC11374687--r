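# Independent oracles used to cross-check the implementation. These are
# deliberately naive (enumeration, double loops, literal lookup tables) and
# share no code with the package internals.

# Two-sided Fisher p by full hypergeometric enumeration: sum the
# probabilities of all tables (with the observed margins) whose probability
# does not exceed that of the observed table.
oracle_fisher_p <- function(both, a_only, b_only, neither) {
  n <- both + a_only + b_only + neither
  r1 <- both + a_only   # carriers of gene a
  c1 <- both + b_only   # carriers of gene b
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(ks, c1, n - c1, r1)
  p_obs <- dhyper(both, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force Buffa score: explicit per-gene sign comparison loops.
oracle_buffa <- function(expr, sig, tumours) {
  scores <- integer(ncol(expr))
  for (s in seq_len(ncol(expr))) {
    total <- 0L
    for (g in sig) {
      med <- median(expr[g, tumours])
      total <- total + if (expr[g, s] > med) 1L else -1L
    }
    scores[s] <- total
  }
  data.frame(sample_id = colnames(expr), score = scores,
             stringsAsFactors = FALSE)
}

# Literal copy-number state lookup over the admissible (tcn, lcn) grid.
oracle_cn_state <- function(tcn, lcn) {
  if (tcn == 0 && lcn == 0) return("homozygous_deletion")
  if (tcn == 1 && lcn == 0) return("loh")
  if (tcn == 2 && lcn == 0) return("copy_neutral_loh")
  if (tcn == 2 && lcn == 1) return("wild_type")
  if (tcn %in% 3:4 && lcn == 0) return("gain_loh")
  if (tcn %in% 3:4 && lcn >= 1) return("gain")
  if (tcn >= 5 && lcn == 0) return("amp_loh")
  if (tcn >= 5 && lcn >= 1) return("amp")
  stop("inadmissible combination")
}

# Naive maximally-selected standardized log-rank statistic: log-rank (Peto)
# scores from an explicit double loop over distinct event times, then an
# exhaustive scan over all admissible splits.
oracle_maxstat <- function(values, time, event, min_group_fraction = 0.1) {
  n <- length(values)
  a <- numeric(n)
  for (i in seq_len(n)) {
    lam <- 0
    for (t in unique(time)) {
      if (t <= time[i]) {
        lam <- lam + sum(event[time == t]) / sum(time >= t)
      }
    }
    a[i] <- event[i] - lam
  }
  abar <- mean(a)
  ss <- sum((a - abar)^2)
  min_m <- max(1, ceiling(min_group_fraction * n))
  vs <- sort(unique(values))
  best <- list(stat = -Inf, cutpoint = NA)
  for (k in seq_len(length(vs) - 1)) {
    c0 <- (vs[k] + vs[k + 1]) / 2
    low <- values <= c0
    m <- sum(low)
    if (m < min_m || n - m < min_m) next
    S <- sum(a[low])
    stat <- abs(S - m * abar) / sqrt(m * (n - m) / (n * (n - 1)) * ss)
    if (stat > best$stat) best <- list(stat = stat, cutpoint = c0)
  }
  best
}

# All permutations of 1..n (for exact Spearman enumeration at tiny n).
oracle_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_permutations(n - 1L)) {
    for (i in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = i)
    }
  }
  out
}

# Exact two-sided Spearman p at tiny n: enumerate all rank permutations and
# take 2 * min(lower tail, upper tail) of the observed rho (the canonical
# exact two-sided tail).
oracle_spearman <- function(x, y) {
  rho_obs <- cor(rank(x), rank(y))
  rhos <- vapply(oracle_permutations(length(x)),
                 function(p) cor(rank(x), p), numeric(1))
  p <- 2 * min(mean(rhos <= rho_obs + 1e-12), mean(rhos >= rho_obs - 1e-12))
  list(rho = rho_obs, p = min(1, p))
}
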