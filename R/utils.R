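# Internal validation helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_na = FALSE) {
  if (!is.numeric(x)) stop_input("`%s` must be numeric", name)
  bad <- !is.na(x) & (x < lower | x > upper)
  if (any(bad)) {
    stop_input("`%s` must be in [%s, %s] (offending value: %s)",
               name, format(lower), format(upper), format(x[bad][1]))
  }
  if (!allow_na && anyNA(x)) stop_input("`%s` contains missing values", name)
  invisible(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_input("`%s` is missing required column(s): %s", name,
               paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Cohort quartiles under the pinned interpolation convention
#'
#' Median and quartiles are computed by linear interpolation of order
#' statistics at positions (n-1)*p (the default convention of mainstream
#' statistical environments, \code{stats::quantile} type 7). All
#' quantile-based rules in the package (hypermutation threshold, mitochondrial
#' cutoff derivation) use this single convention so that worked examples are
#' exact.
#'
#' @param x numeric vector.
#' @return named vector with elements \code{q25}, \code{median}, \code{q75}.
#' @keywords internal
cohort_quartiles <- function(x) {
  q <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(q25 = q[1], median = q[2], q75 = q[3])
}

# Run an expression with a locally seeded RNG stream, restoring (or clearing)
# the global .Random.seed afterwards so generators have no global side effects.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
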