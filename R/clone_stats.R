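#' Upper-tail probability of the chi-square distribution
#'
#' Thin, validated wrapper around [stats::pchisq()] used throughout the
#' clone-count pipeline. For `df = 4` the survival function has the closed
#' form `exp(-x/2) * (1 + x/2)`, which the test suite uses as an independent
#' cross-check.
#'
#' @param x chi-square statistic, `>= 0`.
#' @param df degrees of freedom, `>= 1`.
#' @return Upper-tail probability `P(X > x)`.
#' @examples
#' chisq_sf(24.92, 4) # 5.221e-05
#' @export
chisq_sf <- function(x, df) {
  if (any(is.na(x)) || any(x < 0))
    stop("chi-square statistic must be non-negative", call. = FALSE)
  if (any(df < 1))
    stop("degrees of freedom must be >= 1", call. = FALSE)
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Chi-square critical value
#'
#' The statistic threshold whose upper-tail probability equals `alpha`;
#' `chisq_critical(0.01, 4)` is 13.28 (2 dp), the threshold against which the
#' replicated clone-count statistics are judged.
#'
#' @param alpha upper-tail probability in `(0, 1)`.
#' @param df degrees of freedom.
#' @return `x` with `chisq_sf(x, df) == alpha`.
#' @export
chisq_critical <- function(alpha, df) {
  if (any(alpha <= 0) || any(alpha >= 1))
    stop("alpha must lie strictly inside (0, 1)", call. = FALSE)
  stats::qchisq(alpha, df, lower.tail = FALSE)
}

#' Chi-square goodness of fit for a clone-count series
#'
#' Compares the observed type counts of each transfer in one
#' (isolate, life-stage) series against the expected counts implied by the
#' isolate's baseline type-Z frequency: per transfer with `k` scored clones,
#' `E_Z = f * k` and `E_Y = (1 - f) * k`, and the statistic is the usual
#' `sum((O - E)^2 / E)` accumulated over transfers and both types.
#'
#' Two degrees-of-freedom conventions are provided. `"study"` (the default,
#' used for reproducing the published tables) sets `df = n - 1` from the
#' number of transfers `n`; `"orthodox"` sets `df = n * (types - 1) = n`,
#' the standard convention for `n` independent binomial observations, and is
#' the one under which the test is calibrated (type-I error equals alpha).
#'
#' @param series data frame with one row per transfer and integer columns
#'   `count_Z` and `count_Y`, or a two-column matrix (Z then Y).
#' @param expected_freq baseline proportion of type Z, strictly inside (0, 1)
#'   (a boundary frequency gives an expected count of zero).
#' @param df_convention `"study"` or `"orthodox"`, see Details.
#' @return Object of class `chisq_gof` with fields `statistic`, `df`, `p`,
#'   `n_transfers`, `expected_freq`, `df_convention`. For a single transfer
#'   under the `"study"` convention `df` is 0 and `p` is `NA`.
#' @examples
#' chisq_gof(data.frame(count_Z = 36, count_Y = 24), 0.5,
#'           df_convention = "orthodox")
#' @export
chisq_gof <- function(series, expected_freq,
                      df_convention = c("study", "orthodox")) {
  df_convention <- match.arg(df_convention)
  if (length(expected_freq) != 1L || is.na(expected_freq) ||
      expected_freq <= 0 || expected_freq >= 1)
    stop("expected_freq must lie strictly inside (0, 1)", call. = FALSE)
  counts <- as_count_matrix(series)
  n <- nrow(counts)
  if (n < 1L) stop("series must contain at least one transfer", call. = FALSE)
  k <- rowSums(counts)
  e <- cbind(expected_freq * k, (1 - expected_freq) * k)
  statistic <- sum((counts - e)^2 / e)
  df <- if (df_convention == "study") n - 1L else n
  p <- if (df >= 1L) chisq_sf(statistic, df) else NA_real_
  structure(list(statistic = statistic, df = df, p = p,
                 n_transfers = n, expected_freq = expected_freq,
                 df_convention = df_convention),
            class = "chisq_gof")
}

as_count_matrix <- function(series) {
  if (is.data.frame(series)) {
    miss <- setdiff(c("count_Z", "count_Y"), names(series))
    if (length(miss))
      stop("series is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    counts <- cbind(series$count_Z, series$count_Y)
  } else {
    counts <- as.matrix(series)
    if (ncol(counts) != 2L)
      stop("a count matrix must have two columns (Z, Y)", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0))
    stop("clone counts must be non-negative", call. = FALSE)
  counts
}

#' @export
print.chisq_gof <- function(x, ...) {
  cat("Chi-square goodness of fit (", x$df_convention, " df convention)\n",
      sep = "")
  cat("  X^2 = ", format(x$statistic, digits = 6), ", df = ", x$df,
      ", P = ", format(x$p, digits = 4), "\n", sep = "")
  cat("  ", x$n_transfers, " transfer(s), expected type-Z frequency ",
      x$expected_freq, "\n", sep = "")
  invisible(x)
}

#' Fisher's combined probability test
#'
#' Combines independent tail probabilities of replicate tests into the
#' statistic `-2 * sum(log(p))`, which under the joint null is chi-square
#' distributed with `2k` degrees of freedom for `k` tests. Probabilities
#' below `p_floor` are clamped before taking logs so that numerically
#' underflowed p-values cannot produce infinities.
#'
#' @param p_values tail probabilities, each in `(0, 1]`.
#' @param p_floor underflow floor applied before `log()`.
#' @return Object of class `fisher_combined` with fields `statistic`, `k`,
#'   `df` (`= 2k`), `p_combined` and `per_test` (data frame of `p`, `log_p`).
#' @examples
#' fisher_combine(c(0.010, 5.221e-5, 3.007e-5, 7.592e-5))$statistic # 68.726
#' @export
fisher_combine <- function(p_values, p_floor = 1e-300) {
  p_values <- as.numeric(p_values)
  if (!length(p_values))
    stop("at least one p-value is required", call. = FALSE)
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  log_p <- log(pmax(p_values, p_floor))
  statistic <- -2 * sum(log_p)
  k <- length(p_values)
  df <- 2L * k
  structure(list(statistic = statistic, k = k, df = df,
                 p_combined = chisq_sf(statistic, df),
                 per_test = data.frame(p = p_values, log_p = log_p)),
            class = "fisher_combined")
}

#' @export
print.fisher_combined <- function(x, ...) {
  cat("Fisher's combined probability test\n")
  cat("  -2 sum ln(P) = ", format(x$statistic, digits = 6), ", df = 2k = ",
      x$df, ", combined P = ", format(x$p_combined, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Significance call against a chi-square critical value
#'
#' Declares significance when the statistic strictly exceeds
#' `chisq_critical(alpha, df)`; a statistic exactly at the threshold is not
#' significant.
#'
#' @param x a numeric statistic, a [chisq_gof()] result or a
#'   [fisher_combine()] result (from which `df` is taken when not supplied).
#' @param alpha upper-tail significance level.
#' @param df degrees of freedom; required when `x` is a bare number.
#' @return Object of class `significance_call`: list with `significant`,
#'   `statistic`, `alpha`, `df` and `critical`.
#' @examples
#' significance_call(18.34, alpha = 0.01, df = 4)$significant # TRUE
#' @export
significance_call <- function(x, alpha = 0.01, df = NULL) {
  if (inherits(x, "chisq_gof") || inherits(x, "fisher_combined")) {
    if (is.null(df)) df <- x$df
    x <- x$statistic
  }
  if (is.null(df))
    stop("df must be supplied with a bare statistic", call. = FALSE)
  critical <- chisq_critical(alpha, df)
  structure(list(significant = x > critical, statistic = x,
                 alpha = alpha, df = df, critical = critical),
            class = "significance_call")
}

#' @export
print.significance_call <- function(x, ...) {
  cat(if (x$significant) "SIGNIFICANT" else "not significant",
      ": X^2 = ", format(x$statistic, digits = 6), " vs critical ",
      format(x$critical, digits = 6), " (alpha = ", x$alpha, ", df = ",
      x$df, ")\n", sep = "")
  invisible(x)
}
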