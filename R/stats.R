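# Cohort-level statistics: Pearson correlation matrices, strength
# classification, normality screening, summary tables.

#' Pearson correlations for a set of variable pairs
#'
#' Computes the Pearson product-moment correlation, its two-sided p-value
#' (t distribution on n - 2 degrees of freedom), and the strength class
#' for each requested pair of cohort-table columns. Complete cases are
#' used per pair. Alongside the uncorrected p-values (the study design:
#' alpha = 0.05, no multiple-testing correction), a Holm-adjusted column
#' across the requested pairs is emitted for reference.
#'
#' @param table a data frame, one row per participant.
#' @param pairs a two-column data frame or matrix of variable names
#'   (`var_x`, `var_y`); defaults to all distinct pairs of numeric columns.
#' @return a data frame with columns `var_x`, `var_y`, `r`, `p`, `n`,
#'   `dof`, `strength`, `p_holm`.
#' @export
pearson_matrix <- function(table, pairs = NULL) {
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  if (is.null(pairs)) {
    if (length(num) < 2L)
      af_stop("need at least two numeric variables", "archforce_input_error")
    pairs <- t(utils::combn(num, 2))
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs)[1:2] <- c("var_x", "var_y")
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    vx <- pairs$var_x[i]; vy <- pairs$var_y[i]
    if (!vx %in% names(table) || !vy %in% names(table))
      af_stop(sprintf("unknown variable in pair (%s, %s)", vx, vy),
              "archforce_input_error")
    x <- table[[vx]]; y <- table[[vy]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L)
      af_stop(sprintf("fewer than 3 complete cases for (%s, %s)", vx, vy),
              "archforce_input_error")
    if (sd(x) == 0 || sd(y) == 0)
      af_stop(sprintf("zero variance in (%s, %s): correlation undefined",
                      vx, vy), "archforce_undefined_correlation_error")
    ct <- cor.test(x, y, method = "pearson")
    data.frame(var_x = vx, var_y = vy,
               r = unname(ct$estimate), p = ct$p.value,
               n = length(x), dof = length(x) - 2L,
               strength = classify_strength(unname(ct$estimate)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Classify correlation strength
#'
#' Correlations are strong for `|r| >= 0.7`, moderate for
#' `0.4 <= |r| < 0.7` and weak for `|r| < 0.4`; negative correlations
#' classify by magnitude.
#'
#' @param r correlation coefficient(s) in \[-1, 1\].
#' @return character vector: `"strong"`, `"moderate"` or `"weak"`.
#' @export
#' @examples
#' classify_strength(c(0.74, 0.40, -0.22))
classify_strength <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1))
    af_stop("correlation coefficients must lie in [-1, 1]",
            "archforce_input_error")
  a <- abs(r)
  ifelse(a >= 0.7, "strong", ifelse(a >= 0.4, "moderate", "weak"))
}

#' Normality screen
#'
#' Kolmogorov-Smirnov-type screen against a normal distribution. Because
#' the reference mean and standard deviation are estimated from the sample,
#' the Lilliefors correction is used for the p-value (method
#' `"lilliefors"`, the default); method `"ks"` runs the plain one-sample
#' KS test against the fitted normal, whose p-value is only approximate in
#' this situation. The result is reported for screening; it never switches
#' methods silently.
#'
#' @param values numeric vector, at least 4 non-missing values.
#' @param method `"lilliefors"` or `"ks"`.
#' @return list with `statistic`, `p`, `method`, `approximate`.
#' @export
normality_screen <- function(values, method = c("lilliefors", "ks")) {
  method <- match.arg(method)
  x <- values[is.finite(values)]
  if (length(x) < 4L)
    af_stop("at least 4 values are needed for the normality screen",
            "archforce_input_error")
  if (sd(x) == 0)
    af_stop("constant input: normality test undefined",
            "archforce_undefined_test_error")
  if (method == "lilliefors") {
    if (length(x) < 5L)
      af_stop("the Lilliefors variant needs at least 5 values (use method = 'ks' for n = 4)",
              "archforce_input_error")
    ht <- nortest::lillie.test(x)
    list(statistic = unname(ht$statistic), p = ht$p.value,
         method = "Lilliefors (Kolmogorov-Smirnov, estimated parameters)",
         approximate = FALSE)
  } else {
    ht <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), sd(x)))
    list(statistic = unname(ht$statistic), p = ht$p.value,
         method = "one-sample Kolmogorov-Smirnov against fitted normal",
         approximate = TRUE)
  }
}

#' Cohort summary table (mean +/- SD)
#'
#' Column means and sample standard deviations of the numeric variables of
#' a cohort table.
#'
#' @param table a data frame with one row per participant.
#' @param variables optional character vector restricting the summary.
#' @return data frame with columns `variable`, `mean`, `sd`, `n`.
#' @export
cohort_summary <- function(table, variables = NULL) {
  if (nrow(table) < 2L)
    af_stop("at least 2 participants are needed", "archforce_input_error")
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  if (!is.null(variables)) num <- intersect(variables, names(table))
  if (length(num) == 0L)
    af_stop("no numeric variables to summarise", "archforce_input_error")
  rows <- lapply(num, function(v) {
    x <- table[[v]][is.finite(table[[v]])]
    if (length(x) == 0L)
      af_stop(sprintf("column '%s' has no observed values", v),
              "archforce_summary_error")
    data.frame(variable = v, mean = mean(x), sd = sd(x), n = length(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
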