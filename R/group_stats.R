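# Group-level statistics: factorial ANOVA (Type II sums of squares), paired t
# tests, Benjamini-Hochberg FDR correction, and Pearson correlation, each
# returning a tidy report row.

#' Factorial ANOVA
#'
#' Fits a fully-crossed linear model of `value` on the given factors and
#' reports main effects and interactions with Type II sums of squares
#' (unbalanced designs accepted). Degenerate zero-residual designs get
#' explicit conventions: a nonzero effect over zero residual variance reports
#' p = 0, a zero effect reports p = 1.
#'
#' @param table Long-format data frame with a numeric `value` column and one
#'   column per factor.
#' @param factors Character vector of factor column names (each >= 2 levels).
#' @param value Name of the response column (default `"value"`).
#' @return Data frame `term`, `sum_sq`, `df`, `statistic` (F), `df_resid`, `p`.
#' @export
anova_factorial <- function(table, factors, value = "value") {
  stopifnot(is.data.frame(table), value %in% names(table))
  if (!all(factors %in% names(table))) {
    stop("missing factor columns: ",
         paste(setdiff(factors, names(table)), collapse = ", "), call. = FALSE)
  }
  for (f in factors) {
    table[[f]] <- factor(table[[f]])
    if (nlevels(table[[f]]) < 2L) {
      stop(sprintf("factor '%s' has fewer than 2 levels", f), call. = FALSE)
    }
  }
  fml <- stats::as.formula(paste(value, "~", paste(factors, collapse = " * ")))
  fit <- stats::lm(fml, data = table)
  tol0 <- 1e-10 * max(abs(table[[value]]))^2 * nrow(table) + 1e-300
  aa <- if (sum(stats::residuals(fit)^2) <= tol0) {
    # car refuses zero-residual fits; sequential SS are equivalent here for
    # the purpose of the noiseless p = 0 / p = 1 conventions below
    suppressWarnings(stats::anova(fit))   # conventions below replace its F/p
  } else {
    car::Anova(fit, type = 2)
  }
  res_row <- rownames(aa) == "Residuals"
  ss_res <- aa[res_row, "Sum Sq"]
  df_res <- aa[res_row, "Df"]
  terms <- rownames(aa)[!res_row]
  ss <- aa[!res_row, "Sum Sq"]
  df <- aa[!res_row, "Df"]
  tol <- 1e-10 * max(abs(table[[value]]))^2 * nrow(table)
  Fv <- (ss / df) / (ss_res / df_res)
  p <- stats::pf(Fv, df, df_res, lower.tail = FALSE)
  if (ss_res <= tol) {                          # noiseless design
    Fv <- ifelse(ss <= tol, 0, Inf)
    p <- ifelse(ss <= tol, 1, 0)
  }
  data.frame(term = terms, sum_sq = ss, df = df, statistic = Fv,
             df_resid = df_res, p = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Paired t test
#'
#' Two-sided t test on the paired differences (`dof = n - 1`). Zero-variance
#' nonzero-mean differences report p = 0 with a warning; zero differences
#' report t = 0, p = 1.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return Data frame `test`, `statistic`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("`x` and `y` must be equal-length with n >= 2", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y)
  d <- (x - y)[ok]
  n <- length(d)
  if (n < 2L) stop("fewer than 2 complete pairs", call. = FALSE)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(data.frame(test = "paired_t", statistic = 0, df = n - 1, p = 1,
                        mean_diff = 0, n = n, stringsAsFactors = FALSE))
    }
    warning("zero-variance nonzero-mean differences; reporting p = 0", call. = FALSE)
    return(data.frame(test = "paired_t", statistic = sign(mean(d)) * Inf,
                      df = n - 1, p = 0, mean_diff = mean(d), n = n,
                      stringsAsFactors = FALSE))
  }
  tt <- stats::t.test(d)
  data.frame(test = "paired_t", statistic = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value,
             mean_diff = mean(d), n = n, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values, monotone and capped at 1.
#'
#' @param p Numeric vector of p values in \\[0, 1\\].
#' @return Adjusted p values in input order.
#' @export
fdr_correct <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation with t-transform p value
#'
#' @param x,y Numeric vectors, n >= 3, finite, nonzero variance.
#' @return Data frame `test`, `estimate` (r), `statistic` (t), `df`, `p`, `n`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("`x` and `y` must be equal-length with n >= 3", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("values must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for zero-variance input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(test = "pearson", estimate = unname(ct$estimate),
             statistic = unname(ct$statistic), df = unname(ct$parameter),
             p = ct$p.value, n = length(x), stringsAsFactors = FALSE)
}
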