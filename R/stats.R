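#' Paired t-test with mean-difference confidence interval
#'
#' Classical two-sided paired t-test reporting the mean difference `x - y`,
#' its 95% confidence interval, and a derived eta-squared effect size
#' `t^2 / (t^2 + df)` (the two-level repeated-measures ANOVA equivalent).
#'
#' @param x,y paired numeric vectors of equal length >= 3.
#' @param conf_level confidence level for the mean-difference interval.
#' @return List of class `paired_t_result`: `t`, `df`, `p`, `mean_diff`,
#'   `ci95` (low, high), `eta_squared`, `n`.
#' @examples
#' paired_t(c(2, 4, 6, 8), c(0, 0, 0, 0)) # t = 3.873, df = 3
#' @export
paired_t <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired (equal length)",
                                   call. = FALSE)
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  d <- x - y
  if (sd(d) == 0) stop("degenerate pairing: zero difference variance",
                       call. = FALSE)
  ht <- t.test(x, y, paired = TRUE, conf.level = conf_level)
  t_stat <- unname(ht$statistic)
  df <- unname(ht$parameter)
  structure(list(
    t = t_stat, df = df, p = ht$p.value,
    mean_diff = unname(ht$estimate),
    ci95 = unname(ht$conf.int),
    eta_squared = t_stat^2 / (t_stat^2 + df),
    n = length(x)
  ), class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf(
    "t(%d) = %.2f, p = %.3f, mean difference = %.2f [%.2f, %.2f], eta^2 = %.3f\n",
    x$df, x$t, x$p, x$mean_diff, x$ci95[1], x$ci95[2], x$eta_squared
  ))
  invisible(x)
}

#' Ordinary least squares regression with overall F test
#'
#' Fits `y ~ X` with an intercept and reports the overall F statistic on
#' (k, n - k - 1) degrees of freedom, its p value, R-squared, and the
#' coefficient table. Rank-deficient predictor matrices are rejected with the
#' offending columns named.
#'
#' @param y outcome vector.
#' @param X predictor matrix or data.frame (rows >= predictors + 2).
#' @return List of class `ols_result`: `f`, `df1`, `df2`, `p`, `r_squared`,
#'   `coefficients` (data.frame term/estimate/se/t/p), `model` (the `lm` fit).
#' @examples
#' fit <- linear_regression(c(3, 5, 7, 9), data.frame(x = 1:4))
#' fit$coefficients
#' @export
linear_regression <- function(y, X) {
  X <- as.data.frame(X)
  ok <- complete.cases(y, X)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  k <- ncol(X)
  n <- length(y)
  if (n < k + 2L) {
    stop(sprintf("need at least %d rows for %d predictors", k + 2L, k),
         call. = FALSE)
  }
  mm <- cbind(`(Intercept)` = 1, as.matrix(X))
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop(sprintf("rank-deficient predictors: collinear column(s) %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  dat <- cbind(.y = y, X)
  fit <- lm(.y ~ ., data = dat)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "t", "p")
  co <- cbind(term = rownames(co), co)
  rownames(co) <- NULL
  structure(list(
    f = unname(fstat["value"]), df1 = unname(fstat["numdf"]),
    df2 = unname(fstat["dendf"]),
    p = pf(fstat["value"], fstat["numdf"], fstat["dendf"],
           lower.tail = FALSE)[[1]],
    r_squared = sm$r.squared, coefficients = co, model = fit
  ), class = "ols_result")
}

#' @export
print.ols_result <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.2f, p = %.3f, R^2 = %.3f\n",
              x$df1, x$df2, x$f, x$p, x$r_squared))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Pairwise Pearson correlations with Benjamini-Hochberg FDR adjustment
#'
#' Computes two-sided Pearson correlations over every pair of the supplied
#' variables (pairwise deletion; at least 4 complete cases per pair), then
#' adjusts the p values across all pairs with the Benjamini-Hochberg step-up
#' procedure (adjusted p = cumulative minimum of `m * p / rank`, capped at 1).
#' Constant variables have their pairs flagged missing with a warning.
#'
#' @param data data.frame of per-participant indices (numeric columns).
#' @param variables columns to correlate; defaults to all numeric columns.
#' @return List of class `correlation_table`: `variables`, symmetric matrices
#'   `r`, `p`, `p_fdr` (NA diagonal), and `pairs` (long-format data.frame).
#' @examples
#' d <- data.frame(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(4, 3, 2, 1))
#' ct <- correlation_matrix_fdr(d)
#' ct$r["a", "b"] # 0.8
#' @export
correlation_matrix_fdr <- function(data, variables = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  v <- length(variables)
  if (v < 2L) stop("need at least 2 variables", call. = FALSE)
  r <- p <- matrix(NA_real_, v, v, dimnames = list(variables, variables))
  pairs <- expand.grid(i = seq_len(v), j = seq_len(v))
  pairs <- pairs[pairs$i < pairs$j, ]
  pair_r <- pair_p <- rep(NA_real_, nrow(pairs))
  flagged <- character(0)
  for (k in seq_len(nrow(pairs))) {
    xi <- data[[variables[pairs$i[k]]]]
    yj <- data[[variables[pairs$j[k]]]]
    ok <- complete.cases(xi, yj)
    if (sum(ok) < 4L) next
    if (sd(xi[ok]) == 0 || sd(yj[ok]) == 0) {
      flagged <- union(flagged, c(variables[pairs$i[k]], variables[pairs$j[k]]))
      next
    }
    ct <- cor.test(xi[ok], yj[ok], method = "pearson", alternative = "two.sided")
    pair_r[k] <- unname(ct$estimate)
    pair_p[k] <- ct$p.value
  }
  if (length(flagged)) {
    warning(sprintf("constant variable(s) flagged missing: %s",
                    paste(flagged, collapse = ", ")))
  }
  # BH family = the pairs actually tested
  pair_p_fdr <- rep(NA_real_, length(pair_p))
  tested <- !is.na(pair_p)
  pair_p_fdr[tested] <- p.adjust(pair_p[tested], method = "BH")

  p_fdr <- r
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]
    j <- pairs$j[k]
    r[i, j] <- r[j, i] <- pair_r[k]
    p[i, j] <- p[j, i] <- pair_p[k]
    p_fdr[i, j] <- p_fdr[j, i] <- pair_p_fdr[k]
  }
  pairs_df <- data.frame(
    var1 = variables[pairs$i], var2 = variables[pairs$j],
    r = pair_r, p = pair_p, p_fdr = pair_p_fdr,
    n = vapply(seq_len(nrow(pairs)), function(k) {
      sum(complete.cases(data[[variables[pairs$i[k]]]],
                         data[[variables[pairs$j[k]]]]))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  structure(list(variables = variables, r = r, p = p, p_fdr = p_fdr,
                 pairs = pairs_df), class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, digits = 3, ...) {
  cat(sprintf("<correlation_table> %d variables, %d pairs (%d with p < 0.05 uncorrected, %d after FDR)\n",
              length(x$variables), nrow(x$pairs),
              sum(x$pairs$p < 0.05, na.rm = TRUE),
              sum(x$pairs$p_fdr < 0.05, na.rm = TRUE)))
  print(round(x$r, digits))
  invisible(x)
}
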