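# Two-way ANOVA mean squares of an n x k ratings matrix.
ratings_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  list(
    msr = ss_rows / (n - 1),          # between subjects
    msc = ss_cols / (k - 1),          # between raters
    mse = ss_err / ((n - 1) * (k - 1)),
    n = n, k = k
  )
}

#' Intraclass correlation coefficient
#'
#' Single-measures ICC from the two-way ANOVA decomposition of an
#' n-subjects x k-raters table. The default model is two-way random
#' effects, absolute agreement — ICC(2,1) — appropriate for interrater
#' reliability of continuous kinematic measures; two-way mixed,
#' consistency — ICC(3,1) — is selectable for intrarater analysis. The 95%
#' confidence interval uses the standard F-based formulas for the chosen
#' model, and the point estimate is classified with [classify_icc()].
#'
#' @param table Data frame or matrix of ratings, n subjects (rows) x k
#'   raters or rating occasions (columns), no NAs, n >= 2, k >= 2. A long
#'   data frame with columns `subject`, `rater`, `value` is also accepted.
#' @param model `"two_way_random_absolute"` (ICC(2,1), default) or
#'   `"two_way_mixed_consistency"` (ICC(3,1)).
#' @param conf_level Confidence level, default 0.95.
#' @return List of class `icc_result`: `icc`, `ci_low`, `ci_high`, `model`,
#'   `category`, `n`, `k`, and the mean squares `msr`, `msc`, `mse`.
#' @export
icc <- function(table,
                model = c("two_way_random_absolute", "two_way_mixed_consistency"),
                conf_level = 0.95) {
  model <- match.arg(model)
  if (is.data.frame(table) && all(c("subject", "rater", "value") %in% names(table))) {
    wide <- tidyr::pivot_wider(table[, c("subject", "rater", "value")],
                               names_from = "rater", values_from = "value")
    m <- as.matrix(wide[, -1, drop = FALSE])
  } else {
    m <- as.matrix(table)
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("ratings table must have no NAs")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  if (sum((m - mean(m))^2) == 0) stop("degenerate ratings: zero total variance")
  ms <- ratings_mean_squares(m)
  alpha <- 1 - conf_level
  with(ms, {
    if (model == "two_way_random_absolute") {
      est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
      # Satterthwaite df for the absolute-agreement interval
      a <- k * est / (n * (1 - est))
      b <- 1 + k * est * (n - 1) / (n * (1 - est))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f_l <- stats::qf(1 - alpha / 2, n - 1, v)
      f_u <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - f_l * mse) /
        (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (f_u * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    } else {
      est <- (msr - mse) / (msr + (k - 1) * mse)
      fo <- msr / mse
      f_l <- fo / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      f_u <- fo * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      lo <- (f_l - 1) / (f_l + k - 1)
      hi <- (f_u - 1) / (f_u + k - 1)
    }
    structure(
      list(icc = est, ci_low = min(lo, est), ci_high = max(hi, est),
           model = model, category = classify_icc(est),
           n = n, k = k, msr = msr, msc = msc, mse = mse,
           conf_level = conf_level),
      class = "icc_result"
    )
  })
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC = %.4f [%.4f, %.4f] (%s, %s agreement), n = %d, k = %d\n",
              x$icc, x$ci_low, x$ci_high, x$model, x$category, x$n, x$k))
  invisible(x)
}

#' Classify an ICC value
#'
#' Agreement is excellent above 0.75, good from 0.60 through 0.75, moderate
#' from 0.40 up to (but excluding) 0.60, and poor below 0.40. The printed
#' rule requires strictly greater than 0.75 for excellent, so the 0.75
#' boundary itself is good.
#'
#' @param value ICC in \[-1, 1\].
#' @return One of `"excellent"`, `"good"`, `"moderate"`, `"poor"`.
#' @export
classify_icc <- function(value) {
  stopifnot(is.finite(value), value >= -1, value <= 1)
  if (value > 0.75) "excellent"
  else if (value >= 0.60) "good"
  else if (value >= 0.40) "moderate"
  else "poor"
}

#' Pearson correlation with significance test
#'
#' Sample Pearson r with a two-sided p-value from the t transform on n - 2
#' degrees of freedom (the conventional reporting threshold is p < 0.05).
#'
#' @param x,y Numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return Tibble with columns `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in input")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bland-Altman agreement analysis
#'
#' Differences `measured - reference`: the bias is their mean and the 95%
#' limits of agreement are bias +/- 1.96 times their SD (n - 1
#' denominator). The per-pair (mean, difference) table for the agreement
#' plot is returned alongside.
#'
#' @param measured,reference Numeric vectors of equal length >= 2.
#' @return List of class `bland_altman_result`: `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `n`, and tibble `pairs` (columns `mean`,
#'   `difference`).
#' @export
bland_altman <- function(measured, reference) {
  if (length(measured) != length(reference)) stop("length mismatch")
  if (length(measured) < 2L) stop("need at least 2 pairs")
  d <- measured - reference
  bias <- mean(d)
  sdd <- stats::sd(d)
  structure(
    list(bias = bias,
         loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
         sd_diff = sdd, n = length(d),
         pairs = tibble::tibble(mean = (measured + reference) / 2, difference = d)),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman_result> bias = %.4g, 95%% LoA [%.4g, %.4g], n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}
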