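#' Two-way random-effects intraclass correlation (absolute agreement)
#'
#' Shrout–Fleiss / McGraw–Wong ICC from the two-way ANOVA decomposition of
#' an n-subjects x k-raters score table without replication. With MSR the
#' between-subject, MSC the between-rater and MSE the residual mean
#' square:
#' \deqn{ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}}
#' \deqn{ICC(A,k) = \frac{MSR - MSE}{MSR + (MSC - MSE)/n}}
#' `unit = "single"` gives the reliability of one rater's scores,
#' `unit = "mean_k"` that of the mean of the k raters (the usual choice
#' when the mean rating is the working measurement). 95% confidence
#' intervals use the F-distribution method for the absolute-agreement
#' forms; the mean-rating interval is the single-rating interval pushed
#' through the Spearman–Brown step-up. The computational formula for the
#' two-way mixed-effects absolute-agreement single-rating ICC coincides
#' with the random-effects one, so this one function covers both uses.
#'
#' @param scores numeric matrix or data.frame, n subjects x k raters,
#'   no missing cells, n >= 3, k >= 2.
#' @param unit `"single"` or `"mean_k"`.
#' @param conf confidence level (default 0.95).
#' @return A list with `icc`, `ci` (length-2 vector), `unit`, `n`, `k`,
#'   and the mean squares `msr`, `msc`, `mse`. With zero between-subject
#'   variance the ICC is undefined and returned as `NA` with a diagnostic
#'   attribute.
#' @examples
#' x <- c(9, 8, 7, 6, 5, 4)
#' iccTwoWay(cbind(x, x + 1), unit = "mean_k")$icc
#' @export
iccTwoWay <- function(scores, unit = c("single", "mean_k"), conf = 0.95) {
  unit <- match.arg(unit)
  m <- as.matrix(scores)
  if (any(!is.finite(m))) stop("scores must have no missing cells",
                               call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 3L || k < 2L)
    stop("need at least 3 subjects and 2 raters", call. = FALSE)
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  ssr <- k * sum((rowm - grand)^2)     # subjects
  ssc <- n * sum((colm - grand)^2)     # raters
  sse <- sum((m - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  out <- list(icc = NA_real_, ci = c(NA_real_, NA_real_), unit = unit,
              n = n, k = k, msr = msr, msc = msc, mse = mse)
  denom1 <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (msr <= 0 || denom1 <= 0) {
    attr(out, "diagnostic") <- "zero between-subject variance"
    return(out)
  }
  r1 <- (msr - mse) / denom1
  alpha <- 1 - conf
  if (mse > 0) {
    a <- (k * r1) / (n * (1 - r1))
    b <- 1 + (k * r1 * (n - 1)) / (n * (1 - r1))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  } else {
    lo <- hi <- 1  # perfect agreement: degenerate interval
  }
  if (unit == "single") {
    out$icc <- r1
    out$ci <- c(lo, hi)
  } else {
    sb <- function(r) k * r / (1 + (k - 1) * r)
    out$icc <- (msr - mse) / (msr + (msc - mse) / n)
    out$ci <- c(sb(lo), sb(hi))
  }
  out
}

#' Bland–Altman limits of agreement
#'
#' Summary of the paired differences `x - y` between two measurement
#' methods (here oriented human minus automated): their mean (systematic
#' bias), sample standard deviation (n - 1 denominator) and the limits of
#' agreement, mean ± 1.96 SD, within which 95% of differences are expected
#' to fall.
#'
#' @param x,y equal-length numeric vectors (length >= 2) of paired
#'   measurements.
#' @return A list with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `n`.
#' @examples
#' blandAltman(c(1, 2, 3), c(1.2, 1.9, 3.1))
#' @export
blandAltman <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2L)
    stop("need at least 2 paired measurements", call. = FALSE)
  d <- x - y
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       n = length(d))
}
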