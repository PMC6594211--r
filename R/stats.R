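#' Paired-sample t test
#'
#' Implemented at formula level: with differences \eqn{d = x - y},
#' \eqn{t = \bar d / (s_d / \sqrt n)} with the sample SD and a two-sided
#' p-value from the Student t distribution with \eqn{n - 1} degrees of
#' freedom.
#'
#' @param x,y paired numeric vectors of equal length, \eqn{n \ge 2}.
#' @return list of class \code{paired_t_result}: \code{n},
#'   \code{mean_difference}, \code{t}, \code{df}, \code{p_value}.
#' @export
#' @examples
#' paired_t_test(c(2, 4, 6), c(1, 2, 3))  # d = 1,2,3: t = 3.4641, df 2
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired t test needs equal-length vectors")
  ok <- !is.na(x) & !is.na(y)
  d <- (x - y)[ok]
  n <- length(d)
  if (n < 2) stop("paired t test needs at least 2 complete pairs")
  sd_d <- sqrt(sum((d - mean(d))^2) / (n - 1))
  if (sd_d == 0) stop("zero variance of paired differences: t undefined")
  t_stat <- mean(d) / (sd_d / sqrt(n))
  out <- list(n = n, mean_difference = mean(d), t = t_stat, df = n - 1L,
              p_value = 2 * stats::pt(-abs(t_stat), df = n - 1))
  class(out) <- "paired_t_result"
  out
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf(
    "<paired_t_result> n=%d, mean diff %.4f, t=%.4f (df %d), p=%.3g\n",
    x$n, x$mean_difference, x$t, x$df, x$p_value))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Computed directly from sums of centred cross-products; the two-sided
#' p-value uses the t transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with
#' \eqn{n - 2} degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, \eqn{n \ge 3}.
#' @return list of class \code{correlation_result}: \code{n}, \code{r},
#'   \code{r_squared}, \code{p_value}.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("correlation needs equal-length vectors")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("correlation needs at least 3 complete pairs")
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2)
  if (sxx == 0 || syy == 0) stop("zero variance: correlation undefined")
  r <- sum(xc * yc) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  out <- list(n = n, r = r, r_squared = r^2, p_value = p)
  class(out) <- "correlation_result"
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> n=%d, r=%.4f (R2=%.3f), p=%.3g\n",
              x$n, x$r, x$r_squared, x$p_value))
  invisible(x)
}
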