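# Group statistics implemented from first principles (auditable formulas);
# tests cross-check them against stats::cor and stats::t.test.

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks), computed by
#' formula. With only 6 contacts per hemisphere the coefficient is coarse but
#' exact. When either input has zero variance in ranks (all values tied) the
#' coefficient is undefined: `NA` is returned with a warning and an
#' `undefined` attribute.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation coefficient in \[-1, 1\], or flagged `NA`.
#' @examples
#' spearman_rho(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) {
    warning("zero variance in ranks; Spearman correlation undefined")
    return(structure(NA_real_, undefined = TRUE))
  }
  sum(dx * dy) / (sx * sy)
}

#' One-sample t test
#'
#' `t = (mean(x) - mu0) / (sd(x) / sqrt(n))`, df = n - 1, two-sided p-value
#' from the t distribution. A degenerate sample in which every value equals
#' `mu0` exactly carries no evidence either way and is reported as t = 0,
#' p = 1; zero variance around any other mean is an error.
#'
#' @param x Numeric vector, length >= 2.
#' @param mu0 Null mean.
#' @return Object of class `group_test`: list with `statistic`, `df`, `p`,
#'   `mean`, `sem`.
#' @examples
#' one_sample_t(c(1, 2, 3))
#' @export
one_sample_t <- function(x, mu0 = 0) {
  if (anyNA(x)) stop("missing values not allowed")
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  s <- stats::sd(x)
  if (s == 0) {
    if (all(x == mu0))
      return(structure(list(statistic = 0, df = n - 1L, p = 1,
                            mean = mu0, sem = 0),
                       class = "group_test"))
    stop("zero variance")
  }
  sem <- s / sqrt(n)
  tval <- (mean(x) - mu0) / sem
  structure(list(statistic = tval, df = n - 1L,
                 p = 2 * stats::pt(-abs(tval), df = n - 1L),
                 mean = mean(x), sem = sem),
            class = "group_test")
}

#' Paired t test
#'
#' [one_sample_t()] applied to the paired differences `a - b` with `mu0 = 0`.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return A `group_test` object.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  one_sample_t(a - b, mu0 = 0)
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g (mean = %.3f, SEM = %.3f)\n",
              x$df, x$statistic, x$p, x$mean, x$sem))
  invisible(x)
}
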