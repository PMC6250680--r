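#' Two-sided Fisher's exact test for a 2x2 contingency table
#'
#' Exact test of association in a 2x2 table of non-negative integer counts
#' (rows = groups, columns = outcome classes, e.g. skipping vs inclusion
#' reads). The two-sided p-value follows the probability rule: it is the sum
#' of hypergeometric probabilities, over all tables with the observed
#' margins, of tables whose probability does not exceed that of the observed
#' table. The reported odds ratio is the sample odds ratio `(a*d)/(b*c)`,
#' with `Inf` when `b*c == 0`.
#'
#' @param table A 2x2 matrix of counts, or a numeric vector `c(a, b, c, d)`
#'   read row-wise.
#' @return A list with components `odds_ratio`, `p.value`.
#' @examples
#' fisher_exact_two_sided(matrix(c(10, 1, 1, 10), 2, byrow = TRUE))
#' @export
fisher_exact_two_sided <- function(table) {
  tab <- as_table2x2(table)
  if (sum(tab) == 0) {
    stop("fisher_exact_two_sided: all margins are zero")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  or <- if (b * c_ == 0) Inf else (a * d) / (b * c_)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(odds_ratio = or, p.value = min(p, 1))
}

as_table2x2 <- function(table) {
  x <- as.numeric(table)
  if (length(x) != 4L) {
    stop("expected a 2x2 table (4 counts), got ", length(x), " values")
  }
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
    stop("2x2 table cells must be finite non-negative integers")
  }
  matrix(x, nrow = 2L, ncol = 2L,
         byrow = !is.matrix(table))
}

#' Welch's two-sample t-test on heteroscedastic groups
#'
#' Two-sided unequal-variance t-test, the appropriate comparison when group
#' variances cannot be assumed equal (as for log-transformed reporter-ion
#' ratios). Degenerate zero-variance inputs return documented sentinels
#' rather than raising, so pipeline stages can filter: two identical
#' constant groups give `t = 0, p = 1`; two constant groups with different
#' means give `t = +/-Inf, p = 0`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A list with components `statistic` (t), `df`
#'   (Welch-Satterthwaite degrees of freedom) and `p.value`.
#' @examples
#' welch_test(c(1, 2, 3), c(2, 3, 4))
#' @export
welch_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("welch_test: each group needs at least 2 values")
  }
  if (any(!is.finite(c(x, y)))) {
    stop("welch_test: inputs must be finite")
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    dm <- mean(x) - mean(y)
    if (dm == 0) {
      return(list(statistic = 0, df = length(x) + length(y) - 2, p.value = 1))
    }
    return(list(statistic = sign(dm) * Inf,
                df = length(x) + length(y) - 2, p.value = 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values for multiple testing by the
#' Benjamini-Hochberg step-up procedure; the adjusted values are referred
#' to as q-values throughout the package. Output follows the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order as `p`.
#' @examples
#' benjamini_hochberg(c(0.01, 0.04, 0.03, 0.002))
#' @export
benjamini_hochberg <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("benjamini_hochberg: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
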