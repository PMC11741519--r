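#' @include AllClasses.R
NULL

#' Two-sided Wilcoxon signed-rank test for paired responses
#'
#' Standard paired signed-rank test as used for pre/post antagonist
#' comparisons: zero differences are dropped (flagged), the exact null
#' distribution is used for n <= 25 untied pairs and the normal approximation
#' with continuity correction otherwise. All-tied input returns p = 1 with a
#' flag rather than an error.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list with `p_value`, `statistic` (V), `n_used` (pairs after
#'   dropping zeros) and `flagged`.
#' @export
wilcoxonSignedRank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  keep <- !is.na(d) & d != 0
  n <- sum(keep)
  if (n == 0)
    return(list(p_value = 1, statistic = NA_real_, n_used = 0L,
                flagged = TRUE))
  dd <- d[keep]
  ties <- anyDuplicated(abs(dd)) > 0
  wt <- suppressWarnings(stats::wilcox.test(
    dd, mu = 0, exact = (n <= 25 && !ties), correct = TRUE))
  list(p_value = unname(wt$p.value), statistic = unname(wt$statistic),
       n_used = as.integer(n), flagged = FALSE)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t-distribution approximation
#' \eqn{t = \rho \sqrt{(n - 2) / (1 - \rho^2)}} on n - 2 degrees of freedom.
#' A constant input vector yields NA with a flag.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list with `rho`, `p_value`, `n` and `flagged`.
#' @export
spearmanCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, flagged = TRUE))
  rho <- stats::cor(x, y, method = "spearman")
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, flagged = FALSE)
}
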