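#' Friedman rank test across matched treatments
#'
#' Nonparametric omnibus test for differences among `k` treatments
#' (segmentation methods or mask conditions) observed on the same blocks
#' (cases). Delegates to the tie-corrected rank statistic of
#' `stats::friedman.test`; the p-value comes from the chi-square
#' distribution with `k - 1` degrees of freedom.
#'
#' @param x numeric matrix, blocks (cases) in rows, treatments in
#'   columns; no missing cells, at least 2 rows and 2 columns.
#' @return List with `statistic`, `df`, and `p.value`.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
#' friedman_test(m)$statistic  # 6 for strictly ordered treatments
#' @export
friedman_test <- function(x) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("'x' must have no missing cells")
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need at least 2 blocks and 2 treatments")
  r <- t(apply(x, 1L, rank))
  if (all(r == r[, 1])) {
    # every block fully tied: no evidence of any treatment effect
    return(list(statistic = 0, df = ncol(x) - 1L, p.value = 1))
  }
  ft <- stats::friedman.test(x)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p.value = ft$p.value)
}

#' Wilcoxon signed-rank test (Pratt zero handling)
#'
#' Paired two-sided signed-rank test. Zero differences are handled by the
#' Pratt method: they participate in the ranking of absolute differences
#' and are then discarded from the test statistic. Ties receive average
#' ranks. For up to 25 non-zero differences the p-value is computed by
#' exact enumeration of all sign assignments of the observed ranks;
#' beyond that a normal approximation with tie-corrected variance is
#' used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return List with `statistic` (the positive-rank sum `V`), `p.value`,
#'   `n_nonzero`, and `method` (`"exact"` or `"normal"`).
#' @examples
#' signed_rank_test(2:7, 1:6)$p.value  # 2/64: all six differences positive
#' @export
signed_rank_test <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  d <- x - y
  d <- d[is.finite(d)]
  if (length(d) == 0L) stop("no finite paired differences")
  r <- rank(abs(d))           # Pratt: zeros are ranked ...
  nz <- d != 0
  r <- r[nz]; s <- sign(d[nz])  # ... then dropped from the statistic
  m <- length(r)
  if (m == 0L)
    return(list(statistic = 0, p.value = 1, n_nonzero = 0L, method = "exact"))
  V <- sum(r[s > 0])
  if (m <= 25L) {
    # exact: distribution of the positive-rank sum over all 2^m sign
    # flips, via shift-convolution on doubled ranks (average ranks are
    # multiples of 1/2, so doubled ranks are integers)
    r2 <- as.integer(round(2 * r))
    cnt <- numeric(sum(r2) + 1L)   # cnt[s+1] = #subsets with doubled sum s
    cnt[1] <- 1
    for (ri in r2)
      cnt <- cnt + c(numeric(ri), cnt[seq_len(length(cnt) - ri)])
    sums <- seq_along(cnt) - 1L
    v2 <- round(2 * V)
    tot <- sum(cnt)
    p_ge <- sum(cnt[sums >= v2 - 1e-9]) / tot
    p_le <- sum(cnt[sums <= v2 + 1e-9]) / tot
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (V - mu) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = V, p.value = p, n_nonzero = m, method = method)
}

#' Pairwise post hoc Wilcoxon tests with Bonferroni adjustment
#'
#' Runs [signed_rank_test()] on every pair of treatment columns and
#' multiplies each raw p-value by the number of pairs (capped at 1).
#'
#' @param x numeric matrix, blocks in rows, treatments in columns
#'   (column names label the output).
#' @param alpha significance level for the flags (default 0.05).
#' @return Data frame with one row per pair: `a`, `b`, `p.raw`, `p.adj`,
#'   `significant`.
#' @export
wilcoxon_bonferroni <- function(x, alpha = 0.05) {
  x <- as.matrix(x)
  k <- ncol(x)
  if (k < 2L) stop("need at least 2 treatments")
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("T", seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  res <- data.frame(a = nm[pairs[1, ]], b = nm[pairs[2, ]],
                    p.raw = NA_real_, p.adj = NA_real_,
                    significant = NA)
  for (j in seq_len(m)) {
    p <- signed_rank_test(x[, pairs[1, j]], x[, pairs[2, j]])$p.value
    res$p.raw[j] <- p
    res$p.adj[j] <- min(1, m * p)
  }
  res$significant <- res$p.adj < alpha
  res
}

#' Box-and-whisker summary statistics
#'
#' Five-number summary in the convention of the package's box plots:
#' median, lower and upper quartiles (linear interpolation between order
#' statistics, `stats::quantile` type 7), whiskers at `Q1 - 1.5 IQR` and
#' `Q3 + 1.5 IQR`, and flags for values outside the whiskers (outliers,
#' removed from plots for display).
#'
#' @param values numeric vector with at least one finite value.
#' @return List with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   and logical `outlier` flags aligned with `values`.
#' @examples
#' box_stats(1:8)[c("median", "q1", "q3")]
#' @export
box_stats <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0L) stop("need at least one finite value")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = lo, whisker_high = hi,
       outlier = !is.na(values) & is.finite(values) &
         (values < lo | values > hi))
}
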