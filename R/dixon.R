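# Dixon's gap-to-range ratio test for a single outlier in small samples.
#
# The ratio variant follows the conventional sample-size switching:
#   r10 for n <= 7, r11 for 8-10, r21 for 11-13, r22 for n >= 14.
# The two-sided statistic is the larger of the low-end and high-end ratios;
# its null distribution under normal sampling is tabulated once per sample
# size by Monte Carlo (fixed internal seed, cached for the session) and the
# p-value is the upper-tail probability of the observed statistic.

.dixonCache <- new.env(parent = emptyenv())
.DIXON_NULL_N <- 40000L

dixonVariant <- function(n) {
  if (n <= 7L) "r10" else if (n <= 10L) "r11" else if (n <= 13L) "r21" else "r22"
}

# low-end and high-end ratios for a sorted vector (or row-sorted matrix)
dixonRatios <- function(s) {
  if (is.null(dim(s))) s <- matrix(s, nrow = 1L)
  n <- ncol(s)
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  switch(dixonVariant(n),
    r10 = cbind(low  = safe(s[, 2] - s[, 1], s[, n] - s[, 1]),
                high = safe(s[, n] - s[, n - 1], s[, n] - s[, 1])),
    r11 = cbind(low  = safe(s[, 2] - s[, 1], s[, n - 1] - s[, 1]),
                high = safe(s[, n] - s[, n - 1], s[, n] - s[, 2])),
    r21 = cbind(low  = safe(s[, 3] - s[, 1], s[, n - 1] - s[, 1]),
                high = safe(s[, n] - s[, n - 2], s[, n] - s[, 2])),
    r22 = cbind(low  = safe(s[, 3] - s[, 1], s[, n - 2] - s[, 1]),
                high = safe(s[, n] - s[, n - 2], s[, n] - s[, 3])))
}

# Monte-Carlo null distribution of the two-sided statistic, cached per n
dixonNull <- function(n) {
  key <- as.character(n)
  if (!is.null(.dixonCache[[key]])) return(.dixonCache[[key]])
  null <- withSeed(1000000L + n, {
    x <- matrix(stats::rnorm(.DIXON_NULL_N * n), .DIXON_NULL_N, n)
    s <- t(apply(x, 1L, sort.int, method = "quick"))
    r <- dixonRatios(s)
    sort.int(pmax(r[, "low"], r[, "high"]), method = "quick")
  })
  .dixonCache[[key]] <- null
  null
}

dixonInapplicable <- function(msg) {
  stop(errorCondition(msg, class = c("dixonInapplicable", "error")))
}

#' Dixon's two-sided single-outlier test
#'
#' Tests whether the most extreme value of a small sample (3 <= n <= 30) is
#' an outlier, using the gap-to-range ratio variant appropriate to the
#' sample size (r10 up to n = 7, r11 for 8-10, r21 for 11-13, r22 beyond).
#' The candidate is whichever of the minimum and maximum has the larger
#' ratio (ties resolved toward the maximum); the reported p-value is
#' two-sided, i.e. the null probability that the larger of the two end
#' ratios exceeds the observed statistic under normal sampling.
#'
#' @param values Numeric vector, `3 <= length(values) <= 30`, not all equal.
#' @return A list with `qStatistic`, `pValue`, `candidateIndex` (position
#'   of the candidate in `values`), and `variant`.
#' @section Inapplicable inputs: fewer than 3 (or more than 30) values, or
#'   all values equal, signal a condition of class `dixonInapplicable`;
#'   callers such as [removeOutliers()] then skip outlier removal for that
#'   feature.
#' @examples
#' dixonTest(c(0.10, 0.15, 0.16, 0.18, 0.20, 0.21, 0.90))
#' @export
dixonTest <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L || n > 30L)
    dixonInapplicable(sprintf("Dixon's test requires 3 <= n <= 30 (got %d)", n))
  if (max(values) == min(values))
    dixonInapplicable("Dixon's test is undefined for all-equal values")
  s <- sort(values)
  r <- dixonRatios(s)
  q <- max(r)
  candidate <- if (r[, "high"] >= r[, "low"]) which.max(values) else which.min(values)
  null <- dixonNull(n)
  p <- (sum(null >= q - 1e-12) + 1) / (length(null) + 1)
  list(qStatistic = unname(q), pValue = min(p, 1),
       candidateIndex = unname(candidate), variant = dixonVariant(n))
}
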