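# Intersection-hypothesis (local) tests used inside closed testing.

#' Fisher combination p-value
#'
#' Combines `k` independent p-values into one via Fisher's method: the
#' statistic \eqn{-2 \sum_j \log p_j} is referred to a chi-square distribution
#' with \eqn{2k} degrees of freedom. Log-space summation keeps the statistic
#' finite for very small inputs.
#'
#' @param p numeric vector of p-values in `(0, 1]`; exact zeros are clamped to
#'   `floor` with a warning.
#' @param floor clamping value for zero p-values.
#' @return The combined upper-tail p-value.
#' @examples
#' fisher_pvalue(0.5)          # one p-value: unchanged
#' fisher_pvalue(c(0.1, 0.1))  # 0.056053
#' @export
fisher_pvalue <- function(p, floor = 1e-300) {
  if (length(p) == 0L) stop("empty p-value collection")
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("zero p-value(s) clamped to ", floor)
    p[p == 0] <- floor
  }
  stat <- -2 * sum(log(p))
  stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
}

#' Simes intersection test
#'
#' Rejects the intersection hypothesis of `k` p-values when
#' \eqn{\min_j k\, p_{(j)} / j \le} `level`. Provided as an alternative local
#' test; the Simes p-value itself is `min_j k p_(j)/j`.
#'
#' @param p numeric vector of p-values.
#' @param level significance level in `(0, 1)`.
#' @return `TRUE` if the intersection hypothesis is rejected.
#' @export
simes_reject <- function(p, level) {
  if (length(level) != 1L || is.na(level) || level <= 0 || level >= 1)
    stop("'level' must lie in (0, 1)")
  if (length(p) == 0L) stop("empty p-value collection")
  ps <- sort(p)
  k <- length(ps)
  min(k * ps / seq_len(k)) <= level
}

#' Two-sample t-test p-values for a feature matrix
#'
#' Equal-variance two-sample t-tests of each feature (column) against a binary
#' response, vectorised across features. Features with zero pooled variance
#' get p = 1 with a warning.
#'
#' @param x numeric matrix, `n` samples by `w` features.
#' @param y binary response of length `n` (two nonempty groups).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (alternatives refer to the mean of the `y == levels[2]` group minus the
#'   first).
#' @return Named vector of `w` p-values (names from `colnames(x)`).
#' @export
two_sample_t_pvalues <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(y) != n) stop("'y' must have one entry per row of 'x'")
  g <- as.integer(factor(y))
  if (length(unique(g[!is.na(g)])) != 2L) stop("'y' must define exactly two groups")
  if (n < 4L) stop("need at least 4 samples")
  i1 <- g == 1L; i2 <- g == 2L
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 1L || n2 < 1L) stop("both response groups must be nonempty")
  m1 <- colMeans(x[i1, , drop = FALSE]); m2 <- colMeans(x[i2, , drop = FALSE])
  ss1 <- colSums(sweep(x[i1, , drop = FALSE], 2, m1)^2)
  ss2 <- colSums(sweep(x[i2, , drop = FALSE], 2, m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m2 - m1) / se
  p <- switch(alternative,
    two.sided = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
    greater   = stats::pt(tstat, df, lower.tail = FALSE),
    less      = stats::pt(tstat, df, lower.tail = TRUE))
  degenerate <- !is.finite(tstat)
  if (any(degenerate)) {
    warning(sum(degenerate), " feature(s) with zero pooled variance; p set to 1")
    p[degenerate] <- 1
  }
  names(p) <- colnames(x)
  p
}
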