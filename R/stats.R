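# Cohort statistics: Lilliefors normality testing (Monte-Carlo p-values),
# two-sample t-tests (raw data and summary statistics), Wilcoxon rank-sum
# with exact small-sample enumeration, simple linear regression, and the
# normality-gated two-group comparison used for every force-ratio metric.

.testResult <- function(statistic, df, p, method, note = NULL) {
  structure(list(statistic = statistic, df = df, p = p, method = method,
                 note = note), class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g\n", x$method, x$statistic,
              if (!is.null(x$df) && !is.na(x$df))
                sprintf(", df = %.3g", x$df) else "", x$p))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

# Lilliefors (KS-against-fitted-normal) statistic for one sorted sample.
.lillieforsStat <- function(x) {
  n <- length(x)
  xs <- sort(x)
  z <- (xs - mean(xs)) / stats::sd(xs)
  Fz <- stats::pnorm(z)
  i <- seq_len(n)
  max(max(i / n - Fz), max(Fz - (i - 1) / n))
}

# Cached Monte-Carlo null distributions of the Lilliefors statistic, keyed
# by (n, nMc, seed): the null depends only on the sample size.
.lillieforsCache <- new.env(parent = emptyenv())

.lillieforsNull <- function(n, nMc, seed) {
  key <- paste(n, nMc, seed, sep = "_")
  if (!is.null(.lillieforsCache[[key]])) return(.lillieforsCache[[key]])
  D0 <- .withSeed(seed, {
    m <- matrix(stats::rnorm(nMc * n), nMc, n)
    m <- t(apply(m, 1L, sort))
    mu <- rowMeans(m)
    sdv <- sqrt(rowSums((m - mu)^2) / (n - 1))
    z <- (m - mu) / sdv
    Fz <- stats::pnorm(z)
    i <- matrix(seq_len(n), nMc, n, byrow = TRUE)
    pmax(apply(i / n - Fz, 1L, max), apply(Fz - (i - 1) / n, 1L, max))
  })
  .lillieforsCache[[key]] <- D0
  D0
}

#' Lilliefors normality test with Monte-Carlo p-value
#'
#' Kolmogorov-Smirnov statistic of the sample against a normal
#' distribution with mean and SD estimated from the sample itself; the
#' p-value comes from a seeded Monte-Carlo null (standard-normal samples
#' of the same size) rather than table interpolation. Null distributions
#' are cached per sample size, so repeated calls (e.g. inside cohort
#' simulations) cost one statistic evaluation each. The statistic is
#' invariant under affine transforms of the data.
#'
#' @param x numeric sample, n >= 4, not constant.
#' @param nMc Monte-Carlo replicates (default 10000).
#' @param seed RNG seed for the null simulation.
#' @return a `TestResult`.
#' @export
lillieforsTest <- function(x, nMc = 10000L, seed = 20170607L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) stop("Lilliefors test needs at least 4 observations")
  if (stats::sd(x) == 0) stop("Lilliefors test undefined for a constant sample")
  D <- .lillieforsStat(x)
  D0 <- .lillieforsNull(n, nMc, seed)
  p <- (1 + sum(D0 >= D)) / (nMc + 1)
  .testResult(D, NA_real_, p, "lilliefors")
}

#' Two-sample t-test
#'
#' Pooled-variance Student (default; df = n1 + n2 - 2) or Welch variant,
#' always two-sided.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param variant "pooled" or "welch".
#' @return a `TestResult`.
#' @export
ttestTwoSample <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(x) == 0 && stats::var(y) == 0 && variant == "pooled" &&
      mean(x) != mean(y))
    stop("zero pooled variance with distinct means: t undefined")
  ht <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  .testResult(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              if (variant == "pooled") "pooled-t" else "welch-t")
}

#' Two-sample t-test from summary statistics
#'
#' Identical formulas to [ttestTwoSample()] applied to sufficient
#' statistics (group means, SDs and sizes), as needed to re-analyze
#' published mean +/- SD summaries.
#'
#' @param m1,s1,n1 mean, SD and size of the first group.
#' @param m2,s2,n2 mean, SD and size of the second group.
#' @param variant "pooled" or "welch".
#' @return a `TestResult`.
#' @export
ttestFromSummary <- function(m1, s1, n1, m2, s2, n2,
                             variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2L, n2 >= 2L)
  if (s1 == 0 && s2 == 0 && m1 != m2)
    stop("both SDs are zero with distinct means: t undefined")
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    a <- s1^2 / n1; b <- s2^2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  .testResult(t, df, p, if (variant == "pooled") "pooled-t" else "welch-t")
}

#' Wilcoxon rank-sum test
#'
#' Exact permutation p-value by full enumeration of rank assignments when
#' n1 + n2 <= 12 (valid with ties via midranks); normal approximation with
#' tie correction otherwise. Two-sided throughout; p-values are invariant
#' under monotone transforms of the data.
#'
#' @param x,y numeric samples (each n >= 2).
#' @return a `TestResult`.
#' @export
wilcoxonRanksum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2L, n2 >= 2L)
  if (n1 + n2 <= 12L) {
    r <- rank(c(x, y))
    wObs <- sum(r[seq_len(n1)])
    combos <- utils::combn(n1 + n2, n1)
    wAll <- colSums(matrix(r[combos], nrow = n1))
    pLo <- mean(wAll <= wObs + 1e-9)
    pHi <- mean(wAll >= wObs - 1e-9)
    p <- min(1, 2 * min(pLo, pHi))
    .testResult(wObs - n1 * (n1 + 1) / 2, NA_real_, p,
                "wilcoxon", note = "exact enumeration")
  } else {
    ht <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    .testResult(unname(ht$statistic), NA_real_, ht$p.value,
                "wilcoxon", note = "normal approximation")
  }
}

#' Simple linear regression of a response on one covariate
#'
#' Ordinary least squares; r-squared equals the squared Pearson
#' correlation and the p-value is the slope's two-sided t-test.
#'
#' @param x covariate (not constant), n >= 3.
#' @param y response.
#' @return a `RegressionResult`: slope, intercept, r2, p, n.
#' @export
linearRegression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n >= 3L, length(y) == n)
  if (stats::sd(x) == 0) stop("covariate is constant: regression undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = sm$r.squared,
                 p = sm$coefficients[2L, 4L], n = n),
            class = "RegressionResult")
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat(sprintf("linear regression (n = %d): slope %.4g, r^2 = %.4f, p = %.4g\n",
              x$n, x$slope, x$r2, x$p))
  invisible(x)
}

#' Normality-gated two-group comparison
#'
#' Runs the Lilliefors test within each group; when both groups are
#' compatible with normality (p > `alphaNormality` in both) the groups are
#' compared with a pooled-variance t-test, otherwise with the Wilcoxon
#' rank-sum test. Subjects with an undefined metric (e.g. E-wave-specific
#' ratios in a subject whose E-wave could not be delineated) are dropped
#' from that comparison only. The route taken is recorded.
#'
#' @param table data.frame with a `group` column (exactly two levels) and
#'   the metric column.
#' @param metric name of the metric column.
#' @param alphaNormality normality-gate level (default 0.05).
#' @param groupCol name of the group column (default "group").
#' @return a `TestResult` whose `method` records the route.
#' @export
compareGroups <- function(table, metric, alphaNormality = 0.05,
                          groupCol = "group") {
  stopifnot(is.data.frame(table), metric %in% names(table),
            groupCol %in% names(table))
  gl <- sort(unique(as.character(table[[groupCol]])))
  if (length(gl) != 2L)
    stop("exactly two group labels are required, found: ",
         paste(gl, collapse = ", "), call. = FALSE)
  x <- table[[metric]][table[[groupCol]] == gl[1L]]
  y <- table[[metric]][table[[groupCol]] == gl[2L]]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 4L || length(y) < 4L)
    stop("need >= 4 defined values per group for the normality gate",
         call. = FALSE)
  # degenerate (constant) groups cannot be normality-tested or t-tested:
  # route them to the rank test
  normal <- stats::sd(x) > 0 && stats::sd(y) > 0 &&
    lillieforsTest(x)$p > alphaNormality &&
    lillieforsTest(y)$p > alphaNormality
  res <- if (normal) ttestTwoSample(x, y, "pooled") else wilcoxonRanksum(x, y)
  res$note <- sprintf("route: %s (%s vs %s, n = %d vs %d)",
                      if (normal) "pooled t-test" else "wilcoxon rank-sum",
                      gl[1L], gl[2L], length(x), length(y))
  res
}

#' Group summary in the conventional reporting format
#'
#' Mean +/- SD for metrics compatible with normality, median (range)
#' otherwise (gate: Lilliefors at `alphaNormality`).
#'
#' @param x numeric sample.
#' @param alphaNormality normality-gate level.
#' @return character summary.
#' @export
summarizeGroup <- function(x, alphaNormality = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return("NA")
  if (length(x) == 1L || stats::sd(x) == 0)
    return(sprintf("%.3g ± 0", mean(x)))
  if (length(x) >= 4L && lillieforsTest(x)$p > alphaNormality)
    sprintf("%.3g ± %.3g", mean(x), stats::sd(x))
  else
    sprintf("%.3g (%.3g)", stats::median(x), diff(range(x)))
}
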