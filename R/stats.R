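#' Exact McNemar test on discordant pair counts
#'
#' Exact two-sided binomial McNemar test for paired binary classifications:
#' conditional on the number of discordant pairs `b + c`, the smaller
#' discordant count is referred to Binomial(b + c, 1/2), and the two-sided
#' p-value is `min(1, 2 * P(X <= min(b, c)))`. When there are no
#' discordant pairs the p-value is 1.
#'
#' The exact version is used (rather than the chi-square approximation with
#' continuity correction) because it is well defined at the small
#' discordant counts typical of reclassification analyses.
#'
#' @param b count of pairs discordant in one direction (e.g.
#'   pathological before, normal after).
#' @param c count discordant in the other direction.
#' @return the exact two-sided p-value.
#' @examples
#' mcnemar_exact(9, 2)   # ~0.065
#' @export
mcnemar_exact <- function(b, c) {
  if (length(b) != 1L || length(c) != 1L || b < 0 || c < 0 ||
      b != round(b) || c != round(c))
    stop("`b` and `c` must be single non-negative integer counts")
  n <- b + c
  if (n == 0) return(1)
  min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
}

#' Two-sided F test for equality of variances
#'
#' Ratio of sample variances referred to the F distribution (the classical
#' variance-ratio test for normally distributed data). Wraps
#' [stats::var.test()] with explicit degenerate-input errors.
#'
#' @param x,y numeric samples, each with at least 2 values and nonzero
#'   variance.
#' @return two-sided p-value.
#' @export
f_test_variance <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 values")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero-variance sample: the F test is undefined")
  stats::var.test(x, y)$p.value
}

#' Rank-based (non-parametric) Levene test for equality of spread
#'
#' Levene's test computed on the rank-transformed pooled data with median
#' centering (a Brown-Forsythe test on ranks): pool the two samples, rank
#' them, take absolute deviations of each group's ranks from the group
#' median rank, and compare group means of those deviations by one-way
#' ANOVA, F(1, n - 2). Being rank-based, the test is invariant to strictly
#' monotone transformations of the pooled data.
#'
#' @param x,y numeric samples, each with at least 3 values.
#' @return two-sided p-value.
#' @export
levene_rank <- function(x, y) {
  if (length(x) < 3L || length(y) < 3L)
    stop("each sample needs at least 3 values")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    stop("all observations tied: spread test is undefined")
  r <- rank(pooled)
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  out <- car::leveneTest(r, g, center = stats::median)
  p <- out[["Pr(>F)"]][1L]
  if (!is.finite(p)) stop("degenerate data: Levene statistic undefined")
  p
}

#' Intra-class correlation, two-way mixed, absolute agreement, single
#' measures
#'
#' ICC for agreement between two repeated ratings of the same subjects
#' (e.g. intra- or inter-observer variability), from the standard two-way
#' ANOVA decomposition: with `MSR` the between-subject, `MSC` the
#' between-rater and `MSE` the error mean squares over `n` subjects and
#' `k = 2` raters,
#' \deqn{ICC = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}}
#' Negative values are possible and returned unclamped.
#'
#' @param ratings numeric n x 2 matrix: one row per subject, one column per
#'   rating.
#' @return the ICC (single number).
#' @export
icc_absolute_single <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) != 2L) stop("`ratings` must have exactly 2 columns")
  n <- nrow(ratings)
  if (n < 3L) stop("need at least 3 subjects")
  if (stats::var(as.vector(ratings)) == 0)
    stop("constant ratings: ICC is undefined")
  k <- 2L
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom == 0) stop("degenerate ratings: ICC denominator is zero, undefined")
  (msr - mse) / denom
}

#' Kolmogorov-Smirnov normality gate
#'
#' One-sample KS test of the sample against a normal distribution with the
#' sample's own mean and SD; labels the sample `"normal"` when p >= 0.05.
#' The gate routes downstream test choice: F test and t tests for normal
#' data, rank-based Levene / Mann-Whitney / Wilcoxon otherwise. Estimating
#' the parameters from the sample makes the gate conservative (prone to
#' calling data normal), as is typical of clinical software.
#'
#' @param x numeric sample, n >= 5.
#' @param alpha gate level.
#' @return `"normal"` or `"non-normal"`.
#' @export
ks_normality_gate <- function(x, alpha = 0.05) {
  if (length(x) < 5L) stop("need at least 5 observations")
  if (stats::sd(x) == 0) return("non-normal")
  p <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  if (p >= alpha) "normal" else "non-normal"
}

#' Normality-gated two-sample location test
#'
#' Dispatches the location comparison the normality gate calls for:
#' paired or unpaired t test when both samples (the differences, if paired)
#' gate as normal; Wilcoxon signed-rank (paired) or Mann-Whitney U
#' (unpaired) otherwise. Two-sided throughout. Identical paired samples
#' (all differences zero) return p = 1.
#'
#' @param x,y numeric samples; equal length when `paired`.
#' @param paired paired comparison?
#' @param gate `"auto"` (apply [ks_normality_gate()]), `"normal"` or
#'   `"non-normal"`.
#' @return list with `p.value`, `test` (the test dispatched), `gate`.
#' @export
location_tests <- function(x, y, paired = FALSE, gate = "auto") {
  if (paired && length(x) != length(y))
    stop("paired samples must have equal length")
  gate <- match.arg(gate, c("auto", "normal", "non-normal"))
  if (gate == "auto") {
    gate <- if (paired) ks_normality_gate(x - y)
    else if (ks_normality_gate(x) == "normal" &&
             ks_normality_gate(y) == "normal") "normal" else "non-normal"
  }
  if (paired && all(x == y))
    return(list(p.value = 1, test = "degenerate (all differences zero)",
                gate = gate))
  if (gate == "normal") {
    ht <- stats::t.test(x, y, paired = paired)
    test <- if (paired) "paired t-test" else "unpaired t-test"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, paired = paired))
    test <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney U"
  }
  list(p.value = ht$p.value, test = test, gate = gate)
}

#' Median-dichotomized precision screen over patient characteristics
#'
#' For each covariate, subjects are dichotomized at the covariate median
#' (ties go to the low group), and the variability of the outcome (e.g.
#' corrected Qp/Qs) is compared between the high and low groups with the
#' normality-gated spread test: the F test when both groups gate as
#' normal, the rank-based Levene test otherwise. Significance is assessed
#' at the Bonferroni-corrected level `alpha / m`; with the defaults
#' `m = 20`, `alpha = 0.05` the threshold is p < 0.0025.
#'
#' @param data data.frame of subjects.
#' @param outcome name of the numeric outcome column.
#' @param covariates character vector of covariate column names (numeric or
#'   binary); defaults to every column except the outcome.
#' @param m number of comparisons assumed for the Bonferroni correction.
#' @param alpha family-wise significance level.
#' @return data.frame with one row per covariate: group sizes, the test
#'   dispatched, p-value, and the Bonferroni flag; skipped covariates carry
#'   `NA` and a warning. The Bonferroni threshold is in
#'   `attr(, "threshold")`.
#' @export
covariate_precision_screen <- function(data, outcome, covariates = NULL,
                                       m = 20L, alpha = 0.05) {
  if (m < 1L) stop("`m` must be >= 1")
  if (!outcome %in% names(data)) stop("outcome column not found")
  if (is.null(covariates)) covariates <- setdiff(names(data), outcome)
  yout <- data[[outcome]]
  threshold <- alpha / m
  rows <- lapply(covariates, function(cv) {
    v <- data[[cv]]
    if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v))
    if (is.logical(v)) v <- as.numeric(v)
    hi <- v > stats::median(v)           # ties to the low group
    ylo <- yout[!hi]; yhi <- yout[hi]
    if (sum(hi) < 3L || sum(!hi) < 3L) {
      warning(sprintf("covariate '%s' skipped: fewer than 3 subjects per group", cv))
      return(data.frame(covariate = cv, n_low = sum(!hi), n_high = sum(hi),
                        test = NA_character_, p.value = NA_real_,
                        significant = NA))
    }
    gate_ok <- ks_normality_gate(ylo) == "normal" &&
      ks_normality_gate(yhi) == "normal"
    p <- if (gate_ok) f_test_variance(ylo, yhi) else levene_rank(ylo, yhi)
    data.frame(covariate = cv, n_low = sum(!hi), n_high = sum(hi),
               test = if (gate_ok) "F" else "rank-Levene", p.value = p,
               significant = p < threshold)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  out
}

#' Summarize reclassification of paired before/after labels
#'
#' Builds the 2x2 paired-classification table behind the McNemar test:
#' labels other than `"normal"` count as pathological. Reports the counts
#' `a` (normal before and after), `b` (pathological before, normal after),
#' `c` (normal before, pathological after), `d` (pathological both),
#' the pathological proportions before and after as rounded integer
#' percentages, the fraction of initially pathological subjects normalized
#' by correction, and the exact McNemar p-value.
#'
#' @param before,after equal-length classification vectors (character
#'   labels, with `"normal"` vs anything else, or logical pathological
#'   flags).
#' @return list of class `reclassification_summary`: `n`, counts
#'   `a`, `b`, `c`, `d`, `pct_pathological_before`,
#'   `pct_pathological_after` (integer percent), `normalized_fraction`
#'   (`NA` when no subject was pathological before), `pct_normalized`,
#'   `p_mcnemar`.
#' @examples
#' before <- rep(c("left-to-right", "normal"), c(16, 75))
#' after <- c(rep(c("left-to-right", "normal"), c(7, 9)),
#'            rep(c("left-to-right", "normal"), c(2, 73)))
#' reclassification_summary(before, after)
#' @export
reclassification_summary <- function(before, after) {
  if (length(before) != length(after))
    stop("`before` and `after` must have equal length")
  path_b <- if (is.logical(before)) before else before != "normal"
  path_a <- if (is.logical(after)) after else after != "normal"
  n <- length(path_b)
  a <- sum(!path_b & !path_a)
  b <- sum(path_b & !path_a)
  cc <- sum(!path_b & path_a)
  d <- sum(path_b & path_a)
  norm_frac <- if (sum(path_b) > 0) b / sum(path_b) else NA_real_
  structure(
    list(n = n, a = a, b = b, c = cc, d = d,
         pct_pathological_before = round(100 * sum(path_b) / n),
         pct_pathological_after = round(100 * sum(path_a) / n),
         normalized_fraction = norm_frac,
         pct_normalized = if (is.na(norm_frac)) NA_real_
         else round(100 * norm_frac),
         p_mcnemar = mcnemar_exact(b, cc)),
    class = "reclassification_summary"
  )
}

#' @export
print.reclassification_summary <- function(x, ...) {
  cat(sprintf("Reclassification over %d subjects\n", x$n))
  cat(sprintf("  pathological: %d%% before -> %d%% after correction\n",
              x$pct_pathological_before, x$pct_pathological_after))
  cat(sprintf("  2x2 counts: a=%d b=%d c=%d d=%d (b,c discordant)\n",
              x$a, x$b, x$c, x$d))
  if (!is.na(x$normalized_fraction))
    cat(sprintf("  normalized among initially pathological: %d%%\n",
                x$pct_normalized))
  else cat("  normalized fraction: not applicable (none pathological before)\n")
  cat(sprintf("  exact McNemar p = %.4g\n", x$p_mcnemar))
  invisible(x)
}
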