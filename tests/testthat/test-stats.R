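# full binomial enumeration oracle for the exact McNemar p-value
mcnemar_enum <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  k <- min(b, c)
  min(1, 2 * sum(choose(n, 0:k)) / 2^n)
}

test_that("exact McNemar matches full binomial enumeration and is symmetric", {
  expect_equal(mcnemar_exact(9, 2), 2 * (1 + 11 + 55) / 2048, tolerance = 1e-12)
  expect_equal(mcnemar_exact(10, 0), 2 / 1024, tolerance = 1e-12)
  expect_equal(mcnemar_exact(5, 5), 1)
  expect_equal(mcnemar_exact(0, 0), 1)
  for (b in 0:20) for (cc in 0:20) {
    expect_equal(mcnemar_exact(b, cc), mcnemar_enum(b, cc), tolerance = 1e-12)
    expect_identical(mcnemar_exact(b, cc), mcnemar_exact(cc, b))
  }
  expect_error(mcnemar_exact(-1, 2), "non-negative")
})

test_that("variance F test is symmetric, two-sided, and guards degeneracy", {
  set.seed(8)
  x <- rnorm(30); y <- rnorm(25, sd = 2)
  expect_equal(f_test_variance(x, y), f_test_variance(y, x), tolerance = 1e-12)
  expect_equal(f_test_variance(x, x), 1)
  expect_error(f_test_variance(rep(1, 5), x), "zero-variance")
  expect_error(f_test_variance(1, x), "at least 2")
  # agrees with the explicit F-distribution formula
  fstat <- var(x) / var(y)
  p_manual <- 2 * min(pf(fstat, 29, 24), 1 - pf(fstat, 29, 24))
  expect_equal(f_test_variance(x, y), p_manual, tolerance = 1e-12)
})

test_that("rank Levene matches its manual computation and detects scale shifts", {
  set.seed(5)
  x <- rnorm(20); y <- rnorm(25)
  # manual Brown-Forsythe on ranks
  r <- rank(c(x, y))
  g <- rep(1:2, c(20, 25))
  z <- abs(r - ave(r, g, FUN = median))
  manual_p <- anova(lm(z ~ factor(g)))[["Pr(>F)"]][1]
  expect_equal(levene_rank(x, y), manual_p, tolerance = 1e-10)

  expect_equal(levene_rank(x, x), 1)  # identical samples: statistic 0

  # power: threefold scale difference found in >= 90% of 100 seeds (n = 50)
  hits <- sum(sapply(1:100, function(s) {
    set.seed(1000 + s)
    a <- rnorm(50)
    b <- median(a) + 3 * (rnorm(50) - 0)
    levene_rank(a, b) < 0.05
  }))
  expect_gte(hits, 90)

  # invariance to strictly monotone transforms of the pooled data
  tr <- function(v) exp(v / 2)
  expect_equal(levene_rank(tr(x), tr(y)), levene_rank(x, y), tolerance = 1e-10)
  expect_error(levene_rank(rep(1, 5), rep(1, 6)), "tied")
})

test_that("ICC(2,1) equals a loop-based ANOVA oracle and handles edge cases", {
  icc_oracle <- function(m) {
    n <- nrow(m); k <- ncol(m)
    grand <- mean(m)
    ssr <- 0; ssc <- 0; sse <- 0
    rmeans <- numeric(n); cmeans <- numeric(k)
    for (i in 1:n) rmeans[i] <- mean(m[i, ])
    for (j in 1:k) cmeans[j] <- mean(m[, j])
    for (i in 1:n) ssr <- ssr + k * (rmeans[i] - grand)^2
    for (j in 1:k) ssc <- ssc + n * (cmeans[j] - grand)^2
    for (i in 1:n) for (j in 1:k)
      sse <- sse + (m[i, j] - rmeans[i] - cmeans[j] + grand)^2
    msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
  set.seed(12)
  fixed <- matrix(rnorm(12), 6, 2)
  expect_equal(icc_absolute_single(fixed), icc_oracle(fixed), tolerance = 1e-12)
  for (rep in 1:100) {
    m <- matrix(rnorm(2 * sample(3:12, 1)), ncol = 2)
    expect_equal(icc_absolute_single(m), icc_oracle(m), tolerance = 1e-10)
  }
  # perfect agreement and perfect anti-agreement
  r1 <- rnorm(8)
  expect_equal(icc_absolute_single(cbind(r1, r1)), 1, tolerance = 1e-12)
  anti <- cbind(r1 - mean(r1), -(r1 - mean(r1)))
  expect_lt(icc_absolute_single(anti), 0)
  expect_error(icc_absolute_single(cbind(rep(1, 5), rep(1, 5))), "undefined")
})

test_that("KS gate separates normal from exponential samples", {
  lab_n <- sapply(1:100, function(s) {
    set.seed(s); ks_normality_gate(rnorm(500))
  })
  expect_gte(mean(lab_n == "normal"), 0.95)
  lab_e <- sapply(1:100, function(s) {
    set.seed(s); ks_normality_gate(rexp(500))
  })
  expect_gte(mean(lab_e == "non-normal"), 0.95)
  expect_equal(ks_normality_gate(rep(3, 10)), "non-normal")
  expect_error(ks_normality_gate(c(1, 2)), "at least 5")
})

test_that("gated location tests dispatch correctly and have power", {
  set.seed(3)
  x <- rnorm(40)
  res <- location_tests(x, x, paired = TRUE)
  expect_equal(res$p.value, 1)
  # forced dispatch
  y <- rnorm(40, 1)
  expect_match(location_tests(x, y, gate = "normal")$test, "t-test")
  expect_match(location_tests(x, y, gate = "non-normal")$test, "Mann-Whitney")
  expect_match(location_tests(x, y, paired = TRUE, gate = "non-normal")$test,
               "Wilcoxon")
  expect_error(location_tests(1:4, 1:5, paired = TRUE), "equal length")

  # power: 1 SD shift at n = 50 detected in >= 90% of seeds
  hits <- sum(sapply(1:100, function(s) {
    set.seed(2000 + s)
    location_tests(rnorm(50), rnorm(50, 1))$p.value < 0.05
  }))
  expect_gte(hits, 90)

  # Mann-Whitney branch invariant under monotone transform of pooled data
  set.seed(4)
  a <- rexp(30); b <- rexp(30) * 1.5
  p1 <- location_tests(a, b, gate = "non-normal")$p.value
  p2 <- location_tests(log(a), log(b), gate = "non-normal")$p.value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("covariate screen dichotomizes at the median with Bonferroni flags", {
  set.seed(19)
  n <- 60
  tab <- data.frame(
    qpqs = rnorm(n, 1, 0.05),
    age = sample(20:80, n, TRUE),
    sex = sample(c(0, 1), n, TRUE),
    constant = rep(2, n)
  )
  expect_warning(
    out <- covariate_precision_screen(tab, "qpqs",
                                      c("age", "sex", "constant")),
    "skipped")
  expect_equal(attr(out, "threshold"), 0.0025)
  expect_true(is.na(out$p.value[out$covariate == "constant"]))
  ok <- out[out$covariate != "constant", ]
  expect_true(all(ok$p.value >= 0 & ok$p.value <= 1))
  # ties go to the low group: a median subject is in n_low
  v <- tab$age
  expect_equal(out$n_low[out$covariate == "age"], sum(v <= median(v)))
})

test_that("null covariates are flagged at about the nominal rate", {
  flags <- sapply(1:200, function(s) {
    set.seed(s)
    tab <- data.frame(qpqs = rnorm(40, 1, 0.05), z = rnorm(40))
    covariate_precision_screen(tab, "qpqs", "z", m = 1L)$significant
  })
  expect_lte(mean(flags), 0.08)  # ~5% nominal with simulation slack
})

test_that("reclassification summary reproduces the printed-count arithmetic", {
  before <- rep(c("left-to-right", "normal"), c(16, 75))
  # 9 of the 16 normalize; 2 initially normal become pathological
  after <- c(rep("normal", 9), rep("left-to-right", 7),
             rep("left-to-right", 2), rep("normal", 73))
  rs <- reclassification_summary(before, after)
  expect_equal(rs$n, 91)
  expect_equal(c(rs$b, rs$c, rs$d), c(9, 2, 7))
  expect_equal(rs$pct_pathological_before, 18)
  expect_equal(rs$pct_pathological_after, 10)
  expect_equal(rs$pct_normalized, 56)
  expect_equal(rs$normalized_fraction, 9 / 16)
  expect_equal(rs$p_mcnemar, mcnemar_exact(9, 2))

  same <- reclassification_summary(before, before)
  expect_equal(c(same$b, same$c), c(0, 0))
  expect_equal(same$p_mcnemar, 1)

  allnorm <- reclassification_summary(rep("normal", 10), rep("normal", 10))
  expect_true(is.na(allnorm$normalized_fraction))
  expect_error(reclassification_summary(before, after[-1]), "equal length")
})
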