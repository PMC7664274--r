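# Group comparison machinery: t-tests with the variance gate, the
# D'Agostino-Pearson omnibus test, the two-stage FDR, result tables.

test_that("closed-form Student t example is reproduced", {
  cmp <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$test, "Student")
  expect_equal(cmp$t, -3.674, tolerance = 1e-3)
  expect_equal(cmp$p, 0.0213, tolerance = 1e-3)
  expect_equal(cmp$df, 4)
})

test_that("identical samples give t = 0, p = 1", {
  cmp <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)
  expect_error(compare_groups(rep(1, 5), rep(2, 5)), "zero variance")
  expect_error(compare_groups(c(1, 2), c(3, 4, 5)), "n >= 3")
})

test_that("the F-test gate selects Welch under strong variance inequality", {
  set.seed(13)
  picks <- vapply(1:200, function(i) {
    a <- rnorm(20, 0, 1); b <- rnorm(20, 0, 10)
    compare_groups(a, b)$test
  }, character(1))
  expect_gte(mean(picks == "Welch"), 0.95)
  # forcing either branch works
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(compare_groups(a, b, gate = "student")$test, "Student")
  expect_equal(compare_groups(a, b, gate = "welch")$test, "Welch")
})

test_that("D'Agostino-Pearson matches an independent reference implementation", {
  # expected values computed once with an independent omnibus-test
  # implementation on the same samples
  x <- c(1.2, 0.8, 1.1, 3.5, 0.9, 1.0, 1.3, 0.7, 6.0, 1.1, 0.95, 1.05)
  r <- dagostino_pearson(x)
  expect_equal(r$k2, 20.01162513080257, tolerance = 1e-10)
  expect_equal(r$p, 4.5136805156841206e-05, tolerance = 1e-10)
  y <- c(2.3, 1.9, 3.1, 2.8, 2.2, 1.7, 2.9, 3.3, 2.0, 2.6, 1.8, 2.4, 3.0, 2.1)
  r2 <- dagostino_pearson(y)
  expect_equal(r2$k2, 2.200326196026272, tolerance = 1e-10)
  expect_equal(r2$z_skew, 0.37061883811281426, tolerance = 1e-10)
  expect_equal(r2$z_kurt, -1.4363035448198893, tolerance = 1e-10)
  expect_error(dagostino_pearson(1:5), "at least 8")
})

test_that("two-stage FDR handles the boundary examples", {
  expect_false(any(bky_fdr(rep(0.9, 10))))
  expect_true(bky_fdr(0.01, q = 0.05))       # single test, stage 1 rejects
  expect_error(bky_fdr(numeric(0)), "empty")
  expect_error(bky_fdr(c(0.5, 1.2)), "\\[0,1\\]")
  # rejects a superset of single-stage BH when some nulls are false
  set.seed(5)
  p <- c(runif(60), rbeta(40, 0.2, 8))
  bky <- bky_fdr(p, q = 0.05)
  bh <- p.adjust(p, "BH") <= 0.05
  expect_true(all(bh[bky == FALSE] == FALSE))   # BH subset of BKY
  expect_gte(sum(bky), sum(bh))
})

test_that("two-stage FDR controls the empirical FDR under mixed signals", {
  set.seed(17)
  fdps <- vapply(1:200, function(i) {
    m <- 60; m1 <- 20
    p <- c(pnorm(-abs(rnorm(m1, 3, 1))) * 2, runif(m - m1))
    null_flag <- c(rep(FALSE, m1), rep(TRUE, m - m1))
    rej <- bky_fdr(p, q = 0.05)
    if (sum(rej) == 0) 0 else sum(rej & null_flag) / sum(rej)
  }, numeric(1))
  mc_se <- sd(fdps) / sqrt(length(fdps))
  expect_lte(mean(fdps), 0.05 + 2 * mc_se)
})

test_that("results tables star only FDR-significant rows at the table thresholds", {
  set.seed(2)
  mk <- function(p_target, label) {
    # construct two groups whose t-test lands near the requested p
    a <- rnorm(10); b <- rnorm(10)
    cmp <- compare_groups(a, b, label = label)
    cmp$p <- p_target
    cmp
  }
  tab <- build_results_table(list(mk(2e-5, "a"), mk(0.003, "b"),
                                  mk(0.02, "c"), mk(0.8, "d")))
  expect_equal(tab$stars, c("****", "***", "*", ""))
  expect_false(tab$fdr_sig[4])
  # all-null table: no stars anywhere
  tab0 <- build_results_table(lapply(1:4, function(i) mk(0.5 + i / 10, "x")))
  expect_true(all(tab0$stars == ""))
  expect_error(build_results_table(list()), "no comparisons")
})
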