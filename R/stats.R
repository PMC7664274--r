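# Group inference: variance/normality gates, t-tests, the two-stage FDR
# step-up, and publication-style result tables.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed-skewness Z (D'Agostino) and transformed-kurtosis
#' Z (Anscombe-Glynn) into the K2 omnibus statistic, chi-square with 2
#' degrees of freedom under normality. Needs n >= 8.
#'
#' @param x Numeric vector (n >= 8).
#' @return List: `k2`, `p`, `z_skew`, `z_kurt`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("dagostino_pearson: need at least 8 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("dagostino_pearson: zero variance")
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2
  # skewness (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / alpha)
  # kurtosis (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(k2 = k2, p = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

#' Compare one metric between two groups
#'
#' Unpaired two-tailed t-test with a variance gate: an F-test compares the
#' group variances and Welch's correction is used when its p < 0.05,
#' Student's pooled test otherwise (either can be forced). The
#' D'Agostino-Pearson omnibus normality p is reported per group (NA below
#' n = 8).
#'
#' @param values_a,values_b Numeric vectors, n >= 3 each.
#' @param gate `"auto"` (F-test decides), `"student"`, or `"welch"`.
#' @param label Metric name carried into the result.
#' @return Object of class `comparison_result`: `metric`, `mean_a`,
#'   `sem_a`, `n_a` (same for b), `test` ("Student" | "Welch"), `t`, `df`,
#'   `p`, `f_p`, `normality_p_a`, `normality_p_b`.
#' @export
compare_groups <- function(values_a, values_b,
                           gate = c("auto", "student", "welch"),
                           label = "metric") {
  gate <- match.arg(gate)
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) < 3 || length(b) < 3)
    stop("compare_groups: need n >= 3 per group")
  if (var(a) == 0 && var(b) == 0)
    stop("compare_groups: zero variance in both groups")
  f_p <- if (var(a) > 0 && var(b) > 0) var.test(a, b)$p.value else 0
  test <- switch(gate,
                 auto = if (f_p < 0.05) "Welch" else "Student",
                 student = "Student", welch = "Welch")
  tt <- t.test(a, b, var.equal = (test == "Student"))
  sem <- function(x) sd(x) / sqrt(length(x))
  norm_p <- function(x) if (length(x) >= 8)
    tryCatch(dagostino_pearson(x)$p, error = function(e) NA_real_)
  else NA_real_
  structure(list(metric = label,
                 mean_a = mean(a), sem_a = sem(a), n_a = length(a),
                 mean_b = mean(b), sem_b = sem(b), n_b = length(b),
                 test = test, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value, f_p = f_p,
                 normality_p_a = norm_p(a), normality_p_b = norm_p(b)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %.3g +/- %.2g (n=%d) vs %.3g +/- %.2g (n=%d), %s t=%.3f, p=%.3g\n",
              x$metric, x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b, x$n_b,
              x$test, x$t, x$p))
  invisible(x)
}

#' Two-stage linear step-up false-discovery-rate procedure
#'
#' The two-stage step-up of Benjamini, Krieger and Yekutieli: stage one
#' runs the linear step-up at level q' = q/(1+q) to estimate the number of
#' true nulls m0 = m - r1 (r1 = stage-one rejections; none rejected if
#' r1 = 0, all if r1 = m); stage two reruns the step-up at level q' scaled
#' by m/m0. Controls the FDR at q for independent tests with better power
#' than the single-stage procedure.
#'
#' @param p_values Numeric vector of p-values in \[0,1\].
#' @param q Target false discovery rate (default 0.05).
#' @return Logical vector of rejection flags, in input order.
#' @export
bky_fdr <- function(p_values, q = 0.05) {
  m <- length(p_values)
  if (m == 0) stop("bky_fdr: empty p-value vector")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("bky_fdr: p-values must lie in [0,1]")
  q1 <- q / (1 + q)
  step_up <- function(p, level) {
    o <- order(p)
    ps <- p[o]
    ok <- which(ps <= seq_len(m) * level / m)
    r <- if (length(ok)) max(ok) else 0L
    flags <- logical(m)
    if (r > 0) flags[o[seq_len(r)]] <- TRUE
    flags
  }
  r1 <- sum(step_up(p_values, q1))
  if (r1 == 0) return(logical(m))
  if (r1 == m) return(rep(TRUE, m))
  m0 <- m - r1
  step_up(p_values, q1 * m / m0)
}

#' Publication-style comparison table with FDR flags
#'
#' Assembles [compare_groups()] results into one table, applies the
#' two-stage FDR across the family (all rows of the table), and assigns
#' significance markers at the 0.05 / 0.01 / 0.005 / 0.0001 thresholds --
#' suppressed for rows the FDR flags as nonsignificant.
#'
#' @param comparisons List of `comparison_result` objects.
#' @param q Target false discovery rate for the family.
#' @return Data frame: metric, group means +/- SEM, test, t, p, `fdr_sig`,
#'   `stars`.
#' @export
build_results_table <- function(comparisons, q = 0.05) {
  if (length(comparisons) == 0) stop("build_results_table: no comparisons")
  stopifnot(all(vapply(comparisons, inherits, logical(1),
                       "comparison_result")))
  p <- vapply(comparisons, function(x) x$p, numeric(1))
  sig <- bky_fdr(p, q = q)
  stars <- vapply(seq_along(p), function(i) {
    if (!sig[i]) return("")
    if (p[i] < 1e-4) "****" else if (p[i] < 0.005) "***"
    else if (p[i] < 0.01) "**" else if (p[i] < 0.05) "*" else ""
  }, character(1))
  data.frame(
    metric = vapply(comparisons, function(x) x$metric, character(1)),
    mean_a = vapply(comparisons, function(x) x$mean_a, numeric(1)),
    sem_a = vapply(comparisons, function(x) x$sem_a, numeric(1)),
    mean_b = vapply(comparisons, function(x) x$mean_b, numeric(1)),
    sem_b = vapply(comparisons, function(x) x$sem_b, numeric(1)),
    test = vapply(comparisons, function(x) x$test, character(1)),
    t = vapply(comparisons, function(x) x$t, numeric(1)),
    p = p, fdr_sig = sig, stars = stars)
}
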