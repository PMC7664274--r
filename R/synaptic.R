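# Spontaneous-IPSC event detection, per-cell summaries, pooled ECDFs, and
# Kolmogorov-Smirnov comparison.

#' Detect synaptic events in a gap-free current trace
#'
#' Deterministic matched-filter detector: the trace (rectified according to
#' `polarity`) is correlated with a unit-peak biexponential template; local
#' maxima of the normalized score above `score_thresh` mark candidate
#' onsets, separated by at least 3 ms (refractory, prevents double counts
#' on one event). Amplitude is the post-onset peak minus the median
#' baseline of the preceding 5 ms; candidates below `threshold` (10 pA) are
#' discarded.
#'
#' @param sweep A gap-free current [sweep_trace()].
#' @param threshold Amplitude threshold (pA), default 10.
#' @param rise,decay Template kernel time constants (ms).
#' @param polarity `"inward"` (events are negative deflections, the sIPSC
#'   case at -80 mV under high internal chloride) or `"outward"`.
#' @param score_thresh Matched-filter criterion in units of the robust
#'   (MAD) score SD.
#' @return Data frame of class-tagged events: `onset` (s), `amplitude`
#'   (pA, baseline-to-peak, positive), `iei` (s, interval to the previous
#'   event, NA for the first).
#' @export
detect_events <- function(sweep, threshold = 10, rise = 0.8, decay = 8,
                          polarity = c("inward", "outward"),
                          score_thresh = 4) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(sweep, "ck_sweep"))
  if (sweep$channel != "current")
    stop("detect_events: expected a gap-free current sweep")
  sr <- sweep$sampling_rate
  x <- if (polarity == "inward") -sweep$samples else sweep$samples
  k <- sipsc_kernel(rise, decay, sr)
  if (length(k) >= length(x))
    stop("detect_events: template kernel longer than the trace")
  k <- k - mean(k)                      # zero-mean template
  n <- length(x)
  L <- length(k)
  # onset-aligned matched-filter score score[i] = sum_m x[i+m-1] * k[m],
  # via zero-padded FFT cross-correlation (padding to a highly composite
  # length keeps the FFT O(n log n) for any trace length)
  N <- stats::nextn(n + L)
  xp <- c(x, numeric(N - n))
  kp <- c(k, numeric(N - L))
  sc <- Re(stats::fft(stats::fft(xp) * Conj(stats::fft(kp)),
                      inverse = TRUE)) / N
  score <- numeric(n)
  valid <- seq_len(n - L + 1)
  score[valid] <- sc[valid]
  s_sd <- stats::mad(score)
  if (s_sd == 0) s_sd <- sd(score)
  if (is.na(s_sd) || s_sd == 0) return(empty_events())
  z <- score / s_sd
  cand <- which(z > score_thresh &
                  z >= c(-Inf, z[-n]) &
                  z >= c(z[-1], Inf))
  if (length(cand) == 0) return(empty_events())
  # enforce 3 ms refractory between onsets, keeping the larger score
  refr <- round(0.003 * sr)
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) == 0 || i - keep[length(keep)] >= refr) {
      keep <- c(keep, i)
    } else if (z[i] > z[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  # amplitude: post-onset peak (the kernel peaks ~2 ms after onset) minus
  # the median baseline of the preceding 5 ms
  amp <- onset <- numeric(length(keep))
  for (j in seq_along(keep)) {
    i0 <- keep[j]
    base_win <- max(1, i0 - round(0.005 * sr)):max(1, i0 - 1)
    base <- median(x[base_win])
    peak_win <- i0:min(n, i0 + round(0.006 * sr))
    pk <- which.max(x[peak_win])
    amp[j] <- x[peak_win[pk]] - base
    onset[j] <- (i0 - 1) / sr
  }
  ok <- amp >= threshold
  if (!any(ok)) return(empty_events())
  out <- data.frame(onset = onset[ok], amplitude = amp[ok])
  out <- out[order(out$onset), , drop = FALSE]
  out$iei <- c(NA_real_, diff(out$onset))
  rownames(out) <- NULL
  out
}

empty_events <- function() {
  data.frame(onset = numeric(0), amplitude = numeric(0), iei = numeric(0))
}

#' Per-cell event summary
#'
#' Mean frequency is event count over recording duration; mean amplitude
#' is the average over all retained events (NA when the cell had none).
#'
#' @param events Event data frame ([detect_events()] output, or a
#'   ground-truth event list with an `amplitude` column).
#' @param duration Recording duration (s), > 0.
#' @param cell_id,group Identity labels carried into the summary.
#' @return Object of class `cell_event_summary`: `cell_id`, `group`,
#'   `n_events`, `frequency` (Hz), `mean_amplitude` (pA), `events`.
#' @export
summarize_cell <- function(events, duration, cell_id = "cell", group = "") {
  if (duration <= 0) stop("summarize_cell: duration must be > 0")
  n <- nrow(events)
  structure(list(cell_id = cell_id, group = group, n_events = n,
                 frequency = n / duration,
                 mean_amplitude = if (n > 0) mean(events$amplitude) else NA_real_,
                 events = events),
            class = "cell_event_summary")
}

#' Pooled amplitude (or interval) sample and ECDF across cells
#'
#' Samples `n_per_cell` events uniformly from each cell (with replacement
#' when a cell has fewer) and pools them, so every cell contributes equally
#' to the cumulative distribution regardless of its event count. Cells with
#' zero events are excluded with a warning.
#'
#' @param cells List of [summarize_cell()] summaries.
#' @param n_per_cell Events sampled per cell (default 100).
#' @param seed RNG seed (required; sampling is deterministic given it).
#' @param what Column to pool: `"amplitude"` (default) or `"iei"`.
#' @return List: `pool` (numeric vector, length n_cells * n_per_cell),
#'   `ecdf` (a [stats::ecdf()] function), `n_cells`.
#' @export
pooled_ecdf <- function(cells, n_per_cell = 100, seed, what = "amplitude") {
  if (length(cells) == 0) stop("pooled_ecdf: no cells")
  has <- vapply(cells, function(cl) cl$n_events > 0, logical(1))
  if (!any(has)) stop("pooled_ecdf: no cell has any events")
  if (any(!has))
    warning(sprintf("pooled_ecdf: excluding %d cell(s) with zero events",
                    sum(!has)))
  cells <- cells[has]
  pool <- with_seed(seed, unlist(lapply(cells, function(cl) {
    x <- cl$events[[what]]
    x <- x[is.finite(x)]
    sample(x, n_per_cell, replace = length(x) < n_per_cell)
  })))
  list(pool = unname(pool), ecdf = ecdf(pool), n_cells = length(cells))
}

#' Two-sample Kolmogorov-Smirnov comparison of pooled distributions
#'
#' @param pool_a,pool_b Numeric vectors (pooled samples); both non-empty.
#'   Pools smaller than 10 trigger a warning.
#' @return List `statistic` (D) and `p` (asymptotic two-sided p-value).
#' @export
ks_compare <- function(pool_a, pool_b) {
  if (length(pool_a) == 0 || length(pool_b) == 0)
    stop("ks_compare: both pools must be non-empty")
  if (length(pool_a) < 10 || length(pool_b) < 10)
    warning("ks_compare: pool smaller than 10; the asymptotic p is unreliable")
  kt <- suppressWarnings(ks.test(pool_a, pool_b))
  list(statistic = unname(kt$statistic), p = unname(kt$p.value))
}
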