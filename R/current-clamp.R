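# Current-clamp analysis: AP detection, per-spike features, passive
# properties, and train metrics.

# centered-difference dv/dt in mV/ms
dvdt_trace <- function(v, sampling_rate) {
  dt_ms <- 1000 / sampling_rate
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt_ms)
  d[1] <- (v[2] - v[1]) / dt_ms
  d[n] <- (v[n] - v[n - 1]) / dt_ms
  d
}

#' Detect action potentials in a voltage sweep
#'
#' An action potential is a voltage excursion crossing `peak_criterion`
#' (0 mV) subsequent to dv/dt exceeding `dvdt_thresh` (10 mV/ms); the
#' threshold point is the latest sub-to-suprathreshold dv/dt crossing
#' preceding the 0 mV crossing, which makes the assignment robust to slow
#' depolarizing ramps. Between spikes the detector re-arms only once the
#' voltage has fallen back below the peak criterion, so one spike yields
#' one event. Suprathreshold depolarizations whose local maximum stays
#' below 0 mV are not counted; those reaching at least -30 mV are recorded
#' in `attr(, "failures")` as failed spikes (the depolarization-block
#' regime).
#'
#' @param sweep A voltage [sweep_trace()] sampled at >= 10 kHz.
#' @param dvdt_thresh Threshold rate of rise (mV/ms).
#' @param peak_criterion Voltage the spike must cross (mV).
#' @return Data frame (one row per AP): `threshold_time`,
#'   `threshold_voltage`, `peak_time`, `peak_voltage`, `peak_index`,
#'   `threshold_index`, `valid`. Failed spikes in `attr(, "failures")`.
#' @export
detect_aps <- function(sweep, dvdt_thresh = 10, peak_criterion = 0) {
  stopifnot(inherits(sweep, "ck_sweep"))
  if (sweep$channel != "voltage")
    stop("detect_aps: expected a voltage sweep, got a current sweep")
  if (sweep$sampling_rate < 10000)
    stop("detect_aps: sampling rate must be >= 10 kHz")
  v <- sweep$samples
  n <- length(v)
  d <- dvdt_trace(v, sweep$sampling_rate)
  dt <- 1 / sweep$sampling_rate
  supra <- d > dvdt_thresh
  # sub->supra dv/dt crossings (candidate threshold points)
  thr_idx <- which(supra & !c(FALSE, supra[-n]))
  # upward crossings of the peak criterion
  up <- which(v >= peak_criterion & c(FALSE, v[-n] < peak_criterion))
  empty <- data.frame(threshold_time = numeric(0), threshold_voltage = numeric(0),
                      peak_time = numeric(0), peak_voltage = numeric(0),
                      peak_index = integer(0), threshold_index = integer(0),
                      valid = logical(0))
  events <- empty
  last_end <- 0L
  for (z in up) {
    if (z <= last_end) next
    cand <- thr_idx[thr_idx <= z & thr_idx > last_end]
    if (length(cand) == 0) next
    ti <- max(cand)
    # spike extent: until voltage falls back below the criterion
    below <- which(v[z:n] < peak_criterion)
    e <- if (length(below)) z + below[1] - 2L else n
    pk <- (z:e)[which.max(v[z:e])]
    events <- rbind(events, data.frame(
      threshold_time = (ti - 1) * dt, threshold_voltage = v[ti],
      peak_time = (pk - 1) * dt, peak_voltage = v[pk],
      peak_index = pk, threshold_index = ti, valid = TRUE))
    last_end <- e
  }
  # failed spikes: suprathreshold dv/dt episodes peaking in [-30, 0) mV
  used <- if (nrow(events)) events$threshold_index else integer(0)
  fails <- empty
  for (ti in setdiff(thr_idx, used)) {
    # local extent: until dv/dt falls below zero and voltage turns down
    e <- min(ti + round(0.01 * sweep$sampling_rate), n)  # 10 ms lookahead
    pk <- (ti:e)[which.max(v[ti:e])]
    if (v[pk] < peak_criterion && v[pk] >= -30 &&
        (nrow(events) == 0 || !any(abs(pk - events$peak_index) <
                                     0.003 * sweep$sampling_rate)))
      fails <- rbind(fails, data.frame(
        threshold_time = (ti - 1) * dt, threshold_voltage = v[ti],
        peak_time = (pk - 1) * dt, peak_voltage = v[pk],
        peak_index = pk, threshold_index = ti, valid = FALSE))
  }
  if (nrow(fails) > 1)   # merge episodes belonging to one failed spike
    fails <- fails[c(TRUE, diff(fails$peak_index) >
                       0.003 * sweep$sampling_rate), ]
  attr(events, "failures") <- fails
  events
}

#' Complete per-spike features
#'
#' Adds half-width, afterhyperpolarization, and peak dv/dt to detected
#' events. Half-width is the time between the half-amplitude crossings
#' (amplitude measured threshold to peak, crossings linearly interpolated).
#' AHP is the minimum voltage between this spike's peak and the next
#' spike's threshold (or the step end) minus this spike's threshold
#' voltage. Peak dv/dt is the maximum centered-difference rate of rise
#' between threshold and peak. Features whose window is truncated by the
#' sweep end are returned as NA rather than extrapolated.
#'
#' @param sweep The voltage [sweep_trace()] the events came from.
#' @param events Output of [detect_aps()].
#' @param step_end End of the stimulus epoch (s); AHP search for the last
#'   spike stops here. Default: end of the sweep's command step, or end of
#'   sweep.
#' @return `events` with columns `half_width` (ms), `ahp` (mV),
#'   `peak_dvdt` (mV/ms), `amplitude` (mV) added.
#' @export
ap_features <- function(sweep, events, step_end = NULL) {
  stopifnot(inherits(sweep, "ck_sweep"))
  v <- sweep$samples
  n <- length(v)
  sr <- sweep$sampling_rate
  d <- dvdt_trace(v, sr)
  step_end <- step_end %||% (if (sweep$command$type == "step")
    sweep$command$onset + sweep$command$duration else n / sr)
  end_idx <- min(n, round(step_end * sr))
  m <- nrow(events)
  hw <- ahp <- pdvdt <- amp <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    ti <- events$threshold_index[i]
    pk <- events$peak_index[i]
    amp[i] <- v[pk] - v[ti]
    half <- v[ti] + amp[i] / 2
    # rising half-amplitude crossing
    ri <- which(v[ti:pk] >= half)[1]
    # falling crossing after the peak
    post <- which(v[pk:n] <= half)
    if (!is.na(ri) && length(post)) {
      iu <- ti + ri - 1L
      id <- pk + post[1] - 1L
      # linear interpolation at both crossings
      tu <- iu - 1 - if (iu > 1 && v[iu] != v[iu - 1])
        (v[iu] - half) / (v[iu] - v[iu - 1]) else 0
      td <- id - 1 - if (id > 1 && v[id] != v[id - 1])
        (v[id] - half) / (v[id] - v[id - 1]) else 0
      hw[i] <- (td - tu) * 1000 / sr
    }
    pdvdt[i] <- max(d[ti:pk])
    ahp_end <- if (i < m) events$threshold_index[i + 1] else end_idx
    if (ahp_end > pk)
      ahp[i] <- min(v[pk:ahp_end]) - v[ti]
  }
  events$half_width <- hw
  events$ahp <- ahp
  events$peak_dvdt <- pdvdt
  events$amplitude <- amp
  events
}

#' Passive membrane properties with quality control
#'
#' Resting membrane potential is the mean voltage over the first 100 ms of
#' the 0 pA sweep; input resistance comes from Ohm's law on the -10 pA
#' step, using the voltage deflection 250 ms into the step. A cell fails QC
#' if its access resistance exceeds 20 MOhm (reason `"Ra"`) or its RMP is
#' depolarized above -64.3 mV (reason `"RMP"`).
#'
#' @param recording A corrected current-step [episodic_recording()]
#'   containing a 0 pA and (for Rin) a -10 pA sweep.
#' @return Object of class `passive_properties`: `rmp` (mV),
#'   `input_resistance` (MOhm, NA if no -10 pA step), `capacitance` (pF),
#'   `access_resistance` (MOhm), `qc_pass`, `qc_reason`.
#' @export
passive_properties <- function(recording) {
  stopifnot(inherits(recording, "ck_recording"))
  if (!isTRUE(recording$corrected))
    stop("passive_properties: recording must be junction-corrected first")
  amps <- command_levels(recording$sweeps)
  i0 <- which(amps == 0)[1]
  if (is.na(i0))
    stop("passive_properties: recording has no 0 pA sweep")
  s0 <- recording$sweeps[[i0]]
  sr <- s0$sampling_rate
  rmp <- mean(s0$samples[seq_len(round(0.1 * sr))])
  im10 <- which(amps == -10)[1]
  rin <- NA_real_
  if (!is.na(im10)) {
    s <- recording$sweeps[[im10]]
    onset <- s$command$onset
    idx <- round((onset + 0.25) * sr)
    win <- max(1, idx - round(0.005 * sr)):idx
    v250 <- mean(s$samples[win])
    rin <- (v250 - rmp) / (-10) * 1000      # mV/pA = GOhm -> MOhm
  }
  reason <- character(0)
  ra <- recording$access_resistance
  if (!is.na(ra) && ra > 20) reason <- c(reason, "Ra")
  if (rmp > -64.3) reason <- c(reason, "RMP")
  structure(list(rmp = rmp, input_resistance = rin,
                 capacitance = recording$capacitance,
                 access_resistance = ra,
                 qc_pass = length(reason) == 0,
                 qc_reason = paste(reason, collapse = "+")),
            class = "passive_properties")
}

#' Firing-train metrics for a current-step family
#'
#' Computes the f-I summary of a step family: AP counts per injection
#' (failed spikes, max voltage < 0 mV, excluded), maximum firing rate (the
#' largest count over the 1-s steps, Hz), rheobase, spike-frequency
#' adaptation (last interspike interval over the second, measured on the
#' max-rate sweep, requiring at least 3 ISIs), depolarization-block index
#' (1 minus the count at the highest injection over the maximum count), and
#' the area under the count-vs-current curve up to 50 pA (trapezoid on the
#' 10 pA grid). Train AP parameters (peak voltage, peak dv/dt, threshold
#' for the first and the subsequent APs) are taken from an analysis sweep
#' chosen by `rule`: 20 pA above the repetitive-firing (> 3 APs) threshold
#' for `"fs"`, a fixed 100 pA step for `"layer6"`, 150 pA for `"layer5"`
#' and `"subiculum"`.
#'
#' @param recording A corrected current-step [episodic_recording()] with at
#'   least 2 positive-current sweeps.
#' @param rule Analysis-sweep rule: `"fs"`, `"layer5"`, `"layer6"`,
#'   `"subiculum"`.
#' @param dvdt_thresh,peak_criterion Detection parameters, see
#'   [detect_aps()].
#' @return Object of class `train_metrics`: `counts` (data frame
#'   current/count), `max_rate` (Hz), `rheobase` (pA), `sfa`,
#'   `block_index`, `auc_low` (AP*pA), and `train` (a one-row data frame of
#'   train AP parameters, NA if the analysis sweep fired no APs).
#' @export
train_metrics <- function(recording, rule = c("fs", "layer5", "layer6",
                                              "subiculum"),
                          dvdt_thresh = 10, peak_criterion = 0) {
  rule <- match.arg(rule)
  stopifnot(inherits(recording, "ck_recording"))
  if (!isTRUE(recording$corrected))
    stop("train_metrics: recording must be junction-corrected first")
  amps <- command_levels(recording$sweeps)
  if (sum(amps > 0, na.rm = TRUE) < 2)
    stop("train_metrics: need at least 2 positive-current sweeps")
  evts <- lapply(recording$sweeps, detect_aps,
                 dvdt_thresh = dvdt_thresh, peak_criterion = peak_criterion)
  counts <- vapply(evts, nrow, integer(1))
  step_dur <- recording$sweeps[[1]]$command$duration
  pos <- which(amps >= 0)
  max_count <- max(counts[pos])
  max_rate <- max_count / step_dur
  rheo <- {
    fired <- which(amps > 0 & counts > 0)
    if (length(fired)) min(amps[fired]) else NA_real_
  }
  top <- which.max(amps)
  block <- if (max_count > 0) 1 - counts[top] / max_count else NA_real_
  # AUC of counts vs current over the grid points in [0, 50 pA]
  grid <- which(amps >= 0 & amps <= 50)
  auc <- if (length(grid) >= 2) {
    x <- amps[grid]; y <- counts[grid]
    o <- order(x)
    sum(diff(x[o]) * (head(y[o], -1) + tail(y[o], -1)) / 2)
  } else NA_real_
  # SFA on the (first) max-rate sweep
  i_max <- which(counts == max_count & seq_along(counts) %in% pos)[1]
  sfa <- NA_real_
  if (max_count >= 4) {
    isi <- diff(evts[[i_max]]$peak_time)
    if (length(isi) >= 3) sfa <- isi[length(isi)] / isi[2]
  }
  # analysis sweep for train AP parameters
  ana_amp <- switch(rule,
    fs = {
      rep_thr <- amps[which(counts > 3 & amps > 0)[1]]
      if (is.na(rep_thr)) NA_real_ else rep_thr + 20
    },
    layer6 = 100, layer5 = 150, subiculum = 150)
  train <- data.frame(first_peak_voltage = NA_real_, first_peak_dvdt = NA_real_,
                      first_threshold = NA_real_, train_peak_voltage = NA_real_,
                      train_peak_dvdt = NA_real_, train_threshold = NA_real_)
  i_ana <- which(amps == ana_amp)[1]
  if (!is.na(i_ana) && nrow(evts[[i_ana]]) > 0) {
    fe <- ap_features(recording$sweeps[[i_ana]], evts[[i_ana]])
    train$first_peak_voltage <- fe$peak_voltage[1]
    train$first_peak_dvdt <- fe$peak_dvdt[1]
    train$first_threshold <- fe$threshold_voltage[1]
    if (nrow(fe) > 1) {
      train$train_peak_voltage <- mean(fe$peak_voltage[-1])
      train$train_peak_dvdt <- mean(fe$peak_dvdt[-1])
      train$train_threshold <- mean(fe$threshold_voltage[-1])
    }
  }
  structure(list(counts = data.frame(current = amps, count = counts),
                 max_rate = max_rate, rheobase = rheo, sfa = sfa,
                 block_index = block, auc_low = auc, train = train,
                 analysis_current = ana_amp),
            class = "train_metrics")
}

#' Tidy per-cell metric table
#'
#' Stacks per-cell metric vectors into the long table the group-comparison
#' stage consumes: one row per cell per metric with its group label.
#'
#' @param cell_metrics Named list (names = cell ids); each element a named
#'   numeric vector of metrics for that cell.
#' @param groups Character vector of group labels, one per cell.
#' @return Data frame with columns `cell_id`, `group`, `metric`, `value`.
#' @export
summarize_cells <- function(cell_metrics, groups) {
  if (length(cell_metrics) == 0) stop("summarize_cells: no cells")
  if (length(groups) != length(cell_metrics))
    stop("summarize_cells: one group label per cell required")
  ids <- names(cell_metrics)
  if (is.null(ids) || anyDuplicated(ids))
    stop("summarize_cells: cell ids must be present and unique")
  do.call(rbind, lapply(seq_along(cell_metrics), function(i) {
    m <- cell_metrics[[i]]
    data.frame(cell_id = ids[i], group = groups[i],
               metric = names(m), value = unname(m), row.names = NULL)
  }))
}
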