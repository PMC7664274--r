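# Study orchestration: generate a full synthetic study to disk, then run
# the complete analysis (current clamp -> voltage clamp -> ramps -> sIPSC
# -> group tables -> survival) from its manifest.

#' Generate the bundled demo study
#'
#' Writes a complete synthetic study in the native container format: FS
#' interneuron current-clamp families, dissociated-cell voltage-clamp step
#' + availability families, nucleated-patch-style step families, ramp
#' trials, gap-free sIPSC traces, and a survival table, with wild-type
#' ("wt") and knockout ("null") cohorts. Cohort sizes default to the
#' figure-matched plan of the study the simulators emulate (11/11 FS,
#' 10/8 dissociated, 10/10 patches, 12/12 sIPSC cells, 62/60 survival
#' subjects); they are parameters so tests can run scaled-down studies.
#'
#' Genotype ground truth: sodium conductance scaled to 0.65 in the FS
#' current-clamp cohort, permeability scaled to 0.70 (30% density loss) in
#' the dissociated cohort and 0.60 (40% loss) in the patch/ramp cohorts,
#' sIPSC rate 3.81 vs 1.38 Hz with matched amplitudes, survival medians 25
#' vs 18 days.
#'
#' @param dir Output directory (created).
#' @param seed Master seed; every cell derives its own seed from it.
#' @param n_fs,n_vclamp,n_patch,n_sipsc,n_survival Two-element vectors
#'   `c(wt, null)` of cohort sizes.
#' @param sipsc_duration sIPSC trace duration (s), default the full 5 min.
#' @param fs_steps,pyr_steps Current-step grids (pA).
#' @return The manifest data frame (also written to `manifest.csv`):
#'   columns `cell_id`, `group`, `cell_type`, `mode`, `path`.
#' @export
make_demo_dataset <- function(dir, seed, n_fs = c(11, 11),
                              n_vclamp = c(10, 8), n_patch = c(10, 10),
                              n_sipsc = c(12, 12), n_survival = c(62, 60),
                              sipsc_duration = 300,
                              fs_steps = seq(-20, 300, 10),
                              pyr_steps = seq(-20, 200, 10)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("make_demo_dataset: cannot create ", dir)
  rows <- list()
  add_row <- function(cell_id, group, cell_type, mode, path) {
    rows[[length(rows) + 1]] <<- data.frame(
      cell_id = cell_id, group = group, cell_type = cell_type,
      mode = mode, path = path)
  }
  cell_seed <- function(k) (seed * 1000L + k) %% .Machine$integer.max
  # mild lognormal inter-cell heterogeneity so cohort statistics behave
  # like biological replicates rather than copies of one cell
  jitter_preset <- function(preset, jseed, sd = 0.05) {
    with_seed(jseed, {
      for (f in c("c_m", "g_leak", "g_na", "g_k"))
        preset[[f]] <- preset[[f]] * exp(rnorm(1, 0, sd))
      preset$e_leak <- preset$e_leak + rnorm(1, 0, 1)
      preset
    })
  }
  jitter_scale <- function(jseed, sd = 0.05)
    with_seed(jseed, exp(rnorm(1, 0, sd)))
  # per-cell gating variability (mV): cells differ in V1/2 and slope the
  # way biological replicates do, so genotype contrasts on gating are null
  jitter_gating <- function(truth, jseed) {
    with_seed(jseed, {
      truth$act_vhalf <- truth$act_vhalf + rnorm(1, 0, 1.5)
      truth$inact_vhalf <- truth$inact_vhalf + rnorm(1, 0, 1.5)
      truth$act_k <- truth$act_k * exp(rnorm(1, 0, 0.05))
      truth$inact_k <- truth$inact_k * exp(rnorm(1, 0, 0.05))
      truth
    })
  }
  k <- 0L
  # FS current clamp
  for (g in c("wt", "null")) {
    for (i in seq_len(n_fs[if (g == "wt") 1 else 2])) {
      k <- k + 1L
      id <- sprintf("fs_%s_%02d", g, i)
      preset <- jitter_preset(
        neuron_preset("FS", genotype = if (g == "wt") "wt" else "null"),
        cell_seed(k) + 500L)
      rec <- simulate_current_clamp(preset, steps = fs_steps,
                                    seed = cell_seed(k), ljp = 14.3,
                                    cell_id = id, group = g)
      p <- file.path(dir, id)
      write_recording(rec, p)
      add_row(id, g, "FS", "cclamp", p)
    }
  }
  # dissociated-cell voltage clamp (steps + availability)
  for (g in c("wt", "null")) {
    for (i in seq_len(n_vclamp[if (g == "wt") 1 else 2])) {
      k <- k + 1L
      id <- sprintf("diss_%s_%02d", g, i)
      scale <- if (g == "wt") 1 else 0.70      # 30% density loss
      truth <- jitter_gating(
        channel_truth(p_max = 1.2e-4 * scale *
                        jitter_scale(cell_seed(k) + 500L)),
        cell_seed(k) + 600L)
      rec <- simulate_ina_step_family(truth, noise_sd = 2, seed = cell_seed(k),
                                      capacitance = 8, cell_id = id, group = g)
      p <- file.path(dir, id)
      write_recording(rec, p)
      add_row(id, g, "dissociated", "vclamp_steps", p)
      av <- simulate_ina_availability(truth, noise_sd = 2,
                                      seed = cell_seed(k) + 1L,
                                      capacitance = 8,
                                      cell_id = paste0(id, "_avail"), group = g)
      pa <- file.path(dir, paste0(id, "_avail"))
      write_recording(av, pa)
      add_row(paste0(id, "_avail"), g, "dissociated", "vclamp_avail", pa)
    }
  }
  # nucleated-patch-style step families (layer 6, reference -20 mV)
  for (g in c("wt", "null")) {
    for (i in seq_len(n_patch[if (g == "wt") 1 else 2])) {
      k <- k + 1L
      id <- sprintf("patch_%s_%02d", g, i)
      scale <- if (g == "wt") 1 else 0.60      # 40% density loss
      truth <- jitter_gating(
        channel_truth(p_max = 6e-5 * scale *
                        jitter_scale(cell_seed(k) + 500L),
                      act_vhalf = -38.75, act_k = 6.03,
                      inact_vhalf = -67.10, inact_k = 5.2),
        cell_seed(k) + 600L)
      rec <- simulate_ina_step_family(truth, noise_sd = 1, seed = cell_seed(k),
                                      capacitance = 1.2, cell_id = id,
                                      group = g)
      p <- file.path(dir, id)
      write_recording(rec, p)
      add_row(id, g, "patch", "vclamp_steps", p)
      # ramp trials for the same cell, persistent fraction 1%
      tr <- simulate_ramp(truth, n_trials = 4, noise_sd = 0.05,
                          seed = cell_seed(k) + 1L, capacitance = 20)
      ramp_rec <- episodic_recording(
        tr, protocol = list(mode = "voltage_ramp", seed = cell_seed(k) + 1L),
        cell_id = paste0(id, "_ramp"), group = g, corrected = TRUE,
        capacitance = 20, access_resistance = 10, input_resistance = 2000)
      attr(ramp_rec, "ground_truth") <- attr(tr, "ground_truth")
      pr <- file.path(dir, paste0(id, "_ramp"))
      write_recording(ramp_rec, pr)
      add_row(paste0(id, "_ramp"), g, "patch", "ramp", pr)
    }
  }
  # sIPSC gap-free traces
  for (g in c("wt", "null")) {
    for (i in seq_len(n_sipsc[if (g == "wt") 1 else 2])) {
      k <- k + 1L
      id <- sprintf("sipsc_%s_%02d", g, i)
      truth <- synaptic_truth(rate = if (g == "wt") 3.81 else 1.38,
                              duration = sipsc_duration)
      sim <- simulate_sipsc(truth, seed = cell_seed(k))
      rec <- episodic_recording(
        list(sim$sweep), protocol = list(mode = "gapfree",
                                         duration = truth$duration,
                                         seed = cell_seed(k)),
        cell_id = id, group = g, corrected = TRUE, capacitance = 20,
        access_resistance = 10)
      attr(rec, "ground_truth") <- list(rate = truth$rate,
                                        events = sim$events)
      p <- file.path(dir, id)
      write_recording(rec, p)
      add_row(id, g, "pyramidal", "sipsc", p)
    }
  }
  # survival table
  surv <- simulate_survival(
    list(wt = list(hazard = hazard_profile(25), n = n_survival[1]),
         null = list(hazard = hazard_profile(18), n = n_survival[2])),
    seed = cell_seed(k + 1L))
  write.csv(surv, file.path(dir, "survival.csv"), row.names = FALSE)
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Run the full study analysis from a manifest
#'
#' Orchestrates every analysis stage over a study directory produced by
#' [make_demo_dataset()] (or laid out the same way): junction-corrects and
#' QC-gates current-clamp cells, extracts passive and train metrics,
#' analyzes voltage-clamp step/availability families and ramps, detects
#' and summarizes sIPSC events with pooled-ECDF comparisons, builds
#' FDR-flagged group tables, and runs the survival comparison. Reruns with
#' the same inputs and seed are deterministic.
#'
#' @param dir Study directory containing `manifest.csv` (and
#'   `survival.csv` if survival analysis is wanted).
#' @param seed Seed for the resampling stages (event pooling).
#' @param q Target false discovery rate for the group tables.
#' @param sipsc_threshold sIPSC amplitude threshold (pA).
#' @param pool_n Events sampled per cell for pooled ECDFs.
#' @param rules Named mapping cell_type -> train-metrics rule.
#' @param out_dir If non-NULL, result tables are written there as CSV.
#' @return List: `cclamp` (per-cell metrics + group table), `vclamp`
#'   (per-cell IV/fits + group table), `ramp`, `sipsc` (per-cell summaries,
#'   comparisons, KS results), `survival` (medians + log-rank), `log`
#'   (character vector, includes every QC exclusion).
#' @export
run_study <- function(dir, seed = 1, q = 0.05, sipsc_threshold = 10,
                      pool_n = 100, rules = c(FS = "fs", pyramidal = "layer6"),
                      out_dir = NULL) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("run_study: no manifest at ", mpath)
  manifest <- read.csv(mpath, stringsAsFactors = FALSE)
  if (nrow(manifest) == 0) stop("run_study: manifest lists no cells")
  if (anyDuplicated(manifest$path))
    stop("run_study: duplicate paths in manifest")
  missing <- manifest$path[!dir.exists(manifest$path)]
  if (length(missing))
    stop("run_study: missing input: ", paste(missing, collapse = ", "))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  out <- list()

  # ---- current clamp ----
  cc <- manifest[manifest$mode == "cclamp", ]
  if (nrow(cc) > 0) {
    metrics <- list(); groups <- character(0)
    for (i in seq_len(nrow(cc))) {
      rec <- read_recording(cc$path[i])
      if (!rec$corrected) rec <- apply_junction_correction(rec)
      pp <- passive_properties(rec)
      if (!pp$qc_pass) {
        note("QC exclusion: %s (%s)", cc$cell_id[i], pp$qc_reason)
        next
      }
      rule <- rules[[cc$cell_type[i]]] %||% "fs"
      tm <- train_metrics(rec, rule = rule)
      metrics[[cc$cell_id[i]]] <- c(
        rmp = pp$rmp, input_resistance = pp$input_resistance,
        capacitance = pp$capacitance, max_rate = tm$max_rate,
        rheobase = tm$rheobase, sfa = tm$sfa,
        block_index = tm$block_index, auc_low = tm$auc_low,
        first_peak_dvdt = tm$train$first_peak_dvdt,
        train_threshold = tm$train$train_threshold)
      groups <- c(groups, cc$group[i])
    }
    gl <- unique(cc$group)
    for (g in gl) if (!g %in% groups)
      stop("run_study: QC excluded every current-clamp cell in group ", g)
    tidy <- summarize_cells(metrics, groups)
    out$cclamp <- list(cells = tidy,
                       table = group_table(tidy, gl, q = q))
  }

  # ---- voltage-clamp step families ----
  vs <- manifest[manifest$mode == "vclamp_steps", ]
  if (nrow(vs) > 0) {
    res <- list(); groups <- character(0)
    for (i in seq_len(nrow(vs))) {
      rec <- read_recording(vs$path[i])
      ref <- if (vs$cell_type[i] == "dissociated") -25 else -20
      iv <- peak_iv(rec, reference_voltage = ref)
      gt <- attr(rec, "ground_truth")
      ctx <- ghk_context(1, gt$conc_in %||% 10, gt$conc_out %||% 30)
      act <- activation_curve(iv, ctx)
      res[[vs$cell_id[i]]] <- c(ref_density = iv$reference_density,
                                act_vhalf = act$fit$v_half,
                                act_k = act$fit$k)
      groups <- c(groups, vs$group[i])
    }
    tidy <- summarize_cells(res, groups)
    out$vclamp <- list(cells = tidy,
                       table = group_table(tidy, unique(vs$group), q = q))
  }

  # ---- availability families ----
  va <- manifest[manifest$mode == "vclamp_avail", ]
  if (nrow(va) > 0) {
    res <- list(); groups <- character(0)
    for (i in seq_len(nrow(va))) {
      rec <- read_recording(va$path[i])
      av <- availability_curve(rec)
      res[[va$cell_id[i]]] <- c(inact_vhalf = av$fit$v_half,
                                inact_k = av$fit$k)
      groups <- c(groups, va$group[i])
    }
    tidy <- summarize_cells(res, groups)
    out$availability <- list(cells = tidy,
                             table = group_table(tidy, unique(va$group), q = q))
  }

  # ---- ramps ----
  rp <- manifest[manifest$mode == "ramp", ]
  if (nrow(rp) > 0) {
    res <- list(); groups <- character(0)
    for (i in seq_len(nrow(rp))) {
      rec <- read_recording(rp$path[i])
      rr <- analyze_ramp(rec$sweeps, capacitance = rec$capacitance)
      res[[rp$cell_id[i]]] <- c(persistent_density = rr$density_at_m20)
      groups <- c(groups, rp$group[i])
    }
    tidy <- summarize_cells(res, groups)
    out$ramp <- list(cells = tidy,
                     table = group_table(tidy, unique(rp$group), q = q))
  }

  # ---- sIPSC ----
  si <- manifest[manifest$mode == "sipsc", ]
  if (nrow(si) > 0) {
    summaries <- list()
    for (i in seq_len(nrow(si))) {
      rec <- read_recording(si$path[i])
      dur <- length(rec$sweeps[[1]]$samples) / rec$sweeps[[1]]$sampling_rate
      ev <- detect_events(rec$sweeps[[1]], threshold = sipsc_threshold)
      summaries[[i]] <- summarize_cell(ev, dur, cell_id = si$cell_id[i],
                                       group = si$group[i])
    }
    gl <- unique(si$group)
    by_g <- function(g, f) vapply(
      summaries[vapply(summaries, function(s) s$group == g, logical(1))],
      f, numeric(1))
    cmp_freq <- compare_groups(by_g(gl[1], function(s) s$frequency),
                               by_g(gl[2], function(s) s$frequency),
                               label = "sipsc_frequency")
    cmp_amp <- compare_groups(by_g(gl[1], function(s) s$mean_amplitude),
                              by_g(gl[2], function(s) s$mean_amplitude),
                              label = "sipsc_amplitude")
    pools <- lapply(gl, function(g) pooled_ecdf(
      summaries[vapply(summaries, function(s) s$group == g, logical(1))],
      n_per_cell = pool_n, seed = seed))
    ks_amp <- ks_compare(pools[[1]]$pool, pools[[2]]$pool)
    out$sipsc <- list(cells = summaries,
                      table = build_results_table(list(cmp_freq, cmp_amp),
                                                  q = q),
                      ks_amplitude = ks_amp)
  }

  # ---- survival ----
  spath <- file.path(dir, "survival.csv")
  if (file.exists(spath)) {
    surv <- read.csv(spath, stringsAsFactors = FALSE)
    gl <- unique(surv$group)
    med <- lapply(gl, function(g) km_estimate(surv, group = g)$median)
    names(med) <- gl
    out$survival <- list(medians = med, logrank = logrank_test(surv))
  }

  out$log <- log
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in intersect(names(out), c("cclamp", "vclamp", "availability",
                                       "ramp"))) {
      write.csv(out[[nm]]$cells, file.path(out_dir, paste0(nm, "_cells.csv")),
                row.names = FALSE)
      write.csv(out[[nm]]$table, file.path(out_dir, paste0(nm, "_table.csv")),
                row.names = FALSE)
    }
    if (!is.null(out$sipsc))
      write.csv(out$sipsc$table, file.path(out_dir, "sipsc_table.csv"),
                row.names = FALSE)
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  out
}

# two-group comparison table from a tidy per-cell metric frame
group_table <- function(tidy, groups, q = 0.05) {
  if (length(groups) < 2) return(NULL)
  comps <- list()
  for (m in unique(tidy$metric)) {
    a <- tidy$value[tidy$metric == m & tidy$group == groups[1]]
    b <- tidy$value[tidy$metric == m & tidy$group == groups[2]]
    if (sum(is.finite(a)) >= 3 && sum(is.finite(b)) >= 3 &&
        (var(a, na.rm = TRUE) > 0 || var(b, na.rm = TRUE) > 0))
      comps[[m]] <- compare_groups(a, b, label = m)
  }
  if (length(comps) == 0) return(NULL)
  build_results_table(unname(comps), q = q)
}
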