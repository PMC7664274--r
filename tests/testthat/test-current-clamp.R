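# AP detection, per-spike features, passive properties, train metrics.

test_that("flat and subthreshold traces yield no events", {
  flat <- sweep_trace(rep(-70, 20000), 20000, channel = "voltage")
  expect_equal(nrow(detect_aps(flat)), 0)
  # a depolarizing hump with fast rise that never crosses 0 mV
  t <- seq(0, 1, length.out = 20000)
  hump <- -70 + 60 * exp(-((t - 0.5) / 0.005)^2)   # peaks at -10 mV
  sw <- sweep_trace(hump, 20000, channel = "voltage")
  expect_gt(max(clampkit:::dvdt_trace(hump, 20000)), 10)
  expect_equal(nrow(detect_aps(sw)), 0)
  cur <- sweep_trace(rep(0, 100), 20000, channel = "current")
  expect_error(detect_aps(cur), "voltage")
})

test_that("detector counts equal the brute-force oracle on simulated sweeps", {
  mismatches <- 0
  for (cfg in list(list(p = neuron_preset("FS"), amps = c(50, 150, 300)),
                   list(p = neuron_preset("FS", genotype = "null"),
                        amps = c(50, 150, 300)),
                   list(p = neuron_preset("RS-layer6"), amps = c(50, 100, 200)))) {
    rec <- simulate_current_clamp(cfg$p, steps = seq(-20, max(cfg$amps), 10),
                                  seed = 1, noise_sd = 0.2,
                                  baseline = 0.1, tail = 0.02)
    for (s in rec$sweeps) {
      if (nrow(detect_aps(s)) != brute_force_spike_count(s$samples))
        mismatches <- mismatches + 1
    }
  }
  expect_equal(mismatches, 0)
})

test_that("triangular-spike geometry gives the analytic features", {
  sw <- make_spike_sweep(1, 100)
  ev <- detect_aps(sw)
  expect_equal(nrow(ev), 1)
  fe <- ap_features(sw, ev)
  expect_equal(fe$half_width, 1.0, tolerance = 0.02)
  expect_equal(fe$peak_voltage, 30, tolerance = 1e-6)
  # AHP: post-spike minimum minus threshold; flat baseline at -70 and
  # threshold at the foot of the rise -> AHP ~ 0 here
  expect_equal(fe$ahp, -70 - fe$threshold_voltage, tolerance = 0.5)
})

test_that("AHP is the post-peak minimum relative to threshold", {
  # spike rising from -60, peak +20, then a trough at -75 before step end
  sr <- 20000
  v <- rep(-60, 3 * sr / 10)
  i0 <- 2000; half <- 20
  v[i0:(i0 + half)] <- seq(-60, 20, length.out = half + 1)
  v[(i0 + half):(i0 + 2 * half)] <- seq(20, -75, length.out = half + 1)
  v[(i0 + 2 * half):length(v)] <- -75
  sw <- sweep_trace(v, sr, channel = "voltage",
                    command = list(type = "step", amplitude = 50, onset = 0,
                                   duration = length(v) / sr, unit = "pA"))
  fe <- ap_features(sw, detect_aps(sw))
  expect_equal(fe$ahp, -75 - fe$threshold_voltage, tolerance = 0.1)
  expect_equal(fe$threshold_voltage, -60, tolerance = 1)
})

test_that("passive properties follow Ohm's law and the QC cutoffs", {
  sr <- 20000
  base <- rep(-70, sr)                      # 1 s at 0 pA
  sweep0 <- sweep_trace(base, sr, channel = "voltage",
                        command = list(type = "step", amplitude = 0,
                                       onset = 0.2, duration = 0.5,
                                       unit = "pA"))
  # -10 pA step deflecting -1.5 mV from 250 ms into the step
  vm <- rep(-70, sr)
  on <- round(0.2 * sr)
  vm[(on + 1):sr] <- -70 - 1.5 * (1 - exp(-(1:(sr - on)) / (0.02 * sr)))
  sweepm <- sweep_trace(vm, sr, channel = "voltage",
                        command = list(type = "step", amplitude = -10,
                                       onset = 0.2, duration = 0.5,
                                       unit = "pA"))
  rec <- episodic_recording(list(sweepm, sweep0),
                            protocol = list(mode = "current_step",
                                            step_increment = 10),
                            corrected = TRUE, capacitance = 20,
                            access_resistance = 10)
  pp <- passive_properties(rec)
  expect_equal(pp$rmp, -70)
  expect_equal(pp$input_resistance, 150, tolerance = 0.01)
  expect_true(pp$qc_pass)
  # depolarized RMP fails QC with reason RMP
  rec2 <- rec
  rec2$sweeps <- lapply(rec$sweeps, function(s) { s$samples <- s$samples + 10; s })
  pp2 <- passive_properties(rec2)
  expect_false(pp2$qc_pass)
  expect_match(pp2$qc_reason, "RMP")
  # high access resistance fails with reason Ra
  rec3 <- rec; rec3$access_resistance <- 25
  pp3 <- passive_properties(rec3)
  expect_false(pp3$qc_pass)
  expect_match(pp3$qc_reason, "Ra")
})

test_that("train metrics reproduce the arithmetic examples", {
  rec <- make_count_recording(c("20" = 0, "30" = 2, "40" = 4, "50" = 6))
  tm <- train_metrics(rec, rule = "fs")
  expect_equal(tm$auc_low, 90)             # trapezoid over the 10 pA grid
  expect_equal(tm$max_rate, 6)
  expect_equal(tm$rheobase, 30)
  expect_equal(tm$block_index, 0)          # no failures, top = max
  # equal ISIs -> SFA exactly 1
  rec2 <- make_count_recording(c("10" = 0, "20" = 5, "30" = 8))
  tm2 <- train_metrics(rec2, rule = "fs")
  expect_equal(tm2$sfa, 1.0, tolerance = 1e-6)
  # block index: max count 30, count at top injection 10 -> 2/3
  rec3 <- make_count_recording(c("10" = 10, "20" = 30, "30" = 10))
  tm3 <- train_metrics(rec3, rule = "fs")
  expect_equal(tm3$block_index, 2 / 3)
  # fewer than 2 positive sweeps is an error
  expect_error(train_metrics(make_count_recording(c("-10" = 0, "10" = 2)),
                             rule = "fs"), "positive-current")
})

test_that("SFA is missing when no sweep has three interspike intervals", {
  rec <- make_count_recording(c("10" = 0, "20" = 2, "30" = 3))
  tm <- train_metrics(rec, rule = "fs")
  expect_true(is.na(tm$sfa))
})

test_that("summarize_cells builds a tidy table and rejects duplicates", {
  m <- list(a = c(rmp = -70, rin = 150), b = c(rmp = -72, rin = 180))
  tidy <- summarize_cells(m, c("wt", "null"))
  expect_equal(nrow(tidy), 4)
  expect_setequal(names(tidy), c("cell_id", "group", "metric", "value"))
  expect_error(summarize_cells(list(), character(0)), "no cells")
  m2 <- list(a = c(x = 1), a = c(x = 2))
  expect_error(summarize_cells(m2, c("g", "g")), "unique")
  # SEM convention check via compare_groups: sd/sqrt(n)
  cmp <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$sem_a, sd(c(1, 2, 3)) / sqrt(3), tolerance = 1e-12)
  expect_equal(round(cmp$sem_a, 3), 0.577)
})

test_that("FS cohorts with reduced sodium conductance fire at significantly lower max rates", {
  max_rate <- function(genotype, i) {
    set.seed(9000 + i + 100 * (genotype == "null"))
    p <- neuron_preset("FS", genotype = genotype)
    for (f in c("c_m", "g_leak", "g_na", "g_k"))
      p[[f]] <- p[[f]] * exp(rnorm(1, 0, 0.05))
    rec <- simulate_current_clamp(p, seed = 9000 + i, noise_sd = 0.2,
                                  baseline = 0.1, tail = 0.02)
    train_metrics(rec, rule = "fs")$max_rate
  }
  wt <- vapply(1:11, function(i) max_rate("wt", i), numeric(1))
  ko <- vapply(1:11, function(i) max_rate("null", i), numeric(1))
  tt <- t.test(wt, ko, alternative = "greater")
  expect_lt(tt$p.value, 0.05)
})
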