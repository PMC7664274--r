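---
title: "Models and methods behind clampkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clampkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampkit)
```

clampkit quantifies whole-cell patch-clamp studies of cortical neuron
excitability: action potentials from current-clamp step families, sodium
currents from voltage-clamp families and slow ramps, spontaneous inhibitory
synaptic currents, junction potentials, and the group and survival
statistics that tie a study together. Because public archives rarely hold
raw episodic recordings for this kind of study, the package also ships
simulators that generate every input class with known ground truth, so the
entire pipeline is testable end to end. This vignette documents the models,
the conventions, and the choices made where the design was genuinely open.

## The neuron model behind the current-clamp simulator

`simulate_current_clamp()` integrates a single-compartment conductance
model: a leak, a transient sodium current with instantaneous cubic
activation and first-order inactivation, a non-inactivating persistent
sodium fraction, and a delayed-rectifier potassium current. The kinetics
follow the classic fast-spiking interneuron formulation (Wang–Buzsáki-type
rate functions) with two extensions:

* *tempo factors* `phi_h` and `phi_n` scale the inactivation and rectifier
  rates — large values give narrow spikes and deep fast
  afterhyperpolarizations (the FS phenotype), small values the broader
  spikes of regular-spiking pyramidal cells;
* a *sodium voltage shift* `na_shift` moves the sodium (and persistent
  sodium) voltage dependence along the voltage axis. Without it, the
  model's sodium window current destabilizes the resting state at the
  depolarized resting potentials of fast-spiking cells; shifting the
  channel a few millivolts depolarized restores a quiet, stable rest
  without touching the leak.

Integration is fixed-step (default 0.01 ms): gates use exponential-Euler
updates and the membrane equation relaxes exactly toward its instantaneous
steady state each step, which is unconditionally stable. Tests verify that
halving the step does not change spike counts. Noise is added only to the
recorded signal, never inside the integrator, so a recording is the
deterministic trajectory plus i.i.d. Gaussian measurement noise, and every
simulator call requires a seed.

The four presets (`FS`, `RS-layer5`, `RS-layer6`, `RS-subiculum`) are
calibrated once against the passive and spike-shape ranges of the
populations the demo study emulates: resting potentials near −71 to −85 mV,
input resistances from ~90 MΩ (layer 5) to ~460 MΩ (layer 6), FS
half-widths inside the 0.5–1.2 ms band with afterhyperpolarizations near
−20 mV, and a layer-6 preset that genuinely enters depolarization block
(spike failures, maximum voltage below 0 mV) by the top of its 200 pA
protocol. The genotype contrast is expressed as a sodium-conductance scale
`g_scale` (0.65 for FS, 0.60 for layer 6); the null layer-6 preset also
lowers capacitance by ~25%, lowers leak (raising input resistance), and
depolarizes rest, matching the passive shifts reported for that
population. One caveat is intrinsic to point models: their f–I curves are
steeper than real neurons', so absolute maximal rates run high and the
genotype contrast on maximum rate is carried by rheobase shifts, reduced
counts, and earlier block rather than by the saturation a real FS cell
shows.

The demo cohorts add mild lognormal inter-cell heterogeneity (5% SD on
capacitance and conductances, 1 mV on resting potential, 1.5 mV on gating
midpoints in the voltage-clamp cohorts). Without it every "cell" is the
same dynamical system and group variances collapse to measurement noise,
which makes null contrasts spuriously significant; 5% reproduces
standard-error-to-mean ratios typical of patch-clamp group data.

## The voltage-clamp simulators and the permeability analysis

The step-family simulator assumes an ideal clamp and writes the
open-channel current with the Goldman–Hodgkin–Katz (GHK) constant-field
form, so the permeability analysis can invert it exactly:

$$I = P_s z_s^2 \frac{E F^2}{RT}\,
   \frac{[S]_i - [S]_o e^{-z_s F E / RT}}{1 - e^{-z_s F E / RT}}$$

with the analytic limit $I = P z F ([S]_i - [S]_o)$ at $E = 0$.
Whole-cell current density (pA/pF) maps to the per-area form through a
specific capacitance of 1 µF/cm². `ghk_permeability()` is the exact
algebraic inversion and refuses voltages at the reversal potential, where
the concentration bracket vanishes.

Channel gating truth is a pair of Boltzmann curves (activation midpoint and
slope, inactivation midpoint and slope). Activation is modeled first-order
with a fast, voltage-independent time constant (0.15 ms) against a slow
inactivation constant (5 ms). Because the two time constants are voltage
independent, the peak open probability at every test potential is the same
fixed fraction of $m_\infty(V)$, so normalizing peak permeability to its
maximum recovers the activation curve *exactly* in the noiseless case —
the property the fit-recovery tests exercise. The availability protocol
uses 500 ms conditioning prepulses from −120 to −10 mV (long against the
inactivation constant) and a fixed test pulse near the peak-current
voltage; this protocol is a documented package choice, since availability
protocols vary between laboratories.

Activation analysis works on GHK-derived permeability normalized to its
maximum, not on chord conductance: permeability is the quantity the
constant-field equation defines, and the normalized curve is invariant to
overall density scaling (a scaled-down mutant and a wild-type cell give the
same curve, which is what makes gating comparisons meaningful). Peak
detection uses a 0.2–10 ms window after step onset, skipping the capacitive
transient; no P/N leak subtraction is applied — leak is negligible in the
simulator and this is flagged as a limitation for real recordings.

For persistent current, a 150 mV / 3 s ramp from −120 mV is slow against
channel kinetics, so the non-inactivating fraction follows its activation
curve instantaneously: $I(V) = f_{pers} P_{max} m_\infty(V)\,\mathrm{GHK}(V)$.
`analyze_ramp()` removes residual transient spikes by flagging samples
whose |dI/dt| exceeds 8 robust (MAD) SDs of the derivative, expanding each
flagged run by 1 ms to reach local baseline, and bridging the gap by linear
interpolation; a trace needing more than 20% excision is refused as
unusable. The detection rule is a package choice (only the interpolation
repair is standard); the 8-SD multiple keeps the false-flag rate on clean
ramps effectively zero while catching transients an order of magnitude
above the noise. Density is read at −20 mV (mean over ±1 mV of command) on
the four-trial average.

## Spontaneous IPSC detection

Events are Poisson in time with truncated-Gaussian amplitudes and a
unit-peak biexponential kernel (0.8 ms rise, 8 ms decay), rendered inward
at −80 mV as recorded under a high-chloride internal with glutamatergic
blockade. The detector is a deterministic matched filter: the rectified
trace is correlated with the zero-mean template (FFT, zero-padded to a
highly composite length), local score maxima above 4 robust SDs become
candidate onsets with a 3 ms refractory, and amplitude is the post-onset
peak minus the median baseline of the preceding 5 ms. Candidates below the
10 pA amplitude threshold are discarded. The original analysis used
interactive software with visual curation of events; a deterministic
detector is the reproducible substitute, so correctness is assessed
against synthetic ground truth (zero false positives on noise-only traces
at SNR ≥ 5; >95% of above-threshold events recovered), not against any
published event count.

Cumulative-distribution comparisons sample 100 events per cell (with
replacement when a cell has fewer — the unweighted rule keeps every cell's
contribution equal) and pool across cells before the two-sample
Kolmogorov–Smirnov test. Cells with zero events are excluded with a
warning.

## Junction potentials

`henderson_ljp()` evaluates the Henderson mixture formula with limiting
relative ionic mobilities (mechanical mobility relative to K⁺, the
convention of the standard junction-potential calculators). The returned
value is the bath potential relative to the pipette; corrected membrane
voltages are recorded values minus this number, which is what
`apply_junction_correction()` does — once, with a guard against double
correction.

`dissociate_recipe()` turns printed recipes into ionic species. Two
titration conventions are offered, and the difference matters more than
any mobility-table detail:

* **printed** (default): each printed component enters once; weak acids
  contribute their predominant anion at the recording pH (HEPES at its
  Henderson–Hasselbalch fraction for pKa 7.55; EGTA, GTP and
  phosphocreatine as di-anions); the unstated quantity of pH base is not
  modeled. The composition is not formally electroneutral — the deficit is
  carried by the unmodeled base — but this mirrors how recipes are typed
  into instrument calculators, and it reproduces all three instrument-
  calculated corrections of the emulated study within 0.6 mV.
* **counterion**: base cations are added to neutralize every acid and
  electroneutrality is enforced (net imbalance under 5% of ionic
  strength). Chemically stricter, but the extra ~25 mM of fast cation
  shifts a K-gluconate/ACSF junction about +1.5 mV away from the
  instrument value.

Large organic polyanions (EGTA, nucleotides, phosphocreatine) carry class
mobility values (0.22–0.30); at their few-millimolar concentrations a
generous error in these moves the result well under 1 mV, which is why the
±1 mV working tolerance quoted for recipe-level junction potentials is
appropriate.

## Statistics

Group comparisons are unpaired two-tailed t-tests with a variance gate: an
F-test on the two variances selects Welch's correction when its p < 0.05
and the pooled Student test otherwise. The source analyses mark Welch per
row without stating a rule, so the gate is explicit here and either form
can be forced. The D'Agostino–Pearson omnibus normality test (transformed
skewness plus transformed kurtosis, χ² with 2 df) is implemented directly —
no installed R package provides it — and validated against an independent
reference implementation; it requires n ≥ 8, so the per-group normality p
is reported as missing below that.

Multiple-comparison control uses the two-stage linear step-up procedure:
stage one runs the Benjamini–Hochberg step-up at level q/(1+q) to estimate
the number of true nulls, stage two reruns the step-up with the level
scaled by m/m₀. The FDR family is all rows of one results table, the
natural analogue of testing all metrics of one figure's panel together;
`build_results_table()` applies it and stars only FDR-significant rows at
the 0.05/0.01/0.005/0.0001 thresholds. Simulation tests confirm empirical
FDR control at q = 0.05 and that the procedure rejects a superset of
single-stage BH when signals are present.

Survival analysis delegates to the standard product-limit estimator and
Mantel–Cox log-rank test (the `survival` package), with the median defined
as the first day at which estimated survival reaches 0.5 or below and ties
handled by the hypergeometric variance; hand-worked product-limit and
2×2-per-day oracles in the test suite pin the conventions down. The
survival simulator draws death days from a discrete daily hazard — zero
before an onset day, then a constant geometric hazard chosen so cumulative
survival crosses 0.5 at the target median.

## Quality control

Current-clamp cells are excluded when access resistance exceeds 20 MΩ or
the resting potential is depolarized above −64.3 mV; nucleated-patch
recordings additionally require input resistance of at least 1 GΩ. The
resting potential is measured over the first 100 ms of the 0 pA sweep — a
stand-in for the "immediately after break-in" reading, which has no
equivalent in synthetic data. Input resistance is Ohm's law on the −10 pA
step read 250 ms into the step. Every exclusion is logged with its reason
by `run_study()`.

Two operational definitions deserve emphasis because alternatives exist in
the literature:

* **AP threshold** is the latest sub-to-suprathreshold crossing of
  dv/dt = 10 mV/ms that precedes the spike's 0 mV crossing. At very high
  firing rates the interspike trajectory can stay above 10 mV/ms for most
  of the interval, in which case the assigned threshold migrates toward
  the preceding trough; this is a property of the definition itself, not
  of the implementation.
* **Half-width baseline** is the threshold-to-peak amplitude (half-width
  measured between the half-amplitude crossings). Measuring from the AHP
  trough instead would systematically lengthen half-widths.
* **Depolarization block** is reported as 1 − (count at highest
  injection)/(maximum count). The alternative reading — the raw ratio —
  is inconsistent with block percentages that grow as firing collapses,
  so the complement is used and the per-sweep failed spikes (maximum
  voltage below 0 mV) are recorded alongside.

## Problem sizes used by the tests

The test suite exercises the pipeline at the sizes the methods are meant
for while staying desk-scale: AP-detector/oracle equivalence over ~220
simulated sweeps across presets, genotypes and noise seeds; FS cohort
contrasts at 11 + 11 cells; voltage-clamp stage recovery at 10 + 8 cells;
Boltzmann recovery over 500 noisy replicates; FDR control over 1000
replicates of 100 tests; sIPSC cohort structure over 100 replicates of
12 + 12 cells at the ground-truth event level, with the detector validated
end to end on rendered 60 s traces separately (rendering and filtering
5-minute traces for every replicate adds nothing to what the two checks
establish jointly). The demo study writer defaults to the full
figure-matched cohort plan (11/11 FS, 10/8 dissociated, 10/10 patches,
12/12 sIPSC cells at 5 minutes, 62/60 survival subjects).

## What passing tests do and do not show

The simulators give the pipeline inputs with *known* ground truth and
realistic protocols, noise levels and effect sizes, so green tests show
the analysis recovers what was put in — detection thresholds behave, fits
are unbiased at realistic noise, QC rules fire, statistics control their
error rates. They do not show that real recordings satisfy the model
assumptions: ideal clamp (no series-resistance error), no electrode drift,
no leak, stationary noise, a single sodium-channel population, and
curation-free event detection. On real data those are exactly the places
to look first.
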