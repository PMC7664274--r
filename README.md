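# clampkit

Simulation and quantification of whole-cell patch-clamp electrophysiology
for studies of cortical neuron excitability — the kind of study that
contrasts fast-spiking (parvalbumin-positive) interneurons and pyramidal
neurons between genotypes using current-clamp step families, sodium-current
voltage clamp, slow voltage ramps, spontaneous IPSC recordings, and
survival follow-up.

Raw episodic recordings for such studies are rarely deposited, so clampkit
pairs every analysis stage with a ground-truth simulator: a
single-compartment conductance neuron (leak + transient Na with
instantaneous cubic activation + persistent Na fraction + delayed-rectifier
K, exponential-Euler integration at 0.01 ms), an ideal-clamp sodium-channel
generator built on the Goldman–Hodgkin–Katz (GHK) flux so permeability fits
can recover their inputs exactly, a Poisson/biexponential synaptic-event
generator, and a discrete-hazard survival generator. The full pipeline is
therefore testable end to end without any external data.

## What it computes

* **Current clamp** — action potentials defined as a 0 mV crossing
  subsequent to dv/dt > 10 mV/ms (the dv/dt crossing is the threshold);
  per-spike half-width, peak dv/dt, and afterhyperpolarization (post-spike
  minimum minus that spike's threshold); resting potential, input
  resistance by Ohm's law on a −10 pA step at 250 ms; f–I counts, maximum
  firing rate, rheobase, spike-frequency adaptation (last/second
  interspike interval), depolarization-block index
  (1 − count@top/max count, with failed spikes peaking below 0 mV
  excluded from counts), and the area under the count–current curve up to
  50 pA. QC: access resistance ≤ 20 MΩ and resting potential ≤ −64.3 mV.
* **Voltage clamp** — peak I–V densities (pA/pF) with reference densities
  at −25 mV (dissociated cells) or −20 mV (nucleated patches, which also
  require Rin ≥ 1 GΩ); permeability from the GHK current equation

  $$I_s = P_s z_s^2 \frac{EF^2}{RT}\,
     \frac{[S]_i - [S]_o e^{-z_sFE/RT}}{1 - e^{-z_sFE/RT}}$$

  inverted exactly per test potential; Boltzmann fits
  $y = 1/(1+e^{(V_{1/2}-V)/k})$ to normalized permeability (activation)
  and prepulse availability (inactivation); persistent current on
  150 mV/3 s ramps with automatic transient excision and linear
  interpolation, density read at −20 mV on the four-trial average.
* **Synaptic** — matched-filter sIPSC detection with a 10 pA amplitude
  threshold, per-cell mean frequency/amplitude, pooled cumulative
  distributions built from 100 events per cell, two-sample
  Kolmogorov–Smirnov comparisons.
* **Junction potentials** — the Henderson equation on dissociated printed
  recipes (`dissociate_recipe()`, `henderson_ljp()`), with a mobility
  table of limiting relative ionic mobilities.
* **Statistics** — unpaired two-tailed t-tests gated between Student and
  Welch by an F-test on variances, D'Agostino–Pearson omnibus normality,
  the two-stage (Benjamini–Krieger–Yekutieli) FDR step-up at q = 0.05
  across each results table, Kaplan–Meier curves with medians, and the
  Mantel–Cox log-rank test.

`make_demo_dataset()` writes a complete synthetic study (figure-matched
cohort sizes by default) in a plain CSV+JSON container, and `run_study()`
analyzes it from the manifest with QC logging and deterministic reruns.

## Worked example

```r
library(clampkit)

# a wild-type and a sodium-deficient fast-spiking interneuron
wt <- simulate_current_clamp(neuron_preset("FS"), seed = 1, noise_sd = 0.2)
ko <- simulate_current_clamp(neuron_preset("FS", genotype = "null"),
                             seed = 1, noise_sd = 0.2)
train_metrics(wt, rule = "fs")$max_rate   # 300
train_metrics(ko, rule = "fs")$max_rate   # 254  (and rheobase 50 -> 60 pA)

# sodium-current family: the permeability fit recovers the gating truth
truth <- channel_truth(p_max = 1.2e-4, act_vhalf = -35.45, act_k = 6.47)
rec <- simulate_ina_step_family(truth, noise_sd = 0)
iv <- peak_iv(rec, reference_voltage = -25)
iv$reference_density                       # -347.9 pA/pF at -25 mV
activation_curve(iv, truth_context(truth))$fit
# Boltzmann activation fit: V1/2 = -35.48 mV, k = 6.50 mV, A = 1.000

# junction potentials for the bundled recording solutions
round(study_junction_potentials(), 2)
#   current_clamp    na_recording nucleated_patch
#           14.05            2.97            4.08
```

The current-clamp numbers say the sodium-depleted cell starts firing
later and sustains fewer spikes at every current; the
voltage-clamp block shows the analysis recovering the generator's
activation midpoint to 0.03 mV in the noiseless case; the junction
potentials are what the correction stage subtracts from recorded voltages
for each solution pairing.

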