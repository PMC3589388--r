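# stimplast

Simulation and analysis of **spike-triggered microstimulation plasticity**
in a thalamocortical network model.

Closed-loop microstimulation — an electrical pulse delivered a fixed 5 ms
after each spike of a recorded reference neuron — can reorganize
somatosensory cortex. `stimplast` implements, for simulated data, the full
computational study of this phenomenon: an event-driven spiking network of
integrate-and-fire neurons with spike-timing-dependent plasticity (STDP),
three-phase stimulation protocols (tactile testing / conditioning /
tactile testing), and the before/after spike-train analysis pipeline that
quantifies the induced changes.

The package is aimed at computational neuroscientists studying
stimulation-induced plasticity and at methods developers who need a
controlled testbed for ensemble spike-train statistics.

## What it computes

**Model.** 14 neuronal populations (thalamic relay + reticular cells;
pyramidal, fast-spiking and low-threshold-spiking cells in cortical layers
2/3, 4, 5, 6), sized in multiples of 495 neurons (1980 at the default
scale). Each neuron carries one membrane state V (mV relative to rest);
synaptic events add per-channel contributions `w·E_i` (i = AMPA, NMDA,
GABA_A) decaying with receptor time constants; a cell fires when
`V_thresh ≤ V < V_block` (depolarization blockade) outside its refractory
period. Within-layer connectivity is distance-dependent,
`p(d) = p_max · exp(−d/λ)`. Excitatory cortical synapses are plastic:
additive STDP with a ±10 ms window and weights clamped to 5× baseline.
Touch is a suprathreshold volley to the central 25% of relay cells;
microstimulation is a forced doublet to a random 10% of layer-5 pyramidal
cells, triggered online 5 ms after each reference-unit spike.

**Analysis.** Gaussian-smoothed PSTHs with peak / above-baseline area /
sharpness and the 3-SD touch-responsiveness rule; sliding-window (20 ms /
3 ms) Fano factors; shuffle-corrected pairwise mutual information on
10 ms binned counts; sub-ensemble multi-information; crosscorrelograms
and count-correlation matrices; percentage-change statistics with
Wilcoxon signed-rank, Kolmogorov–Smirnov and bootstrap tests.

**Synthetic sessions.** `generate_session()` produces experiment-like
recordings (42 ± 8 units, ~10 Hz rates, 0.5 Hz touches) with exactly
injectable before/after effect sizes, so every analysis stage is testable
against known ground truth.

## Worked example

```r
library(stimplast)

cfg <- default_model_config(scale = 1)       # 495 neurons
res <- run_experiment(cfg, mode = "spike_triggered",
                      durations_s = c(100, 100, 100), seed = 1)
res$comparison
```

```
Before/after tactile-phase comparison
              metric   before    after     pc
        peak_rate_hz  9.42300 11.28000 19.700
                 auc  0.20250  0.21890  8.100
 sharpness_hz_per_ms  0.26420  0.33010 24.900
    baseline_rate_hz  3.19600  3.68000 15.200
       fano_baseline  0.95210  0.94550 -0.695
    fano_decrease_pc 14.93000 20.77000 39.100
        mean_mi_bits  0.00889  0.00904  1.700
     multi_info_bits  0.06693  0.06786  1.380
    mean_correlation  0.14560  0.14450 -0.778

Responsiveness proportions:
     always before_only  after_only       never 
      0.412       0.079       0.193       0.316 

Pairs with increased MI: trigger 65%, non-trigger 47%
```

Reading this: after 100 s of spike-triggered conditioning the ensemble
peak touch response of this session rose ~20%, the stimulus-induced Fano
reduction deepened (14.9% → 20.8%), 41% of cortical units were
touch-responsive in both phases, and unit pairs containing the
triggering reference unit gained MI more often than other pairs (65% vs
47%). Single sessions are noisy; seed-averaged results come from
`run_conditioning_batch()`.

A synthetic-data session with a known injected effect:

```r
rec <- generate_session(
  ensemble_spec(n_units = 30,
                effect = before_after_effect(peak_gain_pc = 8)),
  durations_s = c(180, 0, 180), seed = 1)
cmp <- compare_phases(rec)
cmp$summary[cmp$summary$metric == "peak_rate_hz", ]
```

A command-line wrapper is installed at
`system.file("cli", "stimplast", package = "stimplast")` with
`synth`, `run`, `analyze` and `report` subcommands.

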