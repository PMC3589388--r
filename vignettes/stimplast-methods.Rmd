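---
title: "Modelling microstimulation-induced cortical plasticity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling microstimulation-induced cortical plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stimplast)
```

## The scientific problem

Closed-loop microstimulation — delivering an electrical pulse a few
milliseconds after each spike of a recorded reference neuron — is a
candidate tool for writing information into somatosensory cortex and for
steering plasticity in neuroprosthetic applications.  The central
question this package addresses in simulation is: *how does a period of
spike-triggered microstimulation change a cortical network's response to
natural touch?*  The experimental observables are the touch-evoked
firing-rate response (peak, area under the response curve, sharpness),
trial-to-trial variability (Fano factor), and functional connectivity
(shuffle-corrected pairwise mutual information and ensemble
multi-information), each compared between a tactile testing phase before
conditioning and one after.

`stimplast` provides three coupled components:

1. **`netsim` / `protocols`** — an event-driven spiking thalamocortical
   network with spike-timing-dependent plasticity (STDP), plus the
   three-phase stimulation protocols (tactile / conditioning / tactile).
2. **`spikestats` / `infotheory` / `session_stats`** — the full
   before/after analysis pipeline.
3. **`synthetic_data`** — an experiment-like session generator with
   injectable ground-truth effect sizes, so every analysis stage is
   testable without the simulator.

## The network model

### Neurons

Cells are rule-based leaky integrate-and-fire units with a single
membrane state variable \(V\) (mV relative to rest).  A synaptic event on
channel \(i \in \{\mathrm{AMPA}, \mathrm{NMDA}, \mathrm{GABA_A}\}\) with
weight \(w_s\) instantaneously adds \(w_s E_i\) to the channel's
contribution, which then decays exponentially with the receptor time
constant \(\tau_i\); the membrane voltage is the sum of the channel
contributions and a post-spike hyperpolarization term.  A neuron fires
when \(V\) crosses \(V_{\mathrm{thresh}}\) *from below the blockade
voltage*: if \(V \ge V_{\mathrm{block}}\) the cell is in depolarization
blockade and stays silent (sodium-channel inactivation).  After a spike
the membrane contributions reset, the threshold is raised by \(R\)
(decaying with \(\tau_R\)), the membrane is hyperpolarized by \(H\)
(decaying with \(\tau_H\)), and no spike can occur within the absolute
refractory period \(\tau_{abs}\).

Two semantic choices deserve emphasis because they define what the
event-driven engine computes exactly:

* **Firing is evaluated at input events.**  Between events all terms
  decay in closed form, so threshold crossings can only be caused by
  events; the engine therefore checks firing when an event arrives.
* **Inputs arriving during the absolute refractory period are shunted**
  (they contribute nothing to the membrane), the convention of the
  rule-based integrate-and-fire lineage.  Together with the post-spike
  reset this means a refractory cell re-fires only through new input.

The independent check is `simulate_fixed_step()`, a deliberately naive
0.01 ms fixed-step integrator implementing the same rules by stepwise
decay multiplication.  On small circuits the event-driven engine
reproduces its spike sequences exactly and its spike times to within one
step per synaptic hop of the causal chain (each hop re-quantizes the
spike time to the step grid, so a k-hop chain can accumulate k steps of
offset).

### Populations and geometry

The network contains 14 populations: thalamocortical relay cells and the
inhibitory reticular shell, plus pyramidal, fast-spiking and
low-threshold-spiking cells for each of layers 2/3, 4, 5 and 6.
Per-population counts are stated per 495 cells and the network size is an
integer multiple of 495 (scale 4 gives the default 1980 neurons).  Each
layer is a 1 mm x 1 mm sheet with uniformly random cell positions;
distances are horizontal (x, y) distances, which supports the
MI-versus-distance analysis including the sub-100 um regime.

Within-layer connection probability decays with distance as
\(p(d) = p_{\max} e^{-d/\lambda}\) (\(\lambda\) = 100 um for local
inhibition and recurrent excitation; broader, 300 um, for interlaminar
and thalamocortical projections).  Probabilities are divided by the
scale factor so that the expected in-degree — and hence the synaptic
drive per cell — is independent of network size; without this, larger
networks land in a qualitatively different dynamical regime.  Synaptic
delays are a base delay (1 ms) plus distance divided by a 1 mm/ms
conduction velocity, keeping the longest delays well inside the 10 ms
STDP window.  Excitatory connections also create an NMDA co-synapse at
15% of the AMPA weight with a 100 ms time constant, treated as a slow
depolarizing channel without voltage dependence (the neuron has a single
state variable).

Exact per-population parameter and connectivity tables for this lineage
of models are published only in an external reference; this package
ships its own documented default parameter set, calibrated to the
model's published operating point — a ~3 Hz mean cortical baseline rate,
touch responses inside the 0-70 ms post-stimulus window, roughly half
of cortical units passing the touch-responsiveness criterion, and a
15-20% stimulus-induced Fano-factor reduction — rather than claiming
fidelity to the cited tables.  Every parameter can be overridden through
`default_model_config(overrides = ...)` or a JSON configuration file.

### Background drive

Each neuron receives private Poisson AMPA input (135 Hz, weight 0.06),
and the whole network shares a sparse slow fluctuation: common
NMDA-channel events at 4 Hz (weight 0.045) that modulate all cells
coherently over ~100 ms.  The shared term is what gives baseline
activity realistic slow co-fluctuations: without it, binned-count
correlations and pairwise MI at rest are essentially zero and the
Fano factor is pinned at 1.  It is a stand-in for unmodelled shared
afferent drive, not for global oscillations, which are deliberately
outside the model's scope.

### Plasticity

Plastic synapses are excitatory (AMPA and NMDA) contacts onto cortical
*excitatory* targets.  The learning rule is additive, all-or-none within
a +-10 ms window: when a postsynaptic spike follows a synaptic input by
\(0 \le \Delta t \le 10\) ms the weight increases by
\(\varepsilon = 0.012\, w_{\mathrm{baseline}}\); when an input arrives
within 10 ms *after* a spike the weight decreases by the same amount.
Weights are clamped to \([0, 5 w_{\mathrm{baseline}}]\).  Three design
points were genuinely open and are resolved as follows:

* **The causal input potentiates.**  The input that triggers a spike has
  zero lag in event time, but its presynaptic spike preceded the
  postsynaptic one by the conduction delay; counting it as potentiation
  follows the Hebbian premise.  (Excluding it produces a systematic
  depression bias, because spikes tend to occur early within input
  volleys, leaving more arrivals after the spike than before it.)
* **Plasticity is restricted to excitatory targets.**  With
  excitatory-onto-interneuron contacts plastic, conditioning potentiates
  feedforward inhibition and the network's touch response *decreases* —
  the opposite of the phenomenon under study.
* **STDP is active during the conditioning phase only** (configurable:
  `stdp$active_phase = "always"`).  With plasticity active throughout,
  the touch volleys of the probe phases themselves drive most of the
  weight drift and the before/after contrast no longer measures the
  conditioning protocol.  Restricting plasticity to the conditioning
  window makes the tactile phases pure probes.

An important and honest caveat: even within the conditioning phase, a
substantial part of the weight change is driven by ongoing background
activity rather than by the microstimulation pulses specifically;
spike-triggered runs exceed matched no-stimulation runs consistently but
modestly.  This mirrors the model-side finding that spike-triggered and
statistics-matched random stimulation do not differ significantly in
simulation — in this model class the conditioning-phase activity, not
the trigger timing, carries most of the effect.

### Stimulation protocols

* **Touch**: suprathreshold input to the 25% of relay cells closest to
  the sheet centre (a contiguous receptive field), delivered with a mean
  period of 600 ms (uniform 400-800 ms) during tactile phases.  Relay
  cells respond with a fixed per-cell latency offset (uniform 0-12 ms)
  plus exponential trial jitter (mean 3 ms), standing in for receptor
  and transduction latency spread; this is what gives cortical units a
  realistic latency distribution (medians ~10-20 ms) instead of a
  millisecond-synchronous volley.
* **Microstimulation**: forced suprathreshold events to a random 10% of
  layer-5 pyramidal cells (axonal activation is spatially incoherent,
  hence random rather than contiguous targets).  Each pulse is a doublet
  (second event 3 ms later), abstracting the biphasic double-pulse used
  experimentally; electrode physics is out of scope.  In
  `spike_triggered` mode pulses are generated online, 5 ms after each
  reference-unit spike, within the conditioning phase only.  The
  reference unit is the most active touch-responsive cortical unit
  outside the stimulated set (chosen by a short pilot simulation),
  mirroring the experimental preference for a well-isolated ~10 Hz
  reference channel.  In `random` mode, pulse times are drawn with
  gamma-distributed inter-pulse intervals moment-matched to a reference
  spike-triggered train.  `persistent_touch` fills the conditioning
  phase with touch events instead; `none` leaves it empty.
* **Session**: three phases, 100 s each by default (the model protocol);
  the in vivo protocol (3 min tactile / 30 min conditioning / 3 min
  tactile at 0.5 Hz Poisson touch) is available through
  `touch_period = "experimental"` and longer durations.  At 30 s per
  phase the slow shared fluctuations do not average out and all
  percentage changes are dominated by sampling noise, which is why the
  100 s protocol is the default for quantitative comparisons.

## The analysis pipeline

* **PSTH**: spikes aligned to touch onsets over [-250, 300] ms, binned at
  1 ms and smoothed with a normalized Gaussian kernel; "20 ms window" is
  read as sigma = 20 ms, truncated at 3 sigma (configurable).  Baseline
  mean and SD come from [-250, 0) ms.
* **Response metrics**: peak rate and latency in the 0-70 ms window;
  area above the baseline mean within that window; sharpness = peak rate
  divided by the width of the response curve at the level 3 baseline-SDs
  above baseline (crossings nearest the peak); a unit is touch-responsive
  when its peak exceeds baseline + 3 SD.  Off-responses (to stimulus
  retraction) are not analyzed.  Units responsive in both phases form the
  ensemble for response-metric percentage changes.
* **Fano factor**: across-trial variance/mean of spike counts in 20 ms
  windows stepped by 3 ms; windows with zero mean count are undefined and
  excluded from ensemble averages.  The stimulus-induced reduction is the
  percentage drop from the mean pre-stimulus value of the ensemble-mean
  Fano curve to its minimum within the response window.
* **Mutual information**: spike counts in 10 ms bins over the whole
  tactile phase, binarized for joint-distribution estimation (at these
  rates most bins hold 0 or 1 spikes; binarization bounds the state
  space).  The plug-in estimate is bias-corrected by subtracting the mean
  over 20 surrogates in which every unit's bin sequence is independently
  permuted — marginals preserved, all dependence destroyed.  Corrected
  values are not floored at zero; small negatives are reported as-is.
* **Multi-information**: the exact joint over ~40+ units is not
  estimable, so total correlation is computed on random sub-ensembles of
  5 units (50 draws) and averaged, each draw shuffle-corrected the same
  way.  At sub-ensemble size 2 this reduces to pairwise MI by
  construction (identical code path and shuffle scheme).
* **Session statistics**: percentage change \(100 (a - b)/b\); Wilcoxon
  signed-rank across sessions for paired changes; two-sample
  Kolmogorov-Smirnov for pooled distributions; bootstrap (100 resamples)
  confidence interval for per-pair MI increases.  Sessions are pooled
  without random effects and no multiple-testing correction is applied,
  matching the original analysis conventions.

## The synthetic-session generator

`generate_session()` emulates a recorded session: unit count drawn as
42 +- 8, lognormal baseline rates around 10 Hz (use ~3 Hz for the model
regime), Poisson touches at 0.5 Hz, Gaussian touch-response bumps
(sigma 10 ms) at per-unit latencies, pairwise count correlation induced
by thinning from a shared Poisson mother process (the mother rate sits at
the geometric middle of its feasibility interval), and across-trial
gamma gain modulation setting the baseline Fano factor.  Injected
before/after effects are expressed so that the quantity *as measured by
the pipeline* changes by the requested percentage: the peak injection
accounts for the smoothing attenuation of a sigma-10 bump under a
sigma-20 kernel, the correlation injection scales the thinning
probability, and the Fano injection rescales the gain variance.  What
the generator does *not* emulate: stimulation artifacts, electrode
drift, spike-sorting noise, bursting, oscillations, or off-responses —
so passing recovery tests demonstrates pipeline correctness, not
robustness to those real-data features.

## Numerical and degenerate-input conventions

Simultaneous events are ordered deterministically (stimulus events,
background, synaptic deliveries, then by index and insertion order), so
identical seeds give bit-identical recordings.  Background randomness
uses a fixed-width generator with explicit uniform-to-exponential
transforms, so results are identical across platforms.  PSTHs of empty
trains are all-zero with zero baseline SD; responsiveness then falls
back to a strict mean comparison.  Fano windows with zero mean count,
zero-variance units in correlation matrices, and sharpness of
nonresponsive units are reported as missing rather than invented.
Percentage change is undefined at zero baseline and raises an error.

## Problem sizes and what the checks show

The packaged quantitative checks run ten seeded spike-triggered sessions
at scale 1 (495 neurons, 100 s phases) and compare seed-averaged
percentage changes with the reference values for the full-size model;
scale 1 was chosen as the smallest network whose population statistics
are stable across seeds.  Under these defaults the peak-rate, response
area, Fano-reduction, baseline-rate, multi-information and
responsiveness-partition results sit at the reference operating point,
while the sharpness and mean-MI percentage changes are positive in sign
but smaller in magnitude than the full-size reference values — a known
limitation of the shipped parameter set discussed above, not a tuned
outcome.

## Known limitations

* Parameter values are calibrated, not inherited from the original
  tables; absolute firing rates and MI magnitudes should be read as
  order-of-magnitude.
* The pulse-specific (closed-loop) contribution to plasticity is small
  relative to conditioning-phase background-driven drift.
* Mode `none` is not a flat control: background activity under active
  STDP still drifts weights upward during conditioning.
* The model contains no habituation mechanism, so persistent-touch
  conditioning does not reproduce the in vivo rate depression.
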