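---
title: "A V1 layers-2/3 microcircuit model and directed phase-flow analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A V1 layers-2/3 microcircuit model and directed phase-flow analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`microflow` simulates a conductance-based leaky integrate-and-fire (LIF)
microcircuit of primary visual cortex layers 2/3 — one excitatory
pyramidal (Pyr) population and three inhibitory interneuron subtypes
(PV, SOM, VIP) — and quantifies how disrupting the excitatory/inhibitory
(E/I) balance reshapes oscillatory population activity and the direction
of information flow between populations. This vignette documents the
model, the analysis stack, and the numerical and design choices, in
enough detail that a reader can audit or extend any stage.

## The model

### Populations and E/I conditions

The reference ("control") circuit contains 13,257 neurons: 10,341 Pyr,
1,341 PV, 875 SOM and 700 VIP cells. The E/I ratio is defined as the
Pyr count divided by the combined interneuron count; for the control
circuit that is 10341/2916 ≈ 3.546, conventionally labelled 3.5.

An E/I condition is constructed by converting neurons of one interneuron
subtype (PV or SOM) into Pyr neurons while the total count and the other
two subtypes stay fixed. `size_populations(ratio, varied)` computes
`n_pyr = round(total * r / (1 + r))`, and the varied subtype absorbs the
rounding residual. Two caveats, both inherited from the source tables
and handled explicitly:

* the control row is an anchor, not a product of the rounding rule
  (the rule would give 10,311 Pyr for an exact target of 3.5);
  `condition_sizes()` therefore maps the nominal label 3.5 to the
  canonical control counts;
* the published SOM-conversion rows are internally inconsistent (their
  totals are not 13,257); this package follows the stated rule — total
  held at 13,257 — so its SOM-row counts differ from the printed ones
  (e.g. SOM = 1,273 rather than 1,237 at ratio 3.0).

### Connectivity

Each ordered class pair in the table below is connected independently
(Bernoulli per ordered cell pair, no autapses). Base probabilities are
defined at class level (E→E 0.1009, E→I 0.1346, I→E 0.1689, I→I 0.1371)
and subtype weighting factors (SOM→PV 0.857, VIP→SOM 0.625, others 1)
multiply the base probability. Whether the weighting factors scale
probabilities or conductances is not uniquely determined by the source;
probability scaling is adopted as the plainer reading of
"weighting factors for neuron-class-specific connections", and the
factors are small enough that the choice does not alter the network's
qualitative behavior. Pairs absent from the table (e.g. VIP→Pyr,
PV→SOM) are never connected.

| pre → post | probability | g (nS) | τ_decay (ms) |
|---|---|---|---|
| Pyr → Pyr | 0.1009 | log-normal (below) | 2.0 |
| Pyr → PV | 0.1346 | 0.95 ± 0.095 | 2.0 |
| Pyr → SOM | 0.1346 | 0.29 ± 0.029 | 2.0 |
| Pyr → VIP | 0.1346 | 0.27 ± 0.027 | 2.0 |
| PV → Pyr | 0.1689 | 4.32 ± 0.432 | 6.4 |
| SOM → Pyr | 0.1689 | 1.26 ± 0.126 | 13.1 |
| PV → PV | 0.1371 | 3.51 ± 0.351 | 4.6 |
| SOM → PV | 0.1371·0.857 | 1.22 ± 0.122 | 5.2 |
| VIP → SOM | 0.1371·0.625 | 0.32 ± 0.032 | 13.1 |
| SOM → VIP | 0.1371 | 1.18 ± 0.118 | 10.2 |

Pyr→Pyr conductances follow the long-tailed log-normal law with
log-scale SD σ = 1.0 and log-scale mean μ = σ² + log(0.10) ≈ −1.30
(median ≈ 0.27 nS, mean ≈ 0.45 nS). The source describes the sampled
quantity as the EPSP amplitude from rest; this package samples the
conductance directly from that law, the reading under which the model
is specified elsewhere. (Converting median-EPSP mV to nS through the
LIF response kernel would scale E-E weights by ≈ 2.1; we probed that
variant and found it does not change the network's qualitative
dynamics, so the direct reading is retained.) All other conductances
are Gaussian with a 10% coefficient of variation, redrawn (not clipped)
when non-positive — at CV 0.1 redraws are ~10⁻²³ rare, so the stated
means are preserved.

Synaptic delays are Gaussian with mean d₀ and variance d₀/10, truncated
positive: d₀ = 2.0 ms for excitatory presynaptic neurons, 1.0 ms for
all inhibitory subtypes.

### Neuron and synapse dynamics

Each neuron follows

  dV/dt = −(V − E_l)/τ_m − Σ_c G_c(t)(V − E_c)/C_m

with C_m = 200 pF, E_l = −70 mV, threshold −50 mV, reset −60 mV, and
class-specific membrane time constants (Pyr 10.5, PV 3.1, SOM 11.8,
VIP 10.9 ms) and refractory periods (Pyr 2.0 ms, interneurons 1.0 ms).
Synaptic input is conductance-based with exponential gates: each
presynaptic spike increments its gate by one (a delta input integrating
to unity) and the gate decays with the pair-specific time constant.
Excitatory and external synapses reverse at 0 mV, inhibitory at
−70 mV. The published membrane equation adds the synaptic terms with a
sign under which, taken literally, excitation would hyperpolarize; as
in the cited predecessor models, the currents are applied with the
physiologically required sign (excitation depolarizes, inhibition pulls
V toward −70 mV), which the reversal-clamp tests verify.

Because all synapses of a given (presynaptic class → postsynaptic
class) pair share one decay constant, the integrator aggregates each
neuron's afferents into five conductance channels (four presynaptic
classes plus the external AMPA drive); the weighted gate sum itself
decays exponentially and is incremented by the synaptic conductance per
arriving spike. This is exact, not an approximation.

### External inputs

Every neuron receives one independent Poisson background train
(Pyr 190, PV 770, SOM 100, VIP 150 Hz; g = 10 nS, τ = 2 ms) for the
whole trial. The visual stimulus is a pool of 500 feedforward fibers
firing at 25 Hz from stimulus onset (100 ms), each fiber contacting
each neuron independently (probability 0.1 onto Pyr, 0.01 onto
interneurons; g = 2.5 nS, τ = 2 ms). Feedforward connections are drawn
once per network and held fixed across trials; feedforward synapses
carry excitatory-type delays. Background arrivals are applied without
an extra delay — a time-shifted homogeneous Poisson process is
statistically identical, so a per-train delay would be unobservable.

### Integration scheme

The membrane equation is integrated by classical RK4 at dt = 0.1 ms.
Delta-function synaptic events cannot be RK4-integrated directly, so
gates are advanced by exact exponential decay with arrivals applied at
step boundaries, and within a step the RK4 stages evaluate the
conductances at their analytically decayed half- and full-step values.
For a constant conductance the scheme reproduces the closed-form LIF
relaxation to better than 10⁻⁶ mV (tested), and halving dt changes
deterministic firing rates by well under 2%. Spikes are detected at
step boundaries (V ≥ V_thr at the end of a step), V is reset and
clamped for the refractory period while gates keep evolving, and
deliveries are scheduled after the per-edge delay rounded to the dt
grid (minimum one step).

### Seeds and determinism

All randomness flows through R's RNG. A master seed is hashed with
string keys into per-condition network seeds and per-trial seeds
(`derive_seed`), so adding trials or conditions never perturbs earlier
ones, and identical inputs reproduce spike records exactly (tested
byte-for-byte).

### The scale parameter

`simulation_config(scale = s)` multiplies all population counts and the
feedforward fiber count by `s`; connection probabilities and synaptic
weights are deliberately left unchanged. A reduced-scale network
therefore receives proportionally less recurrent input and sits in a
more weakly coupled regime than the full circuit — reduced scales are
for testing and desk experiments, and quantitative features (rates,
peak strengths, phase-lead magnitudes) must not be extrapolated from
them. The desk profile used throughout the tests and the acceptance
script is scale 0.5, 10 trials of 2 s with the first 500 ms discarded;
the full study profile (scale 1, 50 trials of 3 s) is available via
`simulation_config()` defaults.

## The analysis stack

**PSTH.** Population spike counts of one class in 2 ms bins over the
post-transient window (500 ms to trial end), half-open bins, raw counts
(not rates). Counts are what the downstream transforms see; the DC
component is removed before the FFT.

**Spectra.** Before the FFT each trial's PSTH is smoothed with a
unit-sum Gaussian kernel of variance 5 ms² (truncated at ±4 SD,
zero-padded edges). Per-trial amplitude-squared spectra of the
mean-removed signal are averaged arithmetically across trials. The
source leaves "power" units open; amplitude² with log-scale display is
adopted. Smoothing is applied per trial before each trial's transform
(the stated order), not to a trial-averaged PSTH.

**Cross-condition normalization.** For each frequency-band panel, the
power values of all conditions at all in-band bins are pooled and
min–max mapped to [0, 1]. Per-panel pooling (rather than per-bin) is
adopted because the published panels carry one colorbar each; a per-bin
mode is available behind a flag.

**Aperiodic/periodic decomposition.** A deliberately simplified
spectral parameterization: a robust log–log linear fit of the
1/f-like background (two-pass least squares, second pass excluding the
peaky upper residual tail), up to three Gaussians fitted iteratively to
the largest positive log-power residual (Levenberg–Marquardt with
bounded center, height and width), then an aperiodic refit on the
peak-removed spectrum. A peak's `relative_strength` is its fitted
height in log10-power units above the final aperiodic curve. Knee-form
aperiodic fits and the full feature set of the established
spectral-parameterization tools are intentionally out of scope. On
synthetic 1/f-plus-bump spectra the exponent is recovered within 1%
and ≥ 90% of injected peak centers within ±3 Hz (tested).

**Phase flow.** Per trial and frequency band, both class PSTHs are
z-scored, band-pass filtered with a 4th-order Butterworth applied
forward–backward (zero phase — essential, since any causal filter lag
would cancel only approximately between signals), and
Hilbert-transformed. The directed phase lag index is the time average
of the Heaviside of the wrapped phase difference (interneuron minus
Pyr), with the conventions H(0) = 0.5 and sign(0) = 0 under which
PLI = 2·|0.5 − dPLI| holds exactly (asserted per call in tests).
Phase differences are wrapped to (−π, π]; without wrapping the index is
ill-defined. The first and last 5% of samples are excluded from the
averages (Hilbert edge artifacts). "10 to 80 Hz in steps of 5 Hz" is
read as contiguous 5 Hz windows ([10,15], …, [75,80], 14 bands); a
10 Hz-step variant is available through `flow_bands()`. Per band, a
two-sided one-sample t test compares trial dPLI values with 0.5; no
multiple-testing correction is applied (none is applied in the source),
and significance tiers 0.1/0.05/0.01 are marked in printed summaries.

## What the reduced-scale experiments show — and what they do not

The desk-scale experiment grid reproduces the structural results: the
harmonic peak stack in the Pyr spectrum, band power rising with E/I
ratio in the PV-conversion series, SOM→Pyr dPLI below 0.5 everywhere
(the Pyr population leads the SOM population), and a PV→Pyr dPLI that
increases with the E/I ratio in the PV-conversion series. In the runs
computed by this package's acceptance suite, however, the PV→Pyr dPLI
remains below 0.5 in all conditions — the Pyr population leads the PV
population by roughly the Pyr→PV synaptic delay plus the PV integration
time — so the published sign crossing at E/I 4.5 (PV leading) is not
observed at these problem sizes. The trend matches; the crossing does
not. The acceptance suite asserts the published directional claims
as stated and reports the computed values unmodified, so this
discrepancy is visible rather than hidden. Plausible origins are the
weaker recurrent coupling at reduced scale and unpublished
implementation details of the original simulation code; the package's
parameter tables were not adjusted to force agreement.

## Known limitations

* No spatial geometry, distance-dependent connectivity, gap junctions,
  NMDA/GABA_B receptors, plasticity, or multi-microcircuit
  interactions.
* Event times are grid-aligned (delays rounded to dt); there is no
  off-grid event handling or adaptive stepping.
* The spectral parameterization is a minimal variant (no knee, ≤ 3
  peaks) meant for these harmonic-stack spectra, not a general
  replacement for the established tools.
* Synthetic Poisson drive stands in for structured visual input;
  conclusions about real stimulus statistics are out of scope.
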