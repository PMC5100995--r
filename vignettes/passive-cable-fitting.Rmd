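---
title: "Estimating passive membrane parameters from voltage transients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating passive membrane parameters from voltage transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cablefit)
```

## The problem

Whole-cell recordings of human layer 2/3 pyramidal neurons have suggested
that their specific membrane capacitance, Cm, is about 0.5 uF/cm² — half
the ~1 uF/cm² textbook value found in most other neurons, including mouse
cortical cells. The evidence rests on compartmental modelling: a brief
(2 ms) subthreshold current pulse is injected at the soma, the voltage
response is averaged over 50 repetitions, and the three passive cable
parameters of a morphologically detailed model of that same cell —

* **Cm** (uF/cm²), the specific membrane capacitance,
* **Rm** (Ohm cm²), the specific membrane resistivity, and
* **Ra** (Ohm cm), the axial (cytoplasmic) resistivity —

are optimised until the model transient matches the recorded one.
`cablefit` implements that entire workflow: the branched-cable simulator,
the fitting procedure with its spine correction, the statistical and
systematic uncertainty analysis, the independent nucleated-patch estimate
of Cm, and the simulations that explore what a low Cm means functionally.
Because the original recordings and reconstructions are distributed
separately, the package ships a synthetic-data module that generates
morphologies, sweep sets and patch recordings with known ground truth, so
every stage of the pipeline is testable end to end.

## The model

The neuron is a tree of cylindrical/frustum sections discretized into
compartments with centred nodes (an odd number per section). Each
compartment obeys

$$C \frac{dV}{dt} = -\sum_i g_i (V - E_i) - I_{\text{axial}} + I_{\text{inj}},$$

with capacitance `Cm * area`, leak `area / Rm`, and axial conductances
from the closed-form integral of `Ra / (pi r(s)^2)` along the
linearly-tapering neurite. Time stepping is Crank–Nicolson with a direct
Hines solve of the tree system at every step and a staggered (half-step)
update of gating variables, the scheme used by mainstream neural
simulators; it is second-order in `dt` and unconditionally stable. The
default `dt` is 0.025 ms and the default spatial rule caps segment
lengths at 0.1 of the 100 Hz space constant — the tests verify that the
RC and ball-and-stick closed forms are matched to 0.1% and 1% and that
halving either resolution changes the somatic transient by well under
0.5%.

### Dendritic spines

Spine membrane is folded into the cable globally through the factor
`F = (shaft area + spine area) / shaft area`, applied as `Cm * F` and
`Rm / F` to every dendritic compartment at least 60 um from the soma
(proximal dendrites carry few spines; for mouse-style models the start
distance can be set to 0 to spread the factor over the whole tree). The
default `F = 1.9` — i.e. spines nearly double the dendritic membrane —
comes from high-resolution reconstructions of human L2/3 dendrites. This
folding is valid when current flows from dendrite into spines (somatic
stimulation). When a synapse on a spine head drives the cell the
approximation fails, so stimulated spines are modelled explicitly: a
1.35 um x 0.25 um cylindrical neck plus an isopotential head carrying
2.8 um² of membrane, which yields neck resistances of 50–80 MOhm over
the fitted Ra range.

### Active mechanisms

For the functional protocols a Hodgkin–Huxley spike mechanism is added:
8000/3200 pS/um² Na/K at the soma, 200/100 pS/um² on the axon, with the
sodium activation midpoint shifted −8 mV at the soma so spikes initiate
about 20 mV above rest. Two implementation choices deserve note, both
made because the high somatic channel density otherwise leaves the
membrane without a stable resting point (the sodium window current
exceeds the weak leak of a high-Rm membrane):

* the −8 mV shift applies to the somatic mechanism only; the axon keeps
  standard kinetics;
* the mechanism carries the classic HH leak (0.3 mS/cm²), referenced to
  the cell's resting potential rather than the squid value.

With these choices the model rests stably near −85 mV, fires a single
spike to a 300 pA/10 ms somatic pulse, and propagates cleanly along the
axon. Ih, where requested, is a single-gate HCN conductance with the
kinetics and −45 mV reversal used in rat L5 pyramidal models; its density
is flat in basal dendrites and grows with apical distance as
`g_soma * (-0.8696 + 2.087 exp(d/323))`. Synapses are two-state kinetic
conductances (AMPA 0.3/1.8 ms, 0.7 nS; NMDA 3/70 ms, 1.4 nS) normalised
to peak at `g_max`, the NMDA component gated by the sigmoidal magnesium
block `B = 1/(1 + exp(-0.08 V) [Mg] / 3.57)`.

## The fitting procedure

`fit_passive()` minimises the root-mean-square deviation between the
averaged experimental transient (baseline-subtracted; the 16 mV junction
potential only shifts the reported resting level) and the model response,
over a window from 1 to 100 ms after the end of the pulse — the first
millisecond is excluded because it is dominated by electrode artefacts in
real recordings. Whether the window is anchored at pulse offset or onset
is configurable (`window_from`); offset is the default. The fit uses the
strongest depolarizing stimulus and validates the result on the remaining
amplitudes.

The optimiser is Nelder–Mead in log-parameter space (all three parameters
are positive scale parameters) from five Latin-hypercube starting points
within Cm ∈ [0.2, 2] uF/cm², Rm ∈ [5, 100] kOhm cm², Ra ∈ [50, 400]
Ohm cm, with a smooth penalty outside the box; ties between starts are
broken by lowest RMSD, then lowest Cm, so reporting is deterministic for
a given seed. `profile_constrained()` fixes one parameter on a grid and
re-optimises the others: on synthetic cells the profile is sharp in Cm
(its minimum at the ground truth) and more than five-fold flatter in Ra —
the transients simply carry little information about Ra, which is why Ra
estimates are reported but deliberately left loosely constrained.
`fit_with_ih()` repeats the fit with a fixed Ih density; on passively
generated data the fitted Cm then inflates while the early (capacitive)
part of the transient — reported separately as `early_rmsd_mV` — is only
matched with the true Cm. This reproduces the identifiability argument
that short-time behaviour pins down Cm regardless of slow conductances.

## Uncertainty

Statistical errors use a balanced bootstrap: the 50 sweep indices are
repeated 100 times, permuted as one pool, and partitioned into 100
resampled averages, so every sweep is used exactly 100 times and the
grand mean of the replicates equals the full average exactly (an identity
the tests assert to machine precision). Each replicate average is refitted
(warm-started at the full-data optimum) and the SD across replicates is
reported per parameter.

Systematic errors follow a morphology-perturbation design with five
independent normal error variables: a global length scale (SD 0.05), an
additive diameter error (SD 0.3 um), a multiplicative diameter error
(SD 0.1), the spine factor F (SD 0.4) and the spine-territory start
distance (SD 30 um, truncated at zero). Diameters are perturbed
additively then multiplicatively — the order is a documented convention —
and clipped at 0.1 um. Each perturbed morphology is refitted against the
original averaged transient; 100 samples is the default (40 in the
acceptance script). The qualitative outcome on synthetic cells matches
the published analysis: even generous systematic errors spread the Cm
estimate substantially but do not move its centre away from the low
value.

## Nucleated patches

The independent check on Cm uses outside-out patches containing the
nucleus: a −5 mV step is applied, the averaged capacitive transient is
fitted with a single exponential from two samples after the step (the fit
window adapts to ~8 time constants so an all-noise tail cannot dominate),
and the total capacitance is obtained from charge, `C = I0 tau / |dV|` —
deliberately avoiding a series-resistance estimate. The patch surface is
the sphere formula on the mean of the two measured axes,
`(major + minor)² pi/4`, and the specific capacitance is `C / area`.
Patches with input resistance below 200 MOhm are excluded; the threshold
itself passes. When a sealed-pipette residual trace is supplied it is
subtracted before fitting and both estimates are reported — on synthetic
data with a small residual they agree closely, as in the published
recordings.

## What the synthetic data do and do not emulate

`synthetic_spec()` encodes the study conditions: six stimulus amplitudes
(±50, ±100, ±200 pA; 2 ms), 50 sweeps per stimulus, iid Gaussian sweep
noise (default 0.2 mV per sample, a level at which the bootstrap errors
land in the few-percent range), dendritic trees whose maximal path
distance is drawn near 1050 ± 178 um, and series-RC patch recordings
sampled at 250 kHz. The random-tree generator produces an apical trunk
with a branching tuft and four branched basal subtrees with tapering
diameters; it is a pure function of its seed, and its maximal path
distance lands within 10% of the requested target.

Two caveats bound what passing tests show about real data. First, the
synthetic trees are sparser than real human L2/3 cells (total dendritic
length around 5 mm rather than ~10 mm), so absolute quantities that scale
with membrane area — input resistance, the number of synapses needed to
reach spike threshold, absolute EPSP sizes and dendritic delays — are
smaller than the published figures; the package asserts the directions
and ratios of these effects, not their absolute values, which require the
original reconstructions. Second, the noise model is white; real sweep
noise is coloured by the electrode, so the bootstrap SDs on synthetic
data are smaller than those reported for the experimental cells.

## Functional consequences of a low Cm

Three protocols quantify what halving Cm buys, all comparing
Cm = 0.45 against 0.9 uF/cm² with Ra = 203 Ohm cm and Rm = 38907 Ohm cm²
fixed:

* `epsp_transfer()` activates an AMPA+NMDA synapse on an explicit spine
  at the most distal apical and basal terminals: the low-Cm condition
  yields a larger somatic EPSP and a shorter dendritic delay (time from
  local to somatic peak);
* `synapses_to_spike()` scatters N explicit spinous synapses uniformly
  per unit dendritic length over the spine territory, fires them
  synchronously on the active model, and interpolates N50 from the
  spike-probability curve (1000 trials per count in the full protocol;
  desk-scale runs use 20–60): fewer synapses are needed at low Cm;
* `axon_velocity()` attaches a 6 mm, 1 um unmyelinated axon and measures
  spike conduction velocity from maximal-dV/dt times at two sites
  bracketing 1 mm: velocity falls monotonically with Cm, the low-Cm
  condition conducting on the order of 60% faster, while halving the
  somatodendritic Rm (the axon keeps its stated passive properties)
  moves velocity by well under 1%.

`fixed_tau_control()` re-runs the comparison with the membrane time
constant pinned (Cm = 0.9 paired with Rm = 19453.5 Ohm cm², both giving
17.5 ms): delay differences shrink but EPSPs attenuate more, showing the
benefits of low Cm are not merely a time-constant effect.

## Numerical choices and degenerate inputs

* Initial condition `V = e_pas` with gates at steady state; a 200 ms
  settling pre-run precedes any protocol with Ih or HH channels, since
  both shift the resting potential.
* Charge balance holds to ~1e-15 relative per step by construction of
  the implicit solve (a diagnostic mode tracks the residual).
* Recording and stimulation locations snap to the nearest compartment
  centre; children attach at their parent's distal end by default, and
  mid-section attachments connect through the containing compartment's
  distal half-resistance.
* Equal synaptic rise and decay constants, non-positive diameters,
  zero-length sections, missing SWC parents, steps of zero amplitude in
  the patch protocol, and empty RMSD windows are all rejected with
  specific errors rather than silently propagated.
* All stochastic operations (generators, bootstrap, synapse placement)
  are pure functions of an explicit seed and restore the caller's RNG
  state.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes on one CPU while still exercising the
study conditions: 20 synthetic cells (five per ground-truth Cm of 0.45,
0.5, 0.9 and 1.0 uF/cm²) for parameter recovery, 100 bootstrap
replicates, 40 systematic-error samples, 60 trials per synapse count, and
5-point constrained profiles per parameter. The same functions accept the
full-scale settings (1000 trials, 100 samples) unchanged.

## Known limitations

* Only the distal end of a section is an exact attachment point;
  mid-section attachments are snapped, which matters only for very
  coarse grids.
* Ra is estimated but poorly identified from somatic transients alone —
  a genuine property of the data, not of the optimiser; two-electrode
  protocols would be needed to pin it down.
* The Ih kinetics are a standard rat L5 HCN model; only the density
  distribution is specific to these cells.
* No calcium dynamics, synaptic plasticity, myelination, or stochastic
  channels; temperature corrections (Q10) are not applied.
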