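---
title: "Models and methods: receptor mobility, gating kinetics and FLIM lifetimes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: receptor mobility, gating kinetics and FLIM lifetimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptiq)
```

`synaptiq` implements, as one reproducible pipeline, the three quantitative
readouts used to characterise how an auxiliary subunit such as Shisa6
controls AMPA-type glutamate receptors: single-particle tracking of surface
receptors, whole-cell glutamate-evoked current analysis, and
frequency-domain fluorescence-lifetime imaging (FLIM). Each analysis stage
is paired with a seeded generator that produces synthetic data with known
ground truth, so the full chain — generator, file formats, analysis,
statistics — can be validated end to end without any external data. This
vignette documents the underlying models, the parameters that matter, the
numerical choices, and what the packaged fixtures do and do not emulate.

## 1. Receptor mobility

### Generative model

Surface receptors diffuse in a rectangular membrane field containing
disc-shaped postsynaptic clusters (the synaptic compartment, as labelled by
a Homer1C-style marker). Each receptor switches between a freely diffusing
state and a trapped, scaffold-bound state:

* Brownian steps with per-axis variance $2D\,\Delta t$, with $D =$
  `dFree` or `dTrapped` according to the current state;
* a two-state Markov chain with rates `kTrapIn` (free → trapped) and
  `kTrapOut` (trapped → free), taken from the synaptic or extrasynaptic
  parameter set according to the receptor's current position;
* reflecting field boundaries, chosen so long trajectories stay in the
  field without biasing short-lag MSD;
* observed positions carry isotropic Gaussian localization error
  (`localizationSigma`, default 0.02 µm) and each receptor is detected per
  frame with probability `pDetect` (default 0.95), emulating quantum-dot
  blinking.

The trapped-state diffusion coefficient is a small non-zero value
(5×10⁻⁴ µm²/s by default) representing sub-resolution jitter of a
scaffold-bound receptor. Trapping rates in the packaged presets are slow
(residence times of minutes against a 10-s trajectory), so individual
trajectories appear either mobile or immobile — reproducing the bimodal,
heavy-tailed diffusion-coefficient distributions characteristic of
quantum-dot tracking, in which the immobile fraction and the mobile-pool
median can be read off separately.

### Analysis

Detections are linked frame to frame by greedy nearest-neighbour assignment
resolved per frame pair in order of increasing displacement, with a
per-frame displacement gate (`maxDisp`, default 0.5 µm) and gap closing
across up to `maxGap` missed frames with a proportionally enlarged search
radius. The published tracker used for the original recordings is not
publicly specified, so this standard assignment scheme is substituted and
validated against the simulator's ground-truth identities (link accuracy
>95% at the fixture density).

Per trajectory, the time-averaged mean square displacement uses all
overlapping detection pairs at each lag. The diffusion coefficient comes
from an ordinary least-squares fit of the first four MSD points against lag
time with a free intercept, and $D$ = slope/4 (2-D diffusion,
$\mathrm{MSD}(t) = 4Dt$). The free intercept absorbs the constant
$4\sigma^2$ offset produced by localization error; the package's tests
verify that localization noise shifts the intercept and not the fitted
slope. Negative fitted slopes are clamped to zero and flagged. Tracks
shorter than 8 detections (which could not support four lags with at least
four pairs each) are excluded and counted.

A trajectory is synaptic when at least five of its observed positions fall
inside a cluster disc — applied to positions after localization noise, as
an experimenter would. A trajectory is immobile when $D < 0.005$ µm²/s,
a conventional cutoff near the localization-noise floor at 50-ms frames;
the threshold is not derivable from the reported analysis and is therefore
configurable and stamped into every summary. Summaries follow the two
replication units used in this field: medians with 25–75% interquartile
ranges pooled over trajectories, immobile fractions computed per cell and
averaged with standard errors across cells.

### Fixture calibration

The three condition presets (`control`, `shisa6`, `shisa6_dEVTV`) encode
per-compartment `dFree`, `dTrapped` and trapping rates. They were
calibrated once, by running the full simulate–link–estimate–classify
pipeline (24 cells × 42 receptors × 200 frames) and adjusting the preset
parameters until the condition-level outputs matched the reported values:
synaptic median D of 0.0128 µm²/s (control) and 0.0006 µm²/s (Shisa6),
pooled immobile fractions of 35.58% and 57.94%, and the extrasynaptic
medians near 0.038 and 0.003 µm²/s. Because classified synaptic
trajectories include mobile receptors that drift through clusters, the
synaptic preset values differ from the naive "median of the synaptic pool";
the calibration absorbs that bias. The fraction of receptors seeded inside
clusters (0.30) sets the synaptic trajectory count; the relative pool sizes
are not derivable from the reported counts alone and are chosen to give a
few hundred synaptic trajectories per desk-scale run.

## 2. Receptor gating and current features

### Mean-field gating model

Macroscopic currents are generated from a Markov gating scheme integrated
as a mean-field master equation $\dot p = p\,Q(c(t))$ under a
piecewise-constant glutamate concentration $c(t)$; within each protocol
segment the generator is constant and the occupancy is propagated with the
exact matrix-exponential solution (eigendecomposition, with a
scaling-and-squaring fallback for defective generators). Initial occupancy
is the stationary distribution at zero glutamate, which must be unique.
Current is the conductance-weighted open-state occupancy times a scale
(inward negative); all reported features except the peak amplitude are
invariant to that scale. Stochastic single-channel gating is out of scope —
the measurements being emulated are macroscopic whole-cell currents.

Transition rates are affine in concentration, $k_{ij}(c) = k^0_{ij} + c\,
k^1_{ij}$. The minimal scheme (`ampaScheme()`) has four states: unbound
closed C, glutamate-bound closed CG, open O and desensitized D, with
binding proportional to concentration, desensitization from both CG and O,
and recovery D → C.

The packaged condition fixtures use a five-state refinement
(`ampaScheme2D()`) with a shallow and a deep desensitized state. The
four-state scheme couples the sustained current to the ratio of the
desensitization and recovery time constants (at stationarity, the
desensitized pool balance forces steady state ≈ τ_des/τ_recovery), and the
measured condition values violate that relation in both directions; a
shallow, quickly resensitizing D1 plus a deep, slowly recovering D2 is the
standard way receptor models decouple these observables. For the control
condition the deep entry D1 → D2 is proportional to glutamate
concentration: sustained applications then accumulate deep desensitization
(low steady state) while the 1-ms pulses of the paired-pulse protocol leave
D2 unloaded (fast measured recovery).

### Feature extraction

All features operate on the baseline-subtracted deflection and are
polarity-agnostic:

* rise time: linear interpolation between the samples bracketing the 20%
  and 80% crossings of the peak, on the rising limb;
* decay time: interpolated 90% → 10% interval after the peak, absent (and
  flagged) when the trace never reaches 10%;
* desensitization fit: nonlinear least squares of
  $A\,(w e^{-t/\tau_1} + (1{-}w) e^{-t/\tau_2}) + C$ over the post-peak
  window of the 1-s application, with a fixed, documented initializer
  (time constants from the 90–10% time, $w = 0.5$) so fits are
  deterministic. Both single- and double-exponential models are fitted and
  the double fit is reported only when it improves the residual norm by
  more than 5%; the reported τ_des is the amplitude-weighted mean.
* steady state: mean deflection over the final 100 ms of the 1-s
  application divided by the peak (the averaging window is not specified in
  the original analysis; 100 ms is fixed here and configurable);
* recovery: peak2/peak1 ratios at ten inter-pulse intervals (20–3000 ms),
  each peak measured against its local pre-pulse baseline, fitted with
  $R(\Delta t) = 1 - (1 - R_0)\,e^{-\Delta t/\tau_{rec}}$; the floor
  $R_0$ absorbs the fast-recovering component;
* trains: per-pulse peaks against local baselines, with the decaying tail
  of the preceding response removed by fitting a single exponential to the
  late part of the preceding inter-pulse segment and subtracting its
  extrapolation (simpler and more testable than deconvolution);
* integration step: 0.1 ms is the canonical step for all packaged
  protocols. The weighted-τ report can switch between the single- and
  double-exponential branch under resampling, so the step is part of the
  fixture definition.

The scheme fixtures were calibrated once against the four reported
condition-level features each (1-ms-pulse decay, τ_des, steady-state
percentage, τ_recovery), measured by these extractors; residuals are below
0.7% (control: exact to <0.01%). For the Shisa6 fixture the calibration
manifold (nine rates, four targets) was additionally constrained so that
the 50-Hz train depression is weaker than the control fixture's, matching
the synaptic observation that the subunit protects transmission at high
frequency; without that constraint a calibration can reproduce all four
HEK-style features yet invert the train ordering, because per-pulse
desensitization and between-pulse recovery trade off differently in trains
than in paired pulses.

## 3. Miniature EPSCs

Events arrive as a Poisson process (default 0.5 Hz); each adds a
difference-of-exponentials waveform
$A\,(e^{-t/\tau_d} - e^{-t/\tau_r})$, normalized to a peak amplitude drawn
from a normal distribution truncated at zero, on Gaussian recording noise
(2 pA SD at 10 kHz).

Detection emulates a MiniAnalysis-style workflow whose exact criteria are
not published: the trace is smoothed (0.3 ms moving average), the baseline
is its median and the noise SD its median absolute deviation, and events
are negative excursions beyond 5 noise SDs, merged within a 5-ms
refractory window, with a rise-time ceiling of 5 ms rejecting slow drifts.
Per-event rise, decay and amplitude are measured on a 0.8-ms low-pass
filtered copy of the trace: recording noise systematically shortens
threshold-crossing intervals (an early 90% crossing near the peak, an
early 10% crossing in the tail), and the measurement filter suppresses
that bias. The detector is validated against simulator ground truth
(sensitivity ≥0.9, false positives ≤0.05 Hz at the fixture
signal-to-noise).

Two waveform limitations are deliberate. First, the
difference-of-exponentials family ties the 20–80% rise to the 90–10% decay
(ratio ≥ ~8), more tightly than real synaptic currents; the fixtures
reproduce the reported decay times — the quantity the package's acceptance
checks use — with realistic sub-millisecond rise constants that preserve
the WT-slower-than-KO ordering, rather than the reported rise times.
Second, the fixture decay constants were calibrated against the detector's
measured mean on the standard noisy trace (not against the noiseless
waveform), so the committed values (WT 2.5684 ms, KO 1.9621 ms) fold in
the small residual bias of threshold-crossing measurements at 16 pA / 2 pA
signal-to-noise.

## 4. Frequency-domain FLIM

A pixel with mono-exponential lifetime $\tau$ under sinusoidal excitation
at $\omega = 2\pi f$ ($f$ = 40 MHz) emits with phase shift
$\varphi = \arctan(\omega\tau)$ and demodulation
$m = 1/\sqrt{1 + (\omega\tau)^2}$. The generator renders the 12
phase-stepped homodyne frames $I_k \propto 1 + m\cos(2\pi k/12 - \varphi)$,
with optional instrumental phase/demodulation offsets (shared by all
acquisitions of a session) and optional Poisson counting noise.

The analysis fits $I_k = a + b\cos(2\pi k/n - \varphi)$ per pixel via the
first discrete Fourier component (the exact least-squares solution for
uniformly spaced phases), removes the instrumental phase with a reference
acquisition of fluorescein set to 4.00 ns
($\varphi_{true} = \varphi - \varphi_{ref} + \arctan(\omega\tau_{ref})$),
and reports the phase lifetime $\tau_\varphi = \tan(\varphi_{true})/\omega$.
The phase lifetime (not the modulation lifetime) is reported because a
FRET-shortened mixture gives $\tau_\varphi < \tau_m$ and single per-pixel
values are wanted; $\tau_m$ is computed and stored for diagnostics.
Negative corrected phases are clipped to zero and masked; pixels below a
100-count intensity floor are masked. Round-trip recovery is exact to
10⁻³ ns on noiseless stacks for τ in 0.5–5 ns, and the estimator bias is
below 1% at ≥10⁴ expected counts per pixel per stack.

FRET conditions are simulated as intensity-weighted phasor sums of an
unquenched donor (spine 2.381 ns, shaft 2.563 ns) and a quenched donor
fixed at 1.2 ns; the quenched fraction per condition was solved in closed
form so the mixture's apparent phase lifetime equals the reported
compartment mean (e.g. 8.8% quenched for the 2.254-ns spine value). The
ROI summaries average valid pixels per labelled region and keep per-ROI
values for group statistics.

## 5. Statistics

Descriptives are mean ± s.e.m. or median with 25th/75th percentiles
(linear interpolation between order statistics — R's default convention,
which is documented because the original analysis does not state one).
Group comparisons are two-sided throughout: Mann–Whitney for two
independent groups, Kruskal–Wallis with Bonferroni-adjusted pairwise
Mann–Whitney post hocs for k nonparametric groups, one-way ANOVA with
either Bonferroni-adjusted t tests or the classical stepwise
studentized-range Newman–Keuls procedure for parametric designs.
Bonferroni adjustment is exactly $\min(1, m\,p)$. Newman–Keuls is
implemented for fidelity to the original figure-level analyses but is
opt-in, with Bonferroni the default, because the stepwise procedure lacks
strong familywise error control. The configured rank test keeps its
nominal size (type-I error within [0.03, 0.07] at α = 0.05 over 1000 null
resamples in the test suite).

## 6. Reproducibility and scale

Every generator takes an integer seed and restores the caller's RNG state;
identical seeds give byte-identical outputs. Pipeline runs (`runPipeline()`
on a YAML plan) derive per-stage, per-cell seeds deterministically from the
plan's root seed and stamp every stage output with the plan hash, seed and
package version; re-running an identical plan reproduces identical outputs,
and existing stage outputs are refused unless overwriting is forced.

The packaged problem sizes are desk-scale by design: mobility runs use 24
cells × 42 receptors × 200 frames per condition (≈1000 trajectories, ≈300
synaptic), gating simulations integrate at 0.1 ms, the mEPSC acceptance
trace is 480 s at 10 kHz (≈240 events), and FLIM stacks are 32 × 32 × 12.
At these sizes a full acceptance run takes seconds to tens of seconds on
one core while keeping the stochastic targets' sampling error well inside
their tolerances (e.g. the median-D tolerance of 30% reflects median
sampling error at ≈300 synaptic trajectories).

## 7. What passing tests do and do not show

The generators emulate the measurement processes — two-state trapping with
localization noise and blinking, mean-field gating, Poisson synaptic
events, homodyne photon statistics — not the underlying biology. Real
recordings add drift, rebinding, anomalous subdiffusion, dendritic
geometry, series-resistance artefacts, spectral bleed-through and
correlated noise, none of which are modelled. Passing the acceptance
checks therefore shows that the analysis chain is internally correct and
that the fixtures faithfully encode the reported condition-level
measurements; it does not validate the analysis against raw experimental
data. The substituted components — the linking algorithm, the mEPSC
detection criteria, the immobility threshold and the gating scheme — are
explicitly flagged as package choices where the original procedures are
unpublished or unfitted.
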