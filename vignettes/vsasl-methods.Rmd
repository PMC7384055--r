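---
title: "Modelling and processing velocity-selective ASL of the placenta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and processing velocity-selective ASL of the placenta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsasl)
```

## The labeling model and its assumptions

Velocity-selective labeling saturates the longitudinal magnetization of
spins that move faster than a cutoff velocity along the encoding direction,
regardless of where they are. The package models one labeling module by its
effective first gradient moment under an idealised rectangular-lobe
waveform whose effective lobe separation spans the whole module,

\[ m_1 = G\,\delta\,T_{\mathrm{module}}, \]

and defines the cutoff velocity by the laminar-flow convention
\(V_c = \pi / (\gamma m_1)\). With the reference settings (13 mT/m, 1.2 ms,
50 ms) this yields 1.51 cm/s, matching the nominal 1.6 cm/s of the modelled
protocol family to within rounding; the whole-module convention was chosen
over the half-module alternative precisely because the half-module value
does not reproduce that nominal reference. For plug flow at velocity \(v\)
the label-condition response is \(\cos(\pi v / V_c)\); averaging over the
uniform velocity density implied by a parabolic (laminar) profile in a
voxel with mean velocity \(\bar v\) gives
\(m_z(\bar v) = \operatorname{sinc}(2\pi\bar v / V_c)\). Two conventions
deserve note:

* \(V_c\) is the mean velocity of *complete* laminar-averaged saturation
  (\(\sin 2\pi = 0\)); the response first touches zero already at
  \(\bar v = V_c/2\). Both zeros are tested.
* Nominal cutoff velocities other than the reference (0.9, 4.4,
  10.2 cm/s) were realised in the modelled protocols with waveform timing
  adjustments that are not reconstructable from the module summary
  parameters; the package stores the published gradient-strength pairs as
  protocol constants (`vs_cutoff_settings()`) and does not assert that the
  first-moment formula reproduces those nominal values. Sweeps over cutoff
  velocity use the stored gradient strengths, so the *model* cutoff for a
  nominal level differs from its label (for example, 19 mT/m gives a model
  \(V_c\) of 1.03 cm/s rather than 0.9); the ordering, which is what the
  qualitative contracts rely on, is preserved.

The voxelwise difference signal (as a fraction of local blood
magnetization) multiplies the saturation efficiency
\(E_{sat} = 1 - m_z\) at the labeling-time mean velocity, an arrival gate,
and mono-exponential label decay over the effective inflow time. Arrival is
a hard step by default; a linear ramp of configurable width (`ramp_ms`) is
available where a gradual arrival is wanted. The effective inflow time of
slice \(k\) (0-based, ascending from the basal plate) is
\(\mathrm{PLD} + 69k\) ms. For dual VS-ASL the second module, enabled in
both conditions, multiplies the difference by its laminar response at the
voxel's readout-time velocity: voxels whose blood has slowed below the
cutoff by readout (intervillous pools) are barely affected, voxels whose
blood is still fast (fetal-side vasculature) are suppressed.

Background suppression is piecewise inversion recovery with perfect
instantaneous inversions, applied to static tissue only; inflowing blood is
rendered fully relaxed in the control condition, a deliberate
simplification standing in for continuous replacement by fresh spins. The
stored inversion-time pairs per inflow time (50/310, 50/723, 50/1160,
848/1780 ms for PLDs of 400, 1000, 1600, 2200 ms) are protocol constants,
not re-derived, because the tissue relaxation data behind their
optimisation is not part of the module parameters; for other PLDs the
reference timings are scaled proportionally and this approximation is
documented on `bgs_inversion_times()`.

Scan duration is \((2 n_{\mathrm{pairs}} + 1 + n_{\mathrm{prep}})\,
\mathrm{TR}\). The dummy-period count \(n_{\mathrm{prep}} = 3\) was
calibrated once so that the 26-pair, TR 3500 ms reference scan lasts the
nominal 196 s (56 TR periods), and the same count then reproduces the
nominal dual-module duration at TR 6400 ms with no further freedom.

The diffusion-contamination helper uses the declared bipolar-pair
convention \(b = 2(\gamma G \delta)^2(\Delta - \delta/3)\) with
\(\Delta = T_{\mathrm{module}}/2\); exact published waveform timings vary,
so the convention is a documented choice and the returned quantity —
\(1 - e^{-bD}\), the label-image attenuation that leaks into the
subtraction — should be read with that convention in mind.

## What the phantom emulates

`phantom_spec()` describes a parametric, not anatomical, placenta: an
ellipsoid inside a larger uterine ellipsoid on an 88 × 84 × 13 grid of
4 mm voxels (0.4 mm slice gap), matching the modelled acquisition geometry.
Only the statistical structure of the data matters for exercising the
pipeline, which is why no attempt is made at realistic vasculature.

Three tissue classes carry the kinetics. Focal hyperintense regions —
spheres placed with a quadratic bias towards the basal-plate slices —
represent intervillous-space blood pools: high blood volume fraction
(0.85), fast feeding at labeling time, near-stagnant (0.15 cm/s) at
readout, early arrival (200 ms). Maternal-side parenchyma arrives at
350 ms; fetal-side parenchyma arrives late (1000 ms) with readout
velocities above the reference cutoff (3 cm/s), so dual-module suppression
and the delayed fetal-side signal peak are reproducible qualitatively. An
arrival-time gradient (default 200 ms) runs from the basal to the chorionic
plate. Velocity vectors are anterior-posterior dominant, the expected net
maternal inflow direction for an anterior placenta.

Per-voxel velocity magnitudes scatter log-normally around the class means
with `velocity_sdlog = 0.9` (geometric SD ≈ 2.5). This breadth reflects the
span of velocities across the placental feeding tree — from sub-cm/s
pooling in the intervillous space to tens of cm/s in umbilical vessels —
and it is what makes the aggregate signal decrease smoothly and
monotonically with increasing cutoff velocity: for any single velocity the
laminar response oscillates, and a narrow distribution would let those
oscillations surface in ROI means.

The pseudo-M0 field combines smooth low-frequency heterogeneity (±10%)
with darker septa bands over 20% of placental voxels (25% attenuation),
emulating the marked spatial heterogeneity seen in later-gestation
pseudo-M0 images. No voxelwise intensity statistics are available for that
pattern, so its amplitude is a free parameter of the spec.

Amplitude calibration: the generator rescales focal and parenchymal
difference-signal amplitudes so the true whole-placenta mean PWS and the
mean over focal-region means hit requested targets exactly (defaults 2.4%
and 4.3%, typical group means for these ROIs). In parameter sweeps the
rescaling is anchored at the reference protocol and carried over unchanged
to other levels, so across-level differences follow the physics rather
than being renormalised away.

Noise is Gaussian on magnitude images, with SD equal to `noise_sd` times
the mean noise-free placental control intensity. The default 0.067 makes
the whole-placenta mean of the normalized temporal SD of the source images
land near a typical group mean of 6.7%; the estimator reads back slightly
above the injected fraction because the label-control alternation
contributes signal variance and because normalising by dimmer voxels
inflates the ROI mean (Jensen's inequality). A Rician floor is *not*
modelled — justified at the simulated SNR, and listed below as a
limitation. Corrupted pairs receive a global additive offset (default 10
noise SDs) on the label image, mimicking spurious labeling while remaining
exactly detectable; motion is integer-voxel rigid translation per
repetition, so ground-truth alignment is exactly recoverable.

## Processing conventions and numerical choices

* Subtraction sign is control − label, so perfusion is positive.
* Outlier rejection computes the voxelwise temporal mean and *sample*
  (n − 1) SD once over all repetitions — a single pass, never re-evaluated
  after removals, because the modelled criterion is a single rule, not an
  iterative one. Both comparisons are strict: a voxel deviating by exactly
  1.5 SD is not deviant, and a pair with exactly 20% deviant voxels is
  kept. Whether the deviation statistic should be voxelwise or pooled over
  the uterus region is ambiguous in the modelled description; voxelwise is
  the default, with `sd_mode = "pooled"` available.
* The normalized temporal SD is computed over the label/control source
  volumes only, excluding the pseudo-M0 volume: acquired without
  background suppression, its intensity is far from the suppressed source
  images and would dominate the temporal SD it is meant to qualify.
* M0 is the 80th percentile of the pseudo-M0 within the placenta ROI,
  using R's default linear-interpolation (type 7) quantile. On a noisy
  pseudo-M0 volume a high percentile is biased slightly upward, which
  propagates to a small (about −1%) downward bias of PWS at the default
  noise level; this is a property of the percentile normalisation itself.
  The test suite therefore checks end-to-end recovery to within 5% and
  checks strict statistical unbiasedness on the subtraction average
  normalised by the true M0 scalar.
* Temporal SNR uses the sample-SD convention; voxels with zero temporal SD
  (and normalized-tSD voxels with non-positive mean) are flagged `NaN`,
  excluded from ROI averages, and counted in `n_excluded`.
* Motion correction searches integer shifts exhaustively, maximising
  correlation with the voxelwise median volume, visiting candidates in
  order of increasing magnitude so ties resolve to the smallest shift, and
  refines over two passes because the median of a motion-affected series
  is blurred. The absolute frame is unidentifiable from the data — any
  constant offset of all shifts is self-consistent — so the correction
  anchors the per-axis median shift at zero. Constant volumes keep the
  identity transform. The search range must exceed the expected motion
  amplitude by the frame offset (one to two voxels in practice). This
  integer-voxel scheme deliberately replaces nonlinear template
  registration, which is out of scope; it is adequate for the phantom's
  motion model and is validated by exact shift recovery.

## Multi-PLD decay calibration

Group-mean PWS-vs-PLD ratios are turned into a generative decay constant
by fitting \(\log(\mathrm{ratio})\) linearly against PLD
(`fit_pld_decay()`). For ratios of 329%, 180%, 100% and 47% at PLDs of
400, 1000, 1600 and 2200 ms this gives an effective constant of about
934 ms — much shorter than the blood \(T_1\) of 1681 ms, absorbing into a
single exponential the early large-vessel signal that makes the measured
decay faster than blood \(T_1\) at short inflow times. Because the four
ratios do not lie exactly on one exponential, the fitted curve sits about
10% above the 47% ratio at 2200 ms and about 10% above the 329% ratio at
400 ms; phantoms generated with this constant (`pld_ratio_phantom_spec()`,
which also sets all arrival times to 150 ms so the arrival gate never
interacts with the PLD) reproduce the *fitted* ratios, and the residual
mismatch to the original ratio set is the price of the single-exponential
summary. `t1_decay_reference()` provides the pure blood-\(T_1\) reference
curve anchored at the 400 ms value for decay plots.

## Problem sizes and determinism

Unit and property tests run on a reduced 32 × 30 × 10 grid with 8
label-control pairs, which preserves every structural feature of the
full-size phantom while keeping multi-seed property loops (up to 50 seeds)
fast; end-to-end acceptance checks use the full 88 × 84 × 13 grid with 26
pairs and 20-seed ensembles. Every stochastic component — geometry, noise,
motion, corruption — is governed by explicit integer seeds, and identical
inputs produce identical outputs, including byte-identical exported CSV
tables.

## Known limitations

* Gaussian rather than Rician noise; no EPI distortion, B0
  inhomogeneity, or eddy-current artefacts.
* Perfect inversion pulses; no \(T_2\) decay during the labeling modules.
* Parametric ellipsoid geometry; no deformation, no fetal motion beyond
  rigid translation of the whole volume.
* The kinetic model is a saturation-decay description with a single
  effective decay constant per phantom; it does not model dispersed
  bolus arrival or exchange between maternal and fetal pools.
* Relative PWS only; no absolute perfusion quantification.

Passing tests on this phantom therefore demonstrate the correctness of the
processing chain and the internal consistency of the signal model under
the stated assumptions — not the fidelity of any particular in vivo
acquisition.
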