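# vsasl

Simulation and analysis of velocity-selective arterial spin labeling
(VS-ASL) perfusion MRI of the human placenta.

Placental perfusion is a candidate marker of placental function, but the
organ's highly variable double (maternal and fetal) blood supply makes the
spatially selective labeling used in brain ASL hard to plan. VS-ASL labels
blood by its *velocity* instead of its location: motion-sensitising
gradients saturate spins flowing faster than a cutoff velocity Vc anywhere
in the volume, and the control-minus-label difference after an inflow time
(post-labeling delay, PLD) is a perfusion-weighted signal. This package is
aimed at ASL methods researchers who want to reason quantitatively about
VS-ASL protocol choices for the placenta — cutoff velocity, velocity
encoding direction, inflow time, single vs dual labeling modules — without
scanner time: it pairs a closed-form signal model with a seeded digital
placenta phantom and the standard processing chain, so every pipeline stage
can be exercised against known ground truth.

## The model

For a velocity-selective module with gradient strength $G$, gradient
duration $\delta$ and module duration $T$, the effective first gradient
moment is $m_1 = G\,\delta\,T$ and the cutoff velocity is the
laminar-flow value

$$V_c = \frac{\pi}{\gamma\, m_1},$$

with $\gamma$ the proton gyromagnetic ratio. Spins moving at velocity $v$
along the encoding direction retain longitudinal magnetization
$\cos(\pi v / V_c)$ in the label condition; averaging over the parabolic
velocity profile of laminar flow in a voxel with mean velocity $\bar v$
gives

$$m_z(\bar v) = \mathrm{sinc}\!\left(\frac{2\pi \bar v}{V_c}\right),
\qquad E_{sat}(\bar v) = 1 - m_z(\bar v).$$

The voxelwise difference signal combines this saturation efficiency with
label arrival (a step or ramp at the arrival time $\tau_a$) and $T_1$
decay over the effective PLD (the nominal PLD plus 69 ms per slice of the
ascending multi-slice readout):

$$\Delta M = E_{sat}(\bar v)\; H(\mathrm{PLD}_{\mathrm{eff}} - \tau_a)\;
e^{-\mathrm{PLD}_{\mathrm{eff}} / T_{1,\mathrm{blood}}},$$

multiplied, for dual VS-ASL, by the second module's laminar response at the
voxel's readout-time velocity. Background suppression is modelled as
piecewise inversion recovery with perfect inversions. The processing chain
implements pairwise label-control subtraction, single-pass outlier
rejection (a pair is dropped when more than 20% of uterus voxels deviate
from the voxelwise temporal mean by more than 1.5 temporal SDs), M0
normalisation by the 80th percentile of the pseudo-M0 within the placenta
ROI, and the quality metrics PWS $= \Delta M / M_0 \times 100\%$, temporal
SNR, and mean-normalized temporal SD.

## Worked example

```r
library(vsasl)

vs <- vs_module_params()            # 13 mT/m, 1.2 ms, 50 ms
cutoff_velocity(vs)                 # 1.51 cm/s
scan_duration(reference_protocol()) # 196 s (3 min 16 s)

gt  <- build_phantom(phantom_spec(seed = 1))   # 88 x 84 x 13 phantom
sim <- simulate_series(gt, seed = 2)           # 26 pairs + pseudo-M0
res <- analyze_series(sim, phantom_rois(gt))
res
#> Perfusion maps: M0 = 103.561, kept 26 pairs (rejected 0)
#>   whole-placenta PWS: 2.368 +/- 1.546 %
subset(res$roi_stats, metric == "pws")
#>         roi metric mean    sd n_voxels n_excluded
#> 1  placenta    pws 2.37 1.546    15908          0
#> 2   focal_1    pws 4.14 1.529       33          0
#> 3   focal_2    pws 4.39 1.468       33          0
#> 4   focal_3    pws 4.24 1.327       33          0
#> 5   focal_4    pws 4.19 1.468       33          0
#> 6 focal_avg    pws 4.24 0.109        4          0
```

The phantom was generated with a true whole-placenta mean PWS of 2.4% and
a focal-region mean of 4.3% (typical group means for these ROIs); with 26
noisy pairs the pipeline recovers 2.37% and 4.24%. The four `focal_k` rows
are the focal hyperintense regions near the basal plate; `focal_avg`
averages their per-region means.

Parameter sweeps reproduce the one-parameter-at-a-time experimental
design, holding each seed's phantom geometry fixed across levels:

```r
res <- run_sweep("pld", levels = c(400, 1000, 1600, 2200),
                 spec = phantom_spec(), n_seeds = 5)
export_report(res, "pld_sweep/")   # sweep.csv, summary.csv, decay.csv
```

Command-line front ends for both the analysis chain and the sweep harness
are in `inst/cli/`.

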