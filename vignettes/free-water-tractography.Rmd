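---
title: "Free-water-augmented multi-tensor UKF tractography: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-water-augmented multi-tensor UKF tractography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Peritumoral vasogenic edema floods the extracellular space with free water.
In diffusion MRI this adds an isotropic signal compartment to every affected
voxel, which depresses the measured fractional anisotropy (FA) and the
directional contrast of the white matter passing through the edema.
Deterministic tractography that stops on an FA threshold therefore
terminates prematurely at the edema boundary, under-representing tracts a
neurosurgeon needs to see. The usual clinical workaround — globally lowering
the stopping threshold — recovers length at the price of widespread
false-positive tracking elsewhere.

`fwtract` implements and evaluates the model-based alternative: carry a
multi-tensor model *plus an explicit free-water (FW) compartment* along each
streamline inside an unscented Kalman filter (UKF), so that the isotropic
contamination is absorbed by the FW fraction and the stopping decision is
made on the FA of the *corrected* tissue tensor. The filter makes each
step's model fit conditional on the previous step, which regularizes
estimation through the low-contrast edema zone.

## Signal model

For gradient direction $g_k$ and diffusion weighting $b$ the normalized
signal of the two-tensor + free-water state is

$$ s_k \;=\; (1-f)\,\tfrac12\sum_{i=1}^{2} e^{-b\, g_k^\top D_i g_k}
\;+\; f\, e^{-b\, d_{\mathrm{FW}}} , $$

where each tissue tensor $D_i = \lambda_2 I + (\lambda_1-\lambda_2)\,
m_i m_i^\top$ is cylindrically symmetric with principal direction $m_i$ and
eigenvalues $(\lambda_1, \lambda_2, \lambda_2)$, $f \in [0,1]$ is the FW
fraction, and $d_{\mathrm{FW}}$ is fixed at $3.0\times10^{-3}$ mm²/s (free
water at body temperature; never estimated). The tissue compartments share
the non-FW signal equally; per-compartment weights are not estimated, which
keeps the state minimal and identifiable. The plain two-tensor model is the
$f \equiv 0$ special case, and the package guarantees exact nesting: pinning
the FW fraction removes it from the state vector, so a pinned-at-zero run is
bitwise identical to the two-tensor run.

The filter state for the full model is
$(m_1, \lambda_{1,1}, \lambda_{2,1}, m_2, \lambda_{1,2}, \lambda_{2,2}, f)$,
11 parameters. Directions are stored as unnormalized 3-vectors and
renormalized by a projection step after every update; eigenvalues are
floored at `lambda_min` ($10^{-4}$ mm²/s) and re-ordered, and $f$ is clamped
to $[0,1]$. We chose this parameterization over quaternions or spherical
coordinates because every intermediate quantity stays testable against
closed forms.

## Tracking procedure

Seeding places 20 jittered seeds in every brain-mask voxel whose
single-tensor FA exceeds 0.18. Each streamline is tracked bidirectionally;
both halves re-initialize the filter at the seed from a log-linear
single-tensor fit (principal direction and eigenvalues copied into both
compartments, $f$ started at `fw_init`), which avoids direction-history
leakage between the halves. Because the single-tensor fit absorbs whatever
isotropic fraction is present into inflated eigenvalues, the initial
eigenvalues are deflated by $\ln(1/(1-f_0))/b$ so the initial state
reproduces the fitted signal — without this, the filter's first innovations
push $f$ to zero and it can take many steps to recover.

Each step interpolates the normalized signal trilinearly at the current
position, runs one scaled-unscented-transform predict/update cycle
(identity process model plus diagonal process noise $Q$; diagonal
measurement noise $R$), selects the tissue compartment most aligned with
the previous direction, and takes a 0.9 mm Euler step along it
(≈ 0.4 voxel at the 2.3 mm protocol resolution). Tracking stops when

* the tracked compartment's FA falls below 0.15,
* the normalized average signal falls below 0.08,
* the position leaves the brain mask or image grid, or
* the streamline reaches 250 mm; streamlines shorter than 10 mm are
  discarded.

No curvature stop is applied — the stopping rules are exactly the two
thresholds above. The "normalized average signal" is implemented as the
*mean* of the baseline-normalized signal over the diffusion-weighted
directions (a `signal_stat = "sum"` switch is provided): a sum over 30
directions compared against 0.08 would be three orders of magnitude away
from any plausible operating point, so the mean is the only reading of the
threshold that is numerically coherent.

## Filter tuning

At $b = 2000$ s/mm² the FW fraction is weakly identified from a single
voxel's signal: multiplying the tissue signal by $(1-f)$ is almost exactly
equivalent to adding $\ln(1/(1-f))/b$ to both eigenvalues, so the
likelihood has a flat ridge connecting "high FW, healthy tensor" to
"no FW, inflated tensor". Where the filter settles on that ridge is decided
by the relative process-noise scales. The defaults,

| parameter | default | role |
|---|---|---|
| `q_dir`  | $10^{-4}$ | per-step variance of direction components |
| `q_diff` | $10^{-9}$ | per-step variance of diffusivities (mm²/s)² |
| `q_fw`   | $10^{-3}$ | per-step variance of the FW fraction |
| `r_meas` | $0.02$    | measurement noise s.d. per gradient |
| `p0_dir`, `p0_diff`, `p0_fw` | $10^{-2}, 10^{-7}, 2.5\times10^{-2}$ | initial covariance |
| `alpha`, `beta`, `kappa` | $10^{-3}, 2, 0$ | scaled UT parameters |

were tuned once on the noise-free fixed-point experiment (50 repeated
updates on the signal of a known 60° crossing with $f = 0.4$): they are the
setting at which the filter attributes amplitude loss to the FW fraction
rather than to eigenvalue inflation (recovering $f$ within 0.1 and both
directions within a fraction of a degree), while still letting the
two-tensor model adapt its eigenvalues within a few steps when it must.
Larger `q_fw` destabilizes $f$ against its clamping boundary; larger
`q_diff` lets the eigenvalues win the ridge and $f$ collapses. All are
exposed in `tracker_config()`.

The covariance is repaired after every update (symmetrized, eigenvalues
clamped to $10^{-12}$ of the trace) so long tracks cannot die of
accumulated asymmetry.

## The synthetic phantom

No patient data ships with the package; every claim is exercised on
simulated acquisitions matching the emulated protocol: 30
electrostatically-spread directions on the hemisphere (deterministic
golden-spiral initialization plus repulsion sweeps, no RNG), one $b=0$
baseline, $b = 2000$ s/mm², 2.3 mm isotropic voxels on a $30^3$ grid.
Rician noise is applied as $\sqrt{(S+n_1)^2+n_2^2}$ at a baseline SNR of
20 — typical clinical EPI.

The default edema phantom is a straight 60 mm bundle (radius 3 mm) with
tissue eigenvalues $(1.4, 0.5)\times10^{-3}$ mm²/s, i.e. tissue FA ≈ 0.57.
These are deliberately association-tract-like rather than
corpus-callosum-like values: with very stiff tensors (e.g. FA 0.87) the
uncorrected two-tensor fit retains too much directional contrast inside
edema and never crosses the 0.15 stopping threshold before the Rician noise
floor extinguishes the signal for *every* model, so the phenomenon under
study cannot occur at all at this protocol. With realistic moderate
anisotropy the two regimes separate, which is exactly the regime the
clinical observations describe.

The edema region is an ellipsoid (semi-axes $10\times4\times7$ mm,
elongated along the bundle) centered mid-bundle and offset 2 mm laterally,
so that roughly a tenth of the bundle cross-section never enters edema —
providing the non-traversing fiber population needed for the FW-fraction
comparison. Its FW fraction tapers linearly from 0.8 at the center to 0.55
at the boundary: vasogenic edema remains strongly FW-elevated at its
radiological margin, and the graded profile creates a spatially extended
zone in which the uncorrected tracker's FA is below 0.15 while the mean
signal is still above 0.08 — the corridor in which a free-water-aware
tracker can continue and an unaware one cannot. Tissue radial diffusivity
inside edema is raised by `radial_boost` (default 0.5) per unit local FW
fraction, emulating the expanded extracellular space. The isotropic
background (diffusivity $0.8\times10^{-3}$ mm²/s, FW fraction 0.05) mimics
gray matter.

What the phantom does *not* emulate: EPI distortion, motion, eddy currents,
anatomical curvature of real tracts, axonal injury or infiltration inside
edema, and spatially correlated noise. Passing tests on these phantoms
demonstrate that the estimator and the comparison pipeline behave as
designed under the stated acquisition physics — not that the clinical
effect sizes of any patient cohort are reproduced.

## The three-arm comparison

`run_comparison()` mirrors the evaluation design: (1) the two-tensor
tracker at default thresholds, (2) the two-tensor + FW tracker, (3) the
two-tensor tracker swept over stopping-FA values
$\{0.15, 0.13, 0.11, 0.09, 0.07, 0.05, 0.03\}$, from which the
volume-matched arm is selected as the threshold whose whole-tract volume is
closest to the FW arm's (ties go to the larger, more conservative
threshold). All arms share the phantom, noise realization and seed jitter,
so arm differences are purely model differences. Quantification follows the
tract-measurement conventions: tracts are voxelized by supersampling every
segment at 1/20 of the smallest voxel dimension — the same spacing as the
independent verification oracle; coarser spacing (half a voxel) was found
to hop over corner-clipped voxels — volume is nonzero-voxel count times
voxel volume, the
edema-intersection volume counts voxels nonzero in both maps, and fibers
are split into edema-traversing and non-traversing parts with point-weighted
mean FW fraction per part (a fiber-weighted switch exists; point-weighting
was chosen because the per-point FW fraction is the quantity the model
estimates, and it is the default that does not over-weight short fibers).

On batches, `run_edema_batch()` replaces a patient cohort with ten phantoms
of graded edema size (scale 0–13.5 mm, reduced $28\times14\times14$ grid
sized to the bundle so the batch completes in minutes) and correlates the
FW arm's whole-tract volume gain with the edema-bundle overlap volume. Only
the *sign* of this association is asserted anywhere: magnitudes are
cohort-dependent quantities that a synthetic batch cannot and should not
reproduce.

## Numerical choices and degenerate inputs

* Half-open voxel convention: a point belongs to voxel $i$ iff its
  continuous grid coordinate lies in $[i-\tfrac12, i+\tfrac12)$; this
  resolves voxelization ties on voxel faces deterministically.
* TRK streamline files store points in voxel-scaled coordinates with a
  corner origin; the reader/writer converts to/from world RAS mm through
  the header's voxel-to-RAS matrix and is cross-validated against an
  independent reference implementation.
* Signals are clamped at $10^{-8}$ of baseline before any logarithm;
  baselines are floored at the same scale.
* Out-of-grid positions return an all-`NA` signal; callers treat it as a
  stopping condition, never an error.
* Seed jitter is drawn in voxel raster order from a single RNG stream, so
  results cannot depend on execution order; phantom noise, seeding and the
  comparison harness are all reproducible from explicit integer seeds.
* Degenerate statistics (zero-variance paired differences, constant
  correlation inputs) raise errors instead of returning misleading values.

## Problem sizes used in the shipped experiments

The test-suite and acceptance-script experiments run, per arm, roughly
2,500–4,000 eligible seed voxels × 20 seeds on the $30^3$ phantom, and the
threshold sweep and batch use the reduced grid. These sizes were chosen as
the smallest at which the bundle is densely covered and arm differences are
stable across seeds; larger grids change nothing qualitatively.

## Known limitations

* The FW fraction is identified only weakly at single-shell $b=2000$; its
  absolute scale along a streamline depends on the process-noise prior
  (the ridge discussed above). Recovery to ±0.15 is demonstrated noise-free;
  under clinical noise the estimate is best read comparatively
  (traversing vs non-traversing), which is how it is used.
* The equal-weight tissue mixture cannot represent genuinely unequal
  crossing populations; the second tensor then compromises.
* Euler integration at 0.9 mm is standard for this family of trackers but
  first-order; curvature error is negligible for the phantom geometries
  shipped and for typical association-tract curvature.
* The reduced-FA comparison arm inherits the well-known failure mode it is
  meant to exhibit: at 0.03–0.05 it tracks freely through the isotropic
  background. This is the behavior the volume-matching step exists to
  control, and it reproduces on the phantom.
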