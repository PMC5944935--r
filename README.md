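# fwtract

Free-water-augmented multi-tensor unscented Kalman filter (UKF)
tractography for diffusion MRI, with a synthetic edema-phantom simulator
and the tract-quantification suite needed to evaluate it.

## The problem

Peritumoral vasogenic edema adds extracellular free water (FW) to every
voxel it touches. The isotropic FW signal depresses measured fractional
anisotropy (FA), so deterministic tractography that stops when FA falls
below a threshold terminates at the edema boundary and under-represents
fiber tracts that neurosurgical planning needs intact. Globally lowering
the stopping threshold (the common workaround) recovers tract length at the
cost of false-positive tracking everywhere else.

`fwtract` is for researchers studying this trade-off. It implements:

* **Tracking** (`track_whole_volume`, `propagate_streamline`): a recursive
  UKF that carries a two-tensor model — optionally augmented with an
  isotropic FW compartment of fixed diffusivity
  `d_FW = 3.0e-3` mm²/s — along each streamline. The normalized signal
  model is

  `s_k = (1 − f) · ½ Σᵢ exp(−b gₖᵀ Dᵢ gₖ) + f · exp(−b d_FW)`

  with cylindrically symmetric tissue tensors
  `Dᵢ = λ₂I + (λ₁ − λ₂) mᵢmᵢᵀ` and FW fraction `f`. Seeding uses 20
  seeds/voxel where single-tensor FA > 0.18; tracking stops when the
  tracked compartment's FA < 0.15 or the normalized average signal < 0.08.
  With the FW compartment, the stopping FA is that of the *corrected*
  tissue tensor, so tracking continues through FW-contaminated voxels.
* **Phantom simulation** (`phantom_spec`, `build_field`, `synthesize_dwi`):
  ground-truth fiber bundles (straight / arc / crossing) with an
  edema-like FW-elevated region, rendered at the emulated protocol
  (30 directions, 1 b=0, b = 2000 s/mm², 2.3 mm voxels) with Rician noise.
* **Quantification** (`voxelize_tract`, `intersection_volume`,
  `split_by_mask`, `fiber_stats`, `select_rfa_threshold`): tract voxel
  volume, edema-intersection volume, fiber splitting by edema traversal
  with per-part mean FW fraction, length histograms, and volume-matched
  selection of a reduced stopping-FA threshold.
* **Study harness** (`run_comparison`, `run_edema_batch`, `paired_t_test`,
  `pearson_with_fit`): the three-arm comparison — plain two-tensor,
  two-tensor + FW, and volume-matched reduced stopping-FA — plus batch
  experiments over graded edema sizes.
* **I/O**: NIfTI-1 volumes, FSL bval/bvec gradient tables, TrackVis TRK
  streamlines (per-point FA and FW-fraction scalars), ASCII VTK polylines.

## Worked example

```r
library(fwtract)

# Default edema phantom: straight 60 mm bundle, ellipsoidal edema region
# with peak FW fraction 0.8, Rician noise at SNR 20.
phantom <- default_edema_phantom(rng_seed = 1)
field   <- build_field(phantom)
dwi     <- synthesize_dwi(field, make_protocol(), phantom)
edema   <- label_map((field$fw > 0.05 + 1e-9) * 1L, field$affine)

arms <- lapply(c(base = "2t", fw = "2t-fw"), function(m) {
  tract <- track_whole_volume(dwi, NULL,
                              tracker_config(model = m, rng_seed = 1))
  lm <- voxelize_tract(tract, dwi)
  list(tract = tract, vol = labelmap_volume(lm),
       edema = intersection_volume(lm, edema))
})
sp <- split_by_mask(arms$fw$tract, edema)

cat(sprintf("tract volume:        %0.f -> %0.f mm^3\n",
            arms$base$vol, arms$fw$vol))
cat(sprintf("edema intersection:  %0.f -> %0.f mm^3\n",
            arms$base$edema, arms$fw$edema))
cat(sprintf("mean FW fraction:    %.3f (traversing) vs %.3f (spared)\n",
            mean_point_scalar(sp$traversing, "fw"),
            mean_point_scalar(sp$non_traversing, "fw")))
```

Output (seed 1):

```
tract volume:        3881 -> 4429 mm^3
edema intersection:  572 -> 706 mm^3
mean FW fraction:    0.193 (traversing) vs 0.126 (spared)
```

With the FW compartment the tracker recovers ~14% more tract volume, and
the additional volume is concentrated inside the edema region (+23%
edema-intersection volume). Fibers that traverse edema carry a higher mean
estimated FW fraction than the spared fibers — the per-point FW estimate
localizes the edema along the tract. (Exact numbers vary with the RNG
seed; the orderings are stable.)

A command-line interface wrapping the same functions ships in
`inst/cli/fwtract`:

```sh
Rscript inst/cli/fwtract simulate --out-prefix phantom --seed 1
Rscript inst/cli/fwtract track --dwi phantom_dwi.nii.gz \
    --bval phantom.bval --bvec phantom.bvec --mask phantom_mask.nii.gz \
    --model 2t-fw --seed 1 --out tract.trk
Rscript inst/cli/fwtract quantify --tract tract.trk \
    --reference phantom_mask.nii.gz --mask phantom_edema.nii.gz \
    --out report.json
Rscript inst/cli/fwtract compare --seed 1 --out comparison.json
```

## Package layout

* `R/model.R`, `src/ukf.cpp` — signal models, FA formulas, tensor fitting,
  and the compiled UKF kernel.
* `R/phantom.R` — phantom specification, ground-truth fields, DWI synthesis.
* `R/tracking.R` — tracker configuration, seeding, propagation.
* `R/quant.R` — voxelization, volumes, splitting, statistics.
* `R/harness.R` — three-arm comparison, batches, statistical tests.
* `R/dwi.R`, `R/trk.R`, `R/mask.R`, `R/cli.R` — I/O and the CLI.
* `vignettes/free-water-tractography.Rmd` — the models, the phantom design
  and its rationale, filter tuning, and known limitations.
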