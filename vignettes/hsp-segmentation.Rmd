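---
title: "Semiautomated high-signal plaque segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiautomated high-signal plaque segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hspseg)
```

## The measurement problem

On 3D turbo spin-echo T1-weighted black-blood vessel-wall MRI, unstable
carotid plaque components are hyperintense relative to adjacent muscle:
a plaque-to-muscle contrast ratio above 1.3 marks high-signal plaque (HSP,
covering hemorrhagic and lipid-rich/necrotic tissue), and above 1.52 is
consistent with intraplaque hemorrhage specifically. Quantifying HSP volume
by manual slice-by-slice contouring is slow and rater-dependent. `hspseg`
implements a semiautomated pipeline in which the only manual inputs are a
rough seed point near the plaque centre and a muscle reference ROI; every
downstream step is deterministic, so repeated measurements of the same
inputs agree exactly.

## The pipeline

Stage 1 extracts the *plaque region* on a Gaussian-smoothed copy of the
volume:

1. The manual seed is corrected to the brightest voxel of the
   $(2r+1)^3$ window around it ($r = 3$, i.e. $7\times7\times7$), clipped at
   the volume border. This makes the result insensitive to exactly where in
   the bright core the operator clicks.
2. The initial threshold $T_0$ is the window maximum around the corrected
   seed, so at $T_0$ the region is exactly the seed voxel (the criterion is
   strict: voxels join when intensity $> T$).
3. Each pass adds all voxels connected to the region (26-neighbourhood by
   default) with intensity $> T$, then decrements $T$ by one step. Because
   candidate sets are nested as $T$ falls, the per-pass regions are nested
   too, and each pass's region equals the connected component of
   $\{v > T\}$ containing the seed.

Stage 2 segments HSP *within* the plaque: voxels of the **original**
(unsmoothed) volume with intensity strictly above
$\text{coefficient} \times \overline{\text{muscle}}$ form the HSP mask. The
muscle mean is likewise taken on the original intensities — the contrast
ratio is a property of native tissue signal, and smoothing would bias both
sides of the ratio. Volumes come from the voxel count times
$d_x d_y d_z$, or equivalently from the slice-area convention
$\sum_k (\text{count}_k\, d_x d_y)\, d_z$ used by manual planimetry.

## Stop conditions and their interpretation

The growing loop ends in one of three ways, recorded as `stop_reason` in
the trace:

* **`volume_doubled`** — a pass multiplied the region by more than
  `doubling_factor` (default 2). This is the signature of the threshold
  dropping below the plaque/background boundary: the region floods into
  surrounding tissue at once. The region from the pass *before* the flood
  is returned. Keeping the doubled region would defeat the condition's
  evident purpose, which is to reject the flood.
* **`no_new_voxels`** — the region is saturated: no voxel adjacent to it
  exceeds the threshold floor, so no admissible threshold could ever add
  another voxel. We deliberately do *not* stop at the first pass that adds
  nothing: on any volume with flat intensity plateaus (and every smoothed
  synthetic object has them) the histogram has empty gaps, and a literal
  "zero additions this pass" rule would halt inside the first gap below the
  core plateau, truncating the plaque. Passes that add nothing but still
  have brighter-than-floor neighbours simply continue decrementing.
* **`floor_reached`** — the threshold would fall below `threshold_floor`
  (default: the smoothed volume minimum). This guarantees termination; a
  seed whose neighbours never qualify descends to the floor and returns a
  one-voxel mask.

The doubling stop is additionally **armed only once the region holds
`doubling_min_voxels`** (default 100, about 18 mm³ at the default spacing).
Early growth away from a single seed voxel routinely doubles the region
from one pass to the next — accretion of the second, third, tenth voxel is
legitimate growth, not flooding — and in noisy data the region climbs the
upper tail of the core's intensity distribution in bursts that easily
exceed a factor of two while the region is still tiny. Traces on the
package's own phantom show e.g. an 18 → 39 voxel pass deep inside the core;
arming the guard only at plaque-like size confines it to the boundary
flood it is meant to catch. The parameter is exposed precisely because this
choice is a judgement call.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `window_radius` | 3 | voxels | seed-correction / initial-threshold window (7×7×7) |
| `sigma` | 0.5 | voxels | Gaussian smoothing width per axis; 0 disables |
| `connectivity` | 26 | – | voxel neighbourhood (6 / 18 / 26) |
| `threshold_step` | 1 | intensity | per-pass threshold decrement |
| `doubling_factor` | 2 | – | flood detection ratio ("more than doubled") |
| `doubling_min_voxels` | 100 | voxels | region size at which the flood guard arms |
| `threshold_floor` | min(smoothed) | intensity | termination bound |
| `coefficient` | 1.3 | – | HSP contrast-ratio cutoff; 1.52 targets IPH |

σ is interpreted in voxel units applied per axis (the usual convention of
volumetric smoothing filters; at near-isotropic vessel-wall resolutions the
distinction from mm is minor), with the kernel truncated at $4\sigma$,
normalized, and borders handled by edge replication. The decrement of one
intensity unit presumes roughly integer-scaled scanner values; for data on
other scales `threshold_step` should be set to a small fraction of the
noise standard deviation, since a step that is coarse relative to noise
makes per-pass growth lumpy and the flood guard correspondingly
trigger-happy.

Two switches resolve ambiguities the procedure leaves open: seed correction
defaults to the smoothed volume (`seed_on_smoothed = TRUE`) for robustness —
on raw data the window maximum is an extreme noise order statistic — and
26-connectivity is the default neighbourhood for blob-like lesions at
near-isotropic resolution. Ties in window maxima are broken by the lowest
$(i, j, k)$ in lexicographic order, making every step deterministic. All
coordinates are 1-based array indices, matching R's storage convention
exactly, in the API, the CLI and the JSON reports.

## The synthetic phantom

`phantom_spec()` / `generate_phantom()` build the validation scaffold: an
ellipsoidal high-signal core (semi-axes 3 × 3 × 3.6 mm) inside an
ellipsoidal plaque rim (4.5 × 4.5 × 5.4 mm), a separate cuboid of muscle as
the contrast reference, and a darker background, on a 64 × 64 × 32 grid at
the 0.45 × 0.45 × 0.9 mm spacing of 3D TSE vessel-wall acquisitions.
Intensities (background 350, muscle 500, rim 590, core 775 in arbitrary
scanner-like units) encode the defining contrast ordering: the rim sits at
1.18× the muscle mean — below the 1.3 HSP cutoff, fibrous-like — and the
core at 1.55×, above the 1.52 IPH cutoff. Gaussian noise (default sd 10,
i.e. 2% of the muscle mean) is added voxel-wise; geometry is rasterized by
voxel-centre inclusion and ground-truth volumes are those of the rasterized
masks, so volume-recovery checks can demand exact equality. The manual seed
emulates operator imprecision: a random core voxel perturbed by up to two
voxels per axis, kept inside the plaque. Everything is deterministic given
`rng_seed`.

What the phantom does **not** emulate: Rician noise statistics (at
vessel-wall SNR the Gaussian approximation is immaterial for threshold
logic), partial-volume blur at tissue interfaces, receive-coil bias fields,
flow artifacts, and the irregular internal texture of real plaque. Passing
the phantom tests therefore demonstrates the *algorithmic* correctness of
growing, thresholding and volumetry under controlled contrast — not
clinical accuracy on patient data, which requires real cohorts and raters.

## Agreement statistics

`icc21()` implements the two-way random-effects, absolute-agreement,
single-measures intraclass correlation — the standard form for inter-rater
and test–retest reliability of single measurements — from the row, column
and residual mean squares, with the F-based 95% confidence interval of
McGraw & Wong. Degenerate inputs (zero residual and column variance, e.g.
two identical columns; or zero total variance) return a value of 1 with a
flagged degenerate interval rather than NaN. `bland_altman()` reports
mean difference and `bias ± 1.96 sd` limits of agreement using the sample
(n−1) standard deviation, in raw units or as percent of the pair mean —
both conventions appear in reliability studies of lesion volumetry, so both
are provided. `spearman_rho()` is the Pearson correlation of mid-ranks and
rejects constant series instead of propagating NA.

## Problem sizes and numerical checks

The test suite validates the grower against an independently written
per-threshold flood-fill reference (connected components via `igraph`) on
240 random integer volumes of 6³–10³ voxels across all three
connectivities, checks each stop condition on constructed geometries where
the stopping pass is known exactly, and verifies phantom recovery
noise-free (Dice = 1.0 and exact volume demanded) and at 2% noise over 20
generator seeds (medians of Dice and volume error). ICC recovery is checked
against the analytic variance ratio $\sigma_b^2/(\sigma_b^2+\sigma_e^2)$ at
n = 200 and n = 500 simulated lesions. The full-resolution phantom was
sized so that a complete segmentation takes a few seconds and the entire
suite a couple of minutes on one CPU.

## Known limitations

* A single connected plaque per run; multi-lesion cases are handled by
  looping over seeds.
* The threshold-decrement schedule assumes the intensity scale is coarse
  relative to noise structure in the sense discussed above; data stored on
  a unit scale need an adjusted `threshold_step`.
* Individual noisy runs can still terminate early if noise creates a large
  connected burst exactly at the arming size of the flood guard; the
  region-growing trace (always included in the CLI report) makes such runs
  easy to audit.
* The 1.52 coefficient is exposed for hemorrhage-targeted segmentation but
  no hemorrhage-specific validation is claimed; the phantom validates the
  thresholding mechanics only.
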