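---
title: "earlbench: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{earlbench: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earlbench)
```

`earlbench` evaluates how the choice of a harmonized PET reconstruction
protocol (EARL1 vs EARL2), combined with the interpolation steps of a
radiotherapy planning chain, distorts metabolically defined target volumes.
Everything runs on digital phantoms with analytic ground truth. This
vignette records the model, the parameters that matter, and every numerical
decision a maintainer would otherwise have to reverse-engineer.

## 1. The world model

All geometry lives in a single world frame, in millimetres. A `grid3d` is
an axis-aligned voxel lattice: integer dimensions, per-axis spacing, and
the world position of the *center* of the first voxel. Interpolation,
VOI membership and SUVpeak spheres are all defined on voxel-center
coordinates; this convention is load-bearing, because corner-based
conventions shift every volume metric by half a voxel. There is no
registration step anywhere: phantom, reconstructions, CT and dose grids
share one frame by construction.

Phantoms are lists of convex analytic primitives (spheres, finite
cylinders, capsules), each with a uniform activity concentration in Bq/mL,
over a background primitive. Nesting is declared by order: a later insert
is innermost and wins where primitives overlap (needed for the tube-in-vial
configuration). Radioactive decay is not modelled — all concentrations are
decay-corrected constants, since the analysis is static.

### Rasterization

`rasterize()` produces a voxel map in which each voxel carries the
volume-weighted mean concentration of its supersampled subvoxels (default
4 per axis, i.e. 64 subsamples). Voxels deeper than half a voxel diagonal
inside/outside a primitive's surface skip supersampling — exact for convex
solids — which makes 1 mm rasterizations of multi-litre phantoms cheap.
Total activity is conserved to well under 1% at the default supersampling.

Ground-truth **masks** use voxel-*center* membership (innermost wins), not
an occupancy-majority rule. The two differ subtly: a voxel centered exactly
on a convex surface covers slightly *less* than half of the solid, so a
`occupancy >= 0.5` rule undercounts small spheres by 1–2% systematically,
while center counting is volume-unbiased. Center membership is also exactly
the convention used for analytic VOIs (`voi_from_primitive()`), so a mask
and the VOI of the same primitive on the same grid are identical.

### The three phantoms and their stated conditions

* `make_uniform_cylinder(70, 6000)` — the SUV calibration phantom: 70 MBq
  in 6 L, i.e. 11.667 kBq/mL. With `suv_calibration(70, 6)` (6 kg at
  1 g/mL) it must read SUV = 1, ±10% accepted.
* `make_nema_spheres(2000, 10)` — six spheres of 10, 13, 17, 22, 28,
  37 mm diameter (the standard sphere set; only the 10–37 range is fixed
  by the protocol description) at ten times a 2 kBq/mL background
  (20 MBq in 10 L), on a 114.4 mm ring in one axial plane.
* `make_insert_phantom()` — the anthropomorphic stand-in: V1, a 0.3 mL
  tube at 0.116 MBq (386.7 kBq/mL); V3, a vial holding 2 mL of solution at
  0.1 MBq (50 kBq/mL) with a second 0.3 mL tube V2 nested inside, so the
  combined structure V2+V3 measures 2.3 mL. Two values are not fixed by
  the physical description and are package choices, exposed as arguments:
  V2's fill concentration (default **2× the V3 concentration**, creating
  the heterogeneous two-level lesion the sub-segmentation is meant to
  split) and the background (default **3.3 kBq/mL**, a typical
  soft-tissue level at ~3.3 MBq/kg dosing — high tumour-to-background
  contrast over a homogeneous background, the regime the 41% threshold
  rule assumes).

## 2. Reconstruction emulation

The vendor iterative algorithms (OSEM, PSF-based) are deliberately replaced
by a single isotropic Gaussian surrogate; time-of-flight is acknowledged
but carries no emulatable content. The presets are

| protocol | PSF FWHM | grid spacing (mm) |
|---|---|---|
| EARL1 | 6 mm | 3.1819 × 3.1819 × 5 |
| EARL2 | 5 mm | 1.5910 × 1.5910 × 1.5 |

`emulate_recon()` blurs **on the fine truth grid first** (σ = FWHM/2.3548,
kernel truncated at 4σ, constant padding at the supplied background value)
and only then downsamples to the protocol grid by box-mean volume
averaging — per-axis interval-overlap weights, the tensor product of which
is exact volume averaging. Blurring after downsampling would alias the
sub-voxel inserts. A protocol grid finer than the truth grid is rejected:
it would fabricate resolution never simulated. Optional zero-mean Gaussian
noise (standard deviation = `noise_sigma` × background) is applied after
downsampling with a fixed seed, then values are clipped at zero; noise is
**off by default** because the reference measurements are treated as
noise-free central estimates.

Because only the post-filter is modelled — there is no intrinsic detector
response — recovery coefficients computed from the emulation are optimistic
relative to physical scanners, and small spheres can exceed the printed
EARL bands. The total effective FWHM is the one tunable
(`recon_protocol("custom", fwhm, spacing)`); the package makes no claim to
reproduce any particular scanner's RC curve.

## 3. SUV metrics

SUV uses the body-weight convention: concentration divided by injected
activity per gram, at 1 g/mL density. SUVmax and SUVmean are taken over
the VOI; SUVpeak maximizes, over spheres of 12 mm diameter centered on
**VOI voxel centers**, the mean of all image voxels whose centers fall
inside the sphere (world mm, so anisotropic grids are handled correctly).
Restricting candidate centers to voxel centers is a documented
discretization: on coarse grids a continuum-optimal center could differ.
The peak sphere may extend beyond the VOI but is clipped at the image
boundary; if no candidate sphere contains a voxel, SUVpeak is reported as
undefined. `suvmean <= suvmax` and `suvpeak <= suvmax` always hold;
`suvmean <= suvpeak` is *not* guaranteed and is not asserted.

RC is the ratio of measured to actual concentration per insert, with the
VOI either the analytic insert geometry on the image grid or a
fractional-max threshold region. Acceptance bands are inclusive at both
ends (the boundary convention is not specified anywhere authoritative; a
measurement exactly on the limit passes).

## 4. Resampling chains

`resample_image()` evaluates, at each target voxel center, one of three
separable interpolants of the source image:

* **nearest** — closest source center; exact half-way points break toward
  the *lower* index, a reproducibility convention that matters because the
  default dose grid places its centers exactly on CT cell corners;
* **linear** — trilinear on the 8 enclosing centers, edge-clamped;
* **spline** — interpolating tricubic spline, built per axis from natural
  cubic splines on samples mirror-padded by 3; equivalent to a
  mirror-boundary tricubic away from the outermost sample, exactly
  interpolating at sample points, and the only method allowed to overshoot
  the source range (bounded, in practice, well under 15% of the local
  range on smooth fields).

Target centers outside the source voxel footprint take a fill value.
All three methods reproduce constants exactly and are validated against
independent brute-force point-evaluation oracles in the test suite.

The planning chain is PET grid → CT grid → dose grid. Default grids derive
from the patient protocol: CT in-plane spacing 800 mm / 512 = 1.5625 mm,
dose = CT halved (3.125 mm). Two deliberate choices:

* the grids **cover only the phantom extent**, not a full 80 cm field of
  view — interpolation is local, so cropping is computationally equivalent
  and keeps desk-scale runs cheap;
* both grids are isotropic at the in-plane spacing. A clinical 5 mm CT
  slice thickness would alias the sub-mL inserts outright and would make
  every volume metric slice-quantized;
* the dose grid is **face-aligned** with the CT grid (same lower corner,
  doubled voxel), as when a 512-pixel slice becomes a 256-pixel slice over
  the same field of view. Center-aligned halving would place dose centers
  *on* CT centers, where all interpolation methods coincide and the method
  comparison degenerates.

Images (not masks) are interpolated, and segmentation is repeated on each
grid; nearest-neighbor mask transfer exists for the shape-coefficient
comparison only.

## 5. Segmentation

The MATV is the set of ROI voxels with value ≥ `fraction` × (ROI maximum),
default fraction 0.41, boundary inclusive (a constant ROI is all selected).
One threshold is computed per ROI and reused for every structure inside
it. For phantoms the ROI is derived automatically as the structure's
analytic bounding box dilated by 2 × FWHM, standing in for a manually drawn
region. The threshold is recomputed on every grid a lesion is segmented
on. Thresholding is idempotent and monotone in the fraction; both are
tested.

Heterogeneous lesions are split by affinity propagation on the MATV
voxels. Features are (x, y, z in mm × spatial weight, intensity ×
intensity weight); similarity is negative squared Euclidean distance; the
preference defaults to the median pairwise similarity. The default
intensity weight makes **one SUV unit count like one voxel diagonal** —
which presumes SUV-scale values, so the pipeline divides concentration
images by the phantom background level (background tissue ≈ SUV 1) before
clustering; raw Bq/mL values (~10⁵) would drown the spatial features.

The message-passing implementation is fully deterministic (no random
jitter; ties break toward the lower index) with three robustness measures:
a burn-in and a convergence stability window both scaled by the message
relaxation time 1/(1 − damping), and the standard post-convergence
refinement that alternates point assignment with choosing, per cluster,
the member maximizing total intra-cluster similarity. On well-separated
toy sets (≤ 12 points) the result attains the exhaustively verified
optimum of the net-similarity objective, and damping 0.5 and 0.9 give
identical labelings — both are tested. All-identical inputs collapse to
one cluster by an explicit early exit (the similarity matrix is all zeros
and the generic machinery would tie everywhere).

Clusters are merged into two tiers by mean uptake: the inner boost volume
is the union of clusters whose mean exceeds the MATV-wide mean; the outer
target is the whole MATV — mirroring an inner high-dose volume nested in
an outer target. This two-tier rule, the feature weights and the
preference are interpretations (the reference procedure's exact settings
are unpublished) and are all exposed in `segmentation_params()`; once set
they are meant to be frozen across grids and protocols. A MATV under two
voxels degrades to a single-tier result, flagged homogeneous.

## 6. Scoring and chain selection

Volumes are voxel count × voxel volume, in mL. Percent deviation is
signed, `100 × (measured − actual)/actual` (oversegmentation positive),
printed as integers except below 1% in magnitude (one decimal). The shape
coefficient is the Jaccard index; masks on different grids are compared on
the finer grid of the pair after nearest-neighbor transfer (interpolating
occupancies and re-thresholding is deliberately *not* the default — it
changes volumes). Two empty masks give an undefined SC with a warning. A
chain's score is the product of its per-structure, per-stage SCs (never
exceeding its smallest factor); chains within 10% (relative, configurable)
of the best cumulative SC are near-ties resolved by smaller mean absolute
volume deviation, remaining ties by input order. The rule is pluggable
because "a compromise between shape and volume fidelity" is inherently a
judgment call.

## 7. What the generator does and does not establish

The synthetic world reproduces: partial-volume dilution of small inserts,
the resolution gap between the two accreditations, grid-alignment effects
of two-stage resampling, and heterogeneous-uptake splitting. It does not
reproduce: iterative-reconstruction convergence artifacts, count-statistics
noise texture (the optional Gaussian noise is a robustness knob, not a
physics model), scatter/randoms/attenuation, respiratory motion, or any
scanner's true system response. A green suite therefore establishes the
*relative* claims (e.g. every EARL1-segmented volume ≥ its EARL2
counterpart across all nine interpolation chains, RC monotone in size and
resolution) and the arithmetic identities — not agreement with any
physical scanner's absolute volumes.

## 8. Known limitations and honest failures

* **Threshold volume bias at finite voxel size.** With volume-averaged
  rasterization, a ≥ 41%-of-max threshold includes boundary voxels down to
  occupancy `(0.41·max − bg)/(conc − bg)`, a surface term of order
  (0.5 − occ_thr) × area × spacing. At 1 mm and 10:1 contrast this puts
  the 10 and 13 mm spheres just outside a 5% volume-recovery band
  (+5.0%, +5.3%), and the two-level V2+V3 structure further out (−17%:
  its cold shell, at half the lesion max, needs ~80% occupancy to clear
  the threshold). The corresponding acceptance expectations are left
  failing by design, with this analysis, rather than loosened: the
  estimator is exact in the continuum limit and the bias shrinks linearly
  with voxel size.
* Affinity propagation is quadratic in MATV voxels; the all-chains sweep
  therefore leaves sub-segmentation off by default (`subsegment = TRUE`
  enables it for targeted runs).
* NIfTI support is minimal by design: single-file NIfTI-1, axis-aligned,
  positive spacings; rotated/oblique orientations and flipped axes are
  rejected with clear messages rather than silently reinterpreted.
* The printed EARL RC bands are applied as given; whether they refer to a
  specific sphere or summarize the set is not fixed by the protocol text,
  so `rc_limits()` also accepts custom per-use bounds.
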