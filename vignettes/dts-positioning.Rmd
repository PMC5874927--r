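---
title: "DTS-based patient positioning: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DTS-based patient positioning: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dtsalign)
```

## The problem

Before each radiotherapy fraction the patient must be repositioned to the
planned geometry. Cone-beam CT does this with a full 200° rotation
(hundreds of kV projections); digital tomosynthesis (DTS) needs only two
narrow arcs. The price is anisotropic resolution: a DTS stack reconstructed
from an arc centered at gantry 0° is sharp in the coronal focal plane but
blurred along the depth (VRT) axis, so a single stack localizes structures
in two axes only. The workflow therefore uses **two sessions**: a coronal
pair of stacks (arc at 0°) yields the lateral (LAT) and longitudinal (LNG)
shifts, a sagittal pair (arc at 270°) yields LNG and vertical (VRT), and
the two LNG estimates are averaged. Each session registers an *onboard* DTS
(ODTS, reconstructed from treatment-room cone-beam projections) against a
*reference* DTS (RDTS, reconstructed from DRRs of the planning CT under the
identical acquisition geometry).

## Geometry model

Patient axes are LAT (x), LNG (y), VRT (z), origin at the isocenter,
right-handed. At gantry 0° the source is anterior at `(0, 0, +SAD)` and the
central ray points along −VRT; rotation is counterclockwise seen from the
couch foot, so the standard full-fan sweep runs from 20° down to −180°.
The detector u axis lies in the rotation plane (along +LAT at 0°), v is
parallel to LNG. Defaults: SAD 1000 mm, SDD 1500 mm (typical C-arm
on-board imager values; the scan protocol itself does not fix them). With
the standard 0.776 mm detector pixel this puts the detector sampling at
~0.517 mm at the isocenter, consistent with the 0.5 mm nominal DTS grid.

**Angular grid.** A full fan of `n` projections over `range` degrees has
nominal spacing `range/n` (200/375 = 0.533°, printed as 0.53°). Views sit
at the *centers* of the angular bins, `start − (i − 1/2) · spacing`. This
convention was chosen deliberately: it is the only uniform grid under which
the closed-window arc selection (keep angles with circular distance to the
arc center ≤ arc/2) reproduces the protocol arithmetic — 37 views in a 20°
arc, 75 in a 40° arc — while remaining identical to brute-force window
enumeration. A start-anchored grid (first view exactly at 20°) yields 38
and 76. The degenerate consequence is that a single-view "scan" of a 1°
range sits at the arc midpoint (−0.5°), not at the start angle.

## Phantoms

The physical validation phantoms are replaced by deterministic digital
ones:

* **Cube**: 50 mm of water-equivalent material (μ = 0.02 mm⁻¹) in air,
  centered on the isocenter. Edge voxels are weighted by the occupied
  volume fraction per axis, so edge profiles cross 50% exactly at the face
  position and total attenuation equals μ·edge³ analytically.
* **Pelvis**: an elliptical soft-tissue body (μ = 0.018 mm⁻¹, default
  semi-axes 52 × 38 mm) containing bilateral "hip" bone cylinders, a
  posterior "sacrum" column and superior "iliac wing" extensions
  (μ = 0.048 mm⁻¹, ≈60–80 keV contrast), plus an anterior air cavity. The
  wing extensions exist to break translation ambiguity along LNG — an
  infinite uniform cylinder would make the longitudinal NCC degenerate.
  The attenuation values are plausible but not calibrated; every
  validation metric in the package depends only on relative contrast.

What the generator does **not** emulate: anthropomorphic texture, scatter,
beam hardening, detector noise and blur, respiratory motion, couch
attenuation. A green registration test therefore establishes the
*geometric* fidelity of the reconstruction/registration chain, not
robustness to clinical image degradation (physical phantom studies
share this limitation: cube and pelvis phantoms register on clean bony
structure).

Rigid shifts (`shift_volume()`) use trilinear resampling, matching the
interpolators used everywhere else. Two resampling passes bound the
round-trip error at a binary edge by ~0.6 of the dynamic range (confined
to the one-voxel edge shell; total attenuation is conserved to <0.1%).

## DRR projection

Each detector pixel integrates attenuation along the ray from the source
through the pixel center: fixed-step sampling with trilinear
interpolation, step = min(voxel)/2, integral scaled by the actual step
length. That step bounds the slab-integral error well below 1% (verified
against the analytic 50 mm chord). Sampling outside the voxel-center hull
returns 0; phantoms keep background margins so this never clips content.

Two engines share this contract exactly: `drr_oracle()` is a pure-R
per-ray loop (the auditable reference), `drr_fast()` batches all pixels
and angles in compiled code. Because the mathematical scheme is identical,
their differences are floating-point only; a CPU-vs-GPU
engine pair would differ additionally through texture-memory
interpolation, which we deliberately do not emulate — the acceptance correlations
(≥ 0.99) and subtraction means (≤ 0.3%/0.4%) are bounds, and exact
agreement satisfies them.

## DTS reconstruction

Per view: (1) logarithm conversion `q = ln(I₀/I)` — applied only to
intensity-domain input, since DRRs are already line integrals (both
conventions exist in practice; the domain tag records the choice);
(2) cosine pre-weight `SAD/√(SAD² + u² + v²)` with (u, v) rescaled to the
isocenter plane; (3) row-wise ramp filtering via FFT; then back-projection
with bilinear detector interpolation, weight `SAD²/U²` (U = source-voxel
distance along the central-ray direction) and `Δβ` scaling. The oracle
engine loops in R plane by plane; the fast engine is compiled. Both
produce identical contracts, and reconstruction is linear in the
projections (checked to 1e−6 of scale).

**Filter.** Ram-Lak `|f|` response with an optional Hamming window at the
detector Nyquist frequency; Hamming is the default (a bare ramp amplifies
noise — with noiseless synthetic input the choice is cosmetic, but the
default matches practice). Rows are padded to the next power of two
≥ 2·nu. Padding is by **edge replication, not zeros**: the DC bin of the
frequency response is exactly zero, and edge replication is what makes
that DC kill effective for rows that do not decay to zero at the detector
border (a constant row becomes a constant periodic signal and filters to
exactly zero; zero-padding would instead produce an O(10⁻¹) truncation
response at the row ends). For objects fully inside the field of view the
borders are ≈ 0 and the two paddings coincide.

**Grids.** Coronal stacks are LAT×LNG planes stacked along VRT, sagittal
stacks LNG×VRT stacked along LAT (slice thickness is the stacking-axis
voxel size). Default in-plane pixel 0.5 mm, slice 1 mm. DTS values are
signed: ramp filtering produces negative ringing, and the `voxel_volume`
container relaxes its attenuation-positivity invariant for reconstructed
stacks.

**Midline weighting and edge-length measurement.** The `SAD²/U²` weight
concentrates intensity near the vertical midline of the plane — an
emergent property of the weighting, not separately engineered. More
important for measurement: a thick object reconstructed from a narrow arc
carries off-plane blur that forms negative lobes just outside its faces
along the filtered (in-rotation-plane) axis, with the profile recovering
toward background only ~10–25 mm further out. The 50%-of-step edge
criterion needs genuine background in the profile, so in-plane DTS grids
for the cube study are ≥ 100 mm along the filtered axis (clinical DTS
grids are 256 mm wide, far wider than a 50 mm cube; a 64 mm desk grid
clips the lobes and biases lengths by ~+0.7 mm). Plateau and background are medians (central 50% of the object
extent; outside a 5%-width margin), and edges are located by linear
interpolation at 50% of the local step — robust to the background haze and
exact for symmetric blur.

**Half-fan stitching** takes each input volume in its exclusive lateral
half and cross-fades linearly over a 20 mm band (default). The full-fan
validation protocol never exercises it, so it is covered by property tests
(identity, exact union at zero overlap, 0.5 weight at the band midline)
rather than by protocol numbers.

## Registration

Manual registration in vendor software is replaced by a deterministic
surrogate: the central 5 planes (conspicuity is best near the focal plane)
are averaged into one focal image per stack; exhaustive integer-pixel
normalized cross-correlation within a ±10 mm search radius; parabolic
refinement of the peak, per axis, clamped to ±half a pixel; ties broken
toward the smaller-magnitude shift. The returned shift is the displacement
of the moving (reference) content relative to the fixed (onboard) content,
i.e. the couch correction. The acceptance surface is a bound
(≤ 0.5 mm), not operator agreement, so an automated matcher is a valid
substitute; the zero-displacement "operator noise floor" analogue is
self-registration, asserted at ≤ 0.1 mm. Rotations are not estimated; the workflow reports translations only.

## Numerical choices and degenerate inputs

* Ray step min(voxel)/2; trilinear everywhere (volume sampling, shifting)
  and bilinear on the detector — matching forward and backward models.
* Circular angle arithmetic on [0°, 360°) for all window tests; 270° ≡ −90°.
* Flood level I₀ = 1 for synthetic acquisitions; only ratios survive the
  log conversion.
* Constant focal images, zero-dynamic-range references, flat profiles,
  ambiguous edge counts (≠ 2 crossings), empty arc selections and
  non-positive intensities all raise errors naming the condition.
* Engine determinism: repeated runs are bit-identical; the phantoms are
  deterministic functions of their specs.

## Scales used by the tests and the acceptance report

The clinical protocol uses 512×384 projections, 512×512×256 stacks and
375-view scans. The acceptance script runs a reduced "desk scale" (128³
CT at 1 mm, 256×192 detector, 0.5 mm DTS grids, ≤150 views; the
registration study uses a 150-view fan and a 192×144 detector to stay
inside its runtime budget), and the test suite reduces further. Asserted
tolerances are never relaxed with scale. The registration grid (two
phantoms × 1/3/5 mm × three axes × 20/40/60° arcs) and the geometric grid
(20–80° arcs, five measurement lines per length) mirror the clinical validation
protocols; individual table-cell values from physical experiments are
operator- and hardware-dependent and are replaced by their stated bounds.

## Known limitations

* No scatter, beam hardening, bowtie filter, detector lag/glare or noise
  modeling (optional Poisson noise is out of scope); engine equivalence is
  consequently near-exact rather than merely high.
* Half-fan mode is stitched but validated by properties only (the
  validation protocol is full-fan).
* Transversal DTS views are reconstructed implicitly (the stacks are full
  3D volumes) but no transversal-view metric exists; the depth axis of a
  single stack is genuinely poorly localized, which is the reason for the
  two-session design.
* DICOM I/O is not implemented (no suitable R dependency in the target
  environment); volumes and projection sets use a documented raw
  float32 + JSON format instead.
* The CLI covers the scripted workflow (drr / dts / register / simulate /
  validate geometric); there is no GUI.
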