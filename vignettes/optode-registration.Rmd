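---
title: "Photogrammetric optode registration: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photogrammetric optode registration: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optodereg)
```

## The registration model

A photogrammetric reconstruction of a capped head lives in an arbitrary
frame: unknown origin, orientation, and — because structure-from-motion is
scale-blind — unknown global scale. `optodereg` carries digitized optode
positions from that frame into MNI space with a 12-parameter affine
`p ↦ A p + b`, estimated from the five cranial fiducials that both frames
share: nasion, inion, Cz and the two preauricular points. (Some sources
write "periarticular"; standard 10-20 usage is *preauricular*, which is the
vocabulary used throughout this package.)

With five correspondences the least-squares problem has 15 equations and 12
unknowns. All landmarks are weighted equally — nothing in the workflow
justifies a weighting — and the fit is plain OLS on the stacked linear
system. Design consequences:

* **Non-coplanarity is a hard precondition.** Five coplanar landmarks leave
  the out-of-plane column of `A` unconstrained, so `landmark_set()` rejects
  rank-deficient configurations at construction (SVD rank of the centred
  coordinates, relative tolerance 1e-7).
* **Scale is absorbed, by construction.** Multiplying every photo-frame
  coordinate by any `s > 0` changes the fitted `A` by `1/s` and leaves the
  registered MNI positions untouched; this is tested as an invariant.
* **Mirrored reconstructions are flagged, not rejected.** A photogrammetry
  pipeline can deliver a reflected mesh; the fit then succeeds with
  `det A < 0` and a warning, because silently "fixing" a reflection would
  hide a real acquisition failure.
* **Residual threshold.** `fit_rms > 10` mm warns about landmark picking;
  10 mm is about a third of the 28 mm optode separation, past which
  channel-level anatomy becomes unreliable.

## Scalp-to-cortex projection and channels

Channel anatomy is defined on the cortical surface, so scalp positions are
pulled onto a cortex mesh. The default is exact closest-point-on-triangle
over all triangles (vectorized over faces, ties broken by lowest face
index), with a ray-to-centroid alternative that intersects the segment from
the point to the mesh centroid; the method used is recorded in the output's
metadata because the two rules genuinely differ on concave meshes. The
closest-point route is verified in the tests against an independent
brute-force oracle (per-triangle candidate enumeration: interior foot,
clamped edges, vertices).

A data channel is a source–detector pair at the cap's nominal separation
(default 28 mm) within a relative tolerance (default ±20 %); its location
is the pair midpoint. Two orders of operation are defensible for the
cortical midpoint and both are implemented:

* `"scalp-midpoint"` (default): average the scalp endpoints, then project
  the mean onto the cortex — this matches the definition of a channel as
  the midpoint *between the optodes*;
* `"projected-endpoints"`: project endpoints first, average, re-project.

On a convex cortex the two differ by well under a millimetre at 28 mm
separations; the flag exists for sensitivity analyses, not because the
choice is consequential at cap scale. Channel numbering is deterministic
(lexicographic in source then detector id); a measured cap's own numbering
can be imposed via a pairing override table, since real cap numbering is a
design artifact no algorithm can recover.

Separations are computed in whatever frame pairing is run in. Note that
MNI-frame separations differ from tape-measure cap separations by the
affine's scale; pairing the *registered* optodes of a well-fitted cap still
lands inside the ±20 % band.

## The validation metric suite

Given two registrations of the same probe — typically photo-based (POR)
versus MRI-based — the package computes:

* **Displacement** per id: per-axis absolute differences and the Euclidean
  `d`. Report rounding mirrors the conventions of published comparison
  tables (coordinates to integers, distances to one decimal); raw values
  are kept.
* **Composite standard deviation** across participants:
  `Csd = √(sdx² + sdy² + sdz²)` with the sample (n−1) denominator — it
  estimates between-participant variability from a cohort sample. `Csd²`
  is the trace of the coordinate covariance, hence rotation-invariant,
  which the tests exploit as a property check.
* **Channel overlap**: each channel samples a sphere of radius `R = 20` mm;
  the overlap of two estimates at separation `d` is the two-sphere lens
  volume over one sphere's volume, `(4R + d)(2R − d)²/(16R³)` for
  `d ≤ 2R`, else 0. Normalizing by one sphere (not the union) makes
  identical positions score exactly 1, matching the percentage framing
  used in the field. The closed form is validated against a Monte-Carlo
  hit-count oracle.
* **Region estimation**: `n = 10,000` points drawn uniformly in a ball of
  `r = 10` mm about each channel, labelled through a parcellation atlas,
  tabulated as fractions. The "bounding box" of the sampling process is
  the ball itself (the defining equation is a sphere). Sampling uses
  isotropic Gaussian directions with inverse-CDF radii (`r·u^{1/3}`), not
  rejection, so a seed fixes the exact draw count and the table is
  bit-reproducible. Nearest-voxel lookup only — labels are categorical;
  fractional indices exactly on a voxel boundary round half away from the
  grid centre, a fixed deterministic tie rule. No threshold for "detected"
  is standard, so the default `min_fraction = 0.05` is explicit in the
  report metadata. Background (label 0) stays in the denominator by
  default; `normalize = "labeled"` renormalizes over brain samples only,
  with the background row always reported against all samples. Both
  normalizations are offered because published tabulations rarely state
  which they used.

## The synthetic world

The generator exists so that every stage has a testable ground truth
without downloading template meshes or atlas databases.

* **Head**: a subdivided-icosahedron ellipsoid, semi-axes (80, 98, 80) mm.
  These were chosen once against the only scale anchor a cohort description
  gives — an adult head circumference of about 56 cm: the equatorial
  perimeter is 56.1 cm and the nasion-to-inion arc over the vertex is
  280 mm, half the band circumference to within 0.4 %. (A rounder
  90×110×90 mm ellipsoid would imply a 63 cm head and break the arc
  anchor by 12 %.) The cortex is the scalp shrunk by 0.8. Fiducials sit at
  the ellipsoid poles, which guarantees non-coplanarity.
* **Cap**: a 3-row hexagonal lattice (28 mm spacing, row height
  `28·√3/2`) with a frozen 6-source/12-detector role pattern chosen so
  that exactly 23 source–detector pairs sit at lattice distance 28 mm,
  while the next-nearest pair is at 48.5 mm. The lattice is wrapped onto
  the left-lateral scalp by mapping its u axis to azimuth (arc-exact on
  the centre row, same angles on the flanking rows) and its v axis to
  meridian arc length, then snapping every optode to the scalp mesh. The
  wrap distorts distances by a few percent at most — realized separations
  on the default head are 23.9–29.3 mm — so the 23-channel count is robust
  inside the ±20 % pairing band.
* **Sessions**: per participant, the true placement is the cap plus
  *tangent-plane* jitter re-snapped to the scalp (caps slide on heads;
  they do not float off them). The MRI session adds a supine shift
  (default (0, +5, +5) mm: forward and up) before re-snapping; the
  post-MRI photo session retains `post_shift_fraction` (default 0.5) of
  it, modelling a cap that settles back only partially — the recovery
  fraction is a free choice, fixed once, since no measurement constrains
  it. Photo observations are the true MNI positions mapped through the
  inverse of a ground-truth affine (default: scale 1.35 with a small
  rotation, standing in for the arbitrary photo frame) plus isotropic
  per-axis noise (default 1 mm, a digitization-level error); MRI
  observations are MNI positions plus the same noise.
* **Atlases**: half-space, nested-shell and Voronoi label volumes (default
  32³ voxels at 4 mm) whose region volumes are analytic for the first two,
  giving closed-form targets for the Monte-Carlo estimator.

### What a green test does and does not establish

The tangent-plane jitter model implies the composite standard deviation
concentrates ~`√2·σ` rather than `√3·σ` — the surface constraint removes
the normal component — and the tests assert that band. Because the scalp is
curved, a nominal shift vector of magnitude `2R = 40` mm does **not** drive
every channel 40 mm along the surface (snapping removes the radial
component of the shift where it is not tangential), so session-level mean
overlap at a 40 mm nominal shift is small but not zero; the exact-zero
statement holds for pure 40 mm displacement of the channel centres, and the
tests check both forms separately. More generally the synthetic world has
no skull, no hair-induced cap deformation, no anatomy-linked between-
participant variability, and an ellipsoidal (not template-derived) cortex:
green tests establish the correctness of the *algorithms* under a stated
geometry, not the field accuracy of any acquisition protocol.

## Numerical choices

* Closest-point ties (a point equidistant from several triangles) go to the
  lowest face index: the published scalp-projection routines do not
  document their rule, so this one is fixed and recorded.
* Mesh degeneracy: faces with repeated vertices or area ≤ 1e-12 are format
  errors at construction; quads are rejected rather than triangulated.
* The affine fit uses QR (`qr.solve`) rather than normal equations.
* `fit_rms` is the root of the *mean squared Euclidean* landmark residual
  (sum of squared residual components over 5, not over 15).
* Sphere-overlap continuity: the closed form vanishes quadratically at
  `d = 2R`, and the implementation returns exactly 0 beyond.
* NIfTI I/O supports sform and quaternion qform orientations,
  little/big-endian, the common integer dtypes and float volumes with
  slope/intercept scaling; label volumes are written as int32 with an
  sform. PLY is read in ASCII and both binary endiannesses; writers emit
  ASCII with `%.9g` precision, which round-trips coordinates well within
  the 1e-6 mm I/O tolerance.

## Known limitations

* The five-landmark affine cannot correct nonlinear head-shape differences
  against a template; no surface-based (ICP-style) refinement is provided.
* The ray-to-centroid projection method can miss on strongly non-convex
  meshes; failures are per-point records, not run failures.
* Published headline aggregates of the comparison study this package's
  metric suite mirrors (mean Csd ≈ 10.8 mm, mean overlap 46–65 %) depend on
  per-participant coordinates that were never published; they are not
  reproduction targets, and the bundled reference tables cover exactly what
  was printed (group-mean coordinates and their differences).
* CLI figures: the package produces tables, not plots; displacement and
  overlap bar charts are one `barplot()` away from the report CSVs.
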