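---
title: "Static morphometry of the marsupial stifle: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static morphometry of the marsupial stifle: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stiflemorph)
```

## The measurement problem

The marsupial stifle lacks an ossified patella; in its place a
fibrocartilaginous pad rides in the quadriceps insertion tendon, and the
extensor mechanism inserts on a prominently projecting tibial tuberosity.
The joint's static mechanical profile — how long its segments are, how the
extensor tendon's line of action sits relative to the condylar rotation
axis, how much quadriceps is available to load it — is the natural
boundary-condition set for any dynamic model, and it was originally
assembled by hand in CAD software from CT/MRI-derived surface models.
`stiflemorph` turns those manual constructions into deterministic,
testable geometry so the same profile can be recomputed from any
landmark/mesh/mask triplet.

All positions are in millimetres; all angles cross module boundaries in
degrees. Reported tables are rounded to one decimal, half away from zero,
only at serialisation.

## The anatomical frame

The original measurements were read off in "sagittal", "coronal" and
"axial" views whose orientation the source protocol does not pin down.
We make the frame explicit and landmark-derived (`build_frame()`):

* **proximal** — unit vector from the knee centre to the proximal femoral
  midshaft;
* **lateral** — the inter-sulcus (collateral-ligament attachment)
  direction orthogonalised against proximal, sign-flipped for left limbs
  so both sides share one canonical code path;
* **anterior** — proximal × lateral (right-handed triad).

Sagittal, coronal and axial planes are the planes normal to lateral,
anterior and proximal respectively. This is one defensible realisation of
the original views, not a reconstruction of them; all in-plane distances
(`in_plane_distance()`) are ordinary orthogonal projections. Left limbs
are canonicalised inside `build_frame()` rather than by mirroring
coordinates at load time — one mechanism suffices, and the landmark files
stay faithful to the scanner frame.

## The six procedures

**Segment lengths.** Femoral length is the sagittal-plane distance from
greater trochanter to intercondylar notch; tibial length the
coronal-plane distance from tibial plateau to lateral malleolus.

**Flexion angle.** The three midshaft landmarks (femoral midshaft, knee
centre, tibial midshaft) are projected onto the sagittal plane and the
angle at the knee vertex computed with the law of cosines
(`angle_from_sides()`); full extension is 180°. The projected-triangle
construction mirrors the manual protocol; a direct normalised-dot-product
angle serves as its independent oracle in the tests. Cosines may
overshoot [−1, 1] by at most 1e−9 before an input is rejected as an
invalid triangle (floating-point safety without masking bad data).

**Moment arm.** The transepicondylar axis joins the medial and lateral
collateral-ligament sulci. The extensor line of action is obtained by
least-squares plane fit (smallest principal component as normal, oriented
anterior) through ≥3 extensor-path points, taking the in-plane principal
direction oriented proximal-positive. The moment arm is the
common-perpendicular (skew-line) distance between the two lines —
implementing the protocol's "perpendicular distance" literally and in 3D,
since whether the original was read in a projection view is unstated. The
torque-effective lever arm |((p−a)×f̂)·â| is reported alongside as a
diagnostic (`moment_arm_torque()`); the two coincide when the line of
action is orthogonal to the axis in projection.

**Plateau/tuberosity planes.** Three parallel planes with the anterior
normal are placed at the most anterior tuberosity point (P1), the
anterior-cortex reference landmark (P2) and the posteriormost plateau
point (P3). P2 is a user-supplied landmark, not mesh-derived: the
protocol does not define the cortex plane algorithmically, and a landmark
keeps the construction auditable. P1 and P3 come from extreme-vertex
searches restricted to landmark-seeded geodesic submeshes (default
radius 15 mm, graph distance along mesh edges) so a whole-bone search
cannot wander onto the malleolus or condyles. Extreme-point ties within
1e−9 mm resolve to the lowest vertex index — deterministic and
mesh-order reproducible. d1 = |P1P2| and d2 = |P2P3| give the TP:TT
ratio d2/d1 and the projection index 100·d1/TL.

*On the index scale:* the published index values (~15–18) are not jointly
consistent with index = 100·d1/TL and ratio ≈ 1.8 for any plausible d1 on
a 400 mm tibia; the original normalisation cannot be recovered from the
text. We implement the ×100 convention (which matches the human
convention the index is compared against) and always report raw d1 and
d2, so any alternative rescaling is recomputable. Synthetic phantoms
therefore score ~5 on this index while reproducing every other published
median — a deliberate, documented divergence rather than a calibration
target.

**Muscle areas.** Cross-sections are taken in coronal slices. The slab is
the 10 slices centred on the slice containing the midpoint of greater
trochanter and knee centre (mid-femur level); with an even count the
extra slice falls on the increasing-index side, a deterministic rule the
protocol's "approximately 10 slices" leaves open. A labelled voxel
contributes its full in-plane area (count × pixel area, mm²→cm²); there
is no partial-volume weighting, matching manual-segmentation counting —
a known limitation quantified below. QCA sums RF, VL, VI and VM (the
protocol's "WM" is read as VM: the dissection tables and text discuss
VM); sartorius is segmentable but excluded by definition. QCA·FL/1000
(cm²·m) approximates quadriceps volume.

**Pennation.** Aponeurosis and fascicle lines are intersected at their
closest-approach midpoint, unit segments laid along each direction, the
triangle closed and the law of cosines applied; the acute angle is
reported, since pennation is conventionally ≤90° and the construction is
direction-sign ambiguous. Parallel lines return 0, not an error.

## The synthetic phantom

`generate_limb()` builds a primitive-based phantom — capsule femoral
shaft, condylar spheres, plateau slab, tuberosity wedge, planar extensor
strap, ellipsoidal muscle bellies — because analytic ground truth, not
anatomical realism, is the point. Each parameter maps to a closed-form
metric value: the strap is constructed at an exact perpendicular offset
from the inter-sulcus axis (the true moment arm), the wedge apex sits
exactly `tt_projection` anterior of the cortex plane, and belly
cross-sections are exact ellipse sections averaged over the known slab
positions. Defaults are tuned to the published medians (FL 200.7, TL
400.4, flexion 74.1°, moment arm 28.9 mm, ratio 1.8, pennation
27.4°/28.6°, QCA ≈ 84 cm²); `random_limb_spec()` brackets the published
spread (moment-arm offsets 20–40 mm, flexion 65–90°, etc.) with a seeded
random pose per limb.

One placement choice deserves emphasis. A knee flexed at ~74° cannot
present both bones optimally to a single frame: a straight tibia lying in
the sagittal flexion plane is foreshortened by cos(flexion) in the
frame's coronal plane, whereas the original lengths were read in
bone-aligned CAD views. The phantom therefore decouples the landmark
clusters: the tibial-midshaft landmark carries the flexion angle in the
sagittal plane, while the plateau and malleolus landmarks are separated
by exactly TL within the coronal plane. Each measurement procedure is
exercised exactly as specified; the phantom is a measurement phantom, not
a rigid-body skeleton.

All randomness — pose, landmark noise — flows from the spec seed, so
equal seeds give byte-identical meshes, masks and landmarks. The mask
grid's anterior corner is offset by half a slice so the slab-centre
computation never lands on a voxel boundary. Mask spacing defaults to
1 × 2.5 × 1 mm (lateral × anterior × proximal), echoing thick coronal
acquisition slices with finer in-plane resolution; mesh edge targets
default to 1 mm.

## What validation shows — and what it cannot

Noiseless recovery on 50 random phantoms is exact to machine precision
for the nine purely geometric metrics and within ~0.7% for QCA (and hence
QCA·FL), whose only error source is voxel counting: an ellipse of ~20 cm²
at 1 mm² pixels carries a boundary error well under the 2% recovery
criterion. Under 1 mm isotropic landmark noise — a plausible manual
placement error — the moment arm is recovered with ≈2% mean absolute
error and <0.1 mm bias over 50 limbs; individual limbs can err by up to
~9%, dominated by the axis direction wobble from two sulci only ~60 mm
apart. That spread is a property of the measurement itself and is the
main sensitivity result for anyone replicating the protocol manually.

Because the phantom realises each metric by construction, passing these
tests demonstrates that the pipeline computes the stated geometry
correctly and robustly; it does not certify performance on real imaging
data, where segmentation quality, mesh smoothing artefacts, genuinely
ambiguous landmarks and partial-volume effects add error sources the
generator deliberately omits (no cortical/trabecular structure, no
intensity simulation, no segmentation step).

## Numerical conventions and degenerate inputs

* Direction/normal vectors are unit length within 1e−9; zero vectors are
  degenerate-direction errors.
* Parallel-line and parallel-plane tests use a 1e−6 rad angular
  tolerance; parallel lines fall back to point-to-line distance,
  non-parallel planes are an error.
* Degenerate (flat) triangles are permitted in the law of cosines;
  violations beyond the 1e−9 cosine clamp are invalid-triangle errors.
* STL vertices are deduplicated within 1e−6 mm on read; binary STL is
  float32, so round-trip fidelity is quantisation-limited (~1e−3 mm at
  limb scale) while the 9-significant-digit ASCII dialect round-trips
  within 1e−6 mm.
* All tolerances live in `morph_config()`, not at call sites.

Problem sizes in the shipped tests and scripts — 50-phantom recovery
runs, 1 mm default mesh edges, the default mask grid of roughly
105 × 27 × 220 voxels — keep a full validation pass in the low minutes on
one CPU while leaving every geometric check exact.

## Known limitations

* The projection-index scale divergence described above.
* The common anatomical frame is one realisation of the original CAD
  views; real datasets whose plateau–malleolus axis is strongly
  out-of-coronal will foreshorten TL relative to a bone-aligned reading.
* Voxel counting without partial-volume weighting biases areas slightly
  low at coarse spacing (≈0.4% at the default grid).
* The published per-limb table is reproduced for its median row; its FL
  and moment-arm range cells derive from unrounded source data that was
  never published and cannot be reproduced from the printed rows (19.3
  vs 20.1 and 3.7 vs 3.8) — the recomputed values are reported.
* Dynamic (through-range) moment arms, cartilage/fat-pad geometry and
  ligament modelling are out of scope.
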