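---
title: "Phantom-validated condylar morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-validated condylar morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Volumetric follow-up of the mandibular condyle — for example to monitor
condylar growth under orthodontic treatment — is normally done on cone-beam
CT (CBCT), where cortical bone is bright and well resolved but every scan
costs an X-ray dose. High-field MRI is radiation-free, but cortical bone is
dark and its boundary must be inferred from the surrounding soft tissue, so
segmentations from MRI systematically *underestimate* bony surface and
volume. A semiautomatic measurement chain for comparing the two modalities
consists of: threshold segmentation of the condylar head, surface
extraction to a triangle mesh, rigid registration of every replicate model
onto a common reference, isolation of the condylar head by two
landmark-defined cutting planes, surface/volume/cloud-distance
morphometry, and replicate-agreement statistics.

`condylometry` implements that chain end to end and couples it to a
synthetic condyle phantom whose geometry (and therefore true surface `S`
and volume `V`) is known, so that every stage can be verified
quantitatively without patient scans. None of the patient-specific numbers
of any particular clinical data set are reproducible without the original
DICOM series; what is reproducible — and what the test suite and
`scripts/acceptance.R` check — is (a) the arithmetic linking per-group
summaries to pooled operator summaries, and (b) the behaviour of every
pipeline stage against constructed ground truth.

## The phantom

`phantom_spec()` describes a superellipsoid head (the default exponent 2
is an ellipsoid, for which `V = 4/3 π abc` is closed-form) fused by a
smooth union (log-sum-exp blend, scale `blend` = 0.8 mm) to a cylindrical
neck stump. Default semi-axes 8.5 × 6.9 × 4.8 mm, neck radius 3.4 mm and
length 5 mm give a generated mesh volume of ≈ 1426 mm³, inside the range
spanned by published adult condylar volumes (≈ 1.0–1.7 × 10³ mm³). A
medio-lateral skew (`asymmetry` = 0.12) breaks the head's mirror symmetry
so that principal-axes frames are well defined; the left condyle is the
exact mirror image of the right about the mid-sagittal plane, offset
laterally by ±40 mm. Meshes are extracted from the implicit solid by
marching tetrahedra (below) at a 0.25 mm grid pitch.

For solids with a neck the package reports a *reference* `S` and `V`
computed from a fine-pitch (0.15 mm) extraction instead of a closed form;
for the neckless ellipsoid and sphere the closed forms are used. The
sphere-degenerate phantom (`semi_axes = rep(6.2035, 3)`, no neck) has
`V ≈ 1000 mm³` and anchors the absolute-accuracy tests.

## Imaging models

`modality_model()` renders a watertight mesh into an intensity volume:

* **cbct_like** — 0.4 mm isotropic voxels, bone bright (bone = 1000,
  background = 0, arbitrary units), no boundary bias.
* **mri_like** — 0.55 × 0.55 × 0.5 mm voxels, bone dark (bands inverted),
  and an inward `erosion_bias` (default 0.3 mm) that shifts the rendered
  bone boundary inside the true surface — the mechanism by which the
  package emulates the systematic MRI underestimation of `S` and `V`. To
  first order an inward offset of δ removes a shell of volume δ·S, which
  is exactly what the end-to-end bias-recovery check measures.

Both models add Gaussian intensity noise (SD 30 AU) and Gaussian *boundary
jitter* (SD 0.05 mm CBCT-like, 0.12 mm MRI-like) applied through the
signed distance to the surface, and grade intensities linearly across an
`edge_width` ramp (0.4 / 0.6 mm) emulating the scanner point-spread blur —
without the ramp, binary intensities would make the choice of threshold
irrelevant and operator emulation meaningless. Interior/exterior
classification of voxel centres uses a z-column ray-parity test, which is
exact for watertight meshes and far cheaper than per-voxel winding
numbers; the erosion and jitter then act on the signed distance computed
only inside a narrow band around the surface. In the replicate study the
left condyle's boundary jitter is doubled (`left_noise_factor = 2`),
emulating the poorer image reconstruction reported for left-side scans;
the factor is a free configuration parameter, not an estimate. Note one
deliberate consequence visible in noisy runs: strong boundary jitter
*inflates* the stair-cased surface estimate, so on the noisy left side the
`S` bias can turn positive even while `V` stays biased low — under low
noise both `S` and `V` are underestimated, as expected from the erosion
mechanism.

What the phantom does **not** emulate: trabecular texture, MRI sequence
physics, motion or susceptibility artifacts, and anatomical neighbours of
the condyle (fossa, disc). Passing tests therefore demonstrate the
correctness of the measurement chain, not the clinical segmentability of
real TMJ scans.

## Segmentation

The chain follows the standard manual workflow but with every interactive
step replaced by a deterministic equivalent: origin alignment
(`align_origin`), dual-threshold band selection (`threshold_bone`; high
band for bone-bright, low band for bone-dark — `default_bone_band()`
returns the 500 AU mid-band for phantom volumes, and thresholds for real
data are operator-chosen configuration, with no claim to match any
particular study's settings), seeded connected-component retention
standing in for the operator's brush (`seeded_select`, 26-connectivity),
cavity filling (`fill_holes`, 6-connected background — the standard
complementary connectivity pair), and iso-surface extraction
(`extract_mesh`).

Surface extraction uses **marching tetrahedra** (each grid cube split
into six tetrahedra around a fixed diagonal) at iso-level 0.5 of the
binary mask, with one layer of background padding so surfaces are always
closed. The tetrahedral variant was chosen over classic 256-case marching
cubes because it has no ambiguous face configurations: the output is
guaranteed closed and manifold, which the divergence-theorem volume
requires. Grid values exactly at the iso level are welded to per-corner
vertices so the surface stays manifold. Conventions worth knowing: an
isolated voxel yields a closed surface of half the voxel cell volume, and
on a 10 mm sphere mask at 0.4 mm spacing the extracted volume agrees with
an independent marching-cubes implementation to < 0.1% and with the
analytic volume to < 0.5%. No smoothing is applied by default, keeping
volumes reproducible; the stair-cased surface slightly *over*-estimates
smooth-surface area (≈ +8% at 0.4 mm), which is why surface comparisons
in the study are made between identically processed models.

## Registration

`horn_align()` is the closed-form least-squares rigid alignment of
matched point sets (quaternion eigen-decomposition of the
cross-covariance; no scale, reflections excluded by construction). It is
exact on noiseless correspondences and anchors the pre-alignment.

The semiautomatic chain (`register_meshes()`) replaces the operator's
manually picked correspondence points with a pose-invariant construction:
each mesh is put into its principal-axes canonical frame
(`canonical_frame()`, covariance eigenvectors with signs fixed by third
moments), and the landmark triad is the prominent vertex along the
canonical superior axis, the centroid, and the prominent vertex along the
first principal axis. A naive pick along the *world* axes is not
pose-invariant and fails for large perturbations, which is why the
canonical frame is used. Horn alignment of the triads gives the initial
pose; `select_region()` (Euclidean ball, default radius 12 mm) extracts
the condylar patch around the prominent vertex; and `icp_register()`
refines the pose by point-to-surface ICP — each moving patch point is
matched to its closest point on the reference *surface* (exact
point-to-triangle, uniform-grid accelerated), then Horn-aligned, until
the RMS change falls below 1e-7 mm or 300 iterations. Patch-to-patch
point matching was measurably biased at patch boundaries; matching
against the full reference surface removes that bias. Moving patches are
deterministically thinned to 5000 points (2500 in the batch experiments)
— pose accuracy is limited by noise bias, not point count, and thinning
keeps a 20-perturbation recovery experiment under two minutes. The
per-iteration RMS trace is returned and is non-increasing, the classic
ICP monotonicity property.

Under the study conditions (perturbations ≤ 15°, ≤ 10 mm, vertex noise
0.1 mm) the chain recovers poses to ≈ 0.1–0.4° and < 0.05 mm at the
condyle. Pose translation error is reported *anchored at the object
centroid* (`pose_error()`): the condyle sits ~40 mm from the world
origin, so quoting the translation component of the error transform at
the origin would double-count rotation error through the lever arm.

## Condylar head isolation

`build_cut_planes()` constructs plane A through the anterior nasal spine
(ANS) and the two sigmoid notch landmarks, and plane B through the two
notch points with its normal orthogonal to plane A's normal — two exactly
orthogonal planes determined entirely by the three landmarks. Both
normals are sign-canonicalised toward superior so the plane set is
invariant to swapping the left/right notch arguments. `cut_head()` clips
the mesh by each plane, keeping the side containing the most prominent
superior vertex (the head side), and closes every cut loop with a planar
ear-clipped cap so watertightness is preserved; the added cap area is
reported separately in the `cap_area` attribute so its contribution to
`S` is auditable. Cut loops may pinch at vertices lying exactly in the
plane; loop chaining therefore walks directed boundary edges
Eulerian-style rather than assuming one successor per vertex. For the
phantom anatomy plane A performs the head/neck cut (z = −3.5 mm in the
phantom frame) and plane B, placed posterior to the condyle by the
landmark layout, does not intersect it — the phantom has no ramus to
trim. A deliberately missing plane produces a warning and passes the mesh
through unchanged, and a cut that splits the mesh keeps the largest
component by volume, again with a warning.

## Morphometry and statistics

`surface_area()` sums triangle areas; `mesh_volume()` uses the divergence
theorem and refuses non-watertight input, naming the open edges.
`cloud_distance()` computes, for every moving-mesh vertex, the exact
distance to the nearest reference surface point; signed mode (default)
marks points inside the reference negative — underestimation — using a
ray-parity interiority test. Point-to-surface was chosen over strict
vertex-to-vertex correspondence because remeshed replicate models have no
meaningful vertex correspondence (a `method = "vertex"` mode exists for
fidelity checks). Distances are summarised by a 60-equal-width-bin
histogram, median and IQR, and exported as CSV. The accelerated query is
certified exact against a brute-force all-pairs oracle in the tests.

The statistics layer implements the replicate-agreement toolkit:
per-replicate deviations from the group mean in absolute and percentage
form (summing to zero by construction), exact reconstruction of pooled
mean/SD from two group summaries, the two-sided Mann-Whitney test (exact
for combined n ≤ 20 without ties, tie-corrected normal approximation
otherwise — the pooled operator comparison at n = 12 + 12 sits in the
exact range), a single-pass µ ± 3σ outlier screen, and Kruskal-Wallis
with Dunn's pairwise rank post hoc under Bonferroni multiplication by
k(k−1)/2 — the conventional reading of "post hoc Bonferroni" after a
Kruskal-Wallis test; pairwise Mann-Whitney with Bonferroni is a
straightforward alternative the user can assemble from the exported
pieces. The deviation charts follow the per-replicate
deviation-from-group-mean form (with SD reference lines) used in the
replicate-agreement literature for this workflow; a classical
Bland-Altman mode (difference vs pairwise average, limits at bias ±
1.96 SD) is available via `classical = TRUE`.

## The replicate study

`run_study()` wires everything together: 2 pseudo-operators × 2
modalities × 2 sides × 3 replicates = 24 segmentations of 12 rendered
volumes. Replicates differ by a small random rigid offset (≤ 2°, ≤ 1 mm)
applied before voxelization plus fresh render noise; operators differ by
seeded jitter of the intensity threshold (SD 40 AU ≈ 0.016 mm of boundary
shift through the edge ramp) and of the brush seed voxel. Every model is
registered to the reference model of its side (operator A, CBCT,
replicate 1 — overridable), cut with the landmark planes in the shared
frame, measured, and compared to the reference by signed cloud distance.
All randomness derives deterministically from one master seed; two runs
with the same configuration are bit-identical. With the default problem
sizes a full study takes a few minutes on one core; the test suite's
reduced study (smaller phantom, two replicates) runs in under a minute.

Design rationale for the open choices: the erosion default of 0.3 mm
makes δ·S/V ≈ 11–17% of the head volume, the order of magnitude of
reported MRI-vs-CBCT volume deficits; threshold jitter magnitudes are
chosen to make between-operator differences visible but statistically
null (Mann-Whitney p ≫ 0.05), mirroring a replicate study in which
operators are interchangeable; and the study reports both signed and
unsigned distance summaries because published distance tables rarely
state which convention their software exported.

## Numerical choices and degenerate inputs

* Iso-vertices exactly on grid corners are welded (manifoldness);
  combinatorially degenerate triangles are dropped at extraction, but
  zero-area slivers created by plane clipping are *kept*, because
  removing them would open the mesh.
* Ray-parity classification jitters the ray origin by a fixed sub-voxel
  offset and re-casts on grazing hits; a column that fails five offsets
  is classified empty (never observed in practice).
* Ties in prominent-vertex picks break to the lowest index; all stochastic
  steps take explicit integer seeds; derived seeds stay below 2^31.
* `horn_align` rejects < 3 or collinear reference points;
  `build_cut_planes` rejects collinear landmarks; `mesh_volume` rejects
  open meshes rather than returning a biased number.
* Histogram binning of a constant distance field pads the range by 1e-9
  to keep 60 well-defined bins.

## Known limitations

Segmentation assumes axis-aligned volumes (direction cosines are out of
scope; a DICOM-series path would need prior resampling). The ICP has no
outlier rejection by default (`trim` exists for partial overlap). The cap
triangulation handles the simple or pinched loops produced by planar cuts
of manifold surfaces, not arbitrary self-intersecting polygons. Surface
estimates from binary masks carry the stair-casing bias discussed above,
so absolute `S` accuracy is limited by voxel size even when `V` is
accurate to well under 1%.
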