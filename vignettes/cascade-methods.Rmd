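---
title: "Methods: a cascade auto-contouring framework on synthetic pelvic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cascade auto-contouring framework on synthetic pelvic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`cascadeseg` implements the architecture of a clinical CT auto-contouring
system — classification-gated field of view, coarse-to-fine segmentation,
anatomical border rules, cross-training label curation and a surface-distance
evaluation suite — as a desk-scale framework whose every stage is exercised
on synthetic phantoms with exact ground truth. This vignette documents the
model and its assumptions, the parameters that matter, what the phantom
world does and does not emulate, the numerical choices, and the design
decisions taken where the design was genuinely open.

## 1. The cascade

**Preprocessing.** All volumes are resampled to a working grid of
2.5 × 1.17 × 1.17 mm voxels (arrays ordered slice z × row y × col x, z
increasing toward the head). Hounsfield units are clipped to
[−1000, 3000] and shifted by +1000 into [0, 4000]. `clip_shift_intensity()`
refuses already-preprocessed input so the shift can never be applied twice.
Images are interpolated trilinearly, masks nearest-neighbour — the
conventional pairing that preserves mask binarity; the choice is a package
decision, since interpolation is rarely specified in clinical descriptions.

**Extent classification.** One classifier per structure decides slice by
slice whether the structure is present; the per-slice label during training
is "the mask is non-empty on that slice". The loss is weighted
cross-entropy with the positive-class weight equal to the ratio of absent
to present slices in the training set (`auto_ratio`), compensating for the
heavy slice imbalance of small organs. Probabilities are clamped at
ε = 10⁻⁷ inside the loss so it is never NaN. The probability series is
postprocessed into a single cranial-caudal interval: binarise at 0.5, fill
internal gaps of at most `max_gap = 2` slices, keep the longest remaining
run (ties go to the run with larger summed probability). The published
system leaves this postprocessing rule unstated; this rule is robust to
isolated false negatives and always yields one interval. Two properties are
tested: the output is always one contiguous interval, and it is monotone in
`max_gap` in the sense that the interval's *length* never shrinks —
containment monotonicity is false, because filling a gap can merge two
short runs into a new longest run somewhere else. The extent handed to the
segmenters is padded by one slice at each end to absorb off-by-one
classifier errors.

**Segmentation.** Segmenters are trained with the soft Dice loss
`1 − (2·Σpt + s)/(Σp + Σt + s)` with smoothing `s = 1` in numerator and
denominator (standard stabilisation for empty masks; on binary inputs the
loss equals 1 − DSC up to `s`). The optimizer is Adam with β₁ = 0.9,
β₂ = 0.999, ε = 10⁻⁸. Augmentation is horizontal flipping plus in-plane
rotation by a uniform angle in [−30°, 30°] about the axial axis (linear
interpolation for the image, nearest for masks, rotation about the slice
centre). The coarse-to-fine strategy mirrors the clinical pipeline: segment
on an in-plane downsampled copy (half resolution by default), take the
centre of mass (unweighted mean voxel coordinate, rounded), crop a
per-structure box around it on the native grid, and resegment inside the
crop. The crop box defaults to the tightest ground-truth bounding box of
the training cohort dilated by 25% per axis — large enough to enclose the
structure on training data while bounding the field of view. During refine
training the crop centre is drawn uniformly over the structure's bounding
box (the "random centre" augmentation); at prediction it is the coarse
centre of mass. An empty coarse prediction cannot anchor a crop: the
empty prediction is returned with a warning and the scan is recorded as a
failure case rather than aborting the cohort. L4 and L5 share one
multi-label model (one sigmoid channel per vertebra; at prediction a voxel
is assigned to the arg-max channel, keeping the adjacent structures
disjoint). The nodal target volume is predicted by both a 3D and a 2D
model and fused by voxelwise union — "sum" of contours is read as union,
since a binary sum saturates at 1; union is commutative, associative,
idempotent, and can only add foreground, so recall never decreases
relative to either input (tested as a property).

**Pluggable models.** The published system uses clinical-scale CNNs
(classification and 2D/3D encoder-decoder architectures). Those are out of
scope here; what the cascade actually depends on is a pair of contracts —
*fit on labelled slices, emit a per-slice probability* and *fit on
(volume, mask) pairs, emit per-voxel probabilities per structure channel*.
The reference implementations are logistic heads on engineered features:
per-slice mean, spread and 4 × 4 in-plane mean-pools of intensity,
soft-tissue fraction and contrast-vessel fraction for the classifier; and,
per voxel, raw and box-smoothed intensity, three CT band indicators (soft
tissue 1005–1120, contrast vessel 1120–1320, bone > 1400 on the shifted
scale), the absolute raw-smooth divergence (an edge detector that separates
genuine vessel from bone-edge partial volumes), and region-normalised
coordinates with their squares, so a single linear head can carve an
intensity-gated ellipsoid. Features are z-scored on the training sample.
Training subsamples voxels per scan (foreground capped at a quarter; half
of the background budget is spent on *hard negatives*, tissue-like voxels
that are not the target — without them the head learns the intensity
window only and never uses position). Any function honouring the contracts
can replace these models; `refine_segment()` additionally accepts a plain
`function(vol, region) -> probability array`, which the tests use to plug
in oracle predictors.

**Border rules.** The vessel model runs inside a crop anchored on the L4
vertebral body: centre at the L4 centroid, box = L4 bounding box dilated by
8 slices axially and 12 voxels in-plane. The bifurcation slice `b` is read
off the vessel mask geometrically: the smallest slice index such that every
occupied slice at or above it has exactly one in-plane connected component
and the slice below has at least two. In-plane components smaller than 3
voxels are discarded first, and slices holding nothing but such specks do
not count as occupied; a mask with ≥ 3 components on most slices is
rejected as fragmented. How the published system mapped its aorta
segmentation to a bifurcation level is unstated; component counting is the
deterministic, testable reading. On predicted (rather than ground-truth)
vessels the pipeline first applies one morphological opening and drops
small 3D components, because thin false-positive shells around bone or the
nodal sheath can otherwise fake an extra in-plane component. The nodal
volume is truncated at `b − 1` (one slice below the bifurcation); the PAN
volume keeps slices `≥ b` (one slice above the nodal superior border), so
the two are axially adjacent and disjoint by construction. The PAN
*superior* border (renal-vein level) is taken from the extent classifier
rather than auto-detected — the clinical protocol itself treats that
border as physician-adjusted.

**Curation.** Labels are screened by half-split cross-training: split the
scans into two halves (sizes differ by at most one, deterministic under a
seed), train one model per half, predict the opposite half, and flag every
(scan, structure) whose label-vs-prediction DSC falls below the threshold
(0.7 for the rectum, 0.8 for everything else; thresholds for non-OAR
structures are not published, so 0.8 is applied with a config override).
Flagged contours go to a pluggable reviewer (`keep`/`remove`); removal
deletes only that structure's label, not the scan. The process repeats
three times on the refined cohort with a fresh random split each iteration
(whether the published procedure re-split identically is unstated; fresh
splits avoid systematic half-assignment bias, with the iteration seed
derived from the split seed). The loop stops early with a warning if fewer
than four usable scans remain. One honest limitation: with the low-capacity
default trainer, a grossly corrupted label *inside* a training half
degrades that half's model, so clean scans predicted by it can be flagged
along with the truly corrupted one. Flagging is therefore
sensitivity-oriented and the review step supplies the specificity — which
matches the role review plays in the original semi-automatic procedure.
The acceptance-level curation simulation uses an oracle train function, as
its protocol prescribes, and recovers 100% of corrupted labels with no
clean removals.

**Metrics.** DSC is `2|P∩R|/(|P|+|R|)`, defined as 1 when both masks are
empty and 0 when exactly one is. Surfaces are foreground voxels with at
least one six-connected background neighbour, the volume border counting as
background; distances are Euclidean between voxel centres in physical mm
and reported in cm. MSD is the symmetric average of the two directed mean
nearest-surface distances; HD is the maximum of the two directed maxima,
with a percentile parameter (default 100, the true Hausdorff — the cited
convention is not reproduced in the clinical text, so HD95-style variants
are exposed but not default). MSD/HD are undefined for empty masks and
reported as missing, never as zero. Cohort evaluation applies the
evaluation-time trims first — predictions of the PAN volume are cut at the
reference's superior border, rectum and cord at the inferior border — then
aggregates mean ± SD per structure and flags DSC outliers below
Q1 − 1.5 · IQR. The nearest-distance kernel is a small compiled routine
(exact per-axis arithmetic); it is tested against an independent O(n²)
per-point enumeration oracle to 10⁻⁹ cm. An earlier pure-R implementation
using the |a|² + |b|² − 2a·b expansion failed that tolerance through
floating-point cancellation, which is why the kernel forms per-axis
differences.

## 2. The phantom world

`phantom_spec()` states the world once, as fractions of the grid so the
same anatomy scales between the default 64 × 96 × 96 grid and the
48 × 64 × 64 grids used for fast runs: an anterior ellipsoidal bladder, a
gently bent rectal tube and a thin spinal cord posteriorly, two ellipsoidal
kidneys superior-laterally, a pelvic bone ring plus L4/L5 vertebral blocks
separated by a disc-sized gap, and a Y-shaped vessel — a single aorta at
and above the bifurcation slice, two iliac branches below. At the slice
below the bifurcation the branch centres sit one radius plus one voxel off
the midline: the two circles are separated in-plane (component counting
sees the split exactly at the stated slice) while each branch footprint
still overlaps the aorta's, so the ground-truth tree stays six-connected.
Thin nodal and para-aortic sheaths (2-voxel shells around the branches and
the aorta respectively) let the border rules run end to end. Mean
intensities are plausible CT values — background −50 HU, soft organs
30–100 HU, contrast vessel 150 HU, bone 700 HU — with additive Gaussian
noise of σ = 20 HU; `contrast_scale` < 1 shrinks every organ-background
difference to emulate low-contrast scans. Cohorts jitter organ centres
(±2 slices, ±2 voxels in-plane), radii (±8%) and the bifurcation slice
(±3); generation is a pure function of (spec, seed), masks are exact and
pairwise disjoint, and any jitter that would make structures collide or
leave the grid is rejected as a spec error rather than silently clipped.
Two stated-world consequences: the nodal/PAN sheaths need the default
grid's in-plane resolution (on 48 × 64 × 64 they would touch the vertebral
blocks, and the generator refuses), so small-grid runs use the
nine-structure subset; and label corruption (`corrupt_labels()`) is covert
— provenance stays `ground_truth` and the corrupted ids are returned only
for test oracles.

What a green test does and does not establish: the phantom has crisp
single-intensity organs, no partial-volume ramps, no contrast variability,
no pathological anatomy, and its organs are separable by intensity bands
plus a quadratic spatial prior. Passing the cascade-recovery criterion
(held-out median DSC ≥ 0.85 with refinement not degrading the coarse
stage) shows the *plumbing* — extent gating, crop anchoring, compositing,
border rules, bookkeeping — is correct and that the training losses and
optimizer do their job; it says nothing about segmenting clinical CT,
which needs the clinical-scale architectures this package deliberately
replaces.

## 3. Numerical choices and degenerate inputs

- Dice smoothing `s = 1`; probability clamp ε = 10⁻⁷; binarisation of all
  probability maps at 0.5 before any metric.
- Resampling maps output voxel centres through physical coordinates
  (`origin + (i−1)·spacing`), clamped at the volume edge; single-slice
  volumes are rejected as degenerate. A point-sampling resampler can miss
  a delta impulse that falls between output voxel centres — the round-trip
  accuracy property is therefore stated for band-limited content (< 2% RMS
  on a smooth blob).
- NIfTI-1 I/O is implemented in the package (no NIfTI reader is available
  in the target R environment): single-file `.nii`/`.nii.gz`, little- or
  big-endian, uint8/int16/int32/float32/float64. Image data is written as
  float64 by default so write→read round trips are bit-exact; the format
  stores spacing and origin as float32, so those round-trip to single
  precision. Masks are written as uint8. The volume's intensity kind is
  carried in the header description field.
- Configs and manifests are JSON (`jsonlite`); the environment provides no
  YAML parser, and the schema is identical either way.
- Horizontal flipping is disabled for the kidneys in the default registry:
  for a local model a mirrored left kidney is indistinguishable from the
  right one, and flip augmentation made the coarse stage pick the wrong
  kidney on about half the scans. Clinical-scale networks with full-image
  context do not share this failure mode, which is why the clinical recipe
  can flip everything.
- The multi-label (L4/L5) extent entry uses `max_gap = 4`, since the true
  union of the two vertebral bodies contains a genuine anatomical gap at
  the intervertebral disc.
- Crop boxes are clamped to the grid without changing shape; refine output
  is identically zero outside the crop box (leak-free compositing is a
  tested property).
- Ties: equally long extent runs go to the larger summed probability;
  centre-of-mass rounding uses R's `round`; arg-max channel assignment
  breaks ties toward the first channel.

## 4. Known limitations

- The pluggable logistic models are intentionally low-capacity. They
  saturate on the phantom's intensity structure but cannot represent
  arbitrary shapes (e.g. the PAN sheath's annular cross-section is at the
  edge of what an intensity-gated quadratic can express, and its extent
  classification is the weakest link — mirroring the fact that the PAN
  volume is also the hardest structure for the clinical system).
- Curation with the segmenter-backed trainer is a screen, not a verdict:
  poisoned training halves inflate the flag rate, and the reviewer is
  responsible for specificity.
- The bifurcation detector assumes the vessel mask is clean enough that,
  after the speck filter and opening, component counts are 1 above and 2
  below the split; heavily fragmented predictions are rejected rather than
  guessed at.
- Distances are between voxel centres; sub-voxel surface positioning
  (marching-cubes-style) is out of scope, so MSD on identical masks is
  exactly 0 but small masks quantise distances to the lattice.
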