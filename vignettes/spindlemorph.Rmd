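---
title: "Models and methods: Golgi phantoms, spine reconstruction, and cylinder-model morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: Golgi phantoms, spine reconstruction, and cylinder-model morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

spindlemorph quantifies spindle-shaped (putative von Economo) neurons and
their dendritic spines from brightfield Golgi z-stacks. This vignette is the
package's account of its science: the models and their assumptions, every
tunable parameter that matters, what the synthetic phantoms do and do not
emulate, and the numerical conventions the implementation commits to.

## 1. The imaging model

Golgi impregnation fills a sparse subset of neurons with silver chromate, so
a filled cell appears as *dark, roughly tubular structure on a bright ground*
under brightfield optics. A z-stack samples focal planes at a fixed step —
0.5 µm steps at low magnification for whole neurons, 0.1 µm steps at high
magnification (oil immersion) for spiny dendritic segments of typically
100–200 frames. Stacks are converted to 8-bit monochrome before processing;
luminosity inversion (v → 255 − v) is available to display dendritic detail
as bright-on-dark.

Containers: an `image_stack` holds a `[y, x, z]` intensity array with a
physical `voxel_spacing` (dx, dy, dz in µm; dz may differ from dx, dy). The
coordinate convention is voxel-centred: voxel (j, k, i) (1-based row, column,
slice) sits at ((k−1)·dx, (j−1)·dy, (i−1)·dz). A rendered or loaded extent E
along z yields `floor(E/dz) + 1` slices.

The 2D reconstruction of a stack (`composite_projection()`) defaults to the
per-pixel **minimum** across z. Naively summing focal planes saturates and
blurs an 8-bit composite; the minimum-intensity projection is the standard
brightfield analogue — in-focus dark structure from any plane survives into
the composite. `mean` and `sum_clipped` are available for comparison.
RGB input collapses by ITU-R 601 luminance weights (0.299, 0.587, 0.114),
matching common camera software; 16-bit input maps linearly over its full
range.

## 2. The spine-reconstruction pipeline

`reconstruct_spines()` applies six stages in a fixed order, each pure and
recorded in the output's provenance. All intensity-valued parameters are on
the normalized 0..1 scale; all spatial parameters are in µm or voxels as
noted. The defaults (all in `pipeline_config()`) are scaled to spine-stack
geometry: 0.1 µm steps and sub-micron necks.

**(a) Outlier removal** (`remove_outliers`, window 3 voxels, k = 4). A voxel
is replaced by its local median only if it deviates from that median by more
than k times the MAD-scaled local spread *and* has at most 2 similar
neighbours in the window. The isolation guard is the essential part: a plain
median-deviation test erases sub-voxel necks (any thin structure is a
"minority" in its own window), whereas a genuine impulse — a hot pixel or an
isolated silver-precipitate dot — has no similar neighbours. This is the
switching-median idea from impulse-denoising practice. An optional 3D median
prefilter in small subvolumes exists for very contaminated material but is
off by default precisely because it erodes thin necks.

**(b) Edge enhancement** (`enhance_edges`). Unsharp masking,
`clip(x + amount·(x − G_σ(x)))`, followed by an edge-preserving smoothing
pass — a recursive domain-transform filter in which the smoothing kernel
cannot cross intensity discontinuities (transform increments
`step + (σ_s/σ_r)·|ΔI|` computed once from the input act as the guide).
Defaults: `unsharp_amount = 1.0`, lateral `unsharp_sigma = 0.2` µm and axial
`unsharp_sigma_z = 0.4` µm — the 2:1 axial elongation mirrors the brightfield
PSF, so the stronger axial sharpening counteracts the axial smear that
otherwise dilates the shaft along z and hides short or axially oriented
spines; `edge_aware_sigma_s = 1.0` µm and `edge_aware_sigma_r = 0.35`
(normalized intensity) were chosen so that noise steps at a
contrast-to-noise ratio of 10 fall well inside the smoothing regime while
true edges (contrast ≈ 0.5 over one or two voxels) block propagation. The
order (unsharp first, then smoothing) is the default; a config switch swaps
it, since no convention is canonical. `σ_r = Inf` makes the smoothing a
passthrough.

**(c) Adaptive binarisation** (`binarize_adaptive`, block 31 px, offset
5/255). Per-slice 2D local-mean thresholding with edge-replicated borders:
dark-foreground polarity marks voxels *strictly below* `mean_block − offset`.
Strictness carries a 10⁻⁹ numerical guard so exact rational ties resolve to
background regardless of summation order. Constant regions yield background
by construction. Per-slice (not 3D) blocks reflect slice-wise acquisition and
keep the threshold insensitive to axial intensity trends. Note a deliberate
consequence: the interior of a structure much wider than the block reads as
background (its local mean equals its own intensity) — stage (e) exists to
close those interiors.

**(d) False-positive pruning** (`prune_false_positives`, min 30 voxels,
attach radius 0.5 µm). 26-connected components survive iff they are large or
lie within the attach radius of the largest component: a small object touching
the dendrite is a spine candidate, a distant one is an artifact. Output is
always a subset of the input.

**(e) Per-slice flood fill** (`flood_fill_slices`). Background regions not
4-connected to the slice border become foreground. Output is always a
superset of the input; the stage is idempotent.

**(f) Cubic z interpolation** (`interpolate_z`, zfactor 3 by default). The
mask is lifted to a 0/1 field, Catmull-Rom interpolated along z to
`(n−1)·zfactor + 1` slices, re-thresholded at 0.5; dz divides by zfactor and
the original slice positions reproduce the original masks exactly. Fewer than
4 slices fall back to linear interpolation with a warning. One honest
caveat: on a *binary* field re-thresholded at 0.5, cubic interpolation of a
step pattern crosses 0.5 at the slice midpoint, exactly where centred
nearest-neighbour duplication switches — so for solid convex bodies the two
differ little; the interpolation matters for thin oblique structure and for
downstream distance computations on a near-isotropic grid. Stacks that are
already isotropic (the spine fixture: dz = dx = 0.1 µm) use zfactor 1.

Connectivity conventions, stated once and used everywhere: 26-connectivity
for 3D components, 4-connectivity for 2D flood-fill background. Border
handling is edge-replication for all windowed operations. The final stage of
the original workflow — interactive visualization — is realised as export
(`write_mask()`), not a viewer.

## 3. Spine separation and measurement

**Centerline** (`extract_shaft_axis`). The anisotropic Euclidean distance
transform (EDT) of the largest component defines a medialness field; the
shaft axis is the longest geodesic through the component with step costs
penalised away from the EDT ridge (`1 + γ(1 − edt/max)²`, γ = 8), endpoints
found by the classical double Dijkstra sweep. Two hardening measures matter
in practice: the endpoint sweeps run on the *EDT core* (the largest connected
region with edt ≥ half the maximum), so a long spine can never become an
axis endpoint — spine necks fall below the core threshold and disconnect
their heads; and the per-point radius profile gets a wide running median
before smoothing, so spine attachments do not inflate the local shaft
radius. A component whose axis length is below twice its diameter is
rejected as not elongated.

**Segmentation** (`segment_spines`). Foreground farther from the axis than
the local shaft surface plus a margin (default 1.2 in-plane voxels) forms
protrusion candidates. The shaft surface is modelled as an *ellipse* with
axial semi-axis κ·r: brightfield axial elongation dilates the shaft along z,
and κ is estimated from the component's own surface voxels lying axially
from the centerline (κ ≈ 1 on unblurred masks, ~2 under a 0.3 µm axial PSF).
Candidates shorter than the 0.2 µm noise floor are discarded. Two
spine-specific conventions: candidates whose arclength footprint carries
several well-separated radial peaks are split at profile valleys (spines
fused through blur halo), while sub-voxel contacts stay merged and are
flagged `contact_ambiguous` rather than silently split; and end-caps — the
centerline necessarily stops about one radius inside the rounded ends of a
cut segment, so the caps register as protrusions pointing *along* the axis —
are suppressed by exactly that signature, leaving radially pointing spines
near the ends intact. The attachment point is anchored beneath the
candidate's radial apex and projected onto the shaft surface along the
outward direction, where an attachment lives by definition.

**Measurement** (`measure_spine`). The cross-section profile is taken over
radial-height shells of one voxel thickness; widths are volume-equivalent
(cylinder for the neck over a ±0.15 µm window, sphere for the head), which at
0.1 µm voxels is far more robust than inradius estimates on 2–3 voxel
structures. The head is the distal compartment anchored at the tip by
fixed-point iteration of its equivalent diameter; a spinule-robust trim of
the tip anchor applies only when the profile carries a distal bulb (monotone
stubby/wide bumps keep their true apex). A neck exists when head/neck ≥ 1.2
*and* the profile genuinely dips below the head's own width. Protrusions are
counted as distinct distal compartments (≥ 12 voxels) under a sweep of
geodesic cuts; head sphericity compares the equivalent-sphere surface with
the voxel-face surface (corrected by 2/3 for the taxicab overestimate);
spinules are small clusters (length ≤ 0.4 µm, calibre ≤ 0.2 µm) protruding
beyond the head sphere.

## 4. The classification rule table

`classify_spine()` is a pure function of the measured features and
`spine_rules()`, evaluated in priority order: **ramified** (≥ 2 protrusions),
then necked rules — **mushroom** (head/neck ≥ 1.5), **thin** (length/neck ≥ 3
with head/neck < 1.5) — then neckless rules — **wide** (base ≥ 1.5 × length),
**stubby** (length ≤ base). A measurement within ±10% of the deciding
boundary returns **transitional**; anything left is **atypical** (the
residual class for genuinely complex shapes, e.g. serial double bulbs).
Two points where the design was genuinely open:

* The stubby rule alone (length/base ≤ 1) would also capture every wide
  spine, so stubby additionally requires base/length below the wide ratio;
  "wide" itself — not one of the classical classes — is operationalized as
  *neckless with lateral extent at least 1.5 × protrusion length*, and this
  interpretation is deliberately exposed in the rule table.
* A long slender protrusion whose head never clears the 1.2 neck-detection
  ratio is labelled **thin** (the filopodial reading): about half of thin
  spines have heads barely wider than their necks, and headless filopodial
  protrusions belong with thin in common usage, not with the residual class.

All thresholds are ratios, so labels are invariant under joint scaling of
geometry and voxel spacing; the absolute spinule caps affect only spinule
flags, never the class label. The taxonomy's numbers are design choices — the
original classification was by expert visual inspection — and live in one
editable rule table.

## 5. The phantom generator: the study conditions

Because no specimen images of this cell type are publicly deposited, the
generator defines the package's study conditions.

**Morphology** (`generate_spindle_swc`). A prolate soma in the 3-point SWC
convention (centre plus two pole nodes; length = pole-to-pole distance,
diameter = 2 × max soma radius, volume by the prolate ellipsoid model —
consistent with a fusiform cell body; a voxel-integration alternative was
considered and rejected as spurious precision for Golgi material). Two
primary shafts leave opposite poles within `primary_angle_spread` (default
10°) of the vertical, with linearly tapering radii (basal diameter 2.6 µm)
and collaterals by profile: *straight* (none), *sparse* (≈ 1/40 µm) or
*profuse* (≈ 1/12 µm), at 40–80° from the shaft. Soma defaults 37 × 19 µm.
`n_primary > 2` produces oblique extra primaries as a pyramidal-like control
for the qualifier.

**Spines** (`decorate_with_spines`). Placement along dendritic arclength is
a homogeneous Poisson process, or a Neyman–Scott cluster process
(parents + offspring within a 1 µm window) for `grouping > 0` — spines on
real dendrites occur isolated or grouped. On top sits a steric-exclusion
rule: no two spines within 0.7 µm of arclength *and* less than 90° apart in
azimuth, because spines are solid bodies and visual counting presupposes
resolvable protrusions; without it roughly a third of spines at 0.8/µm would
interpenetrate. Class-conditional geometry (all ranges configurable,
`spine_geometry_defaults()`): thin — neck 0.20–0.24 µm calibre, 0.7–0.9 µm
long, head 1.12–1.28 × neck; stubby — prolate half-ellipsoid bump with
length 0.78–0.86 × base; wide — oblate bump with base 1.8–2.6 × length;
mushroom — neck 0.16–0.22 µm, head 0.55–0.70 µm; ramified — two 0.40–0.46 µm
heads forking at 38–50° from one stalk. These ranges realise the taxonomy's
qualitative contrasts with clear margins relative to the rule thresholds;
the published description gives no numbers. Spinules (calibre 0.16 µm,
0.25–0.35 µm long) decorate 15% of mushroom/ramified heads by default.
Density bands are declared in config, not asserted as fact: sparse ≤ 0.3/µm,
moderate 0.3–1/µm.

**Rendering** (`render_stack`). Geometry is voxelized by exact
point-in-primitive tests (capsules with linearly interpolated radii for
frusta, spheres, ellipsoids), blurred with an anisotropic Gaussian PSF
(σ_z : σ_xy = 2 : 1 by default, mimicking brightfield axial elongation),
then punctate dark speckle ("unspecific silver precipitate"), a
multiplicative illumination ramp and additive Gaussian noise are applied
before 8-bit quantization. With zero blur and noise the set of voxels darker
than the foreground/background midpoint equals the ground-truth mask
*exactly* — the anchor for all overlap scoring. Spacing coarser than the
smallest neck raises a warning, not an error.

**The standard fixture** (`standard_fixture`, seed 20220111). A serpentine
dendritic segment — six straight runs joined by right-angle connectors,
75 µm total arclength folded into a 12.7 × 12.7 × 15 µm field — carrying
exactly 60 spines (0.8/µm; the fixture pins the count via a fixed-n draw,
while general decoration keeps the Poisson count), rendered at 0.1 µm
isotropic voxels into a 128 × 128 × 151 stack. Two variants: *noiseless*
(pure geometry — the regime where mask consistency is exact) and *SNR-10*
(PSF 0.15/0.30 µm, speckle, 10% illumination ramp, noise at one tenth of the
contrast). Problem sizes throughout the tests — one 2.5M-voxel stack per
variant, 50 random trees up to ~400 nodes, 500+ spines for mix recovery —
were chosen as the smallest that exercise every code path at realistic
geometry.

**What the phantoms do not emulate.** Real Golgi material has incomplete
impregnation, overlapping neurites from other cells, vendor-specific
"dynamic deconvolution" applied during acquisition, refractive-index
mismatch, tissue shrinkage, and curved gradual spine shapes rather than
piecewise-primitive geometry. Passing the phantom benchmarks therefore
demonstrates that the algorithms recover what they claim *under the stated
optics and noise model* — not segmentation-grade performance on arbitrary
archival slides. Morphometric values on real material are further biased by
fixation shrinkage, which no image analysis can undo.

## 6. Morphometry conventions

Branch counting follows the topological decomposition reading: the count of
unbranched segments delimited by primary origins, branching points and tips
(a primary that splits once contributes 3). Edges from a soma node to the
first dendritic node lie inside the soma and are excluded from length and
volume; the soma volume is reported separately and *not* included in the
total dendritic volume. A "primary dendrite" is a dendritic child of a soma
node; its departure direction is the unit vector from the soma centroid to
its 5th node (or tip if shorter), which makes the angle criteria
deterministic. SWC files carry no anatomical frame, so the vertical (pial)
axis is supplied by the caller. The qualifier's thresholds — exactly two
primaries with basal diameter ≥ 0.6 × the thickest, departure angle ≥ 150°,
each within 30° of vertical, soma elongation ≥ 1.6 — encode the published
inclusion criteria geometrically.

All metrics except the orientation-dependent qualifier are rigid-motion
invariant and scale as s (lengths) and s³ (volumes); the tests verify this to
10⁻⁶ relative, and verify the sums against brute-force per-edge traversal to
10⁻⁹ relative with exact branch counts.

## 7. Determinism and numerical choices

Every stochastic operation takes an explicit seed; one run seed drives all
stages through derived substreams (`derive_seed`), and no stage reads global
RNG state — re-running a manifest reproduces byte-identical CSV/TIFF outputs.
Tie-breaking rules are fixed: strict threshold inequalities with a 10⁻⁹
guard; first-index ties in arg-max selections; background on ties. Degenerate
inputs have defined behaviour: empty volumes reconstruct to empty masks and
classify to empty spine tables; somaless segment SWCs get cylinder metrics
but no qualifier; fewer than 4 slices interpolate linearly with a warning.

## 8. Known limitations

* Spines within ~1 µm of a cut segment end can merge with the end-cap
  region; the cap suppression keeps radially pointing spines but a spine
  pointing along the axis at the very end is indistinguishable from the cap.
* Short spines oriented along z under a strong axial PSF are genuinely
  absorbed into the axial dilation of the shaft; the anisotropic envelope
  recovers most but not all of them, which is why detection recall is
  evaluated separately under SNR-10 conditions.
* Class labels for measurements inside the ±10% transitional band are
  *meant* to be unstable against re-measurement — that is what the band is
  for; evaluation should treat transitional as its own outcome, as the
  acceptance metrics do.
* The serial double-bulb shape is generated as "atypical" but measured as a
  necked, big-headed protrusion; with two bulbs sharing one stalk it would be
  ramified. Where such spines matter, inspect `n_protrusions` and the width
  profile rather than the label.
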