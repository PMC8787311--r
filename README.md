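# spindlemorph

Quantitative morphology of spindle-shaped (putative von Economo) neurons and
their dendritic spines from brightfield Golgi z-stacks.

Golgi impregnation sparsely blackens whole neurons, so a single cell — its
fusiform soma, the two vertically oriented primary dendrites leaving opposite
somatic poles, and micron-scale dendritic spines — can be imaged as a stack of
focal planes under brightfield optics (dark structure on a bright ground,
typically 0.5 µm z-steps for whole neurons and 0.1 µm for spiny dendritic
segments). Turning such stacks into numbers requires three things this package
provides for anatomists and method developers:

1. **3D spine reconstruction** (`reconstruct_spines()`): the staged pipeline
   that converts a raw stack into a clean binary volume of dendritic shaft +
   spines — outlier (impulse) removal, unsharp masking plus edge-aware
   domain-transform smoothing, per-slice adaptive (local-mean) binarisation
   with threshold `t(x) = mean_block(x) − offset`, pruning of components that
   are neither large nor attached to the dendrite, per-slice flood fill, and
   Catmull-Rom z interpolation for anisotropic stacks.
2. **Spine measurement and classification** (`classify_spines()`): centerline
   extraction of the dominant shaft (distance-transform ridge geodesics,
   per-point radius), segmentation of protrusions off the shaft envelope, and
   a rule-based taxonomy on the four classic feature groups — neck presence /
   length / diameter, protrusion count per stalk, head diameter, head shape —
   into *thin, stubby, wide, mushroom, ramified*, plus *transitional* near
   rule boundaries and *atypical* as the residual class, with spinule
   detection on heads. A spine has a neck when head/neck ≥ 1.2; a mushroom
   when head/neck ≥ 1.5; a thin spine when length/neck ≥ 3 with a modest
   head; stubby and wide are neckless with length ≤ base and base ≥ 1.5 ×
   length respectively. All thresholds live in one rule table
   (`spine_rules()`).
3. **SWC morphometry** (`morphometry_report()`, `classify_spindle()`): the
   cylinder-compartment model of an SWC reconstruction — soma length, main
   diameter and prolate-ellipsoid volume `(4/3)π(L/2)(D/2)²`; branch count as
   the number of unbranched segments between primary origins, branching
   points and tips; total dendritic length; total volume as the per-edge
   frustum sum `π·h·(r₁² + r₁r₂ + r₂²)/3` — and the geometric spindle-neuron
   qualifier (exactly two substantial primaries, opposite somatic poles,
   within 30° of the vertical axis, soma elongation ≥ 1.6).

Because specimen images of this cell type are effectively unavailable, the
package is built around a **synthetic Golgi phantom generator**
(`generate_spindle_swc()`, `decorate_with_spines()`, `render_stack()`): it
produces spindle morphologies, decorates them with ground-truth spines from a
configurable class mix, and renders brightfield-like 8-bit stacks with
anisotropic PSF blur, silver-precipitate speckle, illumination gradients and
sensor noise — so every stage is testable against known truth.

## Worked example

The standard benchmark phantom is a 75 µm serpentine dendritic segment
carrying exactly 60 spines (0.8 spines/µm), imaged at 0.1 µm isotropic voxels
into a 128 × 128 × 151 stack:

```r
library(spindlemorph)

fx <- standard_fixture("noiseless")
fx$truth
#> phantom_truth: 60 spines on 75.0 um of dendrite (0.800 /um)
#>   class_label     n
#> 1 mushroom       14
#> 2 ramified        7
#> 3 stubby         11
#> 4 thin           16
#> 5 wide           12

vol <- reconstruct_spines(fx$stack, fx$config)
jaccard(vol, fx$mask)
#> [1] 0.9999406

spines <- classify_spines(vol)
table(spines$class)
#>     mushroom     ramified       stubby         thin transitional         wide
#>           15            7            8           14            5           13

dens <- spine_density(spines)
c(density = dens$density_per_um, band = dens$band)
#> density: 0.852 /um, band "moderate"

ev <- match_spines(spines, fx$truth)
round(c(recall = ev$recall, precision = ev$precision,
        class_acc = ev$mean_class_accuracy), 3)
#>    recall precision class_acc
#>     0.967     0.935     0.867
```

The reconstructed volume overlaps the ground-truth mask almost perfectly
(Jaccard ≈ 1 in the noiseless regime), 58 of the 60 planted spines are found
with two false detections, the estimated density (0.85/µm, "moderate") sits
within 7% of the generator's 0.8/µm, and the mean per-class label accuracy
among matched spines is 0.87 (boundary cases drain into *transitional* rather
than a wrong canonical class).

Whole-cell morphometry of a generated spindle neuron with the soma
parameterised at 37 × 19 µm:

```r
cell <- generate_spindle_swc(spindle_params(soma_length = 37, soma_diameter = 19, seed = 2))
morphometry_report(cell)
#> soma_length 37, soma_max_diameter 19, soma_volume 6994 um^3, n_primary 2,
#> n_branches 16, total_dendritic_length 367 um, total_dendritic_volume 631 um^3

classify_spindle(cell)
#> spindle qualifier: ACCEPTED
#>   criterion              value threshold pass
#> 1 two_primary_dendrites   2          2   TRUE
#> 2 opposite_poles        174.       150   TRUE
#> 3 vertical_orientation    4.61      30   TRUE
#> 4 soma_elongation         1.95       1.6 TRUE
```

`autoplot()` methods draw minimum-intensity projections of stacks and class
distributions of spine tables; `simulate_phantom()` / `run_pipeline()` write
complete, manifest-tracked artifact sets (SWC + TIFF + CSV + JSON), and
`inst/cli/spindlemorph.R` wraps the same functions as a command-line tool
(`simulate`, `reconstruct`, `classify`, `morpho`, `run-all`, `validate-swc`).

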