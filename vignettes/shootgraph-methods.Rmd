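---
title: "Graph-based holistic and component phenotyping of maize shoots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based holistic and component phenotyping of maize shoots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shootgraph)
```

## The measurement problem

High-throughput greenhouse phenotyping systems image each potted plant once
a day against a fixed background, from two or more side-view angles.  For
vegetative-stage maize, the traits that best describe vigor are the timing
of leaf emergence, the number of leaves present on each day, and the growth
and shape of every individual leaf.  Holistic traits — functions of the
whole silhouette — are comparatively easy to compute once the plant is
segmented; component traits require identifying the individual organs
(each leaf, and the stem) in every frame.

`shootgraph` implements both levels.  The plant silhouette is reduced to a
one-pixel skeleton and represented as a typed graph $P = \{V, E\}$ with
$V = \{T, B, J\}$: the **base** $B$ (the bottom-most skeleton point, where
the stem leaves the soil), leaf **tips** $T$ (nodes of degree 1) and
**junctions** $J$ (nodes of degree 3 or more — the collars where leaves
join the stem).  Edges are **leaves** (one endpoint a tip) and
**inter-junctions** (stem segments between collars).  Everything
downstream — leaf counting, emergence tracking, per-leaf geometry, stem
angle — is graph traversal plus curve fitting on edge paths.

## Segmentation

Five stages, mirroring a fixed-background imaging cabinet
(`segment_plant()` composes them):

1. **Registration** (`register_to_background()`, optional, off by
   default): Harris corners are detected in frame and background,
   normalized 11×11 patches matched by correlation, and a similarity
   transform fitted by exhaustive two-point consensus with a final
   least-squares refinement.  Needed only when zoom or rotation changed
   between background and frame; synthetic and fixed-camera data are
   already aligned.
2. **Frame differencing** (`frame_difference()`): a pixel is foreground
   when the maximum absolute channel difference exceeds
   `difference_threshold` (default 15/255 — small enough that anti-aliased
   stroke edges survive, large enough to ignore sensor-level noise).
3. **Green superimposition** (`green_superimpose()`): inside the rough
   foreground, only pixels whose hue falls in the green band
   (default [0.17, 0.45]) keep their values; soil, pot film and lighting
   residue are zeroed.
4. **HSV thresholding** (`hsv_binarize()`): hue 0.051–0.503, saturation
   0.102–0.804, value 0.000–0.786 (all on a 0–1 scale); pure black pixels
   are never foreground, which makes the stage idempotent on its own
   masked output.
5. **Morphological cleanup** (`morphological_clean()`): interior holes up
   to `max_hole_area` px² (default 100) are filled first (a pinhole would
   otherwise be widened through a thin stroke by the erosion; larger
   enclosed background regions — e.g. a pocket closed off where a drooping
   leaf touches the stem — are genuine background and stay open), then a
   disc opening (erosion radius 1, dilation radius 1) removes speckle, and
   the largest 8-connected component of at least `min_component_area` px²
   (default 50) survives.  Equal erosion
   and dilation radii are deliberate: an unequal pair thickens every
   stroke by a constant band, which biases the plant-pixel count (and
   hence plant aerial density) and the mask against any reference
   silhouette.

All thresholds live in `segmentation_config()` and can be overridden from
a flat key–value file (`read_segmentation_config()`).

## Skeletonization and the plant graph

`skeletonize()` thins the mask with Guo–Hall parallel thinning followed by
a sequential completion pass that deletes, in fixed row-major order, every
*simple* pixel (crossing number 1) that is not a curve endpoint.  The
completion pass guarantees strict one-pixel thinness (no 2×2 block
survives) while preserving both connectivity and endpoints; parallel
subiterations alone can leave two-pixel diagonal staircases.  The backend
honors exactly two contracts — thinness, and component count equal to the
input's — and is swappable.

Thinning has two well-known geometric artifacts that the graph stage
corrects:

* **Junction clusters.** Where a 5 px leaf stroke meets the stem, thinning
  produces a small knot of degree-3 pixels connected by tiny edges,
  sometimes with one-pixel cycles.  `prune_spurs()` removes short
  self-loops and the longer edge of short parallel pairs, and contracts
  internal edges of length ≤ threshold between junction nodes, merging
  each knot into a single junction (the lower node is kept so pixel paths
  stay consistent).
* **Endpoint retreat.** A skeleton stops about half a stroke width short
  of the stroke's end.  After classification, `extend_leaf_tips()`
  continues each leaf path from its tip along the local tangent, one pixel
  at a time while still inside the mask (at most 12 px), restoring the
  lost tip length.  Without this, leaf lengths are biased several percent
  short.

**Spur pruning** removes edges with a free (degree-1, non-base) endpoint of
length ≤ 10 px — boundary noise, not leaves — then collapses the redundant
degree-2 nodes left behind so every leaf and inter-junction is one edge;
the whole process iterates to a fixpoint (`prune_spurs(prune_spurs(g))`
equals `prune_spurs(g)`).  The 10 px default follows the threshold that
removes all spurs on real maize sequences of this image scale.

**Classification** (`classify()`): the base is the node at the maximal row
(bottom of the image), ties broken by the leftmost column; remaining
degree-1 nodes are tips, degree ≥ 3 nodes are junctions; an edge with a
tip endpoint is a leaf, the base-incident edge is the base segment.  Two
conventions deserve mention:

* A **pre-junction seedling** is a single edge from the base to a tip.
  The tip rule makes it one leaf, which is also biologically right — what
  is visible at that stage *is* the first leaf, not bare stem.
  `count_leaves(..., count_seedling_leaf = FALSE)` opts out.
* **Crossovers.**  A leaf crossing another creates a cycle in the skeleton
  graph.  Cyclic graphs are flagged at construction and refused by
  `classify()`; the pipeline logs the frame as unanalyzable and moves on.
  Occlusion handling is out of scope by design, and the synthetic
  generator's `crossover` flag exists to exercise exactly this refusal.

**Stem extraction** walks from the base along base-segment and
inter-junction edges, visiting junctions in increasing path distance.
When several continuations exist the longest is taken (the stem is the
dominant chain).

**Emergence tracking** (`track_emergence()`) matches detected leaves day
to day within a 20 px radius — tips first, collars as a fallback — and
assigns each leaf a rank in order of first appearance (ties: lower collar
first).  Tips are matched first because they are unique to a leaf and move
at most one day's elongation, whereas collars are ambiguous: until the
next leaf emerges, the newest leaf's collar is a degree-2 point on the
stem and collapses into the junction below, so two leaves share one
detected collar.  A leaf that disappears for a day (occlusion) keeps its
rank when it returns.

## Holistic phenotypes

`shape_metrics()` measures the silhouette: convex-hull area, bounding
rectangle height, minimum-enclosing-circle diameter (exact, by Welzl's
algorithm on the hull points) and the plant pixel count.  The hull is
taken over pixel *corners* rather than centers: the hull of a filled
convex region then equals the covered area exactly, so a filled shape has
aerial density 1 and the density of any mask is at most 1; center-based
hulls under-cover by roughly half the perimeter.

For each day the side view with the larger convex hull is selected
(`select_view()`; the tie, which the strict inequalities leave undefined,
resolves to 0°).  The three derived ratios are scale invariant:

* **Bi-angular convex-hull area ratio** $BA_{CH}R = \mathrm{Area}_{CH}(0°) /
  \mathrm{Area}_{CH}(90°)$ — plant rotation / phyllotaxy;
* **Plant aspect ratio** $PAR = \mathrm{Height}_{BR}(\text{side}) /
  \mathrm{Diameter}_{MEC}(\text{top})$ — narrow versus wide leaf extent;
* **Plant aerial density** $PAD = \mathrm{Plant}_{Tpx} /
  \mathrm{Area}_{CH}$ — compactness, a biomass proxy.

## Component phenotypes

Each leaf edge becomes a `leaf_geometry`: the ordered path from collar to
tip plus a least-squares polynomial fit.  The independent axis is the
image axis with the greater extent along the path, so near-vertical leaves
are fitted as $x(y)$; internally the independent coordinate is rescaled to
$[0,1]$ (raw pixel powers up to $x^4$ would condition the normal equations
poorly) and every derivative is mapped back through the chain rule.  The
default maximum order is 4 — enough to follow an arched maize leaf without
oscillating on a path of a few dozen pixels; the order never exceeds
$n-1$ points.

From the fit $y = p(x)$:

* **Leaf length** $\int_{x_1}^{x_2} \sqrt{1 + p'(x)^2}\,dx$ between the
  collar and tip abscissae, by adaptive quadrature at relative tolerance
  $10^{-6}$;
* **Junction–tip distance**: the Euclidean chord;
* **Curvature** $K = |p''| / (1 + p'^2)^{3/2}$, evaluated at the leaf apex
  and at mid-leaf.  The apex is the path point (possibly several) at
  maximal *absolute* perpendicular distance from the chord — the printed
  signed form would put a downward-arching leaf's "apex" at an endpoint.
  Mid-leaf is the $b$-th path point with $b = \max(1, \lfloor n/2
  \rfloor)$, evaluated on the fitted curve.  Mid-leaf curvature uses the
  analytic formula; a published alternative constructs a circle through
  the mid-leaf's two neighboring points, but the construction leaves the
  circle underdetermined, so it is documented here and not guessed at;
* **Leaf–junction angle**: the angle between the tangent at the collar
  and the chord, computed from direction vectors (equivalently
  $|\arctan((m_2 - m_1)/(1 + m_1 m_2))|$, with $\pi/2$ when
  $1 + m_1 m_2 = 0$), reported in $[0, \pi/2]$;
* **Integral leaf-skeleton area** $\left| \int_a^b (p(x) - f(x))\,dx
  \right|$ with $f$ the chord — the enclosed area, evaluated analytically
  (polynomial antiderivative); the absolute value is taken because a curve
  dipping below its chord would otherwise report a negative area.  Large
  values relative to the chord indicate drooping.

**Stem angle**: the stem axis is the least-squares line through all
junction coordinates with $x$ regressed on $y$, so a perfectly vertical
stem has slope 0 and angle $\phi = |\arctan(m)| = 0$; regressing $y$ on
$x$ would make the vertical stem a singularity.  At least two junctions
are required.  All angles are radians.

## Ground truth and accuracy

Ground truth uses the UNL-CPPD XML dialect: a `plant` root with `id`,
`base{x,y}` and repeated `leaf{id, status, tip{x,y}, collar{x,y}}`
elements; `status` is the closed vocabulary alive / dead / missing, and
coordinates serialize as integer pixel positions, so
`read_gt_xml(write_gt_xml(x))` is the identity.

`match_leaves()` pairs detected and annotated leaves one-to-one on tip
coordinates within a 15 px radius (the dialect does not define how a
detection is declared wrong; coordinate matching against annotated tips is
the natural operationalization).  The assignment maximizes the number of
matched pairs via augmenting paths, preferring nearest pairs — a
closest-first greedy can drop a feasible match when two detections collide
on one tip.  `missing` leaves are unmatchable and excluded from the
ground-truth count.  Plant-level accuracy over a sequence of $n$ images is

$$\mathrm{accuracy} = \frac{1}{n} \sum_{i=1}^{n}
  \frac{N_{d,i} - N_{f,i}}{N_{G,i}},$$

with $N_d$ detected, $N_f$ falsely detected and $N_G$ annotated leaves per
image; `plant_level_accuracy(..., mode = "aggregate")` gives the pooled
$(\sum N_d - \sum N_f)/\sum N_G$ form in which per-sequence benchmark
tables are usually printed (published per-sequence values are consistent
with either form to ±0.01; some printed rows appear truncated rather than
rounded, and both interpretations are accepted by the consistency tests).
`cppd_benchmark()` ships the published per-sequence counts of the
UNL-CPPD benchmark for exactly these arithmetic checks.

## The per-day effects model

For response $h$ (PAD, $BA_{CH}R$ or $PAR$), block $i$, plant $j$ and day
$t$:

$$y_{h,ij,t} = \mu_{h,t} + \alpha_{h,i,t} + \gamma_{h,\nu(i,j),t} +
  \epsilon_{h,ij,t},$$

fitted independently per day by ordinary least squares under reference
(treatment) coding: the first block and the benchmark genotype have effect
exactly 0, so each $\alpha$ is a difference from the reference block and
each $\gamma$ from the benchmark genotype.  Intervals are t-based with the
residual degrees of freedom; no multiplicity correction is applied, and no
longitudinal correlation structure is imposed — days are separate fits by
construction.  The identifiability constraint for blocks is not dictated
by the model statement; reference coding is used for both factors for
symmetry.  `tidy()`/`glance()` return the estimates broom-style;
`block_contrast()` gives $\alpha_a - \alpha_b$ with its interval and
`genotype_series()` the per-day genotype trajectories
(`plot_genotype_series()` renders them with confidence bars).

`simulate_phenotype_table()` generates balanced designs (genotypes
cyclically assigned within blocks, so the factors are never confounded)
with known effects — the oracle for the exact-recovery and
interval-coverage tests.

## The synthetic plant generator

Real benchmark rasters run to gigabytes; the generator stands in for them
so the whole pipeline is testable from code.  A `plant_spec` holds a stem
(near-vertical, tilt up to ±0.06 rad) and an ordered list of `leaf_spec`s.
Leaf $i$ emerges on a known day on the side opposite its predecessor, at a
collar a fixed height up the stem, and elongates at a constant rate until
its maximum length.  Each center-line is a **quadratic Bézier curve**
leaving the stem at `init_angle` above the horizontal, with total tangent
rotation `arch · length · (1 + droop)` (capped at 1.3 rad); the control
polygon is scaled so the *analytic* arc length equals the intended length
exactly.  This choice is what makes the generator an oracle: the curve's
arc length, curvature ($|B' \times B''|/|B'|^3$) and curve–chord area
(two thirds of the control-triangle area) all have closed forms
independent of the skeleton-and-fit measurement path.

Rendering stamps the center-lines at sub-pixel spacing and dilates with a
disc to a 5 px stroke — thick enough that thinning recovers the
center-line, thin enough that neighboring leaves never merge.  The plant
color sits inside the segmentation HSV band (H 0.33, S 0.45, V 0.55) and
the background outside it (H 0.60, S 0.15, V 0.92), so segmentation
defaults apply unmodified.  The stem is drawn up to the newest emerged
collar, which is where the visible "stem" of a real maize plant ends (the
whorl); a consequence is that the newest leaf's detected collar is the
junction below until the next leaf emerges, a bias the tracking and the
validation statistics are designed around.

Default sampling ranges (`default_plant_ranges()`): first leaf on day 1–2
and a new leaf every 2–4 days (the pacing of vegetative-stage maize imaged
daily, roughly leaf 1 at the start and leaf 11 by around day 19); collars
24–30 px apart starting 18–26 px up the stem; elongation 6–12 px/day to a
maximum of 70–110 px; `arch` 0.004–0.010 /px and `droop` 0.2–0.6
(older/longer leaves arch more); emergence angle 0.45–0.85 rad.  On a
320×240 frame with the base at row 300, these keep six leaves within the
frame and guarantee the no-crossover property (same-side leaves are two
collar gaps apart, more than any leaf's vertical rise).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: photorealistic texture, shadows, soil and pot,
blade width (strokes are constant-width), leaf senescence, wind motion,
self-occlusion (unless the `crossover` flag is set, and then only to test
refusal), and 3D consistency between the 0° and 90° views, which are
rendered as independent projections with per-leaf foreshortening factors.

## Numerical choices and degenerate inputs

* Quadrature: `integrate()` at relative tolerance $10^{-6}$ (leaf length);
  polynomial areas are exact antiderivatives.
* Fits: `lm.fit` on the $[0,1]$-rescaled Vandermonde basis; aliased
  coefficients (collinear sample points) are zeroed.
* Tie-breaks: bottom-row tie for the base → leftmost column; equal hull
  areas → 0° view; equal apex distances within $10^{-6}$ → all reported.
* Degenerate inputs raise typed conditions rather than returning NA:
  empty masks (`empty_input`), multi-component masks, cyclic graphs
  (`unsupported_topology`), leaves with coincident junction and tip
  (`undefined_chord` / `degenerate_leaf`), fewer than 2 junctions
  (`insufficient_junctions`), fewer than 3 path points
  (`insufficient_points`), images with zero annotated leaves in the
  accuracy denominator.
* Determinism: all sampling goes through a seed-preserving wrapper;
  rendering is purely geometric; simulated dataset trees are
  byte-identical across runs (the manifest stores relative paths).

## Validation study sizes

The packaged tests validate the pipeline end to end on 50 sampled
no-crossover plants × 20 daily frames (1000 frames: leaf-count agreement,
median leaf-length error, final-day stem-angle error, and mask IoU against
the renderer truth), 1000 random count vectors for the accuracy formula,
100 randomized XML round trips, and 1000 simulated datasets for the
confidence-interval coverage of the effects model.  The same quantities
are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* Frames whose skeleton graph is cyclic (leaf crossover, self-occlusion)
  are refused, logged and skipped — late vegetative stages with heavy
  crossover will lose frames.
* Leaf geometry assumes each leaf is single-valued along its fitted axis;
  a leaf curling back past vertical in both axes would fit poorly (the
  RMS residual in `leaf_geometry` exposes this).
* The newest leaf's length is biased upward by one collar gap until the
  next leaf emerges (collar indistinguishable from the junction below).
* Pixel units throughout; no camera calibration to millimeters.
* Single plant per frame; no tassel/ear detection; no pixel-level leaf
  segmentation (only the center-line skeleton).
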