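---
title: "Tracking muscle fibers in diceCT stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking muscle fibers in diceCT stacks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myotrace)
```

## The problem

Diffusible iodine-based contrast-enhanced CT (diceCT) renders soft tissue
radiopaque, so muscle fascicles appear as bright tubular tracks separated by
darker interstitial tissue. Muscle architecture — fascicle length,
orientation, curvature — drives estimates of muscle force and function, but
manually digitizing hundreds of fascicles per muscle is prohibitively slow.
`myotrace` reconstructs fascicle paths automatically from a segmented,
isotropic, single-muscle grayscale PNG stack, on the assumption that
radiopacity varies least *along* a fascicle: a walk that follows the path of
least grayscale variation follows the fiber.

## The tracking model

From each seed point the tracker walks forward, then backward, through the
image sequence. At every step it projects a spherical cap of candidate
offsets — all integer offsets $(dx, dy, dz)$ with $\lVert v\rVert_2 \le r$
and $dz \ge 1$ (or $dz \ge -b$ when `backstep` $b \ge 1$ admits in-plane and
backward moves) — rasterizes the straight voxel path to each endpoint with a
3-D DDA, and scores each path:

* grayscale values below `cutoff` are set to 0 (black);
* the path score is the sample standard deviation of the masked values;
* a *trajectory penalty* in $[1, 2]$ is formed by min–max scaling, across the
  candidate set, of each endpoint's Euclidean distance from the point the
  previous step direction would have reached, then adding 1;
* the *diagnostic value* is $\mathrm{scaled\ SD} \times \mathrm{penalty}^{\mathrm{scalar}}$,
  and the candidate minimizing it is taken.

SDs are scaled to $[0,1]$ by dividing by the candidate set's largest SD, not
by min–max normalization. This is deliberate: min–max scaling maps the
smallest SD to exactly 0, so the lowest-SD candidate would always win and
the trajectory penalty could never influence the decision, contradicting the
penalty's documented purpose (and making `scalar` a dead parameter). Scaling
by the maximum preserves proportionality, so a straight continuation with a
slightly higher SD can beat a sharply deviating path with a slightly lower
one. Ties in the diagnostic value resolve to the candidate with the smallest
trajectory deviation, then to cap enumeration order, so every walk is fully
deterministic.

### Stop conditions

A walk ends when (evaluated in this order at each step):

1. no candidate endpoint remains inside the stack (`stack_edge`);
2. the black-voxel fraction pooled over *all* candidate paths reaches
   `black_frac` (default 0.95) — the signature of the noisy end of a
   fascicle (`black_fraction`);
3. every path crosses more than `allowed_black` black voxels
   (`black_paths`);
4. every surviving path ends within `bound_buffer` voxels of the muscle's
   external boundary (`boundary`).

The boundary map is an erosion of the nonzero-support mask by a discrete
Euclidean ball of radius `bound_buffer`: a voxel is safe iff no zero voxel
(or stack face) lies within that distance. Evaluating condition 2 before
condition 1 means a walk surrounded almost entirely by blackness reports
`black_fraction` even when a stray path would also have failed condition 1;
the order is fixed and documented rather than meaningful.

### Keeping walks finite: retrace rules

With `backstep` $\ge 1$ the candidate set no longer forces progress through
the stack, and two failure modes appear: a walk that reaches a fiber's end
can wander indefinitely in the bright cross-section, and it can wrap around
the fiber tip and re-track the same fascicle in reverse. Three rules,
applied only to candidate validity, prevent this:

* **first-step advance** — the first step from a seed must strictly advance
  (`dz * direction >= 1`); a walk's direction identity comes from its first
  step, and backstep moves only make sense once a trajectory exists;
* **turn gate** — a step may not turn more than `max_turn_deg` (default 90°)
  from the previous step direction; curvature accumulates freely across
  steps;
* **self-avoidance** — each accepted step claims the voxels within
  `self_avoid` of its rasterized path, stamped with the step index
  (first claim wins), and a candidate endpoint in territory claimed more
  than `self_avoid + 1` steps earlier is invalid. The recency window keeps
  the corridor just ahead of the walk open (with unit steps, a voxel ahead
  was first claimed at most `self_avoid` steps ago), while territory from
  an earlier pass is sealed. The forward and backward walks of one fiber
  share a claim map, so the backward walk cannot re-track what the forward
  walk covered.

`self_avoid` should be a little *more* than the fascicle radius: the
claimed ball must also cover the boundary-adjacent corridor beside the
walked path, otherwise a finished walk can slip around the fiber tip along
the far side of the same fascicle. The default (5 voxels) suits fascicles
of roughly 3-voxel radius; scale it with your data.

### Why walks crawl, and why that is acceptable

Short candidate paths (2–3 voxels) estimate the SD from very few samples,
so among hundreds of candidates the minimum SD is usually a lucky short
path; inside homogeneous bright tissue the walk therefore advances in
small, slightly wandering steps rather than radius-length jumps. With a
strictly forward cap this costs only runtime; spline smoothing removes the
wiggle. The retrace rules above exist precisely because this small-sample
bias makes the un-gated walk a random walk once `backstep` removes the
forward constraint.

## Seeding

Within each chosen plane, all pixels with gray $\ge$ `threshold` are
clustered by UPGMA (average linkage, `stats::hclust`) on Euclidean
distances; the tree is cut into as many clusters as seeds requested and one
member per cluster is drawn uniformly at random. This spreads seeds over
the whole cross-section while randomizing exact positions. Each plane uses
an RNG substream seeded `start_seed + plane`, so adding planes never
reshuffles existing ones; the within-cluster draw is without replacement
(one member per cluster). Pixel sets beyond 20,000 are subsampled with a
loud warning — the distance matrix is quadratic — and raising `threshold`
is the better remedy.

## Smoothing

Raw tracks are stepwise polylines. Each coordinate is fitted by least
squares on a natural cubic spline basis (`splines::ns`, `df` degrees of
freedom, `df - 1` interior knots) against $t$ = normalized cumulative chord
length; chord-length parameterization is robust to the uneven step sizes
the variable-radius walk produces. `df = 1` is special-cased to an exact
straight-line least-squares fit; `df = 2` admits one arch, `df = 3` an
S-shape. The curve is evaluated at `max(50, 10 n)` uniform parameters, and
the mean Euclidean distance from the raw points to their fitted positions
is recorded as `mean_residual`.

## Processing

* `quality_check()` removes fibers whose quality ratio — SD of raw-track
  gray values divided by raw-track length, i.e. gray variation per unit
  length — is a Tukey-fence outlier (> Q3 + 1.5 IQR), re-evaluating the
  fence until no outlier remains so the filter is idempotent; then fibers
  shorter than `min_length`, if given. The raw-track (not smoothed) length
  is used in the denominator because the ratio diagnoses the raw walk.
* `check_overlap()` removes redundant fibers tracked from different seeds
  in one fascicle: fibers are swept longest-first and discarded when their
  redundancy distance to a kept fiber is within `min_vox`. The distance is
  the *smaller* of the two directed mean nearest-neighbour distances
  between dense curves: a short fiber lying along part of a longer one is
  redundant even though the symmetric average would be inflated by the long
  fiber's unshared stretch.
* `fuse_fibers()` joins partial tracks of one interrupted fiber: pairs with
  closest raw endpoints within `min_vox` (closest first) are concatenated
  end-to-start and re-smoothed, and the merge is kept only if the result is
  strictly longer than either part with a mean residual no worse than the
  worse part; repeated to a fixed point. De-duplication runs *before*
  fusion in `run_pipeline()`: fusing two redundant copies of one fiber
  would concatenate them back-to-back into a doubled track that the
  residual test must then catch — removing the copies first avoids the
  hazard entirely.

Set `min_vox` to about half an average fascicle width. Larger values make
adjacent parallel fascicles look redundant and delete real fibers.

## Metrics and export

Lengths are dense-polyline lengths (× `res`, the isotropic physical voxel
size, when given). Orientation is the angle between the endpoint chord and
a reference axis, folded to [0°, 90°] since fibers are unoriented; the
chord (not a principal axis) matches the axis-comparison framing and stays
well defined for curved fibers. Tortuosity is arc length over chord length
(the standard tractography definition), 1 for straight fibers, $\pi/2$ for
a semicircle.

STL export sweeps each dense curve into a closed tube (default radius 1
voxel, 8-gon cross-section) using parallel-transport frames, which avoid
tube twist at inflections; with `s` segments and `c` sides each tube has
$2cs + 2c$ triangles and every edge borders exactly two of them. Binary
STL is the default, ASCII behind a flag. Rendering is a static orthographic
projection (headless-safe and deterministic); interactive viewing is best
done on the exported STL in a mesh viewer.

## The phantom generator

`generate_phantom()` builds the test substrate: straight, arc or helical
tube fibers on a grid (center spacing `2 * tube_radius + spacing`, so tubes
never touch), rendered by distance to the analytic centerline — fiber
tissue within `tube_radius`, interstitium within `tube_radius + spacing`,
black background outside — with Gaussian gray levels (fiber 0.8 ± 0.05,
interstitium 0.25 ± 0.05, voxel noise 0.02) chosen so a conservative
threshold 0.7 / cutoff 0.65 separates the classes cleanly. Fibers have
*flat end caps* (voxels whose nearest centerline sample is an endpoint are
not fiber tissue): a fiber's bright extent then equals its analytic length,
without which "ground-truth length" would be ambiguous by two cap radii.
Ground truth includes dense centerlines plus analytic length, chord angle
and tortuosity.

What the phantom does *not* emulate: staining gradients, ring artifacts,
partial-volume blur at fascicle boundaries, fascicles of varying diameter,
and branching. Passing phantom recovery therefore shows the algorithm is
implemented correctly and behaves as designed on resolvable, well-separated
fibers; it does not certify performance on noisy or unevenly stained scans.
Fibers run mainly through the image sequence, the orientation the tracker
is designed for; an `in_plane` option lays them parallel to the image plane
to reproduce, qualitatively, the known failure mode of grayscale trackers
in that geometry.

Validation problem sizes (used by the test suite and
`scripts/acceptance.R`): 10 straight tubes of length 60 voxels (radius 3,
spacing 4) seeded with 40 seeds over two planes, and 6 arcs of radius 20
and extent $\pi/2$ (length $10\pi \approx 31.4$, tortuosity 1.1107) seeded
with 12 seeds over six planes with `backstep = 1` and `df = 2`. Straight
recovery achieves full detection with mean absolute length error of a few
percent; arc recovery lands within several percent on length and within a
few percent on tortuosity. Exact figures for a given seed are computed, not
quoted: run the acceptance script.

## Parameter defaults at a glance

| parameter | default | meaning / rationale |
|---|---|---|
| `threshold` | 0.7 | seed pixels; conservative so seeds sit in bright fascicle cores |
| `cutoff` | 0.65 | tracking black level; at or below `threshold` |
| `radius` | 7 | cap radius (1–11); 5–9 works for most data, smaller for tight curves |
| `backstep` | 0 | 0 = strictly forward; 1+ admits in-plane/backward steps |
| `scalar` | 1 | trajectory-penalty exponent; 0 disables penalization |
| `allowed_black` | 0 | black voxels a path may cross; raise for noisy scans |
| `black_frac` | 0.95 | pooled black fraction that ends a walk |
| `bound_buffer` | 5 | minimum distance to the muscle boundary (suggested 2–5); the top of that range keeps walks off boundary tissue and trims end overshoot |
| `self_avoid` | 5 | claim radius; a little more than the fascicle radius |
| `max_turn_deg` | 90 | per-step turn limit |
| `min_track_points` | 3 | shorter tracks cannot be splined |
| `df` | 1 | spline flexibility; 2–4 for curved vertebrate fibers |
| `min_vox` | 8 | fuse/overlap gate; ≈ half a fascicle width *in your data* |
| `res` | — | physical voxel size; converts lengths and scales STL |

## Numerical choices and degenerate inputs

* Rasterization rounds with `floor(x + 0.5)`, not `round()`: R's
  round-half-to-even is not invariant under integer translation, which
  would break the precomputed relative candidate paths (and oracle
  agreement). The DDA samples at `max(|dx|,|dy|,|dz|)` equal steps, giving
  Chebyshev + 1 voxels and exact reversal symmetry.
* All-equal SDs scale to all-zero, so the decision falls to the deviation
  tie-break (prefer the straighter candidate, then enumeration order).
* An all-equal deviation set (including the first step, which has no
  trajectory) yields penalty 1 everywhere.
* `equalize_stack()` is a global min–max stretch, not histogram
  equalization: the named operation's algorithm is unspecified in the
  field's tooling, and a monotone stretch is the only choice under which
  threshold semantics survive equalization.
* Cropping records offsets satisfying `original = cropped + offsets`
  (negative when black padding had to be synthesized at a touched face), so
  realignment is exact integer arithmetic.
* 16-bit PNGs normalize by 65535, 8-bit by 255; RGB slices collapse to the
  channel mean with a warning.
* A seed on a post-cutoff black voxel, or a merged track shorter than
  `min_track_points`, produces no fiber; this is why the fiber count is at
  most the seed count.

## Known limitations

* The boundary map and the per-walk claim map are full-volume arrays (one
  logical / one integer per voxel). Grayscale slices respect the
  `radius + backstep + 1` streaming budget, but these two masks do not
  stream; for very large scans they add ~8 bytes per voxel.
* Fibers lying parallel to the image plane track poorly (the candidate cap
  is anisotropic in `z`); reorient the stack so fibers pass through the
  image sequence, as the `in_plane` phantom demonstrates.
* The SD of 2–3-voxel paths is a noisy estimator, so walks wander at the
  voxel scale; smoothing absorbs this, but raw tracks should not be used
  for curvature estimates directly.
* `fuse_fibers()` cannot merge two partial tracks that overlap along their
  shared stretch (concatenation would double it); overlapping partials are
  instead resolved by `check_overlap()` keeping the longest.
* Orientation uses the endpoint chord; for strongly S-shaped fibers the
  chord may not represent any local fiber direction.
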