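---
title: "Tracing DNA topology in AFM height maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing DNA topology in AFM height maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topotrace)
```

## The problem

Atomic force microscopy resolves individual DNA molecules deposited on mica
as ridges about 2 nm high in a calibrated height map.  For molecules that
cross themselves or each other — knots, catenanes, supercoiled plasmids,
replication intermediates — the planar path alone does not determine the
molecule's topology: at every crossing one duplex passes over the other, and
the set of over/under choices is exactly what distinguishes, say, a 5-node
torus knot from a pair of unlinked circles.  AFM records genuine height, so
that information is present in the image; `topotrace` extracts it
automatically.

The pipeline runs: flatten → mask → height-biased skeletonisation → crossing
node detection and merging → branch pairing → crossing-order calling by FWHM
→ trace ordering and molecule separation → crossing-diagram extraction →
Jones-polynomial classification in Rolfsen notation → morphometrics and data
cleanup.  A seeded pseudo-AFM generator produces ground-truthed synthetic
images of every supported topology so each stage, and the whole chain, is
testable without instrument data.

## Crossing order from height profiles

A duplex passing *over* another bridges the crossing in a wide "humpback"
profile, while the under-passing duplex shows only a narrow spike where the
other strand covers it.  For each crossing node the emanating branches are
paired by exact maximum-weight matching on their propagation vectors (most
anti-parallel branches continue through each other), and the height profile
is traced along each paired path through the crossing.  The pair with the
larger full width at half maximum (FWHM) is called over-passing.  FWHM is
used rather than mean height or area because it is robust to nearby nodes
and nicks and needs no model fitting.

Numerical choices worth stating: the half-maximum level is measured from the
*profile minimum* (the duplex shoulder at the edge of the clipped crossing
region), not from the image background.  With the background as baseline,
both strands of a crossing whose apex is about twice the duplex height sit
above the half-maximum along the entire clipped trace and the measurement
saturates; the local baseline keeps the over/under contrast.  A peak must
still rise above the flattened background, and a peak prominence below
0.1 nm — far below any crossing signal, at the level of filter ripple —
marks the crossing as carrying no crossing-order information (a crossing
compressed to single-duplex height), flagged degenerate with reliability 0.

Each crossing gets a *crossing order reliability*: all unordered pairs of
duplex FWHM values contribute `1 - min/max`, averaged over the pairs.  Equal
widths give 0; the default reporting threshold is 0.263.

```{r cor}
crossing_order_reliability(c(0.2, 0.5))
crossing_order_reliability(c(0.2, 0.5, 0.7))
```

## Height-biased thinning

Standard Zhang–Suen thinning erodes boundary pixels symmetrically and lands
on the geometric centre of the mask, which at bulging crossings can sit off
the actual molecular backbone.  The biased variant pools the deletable
boundary pixels of both sub-iterations each round, deletes them one at a
time in ascending height order (re-checking deletability against the current
image so topology is preserved), and spares the highest candidate tier of
each round.  Erosion therefore consumes the lower flank first and the
surviving single-pixel line settles on the height crest.  When all
candidates share one height there is nothing to bias and a classic
simultaneous iteration keeps the erosion symmetric, so constant-height
ridges still thin to their medial line.  Ties in deletion order are broken
by raster order for determinism.

Terminating branches shorter than 15 % of the skeleton or whose centre
pixel lies more than 0.85 nm (the depth of the DNA major groove) below the
backbone mean height are pruned, repeatedly until stable.  The height rule
compares against the mean of the *backbone* (skeleton excluding terminating
branches): a low spur on a tall loop should be pruned regardless of how much
of the skeleton it makes up, and including branch pixels in the mean would
let a long spur drag the threshold down and save itself.

## Nodes, junctions and molecule separation

Skeleton pixels with three or more neighbours are grouped into nodes;
nodes within 7 nm (about twice the tip-convolved DNA width) are merged
together with the skeleton path joining them, and the shortest path between
two odd-branched nodes is absorbed so crossings split by segmentation
reunite with even parity.  Four-branch nodes are crossings; three-branch
nodes are junctions — replication forks — and are never paired.  Ordered
traces follow branch pairings through each crossing, assigning
pseudo-heights as ascending integer ranks per node (1 = deepest under).
Leftover segments seed further molecules, which is how the two circles of a
catenane separate.  Where the two strands' paths through a node share a
pixel, the second pass is nudged 0.35 px off the lattice in the trace
output so the projected polylines cross transversally; consequently every
connecting-segment pixel appears in exactly one molecule while crossing
regions are shared between the strands that traverse them.

## Classification

The XY path of each closed molecule, with pseudo-height deciding the over
strand at each self-intersection, gives a planar crossing diagram
(sign convention: positive when the 2D cross product of over- and
under-tangent is positive).  Reidemeister I/II reductions strip trivial
self-crossings, the Kauffman bracket is summed over all `2^n` smoothings
(refused above 14 crossings rather than approximated), normalised by writhe
to the Jones polynomial, and matched against a reference table.  The table
is computed at first use from exact diagrams of the families the Xer
recombination system produces — torus knots 3_1, 5_1, 7_1 (closed 2-braids),
twist knots 4_1, 5_2, 6_1, 7_2 (4-plats of the rational tangles C(k, 2)) and
the torus links 2^2_1, 4^2_1, 6^2_1 — and each entry is verified against the
knot determinant `|V(-1)|` when built.  Composite knots and anything outside
the table report `unclassified`.  Restricting the table to these families
(rather than all prime knots to 7 crossings) is a deliberate scope choice:
within it, Jones polynomials are distinct and the determinant check pins
each reference diagram.

Because strand direction is unknowable from a topograph, link polynomials
are pooled over component orientations, and chirality is reported with a
`*` for mirror forms where the polynomial distinguishes them
(anchored so the unstarred form has its Jones polynomial in negative powers
of t, the usual table convention).  For the Hopf link the pooled polynomial
cannot see handedness at all, and the chirality flag says `ambiguous`.

Per-crossing reliabilities propagate into the result: the classification
after inverting the single least reliable crossing is reported as the
alternate label, which recovers molecules whose one ambiguous crossing was
mis-called.

```{r classify}
d <- diagram_from_curves3d(topotrace:::torus_curves(2L, 4L, 2L))
glance(classify_diagram(d))
classification_probability(d, p = 0.82)
```

## The synthetic generator

`synth_spec()` + `make_curve()` + `render_pseudo_afm()` emulate deposited
DNA: a parametric closed curve (torus knots/links, 4-plat twist knots,
circles, theta structures, figure-of-8 intermediates) is scaled so its
XY-projected length matches the target contour length — the deposited
molecule lies in the surface plane, the z component only encodes stacking —
then projected, rasterised as a 2 nm ridge with a 2 nm core width, elevated
at crossings (the over strand's apex rises toward twice the duplex height,
reduced by `crossing_compression`; at 1 the crossing flattens to
single-duplex height and the crossing-order signal is gone), dilated by a
5 nm tip radius (grey-scale disc dilation emulating tip convolution),
Gaussian-smoothed, and overlaid with i.i.d. Gaussian pixel noise.  Every
spec is classified at generation time by projecting the exact curve through
the same diagram machinery, so ground-truth labels are verified, and the
seed fully determines the render (placement jitter and noise included).

Default study conditions: 768 nm contour for 2260 bp plasmid-sized knots
(0.34 nm/bp), 561 nm total for the 4-node catenane, 1 nm/px, noise 0.15 nm
for the noisy condition, compression 0.9 for the compressed condition, and
a third of the contour length for the clustered condition (which forces
crossings inside the 7 nm merge distance).

What the generator does *not* emulate: polymer mechanics of deposition
(conformational ensembles come from a Langevin model outside this package's
scope), scanner drift and feedback artefacts beyond simple scar streaks,
ssDNA/dsDNA height differences, and unequal catenane circles.  Passing the
synthetic suite therefore demonstrates the correctness of the analysis
chain on idealised but tip-convolved, noisy images — not performance on
every real-world deposition pathology.

## Measurements and cleanup

Contour length is the sum of trace step lengths (1 px axial, sqrt(2)
diagonal) times the pixel size, closing step included for closed molecules.
An 8-connected chain systematically overestimates a smooth curve's length
by several percent, so the pipeline's reported lengths use a circular
moving average of 5 px on the path first; raw step sums remain the default
of `contour_length()`.  The test suite verifies that lengths on the clean
synthetic suite stay within 7 % of ground truth.

Replication intermediates are analysed by breaking the skeleton at
odd-branched junctions: exactly two forks and three segments make a theta
structure, whose unreplicated segment is the one most dissimilar in length
from the other two (ties resolved toward the shortest, which the
bidirectional-replication geometry makes the natural coincident answer; a
margin below 5 % of the mean flags low confidence, and the shortest-segment
answer is always reported alongside).  Reversed forks are 4-way junctions
with exactly one terminating arm shorter than 50 nm.  Conformation classes
(open / taut / clustered / bow-tie) are a user-editable rule table on node
count and branch multiset, defaults documented in `conformation_rules()`;
they are a heuristic, not a measurement.

Cleanup steps (empty contour, linear molecules, clustered crossings,
unexpected molecule count) are applied per analysis mode exactly as
documented in `cleanup_filter()`, with per-step removal counts logged.

## Problem sizes and determinism

The synthetic suite renders molecules of 400–900 nm at 1 nm/px (images
about 250–350 px square), where a full pipeline run takes well under a
second; the validation sweep covers six topologies across 50 seeds.  The
bracket state sum is exact up to 14 crossings; misclassification
enumeration up to 20.  The analysis path contains no randomness; all
generator randomness derives from the spec seed, so runs are reproducible
bit for bit.

## Known limitations

Molecules stacked over extended regions are not resolvable; clustered
crossings (more than two duplexes in one merged node) are excluded from
topology rather than guessed; the conformation rule defaults are heuristics;
chirality of classified links is reported only up to the orientation
ambiguity inherent in an unoriented topograph; and the knot table covers
the torus and twist families up to 7 crossings, not all prime knots.
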