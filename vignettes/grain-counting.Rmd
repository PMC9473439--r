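---
title: "Counting touching crop grains on white paper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting touching crop grains on white paper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graincountr)
```

## The problem

Thousand-grain weight, a standard yield and seed-quality indicator, needs
an exact count of several hundred seeds. When seeds are scattered on white
paper and photographed, a global threshold recovers the seed pixels
reliably, but touching seeds merge into single connected regions, and the
shape, size and colour of the seeds differ by crop. `graincountr`
implements a counting pipeline designed to work across wheat, corn, mung
bean, soybean, peanut and rapeseed with one parameter set.

## The model

### Binarization

The photograph is downscaled so its long side is
`target_long_side = 1920` px (area-average resampling; images already at
or below the target are never upscaled, since upscaling adds no
information and would change the pixel scale of every later parameter).
After grayscale conversion and 5×5 Gaussian smoothing, a global Otsu
threshold splits seed from paper. Polarity is decided by border occupancy:
of the two Otsu classes, the one covering the smaller share of the image
border is the seed class, which makes the pipeline indifferent to dark
seeds on light paper versus the inverse. Components below
`min_blob_area = 9` px² are discarded as sensor noise; at the 1920-px
working scale even rapeseed (the smallest preset) is two orders of
magnitude above this floor.

### Short-axis-adaptive erosion

The separation step rests on one geometric observation: where two convex
seeds touch, the union is locally *narrower* than either seed core. Each
region is thinned to a one-pixel, topology-preserving skeleton (sequential
directional peeling that only removes simple points, so components and
holes survive). At every skeleton pixel, the local seed width is twice the
Euclidean distance to the nearest background pixel; the maximum over the
skeleton is the region's short axis $X$ — for a single convex seed this
is its minor-axis width. The region is then eroded by a disk of extent

$$e = w X, \qquad w = 0.4$$

implemented exactly by thresholding the distance transform at $e$.

The extent is used as the erosion *radius*. That choice is what gives the
coefficient $w$ its documented sweet spot: a seed core survives erosion
only while the radius stays below its half-width $0.5X$, so $w = 0.4$
removes every neck that is thinner than 80% of the seed width while never
deleting a seed, $w \ge 0.5$ begins to delete whole seeds (first in
clusters, where $X$ reflects the widest member), and small $w$ leaves
pairs merged. The package's coefficient sweep (`sweep_w()`) reproduces
exactly this tradeoff on a synthetic adhesion benchmark. Two numerical
guards handle discretization: fragments whose peak depth does not exceed
$e + 1$ px are slivers of the jagged threshold contour and are dropped
(keeping at least the deepest fragment), and if erosion would empty a
region entirely the extent is halved until a pixel survives, so a region
can split but never disappear.

Erosion is applied per region, each with its own $X$: a global extent
would over-erode small seeds whenever large seeds are present.

### Corner-point counting

Fragments define the split lines, but counting geometry stays on the
*original* region outline: erosion destroys the concavities the corner
formula depends on, so where a region fell into several fragments the
original pixels are partitioned among fragments by seeded region growing,
and every resulting unit keeps its true boundary.

Each boundary pixel of a unit is scored by the fraction of seed pixels in
the centred `corner_window = 13` px square. On a convex or straight
boundary this fraction stays near or below one half; in the concave notch
where two seeds meet, the window fills from both sides and the fraction
rises above `corner_fraction = 0.66`. Candidates above the threshold
(strict inequality) are reduced by non-maximum suppression within a
Chebyshev radius of one window side, ties resolved in scan order. Windows
reaching past the photo border treat the missing pixels as background —
the white paper continues past the frame — and are always normalised by
the full window area; normalising by the visible area instead would
inflate the score of seeds lying on the border and mint false corners
(measured: a convex seed touching the canvas edge scores 0.68).

A unit with $C$ corners and $R$ enclosed holes (4-connected background
components not reaching the outside) counts

$$N = C/2 - R + 1 .$$

Every junction between two adhered seeds exposes two concave corners, so
a chain of $k$ seeds has $2(k-1)$ corners and counts exactly $k$; a closed
ring picks up one extra unit from its cycle, which the hole term removes.
Fractional results signal an occluded corner and are rounded half up
(floored at one): a half value means a junction was seen from one side
only, i.e. an undercount.

### Linear adhesions

When two elongated seeds overlap almost end-to-end, one junction corner
is typically hidden and the formula lands on 1.5. Such units are
recognised by their skeleton: total length above
`length_factor = 1.5` times the image-mean skeleton length, and an
included angle at the midpoint of the longest skeleton path inside
`angle_band = [160, 200]` degrees (180° = straight). The angle is measured
between least-squares principal directions fitted to the two halves of the
path, oriented along it. Units so flagged are counted by the average-area
rule, area / mean single-grain area, rounded half up. The mean
single-grain area is taken from units whose raw formula value rounds to
one *and* that are not themselves flagged linear (a linear pair also
scores near one and would inflate the mean); when fewer than three such
units exist, the median unit area divided by the median raw value stands
in, with a warning.

## Synthetic scenes and what they do (not) show

`generate_scene()` renders $n$ seeds of one crop preset — ellipses, the
corn wedge (an ellipse clipped by a chord at 70% of its major axis, giving
the flat end that produces corn's notorious false corners), or circles for
rapeseed — at uniform random positions and orientations on paper of
intensity ~N(245, 4) with a mild horizontal illumination gradient
(±2.5 digital numbers by default) and per-seed intensity jitter,
anti-aliased by 2×2 supersampling and quantised to 8 bits. A requested
fraction of seeds is laid out in touching pairs/triples with a prescribed
overlap depth along the contact line; everything else keeps a 6-px
clearance, enforced on the rasterised silhouettes, so the true cluster
structure is known exactly. The pixel scale defaults to 10 px/mm, reduced
automatically so the silhouettes fill about 15% of the canvas. Placement
runs by rejection sampling; an impossible request fails with the achieved
count rather than silently under-filling.

Passing tests on these scenes demonstrates the geometry of the method —
separation, corner topology, the correction rules — under controlled
adhesion with exact ground truth. They do not demonstrate robustness to
real-photo nuisances the renderer omits: specular highlights, shadows
cast by seeds, husk texture and broken seeds, perspective, or JPEG
artefacts.

The standard problem sizes used by the test-suite benchmarks are twenty
scenes of 50–400 grains for accuracy recovery and twelve 40-grain scenes
(six presets × two overlap depths, 60% adhesion) for the coefficient
sweep; both run the full pipeline at the default 1920-px scale.

## Design choices on open ground

* **Width definition.** The short axis is taken as the full local width
  (twice the distance-transform value at a skeleton pixel), making $X$
  equal a single seed's minor axis, which is how the crop presets tabulate
  width.
* **Erosion extent as radius.** Discussed above; the alternative
  (diameter) reading makes seed deletion impossible for any $w < 1$ and
  flattens the coefficient sweep, contradicting the documented behaviour
  of the separation stage.
* **Structuring element.** A Euclidean disk (via the distance transform):
  seeds have no preferred orientation, and disk erosion by threshold is
  exact rather than an approximation by a discrete brush.
* **Corner geometry after splitting.** Corners and holes are measured on
  the pre-erosion outline mapped to fragments (seeded region growing on
  constant intensity, i.e. a geodesic Voronoi partition of the region).
  Units, not original regions, are the counting grain.
* **Rounding.** Half values are rounded up and floored at one, applied
  only when the linear-adhesion rule does not fire; a half value always
  means a hidden junction.
* **NMS tie-breaks** follow scan order, making corner sets deterministic.
* **Border windows** count out-of-frame pixels as background with
  full-window normalisation (see above).
* **Skeleton length** sums unit steps with $\sqrt2$ diagonals after
  removing diagonal edges that shortcut an axial pair, so staircase pixels
  are not double counted.

## Degenerate inputs

Uniform images (degenerate Otsu) return an empty mask with a warning, and
an empty mask counts zero with a warning — neither is an error. A
one-pixel region is its own skeleton with zero length. Regions with
skeletons under three pixels cannot carry an included angle and are never
flagged linear. Convex regions legitimately have zero corners.

## Known limitations

* Clusters of four or more mutually overlapping seeds at deep overlap can
  hide several junctions at once; the corner formula then undercounts and
  the average-area fallback inherits any bias in the single-seed pool.
* Seeds differing strongly in size within one image stress the per-region
  erosion less than a global extent would, but the average-area rule still
  assumes one dominant seed size.
* The renderer's wedge is a stylised corn kernel; real corn shows more
  false corners than the synthetic benchmark does.
* Very small seeds (short axis near the corner window size) can lose one
  of a pair of neck corners to non-maximum suppression; the half-value
  rounding usually absorbs this.
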