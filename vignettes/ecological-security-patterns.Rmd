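---
title: "Constructing ecological security patterns with espmcr"
author: "espmcr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing ecological security patterns with espmcr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`espmcr` builds an ecological security pattern (ESP) for a raster
landscape: it evaluates ecological sensitivity and ecosystem-service
importance cell by cell, extracts large high-value patches as *ecological
sources*, constructs a movement-resistance surface, links the sources with
least-cost *corridors* under the minimum-cumulative-resistance (MCR)
model, locates *pinch points* with circuit-theory current flow, and zones
the territory by ecological safety. This vignette explains the model, its
assumptions, the tunable parameters, the synthetic-data generator used for
testing, and the design decisions taken where the methodology was open.

## 1. Data model

All layers are `esp_grid` objects: a numeric matrix (row 1 = north), a
square cell size in metres, the map coordinates of the top-left corner,
and a nodata sentinel used on disk (`NA` in memory). Two grids are
*aligned* when shape, cell size and origin coincide; every multi-layer
operation requires alignment, and all arithmetic propagates nodata. Cell
values refer to cell centres; patch areas are cell counts times
cellsize². I/O uses the Esri ASCII grid format, which round-trips values,
metadata and nodata exactly; road vectors are plain-text segment lists
(`x1 y1 x2 y2` per line). Reprojection, multi-band imagery and non-square
cells are out of scope: heterogeneous inputs are expected to be resampled
onto one common template (nearest-neighbour for categorical layers,
bilinear for continuous ones) before analysis.

## 2. Sensitivity and service-importance indices

Six assessment factors are first *graded* onto the ordinal scale
{1, 3, 5, 7, 9} (`grade_factor()`), which makes physically heterogeneous
quantities commensurable before they are combined:

| factor | meaning | band cuts (grade 1 → 9) |
|---|---|---|
| `R`  | rainfall erosivity | 532, 560, 583, 604 |
| `LS` | topographic relief (m) | 70, 123, 178, 248 |
| `C`  | vegetation coverage | 0.95, 0.85, 0.75, 0.55 (descending) |
| `K`  | soil texture | categorical, by USDA texture code |
| `I`  | aridity index | 0.55, 0.65, 0.75, 0.85 |
| `W`  | sand-blowing days | 100, 140, 190, 250 |

Bands are left-open/right-closed, so a value on a boundary falls in the
lower band. Rainfall erosivity is the affine sum
`R = Σ_i (−2.6398 + 0.3046 · P_i)` over the twelve long-term mean monthly
rainfalls (mm); months below ≈8.7 mm contribute negative terms, which are
deliberately retained — the subsequent natural-breaks grading is invariant
to the absolute level. Relief is the focal range (max − min) of the DEM in
a 37×37-cell window: an even 36-cell neighbourhood has no centre cell, so
the odd window centred on each cell is used; the difference is one ring of
cells.

The three sensitivity indices are computed **on the grades**, not the raw
values (that is what the 1–9 assignment is for):

* `SSWL = (R·K·LS·C)^{1/4}` — geometric mean, soil-and-water loss;
* `SSE  = (LS + R + K + C)/4` — arithmetic mean, soil erosion;
* `SLD  = (I·W·K·C)^{1/4}` — geometric mean, land desertification.

Both index families are bounded in [1, 9] and, by the AM–GM inequality,
`SSE ≥ SSWL` on identical grades — properties the test suite asserts on
random grade rasters. The composite sensitivity is the weighted sum
`0.43·SSWL + 0.39·SSE + 0.18·SLD`.

The service indices use inputs min–max normalized to [0, 1]:

* `WR = NPP · F_sic · F_pre · (1 − F_sio)` (water retention),
* `Spro = NPP · (1 − K) · (1 − F_sio)` (soil conservation),
* `Sbio = NPP · F_pre · F_tem · (1 − F_alt)` (biodiversity maintenance),

composited as `0.45·WR + 0.30·Spro + 0.25·Sbio`. Here `F_sic` is the USDA
texture code divided by 13 (sandier soils percolate more), `F_sio` is
slope in degrees / 90 with slope derived from the DEM by Horn's 3×3
method, `K` is the texture grade rescaled by 1/9, and `F_alt` is the
normalized elevation. Normalizing the inputs is a design decision: raw
products of NPP, rainfall and temperature would carry arbitrary units,
whereas normalized inputs give indices bounded in [0, 1] (testable
invariants) and the downstream Jenks classification is scale-free either
way. `F_alt` enters only through `(1 − F_alt)` and is implemented as
normalized elevation.

Sensitivity and importance are each min–max normalized and superposed
with equal weights 0.5/0.5 (configurable; equal weighting is the neutral
reading of "spatial superposition"), then all three scores are classified
into five classes by Jenks natural breaks — class 1 "generally important /
low sensitivity" up to class 5 "extremely important / high sensitivity".

## 3. Natural-breaks classification

`jenks_breaks()` implements Fisher's optimal contiguous partition of the
sorted values into `k` classes, minimizing total within-class sum of
squared deviations by dynamic programming (exact, O(k·n²)); the test suite
checks it against exhaustive enumeration of all contiguous partitions for
n ≤ 12, k ≤ 4. Interior cut values are the class maxima;
`classify()` assigns values ≤ the first cut to class 1 and values above
the last cut to class `k`. For rasters with more than 10,000 finite cells,
breaks are computed on a uniform 10,000-value subsample taken in row-major
stride order — deterministic by construction, no RNG involved. Breaks are
computed per layer on all non-nodata cells.

## 4. Ecological sources

Connected components of the extremely-important class are labelled with
8-connectivity (diagonal contact counts, the usual convention for
landscape patch delineation; 4-connectivity is available). Patches whose
minimum edge-to-edge distance is strictly below 500 m are merged
transitively (union–find over the pairwise predicate, distances via one
exact Euclidean distance transform per patch). Merged patches are
multi-part: gap cells stay background, so areas and land-use composition
are not inflated. Patches strictly larger than 8 km² become the ecological
sources, relabelled in order of descending area. Both thresholds follow
the published wording ("less than", "larger than") and are configurable.
Edge-to-edge (rather than centroid) distance was chosen because the
ecological intent of the merge is to aggregate adjacent habitat.

## 5. Resistance surface

Five factors are reclassified onto resistance values {1, 20, 40, 60, 80,
100}: land-use class (forest/grass 20, water 40, cultivated 60, bare 80,
construction 100), vegetation coverage (descending from 100 below 0.15 to
20 above 0.65), slope (20 below 5° to 100 above 35°), and distance to
county roads / highways (20 nearest, rising to 100, then dropping to 1
beyond 800 m / 2000 m). That terminal value 1 — *below* the nearest band's
20 — is preserved exactly as published; a monotone variant replacing 1 by
20 is available behind the `monotone` flag for sensitivity analysis. The
comprehensive surface is the weighted overlay with weights 0.095 (land
use), 0.213 (coverage), 0.236 (slope), 0.118 (county roads), 0.173
(highways).

These printed weights sum to 0.835 and are *not* the principal eigenvector
of the accompanying five-factor pairwise comparison matrix (which is
0.048/0.316/0.371/0.102/0.164). The package therefore treats the printed
values as configuration defaults — reproducing the published scheme — and
exposes `resistance_weights(matrix)` to recompute weights from any
comparison matrix instead. The discrepancy is documented here rather than
silently "fixed".

## 6. AHP

`principal_eigen()` computes the dominant eigenvalue and normalized
eigenvector of a validated reciprocal comparison matrix by power iteration
from the uniform vector (relative tolerance 1e−10, at most 10,000
iterations; deterministic). Consistency follows Saaty:
`CI = (λ_max − n)/(n − 1)` (0 for n ≤ 2), `CR = CI / RI(n)` with the
standard RI table for n = 1…10, and `CR < 0.1` accepted. Matrix files
parse fractional entries (`1/6`) as exact rationals so the reciprocal
invariant holds to machine precision. For the shipped five-factor matrix
this yields λ_max = 5.1883, CI = 0.047, CR = 0.042.

## 7. MCR cost distance, corridors, current flow

The MCR formulation accumulates distance × resistance along paths and
wraps the minimum in an unspecified monotone-increasing function; since
any monotone transform preserves the ranking of paths, it is taken as the
identity. `cost_distance()` runs multi-source Dijkstra on the 8-connected
cell graph with the de-facto cost-distance convention: step cost between
neighbours i, j is `(R_i + R_j)/2 · d`, `d` = cellsize orthogonally and
cellsize·√2 diagonally. Heap pops are ordered lexicographically by (cost,
row, column), making costs, allocations and back-traced paths
deterministic across runs. Nodata cells are barriers; unreachable pairs
yield an explicit *disconnected* result rather than an error.

`corridor_network()` extracts, by default, one corridor per pair of
sources whose cost-allocation regions share a cell edge (the core-area
adjacency used by corridor-mapping tools); `all_pairs` mode connects every
pair. Corridor cost is symmetric in its endpoints and scales linearly
under uniform scaling of the surface (paths unchanged) — both asserted in
tests against an independent relaxation oracle.

`current_flow()` reimplements the circuit-theory pinch-point idea
directly: the corridor swath (cells with
`cost_a + cost_b ≤ (1 + s) · pairwise cost`, default slack s = 0.05, since
no corridor width is prescribed by the methodology) becomes a resistive
network — one node per cell, edge conductance the reciprocal of the
Dijkstra step cost, source-a cells collapsed into a unit-current injection
supernode, source-b cells grounded. The sparse graph-Laplacian system is
solved with `Matrix`; cell current is half the sum of absolute incident
edge currents, so a single-file chain carries current 1 and two equal
parallel chains carry 0.5 each. Tests verify current conservation and
agreement with a dense solve to 1e−8. `extract_nodes()` takes the cellwise
maximum over corridors, splits positive-current cells into general vs
important by a two-class natural break (a constant field admits no split:
all general), and keeps important patches larger than 1 km² as the
important ecological nodes.

## 8. Safety zoning

Zoning is computed on the source-based cumulative-cost surface by default
— the reading most consistent with "the higher the resistance, the lower
the safety" — with `use_raw_surface = TRUE` available to classify the
weighted resistance surface directly. Five Jenks classes are ordered so
class 1 (lowest accumulated cost) is the *high* ecological safety zone.
The default policy mapping sends the low and lower safety zones to the
ecological *restoration* area, medium and higher to *control*, and the
high safety zone to *conservation*; where the source literature labels the
high-safety class both "development" and "conservation", the package
follows the headline (abstract/conclusion) usage and leaves the mapping
fully configurable.

## 9. The synthetic landscape generator

`make_landscape(seed, n_rows, n_cols, cellsize)` emulates the statistical
structure of the real inputs rather than any specific geography:

* smooth random fields (truncated-Gaussian blur of white noise,
  autocorrelation range ≈ 10 cells; separable band-matrix convolution was
  chosen over spectral synthesis for exact cross-platform
  reproducibility);
* a DEM trending high-northwest / low-southeast;
* twelve monthly rainfall layers with a monsoon seasonal profile scaled to
  ≈ 1700 mm yr⁻¹ and an elevation-correlated anomaly;
* NPP and vegetation coverage positively correlated with each other and
  suppressed near roads;
* patchy categorical land use (forest/grass majority near 80%, cultivated
  blobs, water, rare bare spots, construction clustered along roads) and
  soil texture; a few road polylines.

Five high-value patches are planted at fixed layout positions (small
seeded jitter): locally elevated NPP, rainfall, temperature, aridity, wind
and relief, reduced vegetation coverage, radius ≈ 4.5 cells. At the
default 1 km cells each patch spans well above the 8 km² source threshold,
so the planted structure is recoverable by the full pipeline — the
acceptance suite requires ≥ 90% of planted centres to fall inside
extracted sources on a seeded 200×200 landscape. All randomness flows
through one seeded generator whose state is restored afterwards, so
identical seeds give bit-identical bundles and partial regeneration is
impossible by construction.

What the generator does **not** emulate: real coordinate reference
systems, the actual class proportions of any basin beyond the qualitative
bands above, station-based interpolation artefacts (a simple IDW utility
is provided but sits on no tested path), temporal change, or the empirical
correlation structure of real remote-sensing products. Passing tests on
synthetic data therefore demonstrate algorithmic correctness and pipeline
integrity, not calibration to any real landscape.

`make_fixture()` complements the generator with ≤ 12×12 hand-written
cases (catalogued in its help page) whose answers are known exactly: the
300 m / 600 m patch pairs for the merge rule, a uniform corridor surface,
a two-room bottleneck whose neck must carry maximal current, the
six-value Jenks vector, and grading band probes.

## 10. Numerical choices and problem sizes

* Power iteration: relative tolerance 1e−10, ≤ 10,000 iterations.
* Reciprocal validation: relative tolerance 1e−6; weights sum to 1 within
  1e−9.
* Dijkstra tie-break: lexicographic (cost, row, column).
* Jenks subsampling threshold: 10,000 values, stride subsample.
* Laplacian solves: sparse Cholesky via `Matrix::solve`; singular or
  isolated swaths return a disconnected result.
* Composite weights are warned about (and used as given) when they do not
  sum to 1 within 1e−6, since the published resistance weights themselves
  sum to 0.835.
* Degenerate inputs error early: constant grids cannot be normalized or
  classified into more classes than distinct values; empty feature lists
  and all-nodata surfaces are rejected; an absent target class yields an
  empty patch set, and an empty source set after filtering is a warning,
  not an error.

The shipped tests exercise the full pipeline at 200×200 cells (the
acceptance suite) and 64×64 cells (unit tests); both sizes complete in
seconds to a couple of minutes on a single CPU, and the 200×200
configuration is the package's reference study condition for structure
recovery.

## 11. Known limitations

* Only the Esri ASCII grid raster format is supported; there is no
  GeoTIFF reader/writer and no CRS handling.
* `merge_nearby()` computes one distance transform per patch — fine for
  the tens of patches typical after classification, quadratic in patch
  count beyond that.
* Current flow solves one linear system per corridor; very wide swaths
  (large slack values) on large rasters grow the system accordingly.
* The adjacency rule for corridor pairs is a documented approximation of
  the pairing behaviour of interactive corridor-mapping tools; the
  methodology source does not specify how its corridor pairs were chosen.
* Zoning on the cumulative-cost surface vs the raw weighted surface is a
  genuine ambiguity in the methodology; both are provided, one is the
  default.
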