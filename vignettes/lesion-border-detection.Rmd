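---
title: "Density-based lesion border detection with shingled partitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-based lesion border detection with shingled partitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shinglescan)
```

## The problem and the model

Dermoscopy images of pigmented skin lesions are segmented to delineate the
lesion border, the feature dermatologists weigh most heavily when screening
for melanoma. Because a lesion is a dark, dense, irregularly shaped region on
lighter skin, density-based clustering is a natural fit: it finds clusters of
arbitrary shape and labels sparse outliers (hairs removed, dust, sensor
speckle) as noise rather than absorbing them into the lesion.

`shinglescan` clusters the *node set* $D$ — the pixels whose chosen channel
intensity falls at or below a threshold — with DBSCAN adapted to a pixel
grid:

* the distance between pixels $p, q$ is the **Manhattan distance**
  $|p_x - q_x| + |p_y - q_y|$, whose radius-$\varepsilon$ ball is a diamond
  of $\varepsilon^2 + (\varepsilon+1)^2$ pixels — integer arithmetic that
  maps directly onto a raster;
* a node is **dense (core)** when its $\varepsilon$-neighborhood holds at
  least `min_pts` nodes, itself included;
* clusters are the connected components of the dense nodes under
  "within $\varepsilon$" adjacency; a non-dense node within $\varepsilon$ of
  a dense node joins as a **border** member; everything else is **noise**.

Every pixel has a unique id `pid = y * width + x` (0-based, row-major).
Cluster identity is a pid: the smallest pid of any member. This total order
is what lets two completely different execution strategies — a serial sweep
and an iterative, partition-parallel negotiation — be compared bit for bit.

## Two routes, one answer

### The serial oracle

`dbscan_serial()` is the classic algorithm: visit nodes in ascending pid
order, expand a cluster from each unvisited dense node, attach reachable
non-dense nodes as borders. Classic DBSCAN is order-dependent in exactly one
place: a border node within $\varepsilon$ of two clusters joins whichever
claimed it first. We make this deterministic by attributing every border
node to the candidate cluster with the smallest label. One consequence is
deliberately accepted: when border nodes are stolen away, a cluster can be
left with fewer than `min_pts` members; such groups are demoted to noise (in
both routes) under the same rule the classifier uses, so the two routes and
the classifier never disagree about the noise set.

### The partitioned route

`run_pipeline()` re-derives the same answer through independent
per-partition computations:

1. **Shingled partitioning** (`create_partitions()`). The image is tiled by
   core rectangles; each partition's working view extends a *lap region* of
   $2\varepsilon + 1$ pixels past its core to the right and bottom. The lap
   guarantees that every pixel has its complete $\varepsilon$-neighborhood
   inside at least one view. Density judged inside a view can only
   *under*-count (the view is a subset of the image), so "dense in some
   view" is exactly "globally dense" — the property all merging correctness
   rests on.
2. **Iterative minimum-id negotiation** (`scan_once()`,
   `process_partition()`). Every node starts with its own pid as its
   cluster id $C$. Each synchronous pass replaces a dense node's $C$ with
   the minimum $C$ among its dense $\varepsilon$-neighbors (itself
   included), and a non-dense node's $C$ with the minimum over its dense
   neighbors when it has any. Passes repeat until nothing changes; at the
   fixed point every density-connected group shares the minimum pid of its
   dense members.
3. **Transitive merging** (`merge_partitions()`). Pixels in a lap are
   observed by several partitions and may carry different local ids. For
   every *dense* doubly-observed pixel, all the ids it carries (and its own
   pid) are unified in a union-find; the resolved id of a component is its
   minimum element. Non-dense nodes are then attributed to the smallest
   *resolved* candidate cluster, pooled over every view.

### Design choices where the design was open

These points were genuinely open and are the package's own decisions:

* **Synchronous (Jacobi) scans.** A per-pixel-thread formulation leaves the
  read/write interleaving unspecified; asynchronous in-place updates reach
  the same fixed point but make intermediate states schedule-dependent.
  Reading only the previous pass's labels makes each pass a pure function,
  gives a provable pass bound, and makes iteration counts reproducible.
* **Dense nodes negotiate only with dense nodes.** Letting a dense node
  absorb a *non-dense* neighbor's id looks harmless but is not: a non-dense
  pixel lying between two clusters would leak ids from one to the other and
  fuse clusters that classic DBSCAN keeps apart, and border pids would end
  up naming clusters. Restricting the minimum to dense neighbors makes the
  fixed point exactly the classic core components — border membership stays
  what it is in classic DBSCAN: attribution, not identity.
* **Merging unions only dense overlap pixels.** The same reasoning at merge
  time: a shared *border* pixel does not prove two clusters are one, so
  only dense doubly-observed pixels drive unions. Border attribution is
  finalized after resolution because resolution is not monotone in the raw
  id value — a numerically larger local id can resolve to a smaller global
  cluster, so each partition records *all* candidate ids its non-dense
  nodes saw, and the minimum is taken over resolved ids.
* **Convergence test.** The historical formulation compares successive
  checksums (sums of all $C$); a checksum can in principle collide across
  distinct labelings, so the package records the checksum trace for
  observability but declares convergence on elementwise equality.
* **Iteration counting.** `iterations` counts every pass including the
  final no-change pass that detects the fixed point; `moves = iterations -
  1` counts passes that changed labels. On a length-$L$ serpentine with
  $\varepsilon = 1$ the minimum label travels one pixel per pass, so
  `iterations` is exactly $L$; for general $\varepsilon$,
  `moves` $\le \lceil (L+1)/\varepsilon \rceil$ (one lap of label travel
  per pass covers $\varepsilon$ pixels of path).

## Parameters

| parameter | unit | default | role |
|---|---|---|---|
| `eps` | pixels (Manhattan) | 3 | neighborhood radius; larger bridges bigger gaps and thickens the border band |
| `min_pts` | nodes | 4 | density threshold, query pixel included; larger rejects thin structures as noise |
| `channel` | — | `"B"` | channel thresholded into nodes; blue separates pigmented lesions from skin best |
| `threshold` | intensity 0–255 | 128 | node = value ≤ threshold (lesions are dark) |
| `core_width/height` | pixels | 256 | partition core size; any value ≥ 1 gives identical output, smaller cores exercise more merging |
| `workers` | processes | 1 | partitions are independent; results are byte-identical for any worker count |

The `eps = 3`, `min_pts = 4` defaults are the configuration the method's
dermoscopy experiments used. The partition size only trades memory and
parallelism against merge work — it never changes the answer, which the
test suite asserts rather than assumes.

## What the synthetic fixtures emulate

No dermoscopy image set with manual borders is redistributable here, so the
package generates its own inputs (`make_lesion_image()`,
`make_random_mask()`, `make_serpentine()`, `make_split_cluster()`), all
pure functions of a seed:

* **Lesion blobs** model only what the detector consumes: one dark
  *connected* irregular region (largest component of a thresholded smooth
  noise field over a radial gradient) on lighter skin, plus isolated dark
  salt pixels kept more than 4 Manhattan steps from the blob and from each
  other, so at $\varepsilon \le 3$ each salt pixel is a singleton and must
  classify as noise. They do not model hair, specular glare, color
  calibration, or gradual lesion fade-out — so a perfect score on fixtures
  demonstrates the clustering, classification, and metric machinery, not
  clinical accuracy on real dermoscopy images.
* **Random Bernoulli masks** drive the serial/partitioned equivalence sweep
  at densities 0.2–0.7 where cluster topology is most adversarial (many
  touching components, borders shared between clusters).
* **Serpentines** are the worst case for label propagation: a 1-pixel path
  whose non-consecutive pixels never touch, forcing one pass per pixel at
  $\varepsilon = 1$.
* **Split-cluster lattices** cross every partition boundary so every merge
  edge is exercised, including transitive chains.

Problem sizes in the tests and the acceptance script — masks up to
128×128 over a hundred-case sweep, 16×16 partition cores, serpentines to
length 50 — were chosen as the smallest sizes at which every partition
regime (interior, edge, corner, multi-overlap) and every merge pattern
occurs many times per run.

## Numerical and degenerate-input behavior

* All label arithmetic is integer (pids, ids); `Inf` marks non-nodes inside
  the scan state only. Noise is the sentinel `-1`, distinct from every pid;
  non-nodes are `NA`.
* Empty masks, all-node masks, single-pixel masks, partitions smaller than
  the lap, cores larger than the image, and 1-pixel-wide images are all
  defined inputs with tested behavior.
* Ties: border attribution and largest-cluster selection both break ties
  toward the smaller cluster id; with canonical min-pid ids this is a total
  order, so no tie survives.
* The lap must be $2\varepsilon + 1$; the package exposes narrower laps
  only so the tests can demonstrate equivalence *breaking* (a 1-px line
  with `min_pts = 3` and `lap = eps` splits at the partition boundary).

## Evaluation metrics

With the manual mask $M$ as truth and the automatic filled lesion region
$A$ (core ∪ border of the selected cluster — region-wise, not a 1-px
contour):

$$\mathrm{precision} = \frac{TP}{TP+FP},\quad
  \mathrm{recall} = \frac{TP}{TP+FN},\quad
  \mathrm{XOR\ border\ error} = 100\cdot\frac{|A \oplus M|}{|M|}
  = 100\cdot\frac{FP+FN}{TP+FN}\ \%.$$

The border error is normalized by the manual lesion area, is zero iff the
masks agree, and exceeds 100 % under gross over-segmentation. Swapping $A$
and $M$ swaps precision and recall; both identities are tested.

## Known limitations

* Node extraction is a single-channel threshold; real pipelines add hair
  removal and contrast normalization upstream, which are out of scope here.
* `dbscan_serial()` and the per-partition scan are exact but quadratic in
  $\varepsilon$ per pixel; the package targets desk-scale rasters, not
  gigapixel virtual slides.
* Forked parallelism (`workers > 1`) relies on `parallel::mclapply`, which
  degrades to sequential on platforms without fork; results are identical
  either way.

## A worked example

```{r example, eval = FALSE}
fx <- make_lesion_image(128, 128, seed = 7, noise_rate = 0.01)
mask <- extract_nodes(fx$image, channel = "B", threshold = 128)
params <- db_params(eps = 3, min_pts = 4)

cmap <- run_pipeline(mask, params, core_width = 16, core_height = 16)
identical(cmap$labels, dbscan_serial(mask, params)$labels)  # TRUE

cls <- classify_nodes(cmap, mask, params)
region <- lesion_region_mask(cls, cmap, "largest_cluster")
evaluate_masks(region, fx$mask)
```
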