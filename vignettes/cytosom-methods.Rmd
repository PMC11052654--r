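---
title: "Two-level cytometry clustering: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level cytometry clustering: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytosom)
```

## The model

Cytometry samples contain $10^5$–$10^7$ events (cells) measured on a few
to a few dozen markers. Manual gating identifies cell populations by
sequential 2-D thresholding; the automated alternative implemented here
clusters in two stages:

1. an **over-clustering** stage: a self-organizing map with many more nodes
   (default $10 \times 10 = 100$) than expected cell types, which
   quantizes the marker space into fine-grained, spatially organized
   clusters, and
2. a **metaclustering** stage: consensus hierarchical clustering of the
   100 node codes into $k$ metaclusters, which are the objects a
   cytometrist interprets as cell types.

The split matters: the SOM is robust and cheap but has no notion of "the
right number" of populations, while hierarchical clustering is good at
merging a small number of prototypes but would not scale to events. Running
the hierarchical stage on node codes rather than events makes the
metaclustering cost independent of sample size.

## SOM training

Training is online. With $T = \texttt{rlen} \cdot n$ total steps, step $t$
draws an event $x$ uniformly at random, finds the best matching unit
$b = \arg\min_j d(x, w_j)$ (ties to the lowest node index) and updates
every node $j$ with $\mathrm{grid}^2(j, b) \le r(t)$:

$$ w_j \leftarrow w_j + \alpha(t)\,(x - w_j), $$

where $\mathrm{grid}^2$ is the squared Euclidean distance between grid
coordinates, and both $\alpha(t)$ (from 0.05 to 0.01) and $r(t)$ (from the
67th percentile of the squared grid-distance distribution down to 0) decay
linearly in $t$. The neighbourhood is a *bubble*: every in-radius node
receives the full $\alpha$, with no Gaussian weighting. Once $r(t) < 1$
only the BMU updates. Distances in marker space default to Euclidean;
Manhattan, Chebyshev and cosine ($1 - $ similarity, zero vectors given
similarity 0 to avoid NaN) are available.

Parameters and defaults:

| parameter | default | meaning |
|---|---|---|
| `xdim`, `ydim` | 10, 10 | grid size; 100 nodes suits samples with up to a few dozen populations |
| `rlen` | 10 | passes over the data |
| `alpha_start`, `alpha_end` | 0.05, 0.01 | learning-rate bounds |
| `radius_start` | 67th pct of squared grid distances | initial neighbourhood reach |
| `radius_end` | 0 | final reach (BMU-only) |
| `distance` | euclidean | metric on marker space |

All randomness — the sampled-event initialization of the codes and the
presentation order — is drawn from R's seeded Mersenne-Twister stream, so a
(data, parameters, seed) triple reproduces bit-identically across platforms
and is unaffected by thread counts (the kernel is single-threaded by
design).

**A note on very small grids.** With a $2 \times 2$ grid the default
radius schedule starts at 1 and falls below 1 after the first step, so
training immediately degenerates to BMU-only (k-means-style) updates and
the outcome depends strongly on whether the sampled initialization covered
every population. This is not the regime the method is designed for: the
grid should over-cluster (nodes $\gg$ populations), in which case every
well-separated population reliably attracts nodes and surplus nodes either
subdivide populations or become empty/dead units between them — both
handled downstream (empty nodes get missing medians and minimal glyph
radii; subdivided populations are merged by metaclustering). The test suite
therefore checks planted-population *coverage* under mild over-clustering
(a $3\times3$ grid on 4 blobs) rather than exact node-per-blob recovery on
a square grid the same size as the mixture.

## MST and layout

The minimum spanning tree is built on the complete graph over node codes
with Euclidean weights — regardless of the SOM training metric, since the
tree is a visualization of code geometry, not part of the clustering. The
2-D embedding minimizes the Kamada-Kawai stress of the tree's weighted path
distances, initialized from a deterministic circular layout ordered by node
index, so figures are reproducible without a separate seed; positions are
rescaled to the unit square. A plain grid layout is available as the
classic alternative view.

## Consensus metaclustering

For $h = 1 \dots H$ (default 100), $\lceil p \cdot m \rceil$ of the $m$
nodes are sampled without replacement (default $p = 0.9$), their codes are
hierarchically clustered (Euclidean distance, average linkage by default;
complete and Ward's ward.D2 available) and cut into $k$ groups. The
consensus matrix entry $M_{ij}$ is the fraction of co-clusterings among
co-samplings (0 if never co-sampled; diagonal fixed at 1). The final
partition cuts an agglomerative tree of $1 - M$ (same linkage) into $k$
groups, and labels are renumbered $1..k$ by first appearance over the node
index so seeded runs are comparable across platforms. Agglomeration ties
follow `stats::hclust`'s deterministic merge order.

Subsampling operates on nodes, never events: the consensus stage sees only
the cluster centers. $k$ is user-chosen; automatic selection is out of
scope. In the degenerate setting $p = 1, H = 1$ the procedure reduces
exactly to plain hierarchical clustering of the codes, which the tests
exploit as a closed-form oracle.

## Preprocessing

No transform is applied by default — silent transforms would hide data
provenance. Opt-in transforms act on the clustering channels
(`cols_used`): `arcsinh` ($x \mapsto \mathrm{asinh}(x/c)$, cofactor 5 as is
usual for mass cytometry; fluorescence data typically wants ~150) and
`zscore` (per-channel standardization; a zero-variance channel becomes all
zeros rather than NaN). Applied transforms are appended to the frame's
transform log and replayed verbatim when new samples are mapped onto a
trained model with `map_new_data()`. Spillover compensation is not
implemented; data are assumed pre-compensated.

## Evaluation metrics

`mean_f1()` follows the manually-gated benchmark convention: events whose
reference label equals the unassigned token are dropped; per
(population, group) pair precision, recall and F1 come from the contingency
table; populations are matched **one-to-one** to predicted groups by the
assignment maximizing total F1 (optimal bipartite matching — greedy
matching can reuse a group and overstate performance); the score is the
unweighted mean over populations, unmatched populations scoring 0. Both the
cluster (node) and metacluster granularities are exposed; note that
cluster-level mean F1 is structurally low when nodes $\gg$ populations
(each population can be matched to only one of its many nodes), which is
why metacluster-level scores are the headline numbers. `purity()` is the
event-weighted fraction of the dominant label per group and does not
penalize over-clustering.

## The result container

A run produces two modalities: the **cell** table (intensities, channel and
marker names, per-event cluster/metacluster labels, distance to BMU) and
the **cluster** table (codes, grid coordinates, counts, percentages,
per-channel medians, metacluster labels, MST edges, layout). Medians are
computed on the transformed scale stored in the cell matrix — the space the
SOM saw — and empty nodes carry missing values, never zeros. The HDF5
serialization mirrors the one-group-per-modality convention of multi-modal
single-cell containers (groups `cell` and `cluster`, observation
annotations as named arrays, parameters as a JSON attribute), so files open
with any generic HDF5 reader; all invariants are re-validated on load.
Node and metacluster labels are 1-based throughout, following R indexing
convention; the node at index $i$ sits at grid position
$((i-1) \bmod xdim,\ (i-1) \operatorname{div} xdim)$.

## Visualization choices

Star glyphs draw one wedge per marker, angular width $2\pi/m$, wedge 1
starting at 90° (top) and proceeding clockwise — orientation is fixed,
since it is otherwise an arbitrary implementation detail that varies
between implementations. Wedge radial extents are per-marker min–max
scaled medians across nodes (a marker constant across nodes maps to 0.5;
an empty node to 0); scaling is per plot, not global. Node radius encodes
the node's share of cells with area-proportional scaling
($r \propto \sqrt{pct}$) by default so that visual area tracks cell count;
empty nodes get a fixed 5% floor radius to stay visible. The metacluster
palette is a fixed categorical palette cycled by metacluster index.
Figures render through R's cairo devices; SVG output is byte-stable for
identical inputs.

## Synthetic data: what it does and does not emulate

The generator draws events from a diagonal-covariance Gaussian mixture over
$d$ markers, with population means placed on a regular simplex at pairwise
distance `separation` × mean(sd) (requiring $k \le d$; supply `means`
otherwise). This emulates the geometry of well-transformed cytometry data —
roughly ellipsoidal populations of configurable overlap and abundance — and
supports an oversampler that inflates a sample to a target event count by
resampling rows with replacement. It does **not** simulate marker
correlations within populations, spillover, doublets, debris, rare
populations below the grid's resolution, or heavy-tailed measurement
noise. Passing the planted-recovery tests therefore demonstrates correct
mechanics of the pipeline (quantization, merging, label propagation,
scoring), not performance on real samples, where population shapes are
less benign.

Default study conditions used by the tests and the acceptance script:
50 000 events, 8 markers, 6 populations at 6×-sd separation for the
end-to-end run (10×10 SOM, $k = 6$); 100 codes from 5 Gaussians at 10×-sd
separation for the metacluster-recovery check; the 7-color demo fixture is
5 populations over 7 markers at 50 000 events. These sizes exercise the
full pipeline while keeping a complete test run in the low minutes.

## Numerical details and edge cases

- BMU and hierarchical-cut ties break to the lowest index; MST edges are
  reported as (smaller node, larger node) sorted lexicographically, which
  fixes the output under equal-weight ties.
- The FCS writer emits FCS 3.1, `$DATATYPE F` (float32), little-endian,
  one dataset per file; intensities therefore round-trip at float32
  precision (~7 significant digits). The reader accepts FCS 3.0/3.1 with
  `F`, `D`, or uniform 16/32-bit `I` data.
- `consensus_matrix()` requires $k \le \lceil p \cdot m \rceil$; the SOM
  requires at least as many events as nodes (initialization samples
  events without replacement).
- Training rejects non-finite input up front rather than producing NaN
  codes.
- Percentages sum to 100 within $10^{-9}$; counts are conserved exactly;
  the cross-modality label consistency
  (`clusters$metacluster[cells$cluster_id] == cells$metacluster_id`) is
  validated on construction and on load.

## Known limitations

No batch SOM (training is online only), no hexagonal or toroidal grids, no
Logicle/biexponential transforms, no spillover compensation, no automatic
choice of $k$, no sparse or lazy-loading backing for the container, and
the plot gallery is limited to the star, pie and single-marker views.
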