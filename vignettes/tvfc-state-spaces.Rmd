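---
title: "Simplicial and topological state spaces for time-varying functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simplicial and topological state spaces for time-varying functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvfcstates)
```

## The problem

Whole-brain recordings such as parcellated BOLD fMRI evolve through
recurring patterns of inter-regional coordination. Whether those patterns
are best compared *simplicially* — by differencing the numbers decorating
nodes and edges of instantaneous connectivity graphs — or *topologically* —
by comparing the multiscale structure of holes and components those graphs
support — is an empirical question. `tvfcstates` implements both families
of metric spaces over coherence-based time-varying functional connectivity
(TVFC), embeds each metric space in two dimensions, segments the embedding
into density-based clusters, and asks, with permutation statistics, which
space best separates experimentally defined brain states.

Because the motivating data (multi-task 7 T scans) are external, the
package ships a synthetic study generator that emulates the relevant
structure: a continuous block-design session, condition-specific coupling
in the 0.009–0.08 Hz band, volunteer idiosyncrasy, performance-modulated
coupling, and AR1 noise for null calibration. Every stage of the pipeline
is testable against that generator.

## Time-varying connectivity

Each regional signal is decomposed with a complex Morlet continuous
wavelet transform, `psi(x) = exp(i omega0 x) exp(-x^2 / 2)` with
`omega0 = 6` (the smallest base frequency whose nonzero kernel mean is
below machine precision; smaller values would trade away spectral
selectivity). The filterbank holds 15 scales whose center frequencies are
log-spaced between 0.007 and 0.15 Hz inclusive, converted through the
Morlet approximation `f = omega0 / (2 pi s)`. The kernel is discretized on
a ±4 s support with `dt = TR`; signals are zero-padded for the FFT
convolution and the contaminated margins are discarded below.

The wavelet squared coherence between two spectrograms is

    R2_t(s) = |<s^-1 W^XY_t(s)>|^2 / ( <s^-1 |W^X_t(s)|^2> <s^-1 |W^Y_t(s)|^2> )

with `W^XY = W^X conj(W^Y)` the cross-wavelet spectrum. The smoothing
`<.>` is a Gaussian in time with standard deviation equal to the scale
(in seconds) and a 3-scale boxcar across scales — a standard choice; only
"smoothing in both time and scale" is prescribed by the method, so the
windows are configurable arguments. Squared coherence is an instantaneous,
scale-resolved analogue of a squared Pearson correlation and lies in
[0, 1] up to numerical clipping.

Multispectral coherence is collapsed to one broadband value per time point
as a weighted mean with cross-wavelet-power weights
`w_s(t) = |W^XY_t(s)|`. We normalize by the *sum* of the weights. A
max-normalization cannot keep an 11-term sum of values ≤ 1 bounded by 1,
while boundedness of the broadband coherence is asserted by the method;
the sum-normalized weighted mean is the reading that satisfies it. Graph
edges are `1 − coherence`, i.e. coherence distances.

Edge effects are handled by trimming: 120 samples at each temporal edge
(the cone of influence of the largest scales) and 2 scales at each
spectral edge, leaving 11 of 15 scales. With the default 1024-sample
session this retains 784 graphs per volunteer.

## Six metric spaces

For every retained time point the package extracts:

* **node** — the vector of `|W|` wavelet amplitudes over regions and the
  11 retained scales, compared by Euclidean distance;
* **edge** — upper-triangle edge weights, compared by the weighted
  Jaccard distance `1 − sum(min) / sum(max)`;
* **strength** — node-wise weighted degree, also under weighted Jaccard;
* **H0, H1, H2** — persistence diagrams of the Vietoris–Rips filtration
  of the coherence-distance graph, compared by sliced-Wasserstein
  distance.

The Jaccard-based metrics operate on *coherence* weights (`1 − distance`)
by default: Jaccard overlap semantics ("shared connectivity") read
naturally on connectivity intensity, and the strength–homology link that
motivates the strength metric is stated in terms of connection intensity.
A `distance` mode is available since the source convention is ambiguous.
Two all-zero weight vectors are defined to be at distance 0.

Vietoris–Rips persistence is computed by the package's own Z/2
boundary-matrix reduction (compiled, processed top-down with clearing),
so the filtration convention, tie-breaking, and pairing rules are fully
specified by this document rather than inherited from a backend. The
filtration uses strict sub-level sets `Rips(G(E < r))`; ties in filtration
value are ordered by dimension then lexicographic vertex order, which
makes the reduction deterministic and places faces before cofaces.
Zero-persistence pairs are dropped. H0 diagrams are obtained faster
through single-linkage agglomeration (`stats::hclust`), whose merge
heights equal the H0 death times; the equivalence is enforced in the test
suite against a brute-force dense reduction oracle, and H0 births are
exactly zero. More than 400 nodes with `max_dim = 2` are refused without
`force = TRUE` — the tetrahedron count grows as `n^4`.

The sliced-Wasserstein distance augments each diagram with the diagonal
projections of the other's points, projects both onto 20 evenly spaced
directions in `[-pi/2, pi/2)`, and averages the sorted l1 matching costs.
Fixed (not random) angles keep the distance deterministic. Essential
classes are excluded: the single essential H0 component is common to
every diagram and carries no contrast. A cap-at-max-radius alternative
can be emulated by truncating the filtration with `max_radius`.

## Embedding and watershed segmentation

The two-dimensional embedding follows the three-step neighbor-graph
contract: k-nearest neighbors from the precomputed distance matrix
(`n_neighbors = 15`), promotion of neighborhoods to a fuzzy simplicial
set (per-point bandwidths calibrated so the effective neighbor count is
`log2(k)`, symmetrized by probabilistic union), and a layout that
preserves the fuzzy graph, initialized spectrally and refined by
attraction along edges with sampled repulsion (`min_dist = 0.1` shapes
the attraction kernel). The embedding is implemented natively so that
every step — neighbor calibration, initialization, refinement — is
deterministic given its seed and documented here; points at zero
distance are embedded identically by construction. Out-of-sample points are placed by sharp inverse-distance
weighting over their nearest training points, so a point identical to a
training point lands on its twin. Hyperparameters are declared defaults,
not tuned values.

Cluster structure is read off a Gaussian kernel density on a grid of at
most 256 × 256 pixels; the axis with the smaller coordinate range is
trimmed to keep pixels square. The kernel bandwidth is
`0.08 × the axis coordinate range`. We interpret the bandwidth factor
relative to the grid extent rather than the point standard deviation: the
sd reading produces one local maximum per data point at realistic sample
sizes (hundreds of single-pixel clusters for a single Gaussian cloud),
which contradicts the intended "one cluster per density mode" behaviour.
The watershed labels every pixel by steepest ascent on the density — each
pixel points to its highest 8-neighbor, plateau ties resolved toward the
lower linear pixel index, chains terminating in local maxima that seed
the clusters — and pixels below `1e-6 ×` the peak density stay unlabeled.
Increasing the bandwidth can only merge catchment basins, so the cluster
count is non-increasing along a bandwidth ladder (a tested invariant).

## Statistics

Volunteers are split at random into three equal groups: embedding
training, watershed clustering, and testing; all reported statistics are
computed on the test group only. Within each volunteer, one of the two
presentations of each repeated task (math, memory) is removed at random
to balance conditions — at full scale, 777 retained points minus two
120-point presentations leaves 537. Embedding training uses 100 points
per training volunteer on an evenly spaced lattice with random phase, the
deterministic reading of "maximal temporal separation".

All tests permute labels 300 times and summarize the null by its mean
and standard deviation; p-values use the normal summary of that null (an
empirical-rank mode is provided, as the original convention is not
stated). The *unit* of permutation matters. Coherence smoothing spans
tens to hundreds of seconds, so time points within a task presentation
are strongly autocorrelated, and permuting point labels treats highly
dependent points as exchangeable: on an exchangeable synthetic null
(identical coupling across conditions) point-permutation enrichment
shows a corrected per-comparison false-positive rate around twice its
nominal level and a family-wise rate above one half (both are
recomputed by `scripts/acceptance.R`).
The exchangeable unit of a block design is the presentation, so the
enrichment and performance tests accept per-point block identifiers
(`infer_blocks()`) and then permute labels across whole presentations;
`bootstrap_driver()` defaults to this block unit, which brings the
corrected per-comparison rate to its nominal 0.05. The point-label mode
remains available (`blocks = NULL`, `perm_unit = "point"`) as the
literal original convention. Block permutation also demands cross-block
consistency from a "significant" cluster, which is precisely the kind of
evidence a brain-state claim needs. Volunteer generalizability runs a left-tail test per
(cluster, volunteer) at `alpha / (V × C)`: a volunteer is *represented*
unless significantly under-represented, and points are binned by how many
volunteers their cluster represents. Stimulus enrichment runs a
right-tail test per (cluster, condition) at `alpha / (conditions × C)`
and reports per-condition colocalization — the share of a condition's
points in clusters enriched for it. Effect sizes compare observed
colocalization against a restricted null (labels permuted, significant
clusters held fixed) with pooled-SD Cohen's d; a full-pipeline permuted
null tracks false positives. Performance tests are confined to clusters
already enriched for the task and flag high/low valence two-tailed, ties
going high. The bootstrap driver reinitializes the whole split → embed →
segment → test chain (256 draws at full scale) and aggregates means with
95% quantile intervals.

Mean performance graphs average the coherence-distance graphs of all
points pooled across draws (duplicates intended), and are compared
across valences with the weighted Jaccard distance over edges and the
sliced-Wasserstein distance over H0 diagrams, reusing the metric
operations above.

## The synthetic generator

`generate_study()` emulates a 25.6-minute session: eight blocks (rest,
video, math, memory, each twice), a 12-s instruction segment before each
180-s task segment, TR 1.5 s, 1024 samples. The session opens with rest
and closes with video so the temporal trim consumes most of one rest and
one video presentation. Defaults are 6 volunteers × 60 regions — large
enough for hundreds of retained graphs per volunteer while keeping H2
computable at desk scale.

Within a coupled block, the regions of each community share a random-phase
Fourier latent band-limited to 0.009–0.08 Hz (spectrally faithful to the
preprocessing of the motivating data; no hemodynamic convolution). Three
design choices deserve emphasis:

* **Structural condition contrasts.** Each task couples the regions into
  a different number of communities (video 2, math 4, memory 8; rest and
  instruction uncoupled). H0 persistence of single-linkage heights is
  invariant under region permutation, so conditions that differed only in
  *which* regions formed the same number of equally strong communities
  would be exactly indistinguishable to every homological metric — no
  statistic could then separate them. Distinct community counts are the
  minimal realistic asymmetry: different tasks recruit different network
  configurations.
* **Variance-preserving coupling.** The mixed coupled component and the
  AR1 noise are rescaled region-wise within each block so the marginal
  standard deviation is constant across conditions; coupling with gain
  `g` changes within-community correlation (`g^2 / (1 + g^2)` for an
  unperturbed mixing), not signal power. Amplitude-normalized BOLD does
  not multiply band power tenfold under task, and condition information
  should live in connectivity. With purely additive latents the node
  metric would separate conditions by raw amplitude alone.
* **Volunteer idiosyncrasy of order one.** Each volunteer's coupled
  component passes through `I + E` with `E` standard normal scaled by
  `1/sqrt(R)`. The magnitude (default `idiosyncrasy_strength = 1`) is a
  free parameter: the motivating phenomenon is that node/edge topography
  acts as a volunteer fingerprint whose idiosyncratic similarity rivals
  condition structure, which a near-zero perturbation would not emulate.
  Performance modulates coupling multiplicatively about 0.5, creating
  separable high/low-performance states.

The generator does **not** emulate volumetric noise, physiological
artifacts, hemodynamic response variability, spatial autocorrelation of
parcels, or non-stationary coupling within a block. Tests passing on this
generator therefore certify the pipeline's statistical behaviour — type-I
control, recovery of planted structure, determinism — not performance on
real scans.

`ar1_surrogate()` refits each region's lag-1 autocorrelation by moments
and draws an independent matched AR1 series; the 5% lower quantile of
coherence distances between independent surrogate pairs serves as the
significance threshold for coherent edges.

## Numerical choices and degenerate inputs

* Coherence values are clipped to [0, 1]; zero-power denominators and
  all-zero broadband weights define the result as 0 rather than NaN.
* Weighted Jaccard between two all-zero vectors is 0; negative weights
  are rejected.
* Duplicate points (zero distance) embed onto identical coordinates;
  an all-identical point cloud segments into a single warned cluster.
* Permutation nulls with zero standard deviation yield z = 0 (p = 0.5 /
  1 two-tailed); degenerate single-cluster single-label nulls warn.
* Cohen's d on two zero-variance distributions reports a signed `Inf`
  sentinel with a warning.
* Persistence ties are broken lexicographically; diagram CSV round trips
  are lossless to 1e-12 (17 significant digits).

## Problem sizes used by the test suite

Unit tests run on shortened sessions (60-s blocks, an 8-scale
0.02–0.15 Hz filterbank) and 8–20 regions. The statistical acceptance
checks use the full-length default geometry — 6 volunteers × 60 regions ×
1024 samples with the 15-scale filterbank — with 50 reinitializations for
type-I control and 10 bootstrap draws (cluster/test groups subsampled to
180 points per volunteer) for the H0-versus-node comparison. These sizes
were chosen as the smallest at which the tested contrasts are stable
across seeds.

## Known limitations

* H1/H2 diagrams over many time points are expensive above ~30 regions;
  the pipeline computes them on demand and the guard refuses `max_dim = 2`
  beyond 400 nodes. H0 covers the headline comparisons cheaply.
* The embedding is a faithful but simple implementation of the
  neighbor-graph contract; it is not a drop-in reimplementation of any
  particular UMAP release, and out-of-sample projection is interpolative
  (new points cannot open new clusters).
* The exact smoothing windows, the broadband normalization, the scale-grid
  convention (a naive endpoint-inclusive log grid does not reproduce the
  printed retained band edges 0.0095–0.1 Hz), and the watershed bandwidth
  semantics are under-specified in the source method; the package
  documents its choices and exposes them as arguments.
* Statistical defaults (300 permutations, Bonferroni, normal-summary
  p-values) mirror the original procedure. With block-level permutation
  the null counts are discrete (a test group holds a few dozen
  presentations), and the normal summary's far tail is optimistic there:
  per-comparison rates are calibrated, but family-wise error across all
  (cluster, condition) tests remains above alpha on exchangeable nulls.
  The empirical-rank mode is exact but cannot reach Bonferroni
  thresholds below 1/301 at 300 permutations — a resolution limit
  inherited from the original design.
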