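# tvfcstates

Simplicial and topological state spaces for time-varying functional
connectivity (TVFC).

Parcellated brain signals pass through recurring patterns of
inter-regional coordination. This package asks which *metric space over
instantaneous connectivity graphs* best separates experimentally defined
brain states: the simplicial spaces that difference the numbers decorating
graphs — node topography (Euclidean), edge weights and degree strengths
(weighted Jaccard, `D_J = 1 − Σ min(w¹,w²) / Σ max(w¹,w²)`) — or the
topological spaces that compare persistence diagrams of the Vietoris–Rips
filtration `K_r = Rips(G(E < r))` in homological dimensions H0, H1, H2
(sliced-Wasserstein distance over 20 fixed slices).

The pipeline, intended for methods researchers in network neuroscience:

1. **TVFC** — complex Morlet CWT (`ω₀ = 6`, 15 log-spaced scales,
   0.007–0.15 Hz), smoothed wavelet squared coherence
   `R²ₜ(s) = |⟨s⁻¹W^XY⟩|² / (⟨s⁻¹|W^X|²⟩⟨s⁻¹|W^Y|²⟩)`, collapsed per time
   point by cross-power-weighted averaging; edges are coherence distances
   `1 − C_t`. The outer 120 samples and 2 scales are trimmed.
2. **Six metric spaces** over the retained time points.
3. **State space** — 2-D neighbor embedding of each distance matrix,
   Gaussian density on a ≤256×256 grid (bandwidth factor 0.08), watershed
   clusters grown by steepest ascent from density maxima.
4. **Statistics** — volunteers split into embed / cluster / test thirds;
   label-permutation nulls (300 draws, normal summary, α = 0.05,
   Bonferroni) for volunteer generalizability, stimulus enrichment with
   Cohen's d effect sizes, and performance-valenced clusters; all
   bootstrapped over re-splits.

A synthetic block-design study generator (rest / video / math / memory,
condition-specific community coupling in 0.009–0.08 Hz, volunteer
idiosyncrasy, performance effects, AR1 noise) makes every stage testable
without external scans. Vietoris–Rips persistence and the pairwise
sliced-Wasserstein kernels are implemented in compiled code inside the
package.

## Worked example

```r
library(tvfcstates)

cfg   <- study_config(n_volunteers = 6, n_regions = 24, seed = 1)
study <- generate_study(cfg)
study[[1]]
#> <parcel_series> volunteer vol01: 24 regions x 1024 samples (TR 1.50s), 16 events

fb <- build_filterbank(0.007, 0.15, 15, 6, tr = 1.5)
tvfc <- lapply(study, compute_tvfc, fb = fb)
tvfc[[1]]
#> <tvfc_series> vol01: 784 graphs on 24 regions, 11 retained scales (0.01085-0.09682 Hz)
```

1024 samples minus 120 per temporal edge leave 784 coherence-distance
graphs; 15 scales minus 2 per spectral edge leave 11. Each graph's
zeroth-homology diagram has one (0, death) pair per single-linkage merge:

```r
pts <- lapply(tvfc, state_points)
state_diagram(pts[[1]][[100]], dimension = 0)
#> <persistence_diagram> H0: 23 finite pairs, 1 essential
```

Bootstrapping the split → embed → watershed → test chain compares metric
spaces by the share of each condition's test points that land in clusters
significantly enriched for that condition (labels permuted across whole
task presentations — the exchangeable unit of a block design):

```r
boot <- bootstrap_driver(pts, metrics = c("H0", "node"), n_boot = 5,
                         eval_subsample = 150, seed = 7)
boot
#> <bootstrap_result> 5 draws
#>  metric   condition       mean     ci_lo      ci_hi n_boot
#>      H0 instruction  0.0000000  0.000000   0.000000      5
#>      H0        math 71.6130536 46.668998  87.104895      5
#>      H0      memory 93.0303030 84.848485 100.000000      5
#>      H0        rest 73.0555556  8.888889  92.916667      5
#>      H0       video 67.8787879 62.575758  71.060606      5
#>    node instruction  0.0000000  0.000000   0.000000      5
#>    node        math  0.9230769  0.000000   4.153846      5
#>    node      memory  0.0000000  0.000000   0.000000      5
#>    node        rest 19.7222222  0.000000  88.750000      5
#>    node       video  3.0303030  0.000000  13.636364      5
```

The H0 space colocalizes 68–93% of task and rest points inside
condition-enriched watershed clusters; the node-topography space, whose
amplitude patterns are dominated by volunteer idiosyncrasy, manages
0–20% — the topological lens segments the planted brain states better,
which is the comparison the package exists to make. (Instruction
segments are generated without coupling, so no metric can tell them from
rest.) `run_pipeline(pipeline_config(...))` drives the same chain end to
end and writes per-metric distance matrices, the bootstrap summary, and
a reproducible run manifest.

See the vignette (`vignettes/tvfc-state-spaces.Rmd`) for the model,
parameter semantics, and the design decisions behind the generator,
embedding, and watershed.

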