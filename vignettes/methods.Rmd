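---
title: "Mapping group-convergent neural representations: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping group-convergent neural representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`repnets` implements a data-driven multivariate pipeline for asking two
questions of surface-sampled fMRI pattern estimates: *where* do members of a
group converge on a common representational geometry of a stimulus set, and
*what* do those convergent representations encode. This vignette explains
the models and procedures, the parameters that matter, the synthetic-data
generator that stands in for fMRI data, and the design decisions taken where
the method left genuine freedom.

## The analysis model

**Node-level representational geometry.** Every analysis works on item
dissimilarity matrices (DMs). At each node of a standard cortical surface
mesh, each stimulus item's response pattern is the vector of its
beta-estimate values over the node's searchlight patch (a k-ring mesh
neighborhood), and the node's DM holds `1 - Pearson r` for every item pair
(`compute_item_dm()`). Correlation distance is the standard MVPA choice: it
ignores per-item mean level and gain, so only the *shape* of the local
pattern matters. Entries lie in [0, 2].

**Intersubject convergence.** Within a group, the condensed DM vectors of
every subject pair are correlated at every node, Fisher z-transformed
(`atanh`, variance-stabilizing), and averaged (`intersubject_convergence()`).
A high node value means the group agrees on which items look alike at that
location, without any a priori model of *how* they should look alike.

**Noise thresholding by negative extent.** A negative intersubject DM
correlation has no representational interpretation -- it can only arise from
noise. The magnitude of the most negative observed map value therefore
estimates the spread of chance correlations, and the map is thresholded
strictly at `z > |min|` (`estimate_noise_threshold()`). The rule, not any
particular printed number, is the method: the threshold is recomputed from
each dataset (on the synthetic reference data it lands around z = 0.015 to
0.02). A permutation null (`permutation_null()`, within-subject item-label
shuffling applied consistently across nodes) validates the threshold: the
95th percentile of permuted map maxima should bracket it. The shuffling
scheme is a documented implementation choice; it preserves each subject's
node-level DM value distribution exactly while destroying item alignment
across subjects.

**Overlay and cluster correction.** The two groups' thresholded maps are
overlaid into four classes (group-A-only, group-B-only, overlap, none); the
stricter of the two group thresholds is applied to both, so a single common
criterion governs the comparison. Components smaller than 5 contiguous
nodes (shared-edge contiguity) are removed (`overlay_and_cluster()`).

**Informational networks.** Within each region class and group, the
group-average node DMs (mean-centered, unit-normalized) are Ward-clustered
(`stats::hclust`, `ward.D2` on Euclidean distance -- the proper Ward
criterion; on normalized vectors this is a monotone transform of correlation
similarity). The cluster count is selected by split-half cross-validation
(`select_k_split_half()`): subjects are repeatedly split in half, each
half's region-average DMs are clustered at every candidate k, and
reproducibility(k) is the adjusted Rand index (ARI) between the two halves'
node assignments. ARI is label-permutation-invariant, so no cluster matching
step is needed. The selected k maximizes mean reproducibility, ties going to
the smallest k; the final solution is refit on all subjects at k*.

Two guards matter here. First, candidate k runs from 2 up to a cap of 100.
Second, k is additionally bounded by *half* the region's node count: the ARI
between two partitions degenerates to 1 as k approaches n (two all-singleton
partitions are identical no matter the data), so cluster solutions are only
meaningful while clusters average at least two nodes. At full mesh scale
(regions of thousands of nodes) the bound is inactive and only the cap of
100 applies.

**Network RSA.** For every informational network and participant, the
network-average DM is compared with a model DM by *normalized correlation*:
both condensed vectors are mean-centered, scaled to unit norm, and their dot
product taken -- algebraically the Pearson correlation of the condensed
vectors, bounded in [-1, 1]. Participant values are Fisher z-transformed and
tested against zero with a two-sided one-sample t-test (`network_rsa()`).
Raw p-values are reported by default (matching the convention of reporting
peak statistics unadjusted); Benjamini-Hochberg adjustment across networks
is available via `adjust_p = TRUE`. Node-wise t-gradient maps
(`gradient_map()`) and peak networks (`find_peak_network()`, ties broken
toward larger networks then smaller ids) summarize the result.

**Model DMs.** The mechanical-category model is binary: 0 for item pairs in
the same category (cantilever, truss, vertical load), 1 otherwise. The
original expert similarity ratings behind the category partition are not
available; the discrete three-category reading is the claimed structure and
is what `category_model_dm()` builds. Arbitrary model DMs can be loaded from
square CSV (`read_item_dm()`). The visual control model is the C1 layer of
HMAX: a bank of zero-mean, unit-norm Gabor filters (4 orientations, 16 sizes
from 7 to 37 px paired into 8 scale bands, the standard parameterization) is
cross-correlated with the image with local contrast normalization, and
responses are max-pooled over space (overlapping pools, stride half a pool)
and over the two sizes of each band. Two implementation details depart from
naive convolution for exactness: images are replicate-padded so every output
pixel has full filter support (a constant image then yields exactly zero),
and the normalizer is the *centered* patch norm, making responses exactly
invariant to global luminance offsets. A corollary worth knowing: with the
absolute-value response, C1 is exactly polarity-invariant, so an image and
its photometric negative are indistinguishable to this model. The visual DM
is correlation distance between C1 feature vectors, matching the neural
metric.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `linear_divisions` | 32 (full), 8 (test) | Mesh subdivision; nodes per hemisphere = 10 L^2 + 2, so L = 32 gives the standard 20,484-node whole brain |
| `rings` | 2 (full-scale searchlight) | Searchlight patch radius in edge hops; the patch extent is unstated in the source method, so it is a configuration parameter |
| `clip_eps` | 1e-7 | arctanh clipping; keeps perfectly convergent synthetic data finite |
| `min_cluster_size` | 5 | Surface cluster-correction extent (contiguous nodes) |
| `k_range` | [2, 100] | Candidate cluster counts, additionally bounded by half the region size |
| `n_repetitions` | 100 (test scale) | Split-half repetitions; 1000 at full scale. The reproducibility profile is stable well before 100 at the test-scale region sizes |
| `probability` | 0.95 | Concentration-ellipsoid coverage; semi-axes = sqrt(eigenvalue x chi-square quantile, 3 df) |

## The synthetic-study generator

No fMRI data ship with the method, so `simulate_study()` generates complete
studies in which every pipeline claim is checkable by parameter recovery.
The reference configuration is the study's own: two groups (16 "experts",
15 "novices"), 24 items in three categories of 8, and a whole-brain surface.
Tests and the acceptance analysis run at L = 8 (1,284 nodes) so that a
20-seed full-pipeline study completes in minutes; L = 32 is supported
unchanged. At L = 8 the searchlight uses 1 ring: the mesh is four times
coarser than the L = 32 standard mesh, so one ring spans a comparable
cortical fraction to a multi-ring patch at full scale.

**Planted structure.** Three disjoint disc regions (radius 5 rings) are
planted, one per role: an expert-only category region (left hemisphere,
dorsal pole), a shared visual region (right hemisphere) and a novice-only
region (left hemisphere, ventral pole). Each disc is split at its tangent
median into two halves carrying *different* prototypes, so the true cluster
count in every region class is 2 and the k-selection step has a recoverable
target. In the expert-category disc one half carries the category-model
prototype and the other an arbitrary shared prototype; in the shared-visual
disc one half carries the visual-model prototype; the novice-only disc
carries two arbitrary prototypes. Novices receive pure noise in the expert
region and vice versa.

**From a model DM to patterns.** `planted_dm_prototype()` turns a target DM
into an item covariance: the similarity `1 - dm` has its off-diagonal
structure standardized (z-scored and scaled to sd 0.3) and is projected to
the nearest positive-semidefinite correlation matrix. The standardization
makes every role plant *equally strong* structure at equal snr -- without
it, a binary block model plants several times the structured variance of a
diffuse empirical similarity, and cross-model leakage (the visual and
category models correlate ~0.3 by construction of any image set with
category-correlated appearance) can misplace peaks. Normalized correlation
is invariant to affine transforms of either vector, so the standardized
prototype still targets the original model exactly.

**Subject variability.** Each subject's planted signal is
`sqrt(0.3) x shared core + sqrt(0.7) x subject-specific draw`, both from the
prototype covariance, scaled by `sqrt(snr)` against unit Gaussian noise
(snr = 1 at the reference configuration; variance ratio). Subjects therefore
share representational *geometry* -- the prototype -- rather than identical
activation patterns, as in real groups of brains. This also matters
statistically: if subjects shared the signal realization exactly, every
node's idiosyncratic realization detail would be perfectly reproducible
across split halves, and the k-selection step would lock onto that detail
instead of the planted two-prototype structure (real data behave the same
way: reproducible fine structure drives selected k upward).

**What the generator does not emulate.** Patterns are independent Gaussian
across nodes and items (no spatial autocorrelation, no hemodynamic
structure, no anatomical variability in region placement); stimuli are
schematic line drawings, not photographs; region boundaries are crisp discs.
Passing recovery tests therefore demonstrates that the pipeline's inference
machinery is correct and calibrated under its stated noise model -- not that
real fMRI data would yield these effect sizes. One searchlight-specific
caveat is visible in the recovery scores: detection dilates planted regions
by roughly the patch radius (a node just outside a region sees signal
through its neighborhood), which bounds the achievable boundary Jaccard
below 1 by geometry, not by error.

## Numerical choices and degenerate inputs

* Correlations are clipped to `[-1 + 1e-7, 1 - 1e-7]` before `atanh`.
* Zero-variance item patterns raise an error at the DM level; the
  searchlight flags such nodes missing, convergence drops the affected
  subject pairs node-wise, and region averaging flags nodes degenerate
  (averages that collapse to a constant vector are detected with a relative
  1e-12 tolerance).
* Ward clustering and `cutree` inherit `hclust`'s deterministic
  tie-handling; split-half draws and permutations are governed by explicit
  seeds, and the full Step-3 path is bit-reproducible for fixed seed.
* `nmds_embed()` (Kruskal nonmetric scaling via `MASS::isoMDS`) starts from
  the classical-scaling solution plus random restarts and keeps the lowest
  final stress (reported on [0, 1]); zero dissimilarities are lifted by a
  relative 1e-6 epsilon since nonmetric scaling requires positive
  dissimilarities. A constant positive DM (an equilateral configuration) is
  a valid target; only an all-zero DM is rejected.
* Concentration ellipsoids flag axes with eigenvalues below a relative
  1e-10 tolerance as degenerate rather than inverting a singular
  covariance.
* Surface maps, DMs, network memberships and traces are exchanged as plain
  CSV (0-based node indices); mesh geometry as node/face CSV tables. No
  binary neuroimaging container is required anywhere in the pipeline.

## Design decisions on genuinely open points

* **Dissimilarity metric**: `1 - Pearson r`, the toolkit-lineage standard,
  for both neural and visual DMs ("pairwise correlation" fixes the family
  but not the sign convention).
* **Intersubject and model correlations** are Pearson on condensed DM
  entries; the normalized dot product *is* Pearson after the prescribed
  normalization, which is the only reading that makes it a bounded
  correlation.
* **Threshold sharing**: one common threshold -- the stricter group value --
  is applied to both maps before overlay, reproducing a single-criterion
  comparison for arbitrary data.
* **Negative extent** is read as the single minimum, not a quantile of the
  negative tail.
* **Split-half reproducibility statistic**: ARI at matched k. The upstream
  description defers to a cited procedure whose details are not restated;
  ARI is the label-matching-free choice and is recorded as a possible
  divergence.
* **Final solution**: refit on all subjects at k*, rather than aggregated
  across halves.
* **Two-sided p-values** throughout, consistent with the reported peak
  statistics.
* **Searchlight extent** is a parameter (rings), scale-free on synthetic
  meshes of arbitrary units.

## Known limitations

* The pipeline tests convergence within each group and overlays the maps;
  it does not test group differences node-wise (no A vs B contrast map),
  mirroring the method it implements.
* Recovery scores are reported against crisp planted truth; the searchlight
  dilation described above is inherent to the method, so boundary-exact
  recovery is not an achievable target and is not claimed.
* The HMAX implementation covers S1/C1 only (no S2/C2, no color), which is
  all the control analysis requires.
* On pure-noise data the negative-extent threshold still admits a small
  positive tail by construction; the 5-node cluster correction is what
  keeps the false-positive region count near zero, and both behaviors are
  exercised in the test suite.
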