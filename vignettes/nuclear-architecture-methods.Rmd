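---
title: "Models and methods behind nucarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nucarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

nucarch reimplements, as a tested pipeline on synthetic data, the
quantitative analyses used to characterize nuclear architecture after acute
cohesin depletion: voxel-level chromatin-compaction classification of 3D
DAPI stacks, allocation of functional markers to compaction classes,
segmentation and statistics of pulse-labeled replication domains (RDs),
DNA-halo loop-size measurement, degradation-kinetics trace filtering, and
matrix-level Hi-C/Repli-Seq compartment analyses. This vignette explains the
models, the tunable parameters, the synthetic-data generators and what
passing tests do and do not establish.

## The compaction classifier: an equal-variance Gaussian HMRF

The central method classifies every nuclear voxel of a DAPI stack into K = 7
intensity classes used as proxies for chromatin compaction: class 1 collects
voxels near background intensity (the DNA-sparse interchromatin compartment,
IC), class 7 the most compacted heterochromatin. The model is a hidden
Markov random field: emissions are a finite Gaussian mixture with class
means $\mu_1 < \dots < \mu_K$, one shared standard deviation $\sigma$
("equal intensity variance", read literally as a single $\sigma^2$ for all
components), and mixture weights $\pi_k$; the labels carry a Potts spatial
prior that pays $\beta$ for every 6-connected in-mask neighbor pair with
different labels. The posterior energy minimized is

$$U(x) = \sum_v \left[ \frac{(I_v - \mu_{x_v})^2}{2\sigma^2} + \log\sigma -
\log\pi_{x_v} \right] + \beta \sum_{v \sim w} \mathbf{1}[x_v \neq x_w].$$

This makes the classification threshold-independent: a voxel's class is
decided by its intensity relative to the fitted mixture and by its
neighborhood, not by a global cut.

Inference is ICM (iterated conditional modes) alternating with closed-form
M-steps, chosen over mean-field or annealing because it is deterministic,
fast at SIM-stack scale, and each sweep provably decreases $U$ at fixed
parameters — a property the test suite asserts sweep by sweep. Labels are
initialized by K-quantile slicing of the in-mask intensities. Numerical
choices that matter:

* **Annealed coupling.** $\beta$ ramps linearly to its target over the first
  five outer iterations (constant within each ICM phase, so per-phase energy
  descent is untouched). Hard ICM at full coupling from a quantile
  initialization can lock into basins where adjacent components merge.
* **Component rescue.** Hard (classification) EM is prone to component
  death: a class squeezed between two heavier neighbors loses all voxels,
  and its $-\log \pi_k$ penalty then keeps it dead. As `stats::kmeans` does
  for empty clusters, a dying component is reseated at the midpoint of the
  widest gap between surviving means and given a fresh uniform prior share.
* **Sigma floor.** On noiseless input the fit is exact and $\sigma \to 0$;
  the shared $\sigma$ is clamped at a relative floor ($10^{-9}$ of the
  intensity range) so classification stays defined. Constant in-mask
  intensity is an error.
* **Ordering.** After convergence classes are relabeled ascending by fitted
  mean, so class 1 is always the dimmest regardless of initialization.
* **Masking.** Out-of-mask voxels take part in neither the emission fit nor
  the neighbor terms; mask-boundary voxels simply have fewer neighbors.

The default fit coupling is $\beta = 0.5$ and is user-configurable; the
paper-scale analyses in `analysis/` and the acceptance suite use
$\beta = 0.8$, the value whose final labelings reproduce the
neighbor-agreement of the default generator scenes (the generator's
exchange-ensemble coupling, below, is not numerically comparable to the
single-site ICM coupling, so "matched" means matched on coherence). At
$\beta = 0$ the fit reduces exactly to per-voxel MAP classification under
the fitted mixture, which the tests verify against an exhaustive per-voxel
argmax oracle.

## Synthetic nuclei

`generate_nucleus_scene()` renders scenes at SIM-like sampling (40 × 40 ×
125 nm voxels, default 128 × 128 × 32 grid). That grid holds a small
nucleus of roughly 4 × 3.7 × 3 µm — a deliberately scaled-down cell
(real HCT116 nuclei are ~10 µm wide) so that a full fit runs in seconds;
all structural features are preserved at scale.

* **Shape**: one axis-aligned ellipsoid, or for multilobulated (MLN-like)
  nuclei a union of `n_lobes` randomly oriented ellipsoids smoothed by
  morphological closing. `nucleus_scale` scales the semi-axes; volume goes
  with its cube, which is how the 4n (post-endomitotic) condition is built.
* **Label field**: quantile-sliced smoothed Gaussian noise (blur 12 × 12 × 6
  voxels sets the chromatin-domain-cluster scale) provides a spatially
  coherent start with exactly the target class proportions; 30 Gibbs sweeps
  of the Potts model follow. The sweeps run in the fixed-composition
  (exchange/Kawasaki) ensemble — label swaps between random in-mask voxel
  pairs, Metropolis-accepted on the Potts energy change. A single-site chain
  at any coupling strong enough for SIM-like coherence coarsens and
  evaporates the minority classes; exchange dynamics conserves the planted
  class profile exactly while `potts_beta` (default 2) still controls
  boundary smoothness. At `potts_beta = 0` the swaps randomize the field and
  the neighbor-agreement rate drops to $\sum_k f_k^2$, the independence
  value — a closed form the tests check.
* **Rim and IC channels**: voxels within `rim_thickness` (default 160 nm) of
  the border become class K (the compacted lamina-associated shell); a
  smoothed-noise threshold carves `ic_channel_fraction` (default 12%) of the
  interior into class-1 channels that meander between domains. The Potts
  target weights are pre-compensated for both overrides so the final class
  fractions match `class_weights`.
* **Emissions**: intensity = class mean + N(0, `class_sigma`), optional
  separable-Gaussian PSF blur (120 nm lateral / 300 nm axial FWHM if
  enabled, the SIM resolution limit), optional additive Gaussian readout
  noise and Poisson shot noise. With `class_sigma = 0` and no noise the
  DAPI channel equals the class means exactly.
* **Markers**: a marker spec gives per-class relative emission weights and a
  target density; each in-mask voxel turns marker-positive by an independent
  Bernoulli draw with probability proportional to its class weight, which
  makes the expected class share of marker voxels exactly
  $f_k w_k / \sum_j f_j w_j$. `marker_weights_for_delta()` inverts this to
  plant a chosen percentage-point enrichment.
* **Replication domains**: spheres with lognormal volumes placed in
  pattern-dependent zones (early: interior low-compaction classes 2–3; mid:
  near the rim; late: few large blobs in classes ≥ 5 near the rim), with a
  minimum center separation; the channel is rendered on an 8-bit scale
  because the published segmentation threshold is defined on one.
* **Determinism**: every generator consumes R's RNG under a caller-supplied
  seed and restores the RNG state; identical (spec, seed) give bit-identical
  scenes.

What the scenes do *not* emulate: SIM reconstruction artifacts, nucleoli,
chromocenters, intensity vignetting, or the true granularity of ~Mb
chromatin domains at full nuclear size. Passing tests therefore demonstrate
correctness of the algorithms against known truth at realistic noise, not
performance on raw microscope output.

## Marker enrichment over compaction classes

For each nucleus the DAPI baseline $f_k$ is the unweighted share of in-mask
voxels in class k, the marker share $m_k$ is the intensity-weighted share of
segmented marker voxels mapped to class k, and the profile reports
$\Delta_k = 100\,(m_k - f_k)$ percentage points: positive = enrichment over
a random distribution, negative = depletion, with $\sum_k \Delta_k = 0$ by
construction. The DAPI side is deliberately count-based while the marker
side is intensity-weighted (an `intensity_weighted = FALSE` switch makes
both count-based); averages and SEM are taken across nuclei. Marker
segmentation is Otsu's threshold on in-mask intensities times a
configurable factor — a reproducible stand-in for interactive tuning.

## Replication domains

RD segmentation follows the published recipe: fixed threshold at 32/255 of
the channel's nominal maximum, restriction to the nuclear mask, connected
components, separation of touching objects, and exclusion of objects below
0.005 µm³ (the 3D-SIM resolution limit, which also pins the lower edge of
the volume distribution in every condition). "Separate touching objects
with a 0.002 µm³ size guide" is realized as a distance-transform split:
seeds are 26-neighborhood local maxima of the anisotropic Euclidean
distance transform, greedily pruned (deepest first) so no two seeds lie
within the radius of a 0.002 µm³ sphere, and component voxels go to the
nearest surviving seed. Objects clipped at the stack's Z faces are
included. Summaries use Tukey-hinge quartiles and 1.5 × IQR whiskers to
match the plotting convention of the source figures.

Condition comparisons use the two-sided Mann–Whitney (Wilcoxon rank-sum)
test — exact enumeration when the pooled sample is ≤ 12 and tie-free,
otherwise the normal approximation with tie and continuity corrections —
with Bonferroni–Holm correction across the family of pairwise contrasts.
Both are delegated to base R (`wilcox.test`, `p.adjust`); the test suite
cross-checks the exact path against an exhaustive permutation oracle.

## Nuclei, volumes, DNA content, traces

Nucleus segmentation: Gaussian smoothing (100 nm), Otsu threshold,
dilate / fill-holes / erode (15 iterations each by default, matching the
published recipe for full-size stacks; the scaled-down analyses use 3), then
removal of objects under 200 µm³ and of objects touching the XY border
(Z truncation is normal in stacks and tolerated). Volumes are voxel counts
times the anisotropic voxel volume. Integrated DNA content subtracts the
frame's modal gray value (256-bin histogram mode) and clips at zero, so a
4n nucleus reads twice a 2n nucleus.

Degradation traces: cells starting at ≤ 50 counts are excluded; retained
traces are normalized to their first value; each cell's fluctuation is the
maximum *relative* deviation from its own centered rolling mean of 5
timepoints (window truncated at the ends), and cells strictly above the 90%
across-cell quantile are dropped — the relative reading of the published
fluctuation rule; the wording is ambiguous and the alternative (absolute
deviation) differs only in scale. With all-constant traces every
fluctuation is 0 and nothing is dropped.

## DNA halo

High-salt histone extraction leaves a dense scaffold inside a faded halo of
extruded chromatin loops. The generator renders a bright core disc inside a
linearly fading annulus; segmentation is a two-level (three-class) Otsu
partition of the histogram — total area $A_t$ above the low threshold,
scaffold area $A_s$ above the high one, both hole-filled. If the middle
class is indistinct (an effectively bimodal, core-only image) the method
falls back to a single threshold and reports $A_h \approx 0$. The halo
radius is $R = \sqrt{A_h / \pi}$ with $A_h = A_t - A_s$; it depends on the
areas only through their difference. Conditions are compared with the same
two-sided rank-sum machinery as RDs.

## Hi-C and Repli-Seq

All analyses are intra-chromosomal at matrix level (binned counts in, no
read processing). Balancing finds the symmetric diagonal scaling with unit
row sums via the fixed-point iteration $x \leftarrow \sqrt{x / (Mx)}$
(zero rows masked; convergence asserted at $10^{-6}$ row-sum deviation and
verified against the closed form for the rank-1 matrix [[1,2],[2,4]]).
The observed/expected transform divides by per-diagonal means (no
smoothing); the Pearson map correlates O/E rows pairwise; the compartment
eigenvector is the leading eigenvector of the double-centered Pearson
matrix, sign-anchored so its correlation with a reference track (the
log2 early/late replication ratio) is positive — A compartment co-varies
with early replication. Histone-mark clustering z-scores each of the 9
marks across bins (equalizing dynamic range) and runs k-means with k = 6,
a fixed seed, 25 restarts and relabeling by descending size; the numbering
is arbitrary. Between-cluster contact change is
$\log_2(\bar c^{post}_{ab} / \bar c^{pre}_{ab})$ over off-diagonal bin
pairs, computed on balanced counts (an O/E option is a one-line change by
passing O/E matrices). APA sums (2 × 10 + 1)² submatrices centered on loop
pixels, skipping loops within 10 bins of the diagonal or edges, and scores
center / mean of the 5 × 5 lower-left corner block — the
distance-conservative denominator; window and corner are declared
conventions, configurable. Replication timing is
$\log_2((E+1)/(L+1))$ with percentile transform, and preservation is the
Spearman correlation of percentiles.

The genome generator plants: alternating (or random) compartment blocks, a
blockwise cluster assignment that cycles through each cluster set so all
six clusters cover comparable genome shares, distance-decaying expected
counts (~1/d) with same-compartment and same-cluster block boosts, focal
loop pixels ≥ 25 bins off the diagonal, a post-treatment matrix whose
within-strengthen-cluster contacts are multiplied by a stated factor
(exactly, when `count_noise = "none"`), archetype-plus-noise mark tracks
(cluster 4's archetype is depleted of both activating and repressive marks
apart from mild H3K79me2), and early/late Repli-Seq counts tied to the
compartment sign.

## Problem sizes and runtimes

The defaults are chosen so the full test suite runs in about two minutes
and the acceptance script in under two: 128 × 128 × 32 classifier scenes
(~1.2 × 10⁵ in-mask voxels), 64 × 64 × 16 scenes for per-nucleus
statistics, 240-bin synthetic chromosomes at 25 kb, 20 cells per halo arm,
RD conditions of 20–38 planted domains per nucleus (two orders of magnitude
below real stacks, where thousands of RDs per nucleus are segmented — the
statistical contrasts scale down but the code paths are identical).

## Known limitations

* ICM is a greedy optimizer; voxel labels near class boundaries depend on
  the initialization and sweep order (both fixed and deterministic here).
  Accuracy claims hold against synthetic truth, not against any manual
  annotation of real stacks.
* The exchange-ensemble Potts field has slightly different boundary
  statistics from a free Potts draw; it was chosen to keep planted class
  fractions exact.
* The nearest-seed split is a Voronoi approximation of a full watershed;
  for near-spherical RDs the two agree, for strongly concave objects they
  may not.
* Plain multi-page TIFF with a JSON sidecar stands in for OME-TIFF
  metadata.
* Hi-C analyses are intra-chromosomal only, and the expected model is the
  per-diagonal mean without smoothing.
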