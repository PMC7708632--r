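# nucarch

Quantitative analysis of nuclear architecture after acute cohesin depletion,
rebuilt as a tested R pipeline that runs end-to-end on synthetic data with
known ground truth.

Acute degradation of the cohesin subunit RAD21 eliminates chromatin loops
and TADs, yet cells retain — and, after passing through an endomitosis into a
multilobulated nucleus (MLN), rebuild — a compartmentalized nuclear
architecture: chromosome territories pervaded by interchromatin channels,
zonal chromatin-compaction gradients, intact A/B compartments and preserved
replication timing, while individual replication domains grow in number,
volume and heterogeneity. Testing those claims requires a specific set of
quantitative tools, which this package implements:

* **Compaction classification** — a hidden Markov random field: a K = 7
  equal-variance Gaussian mixture over DAPI voxel intensities coupled by a
  Potts prior (cost β per disagreeing 6-connected neighbor pair), minimized
  by raster-order ICM alternating with closed-form M-steps,

  U(x) = Σ_v [ (I_v − μ_{x_v})² / 2σ² + log σ − log π_{x_v} ] + β Σ_{v∼w} 1[x_v ≠ x_w].

  Class 1 = interchromatin compartment, class 7 = densest heterochromatin.
* **Marker enrichment** — per class, Δ_k = 100·(m_k − f_k) percentage points
  between a marker's intensity-weighted class share m_k and the DAPI voxel
  share f_k (Σ Δ_k = 0), mean ± SEM across nuclei.
* **Replication domains** — threshold 32/255, distance-transform separation
  of touching objects (0.002 µm³ size guide), exclusion below 0.005 µm³;
  counts and volume distributions compared by two-sided Mann–Whitney tests
  with Bonferroni–Holm correction.
* **DNA halo** — two-level Otsu segmentation of scaffold (As) and total (At)
  areas; halo radius R = √((At − As)/π).
* **Degradation kinetics** — per-cell trace filtering (50-count floor,
  normalization to start, 90%-quantile fluctuation rule against a centered
  rolling mean of 5 timepoints).
* **Genome compartments** — contact-matrix balancing to unit row sums,
  observed/expected and Pearson maps, compartment eigenvector anchored to
  replication timing, z-scored k-means clustering of 9 histone marks (k = 6),
  between-cluster contact log2 ratios, aggregate peak analysis, and
  Spearman preservation of early/late replication percentiles.
* **Synthetic data generators** for every input: 3D nuclei with a
  fixed-composition Potts label field, compacted rim and carved IC channels,
  marker and replication-domain channels; halo images; decay traces with a
  non-responder fraction; contact matrices with planted compartments,
  clusters, loops and a strengthening cluster. Each exports its ground
  truth, so every downstream module is testable without any external data.

## Worked example

```r
library(nucarch)

spec <- nucleus_scene_spec(seed = 21)            # 128 x 128 x 32 voxels
spec$class_sigma <- min(diff(spec$class_means)) / 2  # heavy emission overlap
sc <- generate_nucleus_scene(spec)

mask <- nucleus_mask(sc$truth$mask, spec$voxel_size)
cf <- fit_hmrf(sc$channels$DAPI, mask, hmrf_params(beta = 0.8))

mean(cf$labels[sc$truth$mask] == sc$truth$label_field[sc$truth$mask])
#> [1] 0.9577263
round(class_profile(cf), 3)
#> class1 class2 class3 class4 class5 class6 class7
#>  0.097  0.124  0.185  0.145  0.121  0.091  0.237
round(cf$params$mu)
#> [1]  6012 14863 24042 33327 42361 51010 59749
```

Even with the emission noise at half the inter-mean gap (adjacent classes
overlap heavily voxel by voxel), the spatial prior recovers ~96% of voxel
labels; the fitted class means land within ~1.5% of the generator's
(6000–60000), and the class profile tracks the planted fractions. The
per-class profile is what the condition comparisons (control vs 6 h auxin
vs 30 h MLN) are built on.

The full study-shaped analysis lives in `analysis/01...07` — numbered
scripts that generate the three experimental conditions, classify
compaction, profile SC35-like and H3K27me3-like markers, segment and
compare replication domains, filter degradation traces, quantify halos and
run the Hi-C/Repli-Seq analyses, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_scenes.R   # then 02 ... 07 in order
```

Representative output (script 06, DNA halo):

```
median R control: 3.34 um, auxin: 4.38 um
two-sided Wilcoxon rank-sum p = 2.56e-07
```

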