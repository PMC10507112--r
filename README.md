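# neutroscreen

Quantitative analysis of genome-wide CRISPR-interference (CRISPRi) screens of
neutrophil-like cell biology — proliferation, differentiation, and cell
migration — together with the single-cell imaging and cytometry assays used to
characterise screen hits. The package targets the HL-60 / dHL-60 experimental
system (pooled sgRNA libraries with 3 guides per gene and ~500 non-targeting
controls; transwell, chemokinesis, and 3D extracellular-matrix migration
assays; nuclei-tracking time-lapse microscopy; two-channel surface-marker flow
cytometry), but every component is parametric and reusable.

It is written for computational biologists who want a tested, end-to-end
reference implementation of this analysis style with synthetic-data generators
for every input, so each stage can be validated against known ground truth.

## What it computes

**Screen scoring.** Guide abundances are compared between a selected and a
reference population as pseudocount log2 fold-changes,

    lfc_g = log2(c_sel,g + 32) - log2(c_ref,g + 32),

median-centred per measurement (the median normalization, which also absorbs
depth differences). For differentiation and migration screens each measurement
column is scaled to unit variance before averaging; migration assays collect
two populations per replicate and the less-migratory population's fold-changes
are multiplied by −1 so both report the same phenotype sign. Guide scores are
averaged into gene scores over each gene's guide triple. Significance comes
from an empirical null of pseudo-genes — means of randomly drawn triples of
non-targeting control guides — with directional permutation p-values
`(1 + #{null at least as extreme}) / (1 + n_perm)`, doubled so null p-values
are uniform, and Benjamini–Hochberg FDR adjustment.

**sgRNA quantification.** Amplicon FASTQ reads (8-bp sample barcode + vector
flank + 20-nt guide) are mean-Phred filtered, demultiplexed, and mapped to the
library by exact sequence identity (optional single-substitution rescue).

**Cell tracking.** Nuclei are detected by disk mean-filter background
suppression, Otsu thresholding, and intensity-weighted centroids (weighted
average plane index for z); consecutive frames are linked by the one-to-one
assignment minimizing total displacement (maximum-cardinality, gated);
kinematics report speed, directed speed along a gradient axis, and angular
bias.

**Persistence inference.** Cell velocities follow a heterogeneous random walk
`v[t+1] = q v[t] + a xi[t]`; a sequential Bayesian filter on a 200 × 200
(persistence, activity) grid — likelihood update, box-kernel propagation,
uniform jump floor `p_min = 1e-5` — yields per-step posterior means of `q` and
`a` (activities up to 0.5 µm/s).

**Cytometry.** Scatter gating, a pooled-PCA co-induction axis over two
log-fluorescence channels, percentile-bootstrap CIs of the mean projection,
and two-sided Mann–Whitney U comparisons.

## Worked example

```r
library(neutroscreen)

lib <- simulate_guide_library(n_genes = 200, n_controls = 500, seed = 1)
eff <- gene_effects(lib, c(GENE00007 = -1.5, GENE00042 = 1))
cnt <- simulate_screen_counts(lib, eff, screen = "proliferation",
                              n_replicates = 4, depth = 1e6, seed = 2)
res <- score_screen(cnt, lib, n_perm = 1e5, seed = 3)
res
#> <screen_result> proliferation screen: 200 genes, 4 measurements, 500 controls
#>   significant at q < 0.05: 2
dplyr::arrange(tidy(res), q) |> head(4)
#> # A tibble: 4 × 7
#>   gene       score         p       q direction n_guides n_measurements
#>   <chr>      <dbl>     <dbl>   <dbl>     <int>    <int>          <int>
#> 1 GENE00007 -1.45  0.0000200 0.00200        -1        3              4
#> 2 GENE00042  0.936 0.0000200 0.00200         1        3              4
#> 3 GENE00158 -0.173 0.00182   0.121          -1        3              4
#> 4 GENE00063  0.162 0.00464   0.232             1        3              4
```

The two planted effects are recovered at q = 0.002 with estimated fold-changes
(−1.45, +0.94) close to the planted (−1.5, +1); every unperturbed gene stays
above q = 0.05. The slight shrinkage toward zero is the pseudocount acting at
~900 reads per guide. `autoplot(res)` draws the volcano.

The imaging side works the same way:

```r
tr  <- simulate_tracks(n_cells = 10, n_steps = 300, q = 0.7, a = 0.2, seed = 4)
fit <- infer_persistence(tr)
glance(fit)
#> # A tibble: 1 × 5
#>   n_cells mean_q mean_a grid_size   p_min
#> 1      10  0.675  0.199       200 0.00001
```

Ten simulated cells with true persistence 0.7 and activity 0.2 µm/s are
recovered at 0.675 and 0.199. `run_screen_demo()` and `run_tracking_demo()`
run these chains end to end — including FASTQ writing/re-quantification and
movie rendering/re-tracking — and write all tables plus a resolved
configuration into an output directory.

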