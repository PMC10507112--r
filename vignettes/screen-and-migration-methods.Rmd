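---
title: "Models and methods: CRISPRi screen scoring and neutrophil migration analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: CRISPRi screen scoring and neutrophil migration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutroscreen)
```

This vignette is the package's account of the statistics and algorithms it
implements, the choices that were genuinely open, and what its synthetic-data
validation does and does not establish about real data.

## The experimental system in brief

Pooled CRISPRi screens express one repressive sgRNA per cell from a
genome-wide library (3 guides per gene plus roughly 500 non-targeting
controls) in HL-60 cells, which can be differentiated into neutrophil-like,
post-mitotic dHL-60 cells. A phenotype is read out as a selection: cells that
proliferate, differentiate, or migrate through a transwell membrane or a 3D
extracellular matrix carry their guide with them, and deep sequencing of
PCR amplicons before and after selection converts the phenotype into
per-guide count changes. Migration assays collect *two* populations — the
migratory fraction and the cells left behind — each compared to the same
pre-assay reference. Screen hits are then characterised one gene at a time
with nuclei-tracking microscopy (speed, persistence) and flow cytometry of
differentiation markers.

## Guide quantification

Reads are laid out as an 8-bp sample barcode, a constant vector flank, the
20-nt guide, and a 3' flank.

* **Quality filter.** Reads with mean Phred score below 20 are removed. The
  threshold is the conventional amplicon choice; it is a parameter
  (`min_mean_q`) because "poor quality" is not a sharply defined quantity.
* **Demultiplexing** is exact by default. With `max_mismatch = 1` the barcode
  set is first checked to be pairwise separated by Hamming distance greater
  than 2 so assignments cannot be ambiguous; the built-in barcode generator
  (`sample_barcodes()`) enforces distance ≥ 3.
* **Guide mapping** is exact-only by default: the library's spacers are
  unique by construction, and exact hashing is fast and unambiguous. The
  guide is located by searching for the constant 5' flank and reading the
  next 20 nt, falling back to the fixed layout offset when the flank is not
  found (so a sequencing error in the flank does not lose the read). A
  single-substitution rescue exists behind `max_mismatch = 1`, off by
  default; rescues that match two library guides are left unmapped.

Indel-tolerant alignment is deliberately out of scope: the amplicon is a
fixed-layout PCR product and substitutions dominate.

## Screen scoring

For a selected/reference sample pair, the per-guide statistic is

$$\mathrm{lfc}_g = \log_2(c^{sel}_g + 32) - \log_2(c^{ref}_g + 32)
  - \mathrm{median}_{g'}(\cdot),$$

a pseudocount log2 fold-change, median-centred across guides. The pseudocount
(default 32) bounds the fold-change of poorly represented guides; at typical
coverage (hundreds of reads per guide) it shrinks true effects mildly toward
zero — about 0.1 log2 units for a unit effect at 900 reads per guide — which
is visible in the recovery analyses and is the accepted cost of variance
control. Median centring implements per-measurement normalization and absorbs
sequencing-depth differences in one step; no separate size-factor model is
used.

Measurement columns (replicate × population) are then combined:

1. less-migratory population columns are multiplied by −1, so that a gene
   whose knockdown keeps cells out of the migratory pool scores negative in
   *both* populations;
2. for differentiation and migration screens each column is scaled to unit
   variance (assays differ widely in dynamic range; proliferation screens
   are left unscaled so the score stays in raw log2 units);
3. columns are averaged per guide, and guide scores are averaged per gene.

**The permutation null.** Gene scores are means of guide triples, so the
null model is built the same way: pseudo-genes are means of `group_size = 3`
control guides drawn without replacement within a triple, independently
across `n_perm = 1e5` draws. The p-value is directional — the tail is chosen
by the sign of the gene score relative to the null median — with the add-one
correction, and then doubled (capped at 1). Doubling was an open design
point: the directional p alone is uniform on (0, 0.5] under the null, which
would make a nominal α reject at 2α and distort FDR calibration; doubling
restores uniform null p-values while the reported `direction` column keeps
the one-sided information. `permutation_p(..., two_sided = FALSE)` exposes
the raw directional p.

**A calibration caveat.** All genes are tested against the *same* empirical
null built from ~500 control guides, so their p-values share that null's
sampling error (order 1/√500). Individually the p-values are valid, but
across 15,000 genes their deviations from uniformity are correlated: a
goodness-of-fit test of the pooled p-value distribution at genome scale can
detect the shared wobble in a substantial fraction of simulated screens,
even though the realised FDR stays far below nominal (in null simulations
essentially no gene reaches q < 0.05). This is a property of any
finite-control empirical null, not of the implementation; with many more
controls the effect disappears.

**Benjamini–Hochberg** adjustment is the standard step-up procedure applied
across all genes within a screen (no per-direction split).

## The count simulator

The generator exists so every scoring property can be tested against known
truth. Its fixed modelling choices:

* Reference guide abundances are log-normal with sd 1 in log2 units — the
  typical skew of a plasmid library. The distribution of the physical
  library is not otherwise constrained, and this choice matters mainly
  through the pseudocount (low-abundance guides shrink more).
* Sequencing counts are Gamma–Poisson (negative binomial) around
  `depth × abundance share`, with dispersion 0.01 by default — the modest
  replicate-level overdispersion of well-executed amplicon sequencing.
  `dispersion = 0` is an exact multinomial draw, so column sums equal the
  depth exactly and round-trip tests are bit-exact.
* Selection screens multiply a guide's expected abundance by `2^effect`.
  Migration screens instead split each guide's cells binomially between the
  migratory and remaining pools, with the effect shifting the log-odds of
  migrating by `effect × log 2` around a baseline migration probability of
  0.3 (the scale of a 2 h transwell assay). For rare migration the migratory
  log2 fold-change approaches the effect; the remaining pool moves less, so
  after the −1 flip the two populations agree in sign but not magnitude —
  exactly the asymmetry the real dual-collection design has.

The simulator does **not** model PCR amplification bias beyond NB
dispersion, guide-specific knockdown efficacy differences within a gene,
cell division during assays, or chimeric reads. Passing recovery tests on
synthetic data therefore validates the *statistics*, not robustness to those
real-data artifacts.

## Nuclei detection and tracking

Detection subtracts a disk mean filter (radius 50 px by default, matching
nuclei imaged at ×20) from each frame, clips at zero, thresholds with Otsu's
method, and keeps connected components of at least `min_area = 30` px (both
parameters are configurable; the threshold and minimum size were free
choices). Centroids are intensity-weighted, 0-based, pixel-centre. For z
stacks, detection runs on the z-sum projection and the z coordinate is the
intensity-weighted mean plane index over the component footprint — exact for
symmetric intensity profiles.

Linking minimizes the *total* displacement between consecutive frames as a
maximum-weight bipartite matching with weights `C − d` and `C` large enough
that match count dominates: among gate-feasible assignments, the matching
keeps as many cells as possible and, among those, the minimum summed
displacement. The gate `max_disp` defaults to 3× the median
nearest-neighbour displacement between consecutive frames (a calibration
pass); in the intended regime — cell spacing much larger than per-step
motion — the gate is rarely active. There is no gap closing and no merging:
a missed detection terminates the track, matching the consecutive-frame
design of the analysis. Exactness of the assignment is verified against
exhaustive enumeration for frames up to 6×6.

Kinematics use non-overlapping step velocities `Δx/dt`. Directed speed is
the mean projection on a unit gradient axis; angular bias is
`90° − mean |angle(v, axis)|`, zero for isotropic motion.

## Persistence–activity inference

Velocities follow the heterogeneous random walk
`v[t+1] = q[t] v[t] + a[t] ξ[t]`, ξ isotropic standard Gaussian per axis:
`q ∈ [−1, 1]` is persistence (0 diffusive, negative reversive), `a ≥ 0` the
activity (noise amplitude, µm/s after conversion by the frame interval).
The sequential filter tracks a posterior over a `200 × 200` grid of `(q, a)`
with activities in `(0, 0.5]` µm/s:

1. multiply by the step likelihood (isotropic Gaussian of
   `v[t+1] − q v[t]` with per-axis variance `a²`) and renormalize;
2. record the posterior means `q̂_t`, `â_t`;
3. propagate: convolve with a box kernel of radii (2, 2) grid cells
   (edge-truncated with per-cell renormalization, then grid-renormalized)
   and mix with the uniform distribution at weight `p_min = 1e-5`, which
   lets the posterior jump after abrupt behavioural changes.

Estimates are recorded *after* the likelihood update (the filtered
posterior), before propagation; per-cell summaries are unweighted means of
the per-step estimates. The filter is forward-only — no backward smoothing
pass — so estimates at time t use only data up to t; this is the simplest
reading of a sequential inference and keeps change-point response causal
(simulations show the estimate's sign flips within ~10–20 steps of a
mid-track persistence reversal). 3D tracks use all three velocity components
(d = 3 in the likelihood) by default, restrictable to xy with `use_z =
FALSE`.

Numerical details: the a-grid starts at `a_max/G` rather than 0 (zero
activity has a degenerate likelihood); per-step likelihoods are
max-normalized in log space, and weights below `exp(−45)` of the per-step
maximum are set to zero, which avoids denormal-arithmetic stalls without
measurable effect above the `p_min` floor; a step whose likelihood
underflows everywhere resets that step to the uniform distribution. The
inner loop is compiled (Rcpp) because a 200×200 grid over hundreds of steps
and cells is the routine workload. Recovery over the lattice
`q ∈ {−0.5, 0, 0.5, 0.9} × a ∈ {0.05, 0.2, 0.4}` µm/s with 500-step tracks
achieves median absolute errors of ~0.02 in `q` and ~0.002 in `a` µm/s.

The track simulator draws initial velocities from the stationary
distribution (per-axis sd `a·dt/√(1−q²)`), so constant-parameter tracks are
stationary from the first step; the empirical lag-1 velocity autocorrelation
then equals `q` and memoryless walks have exactly linear mean squared
displacement — both are tested invariants.

## Flow-cytometry co-induction axis

Events are analysed in log10 fluorescence. Gating retains events strictly
inside a polygon (point-in-polygon) or ellipse (Mahalanobis) gate. The
differentiation axis is the leading eigenvector of the 2×2 covariance of
*pooled* events from all samples being compared — pooling is what makes
projections of different cell lines comparable on a single axis; per-sample
PCA would give each line its own axis and was rejected for that reason. The
sign convention makes both loadings non-negative when possible, so
double-positive (differentiated) cells project positive; with exactly equal
eigenvalues the axis is set to the diagonal with a warning.

Uncertainty on the mean projection uses the percentile bootstrap (default
10⁴ resamples, 99% level). Percentile rather than BCa: the statistic is a
plain mean over thousands of events, where the percentile interval's
coverage error is negligible (measured 98–99% coverage at nominal 99% over
1000 simulated datasets). Group comparisons use the two-sided Mann–Whitney
U test: exact when both groups have ≤ 8 untied values, otherwise the
tie-corrected normal approximation; identical groups return p = 1 with a
warning rather than an error.

## Reproducibility and problem sizes

Every stochastic function takes an explicit `seed` and leaves the caller's
RNG state untouched; the demo pipelines derive per-stage substreams from one
root seed, so outputs are byte-reproducible. The bundled analyses use
desk-scale problem sizes chosen to exercise every code path at full
parameter settings: genome-scale null calibration at 15,000 genes × 3
guides + 500 controls and depth 10⁶; effect recovery on focused 200-gene
libraries (where the pseudocount bias is small relative to a unit effect);
persistence recovery on 500-step tracks with the full 200-point grid; and
rendered-movie tracking on dozens of cells. These are the package's own
validation conditions, not statements about any particular dataset.

## Known limitations

* The empirical control null couples p-values across genes (see above);
  genome-scale uniformity diagnostics on pooled p-values are accordingly
  noisy around their nominal level.
* Exact-match quantification discards reads with errors in the barcode or
  spacer; with substitution rate e per base the expected loss is
  `1 − (1−e)^28`, which is measured, not corrected.
* The tracker neither closes gaps nor resolves merges; dense fields or
  blinking detections fragment tracks rather than risk identity swaps.
* The persistence filter is forward-only; a smoother would tighten
  change-point localisation at the cost of causality.
* The flow model has no compensation/spillover handling; it assumes
  pre-compensated two-channel data.
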