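---
title: "Whole-genome transcript expression profiling with the CGE index: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome transcript expression profiling with the CGE index: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgescan)
```

## The problem

Time-series RNA-seq experiments that compare treatment regimes across
several tissues — the motivating case is Atlantic salmon moved from fresh
water to seawater either gradually (GSC) or by direct salinity shock (SS) —
produce coverage tracks over a chromosome-level genome for every condition
and molecule class (mRNA libraries and small-RNA/miRNA libraries). Most of
that signal never reaches a gene-level differential-expression table.
`cgescan` works directly on the coverage graphs: it finds *threshold areas*
(genomic intervals whose windowed coverage sits inside a stated band),
quantifies how strongly each locus differs between conditions with a
bounded percent index, relates mRNA and miRNA activity at the same loci,
and emits everything as Circos-ready text tracks.

## The CGE index

For a locus (region) with per-condition mean coverages
$\bar X_1, \dots, \bar X_n$ ($n \ge 2$), the chromosome genome expression
index is

$$\mathrm{CGE} = 100 \cdot
  \frac{\max_i \bar X_i - \min_i \bar X_i}{\max_i \bar X_i + \min_i \bar X_i}.$$

Properties that make it usable as a heatmap statistic:

* bounded in $[0, 100]$;
* 0 iff all condition means are equal; 100 iff the locus is silent in at
  least one condition and active in another (presence/absence);
* symmetric under permuting conditions and invariant under rescaling all
  means by a common factor (so it does not depend on sequencing depth
  shared by all libraries);
* for two conditions it reduces to the symmetric percent difference
  $100\,|a-b|/(a+b)$.

The index is descriptive — no p-value is attached to it. An all-zero locus
is defined to have CGE 0: an untranscribed region exhibits no variation.
`cge_index(..., denominator = "mean")` provides the alternative
normalization $100 (\max - \min)/\overline{X}$ for users who prefer a
mean-relative spread; the default is the bounded form above, which is the
only one that keeps a percent scale for a heatmap. Library-size
normalization between conditions is deliberately *not* applied by default
(tracks are taken as given); `score_regions(scale = ...)` accepts
per-track factors when the user wants to normalize.

## Threshold areas

The per-base coverage graph of each condition is reduced to tiling window
means (`windowed_mean`, default window 10 positions; the trailing partial
window is averaged over its actual length). Tiling rather than sliding
windows were chosen: they are what a downstream interval report needs
(disjoint support, unambiguous boundaries), and this choice is documented
because graph-threshold tools differ here.

`threshold_areas` then reports maximal runs of consecutive windows whose
mean lies in the inclusive band `[low, high]` (defaults 10,000–90,000, the
band appropriate for deeply sequenced pooled transcriptome tracks; for
simulations the band is rescaled to the simulated depth, since the
thresholds are in the units of the input track). Two knobs generalize the
literal definition and default to it: `merge_gap` (runs separated by at
most that many out-of-band windows are merged; a merged region *spans* the
gap windows, and its `n_windows` and base-weighted `mean_coverage` are
computed over the full span) and `min_windows` (regions spanning fewer
windows are dropped). One-sided scans use `low = 0` or `high = Inf`.
Regions detected on several condition tracks are pooled by interval union
(`detect_threshold_regions`): a locus in band in *any* condition is
scored.

## Opposition calls

With exactly two conditions, a locus is *opposed* when the mRNA coverage
change $\bar X_2 - \bar X_1$ and the miRNA change at an overlapping locus
have strictly opposite signs and both loci vary enough
(both CGE $\ge$ `cge_cutoff`, default 20). Matching is any ≥ 1 bp overlap
by default; `min_reciprocal` tightens it. This is a sign test on coverage,
not a target-prediction claim: it flags loci whose mRNA and miRNA activity
move in opposite directions, the pattern expected where miRNAs repress
their local targets.

## Flanks, summaries, Circos

`extract_flanks` cuts `[start - 10\,\mathrm{kb}, end + 10\,\mathrm{kb})`
genome sequence around each detected area (clipped silently at chromosome
bounds, with a `clipped` flag), the window used to re-anchor assembled
contigs near threshold areas. `chromosome_summary` aggregates region CGE
per chromosome with *length-weighted* means — weighting by region count
would let many tiny regions dominate a chromosome's score. The Circos
writers (`write_karyotype`, `write_heatmap_track`, `write_line_track`,
`write_links`) emit byte-stable text (fixed palettes, fixed sort order, no
timestamps); heatmap values are raw CGE percents, and color binning is
left to the emitted `circos.conf` template. Ribbon class labels pass
through to deterministic colors but are not interpreted.

## Feature-level statistics

* **Correlation screen** (`correlation_screen`): all-pairs Pearson r
  between two TPM matrices over shared samples, two-sided p from
  $t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ df, significance at
  $\alpha = 0.01$ by default and *no* multiple-testing correction by
  default (an optional Benjamini–Hochberg mode is provided). Zero-variance
  features are excluded and reported rather than producing NaN.
  A pre-selected feature list (e.g. an externally computed
  differential-expression set) can restrict the screen; the package does
  not compute fold changes itself.
* **k-medians clustering** (`kmeans_manhattan`): features are
  mean-centered (profile shape, not abundance), distances are Manhattan,
  and centroids are updated with component-wise *medians* — the exact L1
  minimizer, which guarantees a monotonically non-increasing objective.
  The "5–6 rounds" of clustering are read as independent seeded restarts
  (default 6, k-means++-style seeding under L1; best objective kept);
  iteration counts are handled by convergence. `centroid = "mean"`
  reproduces conventional mean-update behaviour for comparison.
* **ΔΔCt** (`ddct`): per sample $\Delta Ct = Ct_{gene} - Ct_{ref}$; per
  gene $\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{calibrator}$;
  relative expression $2^{-\Delta\Delta Ct}$, with a housekeeping
  reference (EF-α-style) and a calibrator group (e.g. the freshwater
  control).

## The simulator and what passing tests show

`simulate_coverage` draws independent per-base depths — Poisson by
default, negative binomial for overdispersion, or `"none"` for the
deterministic noise-free limit — at a background rate outside planted
regions and at planted per-condition rates inside. The planted rates give
a closed-form expected CGE (`expected_cge`), so recovery is checkable
end-to-end. The default study conditions used by the tests and the
acceptance script: background 5×, ten 2 kb regions at 30× vs 90×
(expected CGE 50), window 10, band scaled to the simulated depth
([10, 1000]), 20 simulation seeds; opposition uses twenty 2 kb loci (ten
opposed, ten concordant) at 3× contrast. These sizes make every check
exhaustive at desk scale while keeping the law-of-large-numbers error on a
2 kb region far below the 3-percent-point recovery tolerance.

`simulate_expression` plants (gene, miRNA) pairs from a bivariate Gaussian
on the log scale, exponentiated to TPM-like positives. Exponentiation
attenuates a log-scale correlation $\rho$ on the raw scale by the
lognormal factor $(e^{\rho\sigma^2}-1)/(e^{\sigma^2}-1)$; the default
log-scale sd of 0.1 keeps that attenuation below 1%, so the planted
coefficient is what the TPM-scale Pearson screen should see. Raising
`log_sd` is the intended way to study how skew degrades the raw-scale
screen.

Known limitations of the simulator, hence of what green tests demonstrate:
per-base depths are independent (no read-length autocorrelation, so real
tracks are smoother than simulated ones at fixed mean), there is no
mappability structure, no library-size imbalance unless injected via
`scale`, and planted regions have sharp boundaries. Detection boundary
accuracy on real data will be window-quantized and blurred by read ends.

## Numerical and edge-case choices

* Coordinates are 0-based half-open everywhere internally (BED/bedGraph
  convention); FASTA record ids can be switched to 1-based inclusive.
* Overlapping bedGraph records are an error, never summed; unknown
  chromosomes in coverage input are skipped with a counted warning so that
  partial genomes work.
* Alignment depth counts CIGAR M/=/X and D as covered, N as uncovered
  (standard pileup convention); unmapped, secondary and supplementary
  records are always excluded; `min_mapq` defaults to 0 (the upstream
  mapper's multi-mapping policy is not second-guessed).
* Band bounds are inclusive at both ends; thresholds compare against
  window *means*, in the same units as the input track.
* Ranking ties in `chromosome_summary` break by layout order, with
  region-free chromosomes ranked after scored ones.
* k-medians re-seeds an empty cluster at the point farthest from its
  assigned centre; assignment ties go to the lowest cluster index.
* The pipeline (`run_pipeline`) is a deterministic composition of the
  stage functions — rerunning a config reproduces identical manifest
  hashes, and any stage failure aborts naming the stage.
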