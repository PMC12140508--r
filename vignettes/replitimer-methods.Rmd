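---
title: "Models and methods behind replitimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind replitimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`replitimer` implements the analysis chain from binned Repli-seq counts to
replication-timing (RT) tracks, RT segmentation, chromatin-feature
attribution, and Okazaki-fragment (OK-seq) strand-bias statistics. This
vignette records the models, the parameter choices, and the places where a
design had to be decided rather than copied, so that a reader can judge
exactly what a passing test suite does and does not demonstrate.

## The replication-timing model

RT is quantified per fixed-width genomic bin (default 50 kb, 0-based
half-open coordinates everywhere) as

$$\mathrm{RT} = \log_2\frac{E + c}{L + c},$$

where $E$ and $L$ are early- and late-S-phase read counts and $c = 1$ a
pseudo-count. Bins with $E + L < 20$ are masked rather than allowed to be
pseudo-count-dominated; both the pseudo-count and the mask are our
choices — zero handling is rarely stated in published pipelines and the
mask makes it irrelevant in practice.

Smoothing is a per-chromosome loess fit over bin index: tricube weights,
local quadratic, one pass, with span *fraction* = 300 kb / chromosome
length (the only reading under which a length-denominated span is
compatible with loess's fractional span parameter), clipped so at least 5
points enter each local fit, and evaluated with the exact ("direct")
surface. Reads are assigned to bins by fragment midpoint, which conserves
counts exactly and needs no overlap-weighting rule; a midpoint on a bin
boundary belongs to the right-hand bin. Truncated terminal bins shorter
than half a bin are excluded from smoothing.

Differential RT uses an unpaired two-sided Student's *t* with pooled
variance on the smoothed per-replicate tracks (3 vs 3 replicates by
default, df = 4), followed by Benjamini–Hochberg step-up across all
testable bins. Bins are labeled *earlier*/*later* only below the FDR
threshold (default 0.05). Degenerate bins (zero variance both sides,
equal means) get $p = 1$. Smoothing precedes testing because the smoothed
track is the quantity interpreted biologically; each replicate is smoothed
separately so between-replicate variance is preserved.

Principal components of replicate tracks are computed by SVD of the
bins × samples matrix after per-bin centering; the reported quantities
are the normalized squared singular values.

## Segmentation

`cbs_segment()` re-implements circular binary segmentation restricted to
linear (non-wrapping) arcs within each chromosome, which is how the
method is used on linear tracks in practice. For a segment of $n$ bins
the scan statistic for the arc $(i, j]$ of length $m$ is

$$Z_{ij} = \frac{|\bar{x}_{\text{in}} - \bar{x}_{\text{out}}|}
  {\hat\sigma\sqrt{1/m + 1/(n-m)}},$$

maximized over all arcs (cumulative-sum scan, capped at arcs of 5,000
bins — a documented speed limit far above any segment the package
produces). Significance is by permutation: the values of the segment are
shuffled (seeded), the max statistic recomputed, and the split accepted
iff the fraction of shuffles reaching the observed max is at most
`alpha`. With the conventional settings (`nperm = 1000`,
`alpha = 1e-15`) acceptance therefore requires zero exceedances; the
false-split probability per scan is bounded by $1/(nperm+1)$, which the
calibration tests measure at a workable `alpha = 0.05`. The permutation
loop is compiled (Rcpp) with an early exit once a split can no longer be
accepted.

After splitting, "sdundo" pruning repeatedly removes the weakest
changepoint while its flanking segment means are separated by fewer than
`undo_sd` **standard errors** of their difference,
$\hat\sigma_{\text{track}}\sqrt{1/n_1 + 1/n_2}$, with
$\hat\sigma_{\text{track}} = \mathrm{mad}(\Delta x)/\sqrt{2}$ a robust
residual-noise estimate from first differences. An earlier design scaled
the threshold by $\hat\sigma_{\text{track}}$ alone; that rule is
degenerate — at step size $s$ and noise $\sigma$ with
$undo\_sd \cdot \sigma = s$ (exactly the regime of the recovery tests)
every pruning decision sits on a knife edge and merging cascades collapse
the whole track — so the standard-error scaling was adopted as the
package's definition. It keeps the intended behavior (a split must be
many noise units beyond chance) while making `undo_sd = 5` usable on
megabase-scale RT domains.

## The segment × feature matrix

Peak signal is treated as CPM. For each feature, background density is
the CPM of reads outside all peaks divided by the non-peak bp — a
per-bp rate, because subtracting a genome-wide scalar from a per-peak
signal is dimensionally incoherent otherwise. Consensus peaks (present in
every replicate, ≥ 1 bp overlap) carry the mean replicate signal minus
background × peak length, floored at 0 for state matrices (negative
enrichment is noise); delta matrices may be negative by construction. A
peak's corrected signal is summed into the unique segment covering
strictly more than 50% of the peak; a 50/50 split contributes nowhere.
Matrices are log-transformed (`log(v + 0.01)`) and then divided by the
segment length in Mb; delta matrices use the signed log
`sign(v) log(|v| + 0.01)` because the plain log is undefined on
negatives. Logging before length-normalization is our resolution of an
order ambiguity; it keeps the length correction linear on the modeled
scale.

## Elastic-net attribution

`fit_elastic_net()` centers and scales every feature column (constant
columns are zeroed with a warning), then searches mixing parameter
$\alpha \in \{0, 0.1, \ldots, 1\}$ crossed with glmnet's geometric
penalty path, scoring each pair by mean RMSE over 5 repeats of 5-fold
cross-validation with seed-derived fold assignments, and refits the
winner on all rows. Weights are reported on the standardized scale (the
scale on which penalization operates and on which the original workflow
reports them); unstandardized weights are exported alongside. In-sample
predictions and their Spearman correlation with the observed target are
returned; cross-validated predictions can be recomputed from the recorded
scheme. The grid and the RMSE criterion are package choices — the
upstream workflow delegates both to its defaults — and are stated here so
results are reproducible. One numerical contract worth knowing: the
fitting engine expresses the penalty on an internally response-
standardized scale, so the closed-form ridge equivalent of penalty
$\lambda$ is $(X^\top X/n + (\lambda/\hat\sigma_y) I)^{-1} X^\top y/n$;
the test suite pins this correspondence to 1e-6 on a small instance.

Binary targets (initiation-zone presence per bin, from
`iz_bin_labels()`) are fit with the same penalized linear model on a 0/1
response; the model family behind the published IZ prediction is not
stated, and the linear choice keeps weights comparable across targets. A
logistic variant would change weight scales but not ranks in our
simulations.

Univariate and pairwise ordinary least-squares $R^2$
(`univariate_r2()`, `pairwise_r2()`) and the standardized two-predictor
regression of genotype differences in ΔRT on feature and transcription
differences (`coupled_change_regression()`) round out the regression
surface.

## OK-seq strand bias

Okazaki fragments mapping to the + (Crick) strand are products of
rightward-moving forks; `bin_stranded()` counts Watson/Crick per 1 kb bin
by fragment midpoint, and `rfd()` derives $\mathrm{RFD} = (C - W)/(C + W)$
and the Crick fraction, masking bins under 5 reads (variance control; the
identity $\mathrm{RFD} = 2\,\mathrm{CrickFraction} - 1$ holds bin-wise
wherever defined). Metagenes average the per-site Crick fraction per
offset bin over ±25 kb windows, flipping minus-strand sites; the
statistic for condition comparisons summarizes each site by its mean
Crick fraction over covered bins (equal weight per bin, not
read-weighted, to avoid depth confounding) and compares conditions by the
Kruskal–Wallis H test. `stratify()` forms rank quantiles with ties broken
by genomic order, and `filter_fold_change()` expresses the "more than
2-fold" gates as $|\log_2$ change$| > 1$.

## Reference-point matrices

`reference_point_matrix()` mirrors the usual computeMatrix
reference-point behavior: the anchor is the interval midpoint (1 bp TSS
records make that the TSS; for stranded records minus-strand offsets are
flipped), each offset-bin cell is the unweighted mean of overlapping
track bins, flanks leaving the chromosome yield missing cells (kept), and
`missing_as_zero` substitution is applied before `skip_zeros` row
dropping, matching the observable order of those flags. Display smoothing
in `mean_profile()` never feeds statistics.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions, chosen once:

* genome: 2 chromosomes × 50 Mb, 50 kb bins; RT domains 10–40 bins
  (0.5–2 Mb, matching megabase-scale RT domains with ~1 Mb median
  segments), levels uniform in [−3, 3], edges rounded by a 1-bin Gaussian
  kernel;
* differentiation: 30% of bins change RT, half earlier/half later, with
  |ΔRT| = 1.0; the "mutant" genotype multiplies both ΔRT and the coupled
  feature's signal change by a suppression factor (default 0);
* Repli-seq: 3 replicates, expected 50 reads per bin per fraction,
  replicate noise sd 0.2 (log2 units) added to RT before sampling; reads
  follow $N \sim \mathrm{Pois}(2\,\mathrm{depth})$,
  $E \sim \mathrm{Bin}(N, 2^{RT}/(1 + 2^{RT}))$, so the pipeline's
  log-ratio is the exact inverse of the logistic link at infinite depth;
* features: 21 features, causal weights (+1.0, +0.6, −0.8) on the first
  three, peak probability 0.8 per bin, 2 kb peaks, baseline 4 CPM,
  per-peak noise 0.5, replicate noise 0.2, background 2% of a 1M-read
  library. Peak locations and per-peak baselines are drawn once per
  feature and shared across states and genotypes, so condition contrasts
  isolate the coupled shift;
* origins: Poisson-spaced every ~200 kb, baseline efficiency
  U(0.15, 0.45); in the differentiated state efficiency moves by
  0.3 × ΔRT (clipped to [0.02, 0.98]), encoding the feature–RT–origin
  coupling as one recoverable parameter. Fork polarity interpolates
  linearly between consecutive origins — at an origin of efficiency $e$
  the rightward probability steps from $(1-e)/2$ to $(1+e)/2$ — the
  simplest model producing sigmoidal RFD transitions; no explicit
  termination-zone model. Okazaki lengths are N(150, 15) bp, truncated at
  50 bp.

Coupling strength (0.8) and the efficiency coupling (0.3) are free
parameters of the generator: no quantitative value links feature change
to ΔRT in real data, so these are set to make the effect comfortably
inside the detectable range rather than to mimic a measured number.

All randomness derives from one master seed via keyed substreams, so any
(state, genotype, replicate, assay) combination is reproducible in
isolation.

**What passing tests show — and don't.** The generator's bins are
exchangeable given the latent landscape: there is no mappability bias, no
copy-number structure, no sequence composition, no realistic peak-shape
or fragment-length structure, replicates differ only by iid noise, and
feature–RT coupling is linear by construction. Recovery results therefore
validate the *computational* chain (estimators, statistics, bookkeeping),
not robustness to the artifacts of real sequencing data, which upstream
alignment/filtering pipelines are assumed to have handled.

## Problem sizes and numerical choices

The validation suite runs the default 2,000-bin genome for RT recovery
(Spearman ≥ 0.95 against the latent landscape), 20 null runs of an
800-bin chromosome for FDR control, five such runs for sensitivity, a
1,100-bin track with 10 planted breakpoints for segmentation recovery
plus 50 pure-noise tracks for calibration, a ~1,000-segment genome for
elastic-net recovery, and ~1.2M-fragment OK-seq libraries for the
end-to-end contrast — sizes chosen to make every recovery property
measurable while a full run stays interactive. The sensitivity experiment
is sequenced at depth 500 so that the stated replicate noise (sd 0.3) is
the operative noise source; at the default depth 50 the binomial counting
noise is of the same magnitude and detection is bounded by counting
noise rather than by the quantity the experiment varies. Detection is
scored per planted domain (some bin inside the domain significant with
the right direction) — the per-bin rate is also reported but is limited
by the df-4 t distribution's p-value floor under BH at 30% prevalence.

Other numerical conventions: loess uses the exact surface rather than
interpolation; the CBS scan uses mean-centered cumulative sums with a
precomputed per-arc-length scale factor; permutation decisions exit early
once rejection is certain, which changes random-stream consumption but
no decision; elastic-net coordinate descent runs at a tightened
convergence threshold (1e-12 for the final fit) so closed-form checks at
1e-6 are meaningful; ties in stratification are broken by genomic order
to keep labels deterministic.

## Interfaces and scope

The package's surface is its exported functions plus
`scripts/acceptance.R`; the pipeline stages named `simulate`, `rt`,
`segment`, `features`, `fit`, `okseq`, `metagene` exist as function
groups rather than shell subcommands, since the intended users work in R
and every stage consumes and returns tibbles. BED, SEACR-BED, bedGraph
and TSV round-trips are provided; BigWig is treated as a pure format
conversion concern outside the package (no figure-bearing computation
depends on it). Alignment, peak calling, k-means heatmap ordering and all
figure aesthetics are out of scope.

## Known limitations

* Permutation p-values are granular at 1/nperm; with `alpha` below that
  granularity, acceptance means "no shuffle reached the observed max".
* The Kruskal–Wallis comparison gives every site equal weight; very
  low-coverage sites contribute as much as deep ones (masked bins are
  simply dropped from the per-site mean).
* `corrected_peak_signal()` assumes replicate peak sets are
  non-overlapping within a replicate (true of sparse-enrichment peak
  callers); heavily overlapping custom peak sets would need pre-merging.
* The elastic-net weight ranking is stable in simulations, but weight
  *magnitudes* depend on the selected penalty and should be read
  comparatively, not as effect sizes.
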