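# replitimer

Linking DNA replication timing to chromatin state and replication origin
activity.

`replitimer` is an R toolkit for the analysis chain that connects three
genome-wide readouts of DNA replication in mammalian cells:

* **Repli-seq replication timing (RT)** — nascent DNA is sequenced from
  early and late S-phase fractions, reads are summed into fixed 50 kb bins,
  and RT is the loess-smoothed `log2(early / late)` per bin (positive =
  early replication). State or genotype differences (ΔRT) are tested per
  bin with a pooled-variance Student's *t* across replicates and
  Benjamini–Hochberg correction.
* **Chromatin feature attribution** — RT and ΔRT tracks are partitioned
  into domains by circular binary segmentation (permutation-tested splits,
  "sdundo" pruning); background-corrected CUT&Tag-style peak signal is
  summed per segment into a segments × features matrix; an elastic-net
  regression (repeated 5×5 cross-validation over a mixing × penalty grid)
  attributes RT to individual chromatin features through its standardized
  parameter weights.
* **OK-seq replication fork directionality (RFD)** — stranded Okazaki
  fragment reads in 1 kb bins give per-bin
  `RFD = (C − W)/(C + W)` and Crick fraction `C/(W + C)`; ascending RFD
  transitions mark replication initiation. Strand-bias metagenes around
  stratified reference points and Kruskal–Wallis tests on per-site Crick
  density quantify origin-activity differences between conditions.

Every stage runs on tidy tibbles (bins, intervals, matrices) and chains
with the pipe. A seeded synthetic-data generator (`sim_config()`,
`simulate_*()`) produces genomes with a known piecewise-smooth RT
landscape, causally weighted feature peaks, differentiation-coupled RT
shifts with a suppressible "mutant" genotype, and origin-driven stranded
Okazaki reads — so the whole pipeline is validated against ground truth.

## Worked example

Simulate a 25 Mb chromosome, push the reads through the RT pipeline, and
segment the smoothed track:

```r
library(replitimer)

cfg   <- sim_config(n_chromosomes = 1, chrom_length = 2.5e7, seed = 42)
truth <- simulate_rt_landscape(cfg)

counts <- simulate_repliseq_counts(truth, "naive", replicates = 1)
early  <- truth$rt; early$value <- counts$early
late   <- truth$rt; late$value  <- counts$late

rt <- compute_rt(early, late) |> loess_smooth()
correlate_tracks(truth$rt, rt)
#> [1] 0.976

seg <- cbs_segment(rt, cbs_params(seed = 1))
head(seg, 4)
#> # A tibble: 4 × 6
#>   segment_id chrom   start     end n_bins  mean
#> 1 seg0001    chr1        0 1250000     25 1.67
#> 2 seg0002    chr1  1250000 2450000     24 2.17
#> 3 seg0003    chr1  2450000 2500000      1 1.17
#> 4 seg0004    chr1  2500000 4000000     30 0.179
nrow(seg)
#> [1] 19
```

The recovered Spearman correlation of 0.976 against the latent landscape
and 19 segments against 20 planted domains show the binned counts, the
log-ratio, the smoothing, and the segmentation working together. From
here, `build_feature_matrix()` + `fit_elastic_net()` recover feature
weights (`tidy()`, `glance()`, `autoplot()` expose the fit),
`bin_stranded()` + `rfd()` + `strand_bias_metagene()` handle the OK-seq
side, and `quartile_integration()` joins the two.

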