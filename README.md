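# arrestseq

Analysis of bulk mRNA-seq time courses of starvation-arrested *C. elegans*
L1 larvae — and of the tissue-specific RNA Pol II degron (AID) experiments
used to separate **transcription-driven** from **transcript-stability-driven**
expression changes.

Starved L1 larvae arrest development; their transcriptome keeps changing for
days. Most of that apparent regulation is relative: total RNA per worm falls
roughly two-fold between 36 h and 132 h of arrest, somatic transcription
continues (and can be abolished with an auxin-inducible degron on AMA-1, the
large RNA Pol II subunit), while the germline is transcriptionally quiescent
but its transcripts are exceptionally stable — so germline genes appear
up-regulated without any transcription. `arrestseq` implements the complete
computational pipeline for this biology and ships a ground-truthed synthetic
data generator that emulates it, so every stage is testable end to end.

## What is implemented

| Stage | Method |
|---|---|
| Expression filter | CPM > 1 in ≥ 4 libraries, or counts > 10 in ≥ 4 samples |
| Time-course DE | per-gene NB log-linear GLM, likelihood-ratio test across all time points (df = groups − 1), BH FDR |
| Pairwise DE | same GLM, df = 1, log2 fold change |
| Dispersion | Pearson moment estimator per gene, shrunk 50/50 to a mean–dispersion trend (floor 1e-8, cap 10) |
| PCA / rate of change | on log2 mean-normalized CPM; mean cross-replicate Euclidean distance between adjacent time points ÷ Δt |
| Clustering | seeded greedy complete-diameter clustering on d = 1 − Pearson r, max diameter 0.2 (so within-cluster r ≥ 0.8) |
| Heatmap order | clusters sorted by peak time point, then centroid (half-mass rule), then peak Z (descending for peaks in the first six time points, ascending for the last six) |
| Enrichment | exact upper-tail hypergeometric test of gene groups (GMT) per cluster |
| Normalization | upper-quartile factors; control-gene (spike-in) SVD factor of unwanted variation, k = 1 |
| Absolute quantification | per-sample log10–log10 regression of spike counts on known concentrations (attomoles/µL), converted to attomoles per worm via spike volume and worms-per-sample |
| Classification | transcription-dependent (down under soma degron + auxin) ∩/∖ high-confidence up-regulated (up 36→132 h with solvent in all four strains) |
| Simulation | per-gene birth–death dynamics da/dt = s(t) − k·a over four archetypes, gamma-multinomial counts with exact library totals, 92-species spike-in mix, full truth tables |

## Worked example

```r
library(arrestseq)

ds  <- simulate_timeseries(n_genes = 2000, seed = 1)   # 12 time points x 4 reps
dir <- file.path(tempdir(), "sim"); write_dataset(ds, dir)

res <- run_timeseries(timeseries_config(
  file.path(dir, "counts.tsv"), file.path(dir, "samples.tsv"),
  genesets = file.path(dir, "genesets.gmt"),
  out_dir  = file.path(tempdir(), "run")))

res$clustering
#> diameter clustering: 1563 genes in 14 clusters (max diameter 0.2, seed 1)
head(res$ordering$summary, 3)
#>   cluster size peak_timepoint centroid_timepoint   peak_z
#> 1      11    3              1                  5 2.285165
#> 2       1  600              1                  6 1.823463
#> 3      12    3              2                  6 1.469489
```

The run log records every filter and test tally:

```
read 2092 genes x 48 samples
filter: 2000 of 2000 genes expressed (cpm > 1 in >= 4 libraries)
time-course LRT: 2000 of 2000 genes at q < 0.05
clustering input: 1563 genes at q < 1e-30
clustering: 14 clusters (max diameter 0.2, seed 1)
enrichment: 42 group x cluster cells, 6 at p < 0.01
```

Nearly every simulated gene is differentially expressed across the time
course (the real dataset shows the same: starvation touches most of the
transcriptome), the q < 1e-30 subset excludes the flat archetype, and the
compartment gene sets land in the expected clusters — the germline set is
perfectly enriched in the late-peaking cluster (p ≈ 0), muscle in the large
monotone-down cluster.

The degron workflow classifies transcription dependence and reproduces the
compartment pattern (counts from `run_aid` on the default 2,000-gene
simulation, seed 1):

```r
aid <- simulate_aid(n_genes = 2000, seed = 1)
write_dataset(aid, "aid_dir")
res <- run_aid(aid_config("aid_dir/counts.tsv", "aid_dir/samples.tsv",
                          "aid_dir/spikes.tsv", out_dir = "aid_run"))
res$classified
#> classified sets (FDR 0.05, strict mode):
#>   transcription-dependent:      999
#>   high-confidence up-regulated: 710
#>   td up-regulated (overlap):    456 (64%, hypergeometric p = 1.35e-21)
#>   ti up-regulated:              254
```

DE genes in the auxin-vs-solvent contrast at 132 h: soma degron 1074,
germline degron 11, TIR1-only controls 0 — transcription continues in the
soma, not the germline. The spike read share rises only when somatic
transcription is abolished (~0.044 vs ~0.018), the proxy for a falling
mRNA-to-total-RNA ratio.

## Command line

```sh
exec/arrestseq simulate --mode timeseries --n-genes 2000 --seed 1 --out simdir
exec/arrestseq run-timeseries --config cfg.json
exec/arrestseq run-aid --config cfg.json
```

`cfg.json` holds the fields of `timeseries_config()` / `aid_config()`; every
run serializes its configuration, a content-hash manifest, and a log into the
output directory.

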