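# pausescape

Quantification of RNA polymerase II promoter-proximal pausing and
pause-release from aligned ChIP-seq and PRO-seq tags, for regulatory
genomicists studying signal-induced transcription (the motivating system
is LPS-stimulated macrophages, but nothing in the code is specific to
it).

## What it computes

The central statistic is the per-gene **pausing index**

    PI = (TSS tags / TSS length) / (body tags / body length)

with the TSS window at −250..+250 bp around the start site and the gene
body from +250 bp to the TTS, both strand-aware on a unique
longest-variant gene set (≥ 1 kb, chrM/unplaced contigs removed). Genes
are grouped as highly paused (PI ≥ 3, group 1), moderately paused
(1.5 ≤ PI < 3, group 2) or non-paused (PI < 1.5 or a signal-negative
TSS, group 3). TSS activity comes from a genome-wide Poisson-background
threshold: 500 bp windows at half-window steps, estimated FDR =
expected/observed windows above an integer count, threshold at
FDR < 0.001.

Around that core the package provides:

* assay-specific tag processing — ChIP-seq reads extended to 150 bp
  from their 5′ anchor; PRO-seq reads reduced to their 5′ base and
  counted on the strand **antisense** to each gene (the read is
  complementary to the nascent RNA);
* per-10-million normalization, 10 bp binned TSS signal matrices
  (−1 kb..+2 kb) and bedGraph export;
* a windowed peak caller with a condition-as-background differential
  mode, peak annotation (TSS / gene body / intergenic) and
  factor-positive (e.g. NELF⁺, PU.1⁺) gene calls;
* occupancy dynamics with an exact-binomial dismissal test
  (fold change < 0.5 and p < 0.05) and a peak-based cross-check;
* FPKM-based expression classes under stimulation and knockout
  ((FPKM+1) fold-change gates 1.5 / 1.4 / 0.6, q/p < 0.05;
  superinduced = induced in WT and further up in the knockout);
* binomial promoter motif enrichment (−1000..+100 bp windows, PWM
  scanning on both strands) and AP-1 target calling;
* a seeded synthetic multi-assay study generator with per-gene ground
  truth, so every stage is verifiable by parameter recovery without any
  external data.

## Worked example

Simulate a complete study (annotation, seven tag libraries, replicate
RNA-seq counts, promoters, truth table) and run the full analysis:

```r
library(pausescape)

study <- "study_dir"
d <- generate_dataset(generator_config(seed = 1), dir = study)
report <- run_all(study)
report
#> pausing pipeline run
#>   genes: 300
#>   activity thresholds: Pol II 19 tags, PRO-seq 19 tags
#>   groups (rest, ChIP): 150 / 78 / 72 (paused fraction 0.76)
#>   pause-release KS: D = 0.144, p = 0.0041
#>   NELF dismissal: 19 genes (binomial), 34 genes (peaks)
#>   superinduced genes: 33; AP-1 targets among NELF-: 7 of 10
```

Reading this: of 300 genes, any TSS window with more than 19 Pol II
tags is signal-positive at FDR < 0.001; 150 + 78 = 228 genes (76%) are
paused at rest; the LPS Pol II library shifts the PI distribution
(two-sided KS p = 0.004 over all genes — the planted release acts on the
60 induced genes); 19 genes lose NELF occupancy by the count test at the
default dismissal factor 0.5 (a boundary case by construction — the
planted factor sits exactly at the fc < 0.5 gate); and 7 of the 10
NELF⁻ superinduced genes carry an AP-1 promoter motif. Per-gene detail
lives in the report tables:

```r
head(report$pausing_rest[, c("symbol", "tss_count", "body_count",
                             "pi", "tss_active", "group")], 5)
#>   symbol tss_count body_count       pi tss_active group
#> 1   g001         2          5 2.674400      FALSE     3
#> 2   g002        97        118 6.548322       TRUE     1
#> 3   g003       103        121 8.830760       TRUE     1
#> 4   g004       105        699 2.162790       TRUE     2
#> 5   g005         0          1 0.000000      FALSE     3
```

and recovery against the generator's truth is direct:

```r
mean(report$pausing_rest$group == d$truth$group)
#> [1] 1
```

A thin command-line wrapper ships in `inst/cli/pausescape.R`
(`simulate` and `run` subcommands). The methods vignette
(`vignettes/pausing-methods.Rmd`) documents the model, every threshold,
and the design decisions.

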