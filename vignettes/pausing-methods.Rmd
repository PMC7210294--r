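---
title: "Quantifying promoter-proximal Pol II pausing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying promoter-proximal Pol II pausing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pausescape)
```

## The measurement problem

In resting macrophages (and most metazoan cells), a large share of
transcribed genes hold an engaged RNA polymerase II 20–60 nt downstream of
the transcription start site rather than releasing it into productive
elongation. `pausescape` quantifies this state from aligned sequencing
tags and tracks how it changes under stimulation: the **pausing index
(PI)** of a gene is the ratio of tag density (reads per kb) in a TSS
window to tag density in the gene body,

$$\mathrm{PI} = \frac{c_\mathrm{TSS} / \ell_\mathrm{TSS}}
                    {c_\mathrm{body} / \ell_\mathrm{body}},$$

with the TSS window spanning −250..+250 bp around the start site and the
body running from +250 bp to the transcription termination site. Genes
with an occupied (signal-positive) TSS and PI ≥ 3 are called highly
paused (group 1), 1.5 ≤ PI < 3 moderately paused (group 2), and PI < 1.5
— or an unoccupied TSS — non-paused (group 3). Both boundaries follow the
stated inclusive/exclusive convention exactly: PI = 3.0 is group 1,
PI = 1.5 is group 2.

Two assays feed this statistic with different conventions:

* **ChIP-seq** reads are extended from their 5′ end in read orientation
  to the 150 bp fragment length before counting (overlap of ≥ 1 bp with a
  window counts). The literal alternative of anchoring at the 3′ end is
  available via `extension_anchor = "three_prime"` but is not the
  default, because the fragment-length model is what a `-fragLength 150`
  style counting implements.
* **PRO-seq** reads are reduced to the single 5′ base of the aligned
  read, and — because the sequenced read is complementary to the nascent
  RNA — tags aligned **antisense** to a gene report polymerase on its
  sense strand. All PRO-seq counting in this package follows that
  convention (`sense_via_antisense`).

All internal coordinates are 0-based half-open; GTF input is shifted at
the parser boundary, and minus-strand genes take their span end as the
TSS with "downstream" always meaning the direction of transcription.

## Deciding which TSSs carry signal

Calling a TSS "occupied" needs an integer tag-count threshold that
adapts to library depth. We tile the genome with 500 bp windows at
half-window steps, model background as a uniform Poisson with
$\lambda = N \cdot w / G$ (library depth $N$, window $w$, effective
genome size $G$ excluding chrM/chrMT and unplaced contigs), and define
the estimated FDR at integer count $c$ as the Poisson-expected number of
windows with ≥ $c$ tags divided by the observed number. The activity
threshold is the smallest $c$ with estimated FDR below 0.001; a gene is
TSS-active when its window count is *strictly greater* than the
threshold. The same machinery drives peak calling: significant windows
are merged, each peak scored by its per-10M tag count, with the summit at
the base of maximal coverage. In differential mode a window must also
exceed the background library by a per-10M fold cutoff (default 4).

Numerical notes: the threshold scan runs over $c$ in `1..max(observed)`
and fails with `"no significant enrichment"` when nothing passes — on
pure-null data this is the expected outcome and the peak caller returns
an empty set. The estimated-FDR function is returned alongside the
threshold for inspection. Thresholds are computed genome-wide and then
applied to TSS windows, matching the stated order of operations;
computing them over TSS windows only is possible but not the default.

## Occupancy dynamics and dismissal

Factor occupancy (NELF-E, PU.1) is counted in TSS windows per condition.
A gene is factor-positive when a baseline peak summit falls inside its
TSS window. Dismissal between 0 h and 0.5 h is tested two ways:

1. **Count-based:** the depth-normalized ratio
   $fc = (c_{0.5}/N_{0.5}) / (c_0/N_0)$ with a two-sided exact binomial
   test of $c_{0.5}$ among $c_0 + c_{0.5}$ trials at success probability
   $N_{0.5}/(N_0+N_{0.5})$; dismissal requires $fc < 0.5$ and $p < 0.05$
   on the raw p-value (a BH-adjusted column is reported but does not
   gate, matching the stated raw-p criterion). The exact binomial is the
   zero-dispersion limit of a negative-binomial comparison; with a
   single library per condition no dispersion is estimable, so this is
   the honest version of that test.
2. **Peaks-as-background:** peaks called on the 0 h library with the
   0.5 h library as background; a gene is flagged when a summit lands in
   its TSS window. Here the fold cutoff defaults to **2**, not the
   generic 4: the count-based gate ($fc < 0.5$) corresponds to ≥ 2-fold
   enrichment of baseline over treated, and a 4-fold gate would be
   structurally unable to flag occupancy drops between 2- and 4-fold,
   making the two methods incomparable. Both cutoffs are configurable.

Degenerate inputs: genes with zero counts in both conditions get an
undefined ratio and are never dismissed; a zero body count with nonzero
TSS count gives PI = +∞, which classifies as group 1 when TSS-active and
is capped at the per-dataset finite maximum before ECDF/KS comparisons
(dropping infinite values instead would discard exactly the most-paused
genes from the comparison).

## Expression response classes

FPKM is computed as $c \cdot 10^9 / (\ell \cdot N)$; the per-condition
value averages replicate fragment counts first and then normalizes by
the mean replicate library size (average-then-normalize). Genes with
resting FPKM ≥ 1 (inclusive) are "expressed". All fold changes are
pseudocounted $(\mathrm{FPKM}+1)$ ratios with inclusive boundaries:
1 h-inducible needs $q < 0.05$ and FC ≥ 1.5; 0.5 h induced/suppressed
need raw $p < 0.05$ and FC ≥ 1.4 / ≤ 0.6; knockout up/down use the same
1.4/0.6 cuts against $p < 0.05$; superinduced = induced at 0.5 h in WT
and further up in the knockout at the same timepoint (more-suppressed is
the mirror). Significance comes from a per-gene Welch t-test on
$\log_2(\mathrm{FPKM}+1)$ across replicates with Benjamini–Hochberg
adjustment where a q-value gates — a deliberately simple, documented
replicate test; with a single replicate per side the p is `NA`, a
warning is logged, and classification proceeds on fold change alone.
With three replicates this test has good power for the 3-fold effects
the generator plants in p-gated classes (measured sensitivities are in
the high 0.9s in the test suite) but the q-gated 1 h class pays an extra
BH penalty and sits nearer 0.8 — a known property of the design, not a
defect of the data.

## Promoter motifs

Promoters are the strand-aware −1000..+100 bp window around the TSS.
PWMs carry per-position probabilities with a 1e-3 pseudocount before
log-odds against a uniform background; a window is a hit when its score
reaches 0.8 of the maximal log-odds, scanned on both strands, with `N`
scoring as background (zero contribution). Enrichment of a target
promoter set against background promoters is the upper binomial tail
$P(X \ge k \mid n, r)$ where $r$ is the background fraction of promoters
with ≥ 1 hit, with enrichment declared at $p < 0.001$. A per-gene "AP-1
target" is a promoter with ≥ 1 AP-1 (TGASTCA) hit; the set-level
binomial p is reported alongside, since a per-gene count from a
set-level statistic requires exactly this kind of interpretation, which
we state rather than hide. If the background rate is 0 with target hits
present, p is set to the machine floor with a warning.

## What the synthetic study emulates — and what it does not

`generate_dataset()` draws a complete toy study from one seed: 300 genes
on a 10 Mb chromosome; pausing groups at 50/26/24% with true PI levels
8 / 2 / 0.8; Pol II TSS mass placed N(TSS+50, sd 80) truncated to the
window at an expected 100 tags per active TSS; body tags uniform at a
density implied by the true PI; LPS pause-release on induced genes as
TSS mass × 2/3 and body density × 2 (PI ÷ 3); NELF co-placed at positive
TSSs, multiplied by the dismissal factor at 0.5 h and restored at 1 h;
PU.1 enriched among group 1; PRO-seq tags emitted antisense to their
gene with the 5′ base at the polymerase position (TSS+20..+60 paused,
uniform body); negative-binomial replicate RNA-seq counts (dispersion
0.05, three replicates, FC 3 / 0.3 for induced/suppressed, 3 / 1/3 for
knockout effects); uniform-base promoters with ETS consensus planted in
group 1 and AP-1 consensus in NELF-negative superinduced genes.

Deliberate realism choices worth knowing:

* **Factor-library background.** NELF/PU.1 libraries carry a 10 tags/kb
  uniform background (vs 0.5 for Pol II): real factor ChIP libraries are
  background-dominated, which keeps library totals stable when
  occupancy changes globally. Without this, per-10M normalization of a
  signal-dominated toy library absorbs part of a genuine global
  dismissal — a compositional artifact, not a biological one.
* **RNA-seq library size.** The simulated genes are a panel within a
  stable transcriptome, so FPKM uses a fixed mapped total (1e7) rather
  than the panel column sum; otherwise strong induction of a few genes
  deflates every other gene's apparent expression.
* **Truth labels** for expression classes apply the classification rules
  to the noiseless generator means, so boundary effects of the
  pseudocount are part of the truth, not a scoring artifact.

The generator does **not** emulate mappability structure, duplicate
artifacts, fragment-size variation, GC bias, enhancer signal, isoform
structure, or replicate-level ChIP variability. Passing recovery tests
therefore demonstrates that the implementation computes what it claims
on data matching its statistical assumptions — not that those
assumptions hold in any particular real library.

## Problem sizes and numerical conventions in the test suite

The suite exercises 300-gene studies on a 10 Mb chromosome (the
generator default), 2×10⁵-window null calibrations at λ = 5 over 20
seeds, 20-seed pause-release and motif-recovery replications, and a
three-point sequencing-depth ladder (× 0.05 / 0.2 / 1) for group
recovery — sizes chosen so each property is measured with enough
replication to be stable while the whole suite stays interactive.
Statistical conformance is checked against independent oracles written
from first principles: exact rank-sum enumeration and the tie-corrected
normal approximation (no continuity correction) for Mann–Whitney U,
exact lattice-path counting for the two-sample KS p-value, log-space
term summation for binomial tails, and the textbook Welch formula.
Ties in longest-variant selection break on the lexicographically
smallest transcript id; all outputs are sorted deterministically; every
stochastic stage is seed-controlled.

## Known limitations

* The peak caller implements the quoted contract (Poisson background,
  windowed search, FDR < 0.001) and is not bit-compatible with HOMER's
  `findPeaks`; no local-lambda background or input-chromatin control.
* PI is span-level: exon/intron structure and isoform selection beyond
  the longest variant are out of scope, as is any pause half-life or
  elongation-rate modeling.
* The Welch/BH replicate test is a transparent substitute for a
  dedicated differential-expression model; with three replicates its
  q-gated calls are conservative.
* Whether the original analysis computed activity thresholds over
  genome-wide windows or TSS windows only is not decidable from the
  stated procedure; we compute genome-wide and apply to TSS windows,
  and expose the window size and FDR as configuration.
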