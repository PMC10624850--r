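---
title: "Methods: nucleotide-resolution analysis of PRO-IP-seq data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleotide-resolution analysis of PRO-IP-seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proipr)
```

## The measurement and its two signals

PRO-IP-seq couples a nuclear run-on reaction — which incorporates a single
biotinylated nucleotide at the active site of every engaged RNA polymerase —
to immunoprecipitation of Pol II complexes selected by the phosphorylation
state of their C-terminal domain (CTD: tandem Y~1~S~2~P~3~T~4~S~5~P~6~S~7~
heptads whose serines 2, 5 and 7 are differentially phosphorylated through
the transcription cycle). Sequencing the purified nascent RNAs yields two
single-nucleotide signals per molecule:

* the **5'-most nucleotide** of the nascent RNA marks the exact initiating
  nucleotide (the transcription start nucleotide, TSN or +1 nt);
* the **3'-most nucleotide** marks the site of active transcription at the
  moment of the run-on.

`proipr` stores each signal as a sparse, strand-specific per-nucleotide count
table (`end_track`) and implements the downstream analysis: demultiplexing
and UMI deduplication, spike-in accounting, normalization, TSN and pause
calling, per-nucleotide CTD-phosphorylation ratios, and composite metagene
profiles. All internal coordinates are 0-based; distances from the TSN are
reported on the field's 1-based scale, where +1 is the TSN itself, there is
no position 0, and −1 is the first upstream nucleotide.

## Normalization: nf-cRPM

Plain reads-per-million (RPM) scaling assumes all samples share the same
total transcriptional output, which fails during genome-wide perturbations
such as heat shock. The nf-cRPM scheme (normalization-factor corrected
control RPM) instead multiplies every count of a sample by

$$\frac{1}{nf_{spike\text{-}in}} \times \frac{1}{nf_{longGE}} \times
  \frac{10^6}{depth_{control}}$$

with three components:

1. **Spike-in factor.** Foreign (mouse) chromatin is added to every sample
   before the run-on, at a proportion estimated from genome-content
   arithmetic (`estimate_spikein_fraction()`; 250,000 diploid spike-in cells
   per 30 million ~3n primary cells give 0.5%). For each sample,
   $nf_{spike\text{-}in} = \text{spikeCount}_{sample} /
   \text{spikeCount}_{unPh}$ where the denominator is the
   unphosphorylated-CTD sample of the same run-on reaction. Spike-in reads
   are counted only where they map uniquely outside a cross-mapping mask
   (the merged footprint of deep primary-genome nascent RNA data aligned to
   the spike-in genome; any ≥1 bp overlap excludes a read — a conservative
   choice the upstream protocol leaves open).
2. **Long-gene-end factor.** Between conditions,
   $nf_{longGE} = \text{endCount}_{cond} / \text{endCount}_{ref}$ computed
   on the control antibody over the ends of genes longer than 150 kb, where
   a 30-minute perturbation wave (≈2 kb/min) cannot have arrived. The
   formula uses raw end counts. Published practice does not fix the extent
   of "ends of long genes"; this implementation uses the
   final 25% of the annotated gene body, capped at the last 50 kb — far
   enough from the promoter on every qualifying gene, and wide enough to be
   count-rich. Whether end counts are 3'-end or whole-read counts is also
   open; 3'-end counts are used, consistent with every other quantification
   in the package.
3. **Control-depth RPM.** Finally all samples are scaled by $10^6$ over the
   uniquely mapped primary-genome read count of a single designated control
   sample (unphosphorylated CTD, unperturbed condition). The control's two
   nf factors are identically 1 by construction, a property the test suite
   asserts exactly.

Replicates are merged *before* normalization by summing raw counts and raw
spike-in counts, so the merged sample's factors are count-weighted.

## TSN and pause calling

Reference annotations report the longest isoform, not where initiation
actually occurs; genome-wide, nascent 5'-ends sit a median of tens of
nucleotides downstream of the annotated TSS. `call_tsn()` therefore scans
the strand-aware window **−100..+400** around the annotated TSS and returns
the position with the highest 5'-end count. Ties break to the most upstream
position — a deterministic rule biased toward the annotated direction of
transcription (the upstream choice is ours; the procedure as published does
not state one). Zero signal in the window leaves the gene uncalled. In the
pipeline one representative TSN — from the unphosphorylated-CTD,
unperturbed sample — is reused for every antibody and condition of a gene
(5'-ends are empirically insensitive to the CTD state); `per_sample_tsn =
TRUE` overrides this.

`call_pause()` applies the same argmax to the 3'-end signal and reports the
distance from the TSN in the 1-based convention. Distances +1..+30 are the
**early pause**, +31..+60 the **late pause**; these counting windows follow
the quantification used in the source histograms (the narrower "+18 to +30"
phrasing seen elsewhere describes where early-pause signal *peaks*, not the
counting window). `pause_fraction()` reports the share of +1..+60 signal in
each window, and `detect_clear_pause()` flags genes whose pause peak reaches
a minimum count (default 5) and exceeds a background ratio (default 3× the
median per-nucleotide count over +201..+400). That criterion is this
package's own operationalization — the source describes pause detection
rates without printing a rule — so both parameters are exposed.

## Ratio tracks and composite profiles

CTD-state comparisons divide nf-cRPM-normalized 3'-end counts of a
phosphorylated-CTD sample by the unphosphorylated sample at each nucleotide
and take log2, so equal signal sits at 0. Zeros are handled with a
symmetric pseudocount (default 0.5) added to both numerator and
denominator; this preserves exact centring for equal inputs, including
double zeros. (Dropping zero-denominator positions instead would bias
promoter-distal bins; the published figures do not state their choice.)

Composite (metagene) profiles extract per-gene signal strand-aware —
minus-strand genes are coordinate-reversed so downstream is rightward, and
antisense profiling reads the opposite genomic strand in the gene's frame —
in three anchorings: linear −1000..+1000 around the TSN (1- or 5-nt bins),
the gene body scaled to 50 equal-share bins, and linear −1000..+5000 around
the cleavage-and-polyadenylation site (CPS). Body bin *b* of a gene of
length *L* covers positions `floor((b−1)·L/50)` to `floor(b·L/50)`, and the
bin value is the mean per-nucleotide signal, so `sum(bin value × bin
width)` reproduces the gene's summed signal exactly (the suite checks this
to 10⁻⁹ relative tolerance). Genes shorter than the bin count are excluded
with a warning. Across genes, each bin is summarised by its mean and the
12.5–87.5% band. `crossing_point()` locates the first bin where one per-bin
profile exceeds another and stays above it for at least 5 consecutive bins
(the run-length requirement suppresses single-bin noise crossings).

## Quantification and response classes

`gb_rpk()` measures productive elongation as normalized 3'-end counts over
the gene body divided by body length × 1000 (reads per kilobase). The body
starts 500 nt downstream of the TSN — excluding the promoter-proximal
region, whose occupancy reflects pausing rather than elongation — and runs
to the CPS; the offset is configurable because published practice varies.
Summed-antibody activity adds the gbRPK of the four CTD states, genes are
split into quantile activity groups (ties resolved by gene id for
determinism), and the heat-shock response is classified by fold change
(defaults: ≥2 activated, ≤0.5 repressed, otherwise unchanged; a zero
reference with treated signal is activated). Genes with summed activity
above 0.01 normalized units count as "active" — a configurable default, as
the activity filter behind published gene counts is not reproducible from
the text.

## What the synthetic data emulates — and what it does not

`sim_config()` / `simulate_experiment()` generate ground-truthed
experiments with the statistical structure the analysis assumes:

* TSN–TSS offsets from a log-normal with median 55 nt and mean 77 nt,
  matching the genome-wide discrepancy reported for nascent 5'-ends,
  clamped to the −100..+400 calling window.
* A promoter-proximal pause as a two-component positional mixture:
  discretized truncated normals over +1..+30 (mean +25, sd 3 — echoing the
  +25 peak of unphosphorylated Pol II) and +31..+60 (mean +45, sd 6), with
  default prior weights 0.65/0.35. Each gene draws one dominant pause
  nucleotide; 60% of its pause-bound molecules sit exactly there, the rest
  re-draw from the mixture, producing the single sharp pause the assay
  resolves.
* Antibody-specific compartment weights (pause / gene body / termination
  window) chosen to echo the biology: unphosphorylated CTD mostly paused
  (0.70/0.25/0.05), Ser2Ph body-dominated (0.30/0.55/0.15), Ser5Ph
  intermediate (0.40/0.50/0.10), Ser7Ph body-weighted (0.25/0.65/0.10).
* Gene-body lengths log-normal with median 20 kb (the median human gene),
  expression weights log-normal (sdlog 1), 10% uniform background noise,
  0.5% spike-in molecules, Poisson PCR duplication (rate 1), and a
  two-condition design in which 10% of genes activate (×4) and 30% repress
  (×0.25) under heat shock.
* Condition fold changes propagate only a finite distance into the gene: a
  wave front at 60 kb from the TSN (2 kb/min over 30 min). The pause and
  proximal body scale with the gene's response, while density beyond the
  front — including the ends of >150 kb genes — keeps its reference level.
  This is precisely the premise that makes the long-gene-end normalization
  factor a valid estimator, so the generator respects it; it also means
  whole-body gbRPK deliberately understates fold changes on genes longer
  than the wave front, as in the real 30-minute experiment.
* At the read level, `simulate_read_pool()` reproduces the adapter
  architecture (3'-adapter: constant G then a 6-nt inline barcode;
  5'-adapter: 6-nt UMI then constant C; read 1 reverse-complemented
  relative to the RNA), with exact-copy PCR duplicates.

Deliberately not modelled: realistic sequence composition, splicing,
enhancer and divergent transcription, multiple TSNs per promoter, dispersed
initiation around the TSN, nucleosome positioning, and mappability
structure. Passing recovery tests therefore demonstrates correctness of the
calling logic under the stated generative assumptions — not robustness to
promoter heterogeneity in real data, where initiation is dispersed and
pause positions drift with the +1 nucleosome.

Two details of the generator matter for interpreting the tests. First, all
non-noise molecules initiate exactly at the TSN, so TSN recovery measures
argmax correctness against noise, not against initiation dispersion.
Second, UMIs are 6-mers drawn uniformly: at a sharp pause, distinct
molecules can collide in (UMI, coordinates), so coordinate-level
deduplication is checked by its collapse-equivalence invariant, while exact
molecule-count recovery is asserted on the read-level path, where random
RNA sequences make collisions vanishingly rare.

## Numerical and design choices

* **Determinism.** Every generator call is seeded (per-sample seeds derive
  from the config seed), the pipeline itself uses no randomness, and argmax
  ties, quantile-group ties and output ordering are all resolved by fixed
  rules, so reruns are byte-identical.
* **Degenerate inputs.** Empty tracks cannot be RPM-normalized (error); a
  zero control spike count or zero reference long-gene-end count aborts
  normalization; genes whose calling window is fully clipped, or carries no
  signal, are left uncalled rather than guessed; pause fractions on an
  empty pause region are (0, 0).
* **Problem sizes.** The test suite simulates 200-gene, 10⁵-read samples
  for recovery and determinism checks and 12–20-gene experiments
  elsewhere; the caller-vs-scan equivalence uses 1,000 random sparse
  windows on both strands. These sizes make per-gene expectations
  count-rich (hundreds of molecules per gene) while keeping the default
  suite fast.
* **Genome-wide published figures** (active-gene counts, pause detection
  percentages, offset means over tens of thousands of genes) depend on the
  deposited sequencing data and on filters not printed in the text; they
  are treated as context, not as reproduction targets.

## Limitations

Only the single dominant TSN and pause per gene are called; promoters with
two initiation sites are represented by the stronger one. The spike-in
factor assumes equal pulldown efficiency of spike-in material across
antibodies — an assumption of the scheme itself, surfaced but not checked.
bigWig export is intentionally omitted (bedGraph is the interchange
format), and alignment is out of scope: the package consumes aligned
coordinates.
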