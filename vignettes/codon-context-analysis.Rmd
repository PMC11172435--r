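---
title: "Codon adjacency and A-site ribosome density by +1 codon context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon adjacency and A-site ribosome density by +1 codon context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codoncontext)
```

## The scientific question

During translation elongation the ribosome decodes the A-site codon while
the next codon (the "+1" codon, immediately 3' of the A site) sits against
the ribosome's CAR surface, an extension of the A-site tRNA anticodon
formed by rRNA residues and a ribosomal-protein arginine. Two linked
observations motivate this package:

* **Sequence composition.** In coding sequences, G is over-represented at
  the first codon position, and this GNN preference is stronger for codons
  immediately 3' of NNU codons (codons with U at the wobble position).
* **Translation kinetics.** In ribosome profiling data, the footprint
  density at an A-site codon — a proxy for dwell time, higher density
  meaning slower decoding — is elevated when the +1 codon is GNN, most
  strongly for A-site NNU codons.

The package provides a tested implementation of both analyses: conditional
position weight matrices with gene-bootstrap inference for the composition
claim, and a footprint-to-density pipeline with a gene-bootstrap context
test for the kinetic claim, plus a synthetic-data generator that plants
known effects so every estimator can be validated against ground truth.

## Codon composition statistics

For a set of ORFs, the background frequency $f_{exp}(n)$ of each
nucleotide is pooled over all sequences irrespective of codon position
(`background_frequencies()`). A position weight matrix over any selected
set of codon instances records, for codon positions 1–3,

$$w(p, n) = \log_2 \frac{f_{obs}(p, n)}{f_{exp}(n)},$$

where $f_{obs}$ is the observed nucleotide frequency at position $p$ of
the selected codons (`codon_pwm()`). `adjacency_pwm()` conditions the
selection on the identity of the 5'-neighbouring codon (e.g. all codons
directly after an NNU codon); codon context never crosses ORF boundaries.
When $f_{obs}$ or $f_{exp}$ is zero the weight is reported as `NaN` and
excluded from comparisons rather than stabilized with pseudocounts:
the statistic is meant for bulk coding sequence where zeros do not arise,
and pseudocounts would distort the small fixtures used for testing.

Codons are classified (`classify_codon()`) by wobble nucleotide and by the
anticodon nucleotide-34 identity of the tRNA that decodes each NNU/NNC
pair: inosine 34 (I34) when the NNA codon of the same family codes for the
same amino acid (inosine also pairs with wobble A), otherwise G34. Glycine
is the known eukaryotic exception and is kept G34 although GGA codes Gly.
CGA is flagged as the single NNA codon read exclusively by an I34
anticodon. A `"prokaryote"` mode relabels all I34 entries G34; it affects
labels only.

## The footprint-to-density pipeline

Inputs are ORF sequences (FASTA) and footprint 5'-end counts — a TSV of
(gene, 0-based 5'-end offset relative to the start codon, read length,
count). Read lengths 27–30 nt form the "28-nt" class (ribosomes with A-
and P-site tRNAs); 20–22 nt form the "21-nt" class (pre-accommodation
ribosomes). The stages, each an exported function:

1. **Gene filtering** (`filter_genes()`): only ORFs strictly longer than
   198 nt with raw class footprint density strictly above 1 per 10 nt are
   analyzed. Both thresholds are exclusive; the density filter uses raw
   totals per class before any offsetting.
2. **A-site offsetting** (`default_offsets()`, `calibrate_offsets()`):
   each read contributes its count at `pos5 + offset`. The default offset
   is 15 nt for every analyzed length, the canonical yeast value.
   Calibration scores candidate offsets 10–20 nt by start-anchored
   metagene signal (reads landing on the first nucleotide of codons 1–5).
   Because elongation coverage is roughly uniform, candidates one codon
   apart score alike; the near-maximal candidates are disambiguated by the
   5'-most observed read end, whose A site sits at the ORF start. This is
   exact on generated data; with fewer than 50 supporting reads for a
   length the default is used with a warning. Calibration assumes the
   major peak lies on frame 0, the common convention and the generator
   default.
3. **Frame assignment and codon densities** (`codon_densities()`): the
   major frame $m$ is chosen dataset-wide as the frame with the largest
   total shifted count — per-gene frames would be unstable for
   low-coverage genes. Codon $i$'s density sums shifted counts at
   nucleotides $3i+m-1$, $3i+m$, $3i+m+1$ (major peak plus both adjacent
   minor peaks), so each interior nucleotide position contributes to
   exactly one codon and counts are conserved. The first codon uses only
   positions ≥ 0 and the last only positions inside the ORF.
   Aggregation happens on raw counts *before* per-gene normalization;
   because the normalizer is a single per-gene constant, this order
   commutes with within-gene aggregation and is the simpler to test.
4. **Normalization** (`normalize_densities()`): each gene's density vector
   is divided by its own mean, so per-gene means are exactly 1 and codon
   instances are comparable across genes; instances then pool with equal
   weight. (The alternative reading — average per-gene means across genes
   — is not the default; the bootstrap below resamples genes either way.)
5. **Context annotation** (`annotate_contexts()`): one row per sense
   A-site codon with a defined +1 codon in the same ORF; `gnn_flag` marks
   +1 codons starting with G. Instances whose +1 codon is a stop are
   flagged and kept in the without-GNN group by default (configurable).
   The pipeline excludes one codon at each ORF end by default
   (`exclude_edge = 1`) to avoid initiation/termination pile-up artifacts.
6. **Context comparison** (`context_comparison()`): per A-site codon type,
   the mean normalized density of instances with +1 GNN versus without,
   their ratio, and `percent_elevation = 100*(ratio - 1)`, with
   gene-bootstrap inference (below). No multiple-testing correction is
   applied across codon types; per-type two-tailed p-values at 0.01 are
   reported as-is.
7. **Class summaries** (`class_summary()`): codon types grouped into
   NNU(G34), NNU(I34), NNC, NNA, NNG; per-group elevation distributions
   and two-tailed Welch t-tests between the 21-nt and 28-nt classes.

`run_all()` orchestrates all stages from files, logs per-stage gene counts
and the chosen frame, writes deterministic TSVs, the resolved
configuration and a checksum manifest; `render_figures()` draws the PWM,
per-codon comparison and class-summary figures from those TSVs.

## Gene-bootstrap inference and the choice of test statistic

All tests resample *genes* with replacement (resample size = number of
genes, multiplicity honoured) and recompute the pooled statistic, with the
small-sample-safe two-tailed estimator

$$p = 2\min\left(\frac{1 + \#\{b \le r\}}{B+1}, \frac{1 + \#\{b \ge r\}}{B+1}\right)$$

capped at 1. Each operation uses a single seeded generator and records its
seed; a degenerate input (a single gene, or fewer than two genes carrying
both context groups) yields p = 1 with a flag.

For the context test two statistics are available. The default,
`method = "difference"`, recomputes the with-GNN minus without-GNN mean
difference in every gene resample and locates 0 two-tailed in that
distribution — a percentile-CI inversion whose type-I error is close to
nominal, which the test suite verifies empirically over hundreds of null
simulations. The alternative, `method = "without_null"`, compares the
observed with-GNN mean against the bootstrap distribution of the
without-GNN mean alone. That variant ignores the sampling variance of the
with-GNN mean, which is computed from the smaller group (roughly a quarter
of instances), and is therefore anti-conservative under the null; it is
provided for comparability but is not used by default. The G1-weight test
(`g1_weight_bootstrap()`) has the same two forms — conditional-minus-
unconditional weight difference (default) versus locating the conditional
weight in the bootstrap distribution of the unconditional weight — for the
same reason. The NNU/NNC abundance test is inherently a difference
statistic, $(\#NNU - \#NNC)/\#\text{codons}$, tested against 0.

## The synthetic-data generator

`sim_config()` defines the generative model; `gen_orfs()`,
`gen_profiles()`, `gen_expression()` and `simulate_dataset()` realize it.
It emulates the features of real profiling data that the pipeline relies
on — per-gene depth variation, 3-nt periodic peak structure, the two
read-length classes, and multiplicative dwell effects keyed by A-site and
+1 codon — and deliberately not others: no initiation/termination
pile-ups, no UTR-resident ribosomes (5' ends may still be negative when
the A site is start-proximal), no sequence-realistic codon usage unless a
usage table is supplied, Poisson counts unless overdispersion is
requested. Passing recovery tests therefore demonstrates estimator
correctness under the modelled structure, not robustness to every artifact
of real libraries.

Defaults chosen once, as study conditions: 200 genes of 300–600 codons
(mean ~450); uniform usage over the 61 sense codons; frame weights
0.70/0.15/0.15; per-gene depth lognormal with median 1 read/nt and
sigma 0.5; 28-nt length mixture 27:0.15, 28:0.55, 29:0.20, 30:0.10 and
21-nt mixture 20:0.2, 21:0.6, 22:0.2; true offsets 15 nt. The
`"paper_effect"` preset applies a 1.4× dwell multiplier to A-site NNU
codons followed by +1 GNN — matching the reported average elevation of
about 40% for NNU codon types — and is the single place that number is
defined; recovery tests reference the preset. The `"adjacency"` preset
multiplies G-starting codon odds after NNU by 1.3; `"null"` plants
nothing and drives the calibration suites. Expected values are available
in closed form (a codon class's expected normalized density is its dwell
multiplier divided by the gene's mean multiplier; expected reads per gene
are depth × length), which the tests exploit.

## Numerical and design choices

* Coordinates are 0-based and half-open, relative to the first nucleotide
  of the start codon; codon $i$ covers nucleotides $[3i, 3i+3)$.
* U and T alphabets are interchangeable on input; sequences are stored in
  one internal alphabet and reported with U in results.
* Records with ambiguous bases or lengths not a multiple of 3 are dropped
  (and counted) rather than masked, keeping codon statistics exact.
* Expression stratification takes the top and bottom
  $\lceil \text{fraction} \cdot n \rceil$ genes, ties broken by gene id;
  with this convention reported top/bottom counts can differ by ±1 from
  roundings used elsewhere.
* Gene resampling multiplicities are drawn as a single multinomial, which
  is exactly the distribution of uniform resampling with replacement.
* TSV reports are written with 6 significant digits in a fixed column
  order, so identical inputs and seeds give byte-identical outputs.
* Deblurring of footprint alignments is out of scope; the readers accept
  already-positioned (optionally externally deblurred) 5'-end count
  tables unchanged.

## Problem sizes used by the checks

The bundled checks run at the documented study conditions scaled for a
single CPU: effect-size recovery uses 200 genes at ~1 read/nt with 1000
bootstrap resamples; calibration uses 300 independent null simulations of
100 genes each; property suites use fixtures of up to a few dozen genes.
These sizes give Monte-Carlo error well inside the stated tolerances.

## Known limitations

* The offset calibrator depends on the ORF-start boundary; libraries with
  heavy UTR contamination or initiation pile-ups would need the default
  (or an externally supplied) offset table instead.
* A single dataset-wide major frame is assumed; datasets mixing libraries
  with different periodicities should be analyzed separately.
* The dwell model is multiplicative and memoryless; real pause structure
  (e.g. P-site or E-site context, peptide-exit effects) is not modelled.
* With very few instances of a codon type in either context group the
  comparison is flagged degenerate rather than tested.
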