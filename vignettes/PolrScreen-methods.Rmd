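---
title: "PolrScreen: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PolrScreen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PolrScreen)
```

## The scientific question

POLR1C is a subunit shared by RNA polymerase I (which transcribes the
rDNA repeat) and RNA polymerase III (which transcribes tRNAs, 5S rRNA and
other small non-coding RNAs). Different point mutations in this one gene
cause two different diseases, and the mechanistic question is whether a
given mutation selectively impairs the *biogenesis* of one of the two
enzymes. PolrScreen implements the two quantitative read-outs used to
answer that question:

1. **AP-MS differential interaction scoring.** A FLAG-tagged version of the
   shared subunit (wild type or mutant) is affinity-purified and the
   co-purifying proteins are quantified by spectral counting. If a mutation
   impairs assembly of Pol III but not Pol I, the mutant bait pulls down
   less of the Pol III-specific subunits while Pol I-specific and shared
   subunits are unchanged.
2. **ChIP occupancy profiling.** Chromatin immunoprecipitation of the same
   tagged subunit, aggregated around the TSS of Pol III target genes
   (stratified by their three promoter classes) and of the rDNA control,
   reads out whether the assembled enzyme actually reaches its target
   genes.

Both analyses are driven by synthetic-data generators with the same
statistical structure, so every stage is testable without external data.

## AP-MS scoring model

The input is a long-format spectral-count table (protein, run, count) and a
run design with three conditions: `WT`, `MUT:<variant>` and `EV` (empty
vector, i.e. the FLAG tag with no bait, which defines nonspecific
background binding). Each mutant replicate is paired with the wild-type
replicate acquired at the same time. The stages, in order:

1. **Cleaning** (`cleanProteinTable`): known contaminants (keratins by
   default) are removed and indistinguishable isoforms are collapsed into
   one record per run. Collapsing *sums* counts: spectra assigned to either
   isoform are evidence for the merged group, and summation preserves the
   total spectral evidence (the alternative, taking the maximum, discards
   spectra).
2. **Zero imputation** (`imputeZeroCounts`): spectral counts of zero carry
   no scale information, so each zero (for any protein of the analysis
   universe) is replaced by a draw from the run's noise floor: a normal
   distribution whose mean and s.d. equal those of the lowest 20% of the
   run's *nonzero* counts. Zeros are excluded from the noise window because
   they are the values being modelled, not measurements of the floor. The
   window takes the lowest `max(2, ceiling(0.2 m))` of the `m` nonzero
   counts so that its s.d. is always defined. Draws are truncated below at
   `max(0.01, mean - 3 s.d.)`: this guarantees strictly positive counts
   (finite ratios downstream) with a deterministic, analysable bias,
   whereas redraw-until-positive would bias the mean in a way that depends
   opaquely on the acceptance rate. The analysis universe is the set of
   proteins observed at least once in the WT/MUT/EV trio under analysis —
   the identification universe of the search engine, not the whole
   proteome. Imputation is performed per run, independently: the noise
   floor is a property of one LC-MS/MS acquisition.
3. **Bait normalization** (`normalizeByBait`): every count is divided by
   its run's bait count, making purifications of different efficiency
   comparable; the bait's normalized count is exactly 1 everywhere.
4. **High-confidence interactor filter** (`flagHighConfidence`): a protein
   passes if (a) it was identified — raw count > 0, an imputed zero is not
   an identification — in *all* replicates of at least one bait arm (WT or
   MUT), and (b) that arm's mean imputed count exceeds 5 times the mean
   imputed EV count, strictly. The enrichment ratio is computed on the
   spectral-count scale rather than the bait-normalized scale: EV
   purifications contain no bait, so an EV "bait count" exists only as an
   imputed noise value, and dividing by it would put EV counts on a scale
   incommensurable with the bait arms (every prey, however specific, would
   be penalized by the ratio of bait to noise floor). On the count scale
   the filter does what it is meant to do: demand that the protein is
   substantially more abundant in the pull-down than in the tag-only
   control.
5. **Paired ratio test** (`differentialInteractionTest`): for each
   high-confidence protein, the per-pair ratios `r_k = MUT_k / WT_k` of
   bait-normalized imputed counts are tested with a two-tailed one-sample
   t-test (df = pairs − 1). The default tests `mean(r)` against 1 on the
   raw ratio scale; `ratioScale = "log2"` instead tests `mean(log2 r)`
   against 0, which is symmetric in up/down fold changes and exactly
   calibrated under multiplicative noise. Both are provided because the
   displayed quantities are log2 ratios while the literal test statistic is
   defined on the ratios themselves; the reported fold change is always the
   arithmetic mean ratio. A zero-variance ratio series at the null value
   yields p = 1; off the null, p = 0.
6. **Multiple testing and classification** (`adjustBH`,
   `classifyInteractions`): Benjamini–Hochberg adjustment is applied within
   one family per mutant-vs-WT comparison — the high-confidence set of that
   comparison, matching one volcano panel per mutant. A protein is called
   `decreased`/`increased` only when the adjusted p is below `alpha` *and*
   the mean fold change falls outside the fold gates. The upper gate is
   1.5; the lower gate defaults to its reciprocal, 1/1.5 ≈ 0.667 — the
   symmetric choice, exposed in `scoringConfig()` for users who prefer a
   different band. The dual criterion trades sensitivity for specificity:
   a tiny but consistent fold change is not called.
7. **Display** (`buildDisplayMatrix`): heatmap values are log2 mean ratios
   with everything below −4.5 capped at −4.5 (ratios that small are
   dominated by the imputation floor, so their exact magnitude is not
   meaningful); volcano tables carry the capped log2 ratio, −log10 adjusted
   p and the significance label.

### Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `hciRatioThreshold` | 5 | strict arm/EV mean-count enrichment |
| `noiseQuantile` | 0.20 | fraction of lowest nonzero counts in the noise window |
| `nRequiredReplicates` | 3 | replicates in which a protein must be identified |
| `alpha` | 0.05 | adjusted-p significance level |
| `fcUpper`, `fcLower` | 1.5, 1/1.5 | fold-change gates |
| `displayCap` | −4.5 | log2 display floor |
| `ratioScale` | `"raw"` | `"raw"` or `"log2"` test scale |

## ChIP occupancy model

The module starts from aligned read intervals (BED); alignment,
deduplication and peak calling are well served by existing tools and are
out of scope. Coordinates are 0-based half-open; the TSS of a minus-strand
gene is its highest transcribed coordinate.

1. **Coverage** (`loadSignal`): per-base read depth aggregated into
   fixed-width bins; each bin stores the *mean* per-base depth, so reads
   spanning bin boundaries contribute proportionally and total read-bases
   are conserved.
2. **Input subtraction** (`normalizeSubtractInput`): the input (sonicated
   chromatin, no immunoprecipitation) track estimates the nonspecific
   background; it is subtracted bin-wise from the ChIP track and negative
   values are clamped to zero, since occupancy cannot be negative. By
   default the subtraction is done on the native depth scale, which is the
   calibrated choice when ChIP and input libraries are sequenced to
   comparable background depth (true by construction for the simulator,
   and approximately true for libraries sequenced on the same flow cell).
   A reads-per-million mode (`scale = "rpm"`) is provided for libraries of
   clearly unequal depth, with a caveat: per-library scaling makes the
   wild-type/mutant comparison sensitive to library *composition* — a
   mutant that genuinely loses occupancy has a smaller enriched fraction,
   so rescaling by total depth inflates its apparent per-locus signal and
   biases the recovered fold toward 1. Users comparing conditions in rpm
   mode should verify that enrichment is a small fraction of each library.
3. **Aggregate profiles** (`aggregateProfile`): 100 windows of 10 bp on
   each side of the TSS (both configurable). Window values are mean
   per-base signal; windows extending past a contig end use only in-bounds
   bases. Minus-strand genes are mirrored base-exactly so that window 1 is
   always the most upstream window in gene orientation. Genes are equally
   weighted (mean of per-gene window values), so highly covered genes do
   not dominate the class profile.
4. **Comparison** (`compareOccupancy`): per class, the ratio of mean window
   signal (mutant over wild type) with its log2; a zero reference mean is
   flagged degenerate rather than divided by.

Two estimator properties worth knowing. First, the zero-clamp after
subtraction adds a small positive offset wherever background noise
fluctuates around zero; because the offset enters both numerator and
denominator of the occupancy ratio additively, recovered log2 ratios are
slightly compressed toward 0 (about +0.06 at the simulator's default
background-to-peak ratio). Second, windows are correlated over roughly a
read length, which matters when judging the flatness of a profile.

## The synthetic generators

`simulateApmsDataset()` draws raw spectral counts as Poisson–lognormal:
count ~ Poisson(abundance × category fold × lognormal replicate factor).
This is the simplest over-dispersed count model, with the coefficient of
variation as a single noise knob (default 10%). Complex subunits default to
an expected wild-type count of 60 (bait 120) — values chosen for
statistical power at three replicates, the realistic regime for abundant
polymerase subunits in a FLAG pull-down. Fifty background proteins with
lognormal(log 4, 1) abundances bind nonspecifically in *every* condition;
EV runs contain only them. Proteins with expected count below 5 drop out
(count 0) with probability 0.2, mimicking identification missingness at
the MS noise floor. The leukodystrophy scenario sets the Pol III-specific
fold to 0.25 with everything else at 1; the assembly-neutral (TCS)
scenario sets every fold to 1.

`simulateChipDataset()` places 20/40/15 genes of promoter classes
type1/type2/type3 non-overlapping on a 400 kb contig plus one rDNA gene on
a dedicated 43 kb contig (mirroring the practice of aligning to a separate
rDNA reference, since the repeat is absent from genome assemblies). Each
ChIP library is uniform Poisson background (0.03 reads/bp) plus per-gene
enrichment: read count ~ Poisson(class depth × fold), centres ~
Normal(TSS, 200 bp), 50 bp reads. Wild-type depths are 600/400/500 reads
per gene for the three classes and 8000 at rDNA (the most heavily occupied
Pol I locus); these were fixed a priori by a noise budget so that
class-level log2 ratios are estimable to a few hundredths. The mutant fold
is forced to 1 at rDNA. The input library is background only, at the same
rate as the ChIP background.

What the generators deliberately do **not** emulate: peptide-level
quantification and protein inference, correlated contaminant structure,
batch effects between paired runs, ChIP fragment-size smearing,
mappability gaps, copy-number variation of the rDNA array, or read
alignment errors. Tests passing on synthetic data therefore demonstrate
that the statistical machinery recovers the patterns it is designed to
detect under its stated noise model — not that any particular real dataset
satisfies that model.

## Numerical and design choices

* Imputation draws are made per run in sorted run order, proteins sorted
  within, so a fixed seed makes the whole pipeline bit-reproducible.
* The noise-window s.d. is the sample (n−1) standard deviation.
* Enrichment ties at exactly 5 are excluded (strict inequality).
* The t statistic is computed directly and the p-value from the t
  distribution, so that zero-variance series can be handled explicitly
  (p = 1 at the null rather than an error).
* BH adjustment delegates to `stats::p.adjust(method = "BH")`; the test
  suite validates it against a literal step-up enumeration.
* Profile windows of minus-strand genes use the span
  `[tss − nw + 1, tss + nw + 1)` reversed, which makes the TSS base the
  first base of the first downstream window on both strands and gives
  exact strand-mirror symmetry.
* Degenerate inputs fail loudly and name the offender: a bait absent from
  a run, a run with fewer than two nonzero counts, a dangling or
  non-bijective MUT/WT pairing, a read past a contig end, an empty gene
  class, a zero reference profile.

## Problem sizes used by the test suite

The packaged tests run the full AP-MS pipeline across 200 simulated
datasets per scenario (73 proteins, 9 runs each), calibrate the null test
on 2000 simulated proteins, compare coverage and profiles against
explicit per-base loops on fixtures of a few kilobases, and run one
full-size ChIP simulation (~105,000 reads across three libraries). These
sizes keep the whole suite under a minute on a single CPU while leaving
the Monte-Carlo error of each checked fraction well below the margin it
is checked against.

## Known limitations

* The raw-scale ratio t-test is slightly miscalibrated under strongly
  skewed noise at n = 3 (the log2 scale is exact under multiplicative
  noise); both scales are one switch apart.
* The EV enrichment filter compares means of imputed counts; with very few
  background identifications in an EV run the imputed noise floor is
  estimated from few values and the ratio becomes noisy.
* Occupancy ratios are mildly compressed toward 0 by the zero-clamp (see
  above); at the default simulator settings the compression is an order of
  magnitude smaller than the class effects of interest.
* The aggregate profile weights genes equally; a per-gene expression or
  mappability weighting is out of scope.
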