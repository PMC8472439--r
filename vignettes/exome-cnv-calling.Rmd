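---
title: "Batch read-depth CNV calling: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batch read-depth CNV calling: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvbatch)
```

## The problem

Exome sequencing captures the coding targets of the genome; the number of
reads landing on each target is, to first order, proportional to the
number of DNA copies of that target in the sample. A patient carrying a
heterozygous deletion has one copy instead of two over the deleted
targets, so those targets receive roughly half the expected reads; a
duplication yields roughly 1.5 times the expectation. The difficulty is
that "expected" varies enormously between targets (capture efficiency,
GC content, mappability) and between samples (library size). Samples
prepared and sequenced together in one batch share most of those
systematic effects, which is why `cnvbatch` always works on a batch —
32 samples for exome libraries, 8 for the targeted-exome design — and
scores each sample against a reference aggregated from its batch mates.

## The observed-fraction model

Let $o_t$ be the test sample's read count at target $t$ and $r_t$ the
summed count of the chosen reference samples, with library totals
$N_s = \sum_t o_t$ and $N_r = \sum_t r_t$. Conditional on the combined
count $n_t = o_t + r_t$, the test fraction $o_t / n_t$ has expectation

$$p_c = \frac{(c/2)\,N_s}{(c/2)\,N_s + N_r}$$

when the test sample carries $c$ copies at $t$. The per-target capture
effect cancels in this fraction — that is the point of conditioning —
and the diploid expectation $p_2 = N_s/(N_s+N_r)$ is constant along the
genome. Residual sample-specific noise makes counts overdispersed
relative to a binomial, so $o_t$ is modelled beta-binomial with
intra-class correlation $\rho$, estimated by the method of moments from
the genome-wide squared deviations of $o_t/n_t$ around $p_2$ and clamped
to $[10^{-6}, 0.5]$. For $c = 0$ the multiplier $c/2$ is floored at
$\varepsilon = 0.01$: real homozygous deletions still attract a trickle
of mismapped reads, and a strictly zero expectation would make a single
stray read veto the state.

### Reference selection

Candidate references are the other batch samples ranked by Pearson
correlation of their count profiles with the test sample. They are
added greedily in rank order as long as the expected beta-binomial
variance of the aggregate fraction keeps decreasing, up to `max_refs`
(default 10). Aggregating correlated samples grows $n_t$ (less binomial
noise) but aggregating dissimilar ones inflates $\rho$; the variance
criterion trades the two off without a tuning knob.

### Segmentation

Per chromosome, copy states $c \in \{0,1,2,3,4\}$ are decoded by a
Viterbi pass over the target lattice. The prior is "stay diploid":
entering a non-diploid state costs $\log(\texttt{transition})$ with
`transition = 1e-4` by default; staying in a state, and returning to
diploid, are free. States are capped at 4 because quadruplication is the
most extreme event encountered in this diagnostic setting; score ties
break toward the state closest to diploid, so a flat likelihood never
invents an aberration. Each maximal non-diploid run becomes a call with:

* `copy_number` — the modal state of the run;
* `quality` — the log10 likelihood ratio of the decoded states against
  the all-diploid path over the run (calls under `call_threshold = 3`
  are suppressed, i.e. odds of 1000:1);
* `mean_ratio` — observed over expected-diploid depth,
  $\sum_t o_t \,/\, \sum_t r_t N_s/N_r$, the quantity later inverted
  for mosaicism.

Targets with $n_t = 0$ contribute log-likelihood 0 to every state: they
carry no copy-number information and merely extend whatever state
surrounds them.

### Mosaicism

A CNV present in a fraction $f$ of cells shifts the expected depth
multiplier to $1 + f\,(c-2)/2$. For single-copy events this inverts
uniquely: $f = 2(\bar r - 1)$ for $c = 3$ and $f = 2(1 - \bar r)$ for
$c = 1$, clamped to $[0,1]$. A called duplication with
$\bar r = 1.29$ therefore reports 58% mosaicism. For $c \in \{0, 4\}$
the ratio-to-fraction mapping is ambiguous (a "ratio 2" segment can be a
constitutive quadruplication or something stranger), so no estimate is
made. Fractions at or above 0.95 are reported as constitutive — at
typical depths the estimator cannot distinguish 95% mosaicism from 100%.

## Post-processing rules

* **Merging.** Calls of the same type *and* copy number separated by
  fewer than 3 intervening targets are merged (repeatedly, to a
  fixpoint), because a couple of poorly covered targets can split one
  event; a gap of exactly 3 targets stays split. Merged quality is the
  maximum of the parts, the ratio a target-count-weighted mean.
* **Detectability.** A CNV counts as detectable by an arrayCGH platform
  when at least 3 of the platform's probes intersect it, and by MLPA
  when at least 2 probes do — the minimum-consecutive-probe significance
  rules of those assays.
* **Terminal proximity.** The number of capture targets between a CNV
  and its chromosome's start (pTer) and end (qTer) is reported; 10 or
  fewer flags the call as terminal, since terminal events may be the
  visible part of a larger rearrangement (ring chromosome, unbalanced
  translocation) and deserve cytogenetic follow-up.
* **Frequency.** A batch or database CNV matches when it has the same
  type and ≥ 50% reciprocal overlap (the conventional CNV-matching
  criterion; configurable). Batch frequency uses a sample-level
  denominator. Variants above `rarity_max = 0.01` in either the batch or
  a database are treated as polymorphisms.
* **Size classes.** Larger than 400 kb is "large" (the cut-off used in
  prenatal microarray testing); under 5 kb is "exon_level"; between is
  "gene_size". 5 kb is the unique simple threshold separating the
  bundled fixture's three one-to-two-exon CNVs (≤ 4.4 kb) from its four
  gene-sized ones (≥ 9.4 kb) — an exon-count rule would misfile a
  three-exon, 60 kb event.

## Classification

The classifier is a transparent five-rule cascade over the evidence
classes a diagnostic reviewer actually weighs: frequency, known
pathogenic regions, phenotype-matched dosage-sensitive genes
(ClinGen-style haploinsufficiency/triplosensitivity score 3),
phenotype-matched disease genes without dosage-3 support, and rare
gene-impacting variants without a phenotype match (VUS). Every fired
rule is recorded so a classification is reproducible from its evidence
string alone. The cascade is deliberately not a point-arithmetic
scoring system: it is table-driven and a full scoring scheme can be
substituted without touching the pipeline. Panel filtering is applied
downstream of calling — calls are made genome-wide and filtered against
the requested panel, and `genome_wide` mode keeps out-of-panel calls,
the configuration recommended when panels lag behind gene discovery.

## The synthetic generator

`simulate_batch()` draws counts from a negative binomial (gamma-mixed
Poisson) with mean `depth × sample_effect × target_effect`, lognormal
effects, and $\mathrm{Var} = \mu + \rho\mu^2$. Spikes multiply the mean
by $1 + f(c-2)/2$. The generator's noise family intentionally differs
from the caller's beta-binomial fraction model: recovery results then
test robustness of the model to a misspecified but realistic data
process rather than confirming the caller on its own assumptions.

Defaults mirror the batch conditions the pipeline targets: 32 samples,
200 reads per target on average, sample effects with lognormal sd 0.2
(library-size spread), target effects with sd 0.5 (capture-efficiency
spread), overdispersion $\rho = 0.01$. What the generator does *not*
emulate: GC-dependent coverage waves, mappability dropouts and
pseudogene cross-mapping (the reason *STRC*-like regions are hard),
read-level artifacts, or correlated target effects. Passing recovery
tests therefore demonstrate the statistical engine under honest noise,
not performance on the pathological regions of a real exome; the
low-coverage failure-mode test (below) is the one place a real-data
pathology is reproduced deliberately.

## Validation setup

The test suite exercises, among others:

* Viterbi decoding against exhaustive enumeration of all state paths on
  chromosomes of up to 12 targets (where enumeration is tractable);
* recovery of ≥ 3-target spikes at 200× in 32-sample batches
  (30 seeded batches; ≥ 90% recovered with correct type and ±1-target
  boundaries, ≥ 95% of recoveries with the true copy number);
* specificity on 40 seeded spike-free batches (≥ 95% yield zero calls
  for the scored sample);
* the known failure mode: when one target's coverage is reduced 10-fold
  across the whole batch, a single-target heterozygous deletion on it is
  recovered in fewer than half of 30 seeded batches. This mirrors the
  clinical reality that first exons and low-mappability targets are
  blind spots of read-depth calling — the reason a negative result does
  not exclude a CNV in a poorly covered gene.

Problem sizes (400–500 targets, 10–40 seeds per property) were chosen to
give stable Monte-Carlo estimates while keeping the default test run
fast; the properties are not sensitive to these sizes.

## Fixture design notes

The bundled cohort fixture contains 450 synthetic patient rows
reproducing every per-category patient count and positive count of the
study it encodes, the 162/450 overall diagnostic rate, the 18
CNV-diagnosed patients and the 58-VUS split. Three of the 18
CNV-diagnosed patients carry two disease categories — this is forced:
the per-category CNV positives sum to 21 over 18 patients, so exactly
three dual-category patients reconcile the two. The study's
single/double/triple category breakdown of the full cohort (398/41/11)
is *not* jointly satisfiable with the per-category totals (it implies
at least 513
category slots where the totals provide 495), so the fixture matches
the per-category totals — the quantities all downstream reports
consume — and approximates the multiplicity structure (20 doubles, 11
triples among the undiagnosed). The fixture's patient rows are
privacy-equivalent stand-ins, not real patients.

One fixture CNV (case 3) has a printed size inconsistent with its own
coordinates (">4.4 Kb" vs an `end − start` of 3,191 bp); the fixture
stores both values, flags the row via `size_consistent = FALSE`, and
size-arithmetic checks exclude it. The cohort's quoted "+5.9%"
yield-improvement figure is not derivable from its own counts
(18/450 = 4.0%); the report therefore prints the CNV-diagnosed count
and fraction and leaves that figure alone.

## Numerical and degenerate-input choices

* $\rho$ clamped to $[10^{-6}, 0.5]$: identical profiles would otherwise
  drive it to 0 and make the likelihood degenerate.
* $\varepsilon = 0.01$ floor for $c = 0$ keeps $p_0 > 0$.
* Viterbi ties break toward $|c - 2|$ smallest, so uninformative
  stretches decode as diploid.
* Zero-count targets emit log-likelihood 0 for every state.
* A test sample with zero total reads, a batch of one sample, and
  overlapping same-sample calls of different ploidy are errors, not
  warnings.
* All simulation entry points require an explicit seed; nothing reads
  hidden global RNG state.

## Limitations

Breakpoints are resolved only to the target lattice — real CNV ends
usually lie outside coding regions, so reported sizes are minimal sizes.
Intronic and intergenic CNVs are invisible by construction. Allele
fraction (B-allele) evidence, split reads, SNV calling, and parental
segregation are out of scope, as are genomic regions whose coverage
signal is corrupted by high-homology paralogs; those need assays or
algorithms beyond batch read depth.
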