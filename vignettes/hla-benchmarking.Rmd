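---
title: "Benchmarking HLA callers and building a majority-vote consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking HLA callers and building a majority-vote consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlabench)
library(dplyr)
```

## The problem

The classical HLA genes are the most polymorphic loci in the human
genome. A growing family of tools calls a sample's HLA genotype — an
unordered pair of alleles per gene — from ordinary exome or RNA
sequencing reads. Their error profiles differ: tools disagree most on
class II loci, on low-coverage samples, and on rare alleles. `hlabench`
provides the machinery needed to benchmark such tools against PCR-derived
gold standards and to fuse them into a majority-vote consensus, together
with a synthetic data generator so that every statistic in the package is
exercised end-to-end by code alone.

All analyses operate on plain tables: calls
(`sample_id, gene, tool, allele1, allele2`), gold standards, per-key mean
read depths and population frequency studies. Adapters from the native
output formats of specific callers are deliberately left to user code —
those dialects churn, the evaluation logic does not.

## Allele nomenclature

HLA alleles are named `GENE*f1:f2:f3:f4` with colon-separated fields of
increasing resolution; a trailing letter marks expression status (e.g.
`N` = null) and a final-field `G` marks a *G-group*, an IPD-IMGT-defined
set of alleles identical over the exons encoding the peptide-binding
region. Sequencing-based callers cannot reliably distinguish alleles
within a G-group, so all comparisons in this package happen after
`hla_normalize()`: a name listed as a group member becomes the group
name; everything else is trimmed to second-field resolution.

Three design points deserve a note:

* **G-groups are atomic.** Trimming `A*01:01:01G` to two fields would
  produce a name (`A*01:01`) that no longer denotes the group, so
  trimming leaves G-group names untouched.
* **Low-resolution names.** A two-field name such as `DQB1*06:02` is
  mapped to a group only when *every* listed extension of it belongs to
  the same group; otherwise it is left trimmed. This avoids arbitrary
  disambiguation.
* **Fix-point normalization.** The mapping and trimming rules are applied
  repeatedly until the name stops changing. A single map-then-trim pass
  is not idempotent: trimming an unlisted four-field name can produce a
  two-field name that itself has a unique extension group. Idempotence is
  a property the rest of the pipeline relies on (normalizing twice must
  be harmless), so the fix-point form is used. Alleles given at
  first-field resolution are too ambiguous to normalize; they are
  returned trimmed with a warning, and gold standards reject them.

## The accuracy metric

Each prediction contributes up to two correct alleles: the size of the
multiset intersection with the gold pair. Concretely, a gold allele can
be "used up" by only one predicted slot, so a homozygous prediction
against a heterozygous truth scores 1, and a no-call scores 0. Per tool
and gene,

$$\mathrm{accuracy} = \frac{\#\text{correct alleles}}{2\,n_{\text{samples}}},$$

where the denominator counts the samples with a gold entry for that gene
(others are ignored for that gene; gold-typed samples the tool skipped
count 0 of 2). Partial single-allele calls are scored by the same
multiset rule as the natural limiting case. The unit tests verify the
scorer against a brute-force maximum-matching oracle over every
unordered pair combination of a 3-allele alphabet, including partial and
empty predictions.

Class-level summaries average per-gene accuracies without weighting by
sample count; a pooled-allele variant (`pooled = TRUE`) is provided
because the two differ when per-gene coverage differs, and reasonable
readers may want either.

## Majority-vote consensus and greedy tool selection

The consensus call for a sample × gene is the complete allele pair
predicted by the largest number of tools. Votes are cast by *complete*
pairs only — a partial call has no pair identity, so it abstains, and if
every ensemble member abstains the consensus is a no-call. Ties are
resolved by the pair whose supporting tool has the best individual
accuracy for that gene (rank 1 in `hla_tool_priority()`); a residual tie
falls back to the lexicographically smaller pair, purely for determinism.
Rankings are per-gene by default — "best tool for this gene" — with a
`global_priority` switch that collapses them to one ranking across genes.

The greedy committee search mirrors how one would deploy a minimal
ensemble: start with the best individual tool; add the tool that most
often produces a *fully correct* pair on the keys the first tool got
wrong (wrong = fewer than two correct alleles); then repeatedly add the
unselected tool whose inclusion maximizes mean consensus accuracy, until
all tools are in. The trajectory is nested by construction, and each step
is verified in the tests against exhaustive evaluation of every
single-tool extension. Candidate ties are broken by individual accuracy,
then tool id. Class I and class II committees should be selected
separately (pass `genes = hla_genes("I")` or `"II"`), since tool
strengths differ sharply by class.

## Concordance and population frequencies

`hla_concordance()` reports, per gene and tool pair, the fraction of
shared samples (both tools made a complete call) with an identical
unordered pair — homozygous pairs compare as multisets.

`observed_frequencies()` counts each called allele across both slots and
divides by the number of called samples, so per-gene values sum to 2;
the per-chromosome column divides by twice that number and sums to 1.
Both are reported because published tables follow the per-sample
convention while population genetics uses per-chromosome; Pearson
correlation, the downstream use, is invariant to the positive rescaling
between them (the tests assert bit-identical `r`).

`combine_study_frequencies()` aggregates studies by sample-size-weighted
averaging. An allele a study omits is treated as frequency 0 *with the
study's full weight* — study panels are treated as exhaustive surveys —
with a `drop_missing` switch for the alternative reading. Correlations
default to the union allele universe with absentees at 0
(`universe = "intersection"` is available), and p-values are reported
per gene without multiplicity adjustment, matching how such correlations
are conventionally displayed.

## Coverage statistics

Callers need reads: accuracy collapses below some depth. The package
takes the *mean HLA read depth* — mean coverage over the
peptide-binding-region exons (exons 2–3 for class I, exon 2 for
class II), computed upstream by tools such as mosdepth — as an input
column and provides:

* `depth_group_test()`: Wilcoxon rank-sum comparison of depths behind
  correct vs incorrect pairs (tie-corrected normal approximation,
  without continuity correction so that identical groups give exactly
  p = 1; the statistic is validated against exact pair-counting for all
  group sizes ≤ 5);
* `fit_depth_logistic()`: a binomial GLM of pair correctness on raw
  depth (relative log-likelihood tolerance 1e-8, ≤ 100 iterations), with
  an explicit separation diagnostic instead of a hard failure, and a
  `log_depth` switch as a documented extension;
* `effective_depth()`: the subsampling identity
  `depth × fraction retained`;
* `min_depth_for_accuracy()`: the lowest depth at which the
  piecewise-linear interpolant through the per-fraction curve reaches a
  target accuracy (default 90%). The curve aggregates one point per
  retained fraction (mean effective depth, mean accuracy) rather than
  interpolating per-sample points, matching the five-fraction
  subsampling design (100/50/10/5/1%). A target below the whole curve
  returns the lowest measured depth with a warning; a target above it
  returns `NA` ("unattainable") with a warning.

## The synthetic generator

`sim_config()` + `simulate_benchmark()` emulate the *product* of real
callers on real cohorts, not the callers themselves:

* **Gold standards** are Hardy–Weinberg draws — two independent alleles
  per sample × gene from the gene's frequency table. Default tables come
  from a symmetric Dirichlet with concentration 0.5 over 12 alleles,
  giving the few-common-many-rare profiles typical of HLA loci; explicit
  tables can be supplied.
* **Tool errors.** Each tool has a no-call probability ν and a
  per-allele miscall probability ε (defaults ν = 0.02, ε = 0.05, the
  order of magnitude of mid-range real callers). A miscalled allele is
  drawn frequency-weighted from the gene's other alleles — real callers
  err toward common alleles — which keeps observed frequencies
  near-calibrated even under noise.
* **Depth coupling.** Optionally ε becomes `plogis(a + b·depth)` with
  per-key depths drawn log-normal (default meanlog = log 40,
  sdlog = 0.6, centred on typical exome coverage of the HLA exons).
* **Between-tool correlation.** A `shared_load` λ mixes a per-key latent
  difficulty into every tool's error indicator through a Gaussian
  copula, so marginal rates stay exactly ε while errors correlate
  increasingly with λ — emulating the observation that some samples are
  hard for every caller.
* **Streams.** All randomness descends from one seed through named
  streams (per tool, plus gold/depth/difficulty), so adding a tool to a
  configuration never perturbs the other tools' draws, and identical
  configurations yield byte-identical fixture bundles
  (`make_fixture()`).

What the generator does *not* emulate: linkage between genes, haplotype
structure, read-level artefacts, reference bias, or any specific real
caller's idiosyncrasies (e.g. heterozygote-dropout beyond what per-allele
miscalls induce). Passing tests therefore demonstrate the correctness of
the *evaluation machinery* under its stated model, not the field
performance of any real tool.

## Numerical and scale choices

Deterministic tie-breaks (documented above) make every function a pure
function of its inputs; the test suite includes row-permutation and
relabeling invariance checks. The test suite runs at desk scale — up to
10,000 samples for the frequency-calibration check, 20 seeds × 1,000
samples for the consensus-gain check, 100 datasets × 5,000 records for
logistic parameter recovery — sizes at which the asserted Monte-Carlo
bounds (3–4 standard errors) are comfortably discriminating.

`scripts/acceptance.R` runs a 500-sample, five-tool class I benchmark
plus a depth-coupled coverage analysis and writes its headline numbers
(best-tool accuracy, consensus accuracy and gain, greedy trajectory,
concordance, frequency correlation, Wilcoxon p, logistic slope, minimum
depth for 90% accuracy) as JSON.

## Known limitations

* Ambiguity strings (multiple candidate pairs separated by `/` within a
  single call) and P-group normalization are out of scope; inputs are
  one pair per tool × sample × gene.
* First-field-only gold alleles are rejected rather than interpreted.
* The consensus weights all tools equally; no learned vote weights.
* Accuracy is reported at the normalized (G-group / second-field)
  resolution only.
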