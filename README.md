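# hlabench

Benchmarking and ensemble calling for HLA genotyping tools.

Computational HLA callers infer a sample's HLA genotype — two alleles per
gene for the classical class I (HLA-A, -B, -C) and class II (HLA-DPA1,
-DPB1, -DQA1, -DQB1, -DRB1) loci — from exome or RNA sequencing reads.
Different tools fail on different samples, so two questions recur for
anyone running them at scale: *how accurate is each tool against PCR-typed
gold standards*, and *how much better is a committee of tools than the
best single one*? `hlabench` is a tidy R toolkit for both. It is aimed at
immunogenomics pipelines (neoantigen prediction, transplant matching
research, association studies) that consume HLA calls in tabular form.

## What it computes

**Nomenclature.** Allele names are compared after mapping to IPD-IMGT
G-groups (alleles identical over the peptide-binding-region exons) and
trimming to second-field resolution; a G-group name such as `A*01:01:01G`
is an atomic comparison unit and is never trimmed further.

**Accuracy.** For sample *s* and gene *g*, a predicted allele is correct
when it matches one of the two gold alleles, each gold allele usable at
most once (a homozygous prediction against a heterozygous truth earns at
most 1). With *n* gold-typed samples,

    accuracy(tool, gene) = (# correct alleles) / (2 n)

No-calls count 0 of 2; samples without gold for a gene are ignored for
that gene. Per-class summaries are unweighted means over the class's
genes.

**Consensus (metaclassifier).** The ensemble call for a sample × gene is
the complete allele pair predicted by the most tools; ties go to the pair
backed by the tool with the best individual accuracy for that gene. A
greedy forward selection then finds a small committee: start from the best
tool plus the tool that most often fully rescues its wrong samples, and
repeatedly add the tool giving the largest gain (or smallest loss) in mean
consensus accuracy.

**Concordance, population frequencies, coverage.** Pairwise tool
concordance of complete calls; observed allele frequencies vs published
study frequencies combined by sample-size-weighted averaging, compared by
Pearson correlation; and the depth–accuracy relationship via a Wilcoxon
rank-sum test, a logistic regression of correctness on mean HLA read
depth, subsampling arithmetic (`depth × fraction retained`) and linear
interpolation of the minimum depth reaching a target accuracy.

**Synthetic benchmarks.** A seeded generator draws Hardy–Weinberg
genotypes from an allele-frequency table and corrupts them with per-tool
no-call and miscall rates (optionally depth-coupled, optionally
correlated between tools), so the whole pipeline is testable without
sequencing data.

## Worked example

```r
library(hlabench)
library(dplyr)

# normalize allele names against a G-group mapping
g <- read_g_groups(system.file("extdata", "hla_nom_g_fixture.txt",
                               package = "hlabench"))
hla_normalize(c("A*01:01:01:01", "HLA-B*57:01:05", "C*04:09N"), g)
#> [1] "A*01:01:01G" "B*57:01"     "C*04:01:01G"

# a synthetic three-tool benchmark on the class I genes
cfg <- sim_config(
  n_samples = 200, genes = hla_genes("I"),
  profiles = bind_rows(
    tool_profile("optiluxe",   error_rate = 0.05, no_call_rate = 0.01),
    tool_profile("hlarouter",  error_rate = 0.10, no_call_rate = 0.03),
    tool_profile("typemaster", error_rate = 0.12, no_call_rate = 0.00)),
  seed = 20260925)
sim <- simulate_benchmark(cfg)

acc <- hla_accuracy(sim$calls, sim$gold)
hla_class_accuracy(acc)
#>   tool       mhc_class n_genes accuracy
#> 1 hlarouter  I               3    0.864
#> 2 optiluxe   I               3    0.936
#> 3 typemaster I               3    0.888

# majority-vote consensus beats the best tool
sel <- hla_select_tools(sim$calls, sim$gold)
tidy(sel)
#>    step tool_added accuracy
#> 1     1 optiluxe      0.936
#> 2     2 typemaster    0.95
#> 3     3 hlarouter     0.973
```

The trajectory reads: the best single tool reaches 93.6% allele-level
accuracy (mean over HLA-A/B/C); adding its best complement lifts the
majority vote to 95.0%, and the full three-tool committee to 97.3% —
tools err on different samples, which is exactly what the vote exploits.
`autoplot(sel)`, `autoplot(acc)` and `autoplot(hla_concordance(sim$calls))`
draw the corresponding figures.

## Documentation

The methods vignette (`vignettes/hla-benchmarking.Rmd`) describes the
model, its assumptions, the tunable parameters, numerical choices and
known limitations; every exported function has roxygen reference
documentation.
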