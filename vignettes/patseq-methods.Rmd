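---
title: "Quantifying poly(A) site choice and tag-based expression with patseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying poly(A) site choice and tag-based expression with patseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patseq)
library(dplyr)
```

## The analysis problem

PAT-seq libraries sequence short cDNA tags anchored at the mRNA–poly(A)
junction. Each mapped tag reports one cleavage-and-polyadenylation event, so a
tag set does two jobs at once: the *positions* of tags within a gene's 3'-UTR
measure relative usage of alternative poly(A) sites, and the *number* of tags
per gene is a proxy for mRNA abundance. `patseq` implements both analyses for
a four-genotype design — wild type, a polyadenylation-factor null mutant
(`oxt6`, lacking CPSF30), and two complementation lines (`C30G`, the wild-type
protein; `C30GM`, a protein unable to bind calmodulin) — together with a
synthetic-data generator that emulates the sequencing experiment with a known
ground truth.

The scientific questions the pipeline answers are: does the mutant shift
poly(A) site choice genome-wide, do the complemented lines restore it, and
which genes' expression depends specifically on the intact calmodulin-binding
site (high in the wild type and `C30G`, low in `oxt6` and `C30GM`, or the
inverse)?

## Pipeline structure

The stages mirror how such data are processed in practice:

1. **Demultiplexing** (`demultiplex()`): reads are assigned to the unique
   barcode within a configurable Hamming distance (default 0, i.e. exact;
   conservative because barcode errors are rarer than ambiguous rescues are
   harmful). Reads equidistant from two barcodes stay unassigned.
2. **Trimming** (`trim_tags()`): the leading 5' adapter (exact prefix), the
   first occurrence of the 3' sequencing adapter, and the terminal oligo-dT
   remnant are removed. Tags shorter than 20 nt after trimming are discarded
   (unique mappability at this genome scale).
3. **Reference construction** (`build_extended_utr_db()`): each annotated
   3'-UTR is extended 500 nt downstream (truncated at chromosome ends) and
   stored as the reverse complement of the genomic-sense extended region. The
   extension captures tags from transcripts with inefficient termination
   whose cleavage sites fall past the annotated UTR end. Extensions are *not*
   truncated at neighbouring genes; any resulting ambiguity is resolved at
   mapping time by the unique-best-hit rule.
4. **Mapping** (`map_tags()`): exact 16-mer seeds at three offsets plus
   full-length verification with at most 2 substitutions and no indels — a
   deterministic alignment that is exhaustive for 50-nt tags under that
   budget (three disjoint seed windows cannot all be hit by two
   substitutions). Ties across distinct loci are reported multimapped and
   excluded from profiles. Alignments can be exported as SAM against the
   database sequences.
5. **Site profiling** (`build_site_profiles()`): cleavage positions are
   clustered per gene and sample by single linkage with a 24-nt window (the
   scale of cleavage microheterogeneity); each cluster keeps its modal
   position, tag count, and usage proportion.
6. **Profile comparison** (`genomewide_comparison()`, `compare_all_pairs()`,
   `cumulative_curve()`, `screen_pattern_genes()`).
7. **Digital expression** (`counts_to_tpm()`, `filter_expressed()`,
   `log2_ratio_matrix()`, `cam_dependent_filter()`, `wilcoxon_bin_test()`,
   `baggerly_proportions_test()`).

`run_pat_pipeline()` chains all stages from a single seeded configuration and
logs per-stage read counts; every stage is also exported on its own.

## Orientation conventions

Coordinates are 0-based half-open internally; GFF3 conversion happens only at
the I/O boundary. Database position 0 is the 3'-most base of the extended
region, so positions count upstream into the transcript.

Simulated reads carry the tag in mRNA sense, ending at the cleavage site and
followed by the poly(A) remnant — the layout of the biological molecule. The
database is stored in first-strand cDNA orientation (reverse complement of
the extended UTR), so the mapper reverse-complements each tag before seeding;
the start of that alignment is then exactly the cleavage position, the tag
base adjacent to the removed remnant.

## The oligo-dT remnant rule and its inherent ambiguity

The remnant is stripped as the maximal terminal A-run with at most one non-A
interruption, and only when it contains at least 5 A's — the interruption
tolerates one sequencing error inside the remnant, and the minimum run length
distinguishes a remnant from ordinary 3' sequence. One consequence is
unavoidable: when a transcript's own sequence ends in A (about a quarter of
positions in a random genome), those bases are indistinguishable from the
remnant and are clipped with it, shifting the apparent cleavage position a
few nucleotides upstream. This is a property of oligo-dT-primed data, not of
the implementation; it is why site recovery is assessed within ±3σ of the
cleavage jitter (±9 nt by default) rather than byte-exactly, and why the
24-nt clustering window absorbs it entirely.

## The profile-difference metric

For one gene and two samples, usage vectors are built over the union of the
samples' site clusters (representatives within the clustering window are
matched) and compared with

$$D(p, q) = \tfrac12 \sum_i |p_i - q_i|,$$

the total variation distance. $D$ is 0 exactly for identical profiles, 1
exactly for disjoint support ("all tags moved somewhere else"), symmetric,
and satisfies the triangle inequality — the properties expected of a bounded
per-gene difference score for usage distributions. Genes need at least 10
tags in *both* samples to be scored; below that, usage estimates are
dominated by sampling noise.

Genome-wide structure is read from cumulative curves: the ECDF of $D$ across
genes, one curve per pairwise comparison. Replicate-like pairs rise early;
genuine shifts in poly(A)-site choice push curves right. In the four-genotype
design the informative contrast is `wt–oxt6` against `wt–C30G`/`wt–C30GM`:
restoration of wild-type site choice by a transgene makes its curve coincide
with the replicate curve. We formalize "curve A lies right of curve B" as the
gene-matched one-sided Wilcoxon signed-rank test on per-gene $D$ values
(every comparison scores the same genes, so pairing by gene removes the
between-gene variance that would otherwise swamp a minority of shifted genes)
together with pointwise ECDF dominance on a 0.05-step threshold grid.

The screen for calmodulin-dependent poly(A) choice
(`screen_pattern_genes()`) selects genes that look wild-type-like in `C30G`
(D ≤ 0.2) and mutant-like in `C30GM` (D(oxt6, C30GM) ≤ 0.2) while being
clearly shifted between wild type and both `oxt6` and `C30GM` (D ≥ 0.5).
The low/high thresholds are deliberately separated so sampling noise cannot
move a gene across both at once.

## Digital expression

Counts are normalized to tags per million (tpm). Following the analysis
order used with such data, genes are first filtered — kept only when tpm is
*strictly greater than* 5 in at least one sample — then a pseudocount of 1
is added to every normalized value before ratios, so unexpressed genes yield
ratio 1 rather than dividing by zero. Six pairwise ratios are formed:
`wt/oxt6`, `C30G/oxt6`, `wt/C30GM`, `C30G/C30GM` (discriminating), and
`C30GM/oxt6`, `wt/C30G` (controls). A gene is called calmodulin-dependent
when all four discriminating fold changes exceed 2 and both controls stay
below 2. "Fold change" is the symmetric magnitude `max(r, 1/r)` — ratios of
positive adjusted tpm cannot be negative, so the absolute-value reading of
the cutoff is equivalent to `|log2 r| > 1`, consistent with the log2
workflow.

Functional-bin enrichment uses the two-sided Wilcoxon rank-sum test of a
bin's log2 ratios against all non-member genes, reported as uncorrected p
and `log10(1/p)` (the plotting scale); a Benjamini–Hochberg column is
appended purely as a convenience. The exact null distribution is used when
the smaller group has at most 8 members and no ties are present — for such
sizes the exact Mann–Whitney distribution is identical to exhaustive
enumeration of splits, which the test suite verifies against an independent
enumeration oracle — and the normal approximation with average ranks and
continuity correction otherwise.

The proportions test (`baggerly_proportions_test()`) compares a gene's
library proportion between replicate groups with a weighted t-type
statistic. Within each group, per-replicate proportions are combined with
library-size weights; the variance of the weighted mean is the sum of a
binomial within-replicate term $\hat p(1-\hat p)/N$ and a between-replicate
overdispersion term estimated from the weighted spread of the per-replicate
proportions (a beta-binomial-style decomposition). The reference
distribution is t with $(m_A - 1) + (m_B - 1)$ degrees of freedom; with one
replicate per group the between term is zero — there is nothing to estimate
it from — and the standard normal is used. The variance-formula variant is
isolated in this one function so it can be swapped without touching the rest
of the pipeline.

## What the generator emulates — and what it does not

`pat_sim_config()` fixes the study conditions: a 2 × 250-gene genome with
genes on both strands, four barcoded samples (6-nt barcodes) at an expected
2 × 10⁵ tags each, 1–3 true poly(A) sites per gene placed inside the UTR or
its 500-nt downstream extension at least 60 nt apart, cleavage
microheterogeneity as a discretized Gaussian with σ = 3 nt, 50-nt tags,
substitution-only errors at 0.2% per base, and a poly(A) remnant of 6–12 nt
followed by the 3' adapter. Per-gene, per-sample counts are Poisson around
genotype means (the simplest model consistent with tag counting; an
overdispersed generator can be substituted by drawing counts from
`truth$expression` directly). The read layout — barcode, then 5' adapter,
then tag — is fixed and documented; tag length and the error profile are
declared defaults, not inferred from data.

Planted structure drives the tests: 10% of genes are APA-shifted (identical
usage in `wt`, `C30G`, `C30GM`; the major site moved in `oxt6`, with the
major proportion drawn from 0.75–0.9), and 2% are calmodulin-dependent in
expression with a planted fold of 5 in the `wt ≈ C30G` vs `oxt6 ≈ C30GM`
pattern (direction drawn per gene). Planted expression patterns are placed
on solidly expressed genes (base weight log-uniform on [2.5, 5] against a
[1, 5] background): the planted genes are meant to realize their ratio
pattern, and at tag-count depths an expression floor would let Poisson noise
rather than biology decide their control ratios. An optional
`planted_screen_fraction` plants genes in which `C30GM` *retains* the
shifted usage, exercising the poly(A)-pattern screen; it defaults to 0,
matching the expectation that the screen on restored lines returns nothing.

Real libraries differ in ways the generator deliberately ignores: no
introns or splicing, no internal-priming artifacts (the mapper's optional
A-rich masking is therefore off by default), no PCR duplicates, no
overdispersion beyond Poisson, uniform base composition, and no paired-end
structure. Passing tests therefore demonstrate that the *computational*
pipeline recovers a known truth under realistic counting noise — not that
any biological conclusion about real tissue follows.

## Numerical choices

* Usage vectors must sum to 1 within 1e-6 on entry to the metric; cluster
  counts are renormalized after cross-sample matching, so the metric sees
  exact simplex vectors up to floating-point rounding.
* Cluster representatives are modal positions, ties broken toward the
  smaller coordinate; single-linkage chains are cut where successive sorted
  positions gap by more than the window.
* Mapping ties (equal lowest mismatch count at distinct loci) are
  multimapped, never arbitrarily resolved; equal hits found through
  different seeds at the same locus are deduplicated first.
* Degenerate inputs fail loudly: zero-total samples in tpm, unnormalized
  usage vectors, missing comparisons in the six-ratio filter, out-of-range
  database positions, and misordered screen thresholds are all errors, not
  warnings.
* Sampling from degenerate integer ranges (e.g. a fixed remnant length) is
  guarded against R's `sample(x)` scalar expansion.

## Problem sizes used by the test suite

The deep property checks run at the study's stated scale: 10,000 random
vector pairs for the metric axioms; the full 500-gene, five-sample (the four
genotypes plus a wild-type replicate), 2 × 10⁵-tags-per-sample run for the
cumulative-curve separation; 20 independent seeds of the default design for
planted-gene recovery; 1,000 null simulations for the rank-sum calibration
(empirical type-I within [0.035, 0.065] at α = 0.05); and a 4 × 5 × 10⁴-tag
error-free run for the end-to-end round trip (≥ 99% of emitted tags
recovered at their emitted cleavage position within ±3σ).

## Known limitations

* The profile-difference score is reported without per-gene significance;
  the genome-wide curves, not per-gene calls, are the inferential object.
* The mapper is exact-substitution only; indel-containing tags are lost
  (at 0.2% substitution-only simulated error this is by construction, and
  on real data short tags with indels are rare but nonzero).
* With a single replicate per group the proportions test has no
  between-replicate variance estimate and behaves as a two-proportion
  z-test; its p-values are then anti-conservative under biological
  overdispersion.
* Cleavage positions for genes whose 3' sequence is A-rich are
  systematically shifted upstream by remnant trimming (see above); at the
  default clustering window this does not move tags between clusters.

## A minimal run

```{r example, eval = FALSE}
cfg <- pat_pipeline_config(sim = pat_sim_config(genes_per_chromosome = 25,
                                                depth_per_sample = 2e4,
                                                seed = 1))
run <- run_pat_pipeline(cfg, quiet = TRUE)
summarize_comparisons(run$comparisons)
autoplot(run$comparisons)
dplyr::filter(run$expression$cam_filter, pass)
```
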