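---
title: "Joint differential expression and differential splicing analysis with spliceswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint differential expression and differential splicing analysis with spliceswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceswitch)
```

## The problem

Gene-level differential expression analysis of bulk RNA-seq averages over a
gene's splicing isoforms. A gene whose total output is unchanged between two
conditions can still redistribute that output across its isoforms — in the
extreme, the *major* isoform in one condition becomes a *minor* isoform in
the other ("major–minor isoform switch"). Such genes are invisible to
gene-level tests and require an analysis of within-gene isoform
*proportions*. spliceswitch implements a complete pipeline for this joint
analysis: isoform quantification by EM, abundance and consistency filtering,
a proportion-based differential-splicing test, a six-region joint
classification, and the composition of novel exon-skipping transcripts from
splice-junction evidence. A ground-truthed synthetic-data generator stands in
for patient RNA-seq so that every stage is testable offline.

## Quantification: RAEM and RPKM

Reads are summarized per gene into *equivalence classes*: sets of isoforms a
read is compatible with (every aligned block inside the isoform's exon
union, every spanned junction a junction of that isoform), with read
multiplicities. RAEM (Reads Assign by Expectation Maximization) then
estimates isoform proportions $\theta$ by the standard multinomial EM:

- E-step: a read in class $c$ is assigned to isoform $i \in c$ with weight
  $\frac{\theta_i / \ell_i}{\sum_{j \in c} \theta_j / \ell_j}$, where
  $\ell_i$ is the isoform's effective length;
- M-step: $\theta_i \propto$ the summed fractional assignments.

Numerical choices: uniform initialization (which preserves symmetry, so
structurally identical isoforms get equal proportions rather than an
arbitrary tie-break); effective length equal to the plain transcript length,
because the target regime is short (~54 b) single-end reads for which
fragment-length corrections are immaterial; convergence when the largest
proportion change falls below `tol = 1e-6`, capped at `max_iter = 1000`
iterations; a gene with zero reads returns uniform proportions flagged
`zero_reads` and its proportions are treated as undefined downstream. The
per-iteration observed-data log-likelihood is retained so tests can assert
its monotonicity, and on two-isoform genes the fit is checked against a
grid search of the likelihood.

Abundance is reported as RPKM, $10^9 C / (N L)$ for $C$ reads on a feature
of $L$ bp in a library of $N$ uniquely aligned reads. Isoforms use their
summed exon length; genes use the length of the union of their exon
intervals, and a gene's count is the number of reads compatible with at
least one of its isoforms. The per-million denominator $N$ counts all
uniquely aligned reads of the sample (not only exonic ones) — the simplest
reading, applied consistently. Multi-mapped SAM records are skipped.

## Filtering

Three filters precede the splicing test, all thresholds collected in
`analysis_thresholds()`:

- **Gene abundance** (`min_avg_rpkm = 1`): a gene is removed when its mean
  RPKM is below 1 in *both* conditions. We read "a cutoff of 1 in both
  conditions" as remove-when-low-in-both (keep a gene expressed in at least
  one condition), parallel to the unambiguous isoform-level wording; the
  stricter require-expression-in-both reading is available via
  `require_both_conditions = TRUE`. The comparison is strict, so an entity
  at exactly 1 RPKM is kept.
- **Isoform abundance**: the same rule at isoform level, restricted to
  surviving genes. Isoforms that survive are the "expressed" isoforms; a
  candidate gene must have more than one.
- **Proportion variance** (`variance_cutoff = 150`): replicate-level
  proportions are multiplied by 100 ("enlarged proportions") and a gene is
  kept only when the variance across replicates of every isoform's enlarged
  proportion is below 150 in each condition — i.e. only genes whose
  isoform usage is consistent within condition are tested. The variance is
  the unbiased sample variance (`n-1` denominator, R's default); with three
  replicates the choice is material, so `variance_denominator = "n"` is
  available and the choice is recorded in the pipeline log. The cutoff is
  strict: a variance of exactly 150 fails.

Proportions entering the variance filter and the test are recomputed over
the surviving isoforms (renormalized within each sample), since dropped
low-abundance isoforms would otherwise leave the columns summing below
100%; `renormalize_proportions = FALSE` disables this.

## The differential-splicing test

For each candidate gene an $n \times 2$ matrix is built: row $i$ holds the
average over each condition's replicates of isoform $i$'s enlarged
proportion, so each column sums to 100. These averaged percentages are used
directly as *pseudo counts* in Pearson's chi-square test of independence.
Working on proportions rather than read counts deliberately decouples the
test from expression level: raw counts make trivial proportion shifts
significant in highly expressed genes and mask large shifts in weakly
expressed ones.

Yates' continuity correction ($\max(0, |O - E| - 0.5)$ per cell) is applied
to $2 \times 2$ tables only, mirroring the behaviour of R's `chisq.test`;
tables with more rows use the uncorrected statistic (a `yates = "always"` /
`"never"` override exists). The Yates term is clamped at zero so small
deviations cannot contribute negatively. Pseudo-count columns are not
rounded to integers. Rows that are zero in both conditions are dropped
before testing (with a warning, reducing the degrees of freedom) because a
zero row would produce zero expected counts and an undefined statistic;
fewer than two non-zero rows is an error. P-values are adjusted by
Benjamini–Hochberg across exactly the candidate set (via
`stats::p.adjust`), and results are ranked by FDR. Note that the FDR values
depend on the candidate universe: on synthetic candidate sets they are not
numerically comparable to any genome-wide analysis, though bounds (an
adjusted value never falls below its raw p-value) always hold.

## Joint classification and switch calls

Gene-level differential expression is categorized from the ratio of mean
case RPKM to mean control RPKM: up-regulated above 1.25, down-regulated
below 0.8, and *no change* on the closed interval between them (both
inequalities strict, so the endpoints are no-change). Differential splicing
is significant when $-\ln(\mathrm{FDR}) > 3$, i.e. FDR $< e^{-3} \approx
0.0498$. The (DE category, DS flag) pair maps onto six regions of the
DE-vs-DS plane:

| | not DS-significant | DS-significant |
|---|---|---|
| down | 1 | 2 |
| no change | 3 | 4 |
| up | 5 | 6 |

Region 4 — no expression change, significant splicing change — is the
scientifically interesting novel category. The constraints that fix this
mapping are that region 4 is no-change + DS and that regions 1 and 5 are
the expression-altered, non-DS sides; which side is "down" is a plotting
convention, inferred here from left-to-right panel order and configurable
via `region_orientation` (regions 3/4 and the even/odd split are
unaffected). A *switch* is called when the argmax isoform of the control
column differs from the argmax of the case column; ties are flagged and
reported as no switch. An undefined fold change (both condition means zero)
excludes a gene from region assignment rather than forcing a category.

## Novel transcripts from junction evidence

Junction files (TopHat-style BED12, two blocks flanking one intron) are
matched against the annotated junction universe. A *novel junction call*
requires an unannotated junction whose donor end coincides with an
annotated exon end and whose acceptor start with an annotated exon start of
the same gene, with read support of at least `min_support` (default 2 —
single-read junctions are alignment-noise-prone; the published analysis
states no threshold). Junctions matching two genes are excluded as
ambiguous. A call is condition-specific when observed in at least
`min_case_samples` case samples and no control sample. Junction identity is
exact — `(chrom, donor end, acceptor start)`, no positional fuzz, matched
on either strand since junction strands from aligners may be undetermined;
transcript records, by contrast, must carry explicit strands.

For each parent transcript containing both flanking exons, the novel
transcript is the parent's exon chain minus every exon strictly inside the
junction's intron; its id is the parent id suffixed `_N` (a second junction
on the same parent gets `_N2`, and so on, to keep ids unique). Adjacent
exons (nothing skipped) are an error, as such a junction would already be
annotated. When two skipping junctions of the same gene overlap without
containment they are relabelled `mutually_exclusive`, a deliberately simple
surrogate for full mutually-exclusive-exon pairing, which is out of scope;
composition is still performed per junction. Augmenting the annotation with
composed transcripts and re-running quantification lets the novel isoforms
absorb the junction-spanning reads, after which the joint analysis can be
repeated on the augmented annotation (`run_pipeline()` automates both
passes).

## The synthetic study generator

`sim_config()` / `simulate_splicing_study()` emulate the study design the
pipeline targets: two conditions with three replicates each, genes with 1–5
isoforms, and short single-end reads summarized as equivalence classes.
Genes are laid out as non-overlapping loci; each gene has a full exon chain
and additional isoforms formed by skipping one or two internal exons, so
isoforms share exons and a tunable fraction of reads
(`ambiguous_read_fraction = 0.2`) is ambiguous. Condition-level base
proportions are symmetric-Dirichlet; switch genes move `switch_magnitude`
(50) proportion points from the top to the second isoform between
conditions — e.g. a (75, 25) gene becomes (25, 75). Replicate proportions
are Dirichlet around the condition base with concentration
`replicate_noise = 800`, which keeps the replicate SD of a 50% isoform
near 1.8 points — consistent replicates of the kind the variance filter is
designed to keep. Gene expression is log-normal with planted fold changes
for a `planted_de_fraction` of genes; read counts are Poisson, isoform
assignment multinomial, and junction support binomial per isoform-assigned
read. Planted novel junctions (an internal-exon skip absent from the
annotation) receive evidence only in case samples. Everything is emitted
with full ground truth and is byte-reproducible under the config seed,
which every output file records in a header comment.

What the generator does *not* emulate: sequence content and base quality,
positional/GC bias, paired ends, multi-mapping ambiguity across genes,
overdispersed biological count noise (a negative-binomial flag was
considered and left out; Poisson suffices to exercise every rule), and
annotation incompleteness beyond the planted junctions. Passing recovery
tests on these data therefore demonstrates the correctness of the
implementation under its own model assumptions, not performance on real
patient RNA-seq.

Test problem sizes are the package's choice of a compact but informative
regime: recovery suites use 200 two-isoform genes at roughly 10,000 reads
per gene for power/null behaviour, 1,000 random tables for the statistic
oracle, and toy 2–5 exon genes for junction logic.

## Known limitations

- The EM follows the standard multinomial formulation; the original RAEM
  description lives in prior work and could differ in initialization or
  weighting detail.
- Pseudo-count chi-square p-values are heuristic by construction (the
  "counts" are percentages); they are comparable across genes, which is the
  point, but they are not calibrated tail probabilities for read-level
  noise.
- With three replicates the variance filter has little power against
  outlier replicates; it is a consistency screen, not a robust estimator.
- Novel-transcript composition is limited to exon skipping (and paired
  skips labelled mutually exclusive); alternative donors/acceptors within
  exons, novel exons and intron retention are out of scope.
- Gene-level DE uses plain RPKM-mean fold change, the quantity the region
  scheme is defined on; no count-based DE model (and no moderated
  dispersion estimation) is included.
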