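---
title: "Detecting differentially correlated miRNA pairs in sperm small-RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differentially correlated miRNA pairs in sperm small-RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bulls of normal semen quality can still differ consistently in field
fertility (sire conception rate, SCR). Differential expression of individual
sperm miRNAs has repeatedly failed to explain this idiopathic variation.
`mirdcor` implements a complementary idea: look not at the *level* of single
miRNAs but at the *relationship between pairs* of miRNAs, and ask whether the
correlation between two miRNAs reverses sign between high-fertility (HF) and
low-fertility (LF) animals. A pair positively correlated in HF samples and
negatively correlated in LF samples is called **CH** ("cooperative in high
fertility"); the mirror pattern is **CL**. The unit of analysis is a cohort
of the scale typical for such studies — here 7 HF and 6 LF bulls — with a
sequence-level small-RNA count table as input.

## The analysis funnel

Starting from a table of raw counts per (sequence, annotation) per sample:

1. **Normalization.** Counts-per-million per sample, dividing by the total
   over *all* annotated sequences in the table (the whole library, not just
   miRNAs). CPM is the minimal depth correction; the downstream Spearman
   stages are invariant to any per-sample monotone rescaling, so the choice
   of per-sample divisor only affects the interaction-model scale and the
   mean filter.
2. **Collapsing.** Values are summed over all member sequences (isomiRs) of
   each miRNA annotation, after restricting to rows of biotype miRNA when a
   biotype column is present.
3. **Expression filter.** A miRNA is retained when its mean normalized count
   across all samples (both groups pooled) is at least 100 and it has at
   most one zero-valued sample. Both bounds are strict on the exclusion
   side: a mean of 99.999 is excluded, a mean of exactly 100 retained; two
   or more zero samples exclude. The pooled (not per-group) mean mirrors the
   single joint retention step of the published funnel.
4. **Within-group correlation and the dual gate.** For every unordered pair
   of retained miRNAs, the Spearman correlation and its two-sided p-value
   are computed separately in the HF and LF groups. A pair survives only if
   `p < 0.05` in *both* groups independently.
5. **Interaction model.** For each surviving pair the ordinary least squares
   model

   `miRNA_A = beta0 + beta1 * miRNA_B + beta2 * LOW + beta3 * LOW * miRNA_B`

   is fitted over all samples, where `LOW` is 1 for LF samples. `beta1` is
   the HF slope; `beta3` is the LF-minus-HF slope difference, so `(beta0,
   beta1)` equal an HF-only fit and `(beta0 + beta2, beta1 + beta3)` an
   LF-only fit. Pairs with two-sided `p < 0.05` for **both** `beta1` and
   `beta3` are candidates: the relationship is real in HF and demonstrably
   different in LF.
6. **FDR control.** Benjamini–Hochberg step-up adjustment is applied to the
   `beta3` p-values of the candidate set; pairs with adjusted `p <= 0.05`
   are reported.
7. **Classification.** Significant pairs are labelled CH (`rho_HF > 0` and
   `rho_LF < 0`), CL (the mirror), or DISCORDANT otherwise (including a
   correlation of exactly zero, which triggers a warning).

Every run carries its funnel — the count of pairs alive after each stage —
retrievable with `glance()`; `tidy()` returns the significant pairs.

## Exact Spearman p-values at small n

With 6 or 7 samples per group, the usual large-sample approximations to the
Spearman null are unreliable and p-values are coarse. For tie-free vectors
with `n <= 9`, `spearman_exact()` therefore computes the two-sided p-value
from the exact permutation null: the distribution of
`S = sum (rank_x - rank_y)^2` over all `n!` equally likely pairings,
enumerated once per `n` and cached. Because `S` is integer-valued for
tie-free ranks, tail comparisons are exact integer arithmetic; the two tails
meet at `S = D` (the null median) and that point is counted once. With ties
(average ranks) the classical `t` approximation on `n - 2` degrees of
freedom is used instead, and the result is flagged `exact = FALSE`.

A consequence worth knowing: the exact null is discrete, so the realized
per-group type-I rate at nominal 0.05 is *below* 0.05 (at `n = 6` the
largest attainable p below 0.05 is about 0.044). The dual gate squares this,
which is why null data yields dual-gate pass rates around 0.2% rather than
0.25%.

## Choices the data did not dictate

Several details are underdetermined by the procedure's published
description; the package fixes them as follows, each switchable where
reasonable:

- **Normalization method** is not stated beyond "normalized"; CPM over the
  full table is the default, and restricting the divisor to miRNA rows is
  available by subsetting before `normalize_cpm()`.
- **Orientation of the model.** The interaction model is asymmetric in A
  and B. Default: the lexicographically first annotation is the response —
  deterministic and symmetric-in-expectation. `orientation = "both"` fits
  both orientations and requires the candidate condition in each.
- **The BH family.** The default adjusts the `beta3` p-values of the
  candidate set (the only family arithmetic consistent with a 23-to-18
  style funnel); `bh_family = "survivors"` adjusts across all dual-gate
  survivors instead.
- **Exact vs asymptotic Spearman p.** Exact permutation for tie-free
  vectors up to `max_exact = 9`; `t` approximation beyond or with ties.
- **Expression scale for the OLS stage** is untransformed CPM by default,
  mirroring the stated model; `log2_expr = TRUE` switches to
  `log2(CPM + 1)` (rank-based stages are unaffected).
- **Welch vs Student.** The per-isomiR test is "unpaired, 2-tailed"; the
  package defaults to Welch (unequal variances), with
  `var_equal = TRUE` for the pooled-variance version.
- **Undefined correlations.** A miRNA constant within a group has no
  defined Spearman correlation; its pairs are excluded and counted in the
  funnel (`n_undefined`) rather than failing the run.

## The isomiR layer

IsomiRs are sequence variants of one miRNA locus. Two analyses are provided:

- `isomir_proportions()` ranks each annotation's member sequences by the
  proportion of reads they contribute, pooled over all samples and both
  groups (matching a single profile per miRNA rather than per-sample
  averages). Ties are broken lexicographically. `flag_consensus()` marks
  the sequence matching the reference mature miRNA (U/T-insensitive), and
  `consensus_proportions()` reports the consensus share — zero when the
  reference sequence was never observed.
- `isomir_ttest()` runs an unpaired two-tailed test per sequence between
  fertility groups, then applies BH **within each annotation's family**, the
  family size being that miRNA's isomiR count. This deliberately permissive
  exploratory correction is kept as the method's defining choice rather
  than replaced by a global one. Degenerate sequences (zero variance in both groups) get
  `p = 1` when means are equal and `p = 0` with a `degenerate` flag when
  they differ.

## Shared-target context analysis

For significant pairs, validated miRNA–gene interaction tables (user
supplied, e.g. exports from curated databases) can be intersected:
`shared_targets()` returns genes targeted by both members of a pair,
`filter_by_context()` intersects with a context gene list (e.g. genes
expressed in mature testis or pre-EGA embryos; case-insensitive), and
`co_target_count()` finds genes supported by at least `min_pairs` pairs of
a chosen class. No live database access is performed; homolog conversion is
the user's responsibility via `map_homologs()`.

## The synthetic generator

`simulate_counts()` provides a download-free test bed emulating the study
design. Per fertility group, each sample draws a latent standard-normal
vector whose correlation matrix is the identity except for 2-by-2 blocks at
planted pairs (`rho_hf` in HF samples, `rho_lf` in LF samples). Latent
values pass through the standard-normal CDF and then the negative-binomial
quantile with a miRNA-specific mean times a per-sample depth factor; each
miRNA count is split into isomiR counts by a multinomial with
Dirichlet-drawn proportions held fixed across samples. The Gaussian copula
is used because it controls the *rank* correlation — exactly what the
pipeline measures — up to the monotone-transfer identity; the attenuation of
rank correlation caused by count discretization and normalization is
accepted and typically shrinks a latent 0.9 to an observed 0.8 or so.

Defaults, chosen once to describe a realistic cohort: 7 HF and 6 LF
samples; 250 miRNA annotations with log-normal relative abundances
(`meanlog 5`, `sdlog 1.5`, spanning several orders of magnitude); expected
library size 1e6 reads with a log-normal per-sample depth factor
(`sdlog 0.2`); NB size 10; 1 to 8 isomiRs per miRNA with Dirichlet
concentration 0.5 (skewed profiles whose dominant isomiR is often not the
consensus); and a background layer of 1000 non-miRNA sequences (tRNA,
piRNA, rRNA, other, in the proportions observed in sperm libraries) holding
82% of reads. The background matters: the CPM divisor is the realized
library total, and only a total averaged over many loci is stable enough —
as real library totals are — to leave planted negative correlations intact.
A miRNA-only table with a few dominant miRNAs would make the divisor itself
noisy and systematically destroy negative (not positive) correlations.

What the generator does **not** emulate: read-level artifacts (sequencing
error, adapters), isomiR edit structure (5'/3' trimming classes), biotype
realism beyond a label column, covariance between abundance and dispersion,
and any real biological pathway structure. Passing recovery tests on this
generator therefore demonstrates the pipeline's statistical behaviour under
its stated model, not performance guarantees on any particular real
dataset.

`evaluate_recovery()` scores a run against the generator's truth: a planted
pair counts as a true positive only when it reaches the final set *with the
expected CH/CL class*; a detected pair with flipped class counts as both a
false positive and a false negative.

## Problem sizes and numerical conventions used by the test suite

The suite exercises: exact-p enumeration against brute force over all `n!`
pairings for `n = 4..7` (50 random tie-free vectors each); the OLS identity
against normal-equation fits on 100 random instances at group sizes (7, 6);
BH against the literal step-up definition on 1000 random p-vectors up to
`m = 200`; null calibration on an 80-miRNA simulation (3160 pairs), where
the dual-gate rate is checked against the product of realized per-group
rates within a 99% binomial interval; and recovery on 100 replicates of a
50-miRNA simulation with 20 planted pairs at latent (+0.9, -0.9), requiring
planted detection to exceed unplanted detection (one-sided Fisher test,
p < 0.01) with every detected planted pair classified CH, plus a 30-replicate
mirror run yielding CL. `t * se` reproduces `beta` to within one unit in
the last place; coefficient identities hold to 1e-8; CPM conservation to
relative 1e-9.

## Limitations

- The correlation analysis is descriptive: no partial-correlation or
  network-module inference, and SCR is used only to define groups, never as
  a continuous covariate.
- With 6 or 7 samples per group, only strong rank correlations are
  detectable at the 0.05 dual gate (roughly |rho| above 0.79–0.83); power
  for moderate effects is essentially nil, which the null calibration and
  recovery tests quantify.
- The interaction model is fitted on the expression scale; with heavy-tailed
  CPM values its t-based p-values inherit the usual OLS sensitivity to
  outliers. The `log2_expr` option softens this at the cost of departing
  from the stated model.
- Database annotation of raw sequences (assigning reads to miRNA names) is
  out of scope: the package consumes annotated tables.
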