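---
title: "Single-molecule-tag deduplication of amplicon deep sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule-tag deduplication of amplicon deep sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtdedup)
```

## The problem

Targeted amplicon sequencing interrogates a panel of PCR-amplified regions
at very high depth — the setting this package emulates is ~1,225 targets of
~150 bp sequenced to roughly 1,000X. Because every read of a target starts
and ends at the primer boundaries, the standard positional criterion for
marking PCR duplicates (identical alignment coordinates) is useless: *all*
reads of a target share coordinates. Unrecognised PCR duplicates are not
harmless. A duplicate is a re-observation of a molecule already counted, so
allele-frequency estimates computed from read counts have a smaller
effective sample size than their nominal depth suggests; tests that compare
counts between samples (for instance to detect clonal evolution between two
tumor time points) then overstate their evidence and the false positive
rate climbs above the nominal significance level.

The remedy is a single molecule tag (SMT; the same idea is widely known as
a unique molecular identifier, UMI): a random N-mer, here 8 or 12 bases,
attached to each template molecule before amplification and sequenced as an
index read. Reads within a target that share a tag descend from one
molecule; counting each (target, tag) pair once restores the molecular
sample size.

This package implements the full computational method — read-to-target
assignment, tag-based duplicate marking, collision modelling, and the
Fisher-test machinery quantifying the damage duplicates do — together with
a synthetic-data generator that provides ground truth for every stage.

## Read-to-target assignment

Reads are assigned without alignment. The first 22 bases of Read 1 are
compared against the reverse complement of each target's downstream
locus-specific primer, and the first 22 bases of Read 2 against each
upstream primer, tolerating up to `max_dist = 2` differences in the
Levenshtein (edit) sense, so single-base indels near the read start are
matched as such rather than cascading into many mismatches. The matcher is
a banded dynamic program (band half-width `max_dist`) that abandons a
candidate as soon as every cell of a row exceeds the bound; an `N` in the
read matches nothing, since an ambiguous base cannot support identity.

A pair is `ASSIGNED` only when both mates have the same unique
minimal-distance target. The other outcomes are kept distinct for QC:
`CROSS_TARGET` (the mates match different targets — typically chimeric
molecules), `AMBIGUOUS` (the minimal distance is tied between targets), and
`NO_MATCH`. Ties are never resolved by design order; mis-assigning a read
silently would contaminate a neighbouring target's allele counts, so
ambiguity is surfaced and those pairs are excluded downstream, as are
cross-target pairs. Designs in which two targets' matching windows lie
within edit distance 2 of each other cannot be demultiplexed under this
rule and are rejected when the design is loaded.

After assignment the primer bases are trimmed (with any 3' read-through
beyond the insert, which is computable because the amplicon boundaries are
known), and pairs whose trimmed reads are not longer than 35 bases are
dropped with a QC count.

## Duplicate marking

Within one target of one sample, the first read carrying a given tag (in
input order) is the unique read; all later reads with that tag are
duplicates. The convention matters only for which read represents a
cluster: permuting the input permutes representatives but leaves every
count, rate and histogram unchanged, and the package's tests assert this.
Tags containing `N` are excluded from dedup and all downstream statistics
(with a QC tally) rather than guessed at. Tags are otherwise treated
verbatim: no 1-mismatch merging is applied by default, because in this
tag-length regime the fraction of tag pairs at Hamming distance 1 is tiny
(for uniform random 12-mers the expected pairwise distance is
$12 \times 3/4 = 9$ and the distance-1 fraction is of order $10^{-6}$), so
tag sequencing errors split clusters far too rarely to matter at the rates
studied here. An optional `merge_1mm` flag exposes the merging behaviour
for users who want it.

## Chance collisions: when two molecules draw one tag

A tag-identified "duplicate" can also arise when two independent molecules
of the same target draw the same tag — a birthday-problem collision that no
tag scheme can eliminate. Two complementary quantifications are
implemented.

**Poisson usage model.** With $n$ tags drawn uniformly from the
$K = 4^L$ possible sequences, each sequence's usage count is approximately
$\mathrm{Pois}(\lambda)$ with $\lambda = n/K$. The expected number of
distinct sequences observed is $K(1 - e^{-\lambda})$, the expected number
seen at least $k$ times is $K \cdot P(\mathrm{Pois}(\lambda) \ge k)$, and
the full expected usage-count spectrum is $K \cdot
P(\mathrm{Pois}(\lambda) = k)$. Tails are computed via the survival
function in log space and exponentiated only after adding $\log K$;
computing $K \times (1 - \mathrm{CDF})$ naively underflows long before the
tail becomes scientifically irrelevant.

```{r poisson}
m <- collision_model(L = 12, n_draws = 14485830)
expected_distinct(m)
expected_count_at_least(m, k = 10)
```

**Occupancy resampling.** The within-target collision fraction at working
depth is estimated by drawing `depth` tags i.i.d. from a tag-usage
distribution for each of `n_targets` targets and counting re-draws. The
distribution can be uniform (for which the closed form
$1 - K\,(1 - (1 - 1/K)^d)/d$ is also provided and used as a cross-check) or
an empirical `smt_frequency_distribution` counting each observed tag once
per target per sample — biased tag usage (for example the thymidine-run
enrichment the generator can emulate) raises $\sum_i p_i^2$ above $1/K$ and
with it the collision rate, uniform usage being the minimum. Truncating a
distribution to its first 8 bases (`truncate_to_prefix`) answers the
8-versus-12-mer adequacy question: at around 1,000X the uniform 12-mer
collision fraction is a few times $10^{-5}$, while an 8-mer universe of
65,536 sequences collides at the percent scale — 8 bases do not carry
enough complexity for deep amplicon work.

```{r occupancy}
collision_fraction_uniform(12, 1074)
collision_fraction_uniform(8, 1074)
```

## Allele statistics and the false-positive-rate machinery

Because assigned reads have known offsets, the allele at an annotated SNP
is read directly off the trimmed sequence (Read 1 by convention; each pair
is counted once, so no halving of double-covered counts is needed — a
deliberate simplification relative to genotyper-derived allele counts,
which count both mates). Sites reporting a third allele in more than 10% of
reads are excluded. Heterozygous SNPs are called from unique reads with a
conservative surrogate for a genotyper: depth at least 50 and alternate
frequency within [0.2, 0.8]; both thresholds are exposed as arguments.

Concordance diagnostics separate the two sources of within-cluster
disagreement: `cluster_concordance` stratifies the fraction of fully
internally consistent duplicate clusters by cluster size (chance collisions
merge molecules with independent alleles, so discordance grows with
collision pressure and cluster size), while `paired_read_concordance`
between the two mates of a pair measures the sequencing-error floor, since
mates share a molecule by construction.

Sample comparisons use exact tests. The two-sided 2x2 Fisher test is the
minimum-likelihood summation over the hypergeometric support (the
`fisher.test` definition), vectorised for thousands of sites. The 2x3 test
enumerates all tables with the observed margins over its two free cells up
to a total count of 5,000, beyond which a seeded Monte-Carlo estimate over
margin-preserving random tables (`r2dtable`) is returned with its standard
error; exact enumeration grows quadratically in depth and the cap keeps the
worst case around $2{,}500^2$ evaluated tables. Somatic-site identification
combines the per-site exact test with Benjamini-Hochberg control across
sites and a germline alternate-frequency ceiling of 10%, at a per-site,
per-sample coverage floor of 50X.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions: 1,225 targets of 150 bp with GC drawn uniformly in [0.3, 0.7],
25-base primers whose 22-base matching windows are regenerated until all
pairs are more than `2 * max_dist` edits apart (so error-free assignment is
provably unambiguous), mean depth 1,000, a 12-base tag, duplicate rate 0.1
(the observed germline median), a heterozygous SNP mid-insert on 200/1,225
of targets, and a per-base substitution error of 0.005 — a round value in
the range typical of the sequencing chemistry emulated. Where the emulated
study fixes a value, the default is that value; the remaining defaults were
chosen once as field-realistic and are not tuned.

Per target, depth is negative binomial (`size = 20`, giving a coefficient
of variation around 0.23 at 1,000X — the per-target depth law of the
emulated data is not published, so a moderately overdispersed law was
chosen); `m = round(d (1 - rate))` template molecules each draw a tag and,
on het targets, a Bernoulli(0.5) allele; the remaining `d - m` reads
resample templates with replacement, inheriting tag and allele, so
duplicates disagree with their template only through sequencing error.
This is occupancy-style resampling, matching the published simulation
design; a PCR branching process (per-cycle amplification efficiency) is
deliberately out of scope. Sequencing error is applied to the genomic
reads; the tag read's error rate is a separate knob (`smt_error_rate`)
defaulting to 0, since the method under study treats tags verbatim and the
distance-1 analysis above shows tag errors are a negligible channel at
these rates. Qualities are constant Q30 placeholders — no stage of the
method uses them.

What the generator does *not* emulate, and what passing tests therefore do
not certify about real data: GC- and input-dependent amplification
efficiency (duplicate rates here are homogeneous across targets up to
sampling noise), indel sequencing errors, adapter chimeras beyond simple
cross-target mate pairing, contamination, and any dependence between a
molecule's tag and its allele.

## The splitting / injection experiments

`fpr_experiment` reproduces the null-comparison design: one parent sample
per replicate is pushed through the full pipeline (assignment, trimming,
dedup); het SNPs are called once from the unique reads; the unique-read
allele calls are split at random into two pseudo-samples, which therefore
share one underlying allele urn — an exact null. For each requested
duplicate rate, duplicates are injected into each half separately at
constant depth (`m = round(n(1-rate))` kept uniques plus `n - m` re-draws
with replacement), and the 2x2 Fisher test compares the halves at every
het SNP. At rate 0 the conditional test is exactly valid and its
discreteness can leave the false positive rate slightly below the nominal
5%; injected duplicates shrink the effective sample size while leaving
nominal depth unchanged, inflating the variance of the alternate-frequency
estimate (`vaf_variance_experiment` measures exactly this) and with it the
FPR. `allocate_experimental_duplicates` supports the companion design in
which real, tag-linked duplicates follow their unique read into its half.

## Numerical and reproducibility choices

Every stochastic operation is a pure function of its inputs and a seed;
composite experiments derive per-stage and per-target sub-seeds
deterministically from the root seed (kept below $2^{31}$), so per-target
streams are reproducible independently of execution order. Exact-test
summations include the conventional $(1 + 10^{-7})$ slack on the observed
table's probability before comparison, matching `fisher.test`. Degenerate
tables (any zero margin) return p = 1. The bounded Levenshtein matcher
returns `max_dist + 1` for all distances beyond the bound, which the caller
treats as "no match"; the band makes the per-candidate cost linear in the
window length.

Problem sizes in the shipped tests were chosen to make each assertion
statistically decisive at desk scale: the FPR experiments use 220
het-SNP targets at depth 1,000 with 10 replicates (binomial noise on a
mean FPR near 0.05 is then well inside the asserted ±1.5 percentage
points); the variance experiment uses 100 injections per rate; collision
cross-checks use a few hundred thousand draws, putting three Monte-Carlo
standard errors well below the effect sizes asserted.

## Known limitations

Primer matching assumes the first 22 cycles contain the primer — protocols
that pad or stagger reads need pre-trimming. The het-SNP caller is a
surrogate, not a genotyper: it handles biallelic SNPs only and will reject
genuinely unbalanced heterozygous sites (allele-specific amplification)
that a likelihood-based caller might keep. The 2x3 Monte-Carlo p-value is
an estimate; at the default 10^5 tables its resolution near p = 0.05 is
about ±0.002. Consensus-calling within duplicate clusters to correct
sequencing errors is an application of the cluster map this package
produces, not something it performs itself.
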