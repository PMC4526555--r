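---
title: "Small RNA discovery and hibernation differential expression: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small RNA discovery and hibernation differential expression: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

tormir analyses pooled small RNA sequencing libraries from a two-tissue,
two-state hibernation design (brain and white adipose tissue, hibernating
vs active: libraries HB, AB, HA, AA). This vignette explains the models
behind each stage, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical conventions and
design decisions a user should know before trusting the output.

## Read preprocessing

Small RNA inserts (18–33 nt, gel-purified) are shorter than the sequencing
cycle, so raw reads end in 3′ adapter. `trim_adapter()` removes the longest
read suffix that exactly matches a prefix of the adapter, requiring an
overlap of at least `min_overlap = 6` nt. Matching is exact by design:
tolerance would make trimming ambiguous and results platform-dependent, and
the true adapter is known in a designed experiment. The cost is that an
insert whose last bases happen to extend an adapter prefix is over-trimmed
by a base or two; for mature-miRNA counting this is absorbed by the ±2 nt
quantification window. Inserts longer than `read_cycle − min_overlap`
retain their adapter remnant and are discarded at the length filter — a
real property of adapter trimming at fixed cycle counts.

`clean_reads()` drops reads containing N and reads outside 18–33 nt
(inclusive bounds, matching the gel-purified insert range). Base-quality
filtering is deliberately off by default: pooled small RNA protocols vary
in their quality conventions and the classification steps that follow are
exact-match filters anyway, so low-quality reads fail them naturally.

`collapse_unique()` reduces the library to distinct sequences with
per-library counts. Redundancy, `100·(1 − unique/clean)`, is the headline
duplication statistic of a small RNA library; deeply sequenced miRNA
libraries typically show ~90–95%.

## Mapping, filters and classification

Reads are mapped exactly (both strands) with Biostrings pattern
dictionaries grouped by read length; a minus-strand hit means the read's
reverse complement matches the forward genome. Two filters follow, both
from standard practice for miRNA discovery: reads hitting more than 20
genomic loci are removed (repeat-derived multi-mappers would otherwise
flood hairpin discovery; exactly 20 loci is kept), and reads seen only once
in total are removed as sequencing noise.

Classification assigns exactly one label per read by sequential
precedence: known miRNA → ncRNA subclass (rRNA, tRNA, snoRNA, snRNA,
other) → transcript → repeat class (LINE, SINE, LTR, DNA, SSR, Low) →
unknown. The precedence formalises the screening order of the standard
protocol (miRBase scan first, then ncRNA databases on the remainder, then
repeats); a read matching both a known miRNA and a repeat interval is a
miRNA. Known-miRNA matching allows ≤ 2 mismatches over the overlap with a
±2 nt end slack on each side, reflecting mature length variants from
imprecise Drosha/Dicer cleavage; indels are not modelled. ncRNA and
transcript matching is exact containment of the read in the reference
sequence (either strand); repeat assignment requires the read's genomic
interval to lie entirely within a repeat interval. Coordinates are 0-based
half-open throughout, converted at the GFF3 boundary.

## Hairpin discovery

Both arms of a precursor produce reads, so candidate read loci closer than
200 nt (strictly; measured end-of-previous to start-of-next) are merged
into one genomic block and examined once. Each block is extended by 150 nt
on both sides — precursors are ~90 nt with the mature typically at one stem
end, so this flank comfortably covers the partner arm.

Inverted repeats are found by local alignment of the window against its own
reverse complement (match +3, mismatch −3, linear gap −6, report threshold
30, maximum extent 240 nt; the conventional einverted parameterisation for
miRNA screens, with printed magnitudes interpreted as penalties). The
threshold means a perfect stem of 10 bp is the smallest reportable repeat.
Non-overlapping repeats are reported best-first by masking and re-scanning.

Each repeat, extended by 10 nt per side, is folded by **weighted base-pair
maximisation** (G:C = 3, A:U = 2, G:U = 1; minimum hairpin loop 3 nt;
deterministic traceback). This is a topology-level model, not a
thermodynamic one: the hairpin decision depends on stem/loop topology and
pairedness of the mature, which the weighted maximisation captures while
remaining exactly testable against a brute-force oracle. The weights order
pair stabilities the way nearest-neighbour free energies do on average.
Exact parity with any thermodynamic folder is a non-goal, and an
alternative folder can be substituted upstream of `check_hairpin()` since
the criteria consume only a pairing map.

A maximum-weight fold of a repeat *embedded in flanking sequence* can
reorganise: flank bases pair with each other or with the stem and the
global optimum need not leave the repeat folded as an isolated hairpin.
Discovery therefore anchors on terminal loops: every terminal loop inside
the repeat span is a candidate anchor, its enclosing stem is grown outward
while it still contains exactly one terminal loop, and the criteria are
evaluated against that stem. If no anchor passes in the extended-context
fold, the repeat region is refolded in isolation and re-examined once.
This two-step rule recovers essentially all planted precursors in
simulation while leaving the acceptance criteria strict.

The criteria themselves (`check_hairpin()`) follow the published MirCheck
defaults: one terminal loop; precursor ≤ 240 nt; mature entirely within one
arm, not touching the loop; ≤ 4 unpaired mature bases; no asymmetric bulge
> 2 nt within the mature pairing region. Every violated criterion is
reported, not just the first.

Mature calling (`call_mature()`) implements the both-arms rule: a
candidate needs at least one unique read on *each* arm whose 5′ end lies
within ±2 nt of that arm's count-weighted modal start (the ±2 nt window
models cleavage imprecision; the modal anchor defines "mature position"
for novel miRNAs, where no annotation exists). Confidence is `high` when
an arm carries ≥ 2 unique reads inside the window. Among length variants
the representative is the one with the highest total count, ties broken by
length then lexicographically, so the call is deterministic. A perfect
stem has a mirror symmetry — a read from a minus-strand precursor also
matches the plus strand at the partner-arm locus — so discovery picks the
orientation carrying the majority of (count-weighted) hit support and
stacks only strand-consistent hits; for a perfect stem the two
orientations give the same candidate with the arm labels swapped.

Candidates are deduplicated by genomic overlap (best-supported wins) and
labelled `conserved` when a representative mature matches the known set
within 2 mismatches, else `novel`.

## Differential expression without replicates

Pooled designs have one library per condition, so dispersion cannot be
estimated from the data. The test is the conditional exact negative
binomial test: counts are scaled to the geometric mean of the two library
totals (rounded), and, writing s for the scaled sum, the conditional
distribution of one count given s under equal means is negative
hypergeometric — independent of the mean, depending only on the dispersion
φ. The two-sided p-value sums the conditional probabilities of all
outcomes no more probable than the observed one. At φ = 0 the conditional
distribution is binomial and the implementation switches to the exact
binomial test on raw counts with success probability
`total_h/(total_h + total_a)` (for the Poisson model, exact conditioning
needs no size equalisation). A feature with zero counts in both libraries
returns p = 1 and logFC = 0 and is flagged `absent`.

φ defaults to 0.1 (a conventional squared biological coefficient of
variation for tissue samples) and is the analysis's largest free
parameter: it is a config input, not an estimate, and conclusions should
be checked across a small φ grid. The test-suite cross-checks this
implementation against an independent Bioconductor implementation of the
same conditional test; they agree to machine precision.

logFC uses a 0.5 prior count per library (`log2((y_h+0.5)/N_h) −
log2((y_a+0.5)/N_a)`), keeping one-sided expression finite; `logTPM` is
log2(mean TPM + 1). Base 2 throughout. Significance uses inclusive
thresholds `P ≤ 0.01` and `|logFC| ≥ 1`. Multiple-testing correction is
deliberately not applied to these calls — the pooled design's raw-p
convention is preserved — while the enrichment module does apply BH where
many categories are tested.

A power note computed by the package's own acceptance suite: at baseline
mean 100, φ = 0.1, and a planted 4-fold change, the conditional exact
test calls roughly 60% of true changes at these thresholds. That ceiling
is a property of the no-replicates design (an independent implementation
of the same test gives identical numbers), so sensitivity claims above it
are not attainable under these conditions; the empirical false discovery
rate at the same settings stays below 10% and the null type-I error is
calibrated.

Specificity calls are zero-count rules: tissue-specific means zero counts
in both libraries of the other tissue; state-specific, zero in both
libraries of the other state; `high_count` flags totals above 100, the
threshold below which pooled-library zeros are weak evidence.

## Target prediction

3′UTR inference: with a human ortholog UTR available, the 3-kb window
downstream of the coding stop is globally aligned to it (match +1,
mismatch −1, linear gap −2) and truncated at the last window position
aligned to an ortholog base; alignment gaps inside the kept region are not
removed — the record keeps genomic bases. Without an ortholog the full
(clipped) 3-kb window stands in, justified by the observation that the
overwhelming majority of mammalian 3′UTRs are shorter than 3 kb.

Sites are exact 7mer seed matches (miRNA positions 2–8; no G:U in the
seed), upgraded to 8mer when the base facing position 1 pairs or is an A;
6mers are off by default. Site scores are `ΔΔG = ΔG_duplex − ΔG_open`.
ΔG_duplex is a nearest-neighbour dynamic programme over antiparallel
pairings: stacked pairs add published Watson–Crick stack free energies
(G:U stacks use a simplified documented set), bulges and internal loops
pay an opening (3.0 kcal/mol) plus per-nucleotide (0.5 kcal/mol) penalty,
and the initiation term defaults to 0 so the empty pairing bounds the
score at 0. ΔG_open is the difference between the unconstrained and the
site-blocked fold score of a 70-nt window around the site under the same
weighted fold model as hairpin discovery, scaled at 1 kcal/mol per weight
unit — a deliberate simplification standing in for a partition-function
accessibility calculation; it is exact about *whether* a site is
sequestered in stable local structure, approximate about how much. Gene
level aggregation takes the minimum ΔΔG over sites, and pairs with
`ΔΔG ≤ −10` kcal/mol (inclusive) are retained. Numerical parity with any
external target predictor is a non-goal; the cutoff, seed rules and energy
table are config options.

## Enrichment, links, qPCR

Enrichment is the upper-tail hypergeometric test per category with BH
adjustment — the standard choice where only a significance statement per
category is needed. Category-to-gene maps arrive as plain tables; database
retrieval is out of scope. Per-process activity comparisons are two-sided
pooled-variance t-tests over member-gene scores (≥ 2 values per group;
zero pooled variance with unequal means reports p = 0 rather than an
error). miRNA–mRNA links are emitted per retained target pair whose gene
appears in the mRNA table of the matching tissue; `both_significant`
requires P ≤ 0.01 on both platforms, and anti-correlation of directions is
annotated but not required (miRNAs also act in feed-forward circuits).

qPCR follows the Livak 2^(−ΔΔCt) procedure: technical replicates are
averaged within each biological sample first (the standard aggregation
order; with balanced replication the alternative order gives the same
point estimate), ΔCt is taken against the endogenous control per sample,
ΔΔCt is the case-minus-control group mean difference, and a one-way ANOVA
on per-sample ΔCt gives the p-value. `log2_fold = −ΔΔCt`. Concordance with
sequencing reports sign agreement and significance agreement separately.

## The synthetic-data generator

`simulate_genome()` plants perfect-stem precursors (stem 35–42 bp, loop
8–14 nt, so precursor length centres near 90 nt; matures 20–23 nt at the
stem ends) in a random background genome (GC 0.42), with non-overlapping
placement (≥ 400 nt spacing, clear of the block-merging and flank
geometry) and decoy ncRNA and repeat intervals. Each planted precursor is
re-folded at construction and resampled until it passes `check_hairpin()`,
making the simulator self-consistent with the discovery module — a planted
truth that discovery *should* find. Half the precursors contribute their
matures to the known-miRNA input set ("conserved").

`simulate_reads()` draws distinct read templates — mature-arm reads with
independent 5′ and 3′ offsets from a symmetric ±2 nt distribution
(probabilities 0.05/0.2/0.5/0.2/0.05; the empirical offset distribution of
real libraries is unknown, so this stand-in is a config knob), decoy reads
from annotation intervals, and uniform background — then duplicates them
to the library depth (multinomial copies, mean = `duplication_factor`),
pads with adapter to the 36-cycle read length, and records every read's
true origin. `simulate_counts()` draws i.i.d. NB counts per library
(variance μ + φμ²; Poisson at φ = 0) with DE features' means multiplied by
`2^(±de_logfc)` in the hibernating library of a randomly designated
tissue.

What the simulator does **not** emulate: sequencing errors and quality
variation, ligation and GC bias, imperfect stems and multi-loop
precursors, isomiR 3′ non-templated additions, cross-mapping between
paralogous precursors, and real genome repeat structure. Passing the
recovery tests therefore demonstrates the pipeline's logic is correct on
clean signals at realistic geometry — not that it is robust to every
artefact of real libraries.

## Problem sizes, determinism, degenerate inputs

The test suite exercises discovery on 30–100 kb genomes with 4–30 planted
precursors and libraries of 1,500–10,000 reads, and the count model on
500–2,000 features; these sizes give stable pass/fail behaviour for the
stochastic properties (recovery, calibration) at desk scale. A single RNG
stream, seeded from the configuration, makes every simulation and the full
pipeline byte-reproducible; reruns with the same seed produce
checksum-identical output files. Degenerate inputs follow explicit
conventions rather than erroring where a convention exists: depth 0 gives
an empty library, zero hairpins an empty truth table, (0, 0) counts p = 1,
an all-equal ANOVA F = 0/p = 1, zero within-group variance p = 0, an
unstructured accessibility window ΔG_open = 0. Genuine contract violations
(empty adapter, zero library totals, mature span outside the structure,
missing reference Ct, unknown annotation class) abort with named errors.

## Known limitations

* The dispersion of the exact test is assumed, not estimated; the ~60%
  power ceiling at the default simulated effect size is intrinsic to the
  pooled design (see above).
* The folding model is topological; opening energies are in "weight units"
  scaled to kcal/mol, so ΔΔG values are comparable within a run but not
  against thermodynamic predictors.
* Known-miRNA matching is Hamming-based; indel variants of a mature are
  not matched.
* The manual-inspection step of classical hairpin curation is replaced by
  the explicit criteria set; structures a curator would rescue or reject
  on sight follow the rules here, for better and worse.
* Ortholog detection, annotation retrieval and mRNA differential
  expression are inputs, not computations.
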