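---
title: "Mining genomes for nisin-like biosynthetic gene clusters"
author: "nisinscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining genomes for nisin-like biosynthetic gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Nisin is a class I lanthipeptide: a ribosomally synthesized peptide whose
serines and threonines are dehydrated (Dha/Dhb, −18 Da each) and coupled to
cysteines into lanthionine rings. A nisin-like biosynthetic gene cluster
(nBGC) encodes the precursor (LanA), the dehydratase (LanB), the cyclase
(LanC), a transporter (LanT), a leader protease (LanP), a two-component
regulator (LanRK) and immunity determinants (LanI, LanFEG). These operons
travel: they are repeatedly found on integrative and conjugative elements
(ICEs), plasmids, prophages and composite transposons, often next to
antibiotic-resistance cargo.

`nisinscan` re-implements, as a tested and reusable pipeline, the
genome-mining workflow behind such surveys: detect candidate precursor
genes, classify the surrounding machinery, curate core peptides, detect
composite transposons and join clusters with externally predicted mobile
genetic elements (MGEs), and summarize sharing across genera. Every stage
can be exercised offline against synthetic genomes with planted ground
truth, which is how the package's test suite and acceptance script work.

## Precursor detection

Two detectors are provided.

**The core sequence pattern.** Candidate cores are residues matching

```
..S.S.CT..C.[TS].{1,6}C.{1,4}[TS].{1,2}[TS]C.{1,3}C
```

which encodes the Ser/Thr–Cys spacing of the five nisin rings; matches are
22–34 residues long by construction. The engine applies standard leftmost,
greedy, non-overlapping regex semantics (documented so that every
implementation agrees) and is a pure function of its input.

**The profile model.** To find family members beyond the exact pattern, a
position-specific log-odds profile is built from an alignment of seed core
peptides. Column probabilities use pseudocounts,
$p_a = (c_a + \alpha b_a)/(N + \alpha)$, scored as
$s_a = \log_2(p_a/b_a)$ bits against the background $b$. Defaults:
$\alpha = 1$; background = residue frequencies of the searched proteome
(computed, never assumed); alignment columns with ≥ 50 % gaps are dropped
(majority occupancy, the standard profile-building rule); equal-scoring
overlapping windows resolve to the leftmost. Unaligned seeds are aligned by
a deterministic center-star method (center = maximal summed pairwise
identity, "once a gap, always a gap"), which removes any external aligner
dependency.

Thresholding is empirical rather than statistical: a profile-HMM E-value
machinery would be out of proportion here, so `calibrateThreshold()`
scores a decoy set (shuffled proteins of realistic composition) and sets
the cutoff to the strict decoy maximum plus 1e-6 bits (or a decoy
quantile). By construction a search of the calibration decoys returns
nothing; the threshold parameter plays the role an E-value cutoff plays in
a database search, and the test suite verifies that every planted
precursor in synthetic cohorts still scores above it.

## Neighborhood classification

`extractContext()` collects the CDS within 30 kb of the focal precursor
gene (at most 25 per side). The 30 kb default matches the span used for
cross-cluster synteny comparisons in this family; the exact neighborhood
parameters of database tools vary, so both are explicit arguments.

`classifyMachinery()` assigns each neighborhood protein to the machinery
class whose reference it matches at global identity ≥ 30 % with aligned
coverage ≥ 70 % of the reference length — conventional homology floors that
a fragmented (insertionally inactivated) gene fails by construction. The
bundled reference set is synthetic (one stand-in per class with realistic
length, see `machineryReferences()`); for real data, users should supply
their own reference proteins per class. Flags for LanT-, LanFEG- and
LanP-like classes deserve caution on real genomes because those domains
recur across many protein families. An *orphan* core gene is one with no
LanB in its neighborhood; the completeness call requires LanB, LanC and
LanI jointly.

## Core-peptide curation

Leader cleavage applies the canonical cut motifs with precedence
GASPR > PQ > PK, taking the rightmost occurrence whose downstream segment
is 20–45 residues long *and* matches the core pattern. The length window
brackets the characterized family (cores of 32–34 residues) with margin;
rightmost-qualifying is the declared resolution for leaders holding several
motif copies. When no motif qualifies, the precursor is aligned to every
bundled characterized precursor and the best reference's cut column is
transferred; below 30 % identity the peptide is returned `unassigned`
(whole precursor as core, flagged for review) rather than guessed.

Pairwise identity comes from an affine-gap Needleman–Wunsch aligner
(BLOSUM62, gap open 10, gap extend 0.5 — conventional protein defaults,
configurable) with deterministic tie-breaking (diagonal, then gap in the
second sequence). Percent identity divides matches by the *full alignment
length including gap columns*: the stricter, order-independent convention,
stated in all outputs. Published cross-peptide identities computed under an
unknown convention may therefore differ; none are asserted by the tests.

Scaffold analysis aligns a core to the canonical 34-residue nisin A core.
Ring feasibility requires a Cys at the scaffold's ring-closing columns
(7, 11, 19, 26, 28) and a Ser/Thr at the ring-opening columns; the hinge is
whatever aligns to scaffold positions 20–22 (NMK in nisin A). Mass ladders
use average (not monoisotopic) residue masses because the family's MALDI
ladders are printed on the average-mass scale; each dehydration removes one
water (18.0153 Da) and masses are reported rounded to integer Da. Which
dehydration count is "fully modified" is peptide-specific knowledge and is
supplied by the caller, never inferred.

## Mobile genetic elements

The composite-transposon rule is implemented in-package: two copies of the
same IS element on one contig flanking an nBGC, outer span (first IS start
to second IS end) of 10–130 kb inclusive, curated to require a
transposase-annotated CDS within the span; overlapping candidates
deduplicate to the shortest qualifying span per cluster. "Same IS" is
operationalized as family-label equality or ≥ 95 % sequence identity over
≥ 90 % mutual coverage (conventional IS-clustering practice; both
thresholds configurable). The curation window is taken to be the outer span
itself, i.e. bounded by 130 kb — the only window the rule actually defines.
Span bounds are exact: the tests probe 10,000 and 130,000 bp at ±1 bp.

Plasmid, ICE and prophage calling is delegated: the package consumes
interval tables from external predictors (the `evidence` column records the
producing tool) and assigns a cluster to an MGE only when *fully contained*
in its interval; containment in several intervals is reported as several
rows, and a cluster contained in none is `"none"`. Containment (not
overlap) is the declared semantics, and it makes co-localization monotone
under interval growth. The cargo census then counts, per MGE type, how many
cluster-bearing intervals carry each product label.

## Similarity networks and summaries

The sequence similarity network has unique sequences as nodes and edges
where global identity reaches a threshold (default 70 %). A
database-backed survey would threshold BLAST E-values instead; the package
has no database statistics, so the identity threshold is documented as an
approximate, tunable stand-in that preserves the graph's role — grouping
near-identical family variants into components. Components come from
union-find and are cross-checked against an independent graph traversal in
the tests. The genus-sharing table keeps cores whose total occurrence
count is strictly above ten ("above ten" read strictly). Cohort
percentages round half-up to one decimal, matching how such numbers are
printed.

## The synthetic cohort generator

`generateCohort()` is the statistical stand-in for the public sequence
databases: it emits single-contig genomes with planted operons (canonical
*nisABTCIPRKFEG* or *lanFEGPBCT* order), leaders carrying a sampled
canonical cut motif, cores mutated from the nisin A template only at
pattern-unconstrained positions (so every planted core matches the
detector by contract), machinery genes reverse-translated from the bundled
references with uniform synonymous codons, 30–80 decoy CDS (shuffled
realistic proteins on random strands), intergenic spacers of 20–200 bp,
identical-IS-flanked regions with controlled outer span, MGE interval
labels with planted cargo, and metadata with configured missingness.

Default rates are the observed frequencies of a real survey cohort: every
genome carries a cluster, orphans at 2/915, composite transposons at
34/915, the MGE mix at 187:54:5 ICE:plasmid:prophage over 915, and 49/915
records missing both source and host. The per-position core mutation rate
defaults to 0.1, a divergence at which variants remain recognizably
nisin-like (roughly the spread among characterized natural variants) while
still exercising the aligner and profile search. Per-genome seeds derive
from the master seed as `master + index * 1000003 mod (2^31 - 1)`, so
cohorts regenerate byte-identically and any genome can be regenerated in
isolation.

What the generator does **not** emulate — and hence what perfect recovery
on synthetic cohorts does not show about real data: codon-usage bias (no
stage reads it), phylogenetic structure among genomes, fragmented
assemblies, annotation errors, and machinery divergence (planted machinery
genes are exact copies of the references, so classification operates at its
ceiling; the interrupted-gene case is tested separately via split
fragments). Decoys are shuffled real-composition proteins, which stress
composition-based false positives but not true remote homologs.

Problem sizes used by the test suite and acceptance script are the
package's own choices for a desk-scale check: planted-recovery runs use a
20-genome default cohort plus a 10-genome stress cohort in which rare
events (orphans, composite transposons, every MGE label) are frequent; the
byte-identical determinism check runs the generator and pipeline twice at
8 genomes, determinism being size-independent.

## Numerical choices and degenerate inputs

* Ties in the aligner resolve diagonal > gap-in-b > gap-in-a; ties in
  window search resolve leftmost; the center-star center ties to the first
  index. All outputs are therefore platform-independent.
* `X` residues score 0 in profiles (neutral) and contribute no counts to
  profile columns or position compositions; sequences containing characters
  outside the 20+X alphabet are rejected at parse time, not coerced.
* Empty inputs: scanning an empty proteome, co-localizing against no MGEs
  and deduplicating nothing all return empty tables; fewer than two
  sequences for a profile, matrix or composition is an error.
* GFF3 translation attributes win over nucleotide-derived translations on
  disagreement (database practice), with a warning.
* Coordinates are 1-based inclusive at every public interface.

## A worked example

```r
library(nisinscan)

cfg <- syntheticConfig(seed = 42, nGenomes = 20)
generateCohort(cfg, "cohort")
res <- runNisinPipeline("cohort", "results")
evaluateAgainstTruth("cohort", res)
```

The same sequence of calls — generation, pipeline, evaluation — is what
`scripts/acceptance.R` executes, together with the fixed worked examples
(the nisin A mass ladder and the cohort percentage ratios).

## Known limitations

* The profile search is ungapped and empirically thresholded; it is not a
  profile HMM and reports no E-values.
* Machinery classification quality on real genomes depends entirely on the
  reference set supplied; the bundled references are synthetic stand-ins
  sized for the synthetic cohorts.
* Identity conventions differ across published tools; comparisons against
  numbers computed under other conventions need care.
* MGE boundary quality is inherited from the external predictors whose
  intervals are consumed.
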