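---
title: "Methods: small RNA cleaning, hairpin discovery, target rules and ddCt quantification"
author: "sRNAkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA cleaning, hairpin discovery, target rules and ddCt quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sRNAkit)
```

sRNAkit re-implements, as small composable operations, the standard desk
analysis of a plant small RNA sequencing library: read cleaning with exact
category accounting, collapsing to unique tags, length and nucleotide-bias
profiling, conserved miRNA family annotation, novel hairpin precursor
discovery, miRNA/target duplex filtering, and stem-loop RT-qPCR relative
quantification. This vignette records the models behind each stage, the
tunable parameters, the numerical conventions, and what the synthetic-data
generator does and does not emulate.

## Read cleaning and accounting

A small RNA read is an insert (the biological molecule, 15--30 nt) followed
by the 3' adapter and downstream bases. Reads failing a high-quality filter
(more than 10 % `N`, or mean Phred below Q20; both configurable) are dropped
first. Every high-quality read is then assigned to exactly one category, in
a fixed precedence order so that the labels partition the library:

1. `adapter3_null` — no 3' adapter found. Adapter detection is
   seed-and-extend: the first position (scanning insert starts 1 to
   `max_len + 1`) where the adapter's first 8 nt match with at most one
   mismatch. The published tables this stage mirrors give the categories
   but not the matching rule; one mismatch in an 8-nt seed is the common
   trimmer default.
2. `insert_null` — adapter at position 1 (empty insert).
3. `adapter5_contam` — the trimmed insert starts with the 5' adapter's
   first 8 nt (again at most one mismatch), i.e. an adapter-dimer artefact.
4. `polyA` — insert at least 90 % adenine. The category is conventional but
   undefined in the tables it mirrors; 90 % is this package's documented
   cutoff.
5. `short_lt18` — insert shorter than `min_len` (default 18 nt).
6. `clean` — an insert of 18--30 nt.

Percentages are reported relative to the high-quality count and rounded
half up to two decimals, which is the arithmetic that reproduces published
accounting tables exactly (base R's round-half-to-even does not).
`summarizeCleaning()` re-derives the clean count from the removal counts,
so a printed table can be checked for internal consistency.

Clean inserts are collapsed by `collapseUnique()` into a `TagSet` — each
distinct sequence with its read count, ordered by count (descending) then
sequence. The collapse is exact; counts always sum to the number of input
reads.

## Composition profiles

`lengthDistribution()` tabulates tag lengths 15--30 (anything else pools
under "other"), weighted by read counts by default — the convention that
matches per-read tag statistics; an unweighted mode counts distinct tags.
`firstBaseBias()` and `positionalBias()` report per-position base fractions
with T presented as U; storage stays in the DNA alphabet and conversion
happens only at the reporting layer. Consensus calls take the per-position
argmax with ties broken U > A > G > C, reflecting the 5'-U bias expected of
plant miRNAs.

## Annotation and conserved families

`classifyTag()` walks an ordered list of reference sets (default priority
rRNA > tRNA > snRNA > snoRNA > scRNA > mature miRNA) and stops at the first
class containing the tag as a substring within a per-class mismatch
allowance (0 for structural RNAs, 2 for the mature catalogue). The order
gives every tag exactly one class. At desk scale, exact and near-exact
substring matching replaces database BLAST searches; the allowance of two
mismatches for miRNA variants is the conventional tolerance.

`matchMirbase()` aligns a tag against every catalogue entry at every
ungapped offset with up to 2 nt of overhang per end, counts mismatches over
the opposed positions, and keeps the minimum; ties go to the
lexicographically smallest reference name, then the smallest offset. One or
more mismatches flags the tag as a *variant* of the matched family. Family
names are normalised by stripping the species prefix, the arm suffix and
trailing letter variants (`ath-miR157a` to `miR157`). `aggregateFamilies()`
sums counts per family and drops families under a floor of 500 reads by
default, the conventional reporting floor for family tables.

## The folding model

All folding uses a deliberately minimal energy model: G:C pairs score −3,
A:U −2, the G:U wobble −1 (kcal/mol-like units), hairpin loops must enclose
at least three unpaired bases, and there are no stacking, bulge or loop
terms. `foldHairpin()` computes the exact minimum-energy non-crossing
structure by dynamic programming (a Nussinov-style recursion over pair
energies, implemented in C++), with a deterministic traceback: among
co-optimal structures the leftmost unresolved base pairs whenever possible,
to its largest co-optimal partner. Because the model is a plain sum of pair
energies, every result can be verified against exhaustive enumeration —
the test suite does exactly that on hundreds of short random sequences —
and all numbers in this package are bit-reproducible without external
thermodynamic tables.

The price is that these energies are **not** comparable with
nearest-neighbour values from thermodynamic folding engines: a published
mean precursor folding energy in kcal/mol cannot be reproduced or compared
under this model, and the package deliberately does not try. Relative
statements (ranking, thresholds in model units) are the supported use.

## Novel precursor discovery

`mapTags()` reports every exact occurrence of each tag on both genome
strands; `clusterBlocks()` merges hits on the same chromosome and strand by
single linkage with a 200-nt gap limit. For each block,
`evaluatePrecursor()` takes the dominant tag (highest count, ties by
sequence) as the mature candidate and examines genomic windows of 100, 160,
220, 280, 340 and 400 nt — precursors of plant miRNAs span roughly
100--400 nt — anchored left, centre and right of the tag. The anchoring
matters: the mature can sit on either arm of the hairpin, so a window
centred on the tag can miss a star arm up to ~380 nt away; symmetric-only
windows measurably lose true loci.

Each window is folded and checked against the acceptance criteria, all
exposed in `precursorThresholds()`:

* window length within 74--400 nt (the soft lower bound admits compact
  precursors, which do occur below the canonical 100 nt);
* fold energy at most −20 model units;
* at least 14 of the mature's bases paired and at most 6 unpaired;
* the mature's partner positions form a contiguous region (spread at most
  the mature length + 4) — a genuine mature/star duplex rather than
  scattered pairing;
* the mature does not pair with itself (it must lie outside the hairpin
  loop);
* the energy of the realised mature pairs is at least 74 % of the mature's
  perfect-complement energy.

The last two criteria carry the discrimination. Under a per-pair model with
no loop penalties, *any* 100--400-nt window — including shuffled sequence —
folds far below −20, and random context can even pair 14 bases of a tag;
what random context essentially never provides is a contiguous,
near-complementary star. The 74 % bound reuses the duplex-quality threshold
from the target rules. On the seeded synthetic benchmark (ten planted
precursors in a 60-kb genome) the defaults recover 10/10 planted loci with
zero calls on an equal-length precursor-free genome.

The star sequence is read off the partner region under the 2-nt 3' overhang
convention of Dicer products; the arm is 5p when the mature precedes its
partner region. Because a hairpin contains the mature's reverse complement
on its other arm, the same locus is usually hit on both strands; accepted
candidates are de-duplicated by genomic overlap (keeping the
highest-count, then lowest-energy, then plus-strand call). Among accepted
windows for one block, the smallest is reported — the most compact hairpin
containing the mature duplex — rather than the lowest-energy one, which
under this model would always be the largest window.

## Target rules

`scoreDuplex()` opposes a miRNA (5'-3') to a transcript site
(reverse-oriented for antiparallel pairing) and classifies each position:
Watson-Crick match (0), G:U wobble (0.5), mismatch (1.0). A site one base
longer or shorter is handled as a single 1-nt bulge scoring 1.0, placed
where the total score is minimal (ties to the 5'-most placement); larger
indels are refused. Wobbles at half weight are required for the rule set to
be meaningful: the window rule's bound of 2.5 has no force under integer
scoring.

`applyRules()` applies the six acceptance rules: total score < 4; no two
adjacent mismatches anywhere; no adjacent mismatches within positions 2--12;
zero score at positions 10--11 (the cleavage site — wobbles and bulges there
also violate it, with a flag to relax the wobble case); windowed score over
positions 1--12 strictly below 2.5; and duplex energy at least 74 % of the
miRNA's perfect-complement energy. Two readings were genuinely open and are
resolved as follows: "adjacent mismatches" counts mismatch and gap
positions, not wobbles; and the rule-1 total is on the half-weight scale
(so three mismatches plus two wobbles, total 4.0, fails). Acceptance is
monotone: degrading a matched position never rescues a rejected duplex.

## Stem-loop RT-qPCR quantification

`deltaDeltaCt()` implements the textbook two-reference-point
quantification: per replicate, dCt = Ct(target) − Ct(reference gene),
paired by replicate index; ddCt subtracts the mean calibrator-tissue dCt;
fold change is 2^−ddCt, so the calibrator's fold is exactly 1 and log2 of
the fold equals −ddCt. Amplification efficiency is fixed at 2 (plain
2^−ddCt); an efficiency-corrected mode is out of scope. The replicate SD is
propagated on the ddCt scale and reported as a fold range
2^−(ddCt ± SD), since error-bar conventions vary. Significance uses a
pooled-variance two-sided Student t test on the replicate dCt values of a
tissue against the calibrator (df = n1 + n2 − 2) — the scale on which qPCR
noise is conventionally near-Gaussian — starred at p < 0.01 (`**`) and
p < 0.001 (`***`). A flag-free design choice: the test is on dCt, not on
folds, whose distribution is log-normal under Gaussian Ct noise.

## The synthetic-data generator

`generateReads()` emulates an adapter-ligated plant sRNA library and emits
a truth label per read, so the cleaner can be scored against a known
answer. Its defaults are the study conditions of the rest of the package:

* category fractions ~99.1 % clean, with small adapter-null (0.146 %),
  insert-null (0.017 %), 5'-contaminant (0.308 %), short (0.387 %) and
  polyA (0.005 %) fractions — the removal profile of a deep, healthy
  library;
* insert lengths with half the mass at 24 nt and a secondary 21-nt mode
  (24 nt ≈ 50 %, 21 nt ≈ 21.8 %, 23/20/22 nt at 9.0/6.9/6.3 %), the
  canonical plant profile dominated by 24-nt heterochromatic siRNAs;
* 5'-U probability of 0.8--0.95 for the miRNA-sized classes, an A-shifted
  18-nt class (0.15), weaker bias at the extremes;
* adapter sequences default to the standard Illumina small RNA adapters —
  they are the generator's own documented strings, not inferred from any
  particular instrument run;
* optionally, mature miRNA sequences spiked into the clean fraction at
  given relative abundances (off by default; the bundled conserved
  catalogue is a convenient source).

Background inserts are rejection-sampled so they cannot collide with the
cleaner's adapter heuristics; residual ambiguity (an insert/adapter
boundary window that happens to match the adapter seed with one mismatch)
affects on the order of 0.02 % of reads and is left in deliberately — it is
exactly the ambiguity a real trimmer faces. The generator does **not**
model sequencing errors, instrument-specific quality profiles, or ligation
bias; a passing recovery test therefore shows correctness of the
accounting and discovery logic under clean signal, not robustness to
platform noise.

`generateGenomeWithPrecursors()` plants near-perfect inverted repeats
(random 5' arm, ≥ 3-nt loop, reverse-complement-derived 3' arm with a
configurable number of substitutions placed outside the mature/star
duplex; total length 100--400 nt) at non-overlapping loci on random
strands, with the 21-nt mature embedded so its 2-nt-overhang star falls
fully on the other arm. `generateCtTable()` produces Ct values with
designed fold changes and Gaussian noise; at zero noise the ddCt analysis
returns the designed folds exactly, which anchors the quantification
arithmetic.

All generator randomness flows from a single integer seed through R's RNG,
one stream per operation in documented order, so identical configurations
give byte-identical FASTQ output.

## Problem sizes, determinism, degenerate inputs

The test suite and the acceptance script size their simulations for a
single-CPU run: 20,000-read libraries for cleaning concordance (binomial
4-sigma tolerances against the generator's fractions), 500 random
sequences of up to 14 nt for fold/enumeration equivalence, 10,000 random
duplexes for rule/oracle agreement, ten planted precursors in 60 kb for
recovery, and 1,000 null qPCR simulations for type-I calibration at
alpha = 0.01. Empty inputs are contracts, not errors, wherever a stage can
meaningfully produce an empty result (an empty read file yields zeroed
reports and empty tables); genuinely undefined requests (an empty tag set
for a distribution, a zero perfect-complement energy in a ratio) raise
errors naming the offending input.

## Known limitations

* The folding model ignores stacking and loop entropies; energies are
  model units, not thermodynamic predictions, and suboptimal structures,
  partition functions and pseudoknots are out of scope.
* Mapping is exact-match only (the discovery contract assumes perfect
  genomic matches); there is no mismatch or indel tolerance in `mapTags()`.
* Target scanning is sense-strand, single-miRNA-width windows with at most
  one 1-nt bulge; translational-inhibition-style loose pairing is not
  modelled.
* Annotation is substring/ungapped matching against user-supplied
  reference sets; covariance-model searches and remote databases are out
  of scope.
* qPCR quantification assumes efficiency 2 for every assay and pairs
  target and reference by replicate index.
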