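---
title: "Genome survey methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome survey methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomesurvey)
```

This vignette is the package's account of the science behind each estimator:
what is being modeled, which parameters matter and why the defaults are what
they are, what the synthetic-data generator does and does not emulate, and
where the design was genuinely open and a choice had to be made.

## Genome size from a k-mer histogram

Counting all length-`k` windows of a shotgun read set and tabulating how many
distinct *canonical* k-mers occur 1, 2, 3, ... times gives a multiplicity
histogram with a characteristic shape: a steep slope at low multiplicity
(k-mers created by sequencing errors are mostly unique or near-unique) and a
peak at the **k-mer coverage** `c*`, the average number of times a
single-copy genomic k-mer is sampled. Two features of the histogram drive
everything:

- the **error trough** `t`: the first local minimum, separating the error
  slope from the genomic peak. We define it as the smallest `c >= 1` with
  `n(c) <= n(c-1)` and `n(c) <= n(c+1)` (with `n(0) = Inf`, absent bins 0,
  ties toward smaller `c`). A histogram with no such minimum (e.g. coverage
  too low for a distinct peak) is an error, with advice to set the threshold
  manually, rather than a silent guess.
- the **coverage mode** `c*`: the `argmax` of `n(c)` over `c > t`, ties
  toward smaller `c`.

Two complementary size estimates follow:

1. **Lower bound**: total non-error k-mer instances divided by the k-mer
   coverage, `sum(c * n(c) for c > t) / c*`. Discarding sub-threshold mass
   (which contains some real genomic k-mers) biases it low.
2. **Upper bound**: total read bases divided by the read coverage
   `c* * L / (L - k + 1)`, the k-mer coverage inflated by the number of
   k-mer windows per `L`-bp read. Repetitive and heterozygous sequence pulls
   the modal k-mer coverage down, so this quotient tends to bias high.

With the same read set and mode, the lower bound can never exceed the upper
bound: the non-error k-mer mass is at most the total window count
`n_reads * (L - k + 1)`, and the upper bound equals exactly that window
count divided by `c*`.

Defaults: `k = 27` (long enough to be mostly single-copy in large plant
genomes, short enough that a 150-bp read carries 124 windows and the 2-bit
encoding fits one machine word), read length 150 (standard short-read
chemistry). Both are explicit arguments everywhere.

### Numerical choices

- **Canonicalization** is the lexicographic minimum of a window and its
  reverse complement (equivalently the numeric minimum under 2-bit `A<C<G<T`
  encoding). This makes the histogram invariant under reverse-complementing
  any input read, which the test suite asserts.
- **Ambiguity codes**: a window containing any non-ACGT symbol is skipped
  whole rather than split or substituted. This is the simplest rule
  consistent with excluding error-like artifacts, and it keeps the mass
  conservation invariant exact: `sum(c * n(c))` equals the number of
  ACGT-only windows in the input.
- **Strict trough**: "non-error" means `count > t`, not `>=`. The boundary
  bin holds a vanishing fraction of the mass in any realistic histogram
  (well under 0.1% at survey scale), but the choice is surfaced as a
  `trough_inclusive` flag rather than hidden.
- **Sharding**: counting can partition k-mer space by canonical value modulo
  a shard count, bounding the in-memory map; the histogram is provably
  independent of the shard count, and the tests check bin-for-bin equality.
- Estimates are carried at full double precision; rounding (one decimal for
  coverage, three significant figures for Gbp) happens only in print
  methods and reports.

### A known small-genome limitation

The mode is an integer, so the lower bound is quantized in steps of roughly
`1/c*` (about 4% at `c* ~ 25`). On a small test genome the histogram is also
noisy: neighbouring positions share covering reads, so a genome of `G` bp
contributes only about `G / (L - k + 1)` effectively independent
multiplicity draws. At the scale used in the recovery test (100-kb genome,
30X reads, so `c* ~ 24.8` and ~800 effective draws) the empirical mode can
land one or two bins away from the expected value, moving the recovered size
by several percent in either direction. At the teragbase scale the method is
meant for, both effects vanish. The test suite runs the recovery at a fixed
seed and the unit tests use a larger simulated genome (200 kb at `k = 21`,
where the expected k-mer coverage is an integer, 26) when asserting that the
histogram peaks near its expectation.

## Telomere length from shotgun reads

Telomeres are tandem arrays of a short motif — `CCCTAAA` in plants,
`CCCTAA` in humans — at both ends of every chromosome. In a uniform shotgun
read set the fraction of reads containing telomeric repeat estimates the
fraction of the genome that is telomeric, giving the closed-form average
length per chromosome end:

    L = G * T / (2 * R * C)

with `G` the genome size, `T` the number of telomeric reads among `R`
examined, and `C` the haploid chromosome count (`2C` telomeres). `G` and `C`
are user inputs, as in any survey application; they come from a k-mer
estimate and cytology, not from this estimator.

Detection: a read is telomeric when the first 100 bp contain five exact
tandem copies of the motif *or of its reverse complement* as a substring.
The strand decision was genuinely open: shotgun libraries are unstranded,
so a telomere is read as `CCCTAAA...` from one strand and `TTTAGGG...` from
the other. Matching only the forward concatemer would halve `T` on real
data; we match both. Phase is immaterial: any pure-repeat run of at least
`5 * m + m - 1` bp contains an in-phase five-copy concatemer of the `m`-bp
motif.

Other choices, all surfaced as `telomere_params()` fields:

- **Exact matching** (no mismatches). A sequencing error inside the 35-bp
  concatemer loses the read, so `T` — and hence `L` — is biased slightly
  low at realistic error rates; tolerant matching would be a different
  method, not a refinement of this one.
- **Trim to 100 bp** before searching; reads shorter than the trim are
  searched whole (and counted in the report) rather than discarded — with
  uniform 150-bp libraries the case never arises.
- **First `R` reads in stream order** (default 10 million). Illumina
  deliveries are not positionally sorted, so a stream prefix behaves as a
  random subsample.
- A boundary-overlap bias is accepted: a read straddling the telomere edge
  is detected only if its searched prefix still contains a full concatemer,
  so `T` under-counts slightly. The simulation tests quantify this — the
  placement oracle and the estimator agree, and recovery of a 5,000-bp
  truth from a 10-Mb genome lands well within 20%.

## Organelle triage

Chloroplasts and mitochondria are present in many copies per nuclear genome,
which makes two rule cascades effective:

**Chloroplast read selection**: retain a read when it is *longer than*
20 kb (strict, matching "longer than") and the union of its alignment
intervals to a reference plastome covers at least 75% of it (inclusive).
The union — not the single best alignment — matters because the target is
circular: a read spanning the origin splits into two alignments.

**Mitochondrial contig triage**: include a candidate contig when it has a
reference-mitochondrial protein hit, *or* mean short-read coverage of at
least 120X (against ~8X nuclear), *or* at least 50% of its length aligning
to a reference mitogenome; exclude it — overriding any inclusion — when at
least 90% of its length aligns to nuclear sequence. Contigs firing no rule
are `unclassified`. Every rule that fired is reported as an ordered reason
code (`PROTEIN_HIT`, `HIGH_COV`, `MITO_ALN`, `NUCLEAR_EXCLUDE`), so the
provenance of every verdict is auditable. Exclusion precedence had to be
made explicit here: applied to well-separated evidence it never matters
(protein-hit contigs with low nuclear similarity are always retained, a
property the tests assert on the synthetic mixture), but NUMT-like contigs
— nuclear segments of mitochondrial origin — fire both an inclusion rule
and the exclusion rule, and exclusion must win.

Coverage is *mean* depth (aligned bases over contig length), supplied as a
TSV by the caller; whether a median would serve better is undecidable from
the rule itself, and mean is the convention coverage tables report.

**Contained-contig elimination** (reference-guided scaffolding clean-up):
a contig is dropped when a single alignment covers its *entire* length
(containment fraction 1.0 by default, overridable) against a *longer*
contig, landing *strictly inside* it — both target flanks non-empty. Flush
placements are kept: an end-to-end abutment is evidence of adjacency, not
redundancy.

## Consensus accuracy and ploidy normalization

Consensus accuracy uses the unanimous-contradiction rule: an assembly
position is an error only when **every** aligned read base differs from the
assembly base. A single agreeing read vetoes the error call. Positions with
depth below `min_depth = 2` are not assessed: at depth 0 the rule is
vacuous, and at depth 1 it degenerates to "one read disagrees", which
measures the read error rate, not the assembly's. Skipped positions are
tallied (zero-depth and low-depth separately) so any alternative convention
can be reconstructed from the report. Disagreement is substitution-only on
aligned columns; indel handling belongs to the upstream pileup producer.

Ploidy normalization divides a gene count by assembly ploidy and rounds
half-to-even for reporting — comparing a triploid assembly's raw count with
haploid assemblies' counts without it overstates the former threefold.

## The synthetic-data generator

Every estimator above is validated against generated data with known truth:

- `simulate_genome()`: equal-length chromosomes (analytic tractability; the
  remainder goes to the last), i.i.d. interior bases at a chosen GC
  (default 0.38, typical of conifer nuclear DNA), and exact phase-aligned
  telomeric arrays — motif-oriented at the 3' end, reverse-complement at
  the 5' end, as on a real double-stranded chromosome. Arrays are
  error-free by default, matching the exact-match detector.
- `simulate_reads()`: uniform placements over both strands, i.i.d.
  substitution errors only (the downstream consumers are exact-match k-mer
  and motif logic, where indels add no test power), constant qualities, and
  read ids carrying `(chromosome, start, strand)` so placement oracles need
  no aligner.
- `expected_telomeric_reads()`: the exact telomeric probability by
  enumerating every placement (as interval unions around every concatemer
  occurrence), the oracle for Monte-Carlo counts.
- `simulate_mixture()`: three replicons at copy ratios 1 : 15 : 40
  (nuclear : mito : chloro) and ~8X nuclear short-read depth, so the
  mitochondrial depth lands at the 120X inclusion threshold by construction;
  contigs chopped from the replicons with truth labels, realized coverage,
  provenance-derived alignment tables, NUMT-like nuclear contigs with
  partial mitochondrial similarity, and a long-read set with wrapped
  alignments to the circular plastome.
- `simulate_pileup()`: constant depth, planted unanimous-error positions,
  and background noise capped at `depth - 1` mismatches so it can never
  fake unanimity.

All generators are pure functions of their seed (byte-identical reruns,
asserted in the tests), and restore the caller's RNG state.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: heterozygosity and repeat structure (the k-mer
histogram of a real conifer genome has a long repetitive tail; the
simulated one is essentially single-copy), telomere length variation among
chromosome ends and interstitial telomeric repeats, GC-biased and
position-dependent error profiles, indels, ONT-style long-read error
models, and real alignment ambiguity (mixture alignments are derived from
provenance, not recomputed by an aligner). The tests demonstrate
correctness of the estimators under their own model assumptions and exact
reproduction of the published worked examples, not robustness to every
artifact of real libraries.

## Problem sizes used in the test suite

Test fixtures are sized so the whole suite runs in a couple of minutes
while keeping every statistical check adequately powered: oracle
equivalence for k-mer counting on tens of kb of reads; genome-size recovery
on a 100-kb genome at 30X; telomere recovery on a 10-Mb genome with 500,000
reads (expected telomeric count ~1,000, binomial sd ~31, so a 20% band on
the recovered length is ~30 sd wide); mixture triage on a 570-kb mixture;
consensus accuracy on 100,000 positions. Statistical assertions use 3-sigma
bands under fixed seeds chosen up front.
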