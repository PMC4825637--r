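---
title: "Methods: the karyoprobe signal model and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the karyoprobe signal model and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`karyoprobe` models the computational half of a FISH-based karyotyping
workflow for plant genomes of the common bean type: two centromeric
satellite families that partition the centromeres between them,
chromosome-specific variants of those satellites, a subtelomeric repeat
at most chromosome termini with strongly uneven copy number, rDNA
landmarks, and single/low-copy BAC clones as per-chromosome identifiers.
This vignette records the models, the parameters that matter, and the
choices made where the design was genuinely open.

## Coordinates and sequence alphabet

Every interval in the package is 1-based and inclusive on both ends, so
`length == last - first + 1`. This is the convention under which the
bundled reference BAC table is internally consistent: each row's printed
insert length equals `last_base - first_base + 1` exactly, which the
test suite asserts for all eleven rows. Conversion to BED's 0-based
half-open convention happens only at the file boundary
(`kp_write_bed()` / `kp_read_bed()`), and is round-trip tested.

Sequences are restricted to A/C/G/T/N on input: lowercase is raised, U
becomes T, and every other symbol collapses to N. Probes and k-mer
windows containing N are skipped rather than interpreted, because a FISH
oligo cannot be synthesized against an ambiguous base and a count over
expanded ambiguity codes would silently inflate specificity
denominators.

## BAC anchoring

An end-sequence hit survives filtering when identity exceeds 99% and
query coverage exceeds 90%; both inequalities are strict, following the
"> 99%" / "> 90%" form of the published criteria, and coverage is
computed per hit as alignment length over query length (how coverage was
computed upstream is not recorded anywhere authoritative; per-hit is the
simplest defensible reading, and an HSP-summing variant would only relax
the filter). A clone is anchored by a hit pair on one chromosome with
opposite strands, the `+` hit upstream of the `-` hit, and outer span
(`max(subject_end) - min(subject_start) + 1`) inside 50–200 kb,
inclusive. Three choices here were open:

* **Inward orientation.** "Opposite directions" alone would also admit
  outward-facing pairs; a cloned insert physically requires the two end
  reads to face each other, so the plus-strand hit must lie upstream.
* **Outer span.** Whether the tabulated first/last base are the outer or
  inner coordinates of the end alignments is not stated; the outer span
  is used, consistent with reference insert lengths of 93,911–147,575 bp
  all sitting inside the 50–200 kb window.
* **One anchor per clone.** A clone with several qualifying placements
  cannot be chromosome-specific; such clones are kept in the anchor
  table but flagged `ambiguous` and excluded from candidate selection.
  On synthetic data these are precisely the clones whose end reads fall
  entirely inside a satellite array.

Candidate selection drops anchors with repeat content at or above 20%
(strict `<` retains a clone at 19.42%, matching the reference table) or
any tandem-repeat overlap, and ranks the rest by distance of the
midpoint-percent to the nearer chromosome end, `min(p, 100 - p)`.
End-proximity is a ranking preference, not a cutoff: the reference table
itself contains a clone at 57.01%, proving no hard threshold was
applied.

## Repeat screening

The masker is an internal library matcher, not a RepeatMasker clone:
exact 12-mer seeds anchor ungapped candidate alignments of each library
entry on both strands, and each aligned footprint is scanned for maximal
segments of length ≥ 30 bp with mismatch fraction ≤ 0.1. Matches never
extend beyond the entry's own footprint, so an exact planted copy masks
exactly its own coordinates. Overlapping or adjacent same-class
intervals merge. Because the matcher is ungapped and seed-based, its
output will not be bit-identical with RepeatMasker's; only the
repeat-content formula (percent of the position-set union of all
intervals) and the screening logic are treated as reproducible, never
the published per-clone content percentages.

Low-complexity and simple repeats are flagged by a DUST-like windowed
entropy mask: non-overlapping 64-bp windows (plus one window anchored at
the sequence end) are masked when Shannon entropy over A/C/G/T
composition is strictly below 1.0 bit. The strict inequality matters at
the boundary: a perfect two-letter repeat (entropy exactly 1.0) is *not*
masked by default; lowering the threshold is the knob for that. A
dedicated short-period tandem finder is deliberately out of scope — at
these window sizes the entropy mask catches the same sequence.

## Satellite variants

Monomer decomposition is greedy consensus tiling: scan left to right,
accept a monomer when the window at the current position matches the
consensus at ≥ 70% identity (substitutions only), and advance by one
monomer length on acceptance, one base otherwise. The original monomer
alignments behind the published variant discovery are not available, so
decomposition is reconstructed this way; on arrays built of exact copies
it recovers every copy at the exact offsets for all array sizes tested
(1–20 copies).

The window profile counts every N-free k-window of every monomer under
its chromosome (k = 25 by default, matching the oligo probe length,
although printed probes actually range 24–26 nt — probe length is a free
parameter everywhere). Each distinct window carries the modal 0-based
offset at which it was observed, and is compared against the
majority-rule consensus at that offset. Consensus ties break by the
fixed base order A < C < G < T; columns with more than 50% gaps are
dropped.

A window is called `specific` for a chromosome when its count there is
at least 5, its on-target fraction is at least 0.95, and it differs from
the consensus window in at least one position. Windows abundant (count ≥
5) on two or more chromosomes are `multi_target` — the situation of a
variant that hybridizes to several centromeres with different
intensities — and windows equal to the consensus are `consensus_like`
and never specific. No numeric criterion for "chromosome-specific" was
published (validation was by hybridization); 0.95/5 are declared package
defaults calibrated qualitatively so that a single-centromere variant is
accepted and a shared variant is not.

## Oligo specificity and cocktails

Genome-wide specificity of an oligo is the per-chromosome count of
binding sites on both strands within Hamming distance d (default 2, no
indels), counting overlapping sites individually, because modelled
signal intensity is proportional to binding-site count. The tolerant
default reflects the observation that short oligos detect conserved
25-mers even where full-length probes fail — hybridization does not
require a perfect match. Counting is implemented with
`Biostrings::countPattern` and checked in the test suite against an
independent naive two-strand Hamming scan. A palindromic oligo (equal to
its reverse complement) counts each site once per strand, i.e. twice, on
both routes; this is documented behaviour rather than a bug, and
irrelevant for real probes, which are never self-complementary over
24–26 nt. An accept/reject decision requires at least 5 on-target hits
and an on-target fraction of at least 0.95. No melting-temperature or GC
filter is applied by default (none was published); a GC ∈ [30, 70]%
filter can be layered on the candidate table by the caller.

Cocktail assembly enforces the fluorophore-to-channel map
(FAM/fluorescein → green, TEX615/Texas Red → red, Cy5 → blue) and warns
for same-channel probes whose target class and chromosomes overlap —
the same confound that forced the 18S rDNA probe out of the published
mixture. The bundled probe table lists the variant probe for chromosome
3 in its red (TEX615) form, the label under which it entered the final
cocktail, although it was synthesized with both labels.

## The karyotype signal model

A karyotype map stores per-probe locus assignments
(probe, chromosome, position class, intensity) and derives merged
records keyed by (chromosome, position class, channel): same-channel
co-located signals merge to the maximum intensity, because a microscope
cannot separate them. Intensity is a four-level ordinal scale (none <
weak < medium < strong); the qualitative published intensities (strong,
middle-strength/secondary, minor/weak) map directly onto it. A
chromosome's signature is its *set* of (position class, channel,
intensity) triples — channels, never probe identities, since probes
sharing a fluorophore are physically confounded. Distinguishability of a
probe subset re-merges from the assignment level (so a subset never
inherits an intensity contributed by an excluded probe) and counts
chromosomes with unique signatures; signatures are per chromosome pair,
and homolog-level differences (e.g. heterozygous centromeric copy
number) are carried as annotations only.

The bundled fixtures encode the published signal statements for seven
genotypes. Two placements are *not* stated in prose and are recorded as
assumptions inside each fixture file: the 5S rDNA locus (placed on the
short arm of chromosome 10) and the exact set of termini carrying minor
subtelomeric signals. Because the minor-termini placement decides
whether chromosomes 1, 3 and 7 are separable without the chromosome-3
variant probe and the chromosome-7 BAC, the package ships two G19833
fixtures: the reference one, in which the six-probe mixture (the four
centromeric probes plus the subtelomeric repeat and 5S rDNA)
distinguishes all 11 chromosomes, and a `g19833_fig1` variant encoding
the occasionally observed appearance in which those minor termini do not
separate 1/3/7 — under the six-probe mixture it groups exactly
{chr1, chr3, chr7}, and the full eight-probe cocktail resolves them.
Both behaviours are asserted in the tests; the wild-accession fixtures
likewise group exactly {chr1, chr4}, the pair distinguished in landraces
only by subtelomeric signal strength.

## The synthetic generator

`kp_genome_spec()` defaults are the package's study conditions and are
not tuned per experiment: 11 chromosomes of 400 kb, i.i.d. background at
38% GC (legume-like), a centromeric array of 40 copies of a 50-bp
satellite placed mid-chromosome, subtelomeric arrays of a 32-bp repeat
within the outer 5% of each end (15 copies per arm, elevated to 60 on
chr4-S and 40 on chr11-L to emulate the two dominant subtelomeric loci),
and one planted variant on chr3 carrying substitutions at monomer
offsets 20/27/34 in 30% of copies — three sites close enough that one
25-mer spans them all, so the canonical diagnostic window sits at
Hamming distance 3 from every consensus copy and survives a d = 2
genome-wide screen with zero off-target hits. Chromosome length is a
desk-scale choice (a 4.4-Mb genome generates in seconds and keeps the
whole recovery pipeline fast) and, because background k-mer collisions
at these sizes are vanishingly rare, the recovery behaviour is not
sensitive to it. BAC libraries place clones uniformly with
insert lengths in 50–200 kb and 700-bp error-free end reads by default;
an error-rate knob adds uniform substitutions for robustness tests.

What the generator does **not** emulate: transposon landscapes (a
transposon can be planted explicitly for masking tests, but there is no
background repeat structure), monomer-length variation and indel
divergence within satellite arrays, higher-order repeat structure,
sequencing-read error models, and assembly artefacts. Passing the
recovery tests therefore shows the pipeline's logic is correct under
clean, known-truth conditions — not that thresholds are optimal on real
satellite arrays, where monomer decomposition must absorb indels and
where multi-chromosome variant families are the norm rather than the
exception.

## Problem sizes and determinism

The test suite runs the oracle-equivalence properties at 100 random hit
sets for anchoring, genomes of ≤ 100 kb for hit-count scans, and 10
seeded genomes for full parameter recovery; these sizes make the whole
suite run in under a minute while leaving every property non-trivial.
All randomness flows through explicit integer seeds (`withr::with_seed`
inside the generators), and identical spec + seed reproduces
byte-identical FASTA output, which is asserted in the tests. The
acceptance script (`scripts/acceptance.R`) recomputes its reported
numbers from the installed package at run time; none are stored.

## Known limitations

* The masker is ungapped; a diverged repeat copy with indels fragments
  into multiple intervals or is missed below the 30-bp segment floor.
* Monomer decomposition assumes substitutions-only divergence from a
  single consensus; arrays with large indels or nested higher-order
  structure need a dedicated decomposer.
* Specificity counting is a binding-site count, not a thermodynamic
  model; it has no notion of duplex stability, secondary structure or
  probe accessibility.
* Karyotype fixtures encode prose-level signal statements at ordinal
  resolution; they are not measurements, and figure-only placements are
  assumptions flagged in the fixture files.
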