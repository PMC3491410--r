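---
title: "Mapping bisulfite reads in base and color space: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping bisulfite reads in base and color space: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsmapr)
```

## The problem

Bisulfite treatment converts unmethylated cytosines to uracil, read as T
after PCR, while methylated cytosines stay C. A bisulfite read therefore
differs from its genomic origin at every unmethylated C, and a mapper that
treats those differences as ordinary mismatches both loses reads and
biases the measured methylation level toward whatever methylation state
its reference model assumes. `bsmapr` maps such reads by minimizing the
number of *non-bisulfite* mismatches: a position where the strandwise
reference base is C and the read base is T is evidence of an unmethylated
cytosine, not an error, and costs nothing.

Two read chemistries are supported. Illumina base reads are handled with
the classical three-letter-alphabet strategy: both the read and the genome
are C-to-T converted before searching, and candidates are verified against
the original sequences. SOLiD color reads cannot be converted in advance
-- each color encodes a *pair* of adjacent bases, a single color error
corrupts every downstream base of a naive translation, and a bisulfite
conversion appears as two adjacent color mismatches -- so they are
searched in color space against converted-then-encoded references and only
translated to bases per candidate locus, by a dynamic program whose
bisulfite mismatches cost zero.

## Reference preparation

From a sanitized genome (every non-A/C/G/T base becomes A, and the
original ambiguous positions are remembered) the package builds:

* base space: the fully converted plus strand and the fully converted
  reverse complement. Conversion happens *after* reverse-complementing, so
  the two texts are not each other's reverse complement.
* color space: the same two texts plus their non-CpG-converted
  counterparts (C kept only when immediately followed by G, modeling
  CpG-methylated DNA), all four encoded into color digits after
  conversion. The non-CpG rule is applied to the strand being converted;
  this is the symmetric reading of an underspecified point and is pinned
  by tests.

The di-base code is the standard SOLiD table (0: AA/CC/GG/TT, 1:
AC/CA/GT/TG, 2: AG/GA/CT/TC, 3: AT/TA/CG/GC), implemented as XOR of
2-bit base codes and locked by an exhaustive decode-encode round-trip test
over every sequence up to length 6.

The search primitive is a contract, not a data structure: `find_hits()`
must return *exactly* the set of positions with Hamming distance at most
`k` (no indels, matching the mismatch-only model of the method). The
implementation is seed-and-extend over a hashed k-mer table with `k + 1`
disjoint pigeonhole seeds, cached per reference; short queries fall back
to a naive scan. A definitional sliding-window oracle in plain R
(`brute_force_hits()`) provides the independent check, and the two are
compared on a thousand randomized instances in the acceptance suite. The
optional counting cap (stop enumerating a mismatch level beyond the list
cutoff) is not implemented: at desk scale full enumeration is cheap and
the cap could only complicate the filtering semantics.

Serialized indexes store the sanitized genome and a JSON manifest only;
converted texts and seed tables are deterministic transforms rebuilt on
load. This keeps the on-disk artifact plain text and versioned without
freezing internals.

## Base-space pipeline

Per read: low-complexity filter, C-to-T conversion, four-orientation
counting, list filtering, bisulfite-aware verification, unique-hit
resolution.

**Entropy filter.** Read complexity is the Shannon entropy of the A/C/G/T
histogram normalized by log2(4) to [0, 1]; reads under 0.25 are discarded
(and reported as *filtered*, not unmapped). Normalization is a deliberate
choice: on an unnormalized log2 scale a 0.25 cutoff would discard almost
nothing, so the published threshold is only scale-meaningful in [0, 1].
For orientation: a homopolymer scores 0, a two-letter alternation 0.5.

**Counting and list filtering.** The converted read and the converted
reverse complement (reverse complement taken first) are searched on both
converted references, giving four hit lists grouped by mismatch count. A
list in which some single mismatch level holds at least 40 hits (the
default cutoff) is discarded wholesale: such a list is repetitive noise
from one strand, and its hits would otherwise render a genuinely unique
hit on the other strand ambiguous. The canonical worked example -- counts
(1, 0, 40, 40) at one level -- leaves one candidate to verify instead
of 81. The threshold is `>=` in base space and strictly `>` (default 10)
in color space, matching the published phrasings; reads whose every
nonempty list is discarded are reported as *list-filtered*.

**Verification and uniqueness.** Surviving candidates are re-compared as
original read against original genome in the orientation the hit list
implies; ref-C/read-T differences count as bisulfite, everything else as
non-bisulfite mismatches. The unique hit is the single candidate with the
strictly smallest non-bisulfite count, judged across all retained
orientations jointly (filtering first, then joint resolution, following
the published pipeline order). The mismatch budget defaults to 3 for
reads longer than 51 bp and 2 otherwise.

One subtlety surfaced during implementation: for a read whose window
contains no converted cytosine on its strand (a fully methylated read, or
a cytosine-free window), the reverse complement of the read *is* the
opposite strand of the same locus, so the forward and reverse-complement
interpretations produce two formally distinct candidates at the same
genomic position with identical mismatch counts. Since uniqueness in this
method is defined over genomic *locations*, such pairs are collapsed into
one candidate before resolution, keeping the read-as-is interpretation
(the one a directional library would produce). Without this, a simulation
at 100% methylation maps nothing at all, which contradicts the method's
published unbiasedness across the whole 0-100% range; with it, the strand
reported for these reads is the read-as-is strand, which is also the
correct one for directional data.

## Color-space pipeline

SOLiD libraries are directional: only reads from the original
bisulfite-treated strands exist, so of the four read/reference
combinations only two are valid -- the read's colors against the plus
converted text and against the reverse-complement converted text. (In
color space a read from the minus strand matches the RC-converted text
*as is*; reversing the color string is the complement-strand operation and
is searched only by the noise estimator.) The primer-transition color is
excluded from search queries; the primer anchors decoding.

Counting runs at a higher budget (default 4) than base space because one
bisulfite conversion costs two adjacent color mismatches. After color
list filtering, candidates are processed by **mismatch stage filtering**:
bucket-grouped by their color-space search mismatch count and examined in
ascending groups. Every hit in a group is decoded against the original
genome and its non-bisulfite base mismatches recounted; the first hit that
is unique at the strictly minimal recount among everything examined so
far is reported, and a resultant unique hit may carry at most three
non-bisulfite mismatches (we cap the recounted *base* mismatches; the
published phrasing is ambiguous between base and color). A read whose
best candidate exceeds the cap yields no hit from that pass. Groups after
the first unique hit are never decoded, which is both the speed and the
ambiguity-reduction argument of the method.

**Decoding.** `decode_color_read()` runs a dynamic program over the four
candidate bases per position, anchored on the primer: a transition costs 1
when the observed color disagrees with the di-base code of the adjacent
pair, an emission costs 1 unless the base matches the reference or is T
over a reference C (the zeroed bisulfite cost). Ties in total cost are
broken toward the path with fewer color violations, i.e. toward trusting
the observed colors: the practically important case is a mismatch at the
final color, which has no second flanking color to disambiguate it and
would otherwise decode arbitrarily as either a base change or a color
error. With this tie-break a final-position substitution decodes as a base
change and is charged, which is the conservative reading. The DP is
checked against exhaustive minimization over all 4^(L-1) base strings for
reads up to length 6.

**Adjacent-color mismatch counting.** Position i of the decoded read
charges 1 non-bisulfite mismatch iff both colors flanking base i disagree
with the reference colors *and* the decoded base disagrees
non-bisulfitically; bisulfite-induced adjacent color mismatches charge 0.
Indexing note: a primer plus n colors decodes to n genomic bases (the
published description is internally off by one), so the final base has a
single flanking color and is charged on that color alone. The rule is
applied literally; in a run of three or more consecutive color mismatches
(e.g. a SNP adjacent to a conversion site) a shared color can revert to
matching and the SNP then escapes the charge. This is documented behavior
of the literal rule, exercised in tests, not an implementation accident.

**Dual indexes and modes.** Reads are mapped against the fully converted
references first (budget M1); only when no unique hit is resolved --
including the ambiguous case, so ambiguous reads get a second chance --
are they mapped against the non-CpG-converted references (budget M2), and
every hit is labeled FULL or NONCPG so downstream analysis can see which
methylation model explained it. Modes: sensitive = (5, 5), default =
(4, 4), fast = (0, 3) (the hyper-methylation-biased member of the
published biased pair, chosen as the cheapest). Unique-mapping counts are
monotone across fast/default/sensitive on a fixed simulation, and this
ordering -- not any real-data percentage -- is what the acceptance suite
asserts.

**Noise estimation.** Directionality gives a built-in error meter: a
genuine read can only match the valid orientations, so a read whose
*reversed* colors find a strictly better hit is noise. The estimate is
(reads whose complement-strand search wins) / (reads uniquely resolvable
on either side). Including the invalid-side-only reads in the denominator
and numerator makes the estimator respond linearly to deliberately
injected reverse-complement reads, which is how it is validated: on clean
valid-orientation simulations the estimate is below 1%, and injecting 5%
reversed reads moves it to within a percentage point of 5%.

## Methylation calling

Every strandwise reference cytosine covered by a uniquely aligned read
tallies read-C as methylated and read-T as unmethylated; any other read
base is ignored as error/SNP. Color reads contribute their decoded base
translation. Context is CG / CHG / CHH (H = A, C or T) classified from the
original genome on the site's strand; a truncated trinucleotide at a
chromosome end is classified from the bases available (next base G gives
CG, otherwise CHH). Sites whose position or strandwise context overlaps an
originally ambiguous reference base are excluded, since those bases were
rewritten to A and would otherwise fabricate or distort contexts. The
per-context level is 100 * sum(methylated) / sum(covered), and the
zero-coverage level is NA rather than 0 -- absence of evidence is not a
level.

## The simulator as a stated world

`simulate_genome()` draws i.i.d. bases at a requested GC fraction
(default 0.4, a vertebrate-like composition). Reads are drawn uniformly
over start positions and strands; each C is retained with the methylation
probability `meth_prob` independently per read and per site, exactly the
uniform-conversion protocol of the published simulations (97% conversion
= methylation 0.03 for the SOLiD benchmarks); 0 to `max_snps`
substitutions are injected uniformly (the SOLiD protocol uses 0-2 with
equal chance); color reads are then encoded with a T primer and per-color
errors at 5% by default. Truth records coordinates (leftmost plus-strand
base), strand, conversion, SNP and color-error positions, and scoring is
exact-coordinate: an off-by-one hit is wrong.

What the generator does *not* emulate: repeat structure, CpG islands,
non-uniform coverage, quality-dependent errors, indels, or chimeras. A
green identity-line test therefore establishes unbiasedness of the
pipeline's bookkeeping -- conversion handling, strand assignment, context
classification -- on repeat-poor sequence; it does not establish mapping
performance on a real genome, which is why no real-data mapping-rate
figure is asserted anywhere in the tests.

Determinism: every stochastic function takes a seed and uses R's integer
Mersenne-Twister state; identical inputs, seed and configuration produce
byte-identical outputs, which the CLI test asserts end to end.

## Numerical and edge-case choices

* Hamming-only alignment; no indels anywhere, by fidelity to the method.
* Internal coordinates are 0-based half-open; files are 1-based (SAM
  convention). Reverse-complement-text offsets mirror as
  `pos' = chrom_length - pos - read_length`.
* Hit lists are sorted by (chromosome, position) and deduplicated;
  searches never cross chromosome boundaries.
* Quality strings are parsed and carried but unused, as in the method.
* A query longer than a chromosome returns an empty hit list, not an
  error; an empty candidate set resolves to "no hit"; a tie at the
  minimum is ambiguous, never arbitrarily broken (except the same-locus
  collapse described above, which is a merge, not a tie-break).
* `M1`/`M2` are capped at 5; list cutoffs must be positive; the entropy
  cutoff applies to the raw read before conversion.

## Known limitations

* Paired-end reads are mapped as independent ends; no insert-size rescue.
* No BAM/CRAM output; alignments are a SAM-flavoured TSV (the method
  defines no output schema, so this package's schema is its own).
* The color pipeline's recovery at intermediate methylation levels on
  short reads is intrinsically limited by the mismatch budget -- each
  retained cytosine outside the reference model costs two color
  mismatches -- which is the bias the dual-index strategy mitigates but
  does not remove.
* The noise estimator assumes a directional library; applying it to
  non-directional data would flag half the genuine reads.
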