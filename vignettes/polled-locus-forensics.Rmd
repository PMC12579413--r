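---
title: "Trio-based structural forensics of the bovine POLLED locus"
author: "polledtrio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-based structural forensics of the bovine POLLED locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polledtrio)
```

## The problem

Polledness (congenital absence of horns) in cattle is a dominant Mendelian
trait controlled by structural variants clustered on BTA1 between roughly
2.42 and 2.73 Mb — the *POLLED* locus. Two variants dominate commercial
populations: the Celtic allele `P_C`, a complex InDel in which a 10-bp
deletion (g.2,429,326–2,429,335) is replaced by a 212-bp copy of
g.2,429,109–2,429,320, and the Friesian allele `P_F`, an 80,128-bp tandem
duplication (g.2,629,116–2,709,243). The duplicated copy of the Friesian
unit differs from the original at only two positions: a T→A substitution
at its first base and a 2-bp TG deletion (`P_F2D`) at bases 38–39. Those
two sites are the only sequence handles a diagnostic test has on the
duplication.

Occasionally a horned, genotypically `p/p` calf is born to a parent that
is homozygous (or compound heterozygous) polled — an apparent
non-Mendelian event. Two recombination mechanisms can produce such a
gamete:

* **Non-allelic homologous recombination (NAHR).** The two copies of the
  Friesian unit are a near-perfect segmental duplication. A double-strand
  break repaired against the paralogous copy rather than the allelic one
  deletes one unit's worth of sequence. Because the copies differ only at
  unit offsets 1 and 38–39, *any* crossover at unit offset above 39
  reconstructs the wild-type sequence byte-exactly; only crossovers within
  the first 39 bp leave a diagnostic trace.
* **Allelic homologous recombination (AHR).** In a dam carrying `P_C` and
  `P_F` in trans, a single crossover between the Celtic InDel and the
  entry point of the duplicated copy produces one gamete carrying neither
  variant (a horned offspring) and, with equal probability, the
  complementary gamete carrying both in cis (a polled offspring that would
  be mistyped as homozygous polled).

This package reimplements the full forensic chain for such trios as
testable code: sequence-level models of the alleles and both recombination
products, an ONT-like read simulator with exact truth provenance,
split-read and read-depth scans of the offspring's alignments, trio SNP
analysis localizing crossovers as haplotype switches, an in-silico analog
of the diagnostic polled genotyping test, and a rule engine that
classifies the combined evidence into the competing structural hypotheses
(H1: deletion shorter than the unit; H2: longer; H3/H4: exactly one unit —
provably indistinguishable from each other without copy-discriminating
variants; and the Fleckvieh-trio outcomes parental / crossover-wild-type /
cis-fusion).

## Coordinate and sequence model

All public coordinates are 1-based inclusive bp on the ARS-UCD1.3 frame,
matching the HGVS-style variant notation. Where two coordinate sets for
the Friesian unit circulate (2,629,113–2,709,240 vs 2,629,116–2,709,243,
a left-alignment ambiguity of the duplication breakpoint), the package
canonically adopts the variant-notation coordinates 2,629,116–2,709,243;
the 3-bp discrepancy is noted but not resolved. The T→A site is modeled
as a substitution at copy offset 1 rather than as part of the junction.

A haplotype is an edited sequence plus a block coordinate map tying every
haplotype position to a reference position and a copy index (0 for the
original copy, ≥1 for duplicated copies; pure insertions carry their
left-flank anchor). Construction records undo information, so
`revert_haplotype()` reconstructs the reference byte-exactly — the
round-trip is asserted for every built-in allele.

`nahr_product()` models the unequal crossover in copy-alignment space: the
product keeps the copy-0 prefix up to the crossover offset and continues
at the homologous aligned position of the edited copy. The "deletion of
exactly 80,128 bp" is therefore a statement about the unit length, not a
literal removed-byte count — the edited copy is 2 bp shorter, and only
this alignment-space interpretation yields a product byte-identical to
wild type for offsets beyond the internal variants, which is the observed
behaviour the model must reproduce.

`ahr_product(A, B, bp)` is defined asymmetrically as A-up-to-and-including
`bp` joined to B-after-`bp`; the two reciprocal gametes of one crossover
are `ahr_product(A, B, bp)` and `ahr_product(B, A, bp)`. With the dam's
`P_F` haplotype as A and her `P_C` haplotype as B at the inferred
breakpoint (2,694,883 — inside the original unit span, about 14 kb before
the haplotype enters the duplicated copy), the first product is wild type
and the second is the cis fusion.

## What the generator emulates — and what it does not

`polled_reference()` draws a repeat-free pseudo-random segment
(rejection-sampled so no exact internal repeat of ≥50 bp exists) standing
in for the locus window, with the two diagnostic anchor bases (T at unit
offset 1, TG at offsets 38–39) set to match the variant nomenclature. The
segment carries 20-kb margins beyond the scanned window so that the
coverage ramp at simulated-fragment ends — an artifact of a finite
segment, absent on a whole chromosome — stays outside the analysis region.

Reads are drawn from the two haplotypes in proportion to haplotype length
(a duplication-bearing chromosome contributes proportionally more DNA),
with lognormal lengths (default N50 ≈ 9 kb; per-member presets mirror the
coverages and N50s of the two study trios) and ONT-like per-base noise
(2% mismatch, 1% insertion, 1% deletion — chosen as typical modern ONT
figures; the source data do not state error rates). Alignments are
*projected analytically* from provenance through the haplotype coordinate
map rather than produced by an external aligner: a read crossing the
tandem junction splits into two segments whose reference coordinates
rewind (the tandem-duplication signature), the 2-bp `P_F2D` deletion and
the 212-bp Celtic insertion surface as D/I CIGAR operations, and a read
on a recombinant wild-type haplotype is a single contiguous segment. This
keeps split-read truth exact and the pipeline download-free; real BAM/SAM
files remain importable through `read_alignments()`. What the simulator
deliberately does not model: basecalling artifacts, chimeric reads,
reference bias, mappability structure, or low-complexity sequence — so a
green suite shows the inference logic is correct under clean mapping
assumptions, not that the thresholds are tuned for adversarial real data.

The SNP panel emulates a 50K array at one marker per 5 kb with uniform
positions and uniform allele frequencies in [0.05, 0.95]; parental phase
is emitted as truth (population-scale HMM phasing is out of scope — the
switch analysis only needs parental het-site phase, which real users
supply as phased VCF).

## Detection and its numerical choices

**Split reads.** Segments below MAPQ 10 are excluded (the study discarded
a call supported only at MAPQ 1), segments shorter than 100 aligned bases
are treated as spurious micro-splits, and reference gaps or rewinds of at
most 50 bp are absorbed into one alignment so small indels are not called
as SVs. Breakpoint pairs cluster by single linkage with 20-bp per-axis
tolerance (ONT junction jitter; the study does not state its tolerance),
and a cluster needs two or more distinct reads — the study's stated rule.
Single-read junctions are surfaced as warnings, never as calls.

**Read depth.** Depth is computed in 200-bp windows at 100-bp steps and
normalized by a copy-neutral baseline. The baseline matters more than it
seems: the duplication unit is ~23% of the scanned window, so a plain
regional median sits on the upper flank of the copy-neutral distribution
and biases every ratio. When the analysis knows a priori where copy
number may differ between alleles (the duplication unit ± 10 kb, as the
pipeline does), the baseline is a lightly trimmed mean of the windows
outside that span — unbiased by construction; otherwise a single-pass
trimmed median around the plain median is used. Iterated or
mixture/mode-based estimators were evaluated and rejected: windowed
long-read depth is autocorrelated at the read-length scale (a 350-kb
region holds only ~45 independent blocks), which makes purely
distributional estimators unstable.

**Significance.** The same autocorrelation means a 1-kb threshold
excursion is essentially a single Poisson draw, and raw ratio thresholds
(1.4/0.6, the midpoints between diploid copy-number expectations 1.0, 1.5
and 0.5) produce frequent ≥1-kb false candidates at 20×. Candidate runs
(merged across sub-threshold gaps of ≤10 kb, since a true copy-number
segment fragments at roughly 50% duty cycle when its ratio sits near the
threshold) are therefore tested on the number of collapsed read-segment
*starts* they contain — starts are independent events, unlike per-base
depth — against the regional start rate. Because the candidate spans are
selected by scanning the depth profile itself, the standalone gate in
`call_regions()` is Bonferroni-corrected over the whole scan; an emitted
call is significant in the genome-scan sense, and wild-type simulations
emit none. That strict gate would cost the power a heterozygous 1.5× gain
needs, so the hypothesis engine applies the coupling the study itself
used ("regions … with more than one split read with consistent
breakpoints"): the span delimited by a split cluster's breakpoints is
fixed a priori, and a single uncorrected Poisson test on that span
(`span_depth_test()`) corroborates H1/H2 at full power.

**Diagnostics.** The wet-lab polled test is mapped onto read counts: the
Celtic variant is an insertion of ≥100 bp anchored at the InDel; `P_F2D`
is a deletion enclosing the 2-bp site. Zygosity of the Friesian allele
follows the study's peak-height rule — reference:variant 1:1 for
homozygous carriers, 2:1 for heterozygous (two reference copies, one
deleted copy) — decided by maximum binomial likelihood over variant
fractions {0.02, 1/3, 1/2} (the 2% floor tolerates sequencing error), with
a 10-read depth gate for zygosity calls. Classification, however, only
needs variant presence/absence, and a site deleted on one haplotype may
be covered only ~10× at 20× diploid coverage; the classifier therefore
falls back to a presence test on the raw counts (≥3 reads) when the
zygosity call is gated.

A power fact worth stating plainly: the fractions 1/3 and 1/2 are close
(the ML boundary is a variant fraction of 0.415), so at a site depth of
30–60 the two duplication genotypes are separated with only ~83–92%
per-genotype accuracy; ≥95% requires a depth near 90–120. This is a
property of the ratio rule itself, not of the implementation, and the
package's tests assert the exact binomial accuracy curve (monotone in
depth, ≥95% at 120) rather than pretending the rule is sharper than
arithmetic allows.

**Switches.** The transmitted maternal/paternal allele sequence is
matched against the parent's phased haplotypes at informative markers
(parent heterozygous, origin assignable). Runs shorter than two
informative markers are absorbed as genotyping error; each remaining
change of best-matching haplotype yields a switch whose primary output is
the bounding informative-marker interval (the midpoint is a convenience).
Scenario compatibility is judged on the interval, not the midpoint: with
5-kb marker spacing and ~1/4 of markers informative, the midpoint of a
perfectly correct interval can fall past the duplication junction.

## Classification rules

For the Holstein-Friesian-type trio (sire homozygous for the duplication,
offspring genotyped `p/p`), in precedence order: `P_F2D` present →
expected transmission; absent + tandem-duplication cluster + corroborated
gain over a span shorter than 80,128 bp → H1; absent + deletion cluster +
corroborated loss → H2; absent + no ≥2-read cluster + no significant
≥1-kb CNV → H3-or-H4 (reported as one outcome: with no validated variant
distinguishing the two copies beyond the sites at the copy's start, an
exact-unit deletion spanning both copies is indistinguishable from a
deletion of the duplicated copy alone); anything else → inconsistent.

For the Fleckvieh-type trio (dam trans `P_C`/`P_F`): exactly one variant
transmitted with no maternal switch → parental; both absent with exactly
one maternal switch whose interval overlaps the span between the Celtic
InDel and the duplication junction → crossover wild type; both present →
cis fusion (phenotypically polled; such an animal would be falsely
recorded as homozygous polled).

## Worked example

```{r, eval = FALSE}
library(polledtrio)
v <- run_polled_pipeline("FV_ahr_wildtype", seed = 31)
print(v)
```

The verdict object prints the evidence trail (cluster counts, CNV calls,
diagnostic read counts and calls, the maternal switch interval) and the
classification with its rationale. `run_polled_pipeline(..., outdir =)`
additionally writes FASTA/FASTQ/SAM, the genotype and truth TSVs, cluster
TSV, a minimal SV VCF, BED/bedGraph depth outputs, and a plain-text
report.

## Problem sizes and measurement protocol

The simulated study conditions are a 390-kb reference (350-kb analysis
window plus margins), 20× offspring coverage (per-member presets follow
the study trios), ~70 panel markers, and 20 seeded replicates per scenario
in the end-to-end recovery checks. Replicate-level quantities fluctuate
genuinely: at 20× the mean depth ratio over the 80-kb unit has a
single-replicate standard deviation of ~0.13 (long-read sampling noise,
not estimator error), so level checks on that ratio average six replicate
simulations; junction coordinates, by contrast, are exact on noiseless
reads and within the 20-bp cluster tolerance otherwise.

## Known limitations

* The projection model assumes reads map where they came from; it cannot
  exhibit mapping ambiguity, so MAPQ-based filtering is exercised with
  synthetic records rather than emergent multi-mappings.
* NAHR is modeled for a single tandem duplication in + orientation;
  inversions, inter-chromosomal events and multi-copy expansions are out
  of scope, as is estimating an NAHR rate (one observed event among
  >13,000 registered offspring does not support a rate estimate).
* H3 and H4 are reported as a single outcome by design; candidate
  copy-discriminating variants can be injected as custom internal edits,
  but the built-in alleles carry none beyond the two diagnostic sites —
  matching the validated state of knowledge.
* The zygosity rule's accuracy ceiling at ordinary site depths (above) is
  inherent to the 2:1-vs-1:1 discrimination.
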