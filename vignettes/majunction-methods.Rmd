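---
title: "Methods: junction micro-homology analysis for mutation accumulation lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction micro-homology analysis for mutation accumulation lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(majunction)
```

## The measurement problem

Mutation accumulation (MA) experiments propagate lineages through repeated
single- or few-animal bottlenecks for 40–60 generations, then sequence the
endpoints against the founder. In a homologous-recombination-deficient
background, the structural variants that accumulate are dominated by the
products of theta-mediated end joining (TMEJ): small deletions with
micro-homology at the junction, junction insertions copied from sequence
near the break, and kilobase-scale tandem duplications. Three quantitative
questions drive the analysis implemented here:

1. Which raw caller records are *bona fide* unique germline events?
2. How much micro-homology does each junction carry, and is an inserted
   sequence templated from the junction neighbourhood?
3. At what per-generation rate does each event class accrue per genotype,
   and how does the observed junction homology compare with what random
   breakage would produce?

## Micro-homology as placement ambiguity

A deletion or tandem duplication whose junction carries shared sequence can
be reported at several equivalent coordinates: `[s, e)` and `[s − 1, e − 1)`
describe the same mutated molecule exactly when the genome base at `s − 1`
equals that at `e − 1`. We therefore *define* junction micro-homology as the
placement-ambiguity length:

* `hom_right` — longest common prefix of the suffixes starting at `s` and
  at `e`;
* `hom_left` — longest common suffix of the prefixes ending at `s` and at
  `e`;
* `hom_total = hom_left + hom_right`.

An event has exactly `hom_total + 1` equivalent placements, which makes the
score invariant to caller representation, reduces to the intuitive
"nucleotides that map to either junction", and is testable against a brute
force that enumerates placements by string reconstruction (the test suite
does this for thousands of fuzzed events on genomes up to 200 bp). The sum
(not the maximum) of the two sides is used because only the sum equals the
enumeration count. Tandem-duplication junctions satisfy the identical shift
condition and are scored by the same formula.

Scans are capped at `max_scan = 200` bases per side — far beyond any
junction homology plausibly produced by TMEJ (the largest we ever expect to
report is on the order of 10–15 bp) — and at contig boundaries. If a
compared base is `N`, the scan stops and the junction is flagged
`evaluable = FALSE` rather than letting `N` count as a match; IUPAC
ambiguity codes are collapsed to `N` on input for the same reason.
Coordinates are 0-based half-open internally; every file interface (event
TSV, VCF) is 1-based inclusive and converted at the boundary, which keeps
the junction arithmetic free of off-by-one cases.

## Templated insertions

An insertion at a deletion junction is classified `TEMPLATED` when the
inserted sequence occurs *exactly*, in forward or reverse-complement
orientation, within the reference slice `[start − window, end + window)`
(the window defaults to 25 bp and the slice includes the deleted or
duplicated body). Exact matching is deliberate: snap-back synthesis by
polymerase theta copies its template faithfully, and allowing mismatches
would inflate the templated fraction on short insertions. Insertions
shorter than `min_template_len = 5` are reported `TOO_SHORT` — below that
length a match carries too little information to distinguish templating
from chance (a 4-mer occurs by chance in a ±25 bp window more often than
not). When several template matches exist, the reported hit is the one
nearest a breakpoint, with forward orientation preferred and then the
leftmost — a deterministic tie-break that favours the mechanistically
plausible (junction-proximal) origin.

Both one-sided lengths and the total are always reported (`hom_left`,
`hom_right`, `hom_total`), so summaries that quantify homology one-sidedly
and those that quantify the total can both be produced from the same
annotation table.

## Call consolidation and filtering

The filter implements the standard MA acceptance rules with the boundary
semantics exactly as printed in the field's methods sections:

| rule | threshold | reason code |
|---|---|---|
| SNV zygosity | homozygous call | `NOT_HOM` |
| SNV genotype quality | GQ ≥ 40 | `LOW_GQ` |
| SNV depth | DP ≥ 8 | `LOW_DP` |
| SV orientation | ≥ 1 forward and ≥ 1 reverse read | `ONE_ORIENTATION` |
| SV support | forward + reverse ≥ 5 | `LOW_SUPPORT` |
| SV reference reads | ref-supporting < 100 (strict) | `HIGH_REF_SUPPORT` |
| cross-sample uniqueness | event in exactly one line | `NOT_UNIQUE` |
| founder subtraction | absent from generation-0 calls | `GENERATION0` |

Design choices in the grey areas:

* *"Supported by at least five reads"* is read as total support ≥ 5 with
  the both-orientations requirement stated separately, matching the
  two-clause sentence structure of the rule.
* *Multi-caller combination* is union-then-merge: a call from any caller
  enters the pool, records of the same line/kind whose left-normalized
  coordinates agree within `tolerance_bp = 10` merge, merged evidence takes
  the per-field maximum of supporting counts (a caller that saw more
  support saw the same event better) and the minimum of reference support.
  Union is the permissive reading appropriate upstream of manual curation,
  and the tolerance is configurable.
* *Homozygosity is enforced for SNVs only*; SV zygosity is implicitly
  handled by the reference-read ceiling.
* *Uniqueness* matches on normalized coordinates within the same
  tolerance, plus identity of the alternate allele (SNVs) or inserted
  sequence (deletion–insertions); rejection applies to *all* carriers of a
  shared event. Founder matching is restricted to the same genotype
  lineage when genotype labels are available on both sides.
* A record failing several rules is reported with the *first* failing
  reason in the table's order, making reject reasons deterministic.

## The random-deletion null

The null model draws deletions with the contig chosen proportional to
length, start uniform, and sizes uniform on 5–50 bp by default
(configurable; the micro-homology fraction is insensitive to the size
distribution, which the suite verifies). `min_size = 2` avoids the mild
dependence between the left and right junction comparisons that size-1
deletions introduce. Events whose body contains `N` are resampled.

For an i.i.d. genome with base frequencies `f`, two fixed positions match
with probability `p = Σ f_b²`, so a random junction has
`P(hom_total ≥ 1) = 1 − (1 − p)²` (the left and right comparisons involve
disjoint position pairs). This closed form is a *validation oracle* for the
Monte-Carlo machinery — uniform composition gives exactly 0.4375, and an
AT-rich worm-like composition (A = T = 0.323, C = G = 0.177; GC ≈ 0.354)
gives ≈ 0.469, consistent with the ≈ 47% random baseline quoted for
real AT-rich genomes. On a real (non-i.i.d.) genome the simulated value,
not the analytic one, is authoritative; the package always reports both.

## Rates, comparisons, spectrum

Rates are defined per line as events ÷ propagated generations, one value
per event class, with `DELETION_ALL` (deletions plus deletion–insertions)
tallied alongside the elementary classes because published rate panels
group the two either way. Genotype comparisons are two-tailed t-tests on
the per-line rates — each MA line is one biological replicate, so SEM uses
the number of lines. Welch (unequal variance) is the default, the pooled
test is available for sensitivity; with zero variance in both groups the
statistic is defined by continuity (`t = 0, p = 1` for equal means). No
multiple-testing correction is applied, matching per-comparison reporting
conventions. Substitutions collapse onto the six pyrimidine-referenced
classes (`G>A` → `C>T`, etc.).

Consistency across sibling lines is screened with a Poisson dispersion
statistic: expected counts proportional to each line's generations at the
pooled rate, `Σ (obs − exp)² / exp` against chi-square with `n − 1` degrees
of freedom. Simulated data shows this calibrates near the nominal α for
per-line expectations of ~20 events; it is a screen, not a formal test, at
small counts.

## What the simulator emulates — and what it does not

`simulate_ma_lines()` generates, per line, per-class event counts from
`Poisson(rate × generations)` — treating each generation's germline input
as independent, which matches the per-generation rate definition; the
within-experiment transfer scheme is not modelled beyond the generation
count. Default rate presets ("wild-type-like": one deletion per 30
generations and essentially no TDs; "brc-1-like": a deletion every 3–4
generations with ~30% carrying insertions and TDs at a tenth of the
deletion rate; "brc-1 polq-1-like": structural variation mostly lost) are
scaled from the magnitudes reported for the corresponding nematode
genotypes. They are test fixtures, not biological claims; SNV rates, which
the structural-variant analysis does not depend on, are set to plausible
modest values.

Junction construction is exact: `plant_deletion_with_homology()` copies
`h_right` bases of the event's head beyond its end and `h_left` bases of
its tail before its start, then forces the next base on each side to
mismatch, so the planted `hom_total` is recovered *exactly* — no
"approximately h" assertions are needed anywhere in the suite. Insertions
are copied from within ±25 bp of the junction (either orientation) with
probability `templated_prob = 0.73` (the magnitude of the observed
templated fraction, 24/33); non-templated insertions are rejection-sampled
until genuinely absent from their window in both orientations, so
classification labels are deterministic on simulator output. Noise records
violating exactly one filter rule each, events shared between two lines,
and a founder call set exercise every reason code.

Deliberate simplifications: events are planted non-overlapping with a
300 bp exclusive margin (real MA data is far too sparse for overlap to
matter at ~0.3 events/generation on a 100 Mb genome); evidence is
summarized at the call-record level (no read-level simulation, no FASTQ);
the genome is i.i.d. (no repeats, no local composition structure). Passing
tests on simulator output therefore demonstrate correctness of the
*computation*, not robustness to repeat-rich regions or alignment
artefacts — on real data those are handled upstream by the callers and by
curation.

Default problem sizes are chosen so the whole suite runs in about a
minute: unit tests simulate 2–6 lines on 0.1–1 Mb genomes (scaled-down
stand-ins for the 100 Mb nematode genome), with tandem-duplication sizes
scaled to 0.5–2 kb on the smallest genomes so that non-overlapping
placement has room; the acceptance-scale checks use a 1 Mb genome with the
default 1–20 kb TD sizes, and the null-model reference computation uses
10,000 deletions on a 10 Mb genome, where the Monte-Carlo standard error
of the homology fraction is ±0.5 percentage points.

## Degenerate inputs and numerical corners

Empty call sets flow through every stage and produce schema-valid empty
outputs. A homology fraction over zero evaluable events is reported as
missing, never as 0. Events at contig edges have their scans truncated by
the boundary (and their planting rejected by the simulator). Left
normalization never crosses an `N`. All stochastic stages take explicit
seeds; a pipeline re-run with identical inputs and seed is byte-identical.

## Limitations

* The analytic null assumes independent bases; it deliberately excludes
  dinucleotide/repeat structure (no Markov genome models).
* Templated-insertion search is exact-match only; a single sequencing
  error in an inserted tract will demote a templated insertion to
  `NON_TEMPLATED`.
* The dispersion screen uses the chi-square approximation, which is
  anticonservative for expected counts below ~5 per line.
* Read alignment and primary variant calling are out of scope: the package
  consumes caller output (VCF or tabular records) and cannot rescue calls
  the upstream callers missed.
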