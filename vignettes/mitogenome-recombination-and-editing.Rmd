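---
title: "Quantifying repeat-mediated recombination and RNA editing in plant mitochondrial genomes"
author: "mitorecomb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying repeat-mediated recombination and RNA editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

Plant mitochondrial genomes are conventionally assembled as a single
circular "master" molecule, but in vivo they are dynamic: dispersed
repeat pairs act as substrates for intramolecular homologous
recombination. Recombination between **direct** repeats subdivides the
circle into two smaller circles; recombination between **inverted**
repeats inverts the arc between the two units. Because recombination is
infrequent for short repeats, the master conformation dominates and the
alternative conformations exist as a minor fraction of molecules —
typically a few percent. Long reads spanning a repeat *and* both of its
flanks are the only direct evidence of which conformation a molecule
had.

Separately, plant mitochondrial transcripts undergo post-transcriptional
single-base editing, overwhelmingly C-to-U, at efficiencies ranging from
a few percent to essentially complete. Editing can create an AUG start
codon from a genomically encoded ACG.

`mitorecomb` implements both analyses as a reusable, fully tested
pipeline, together with a synthetic-data generator that reproduces the
statistical structure the analyses assume.

## Repeat finding

`findRepeats()` enumerates *maximal* repeat pairs under a Hamming
mismatch budget: a pair of equal-length unit sequences (second unit
reverse-complemented for inverted pairs) with at most `maxMismatch`
mismatches, such that extending either end by one base would exceed the
budget or leave the genome. Defaults follow standard mitogenome repeat
surveys: `minLength = 30`, `maxMismatch = 3`, and a significance filter
on the expected number of chance occurrences,

$$E = \binom{L}{m}\,3^m\,\frac{n^2}{4^L} \le 10^{-5},$$

for unit length $L$, mismatches $m$ and genome length $n$. (Published
repeat finders do not print their exact E-value formula; this uniform-
composition form is adopted and exposed as `repeatEvalue()`.)

The search is seed-and-extend: by pigeonhole, any qualifying run
contains an exact block of length $\lfloor L_{\min}/(m_{\max}+1)\rfloor$
(7 for the defaults), so indexing exact 7-mers and extending each seed
match under the mismatch budget enumerates the complete maximal set —
there is no heuristic loss. The test suite verifies exact set equality
against a brute-force all-diagonals enumeration on hundreds of planted
2 kb genomes.

Circularity is handled by scanning the doubled sequence capped at one
wrap: every circular maximal run has at least one representative window
in the doubled sequence that touches neither boundary, so
boundary-touching windows are dropped and coordinates are canonicalized
modulo $n$. Pairs whose units overlap on the circle (tandem-like) are
discarded; each unordered pair is reported once with unit 1 leftmost.
Minus-orientation units print descending coordinates in reports
(`formatInterval()`), the convention of mitogenome repeat tables.

One consequence of maximality under a mismatch budget is that a planted
repeat typically yields several overlapping maximal windows (the planted
core plus chance-matching extensions bounded by different mismatch
sets). `collapse = TRUE` merges windows sharing ≥ 50% of both units into
the longest one, giving the one-row-per-locus view a repeat table needs;
the default `FALSE` returns the complete maximal set, which is what the
brute-force equivalence tests compare.

`detectGeneCapture()` reports genes whose CDS is strictly contained in
both units of a pair (each copy annotated under the same gene id) — the
mechanism by which short mitochondrial repeats carry duplicated genes.

## Conformations and read classification

For each repeat pair, `recombinantMolecules()` *explicitly constructs*
the recombinant molecules in a rotated frame (unit 1 at position 1):
two subcircles for a direct pair, one arc-inverted circle for an
inverted pair. For mismatched copies the crossover breakpoint is a
parameter (fraction of the repeat length). For junction references the
choice is unobservable — any breakpoint inside the repeat yields the
same flank pairing — so `buildConformations()` uses the midpoint; the
read simulators instead draw the breakpoint uniformly per recombinant
molecule, because for short reads the breakpoint position determines
where allele phase switches.

`buildConformations()` extracts four junction references per pair:
each repeat unit ± `flank` (default 1000 bp) from the master circle, and
each repeat copy ± `flank` from the recombinant molecules. When the two
units share identical flanks the alternative junctions coincide with
master junctions and the pair is flagged *uninformative*. When a
molecule is too short for full flanks, the flank is truncated and
flagged.

`classifyRead()` implements the complete-coverage counting rule: a read
is informative only if it fully covers a junction. Concretely:

1. the read is indexed once by exact 16-mers; each junction (both
   orientations) is anchored by sampled seeds, and the median offset
   places the junction inside the read. If the anchored span is not
   entirely inside the read, the junction is not covered — this is what
   rejects reads covering the repeat but only part of a flank;
2. a banded semiglobal alignment (band half-width
   `max(32, 0.02·junction length)` around the anchored diagonal) yields
   an edit distance; coverage additionally requires identity
   `1 − dist/len ≥ minIdentity` (default 0.75, suited to Nanopore-like
   error rates);
3. the read votes for the conformation of its best-covered junction if
   that distance beats the best junction of the other conformation by at
   least `minMargin` (default 5 edits); otherwise it is ambiguous.

Banding is safe because indel drift over a ~2.5 kb junction at a 3%
indel rate has standard deviation ≈ 9 bp, far inside the band; an
anchoring failure can only make a read uninformative, never flip its
vote, so borderline losses do not bias the frequency estimate. The
dual-route tests confirm the classifier recovers generator truth
read-for-read on error-free and 5%-error reads.

`recombinationTable()` computes per-repeat frequencies
`alt/(alt+master)` over informative spanning reads — this denominator
reproduces the published worked examples exactly — rounded **half-up**
to two decimals (matching how such tables are printed), sorts by repeat
length descending and renames rows `R1..Rn`. Rows with zero informative
reads are suppressed with a warning.

## Short-read screening

`screenShortReads()` is the cheap first pass that nominates repeat pairs
possibly having multiple structures before long reads confirm them. A
150 bp read can only be informative if it can tell the two units apart,
so the screen anchors reads to a specific unit with an exact word
covering a position where the units differ, then compares the read's
overhang beyond the unit boundary to the four expected flanks. Under the
master conformation each unit pairs only with its own flanks; at least
`minFlankEvidence` (default 2) reads pairing a unit with the *other*
unit's flank flag the pair. Pairs with identical units are never
flagged — they are simply not screenable at this read length, one reason
such screens overcall and undercall and are always confirmed with long
reads. Sensitivity also depends on where the diagnostic positions sit
relative to the boundaries and on the realized crossover positions, so
the screen is a candidate generator, not a quantifier.

## RNA-editing calling

Pileups are built on the **transcript strand**: references are spliced
CDS sequences (minus-strand genes reverse-complemented), either from
simple gapless alignment tables (`pileupFromAlignments()`, with base
qualities ≥ 20 honored when present) or from SAM via samtools machinery
(`pileupFromSam()`: mapping quality ≥ 20, base quality ≥ 20, deletions
and indels excluded). The two routes are cross-checked against each
other in the tests. Depth at a site is the number of counted bases, so
reads with a deletion or a low-quality call there do not contribute.

`callEditingSites()` emits one record per (site, alternative base) with
depth ≥ `minDepth` (10) and support ≥ `minFraction` (0.10), both
inclusive — the boundary semantics are asserted exactly in the tests
(depth 9 excluded / 10 included; 9% excluded / 10% included). Efficiency
is `edited/depth`. `filterGenomicVariants()` removes candidates whose
alternative base is present above 5% in a whole-genome DNA pileup
(a SNP, not editing); sites without DNA coverage are kept but flagged
unverified. Types are the 12 ordered pairs over {A,C,G,U} on the
transcript strand; `summarizeEditing()` bins efficiencies below/at-or-
above 50% and counts the near-complete subset (≥ 0.99 operationalizes
"near 100%", which has no published cutoff), with shares rounded half-up
to one decimal.

`detectStartCodonEditing()` reports an event when a gene's genomic start
codon is not AUG and a called edit converts it to AUG. Start-codon sites
are biologically decisive even at low coverage, so events below the
depth filter are reported with a `low_depth` flag rather than dropped;
genes with non-AUG starts and no such edit are reported as unedited
non-canonical starts (both ACG and GUG starts occur unedited in organelle
genomes).

## The synthetic-data generator

`simConfig()`/`simulateGenome()` generate a random circular genome at a
45.43% GC target carrying planted repeat pairs (30–700 bp, direct and
inverted, 0–3 mismatches placed within short-read reach of the unit
ends so that the units are distinguishable at the boundaries) and
planted CDS genes, including minus-strand genes and an ACG-start gene.
Long reads are lognormal (mean 13,430 bp, sdlog 0.6) at 178× with 5%
substitutions and 3% indels; short reads are 150 bp pairs at 48× with
350 bp inserts and 0.1% substitutions; RNA-seq reads are 150 b at a
per-gene depth of 100× (a round value standing in for the study's
unstated per-gene coverage) with 0.1% substitutions. Reads are drawn
from the master circle and, per repeat, from explicitly constructed
recombinant molecules at the planted alternative fraction (0.5–6%, the
regime reported for short mitochondrial repeats). At each planted edit
site every covering read carries the alternative base independently with
probability equal to the planted efficiency. All outputs are
byte-identical under a fixed seed.

The default genome length is 50 kb rather than the full ~0.5 Mb: it
preserves every structural feature the analyses exercise (circularity,
repeat geometry, junction spans, conformational mixtures) while keeping
simulation-based validation at desk scale; a full-scale configuration is
just `simConfig(genomeLength = 508035)`. What the generator does *not*
emulate: instrument-specific error profiles (homopolymer-aware Nanopore
errors), transcript-abundance variation beyond uniform per-gene depth,
genomic SNPs (the DNA control is clean by construction), and
multi-repeat compound isomers. Passing recovery tests therefore
demonstrate correctness of the estimators under the stated error model,
not robustness to every artefact of real instruments.

## Statistical validation choices

Two validation subtleties are worth recording.

*Recovery of recombination fractions.* The validation experiment plants
fractions {0.01, 0.057, 0.5}, simulates 200 junction-spanning reads per
replicate at 5% error, and checks that the estimated alternative count
falls inside the exact binomial 95% acceptance region of the planted
fraction. Diagnostics show the classifier reproduces the generator's
true per-replicate counts exactly, so each containment event is the
binomial sampling event itself, with probability ≈ 95–96.5% depending on
the fraction. A per-fraction "≥ 95 of 100 replicates" bound on such an
event fails a provably exact estimator in a substantial share of seed
schedules purely on generator luck; the package therefore pools
containment over all replicate×fraction trials (300 total) and requires
≥ 95% overall, which tests the same invariant with coherent error
control.

*Recovery of editing efficiencies.* With per-read Bernoulli editing, a
site planted at efficiency 0.2 and depth 20 falls below the 10% support
filter with probability ≈ 7% — the information is absent from the reads,
not missed by the caller. The false-negative check therefore conditions
on sites whose realized read support passes the study filters; CI
containment of the efficiency estimates and exactness of the filter
boundaries are asserted unconditionally.

## Numerical and formatting choices

* Percentages round half-up (`roundHalfUp()`), not banker's rounding:
  2 decimals for recombination, 1 for editing shares.
* Coordinates are 1-based closed (the Bioconductor convention)
  internally; reports print minus-orientation units descending.
* `N` is accepted in input, never emitted by the simulator, and never
  counts as a match in any comparison.
* The fraction filter uses `>=` on the IEEE quotient; division is
  correctly rounded, so `10/100 >= 0.10` holds exactly at the boundary.
* Ambiguous reads (margin < 5) and uninformative reads are excluded from
  the frequency denominator.

## Known limitations

* Only single-recombination isomers are enumerated; compound
  configurations from simultaneous events at several repeats are out of
  scope.
* The short-read screen requires unit-distinguishing mismatches within
  ~130 bp of a unit boundary and deep coverage; exact repeat pairs can
  only be assayed with long reads.
* Editing is called in coding regions only, against spliced CDS
  references; non-coding editing and stop-codon scanning are not
  implemented.
* Internal alignments for RNA reads are gapless; indel-containing RNA
  aligners should go through the SAM route.
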