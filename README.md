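# mitorecomb

Plant mitochondrial genomes are large, repeat-rich circles whose dispersed
repeats mediate low-frequency homologous recombination, so that a single
"master circle" coexists with inverted and subdivided alternative
conformations; their transcripts are further reshaped by C-to-U RNA
editing, occasionally creating start codons. `mitorecomb` is an R package
for quantifying both phenomena from sequencing data, built around the
plum (*Prunus salicina*) mitogenome analysis workflow:

* **Repeat finding** — maximal direct (forward) and inverted (palindromic)
  repeat pairs on a circular genome under a Hamming-distance budget
  (defaults: length ≥ 30 bp, ≤ 3 mismatches), with a REPuter-style
  significance filter `E = C(L,m)·3^m·n²·4^(−L) ≤ 10⁻⁵` and detection of
  protein-coding genes captured inside both repeat units.
* **Recombination quantification** — for each repeat pair, master and
  alternative junction references (repeat ± 1000 bp flanks; alternative
  junctions read off explicitly constructed recombinant molecules:
  subdivision into two circles for direct repeats, arc inversion for
  inverted repeats). Long reads that *completely* cover a junction vote
  for a conformation by banded semiglobal alignment, and the
  recombination frequency of repeat *i* is
  `alt_i / (alt_i + master_i)`, reported as percentages rounded half-up
  to two decimals. Short reads give a first-pass multiple-structure
  screen at repeat boundaries.
* **RNA-editing characterization** — transcript-strand pileups over
  spliced CDS references, SNP exclusion against a DNA control, editing
  sites called at depth ≥ 10 with ≥ 10% read support (both inclusive),
  classification into the 12 ordered substitution types, efficiency
  binning, and start-codon creation events (e.g. ACG→AUG).
* **Synthetic data** — a seeded generator for circular genomes with
  planted repeat pairs, conformational long/short-read mixtures at known
  alternative fractions, and RNA-seq reads with planted per-site editing
  efficiencies, so every stage is testable against known truth.

The audience is organelle-genomics researchers who have a circular
mitogenome assembly plus long-read, short-read and RNA-seq data and want
reproducible recombination-frequency tables and editing-site catalogues.

## Worked example

Simulate a 30 kb circular mitogenome with a 511 bp inverted repeat pair
recombining at 5.7% and a 294 bp direct pair at 1.8%, plus a minus-strand
`nad1`-like gene whose ACG start codon is edited, and run the whole
pipeline:

```r
library(mitorecomb)

cfg <- simConfig(seed = 11, genomeLength = 30000,
  plantedRepeats = data.frame(length = c(511L, 294L),
                              orientation = c("inverted", "direct"),
                              mismatches = c(2L, 1L),
                              alt_fraction = c(0.057, 0.018)),
  plantedGenes = data.frame(gene_id = c("nad1", "cox3"),
                            length = c(978L, 798L), strand = c("-", "+"),
                            start_codon = c("ACG", "ATG"),
                            in_repeat = c(NA, NA)),
  plantedEdits = data.frame(gene_id = c("nad1", "cox3"),
                            cds_pos = c(2L, 77L), ref_base = "C",
                            alt_base = "T", efficiency = c(0.6667, 0.95)))
b <- runPipeline(cfg, flank = 1000)

b$recombination[, c("repeat_id", "length", "orientation",
                    "master_count", "alt_count", "master_pct", "alt_pct")]
#>   repeat_id length orientation master_count alt_count master_pct alt_pct
#> 1        R1    514    inverted          144         8      94.74    5.26
#> 2        R2    299      direct          173         1      99.43    0.57

b$start_codon[, c("gene_id", "status", "genomic_codon", "efficiency")]
#>   gene_id       status genomic_codon efficiency
#> 1    nad1 edited_start           ACG  0.6728972
#> 2    cox3    canonical           AUG         NA
```

Reading the output: of the long reads that completely covered the 511 bp
repeat's junctions (repeat plus 1000 bp flanks), 144 supported the master
circle and 8 the inverted alternative conformation, an estimated
recombination frequency of 5.26% against the planted 5.7%; the 294 bp
direct repeat recombined at 0.57% (planted 1.8%, one read — small-count
noise at this depth). The `nad1` start codon is genomically ACG and was
edited to AUG in ~67% of transcript reads. `renderReports(b, "out/")`
writes the corresponding TSV tables.

On published read counts the same table arithmetic reproduces the printed
percentages, e.g. 182 master / 11 alternative reads → 94.30% / 5.70%:

```r
recombinationTable(data.frame(repeat_id = "a", length = 511L,
                              orientation = "inverted",
                              master_count = 182L, alt_count = 11L))
#>   repeat_id length orientation master_count alt_count master_pct alt_pct
#> 1        R1    511    inverted          182        11       94.3     5.7
```

and `compareGenomes(rosaceaeMitogenomes(), reference = "Prunus salicina")`
shows the plum mitogenome to be 63,453 bp larger than sweet cherry's.

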