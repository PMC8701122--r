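#' Published Rosaceae mitogenome summaries
#'
#' Sizes and GC content of the ten complete Rosaceae mitochondrial
#' genomes available in GenBank at the time of the plum assembly,
#' including the 508,035 bp *Prunus salicina* molecule.  Used as input to
#' [compareGenomes()].
#'
#' @return data.frame: `species`, `accession`, `genome_size_bp`,
#'   `gc_pct`.
#' @export
rosaceaeMitogenomes <- function() {
  data.frame(
    species = c("Rosa chinensis", "Fragaria orientalis",
                "Malus domestica", "Malus hupehensis var. mengshanensis",
                "Eriobotrya japonica", "Pyrus betulifolia",
                "Sorbus aucuparia", "Sorbus torminalis", "Prunus avium",
                "Prunus salicina"),
    accession = c("CM009589.1", "NC_057524.1", "NC_018554.1",
                  "KR534606.1", "NC_045228.1", "NC_054332.1",
                  "NC_052880.1", "NC_052879.1", "MT975322.1",
                  "OK563724.1"),
    genome_size_bp = c(313448L, 275143L, 396947L, 422555L, 434980L,
                       469928L, 384977L, 386758L, 444582L, 508035L),
    gc_pct = c(45.48, 45.24, 45.39, 45.21, 45.42, 45.28, 45.39, 45.31,
               45.62, 45.43),
    stringsAsFactors = FALSE)
}

#' Compare genome summaries against a reference species
#'
#' Pairwise size differences and GC deltas of each genome versus a
#' designated reference.
#'
#' @param summaries data.frame with columns `species`, `genome_size_bp`
#'   and optionally `gc_pct`.
#' @param reference Reference species (default: first row).
#' @return data.frame with one row per non-reference species:
#'   `species`, `size_diff_bp` (reference minus species), `gc_delta_pct`.
#' @export
compareGenomes <- function(summaries, reference = summaries$species[1]) {
  if (nrow(summaries) < 2L) stop("need at least two genome summaries")
  if (anyDuplicated(summaries$species))
    stop("duplicate species names")
  if (!reference %in% summaries$species)
    stop("reference species not in summaries")
  ref <- summaries[summaries$species == reference, ]
  oth <- summaries[summaries$species != reference, , drop = FALSE]
  data.frame(
    species = oth$species,
    reference = reference,
    size_diff_bp = ref$genome_size_bp - oth$genome_size_bp,
    gc_delta_pct = if (!is.null(summaries$gc_pct))
      roundHalfUp(ref$gc_pct - oth$gc_pct, 2L) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Run the full synthetic-data analysis pipeline
#'
#' End to end at desk scale: simulate a genome (or accept one), find
#' repeats, screen short reads for multiple structures, build
#' conformation pairs, classify spanning long reads, tabulate
#' recombination frequencies and isomer configurations; then simulate
#' RNA-seq, build pileups, filter genomic variants against a DNA
#' control, call editing sites, detect start-codon editing, and
#' summarize.  All stages are driven by the configuration seed, so
#' reruns with the same configuration reproduce the bundle exactly.
#'
#' @param config A [simConfig()] object.
#' @param flank Junction flank in bp (default 1000).
#' @param minIdentity,minMargin Read-classification thresholds.
#' @param minDepth,minFraction Editing-caller thresholds.
#' @param verbose Print stage progress.
#' @return A bundle list with elements `sim`, `repeats`,
#'   `screen_flagged`, `conformations`, `recombination`, `isomers`,
#'   `editing_sites`, `start_codon`, `editing_summary`, `parameters`,
#'   `log`.
#' @export
runPipeline <- function(config = simConfig(), flank = 1000L,
                        minIdentity = 0.75, minMargin = 5L,
                        minDepth = 10L, minFraction = 0.10,
                        verbose = FALSE) {
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    if (verbose) message(msg)
  }
  say("seed=%d genome=%d bp", config$seed, config$genomeLength)
  sim <- simulateGenome(config)

  say("stage: find-repeats (min_len=30, max_mismatch=3)")
  reps <- findRepeats(sim$genome, collapse = TRUE)
  say("repeats found: %d", nrow(reps))

  say("stage: short-read screen")
  sr <- simulateShortReads(sim)
  flagged <- screenShortReads(sim$genome, reps,
                              c(sr$seq1, sr$seq2))
  say("flagged by short reads: %s",
      if (length(flagged)) paste(flagged, collapse = ",") else "none")

  say("stage: conformations + long-read classification (flank=%d)",
      flank)
  lr <- simulateLongReads(sim)
  counts <- list()
  cps <- list()
  for (i in seq_len(nrow(reps))) {
    rp <- reps[i, ]
    cp <- buildConformations(sim$genome, rp, flank = flank)
    cps[[rp$repeat_id]] <- cp
    if (!isInformative(cp)) {
      say("%s: uninformative conformation pair, skipped", rp$repeat_id)
      next
    }
    cc <- countSpanningReads(lr$seq, cp, minIdentity = minIdentity,
                             minMargin = minMargin)
    say("%s: master=%d alt=%d ambiguous=%d uninformative=%d",
        rp$repeat_id, cc["master"], cc["alternative"], cc["ambiguous"],
        cc["uninformative"])
    counts[[rp$repeat_id]] <- data.frame(
      repeat_id = rp$repeat_id, length = rp$length,
      orientation = rp$orientation,
      start1 = rp$start1, end1 = rp$end1,
      start2 = rp$start2, end2 = rp$end2, strand2 = rp$strand2,
      master_count = cc[["master"]], alt_count = cc[["alternative"]])
  }
  recomb <- if (length(counts)) {
    tab <- do.call(rbind, counts)
    tab <- tab[tab$master_count + tab$alt_count > 0, , drop = FALSE]
    if (nrow(tab)) recombinationTable(tab) else NULL
  } else NULL

  isomers <- enumerateIsomers(sim$genome, reps)

  say("stage: RNA editing (min_depth=%d, min_fraction=%.2f)", minDepth,
      minFraction)
  rna <- simulateRnaSeqReads(sim)
  pu <- pileupFromAlignments(rna$alignments, rna$cds)
  sites <- callEditingSites(pu, genes = sim$genes, cdsSeqs = rna$cds,
                            minDepth = minDepth,
                            minFraction = minFraction)
  dna <- dnaControlPileup(rna$cds, depth = config$shortReadDepth)
  sites <- filterGenomicVariants(sites, dna)
  say("editing sites called: %d", nrow(sites))
  # start-codon scan needs candidate edits below the depth filter too
  lowSites <- callEditingSites(pu, cdsSeqs = rna$cds, minDepth = 1L,
                               minFraction = minFraction)
  sc <- do.call(rbind, lapply(names(rna$cds), function(g)
    detectStartCodonEditing(g, rna$cds[[g]], lowSites,
                            minDepth = minDepth)))
  summ <- summarizeEditing(sites)

  list(sim = sim, repeats = reps, screen_flagged = flagged,
       conformations = cps, recombination = recomb, isomers = isomers,
       editing_sites = sites, start_codon = sc, editing_summary = summ,
       parameters = list(flank = flank, minIdentity = minIdentity,
                         minMargin = minMargin, minDepth = minDepth,
                         minFraction = minFraction, seed = config$seed),
       log = log)
}

#' Error-free whole-genome DNA control pileup over CDS references
#'
#' Stands in for the WGS screen that confirms candidate editing sites are
#' not genomic SNPs: the synthetic genome has no natural variation, so
#' its DNA pileup supports the reference base only.
#'
#' @param cds Named character vector of CDS references.
#' @param depth Uniform DNA depth (default 48).
#' @return Pileup data.frame (layout of [pileupFromAlignments()]).
#' @export
dnaControlPileup <- function(cds, depth = 48L) {
  out <- lapply(names(cds), function(g) {
    refb <- strsplit(cds[[g]], "")[[1]]
    gl <- length(refb)
    df <- data.frame(gene_id = g, cds_pos = seq_len(gl), ref_base = refb,
                     depth = as.integer(depth), A = 0L, C = 0L, G = 0L,
                     T = 0L, stringsAsFactors = FALSE)
    for (b in c("A", "C", "G", "T")) df[[b]][refb == b] <- depth
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Render the report bundle to TSV/text files
#'
#' Writes the recombination-frequency table (unit positions printed
#' 1-based with minus-orientation units descending, percentages with
#' exactly two decimals), the editing-site table, the editing summary
#' (shares with one decimal), start-codon events, and the run log.
#' Re-rendering an unchanged bundle is byte-identical.
#'
#' @param bundle Output of [runPipeline()].
#' @param outdir Output directory.
#' @return Character vector of written file paths, invisibly.
#' @export
renderReports <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <<- c(paths, p)
  }
  rec <- bundle$recombination
  if (!is.null(rec) && nrow(rec)) {
    out <- data.frame(
      Repeat = rec$repeat_id, Length_bp = rec$length,
      Direction = ifelse(rec$orientation == "direct", "direct",
                         "inverted"),
      Position_unit1 = formatInterval(rec$start1, rec$end1, "+"),
      Position_unit2 = formatInterval(rec$start2, rec$end2,
                                      rec$strand2),
      Reads_Master = sprintf("%d (%.2f%%)", rec$master_count,
                             rec$master_pct),
      Reads_Alternative = sprintf("%d (%.2f%%)", rec$alt_count,
                                  rec$alt_pct))
    wr(out, "recombination_frequency.tsv")
  } else {
    wr(data.frame(Repeat = character(0), Length_bp = integer(0),
                  Direction = character(0), Position_unit1 = character(0),
                  Position_unit2 = character(0),
                  Reads_Master = character(0),
                  Reads_Alternative = character(0)),
       "recombination_frequency.tsv")
  }
  es <- bundle$editing_sites
  wr(es, "editing_sites.tsv")
  su <- bundle$editing_summary
  wr(su$per_gene, "editing_per_gene.tsv")
  ty <- su$per_type
  ty$share_pct <- sprintf("%.1f", ty$share_pct)
  wr(ty, "editing_types.tsv")
  bi <- su$efficiency_bins
  bi$share_pct <- sprintf("%.1f", bi$share_pct)
  wr(bi, "editing_efficiency_bins.tsv")
  wr(bundle$start_codon, "start_codon_events.tsv")
  p <- file.path(outdir, "run_log.txt")
  writeLines(bundle$log, p)
  paths <- c(paths, p)
  invisible(paths)
}
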