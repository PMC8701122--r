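#' Simulation configuration for synthetic mitogenome data
#'
#' Defines the study conditions the synthetic data emulate: a circular
#' genome of ~45.4% GC carrying dispersed repeat pairs of 30-700 bp,
#' Nanopore-like long reads (mean ~13.43 kb, lognormal) drawn from a
#' mixture of master and alternative conformations at small planted
#' fractions, ~150 bp paired short reads (insert ~350 bp), and
#' strand-aware RNA-seq reads carrying planted C-to-U (and rarer
#' other-type) edits.  Default depths follow the real study (178x long
#' reads, 48x short reads); the default genome length is 50 kb, a desk
#' scale that preserves every structural feature of the full 508 kb
#' molecule (see the package vignette).
#'
#' @param seed Integer seed; identical configurations (including seed)
#'   produce byte-identical outputs.
#' @param genomeLength Genome length in bp (default 50000).
#' @param gcTarget Target GC fraction (default 0.4543).
#' @param plantedRepeats data.frame with columns `length`, `orientation`
#'   (`direct`/`inverted`), `mismatches`, `alt_fraction`; `NULL` for the
#'   default set.
#' @param plantedGenes data.frame with columns `gene_id`, `length`
#'   (multiple of 3), `strand`, `start_codon`, `in_repeat` (index into
#'   `plantedRepeats` or `NA`); `NULL` for the default set.
#' @param plantedEdits data.frame with columns `gene_id`, `cds_pos`,
#'   `alt_base` (transcript strand, DNA letters), `efficiency`; `NULL`
#'   for the default set.
#' @param longReadMeanLen,longReadSdlog Lognormal read-length model
#'   (mean 13430 bp, sdlog 0.6).
#' @param longReadSubRate,longReadIndelRate Long-read error model
#'   (defaults 0.05 substitutions, 0.03 indels).
#' @param longReadDepth Long-read coverage (default 178).
#' @param shortReadLen,shortReadInsert,shortReadDepth Short-read model
#'   (150 bp, 350 bp insert, 48x).
#' @param shortReadSubRate,rnaSubRate Substitution-only error rates for
#'   short/RNA reads (default 0.001).
#' @param rnaReadLen,rnaDepth RNA-seq read length (150) and per-gene
#'   coverage (default 100).
#' @return A list of class `mitosim_config`.
#' @export
simConfig <- function(seed = 1L, genomeLength = 50000L, gcTarget = 0.4543,
                      plantedRepeats = NULL, plantedGenes = NULL,
                      plantedEdits = NULL,
                      longReadMeanLen = 13430, longReadSdlog = 0.6,
                      longReadSubRate = 0.05, longReadIndelRate = 0.03,
                      longReadDepth = 178,
                      shortReadLen = 150L, shortReadInsert = 350L,
                      shortReadDepth = 48, shortReadSubRate = 0.001,
                      rnaReadLen = 150L, rnaDepth = 100, rnaSubRate = 0.001) {
  if (is.null(plantedRepeats))
    plantedRepeats <- data.frame(
      length = c(511L, 666L, 385L, 294L, 111L),
      orientation = c("inverted", "inverted", "direct", "inverted",
                      "direct"),
      mismatches = c(2L, 2L, 1L, 2L, 0L),
      alt_fraction = c(0.057, 0, 0.018, 0.0325, 0.0058))
  if (is.null(plantedGenes))
    plantedGenes <- data.frame(
      gene_id = c("nad1", "rps4", "rpl16", "nad7", "cox3", "atp1",
                  "nad3"),
      length = c(978L, 1086L, 540L, 1185L, 798L, 1530L, 618L),
      strand = c("-", "+", "+", "+", "-", "+", "+"),
      start_codon = c("ACG", "ACG", "GTG", "ATG", "ATG", "ATG", "ATG"),
      in_repeat = c(NA, NA, NA, NA, NA, NA, 2L))
  if (is.null(plantedEdits))
    plantedEdits <- data.frame(
      gene_id = c("nad1", "nad1", "nad1", "nad7", "nad7", "nad7",
                  "cox3", "cox3", "atp1", "rpl16"),
      cds_pos = c(2L, 50L, 311L, 20L, 101L, 500L, 77L, 230L, 350L, 90L),
      ref_base = c("C", "C", "C", "C", "C", "C", "C", "T", "A", "C"),
      alt_base = c("T", "T", "T", "T", "T", "T", "T", "G", "C", "T"),
      efficiency = c(0.6667, 0.99, 0.5, 1.0, 0.8, 0.2, 0.95, 0.3, 0.25,
                     0.6))
  stopifnot(all(plantedRepeats$alt_fraction >= 0),
            all(plantedRepeats$alt_fraction <= 1),
            all(plantedEdits$efficiency >= 0),
            all(plantedEdits$efficiency <= 1),
            all(plantedGenes$length %% 3L == 0L))
  structure(list(
    seed = as.integer(seed), genomeLength = as.integer(genomeLength),
    gcTarget = gcTarget, plantedRepeats = plantedRepeats,
    plantedGenes = plantedGenes, plantedEdits = plantedEdits,
    longReadMeanLen = longReadMeanLen, longReadSdlog = longReadSdlog,
    longReadSubRate = longReadSubRate,
    longReadIndelRate = longReadIndelRate,
    longReadDepth = longReadDepth, shortReadLen = as.integer(shortReadLen),
    shortReadInsert = as.integer(shortReadInsert),
    shortReadDepth = shortReadDepth, shortReadSubRate = shortReadSubRate,
    rnaReadLen = as.integer(rnaReadLen), rnaDepth = rnaDepth,
    rnaSubRate = rnaSubRate), class = "mitosim_config")
}

#' @noRd
randomDna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' @noRd
otherBase <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L),
         "", USE.NAMES = FALSE)
}

#' Simulate a circular genome with planted repeats, genes and truth table
#'
#' Generates a random circular genome at the target GC, plants CDS genes
#' (some minus strand, at least one with an ACG start by default) and
#' dispersed repeat pairs.  The second unit of each repeat is a copy of
#' the first with the stated number of mismatches placed at even
#' quantiles of the unit (so that short reads can distinguish the units),
#' reverse-complemented for inverted pairs.  Genes with `in_repeat` set
#' are planted inside the first unit and therefore duplicated with the
#' repeat; both copies are annotated under the same `gene_id`.
#'
#' Placement is left-to-right with randomized gaps and a guard margin, so
#' planted elements never overlap; a configuration that cannot be placed
#' is an error.
#'
#' @param config A [simConfig()] object.
#' @return List of class `mitosim`: `genome` ([CircularGenome-class]),
#'   `genes` (`GRanges`), `truth` (list with `repeats`, `genes`, `edits`
#'   data.frames), `config`.
#' @export
simulateGenome <- function(config) {
  set.seed(config$seed)
  n <- config$genomeLength
  s <- randomDna(n, config$gcTarget)
  pr <- config$plantedRepeats
  pg <- config$plantedGenes
  margin <- 1200L
  need <- sum(2L * pr$length) + sum(pg$length[is.na(pg$in_repeat)]) +
    (margin + 300L) * (2L * nrow(pr) + sum(is.na(pg$in_repeat)) + 1L)
  if (need > n)
    stop("config error: planted elements do not fit in the genome")
  cursor <- 1L + sample(300:900, 1L)
  place <- function(len) {
    st <- cursor + sample(margin:(margin + 600L), 1L)
    cursor <<- st + len
    if (cursor > n - margin)
      stop("config error: planted elements do not fit in the genome")
    st
  }
  writeSeg <- function(seq, at) {
    substr(s, at, at + nchar(seq) - 1L) <<- seq
    at
  }

  # genes not inside repeats
  geneRows <- list()
  geneSeqs <- list()
  for (i in seq_len(nrow(pg))) {
    len <- pg$length[i]
    cds <- paste0(pg$start_codon[i],
                  randomDna(len - 6L, config$gcTarget), "TAA")
    # force the configured reference base at planted edit sites so every
    # planted edit is a genuine base change
    ge <- config$plantedEdits[config$plantedEdits$gene_id ==
                                pg$gene_id[i], , drop = FALSE]
    for (k in seq_len(nrow(ge))) {
      if (ge$cds_pos[k] > len)
        stop("config error: edit position exceeds CDS length")
      substr(cds, ge$cds_pos[k], ge$cds_pos[k]) <- ge$ref_base[k]
      if (ge$ref_base[k] == ge$alt_base[k])
        stop("config error: planted edit with ref == alt")
    }
    geneSeqs[[pg$gene_id[i]]] <- cds
    if (is.na(pg$in_repeat[i])) {
      st <- place(len)
      writeSeg(if (pg$strand[i] == "-") revComp(cds) else cds, st)
      geneRows[[length(geneRows) + 1L]] <- data.frame(
        gene_id = pg$gene_id[i], start = st, end = st + len - 1L,
        strand = pg$strand[i], start_codon = pg$start_codon[i])
    }
  }

  # repeats (unit1 content random or carrying a planted gene)
  repRows <- list()
  for (i in seq_len(nrow(pr))) {
    L <- pr$length[i]
    u1 <- randomDna(L, config$gcTarget)
    gIn <- which(pg$in_repeat == i)
    gOff <- NA_integer_
    if (length(gIn)) {
      g <- gIn[1]
      glen <- pg$length[g]
      if (glen + 2L > L)
        stop("config error: gene longer than its host repeat unit")
      gOff <- ((L - glen) %/% 2L)
      cds <- geneSeqs[[pg$gene_id[g]]]
      substr(u1, gOff + 1L, gOff + glen) <-
        if (pg$strand[g] == "-") revComp(cds) else cds
    }
    m <- pr$mismatches[i]
    u2 <- u1
    mpos <- integer(0)
    if (m > 0L) {
      # mismatch positions within short-read reach of the unit ends, so
      # that 150 bp reads can tell the units apart at the boundaries
      p1 <- min(110L, max(20L, L %/% 3L))
      mpos <- unique(pmax(1L, pmin(L, round(seq(p1, L - p1,
                                                length.out = m)))))
      for (p in mpos) {
        b <- substr(u2, p, p)
        substr(u2, p, p) <- otherBase(b)
      }
    }
    st1 <- place(L)
    st2 <- place(L)
    writeSeg(u1, st1)
    writeSeg(if (pr$orientation[i] == "inverted") revComp(u2) else u2,
             st2)
    repRows[[i]] <- data.frame(
      repeat_id = paste0("sim", i), length = L,
      orientation = pr$orientation[i], mismatches = m,
      start1 = st1, start2 = st2,
      alt_fraction = pr$alt_fraction[i])
    if (length(gIn)) {
      g <- gIn[1]
      glen <- pg$length[g]
      for (st in c(st1, st2)) {
        # copy in unit2 of an inverted repeat lies on the opposite strand
        inv <- st == st2 && pr$orientation[i] == "inverted"
        gs <- if (inv) st + (L - gOff - glen) else st + gOff
        geneRows[[length(geneRows) + 1L]] <- data.frame(
          gene_id = pg$gene_id[g], start = gs, end = gs + glen - 1L,
          strand = if (inv) chartr("+-", "-+", pg$strand[g]) else
            pg$strand[g],
          start_codon = pg$start_codon[g])
      }
    }
  }

  genesDf <- do.call(rbind, geneRows)
  genes <- GenomicRanges::GRanges(
    seqnames = "simgenome",
    ranges = IRanges::IRanges(start = genesDf$start, end = genesDf$end),
    strand = genesDf$strand)
  genes$gene_id <- genesDf$gene_id
  genes$feature_type <- "CDS"
  genes$pseudo <- FALSE

  edits <- config$plantedEdits
  for (i in seq_len(nrow(edits))) {
    tx <- geneSeqs[[edits$gene_id[i]]]
    if (is.null(tx)) stop("config error: edit in unknown gene")
    if (edits$cds_pos[i] > nchar(tx))
      stop("config error: edit position exceeds CDS length")
    edits$ref_base[i] <- substr(tx, edits$cds_pos[i], edits$cds_pos[i])
  }

  genome <- CircularGenome(s, id = "simgenome", circular = TRUE)
  structure(list(genome = genome, genes = genes,
                 truth = list(repeats = do.call(rbind, repRows),
                              genes = genesDf, edits = edits),
                 config = config),
            class = "mitosim")
}

#' Apply a substitution/indel error model to reads
#'
#' Uniform substitutions at `subRate`; insertions and deletions each at
#' `indelRate / 2`.
#'
#' @param seqs Character vector of reads.
#' @param subRate,indelRate Per-base error rates.
#' @return Character vector of mutated reads.
#' @export
mutateReads <- function(seqs, subRate = 0.05, indelRate = 0.03) {
  if (!length(seqs)) return(character(0))
  as.character(cpp_mutate_reads(seqs, subRate, indelRate))
}

#' Draw one fragment of length `len` from the conformational mixture.
#' Alternative fragments come from a recombinant molecule with a fresh
#' uniform crossover breakpoint (phase switching inside the repeat is
#' what makes mismatched units informative for short reads).
#' @noRd
drawMixtureFragment <- function(sim, source, len) {
  if (source == "master") {
    mol <- sim$genome
  } else {
    tr <- sim$truth$repeats
    rec <- recombinantMolecules(sim$genome,
                                tr[tr$repeat_id == source, ],
                                crossover = stats::runif(1))
    w <- nchar(rec$molecules)
    j <- if (length(w) > 1L) sample(seq_along(w), 1L, prob = w) else 1L
    mol <- CircularGenome(rec$molecules[[j]], circular = TRUE)
  }
  ml <- length(mol)
  st <- sample.int(ml, 1L)
  circularArc(mol, st, min(len, ml))
}

#' Simulate Nanopore-like long reads from the conformational mixture
#'
#' Reads are drawn from the master circle and, per repeat, from the
#' explicitly constructed alternative molecule(s) at the planted
#' fraction; lengths are lognormal with the configured mean; uniform
#' substitution/indel errors; random strand.  The simulator log reports
#' the realized N50.
#'
#' @param sim A `mitosim` object from [simulateGenome()].
#' @param nReads Number of reads (default from configured depth).
#' @param seedOffset Added to the config seed so different read sets from
#'   one genome are independent (default 1).
#' @return data.frame: `read_id`, `seq`, `source` (`master` or the
#'   originating repeat id), `strand`.
#' @export
simulateLongReads <- function(sim, nReads = NULL, seedOffset = 1L) {
  cfg <- sim$config
  set.seed(cfg$seed + seedOffset)
  n <- length(sim$genome)
  if (is.null(nReads))
    nReads <- max(1L, round(cfg$longReadDepth * n / cfg$longReadMeanLen))
  tr <- sim$truth$repeats
  pAlt <- tr$alt_fraction
  # per-read source: repeat r's alternative with prob alt_fraction[r]
  probs <- c(max(0, 1 - sum(pAlt)), pAlt[pAlt > 0])
  names(probs) <- c("master", tr$repeat_id[pAlt > 0])
  pick <- sample(names(probs), nReads, replace = TRUE, prob = probs)
  meanlog <- log(cfg$longReadMeanLen) - cfg$longReadSdlog^2 / 2
  lens <- pmax(500L, round(stats::rlnorm(nReads, meanlog,
                                         cfg$longReadSdlog)))
  out <- character(nReads)
  strands <- sample(c("+", "-"), nReads, replace = TRUE)
  isM <- pick == "master"
  if (any(isM)) {
    S2 <- strrep(as.character(genomeSeq(sim$genome)), 2L)
    st <- sample.int(n, sum(isM), replace = TRUE)
    out[isM] <- substring(S2, st, st + pmin(lens[isM], n) - 1L)
  }
  for (i in which(!isM))
    out[i] <- drawMixtureFragment(sim, pick[i], lens[i])
  out <- mutateReads(out, cfg$longReadSubRate, cfg$longReadIndelRate)
  flip <- strands == "-"
  out[flip] <- revComp(out[flip])
  data.frame(read_id = sprintf("LR%06d", seq_len(nReads)), seq = out,
             source = pick, strand = strands, stringsAsFactors = FALSE)
}

#' Simulate junction-spanning long reads for one repeat pair
#'
#' Targeted generator for frequency-recovery experiments: every read
#' fully covers the repeat plus `flank` bp on each side, drawn from the
#' alternative conformation with probability `altFraction` (a junction or
#' molecule chosen uniformly within the conformation), with extra random
#' context on both sides and the configured error model.
#'
#' @param genome A [CircularGenome-class].
#' @param rp One [findRepeats()]-style row (planted truth row works too if
#'   it carries `start1`, `start2`, `length`, `orientation`).
#' @param n Number of spanning reads.
#' @param altFraction Planted alternative-conformation fraction.
#' @param flank Junction flank in bp (default 1000).
#' @param subRate,indelRate Error model (defaults 0.05 / 0.03).
#' @param maxExtra Maximum extra context per side (default 2000).
#' @return data.frame: `read_id`, `seq`, `truth` (`master`/`alternative`),
#'   `strand`.
#' @export
simulateSpanningReads <- function(genome, rp, n, altFraction,
                                  flank = 1000L, subRate = 0.05,
                                  indelRate = 0.03, maxExtra = 2000L) {
  rec <- recombinantMolecules(genome, rp)
  altMols <- lapply(rec$molecules, CircularGenome, circular = TRUE)
  L <- as.integer(rp$length)
  gN <- length(genome)
  masterStarts <- c(rp$start1, rp$start2)
  truth <- ifelse(stats::runif(n) < altFraction, "alternative", "master")
  strands <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- character(n)
  for (i in seq_len(n)) {
    if (truth[i] == "master") {
      mol <- genome; st <- sample(masterStarts, 1L); ml <- gN
    } else {
      k <- sample(seq_along(rec$repeat_at), 1L)
      mol <- altMols[[min(k, length(altMols))]]
      st <- rec$repeat_at[k]; ml <- length(mol)
    }
    jlen <- L + 2L * flank
    extra <- sample.int(maxExtra, 2L, replace = TRUE)
    len <- min(jlen + sum(extra), ml)
    left <- min(extra[1], ml - jlen)
    stRead <- ((st - flank - left - 1L) %% ml) + 1L
    seqs[i] <- circularArc(mol, stRead, len)
  }
  seqs <- mutateReads(seqs, subRate, indelRate)
  flip <- strands == "-"
  seqs[flip] <- revComp(seqs[flip])
  data.frame(read_id = sprintf("SP%05d", seq_len(n)), seq = seqs,
             truth = truth, strand = strands, stringsAsFactors = FALSE)
}

#' Simulate paired-end short reads from the conformational mixture
#'
#' 150 bp pairs with ~350 bp inserts drawn from the same master /
#' alternative molecule mixture as the long reads; substitution-only
#' errors.
#'
#' @param sim A `mitosim` object.
#' @param nPairs Number of pairs (default from configured depth).
#' @param seedOffset Seed offset (default 2).
#' @return data.frame: `pair_id`, `seq1`, `seq2`, `source`.
#' @export
simulateShortReads <- function(sim, nPairs = NULL, seedOffset = 2L) {
  cfg <- sim$config
  set.seed(cfg$seed + seedOffset)
  n <- length(sim$genome)
  rl <- cfg$shortReadLen
  if (is.null(nPairs))
    nPairs <- max(1L, round(cfg$shortReadDepth * n / (2 * rl)))
  tr <- sim$truth$repeats
  pAlt <- tr$alt_fraction
  probs <- c(max(0, 1 - sum(pAlt)), pAlt[pAlt > 0])
  names(probs) <- c("master", tr$repeat_id[pAlt > 0])
  pick <- sample(names(probs), nPairs, replace = TRUE, prob = probs)
  ins <- pmax(2L * rl, round(stats::rnorm(nPairs, cfg$shortReadInsert,
                                          35)))
  frags <- character(nPairs)
  isM <- pick == "master"
  if (any(isM)) {
    S2 <- strrep(as.character(genomeSeq(sim$genome)), 2L)
    st <- sample.int(n, sum(isM), replace = TRUE)
    frags[isM] <- substring(S2, st, st + pmin(ins[isM], n) - 1L)
  }
  for (i in which(!isM))
    frags[i] <- drawMixtureFragment(sim, pick[i], ins[i])
  s1 <- substr(frags, 1L, rl)
  s2 <- revComp(substring(frags, nchar(frags) - rl + 1L, nchar(frags)))
  s1 <- mutateReads(s1, cfg$shortReadSubRate, 0)
  s2 <- mutateReads(s2, cfg$shortReadSubRate, 0)
  data.frame(pair_id = sprintf("SR%06d", seq_len(nPairs)), seq1 = s1,
             seq2 = s2, source = pick, stringsAsFactors = FALSE)
}

#' Simulate strand-aware RNA-seq reads with planted editing
#'
#' Reads are drawn from spliced transcripts (minus-strand genes in
#' transcript orientation).  At each planted edit site, every covering
#' read carries the alternative base independently with probability equal
#' to the planted efficiency; substitution errors are added on top.
#'
#' @param sim A `mitosim` object.
#' @param depth Per-gene coverage (default from config).
#' @param seedOffset Seed offset (default 3).
#' @return List: `alignments` (data.frame `gene_id`, `start`, `seq` of
#'   gapless transcript-orientation alignments), `cds` (named character
#'   vector of spliced reference transcripts), `truth` (planted edits).
#' @export
simulateRnaSeqReads <- function(sim, depth = NULL, seedOffset = 3L) {
  cfg <- sim$config
  set.seed(cfg$seed + seedOffset)
  if (is.null(depth)) depth <- cfg$rnaDepth
  rl <- cfg$rnaReadLen
  edits <- sim$truth$edits
  pg <- cfg$plantedGenes
  cds <- character(0)
  rows <- list()
  for (i in seq_len(nrow(pg))) {
    g <- pg$gene_id[i]
    if (g %in% names(cds)) next
    tx <- spliceTranscript(sim$genome, sim$genes, g)
    # multi-copy genes: both copies are identical up to planted repeat
    # mismatches; use the first annotated copy's transcript
    ex <- sim$genes[sim$genes$gene_id == g]
    if (length(ex) > 1L) {
      first <- ex[1]
      tx <- circularSubstring(sim$genome, GenomicRanges::start(first),
                              GenomicRanges::end(first))
      if (as.character(GenomicRanges::strand(first)) == "-")
        tx <- revComp(tx)
    }
    cds[g] <- tx
    gl <- nchar(tx)
    # fragment starts may precede the CDS (mRNA UTRs); reads are clipped
    # to the CDS so coverage is uniform across the whole coding region
    nReads <- max(1L, round(depth * (gl + rl - 1L) / rl))
    starts <- sample(seq.int(2L - rl, gl), nReads, replace = TRUE)
    ge <- edits[edits$gene_id == g, , drop = FALSE]
    seqs <- vapply(starts, function(st) {
      a <- max(1L, st)
      rd <- substr(tx, a, min(gl, st + rl - 1L))
      for (k in seq_len(nrow(ge))) {
        p <- ge$cds_pos[k] - a + 1L
        if (p >= 1L && p <= nchar(rd) &&
            stats::runif(1) < ge$efficiency[k])
          substr(rd, p, p) <- ge$alt_base[k]
      }
      rd
    }, "")
    seqs <- mutateReads(seqs, cfg$rnaSubRate, 0)
    rows[[g]] <- data.frame(gene_id = g, start = pmax(1L, starts),
                            seq = seqs, stringsAsFactors = FALSE)
  }
  list(alignments = do.call(rbind, rows), cds = cds,
       truth = edits)
}

#' Write gapless transcript alignments as a SAM file
#'
#' Minimal single-end SAM (flag 0, MAPQ 60, all-match CIGAR, constant
#' base quality) over the spliced CDS references, suitable for
#' [pileupFromSam()].
#'
#' @param alignments data.frame `gene_id`, `start`, `seq`.
#' @param cds Named character vector of reference transcripts.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
writeSam <- function(alignments, cds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (g in names(cds))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", g, nchar(cds[[g]])), con)
  if (nrow(alignments)) {
    lens <- nchar(alignments$seq)
    writeLines(sprintf("r%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                       seq_len(nrow(alignments)), alignments$gene_id,
                       alignments$start, lens, alignments$seq,
                       vapply(lens, function(l)
                         strrep("I", l), "")), con)
  }
  invisible(path)
}

#' Write reads as a 4-line-record FASTQ file
#'
#' @param seqs Character vector of reads.
#' @param path Output path.
#' @param ids Optional read names.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(seqs, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                    vapply(nchar(seqs), function(l) strrep("I", l), "")),
             con)
  invisible(path)
}

#' Write the simulated dataset (FASTA, GFF3, truth tables) to a directory
#'
#' @param sim A `mitosim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFasta(list(sim$genome), file.path(dir, "genome.fasta"))
  gff <- sim$genes
  gff$type <- "CDS"
  gff$phase <- 0L
  gff$ID <- paste0(gff$gene_id, "_", seq_along(gff))
  rtracklayer::export(gff, file.path(dir, "genes.gff3"), format = "gff3")
  for (nm in names(sim$truth))
    utils::write.table(sim$truth[[nm]],
                       file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
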