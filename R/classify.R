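#' Classify a long read against a conformation pair
#'
#' Implements the complete-coverage counting rule for junction-spanning
#' reads: a read is informative for a repeat only when it fully covers a
#' junction reference (repeat plus both flanks).  Each junction is first
#' anchored inside the read (either strand) by exact k-mer seeds; a
#' junction counts as covered when the anchored junction span lies
#' entirely inside the read and the banded semiglobal alignment of the
#' whole junction against the read reaches `minIdentity`.  The read then
#' votes for the conformation of its best-covered junction when that
#' junction's edit distance beats the best junction of the other
#' conformation by at least `minMargin`; otherwise it is ambiguous.
#'
#' @param read Character string (the read sequence).
#' @param cp A [ConformationPair-class].
#' @param minIdentity Minimum alignment identity `1 - dist/len(junction)`
#'   for a junction to count as covered (default 0.75, suited to
#'   Nanopore-like error rates).
#' @param minMargin Minimum edit-distance margin between conformations for
#'   an unambiguous vote (default 5).
#' @param band Half-width of the alignment band around the anchored
#'   diagonal; default scales with junction length.
#' @return One of `"master"`, `"alternative"`, `"ambiguous"`,
#'   `"uninformative"`.
#' @export
classifyRead <- function(read, cp, minIdentity = 0.75, minMargin = 5L,
                         band = NULL) {
  if (!isInformative(cp)) return("uninformative")
  juncs <- c(as.character(masterJunctions(cp)),
             as.character(altJunctions(cp)))
  bandFrac <- 0.02
  minBand <- 32L
  if (!is.null(band)) { bandFrac <- 0; minBand <- as.integer(band) }
  res <- cpp_classify_read(juncs, read, minIdentity,
                           as.integer(minMargin), bandFrac, minBand,
                           16L, 24L)
  res$call
}

#' Classify a set of long reads and tally conformation support
#'
#' @param reads Character vector, `DNAStringSet`, or path to a FASTA/FASTQ
#'   file of long reads.
#' @param cp A [ConformationPair-class].
#' @inheritParams classifyRead
#' @return Named integer vector with counts `master`, `alternative`,
#'   `ambiguous`, `uninformative`.
#' @export
countSpanningReads <- function(reads, cp, minIdentity = 0.75,
                               minMargin = 5L, band = NULL) {
  reads <- asReadVector(reads)
  cls <- vapply(reads, classifyRead, "", cp = cp,
                minIdentity = minIdentity, minMargin = minMargin,
                band = band, USE.NAMES = FALSE)
  counts <- table(factor(cls, levels = c("master", "alternative",
                                         "ambiguous", "uninformative")))
  stats::setNames(as.integer(counts), names(counts))
}

#' @noRd
asReadVector <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.f(ast)?q$", reads, ignore.case = TRUE))
      "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  if (is(reads, "XStringSet")) reads <- as.character(reads)
  unname(reads)
}

#' Recombination-frequency table from per-repeat read counts
#'
#' One row per repeat pair: counts of informative spanning reads
#' supporting the master and alternative conformation and the derived
#' percentages (`pct = 100 * count / (master + alternative)`, rounded
#' half-up to 2 decimals).  Rows are sorted by repeat length descending
#' and renamed `R1..Rn`; rows with zero informative reads are suppressed
#' with a warning.
#'
#' @param counts data.frame with columns `repeat_id`, `length`,
#'   `orientation`, `start1`, `end1`, `start2`, `end2`, `strand2`,
#'   `master_count`, `alt_count` (coordinate columns optional).
#' @return data.frame with added `master_pct`, `alt_pct` and `R1..Rn` ids.
#' @export
recombinationTable <- function(counts) {
  stopifnot(all(c("master_count", "alt_count", "length") %in%
                  names(counts)))
  tot <- counts$master_count + counts$alt_count
  if (any(tot == 0)) {
    warning("suppressing ", sum(tot == 0),
            " repeat(s) with zero informative reads")
    counts <- counts[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  counts$master_pct <- roundHalfUp(100 * counts$master_count / tot, 2L)
  counts$alt_pct <- roundHalfUp(100 * counts$alt_count / tot, 2L)
  ord <- order(-counts$length)
  counts <- counts[ord, , drop = FALSE]
  counts$repeat_id <- paste0("R", seq_len(nrow(counts)))
  rownames(counts) <- NULL
  counts
}

#' Screen short reads for multiple structures at repeat boundaries
#'
#' First-pass candidate detection: a repeat pair is flagged when short
#' reads anchored to one specific unit (via an exact word covering a
#' position where the two units differ) extend across a unit boundary
#' into the flanking sequence of the *other* unit.  Under the master
#' conformation each unit pairs only with its own flanks, so such crossed
#' pairings indicate an additional structure.  At least
#' `minFlankEvidence` crossed reads are required per extra flank.
#'
#' Repeat pairs whose units are identical (no diagnostic position within
#' reach of a boundary) cannot be screened by short reads and are never
#' flagged.
#'
#' @param genome A [CircularGenome-class].
#' @param repeats [findRepeats()]-style data.frame.
#' @param shortReads Character vector / `DNAStringSet` / FASTA-FASTQ path
#'   of ~150 bp reads (both mates as individual reads).
#' @param minFlankEvidence Minimum crossed reads per extra flank
#'   (default 2).
#' @param anchorLen Exact anchor word length (default 24).
#' @param overhangLen Flank overhang compared beyond the boundary
#'   (default 20).
#' @param maxOverhangMismatch Max mismatches for an overhang to match a
#'   flank (default 2).
#' @return Character vector of flagged `repeat_id`s.
#' @export
screenShortReads <- function(genome, repeats, shortReads,
                             minFlankEvidence = 2L, anchorLen = 24L,
                             overhangLen = 20L, maxOverhangMismatch = 2L) {
  reads <- asReadVector(shortReads)
  readLen <- max(nchar(reads))
  n <- length(genome)
  all <- c(reads, revComp(reads))
  flagged <- character(0)
  for (i in seq_len(nrow(repeats))) {
    rp <- repeats[i, ]
    L <- rp$length
    u1 <- rp$unit1_seq; u2 <- rp$unit2_seq   # matched orientation
    P <- which(charToRaw(u1) != charToRaw(u2))
    if (!length(P)) next
    # flanks in matched orientation: unit1 on +; unit2 flanks must be
    # taken in the unit's matched reading direction
    fl <- overhangLen
    lf1 <- circularArc(genome, ((rp$start1 - fl - 1L) %% n) + 1L, fl)
    rf1 <- circularArc(genome, ((rp$start1 + L - 1L) %% n) + 1L, fl)
    a2 <- circularArc(genome, ((rp$start2 - fl - 1L) %% n) + 1L, fl)
    b2 <- circularArc(genome, ((rp$start2 + L - 1L) %% n) + 1L, fl)
    if (rp$strand2 == "-") { lf2 <- revComp(b2); rf2 <- revComp(a2) }
    else { lf2 <- a2; rf2 <- b2 }
    evid <- c(0L, 0L)  # crossed evidence at left / right boundary
    for (side in c("left", "right")) {
      # diagnostic position nearest this boundary, reachable by a read
      p <- if (side == "left") min(P) else max(P)
      distB <- if (side == "left") p else L - p + 1L
      if (distB + overhangLen > readLen) next
      for (unit in 1:2) {
        useq <- if (unit == 1L) u1 else u2
        ownF <- if (unit == 1L) { if (side == "left") lf1 else rf1 }
                else { if (side == "left") lf2 else rf2 }
        othF <- if (unit == 1L) { if (side == "left") lf2 else rf2 }
                else { if (side == "left") lf1 else rf1 }
        if (hammingDist(ownF, othF) <= maxOverhangMismatch) next
        # exact anchor word covering the diagnostic position, abutting
        # the boundary side
        if (side == "left") {
          aEnd <- min(L, max(p, anchorLen))
          anchor <- substr(useq, max(1L, aEnd - anchorLen + 1L), aEnd)
          gap <- max(1L, aEnd - anchorLen + 1L) - 1L  # bases before anchor
        } else {
          aSt <- max(1L, min(p, L - anchorLen + 1L))
          anchor <- substr(useq, aSt, min(L, aSt + anchorLen - 1L))
          gap <- L - min(L, aSt + anchorLen - 1L)     # bases after anchor
        }
        if (nchar(anchor) < 12L) next
        hits <- regexpr(anchor, all, fixed = TRUE)
        hit <- which(hits > 0)
        for (h in hit) {
          pos <- hits[h]
          rd <- all[h]
          if (side == "left") {
            ovEnd <- pos - gap - 1L
            if (ovEnd < overhangLen) next
            ov <- substr(rd, ovEnd - overhangLen + 1L, ovEnd)
          } else {
            ovSt <- pos + nchar(anchor) + gap
            if (ovSt + overhangLen - 1L > nchar(rd)) next
            ov <- substr(rd, ovSt, ovSt + overhangLen - 1L)
          }
          dOwn <- hammingDist(ov, ownF)
          dOth <- hammingDist(ov, othF)
          if (dOth <= maxOverhangMismatch && dOwn > dOth)
            evid[if (side == "left") 1L else 2L] <-
              evid[if (side == "left") 1L else 2L] + 1L
        }
      }
    }
    if (any(evid >= minFlankEvidence))
      flagged <- c(flagged, rp$repeat_id)
  }
  flagged
}
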