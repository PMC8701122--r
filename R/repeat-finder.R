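#' @useDynLib mitorecomb, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Hamming distance between equal-length DNA strings
#'
#' `N` never counts as a match (an `N` opposite anything is a mismatch).
#'
#' @param a,b Character strings of equal length.
#' @return Integer mismatch count.
#' @export
hammingDist <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  if (length(ra) != length(rb)) stop("sequences must have equal length")
  acgt <- charToRaw("ACGT")
  sum(!(ra == rb & ra %in% acgt))
}

#' Expected number of chance occurrences of a repeat (E-value)
#'
#' For a repeat of given length with `m` mismatches on a genome of length
#' `n`, the expected number of random occurrences is
#' `E = choose(L, m) * 3^m * n^2 / 4^L` (uniform base composition).
#' Monotone decreasing in length and increasing in mismatches.
#'
#' @param length Repeat length in bp (vectorized).
#' @param mismatches Mismatch count.
#' @param genomeLength Genome length in bp.
#' @return Numeric E-values.
#' @export
repeatEvalue <- function(length, mismatches, genomeLength) {
  exp(lchoose(length, mismatches) + mismatches * log(3) +
        2 * log(genomeLength) - length * log(4))
}

#' Find dispersed repeat pairs with mismatches on a (circular) genome
#'
#' Identifies maximal direct (forward) and inverted (palindromic) repeat
#' pairs under a Hamming-distance budget, in the style of classical repeat
#' finders: a pair is maximal when extending either end would exceed the
#' mismatch budget or leave the genome arc.  Inverted pairs are found by
#' comparison against the reverse complement.  On circular genomes the
#' doubled sequence is scanned (capped at one wrap) so repeats spanning
#' the origin are recovered; pairs whose two units overlap on the circle
#' (tandem-like) are discarded, and each unordered pair is reported once
#' with `unit1` leftmost.
#'
#' The search is exact within its thresholds: seeding uses exact blocks of
#' length `floor(minLength/(maxMismatch+1))`, which by pigeonhole every
#' qualifying repeat must contain.
#'
#' @param genome A [CircularGenome-class] (or character string, treated as
#'   circular).
#' @param minLength Minimum repeat unit length in bp (default 30).
#' @param maxMismatch Maximum Hamming distance between units (default 3).
#' @param evalueMax Keep pairs with [repeatEvalue()] at most this
#'   (default 1e-5).
#' @param kinds Character subset of `c("direct", "inverted")`.
#' @param collapse When `TRUE`, overlapping maximal windows of the same
#'   repeat locus (nested windows that share most of both units, a
#'   by-product of the mismatch budget) are collapsed to the longest
#'   window, giving one row per locus as repeat tables conventionally
#'   report.  `FALSE` (default) returns the complete maximal set.
#' @return A data.frame with one row per repeat pair: `repeat_id`,
#'   `orientation`, `length`, `mismatches`, `evalue`, unit coordinates
#'   (`start1`, `end1`, `start2`, `end2`; 1-based ascending, `end < start`
#'   only via `spans_origin`), `strand2`, `spans_origin1/2`, and the unit
#'   sequences (`unit2_seq` oriented so that
#'   `hammingDist(unit1_seq, unit2_seq) == mismatches`).  Sorted by length
#'   descending.
#' @export
findRepeats <- function(genome, minLength = 30L, maxMismatch = 3L,
                        evalueMax = 1e-5,
                        kinds = c("direct", "inverted"),
                        collapse = FALSE) {
  if (is.character(genome)) genome <- CircularGenome(genome)
  kinds <- match.arg(kinds, several.ok = TRUE)
  s <- as.character(genome@sequence)
  n <- nchar(s)
  circ <- genome@circular
  S <- if (circ) paste0(s, s) else s
  N2 <- nchar(S)
  q <- max(2L, min(31L, as.integer(floor(minLength / (maxMismatch + 1)))))

  res <- list()
  if ("direct" %in% kinds) {
    runs <- cpp_find_runs(S, S, q, maxMismatch, as.integer(minLength),
                          TRUE, if (circ) n else -(2L * N2 + 1L))
    if (nrow(runs)) {
      runs$u2s_S <- runs$start2
      runs$orientation <- "direct"
      res$direct <- runs
    }
  }
  if ("inverted" %in% kinds) {
    S2 <- revComp(S)
    runs <- cpp_find_runs(S, S2, q, maxMismatch, as.integer(minLength),
                          FALSE, -(2L * N2 + 1L))
    if (nrow(runs)) {
      # s2 segment [p, p+L-1] maps to S positions [N2-p-L+2, N2-p+1]
      runs$u2s_S <- N2 - runs$start2 - runs$length + 2L
      runs$orientation <- "inverted"
      res$inverted <- runs
    }
  }
  cols <- c("repeat_id", "orientation", "length", "mismatches", "evalue",
            "start1", "end1", "strand1", "start2", "end2", "strand2",
            "spans_origin1", "spans_origin2", "unit1_seq", "unit2_seq")
  if (!length(res)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  cols))
    return(out)
  }
  runs <- do.call(rbind, res)
  L <- runs$length
  if (circ) {
    e1 <- runs$start1 + L - 1L
    e2 <- runs$u2s_S + L - 1L
    # drop windows truncated by the doubled-sequence boundaries: every
    # circular run has an untruncated representative (see vignette)
    keep <- runs$start1 > 1L & runs$u2s_S > 1L & e1 < N2 & e2 < N2 & L < n
    runs <- runs[keep, , drop = FALSE]
    L <- runs$length
    u1 <- ((runs$start1 - 1L) %% n) + 1L
    u2 <- ((runs$u2s_S - 1L) %% n) + 1L
  } else {
    u1 <- runs$start1
    u2 <- runs$u2s_S
  }
  # unit1 leftmost
  swap <- u2 < u1
  tmp <- u1[swap]; u1[swap] <- u2[swap]; u2[swap] <- tmp
  # circular overlap between the two units -> tandem-like, discard
  if (circ) {
    ov <- ((u2 - u1) %% n) < L | ((u1 - u2) %% n) < L
  } else {
    ov <- u1 + L - 1L >= u2
  }
  keep <- !ov & !(u1 == u2)
  runs <- runs[keep, , drop = FALSE]
  u1 <- u1[keep]; u2 <- u2[keep]; L <- L[keep]
  key <- paste(runs$orientation, u1, u2, L)
  dup <- duplicated(key)
  runs <- runs[!dup, , drop = FALSE]
  u1 <- u1[!dup]; u2 <- u2[!dup]; L <- L[!dup]

  ev <- repeatEvalue(L, runs$mismatches, n)
  keep <- ev <= evalueMax
  runs <- runs[keep, , drop = FALSE]
  u1 <- u1[keep]; u2 <- u2[keep]; L <- L[keep]; ev <- ev[keep]
  if (!nrow(runs)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  cols))
    return(out)
  }

  end1 <- u1 + L - 1L
  end2 <- u2 + L - 1L
  sp1 <- circ & end1 > n
  sp2 <- circ & end2 > n
  if (circ) {
    end1 <- ((end1 - 1L) %% n) + 1L
    end2 <- ((end2 - 1L) %% n) + 1L
  }
  u1seq <- vapply(seq_along(u1), function(i)
    circularArc(genome, u1[i], L[i]), "")
  u2arc <- vapply(seq_along(u2), function(i)
    circularArc(genome, u2[i], L[i]), "")
  inv <- runs$orientation == "inverted"
  u2seq <- u2arc
  if (any(inv)) u2seq[inv] <- revComp(u2arc[inv])

  out <- data.frame(
    repeat_id = "", orientation = runs$orientation, length = L,
    mismatches = runs$mismatches, evalue = ev,
    start1 = u1, end1 = end1, strand1 = "+",
    start2 = u2, end2 = end2,
    strand2 = ifelse(inv, "-", "+"),
    spans_origin1 = sp1, spans_origin2 = sp2,
    unit1_seq = u1seq, unit2_seq = u2seq,
    stringsAsFactors = FALSE)
  out <- out[order(-out$length, out$start1, out$start2), , drop = FALSE]
  if (collapse && nrow(out) > 1L) {
    ovl <- function(a, la, b, lb) {
      # circular overlap length of [a, a+la-1] and [b, b+lb-1]
      d <- (b - a) %% n
      o1 <- max(0L, min(la - d, lb))
      d2 <- (a - b) %% n
      o2 <- max(0L, min(lb - d2, la))
      max(o1, o2)
    }
    keep <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      dup <- FALSE
      for (j in which(keep)) {
        if (out$orientation[i] != out$orientation[j]) next
        o1 <- ovl(out$start1[i], out$length[i], out$start1[j],
                  out$length[j])
        o2 <- ovl(out$start2[i], out$length[i], out$start2[j],
                  out$length[j])
        if (o1 >= 0.5 * out$length[i] && o2 >= 0.5 * out$length[i]) {
          dup <- TRUE; break
        }
      }
      keep[i] <- !dup
    }
    out <- out[keep, , drop = FALSE]
  }
  out$repeat_id <- paste0("rep", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Detect protein-coding genes captured inside both units of a repeat pair
#'
#' A gene is "captured" when both units of a repeat pair fully contain a
#' copy of its CDS, the route by which short mitochondrial repeats
#' duplicate genes (nad3/nad6-style multi-copy genes).  Multi-copy genes
#' are expected to be annotated once per copy under the same `gene_id`;
#' each unit must strictly contain at least one annotated CDS range of
#' the gene (containment is circular-aware and strict — a 90% overlap is
#' not capture).  `copy_number` is the number of containing units.
#'
#' @param repeats Output of [findRepeats()].
#' @param genes `GRanges` from [readGffGenes()].
#' @param genomeLength Genome length in bp (for circular containment
#'   arithmetic).
#' @return data.frame with `gene_id`, `repeat_id`, `copy_number`.
#' @export
detectGeneCapture <- function(repeats, genes, genomeLength) {
  out <- data.frame(gene_id = character(0), repeat_id = character(0),
                    copy_number = integer(0))
  if (!nrow(repeats) || !length(genes)) return(out)
  cds <- genes[genes$feature_type == "CDS"]
  if (!length(cds)) return(out)
  n <- as.integer(genomeLength)
  inUnit <- function(us, L, gs, ge) {
    off <- (gs - us) %% n
    off + (ge - gs) <= L - 1L
  }
  rows <- list()
  for (g in unique(cds$gene_id)) {
    gx <- cds[cds$gene_id == g]
    gs <- GenomicRanges::start(gx); ge <- GenomicRanges::end(gx)
    for (i in seq_len(nrow(repeats))) {
      L <- repeats$length[i]
      in1 <- any(inUnit(repeats$start1[i], L, gs, ge))
      in2 <- any(inUnit(repeats$start2[i], L, gs, ge))
      if (in1 && in2)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, repeat_id = repeats$repeat_id[i],
          copy_number = 2L)
    }
  }
  if (length(rows)) do.call(rbind, rows) else out
}
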