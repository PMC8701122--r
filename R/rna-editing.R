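#' The 12 possible single-base editing types (transcript strand)
#' @noRd
editTypeLevels <- function() {
  b <- c("A", "C", "G", "U")
  unlist(lapply(b, function(x) paste0(x, "-to-", setdiff(b, x))))
}

#' Classify a single-base editing event
#'
#' Ordered-pair label on the transcript strand, with `T` reported as `U`
#' (e.g. `classifyEdit("C", "T")` is `"C-to-U"`, the canonical plant
#' mitochondrial editing type).
#'
#' @param ref,alt Reference and alternative base, in `{A,C,G,T,U}`.
#' @return Character label, one of the 12 ordered pairs.
#' @export
classifyEdit <- function(ref, alt) {
  ref <- chartr("T", "U", toupper(ref))
  alt <- chartr("T", "U", toupper(alt))
  if (any(ref == alt)) stop("logic error: ref and alt base are equal")
  ok <- ref %in% c("A", "C", "G", "U") & alt %in% c("A", "C", "G", "U")
  if (!all(ok)) stop("bases must be in {A,C,G,U}")
  paste0(ref, "-to-", alt)
}

#' Per-position base counts over spliced CDS references
#'
#' Builds a transcript-strand pileup from simple gapless alignments
#' (`gene_id`, `start`, `seq`, optional `qual` as phred+33).  Bases below
#' `minBaseQual` are excluded; the reported depth is the number of counted
#' bases at the position, so reads with a deletion or low-quality call at
#' a site do not contribute to its depth.
#'
#' @param alignments data.frame with columns `gene_id`, `start` (1-based
#'   position of the first read base on the spliced CDS), `seq`, and
#'   optionally `qual`.
#' @param cdsSeqs Named character vector of spliced CDS reference
#'   sequences (transcript orientation).
#' @param minBaseQual Minimum base quality when `qual` present
#'   (default 20).
#' @return data.frame: `gene_id`, `cds_pos`, `ref_base`, `depth`,
#'   `A`, `C`, `G`, `T`.
#' @export
pileupFromAlignments <- function(alignments, cdsSeqs, minBaseQual = 20L) {
  out <- list()
  for (g in unique(alignments$gene_id)) {
    if (!g %in% names(cdsSeqs)) {
      warning("gene absent from references, skipped: ", g)
      next
    }
    ref <- cdsSeqs[[g]]
    gl <- nchar(ref)
    al <- alignments[alignments$gene_id == g, , drop = FALSE]
    counts <- matrix(0L, nrow = 4L, ncol = gl,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    for (r in seq_len(nrow(al))) {
      sq <- al$seq[r]
      len <- nchar(sq)
      pos <- al$start[r] + seq_len(len) - 1L
      keep <- pos >= 1L & pos <= gl
      code <- match(strsplit(sq, "")[[1]], c("A", "C", "G", "T"))
      if (!is.null(al$qual) && !is.na(al$qual[r]) && nzchar(al$qual[r])) {
        q <- utf8ToInt(al$qual[r]) - 33L
        keep <- keep & q >= minBaseQual
      }
      keep <- keep & !is.na(code)
      idx <- (pos[keep] - 1L) * 4L + code[keep]
      tab <- tabulate(idx, nbins = gl * 4L)
      counts <- counts + matrix(tab, nrow = 4L)
    }
    refb <- strsplit(ref, "")[[1]]
    out[[g]] <- data.frame(
      gene_id = g, cds_pos = seq_len(gl), ref_base = refb,
      depth = as.integer(colSums(counts)),
      A = counts["A", ], C = counts["C", ], G = counts["G", ],
      T = counts["T", ], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), cds_pos = integer(0),
                      ref_base = character(0), depth = integer(0),
                      A = integer(0), C = integer(0), G = integer(0),
                      T = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pileup from a SAM file of reads aligned to spliced CDS references
#'
#' Converts the SAM to BAM ([Rsamtools::asBam]) and tallies nucleotides
#' per position with [Rsamtools::pileup], applying base quality >= 20 and
#' mapping quality >= 20 (deletions and indels excluded), then joins the
#' transcript-strand reference base.
#'
#' @param samPath Path to a SAM file with header (`@SQ` lines for the CDS
#'   references).
#' @param cdsSeqs Named character vector of CDS reference sequences.
#' @param minBaseQual,minMapq Quality thresholds (default 20).
#' @return Same layout as [pileupFromAlignments()].
#' @export
pileupFromSam <- function(samPath, cdsSeqs, minBaseQual = 20L,
                          minMapq = 20L) {
  bam <- Rsamtools::asBam(samPath,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = TRUE)
  pp <- Rsamtools::PileupParam(
    max_depth = 10000L, min_base_quality = as.integer(minBaseQual),
    min_mapq = as.integer(minMapq), min_nucleotide_depth = 1L,
    distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE, include_deletions = FALSE,
    include_insertions = FALSE)
  p <- Rsamtools::pileup(bam, pileupParam = pp)
  out <- list()
  for (g in names(cdsSeqs)) {
    gl <- nchar(cdsSeqs[[g]])
    sub <- p[as.character(p$seqnames) == g, , drop = FALSE]
    counts <- matrix(0L, nrow = 4L, ncol = gl,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    sub <- sub[as.character(sub$nucleotide) %in% rownames(counts), ,
               drop = FALSE]
    if (nrow(sub))
      counts[cbind(match(as.character(sub$nucleotide), rownames(counts)),
                   sub$pos)] <- sub$count
    out[[g]] <- data.frame(
      gene_id = g, cds_pos = seq_len(gl),
      ref_base = strsplit(cdsSeqs[[g]], "")[[1]],
      depth = as.integer(colSums(counts)),
      A = counts["A", ], C = counts["C", ], G = counts["G", ],
      T = counts["T", ], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call RNA-editing sites from a transcript-strand pileup
#'
#' One site per (position, alternative base) passing both filters: depth
#' at least `minDepth` and alternative-base support at least `minFraction`
#' of the depth (both inclusive).  Efficiency is the supporting fraction.
#'
#' @param pileup Output of [pileupFromAlignments()] / [pileupFromSam()].
#' @param genes Optional `GRanges` from [readGffGenes()] to map CDS
#'   positions back to genome coordinates.
#' @param cdsSeqs Optional named CDS sequences, used to annotate codons
#'   and amino-acid changes.
#' @param minDepth Minimum depth (default 10).
#' @param minFraction Minimum edited-read fraction (default 0.10).
#' @return data.frame of editing sites: `gene_id`, `cds_pos`,
#'   `genome_pos`, `ref_base`, `alt_base`, `edit_type`, `edited_count`,
#'   `depth`, `efficiency`, `codon_position`, `aa_change`.
#' @export
callEditingSites <- function(pileup, genes = NULL, cdsSeqs = NULL,
                             minDepth = 10L, minFraction = 0.10) {
  bases <- c("A", "C", "G", "T")
  rows <- list()
  keepDepth <- pileup$depth >= minDepth
  pu <- pileup[keepDepth, , drop = FALSE]
  for (b in bases) {
    alt <- pu[pu$ref_base != b & pu[[b]] / pu$depth >= minFraction &
                pu[[b]] > 0L, , drop = FALSE]
    if (!nrow(alt)) next
    alt$alt_base <- b
    rows[[b]] <- alt
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), cds_pos = integer(0),
                      genome_pos = integer(0), ref_base = character(0),
                      alt_base = character(0), edit_type = character(0),
                      edited_count = integer(0), depth = integer(0),
                      efficiency = numeric(0), codon_position = integer(0),
                      aa_change = character(0)))
  x <- do.call(rbind, rows)
  x$edited_count <- as.integer(x[cbind(seq_len(nrow(x)),
                                       match(x$alt_base, names(x)))])
  x$edit_type <- classifyEdit(x$ref_base, x$alt_base)
  x$efficiency <- x$edited_count / x$depth
  x$codon_position <- ((x$cds_pos - 1L) %% 3L) + 1L
  x$genome_pos <- NA_integer_
  if (!is.null(genes)) {
    x$genome_pos <- vapply(seq_len(nrow(x)), function(i)
      as.integer(cdsPosToGenome(genes, x$gene_id[i], x$cds_pos[i])), 1L)
  }
  x$aa_change <- NA_character_
  if (!is.null(cdsSeqs)) {
    x$aa_change <- vapply(seq_len(nrow(x)), function(i) {
      ref <- cdsSeqs[[x$gene_id[i]]]
      if (is.null(ref)) return(NA_character_)
      c0 <- (x$cds_pos[i] - 1L) %/% 3L * 3L + 1L
      if (c0 + 2L > nchar(ref)) return(NA_character_)
      codon <- substr(ref, c0, c0 + 2L)
      mut <- codon
      substr(mut, x$codon_position[i], x$codon_position[i]) <-
        x$alt_base[i]
      paste0(translateCodon(codon), (x$cds_pos[i] - 1L) %/% 3L + 1L,
             translateCodon(mut))
    }, "")
  }
  ord <- order(x$gene_id, x$cds_pos, x$alt_base)
  x <- x[ord, c("gene_id", "cds_pos", "genome_pos", "ref_base",
                "alt_base", "edit_type", "edited_count", "depth",
                "efficiency", "codon_position", "aa_change")]
  rownames(x) <- NULL
  x
}

#' @noRd
translateCodon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) "X" else aa
}

#' Remove candidate sites supported by genomic (DNA) variation
#'
#' A candidate editing site is a SNP, not editing, when whole-genome DNA
#' reads support the alternative base above `maxDnaAltFraction`.  Sites
#' without DNA coverage are retained but flagged unverified.
#'
#' @param sites Candidate sites from [callEditingSites()].
#' @param dnaPileup DNA pileup over the same CDS coordinates (layout of
#'   [pileupFromAlignments()]).
#' @param maxDnaAltFraction Maximum tolerated DNA alt fraction
#'   (default 0.05).
#' @return `sites` filtered, with added logical column `dna_verified`.
#' @export
filterGenomicVariants <- function(sites, dnaPileup,
                                  maxDnaAltFraction = 0.05) {
  if (!nrow(sites)) { sites$dna_verified <- logical(0); return(sites) }
  key <- paste(dnaPileup$gene_id, dnaPileup$cds_pos)
  idx <- match(paste(sites$gene_id, sites$cds_pos), key)
  verified <- !is.na(idx) & dnaPileup$depth[idx] > 0L
  altFrac <- rep(0, nrow(sites))
  has <- which(verified)
  if (length(has)) {
    altFrac[has] <- vapply(has, function(i)
      dnaPileup[[sites$alt_base[i]]][idx[i]] / dnaPileup$depth[idx[i]],
      1.0)
  }
  keep <- !(verified & altFrac > maxDnaAltFraction)
  out <- sites[keep, , drop = FALSE]
  out$dna_verified <- verified[keep]
  rownames(out) <- NULL
  out
}

#' Detect start-codon creation by RNA editing
#'
#' Reports an event when the genome-encoded start codon of a gene is not
#' `AUG` and a called editing site converts it to `AUG` (classically
#' `ACG -> AUG` by C-to-U editing at codon position 2).  Genes with a
#' non-AUG start and no such edit are reported as unedited non-canonical
#' starts.  Events below the depth filter are reported with a `low_depth`
#' flag rather than dropped, since start-codon sites are of special
#' interest even at modest coverage.
#'
#' @param geneId Gene identifier.
#' @param cdsSeq Spliced CDS sequence (transcript orientation).
#' @param sites Editing sites (called with `minDepth = 1` to allow the
#'   depth flag to be meaningful, or the default set).
#' @param minDepth Depth below which the event is flagged (default 10).
#' @return One-row data.frame: `gene_id`, `status`
#'   (`canonical` / `edited_start` / `unedited_noncanonical`),
#'   `genomic_codon`, `edited_codon`, `cds_pos`, `efficiency`,
#'   `low_depth`.
#' @export
detectStartCodonEditing <- function(geneId, cdsSeq, sites,
                                    minDepth = 10L) {
  codon <- toupper(substr(cdsSeq, 1L, 3L))
  res <- data.frame(gene_id = geneId, status = "canonical",
                    genomic_codon = chartr("T", "U", codon),
                    edited_codon = NA_character_, cds_pos = NA_integer_,
                    efficiency = NA_real_, low_depth = NA,
                    stringsAsFactors = FALSE)
  if (codon == "ATG") return(res)
  cand <- sites[sites$gene_id == geneId & sites$cds_pos <= 3L, ,
                drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    mut <- codon
    substr(mut, cand$cds_pos[i], cand$cds_pos[i]) <- cand$alt_base[i]
    if (mut == "ATG") {
      res$status <- "edited_start"
      res$edited_codon <- "AUG"
      res$cds_pos <- cand$cds_pos[i]
      res$efficiency <- cand$efficiency[i]
      res$low_depth <- cand$depth[i] < minDepth
      return(res)
    }
  }
  res$status <- "unedited_noncanonical"
  res
}

#' Summarize called editing sites
#'
#' Per-gene site counts, the 12-type histogram, and efficiency bins:
#' below 50% (`< 0.5`), at or above 50%, and the near-complete subset
#' (`>= 0.99`).  Shares are percentages of the total, rounded half-up to
#' one decimal.
#'
#' @param sites Output of [callEditingSites()].
#' @param totalOverride Optional total used as the share denominator
#'   (defaults to `nrow(sites)`).
#' @return List with `total`, `per_gene`, `per_type`, `efficiency_bins`
#'   data.frames.
#' @export
summarizeEditing <- function(sites, totalOverride = NULL) {
  total <- if (is.null(totalOverride)) nrow(sites) else totalOverride
  perGene <- if (nrow(sites)) {
    x <- as.data.frame(table(gene_id = sites$gene_id),
                       stringsAsFactors = FALSE)
    names(x)[2] <- "n_sites"
    x
  } else data.frame(gene_id = character(0), n_sites = integer(0))
  types <- table(factor(sites$edit_type, levels = editTypeLevels()))
  perType <- data.frame(edit_type = names(types),
                        n_sites = as.integer(types),
                        share_pct = if (total > 0)
                          roundHalfUp(100 * as.integer(types) / total, 1L)
                        else 0)
  nBelow <- sum(sites$efficiency < 0.5)
  nAbove <- sum(sites$efficiency >= 0.5)
  nNear <- sum(sites$efficiency >= 0.99)
  bins <- data.frame(
    bin = c("below_50", "at_or_above_50", "near_100"),
    n_sites = c(nBelow, nAbove, nNear),
    share_pct = if (total > 0)
      roundHalfUp(100 * c(nBelow, nAbove, nNear) / total, 1L) else
        c(0, 0, 0))
  list(total = total, per_gene = perGene, per_type = perType,
       efficiency_bins = bins)
}
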