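#' Read genome sequences from a FASTA file
#'
#' Sequences are uppercased and `U` is mapped to `T`.  Circularity is not a
#' property of the FASTA format, so it is supplied by the caller.
#'
#' @param path Path to a (possibly multi-line) FASTA file.
#' @param circular Logical, recycled over records.
#' @return A list of [CircularGenome-class] objects, in file order.
#' @export
readFastaGenomes <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  # read as raw strings first: DNA parsing would silently drop invalid
  # letters, and U must map to T
  ss <- try(Biostrings::readBStringSet(path, format = "fasta"),
            silent = TRUE)
  if (inherits(ss, "try-error") || length(ss) == 0L)
    stop("format error: empty or malformed FASTA: ", path)
  circular <- rep_len(circular, length(ss))
  ids <- sub("\\s.*$", "", names(ss))
  lapply(seq_along(ss), function(i)
    CircularGenome(as.character(ss[[i]]), id = ids[i],
                   circular = circular[i]))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector, `DNAStringSet`, or list of
#'   `CircularGenome` objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
  if (is.list(seqs) && all(vapply(seqs, is, TRUE, "CircularGenome"))) {
    nm <- vapply(seqs, function(g) g@id, "")
    seqs <- DNAStringSet(vapply(seqs, function(g) as.character(g@sequence),
                                ""))
    names(seqs) <- nm
  } else if (is.character(seqs)) {
    seqs <- DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] operating on plain
#' character vectors; `N` maps to `N`.
#'
#' @param seq Character vector of DNA strings (or a `DNAString`).
#' @return Character vector of reverse complements.
#' @export
revComp <- function(seq) {
  if (is(seq, "DNAString"))
    return(as.character(reverseComplement(seq)))
  as.character(reverseComplement(DNAStringSet(seq)))
}

#' Extract a substring from a circular genome with wrap-around
#'
#' Coordinates are 1-based inclusive.  On a circular genome, `start > end`
#' wraps around the origin (e.g. `start = n-1, end = 2` returns 4 bases).
#' On a linear genome, coordinates outside `[1, length]` are an error.
#'
#' @param genome A [CircularGenome-class] (or plain character string,
#'   treated as circular).
#' @param start,end 1-based inclusive positions, each in `[1, length]`.
#' @return Character string of the extracted sequence.
#' @export
circularSubstring <- function(genome, start, end) {
  if (is.character(genome)) genome <- CircularGenome(genome)
  n <- length(genome)
  s <- as.character(genome@sequence)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < 1L ||
      start > n || end > n)
    stop("coordinate error: start/end must lie in [1, ", n, "]")
  if (start <= end) return(substr(s, start, end))
  if (!genome@circular)
    stop("coordinate error: start > end on a linear sequence")
  paste0(substr(s, start, n), substr(s, 1L, end))
}

#' Extract an arc of given length with wrap-around, allowing 0 length
#' @noRd
circularArc <- function(genome, start, len) {
  if (len <= 0L) return("")
  n <- length(genome)
  start <- ((start - 1L) %% n) + 1L
  end <- ((start + len - 2L) %% n) + 1L
  circularSubstring(genome, start, end)
}

#' GC content of a DNA sequence
#'
#' Fraction (G+C)/(A+C+G+T); `N` bases are excluded from the denominator.
#'
#' @param seq Character string, `DNAString`, or [CircularGenome-class].
#' @param percent If `TRUE` return a percentage rounded to 2 decimals
#'   (half-up), as conventionally reported; otherwise a fraction.
#' @return Numeric scalar.
#' @export
gcContent <- function(seq, percent = FALSE) {
  if (is(seq, "CircularGenome")) seq <- seq@sequence
  if (is.character(seq)) seq <- DNAString(toupper(seq))
  af <- Biostrings::alphabetFrequency(seq)
  acgt <- sum(af[c("A", "C", "G", "T")])
  if (acgt == 0L) stop("undefined: sequence has no A/C/G/T bases")
  frac <- sum(af[c("G", "C")]) / acgt
  if (percent) roundHalfUp(100 * frac, 2L) else frac
}

#' Read protein-coding gene models from a GFF3 file
#'
#' CDS features are grouped per gene (via the `ID`, `Parent` or
#' `gene_id` attribute), with exons sorted in genomic order.  The returned
#' object is a [GenomicRanges::GRanges] of CDS exons with metadata columns
#' `gene_id`, `feature_type` and `pseudo`.
#'
#' @param path Path to a GFF3 file.
#' @return A `GRanges` of CDS/tRNA/rRNA exons.
#' @export
readGffGenes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("CDS", "tRNA", "rRNA")
  gr <- gr[keep]
  # gene grouping preference: Parent, then gene_id, then the feature ID
  ids <- rep(NA_character_, length(gr))
  if (!is.null(gr$Parent)) {
    ids <- vapply(gr$Parent, function(p)
      if (length(p)) as.character(p[1]) else NA_character_, "")
  }
  if (!is.null(gr$gene_id))
    ids <- ifelse(is.na(ids) | !nzchar(ids), gr$gene_id, ids)
  if (!is.null(gr$ID))
    ids <- ifelse(is.na(ids) | !nzchar(ids), gr$ID, ids)
  if (any(is.na(ids) | !nzchar(ids)))
    stop("format error: CDS feature without ID/Parent/gene_id attribute")
  gr$gene_id <- as.character(ids)
  gr$feature_type <- as.character(gr$type)
  if (is.null(gr$pseudo)) gr$pseudo <- FALSE
  gr$pseudo <- isTRUE(gr$pseudo) | gr$pseudo %in% c("true", "TRUE", TRUE)
  gr <- gr[order(gr$gene_id, GenomicRanges::start(gr))]
  # per-gene sanity: CDS length divisible by 3 unless flagged pseudo
  cds <- gr[gr$feature_type == "CDS"]
  if (length(cds)) {
    len <- tapply(GenomicRanges::width(cds), cds$gene_id, sum)
    ps <- tapply(cds$pseudo, cds$gene_id, any)
    bad <- names(len)[len %% 3L != 0L & !ps]
    if (length(bad))
      warning("CDS length not divisible by 3 (flagged, not dropped): ",
              paste(bad, collapse = ", "))
  }
  gr
}

#' Spliced transcript sequence of a gene, in transcript orientation
#'
#' Exons are concatenated in genomic order; minus-strand genes are returned
#' as the reverse complement of the concatenation (i.e. 5'->3' of the
#' transcript).
#'
#' @param genome A [CircularGenome-class].
#' @param genes `GRanges` from [readGffGenes()] (or equivalent).
#' @param geneId Gene identifier to splice.
#' @return Character string: the spliced CDS in transcript orientation.
#' @export
spliceTranscript <- function(genome, genes, geneId) {
  ex <- genes[genes$gene_id == geneId]
  if (!length(ex)) stop("gene absent from annotation: ", geneId)
  ex <- ex[order(GenomicRanges::start(ex))]
  pieces <- vapply(seq_along(ex), function(i)
    circularSubstring(genome, GenomicRanges::start(ex)[i],
                      GenomicRanges::end(ex)[i]), "")
  tx <- paste(pieces, collapse = "")
  if (as.character(GenomicRanges::strand(ex)[1]) == "-") tx <- revComp(tx)
  tx
}

#' Map a spliced-transcript position back to the genome
#' @noRd
cdsPosToGenome <- function(genes, geneId, cdsPos) {
  ex <- genes[genes$gene_id == geneId]
  ex <- ex[order(GenomicRanges::start(ex))]
  starts <- GenomicRanges::start(ex); ends <- GenomicRanges::end(ex)
  w <- ends - starts + 1L
  minus <- as.character(GenomicRanges::strand(ex)[1]) == "-"
  total <- sum(w)
  if (cdsPos < 1L || cdsPos > total) stop("cds position out of range")
  # position along the genomic (plus-strand) concatenation
  gpos <- if (minus) total - cdsPos + 1L else cdsPos
  cum <- cumsum(w)
  i <- which(gpos <= cum)[1]
  off <- gpos - c(0L, cum)[i]
  starts[i] + off - 1L
}

## ---- interval report form (Table-3 convention) ----

#' Format / parse repeat-unit intervals in report convention
#'
#' Internally the package uses 1-based ascending coordinates plus a strand.
#' Reports print `start-end` with minus-orientation units descending
#' (start > end), the convention used for mitogenome repeat tables.
#'
#' @param start,end 1-based ascending interval.
#' @param orientation `"+"` or `"-"`.
#' @return `formatInterval`: a string such as `"419510-419000"`.
#' @export
formatInterval <- function(start, end, orientation = "+") {
  ifelse(orientation == "-", paste0(end, "-", start),
         paste0(start, "-", end))
}

#' @rdname formatInterval
#' @param x A string produced by `formatInterval`.
#' @return `parseInterval`: list with `start`, `end` (ascending) and
#'   `orientation`.
#' @export
parseInterval <- function(x) {
  parts <- as.integer(strsplit(x, "-", fixed = TRUE)[[1]])
  if (length(parts) != 2L || anyNA(parts))
    stop("format error: interval must be 'a-b'")
  if (parts[1] > parts[2])
    list(start = parts[2], end = parts[1], orientation = "-")
  else list(start = parts[1], end = parts[2], orientation = "+")
}

#' Round half-up to a number of decimal places
#'
#' `round()` in R rounds half-to-even; reported percentages in this package
#' use conventional half-up rounding (e.g. 2.885 -> 2.89).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}
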