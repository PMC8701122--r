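#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @importFrom S4Vectors isTRUEorFALSE
NULL

#' CircularGenome: a (possibly circular) DNA molecule
#'
#' Container for a single mitochondrial genome sequence with wrap-around
#' coordinate semantics.  Plant mitogenomes are conventionally represented
#' as a single master circle; all substring extraction in this package
#' respects the circular topology when `circular = TRUE`.
#'
#' @slot id Single character, sequence identifier.
#' @slot sequence A [Biostrings::DNAString] over the alphabet A,C,G,T,N.
#' @slot circular Logical flag; when `TRUE` coordinate arithmetic wraps
#'   around the origin.
#'
#' @seealso [CircularGenome()], [circularSubstring()], [gcContent()]
#' @export
setClass("CircularGenome",
  representation(id = "character", sequence = "DNAString",
                 circular = "logical"))

setValidity("CircularGenome", function(object) {
  msg <- NULL
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@sequence) < 1L)
    msg <- c(msg, "sequence must have length > 0")
  af <- Biostrings::alphabetFrequency(object@sequence)
  bad <- sum(af) - sum(af[c("A", "C", "G", "T", "N")])
  if (bad > 0L)
    msg <- c(msg, "sequence alphabet restricted to {A,C,G,T,N}")
  if (!isTRUEorFALSE(object@circular))
    msg <- c(msg, "'circular' must be TRUE or FALSE")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CircularGenome
#'
#' @param sequence A [Biostrings::DNAString], plain character string, or
#'   anything coercible to `DNAString`.  Lowercase is accepted and
#'   uppercased; `U` is mapped to `T`.
#' @param id Sequence identifier.
#' @param circular Logical; `TRUE` (default) for a circular molecule.
#'
#' @return A [CircularGenome-class] object.
#' @examples
#' g <- CircularGenome("acgttg", id = "toy")
#' circularSubstring(g, 5, 2)  # wraps: "TGAC"
#' @export
CircularGenome <- function(sequence, id = "genome", circular = TRUE) {
  if (is.character(sequence)) {
    sequence <- chartr("uU", "tT", sequence)
    sequence <- toupper(sequence)
  }
  seq <- try(DNAString(sequence), silent = TRUE)
  if (inherits(seq, "try-error"))
    stop("format error: sequence contains non-IUPAC DNA characters")
  af <- Biostrings::alphabetFrequency(seq)
  if (sum(af) - sum(af[c("A", "C", "G", "T", "N")]) > 0)
    stop("format error: sequence alphabet restricted to {A,C,G,T,N}")
  new("CircularGenome", id = as.character(id), sequence = seq,
      circular = isTRUE(circular))
}

#' @describeIn CircularGenome-class genome length in bp
#' @param x,object A `CircularGenome`.
#' @export
setMethod("length", "CircularGenome", function(x) length(x@sequence))

#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @describeIn CircularGenome-class the sequence as a `DNAString`
#' @export
setMethod("genomeSeq", "CircularGenome", function(x) x@sequence)

#' @export
setGeneric("isCircularGenome",
           function(x) standardGeneric("isCircularGenome"))

#' @describeIn CircularGenome-class circularity flag
#' @export
setMethod("isCircularGenome", "CircularGenome", function(x) x@circular)

setMethod("show", "CircularGenome", function(object) {
  cat(sprintf("CircularGenome '%s': %s bp, %s\n", object@id,
              format(length(object@sequence), big.mark = ","),
              if (object@circular) "circular" else "linear"))
})

#' ConformationPair: master vs alternative junction references
#'
#' For one repeat pair, the four junction reference sequences used to
#' classify spanning long reads: two junctions from the master circle (each
#' repeat unit with its own flanks) and two from the explicitly constructed
#' recombinant molecule(s) (each repeat copy with crossed flanks).
#'
#' @slot repeatId Repeat identifier.
#' @slot flank Flank size in bp used on each side of the repeat.
#' @slot masterJunctions `DNAStringSet` of length 2.
#' @slot altJunctions `DNAStringSet` of length 2.
#' @slot informative `FALSE` when an alternative junction equals a master
#'   junction (indistinguishable flanks); such pairs cannot be assayed.
#' @slot truncated `TRUE` when a flank was truncated because the genome arc
#'   between the units was shorter than the requested flank.
#' @export
setClass("ConformationPair",
  representation(repeatId = "character", flank = "integer",
                 masterJunctions = "DNAStringSet",
                 altJunctions = "DNAStringSet",
                 informative = "logical", truncated = "logical"))

setValidity("ConformationPair", function(object) {
  msg <- NULL
  if (length(object@masterJunctions) != 2L)
    msg <- c(msg, "need exactly 2 master junctions")
  if (length(object@altJunctions) != 2L)
    msg <- c(msg, "need exactly 2 alternative junctions")
  if (object@flank < 0L) msg <- c(msg, "flank must be >= 0")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ConformationPair", function(object) {
  cat(sprintf(
    "ConformationPair '%s': flank %d bp, junction lengths %s | %s%s\n",
    object@repeatId, object@flank,
    paste(Biostrings::width(object@masterJunctions), collapse = ","),
    paste(Biostrings::width(object@altJunctions), collapse = ","),
    if (!object@informative) " [uninformative]" else ""))
})

#' @export
setGeneric("masterJunctions", function(x) standardGeneric("masterJunctions"))
#' @describeIn ConformationPair-class master-circle junction sequences
#' @param x,object A `ConformationPair`.
#' @export
setMethod("masterJunctions", "ConformationPair", function(x) x@masterJunctions)

#' @export
setGeneric("altJunctions", function(x) standardGeneric("altJunctions"))
#' @describeIn ConformationPair-class alternative-conformation junctions
#' @export
setMethod("altJunctions", "ConformationPair", function(x) x@altJunctions)

#' @export
setGeneric("isInformative", function(x) standardGeneric("isInformative"))
#' @describeIn ConformationPair-class can reads distinguish the conformations?
#' @export
setMethod("isInformative", "ConformationPair", function(x) x@informative)
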