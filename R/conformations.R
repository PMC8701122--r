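#' Rotate a circular genome so that `newStart` becomes position 1
#' @noRd
rotateGenome <- function(genome, newStart) {
  n <- length(genome)
  if (newStart == 1L) return(genome)
  s <- circularSubstring(genome, newStart,
                         ((newStart - 2L) %% n) + 1L)
  CircularGenome(s, id = genome@id, circular = TRUE)
}

#' Explicitly construct the recombinant molecule(s) for a repeat pair
#'
#' Homologous recombination between the two units of a direct repeat
#' subdivides the master circle into two subcircles, each carrying one
#' (hybrid) repeat copy; recombination between inverted repeats inverts
#' the arc between the units within a single circle.  For mismatched
#' copies the crossover breakpoint defaults to the repeat midpoint — for
#' junction references the choice is unobservable (any breakpoint inside
#' the repeat yields the same junction flanks) — while read simulators
#' draw it uniformly per recombinant molecule via `crossover`.
#'
#' All construction is done in a rotated frame with unit 1 at position 1,
#' then returned as explicit circular molecules.
#'
#' @param genome A [CircularGenome-class].
#' @param rp One row of the [findRepeats()] data.frame (or a list with
#'   `start1`, `start2`, `length`, `orientation`).
#' @param crossover Crossover breakpoint as a fraction of the repeat
#'   length (default 0.5).
#' @return List with `kind` (`"subdivision"` or `"inversion"`),
#'   `molecules` (character vector of circular molecule sequences),
#'   `repeat_at` (integer start of each repeat copy in its molecule, all
#'   copies of length `rp$length`), and `segments` (list of data.frames
#'   describing each molecule as oriented master-frame segments).
#' @export
recombinantMolecules <- function(genome, rp, crossover = 0.5) {
  n <- length(genome)
  L <- as.integer(rp$length)
  s1 <- as.integer(rp$start1); s2 <- as.integer(rp$start2)
  rot <- rotateGenome(genome, s1)
  # rotated coordinates: unit1 at [1, L]
  p2 <- ((s2 - s1) %% n) + 1L          # unit2 start, rotated
  U1 <- circularArc(rot, 1L, L)
  U2 <- circularArc(rot, p2, L)        # ascending-arc sequence of unit2
  lenB <- p2 - L - 1L                  # arc between end(U1) and start(U2)
  lenC <- n - (p2 + L - 1L)            # arc after U2 back to origin
  if (lenB < 0L || lenC < 0L)
    stop("repeat units overlap; no recombinant molecule")
  B <- circularArc(rot, L + 1L, lenB)
  C <- circularArc(rot, p2 + L, lenC)
  mid <- max(1L, min(L - 1L, as.integer(round(L * crossover))))
  seg <- function(start, end, strand, role)
    data.frame(start = start, end = end, strand = strand, role = role,
               stringsAsFactors = FALSE)
  # segment coordinates reported in the rotated master frame
  if (rp$orientation == "direct") {
    copy1 <- paste0(substr(U2, 1L, mid), substr(U1, mid + 1L, L))
    copy2 <- paste0(substr(U1, 1L, mid), substr(U2, mid + 1L, L))
    mol1 <- paste0(copy1, B)
    mol2 <- paste0(copy2, C)
    list(kind = "subdivision",
         molecules = c(mol1, mol2),
         repeat_at = c(1L, 1L),
         segments = list(
           rbind(seg(p2, p2 + mid - 1L, "+", "repeat(u2:1..mid)"),
                 seg(mid + 1L, L, "+", "repeat(u1:mid+1..L)"),
                 seg(L + 1L, L + lenB, "+", "arcB")),
           rbind(seg(1L, mid, "+", "repeat(u1:1..mid)"),
                 seg(p2 + mid, p2 + L - 1L, "+", "repeat(u2:mid+1..L)"),
                 seg(p2 + L, n, "+", "arcC"))))
  } else {
    V <- revComp(U2)                   # unit2 in matched (minus) orientation
    mol <- paste0(substr(U1, 1L, mid),
                  substr(V, mid + 1L, L),
                  revComp(B),
                  revComp(substr(U1, mid + 1L, L)),
                  substr(U2, L - mid + 1L, L),
                  C)
    stopifnot(nchar(mol) == n)
    list(kind = "inversion",
         molecules = mol,
         repeat_at = c(1L, L + lenB + 1L),
         segments = list(
           rbind(seg(1L, mid, "+", "repeat(u1:1..mid)"),
                 seg(p2 + mid, p2 + L - 1L, "-", "repeat(u2-half,inv)"),
                 seg(L + 1L, p2 - 1L, "-", "arcB(inverted)"),
                 seg(mid + 1L, L, "-", "repeat(u1-half,inv)"),
                 seg(p2, p2 + mid - 1L, "+", "repeat(u2:mid-tail)"),
                 seg(p2 + L, n, "+", "arcC"))))
  }
}

#' Build master and alternative junction references for a repeat pair
#'
#' Master junctions are the two repeat units each with `flank` bp of their
#' own genomic context; alternative junctions are extracted around the
#' repeat copies of the explicitly constructed recombinant molecule(s)
#' (see [recombinantMolecules()]).  Long reads that completely cover a
#' junction discriminate the conformations.
#'
#' When a molecule is too short to provide full flanks the effective flank
#' is reduced (and `truncated` flagged).  When any alternative junction
#' equals a master junction (e.g. identical flanks on both units) the pair
#' is flagged uninformative.
#'
#' @param genome A [CircularGenome-class].
#' @param rp One row of the [findRepeats()] data.frame.
#' @param flank Flank size in bp (default 1000).
#' @return A [ConformationPair-class].
#' @export
buildConformations <- function(genome, rp, flank = 1000L) {
  n <- length(genome)
  L <- as.integer(rp$length)
  flank <- as.integer(flank)
  rec <- recombinantMolecules(genome, rp)
  molLens <- nchar(rec$molecules)
  f <- min(flank, (min(n, molLens) - L) %/% 2L)
  f <- max(f, 0L)
  truncated <- f < flank

  jm1 <- circularArc(genome, ((rp$start1 - f - 1L) %% n) + 1L, L + 2L * f)
  jm2 <- circularArc(genome, ((rp$start2 - f - 1L) %% n) + 1L, L + 2L * f)
  altJ <- character(2)
  for (i in seq_along(rec$repeat_at)) {
    mol <- CircularGenome(rec$molecules[[min(i, length(rec$molecules))]],
                          circular = TRUE)
    st <- rec$repeat_at[i]
    altJ[i] <- circularArc(mol, ((st - f - 1L) %% length(mol)) + 1L,
                           L + 2L * f)
  }
  informative <- !(altJ[1] %in% c(jm1, jm2)) && !(altJ[2] %in% c(jm1, jm2))
  new("ConformationPair",
      repeatId = as.character(rp$repeat_id), flank = f,
      masterJunctions = DNAStringSet(c(jm1, jm2)),
      altJunctions = DNAStringSet(altJ),
      informative = informative, truncated = truncated)
}

#' Enumerate the alternative genome configurations for selected repeats
#'
#' For each repeat pair, the isomer set produced by one intramolecular
#' recombination event: direct repeats subdivide the master circle into
#' two smaller circles, inverted repeats invert the arc between the units.
#' Total segment length is conserved (equals the genome length).
#'
#' @param genome A [CircularGenome-class].
#' @param repeats [findRepeats()]-style data.frame (selected rows).
#' @return A list with one element per repeat: `repeat_id`, `kind`,
#'   `molecule_lengths`, `segments`.
#' @export
enumerateIsomers <- function(genome, repeats) {
  lapply(seq_len(nrow(repeats)), function(i) {
    rp <- repeats[i, ]
    rec <- recombinantMolecules(genome, rp)
    list(repeat_id = rp$repeat_id, kind = rec$kind,
         molecule_lengths = nchar(rec$molecules),
         segments = rec$segments)
  })
}

#' Write the four junction references of conformation pairs to FASTA
#'
#' Records are named `{repeat_id}.{master|alt}.{1|2}`.
#'
#' @param cps List of [ConformationPair-class] objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeJunctionFasta <- function(cps, path) {
  seqs <- character(0)
  for (cp in cps) {
    v <- c(as.character(cp@masterJunctions), as.character(cp@altJunctions))
    names(v) <- paste0(cp@repeatId, c(".master.1", ".master.2",
                                      ".alt.1", ".alt.2"))
    seqs <- c(seqs, v)
  }
  writeFasta(seqs, path)
}
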