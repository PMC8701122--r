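# Independent oracle for alternative junctions of an exact repeat pair:
# compose them from flanks and the repeat, without molecule construction.
altJunctionsByFormula <- function(g, rp, f) {
  n <- length(g)
  lf <- function(st) circularSubstring(g, ((st - f - 1) %% n) + 1,
                                       ((st - 2) %% n) + 1)
  rf <- function(en) circularSubstring(g, (en %% n) + 1,
                                       ((en + f - 1) %% n) + 1)
  R1 <- circularSubstring(g, rp$start1, rp$end1)
  if (rp$orientation == "direct") {
    c(paste0(lf(rp$start2), R1, rf(rp$end1)),
      paste0(lf(rp$start1), R1, rf(rp$end2)))
  } else {
    # exact inverted: alternative = arc between units reverse-complemented
    # in place; junction 1 keeps u1's left flank, junction 2 u2's right
    c(paste0(lf(rp$start1), R1,
             revComp(circularSubstring(
               g, rp$start2 - f, rp$start2 - 1))),
      paste0(revComp(circularSubstring(g, rp$end1 + 1, rp$end1 + f)),
             circularSubstring(g, rp$start2, rp$end2), rf(rp$end2)))
  }
}

makeExactPair <- function(seed, orientation, L = 120, pre = 1500,
                          mid = 1300, post = 1700) {
  set.seed(seed)
  x <- rndDna(L)
  second <- if (orientation == "inverted") revComp(x) else x
  s <- paste0(rndDna(pre), x, rndDna(mid), second, rndDna(post))
  g <- CircularGenome(s)
  rp <- data.frame(repeat_id = "r1", orientation = orientation,
                   length = L, mismatches = 0L,
                   start1 = pre + 1L, end1 = pre + L,
                   start2 = pre + L + mid + 1L,
                   end2 = pre + L + mid + L, strand2 =
                     if (orientation == "inverted") "-" else "+")
  list(g = g, rp = rp)
}

test_that("alternative junctions equal the flank-composition oracle", {
  for (ori in c("direct", "inverted")) {
    tc <- makeExactPair(20 + (ori == "direct"), ori)
    cp <- buildConformations(tc$g, tc$rp, flank = 400)
    expect_true(isInformative(cp))
    expect_equal(cp@flank, 400L)
    expect_setequal(as.character(altJunctions(cp)),
                    altJunctionsByFormula(tc$g, tc$rp, 400))
    # master junctions are genome substrings around each unit
    expect_equal(as.character(masterJunctions(cp))[1],
                 circularSubstring(tc$g, tc$rp$start1 - 400,
                                   tc$rp$end1 + 400))
  }
})

test_that("origin-spanning repeat pairs build valid conformations", {
  set.seed(23)
  x <- rndDna(100)
  # unit2 wraps the origin
  s <- paste0(substr(x, 41, 100), rndDna(1800), x, rndDna(1500))
  g <- CircularGenome(paste0(s, substr(x, 1, 40)))
  n <- length(g)
  rp <- data.frame(repeat_id = "r1", orientation = "direct",
                   length = 100L, mismatches = 0L,
                   start1 = 1861L, end1 = 1960L,
                   start2 = n - 39L, end2 = 60L, strand2 = "+")
  cp <- buildConformations(g, rp, flank = 300)
  expect_true(isInformative(cp))
  expect_setequal(as.character(altJunctions(cp)),
                  altJunctionsByFormula(g, data.frame(
                    rp[1, c("repeat_id", "orientation", "length",
                            "start1", "end1", "strand2")],
                    start2 = n - 39, end2 = n - 39 + 99), 300))
  ji <- Biostrings::width(altJunctions(cp))
  expect_true(all(ji == 100 + 600))
})

test_that("mismatched copies recombine through midpoint hybrids", {
  set.seed(24)
  L <- 100
  x <- rndDna(L)
  x2 <- mutateAt(x, c(20, 80))
  s <- paste0(rndDna(1200), x, rndDna(1100), x2, rndDna(1300))
  g <- CircularGenome(s)
  rp <- data.frame(repeat_id = "r1", orientation = "direct", length = L,
                   mismatches = 2L, start1 = 1201L, end1 = 1200L + L,
                   start2 = 2401L, end2 = 2400L + L, strand2 = "+")
  rec <- recombinantMolecules(g, rp)
  expect_equal(rec$kind, "subdivision")
  mid <- L %/% 2
  hyb1 <- paste0(substr(x2, 1, mid), substr(x, mid + 1, L))
  hyb2 <- paste0(substr(x, 1, mid), substr(x2, mid + 1, L))
  expect_equal(substr(rec$molecules[1], 1, L), hyb1)
  expect_equal(substr(rec$molecules[2], 1, L), hyb2)
  # crossover position is configurable for simulators
  rec2 <- recombinantMolecules(g, rp, crossover = 0.1)
  expect_equal(substr(rec2$molecules[1], 1, L),
               paste0(substr(x2, 1, 10), substr(x, 11, L)))
})

test_that("identical flanks on both units are flagged uninformative", {
  set.seed(25)
  x <- rndDna(80)
  fl <- rndDna(1100)             # shared flank on both units
  s <- paste0(rndDna(1500), fl, x, fl, rndDna(1200), fl, x, fl,
              rndDna(1400))
  g <- CircularGenome(s)
  st1 <- 1500 + 1100 + 1
  st2 <- st1 + 80 + 1100 + 1200 + 1100
  rp <- data.frame(repeat_id = "r1", orientation = "direct", length = 80L,
                   mismatches = 0L, start1 = st1, end1 = st1 + 79L,
                   start2 = st2, end2 = st2 + 79L, strand2 = "+")
  cp <- buildConformations(g, rp, flank = 1000)
  expect_false(isInformative(cp))
  expect_equal(classifyRead(rndDna(3000), cp), "uninformative")
})

test_that("isomer sets conserve total segment length", {
  set.seed(26)
  for (ori in c("direct", "inverted")) {
    tc <- makeExactPair(26, ori)
    iso <- enumerateIsomers(tc$g, tc$rp)[[1]]
    expect_equal(iso$kind,
                 if (ori == "direct") "subdivision" else "inversion")
    expect_length(iso$molecule_lengths, if (ori == "direct") 2L else 1L)
    expect_equal(sum(iso$molecule_lengths), length(tc$g))
    segTot <- sum(vapply(iso$segments, function(sg)
      sum(sg$end - sg$start + 1), 1))
    expect_equal(segTot, length(tc$g))
  }
})

test_that("spanning reads vote correctly and trimmed coverage is rejected", {
  tc <- makeExactPair(27, "inverted", L = 200)
  cp <- buildConformations(tc$g, tc$rp, flank = 600)
  f <- cp@flank
  jm <- as.character(masterJunctions(cp))[1]
  # error-free read = master junction plus 200 bp extra on each side
  full <- circularSubstring(tc$g, tc$rp$start1 - f - 200,
                            tc$rp$end1 + f + 200)
  expect_equal(classifyRead(full, cp), "master")
  expect_equal(classifyRead(revComp(full), cp), "master")
  # read covering the repeat but only half of one flank: uninformative
  half <- circularSubstring(tc$g, tc$rp$start1 - f %/% 2,
                            tc$rp$end1 + f + 200)
  expect_equal(classifyRead(half, cp), "uninformative")
  # alternative molecule read with 5% errors votes alternative
  set.seed(27)
  rec <- recombinantMolecules(tc$g, tc$rp)
  mol <- CircularGenome(rec$molecules[1])
  nm <- length(mol)
  st <- ((rec$repeat_at[1] - f - 300 - 1) %% nm) + 1
  en <- ((rec$repeat_at[1] + tc$rp$length - 1 + f + 300 - 1) %% nm) + 1
  rd <- circularSubstring(mol, st, en)
  rdErr <- mutateReads(rd, 0.05, 0.03)
  expect_equal(classifyRead(rdErr, cp), "alternative")
})

test_that("direction-independence: swapping conformation roles swaps votes", {
  tc <- makeExactPair(28, "direct", L = 150)
  cp <- buildConformations(tc$g, tc$rp, flank = 500)
  swapped <- new("ConformationPair", repeatId = "sw", flank = cp@flank,
                 masterJunctions = altJunctions(cp),
                 altJunctions = masterJunctions(cp),
                 informative = TRUE, truncated = FALSE)
  set.seed(28)
  sp <- simulateSpanningReads(tc$g, tc$rp, n = 40, altFraction = 0.4,
                              flank = 500)
  a <- vapply(sp$seq, classifyRead, "", cp = cp, USE.NAMES = FALSE)
  b <- vapply(sp$seq, classifyRead, "", cp = swapped, USE.NAMES = FALSE)
  expect_equal(sum(a == "master"), sum(b == "alternative"))
  expect_equal(sum(a == "alternative"), sum(b == "master"))
  expect_equal(a == "ambiguous", b == "ambiguous")
})

test_that("recombination table reproduces printed percentage arithmetic", {
  counts <- data.frame(
    repeat_id = c("a", "b", "c"), length = c(511L, 393L, 111L),
    orientation = c("inverted", "inverted", "direct"),
    master_count = c(182L, 135L, 10L), alt_count = c(11L, 4L, 0L))
  tab <- recombinationTable(counts)
  expect_equal(tab$repeat_id, c("R1", "R2", "R3"))
  expect_equal(tab$master_pct, c(94.30, 97.12, 100.00))
  expect_equal(tab$alt_pct, c(5.70, 2.88, 0.00))
  expect_true(all(abs(tab$master_pct + tab$alt_pct - 100) <= 0.01))
  # zero-informative rows are suppressed with a warning
  z <- counts; z$master_count[2] <- 0L; z$alt_count[2] <- 0L
  expect_warning(tz <- recombinationTable(z), "zero informative")
  expect_equal(nrow(tz), 2L)
})

test_that("short-read screen flags mixtures and ignores pure master data", {
  cfg <- simConfig(
    seed = 29, genomeLength = 20000,
    plantedRepeats = data.frame(length = 200L, orientation = "direct",
                                mismatches = 2L, alt_fraction = 0.05),
    plantedGenes = data.frame(gene_id = "g1", length = 300L,
                              strand = "+", start_codon = "ATG",
                              in_repeat = NA),
    plantedEdits = data.frame(gene_id = "g1", cds_pos = 50L,
                              ref_base = "C", alt_base = "T",
                              efficiency = 0.5))
  sim <- simulateGenome(cfg)
  reps <- findRepeats(sim$genome, evalueMax = Inf, collapse = TRUE)
  expect_equal(nrow(reps), 1L)
  sr <- simulateShortReads(sim, nPairs = 12000)
  expect_equal(screenShortReads(sim$genome, reps,
                                c(sr$seq1, sr$seq2)), reps$repeat_id)
  # master conformation only: nothing flagged
  cfg0 <- cfg; cfg0$plantedRepeats$alt_fraction <- 0
  sim0 <- simulateGenome(cfg0)
  sr0 <- simulateShortReads(sim0, nPairs = 12000)
  expect_length(screenShortReads(sim0$genome, reps,
                                 c(sr0$seq1, sr0$seq2)), 0L)
  # identical units (no diagnostic positions) cannot be screened
  repsEq <- reps; repsEq$mismatches <- 0L
  repsEq$unit2_seq <- repsEq$unit1_seq
  expect_length(screenShortReads(sim$genome, repsEq,
                                 c(sr$seq1, sr$seq2)), 0L)
})
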