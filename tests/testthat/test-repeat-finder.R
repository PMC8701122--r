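test_that("planted exact repeats are recovered with correct coordinates", {
  set.seed(10)
  x <- rndDna(50)
  s <- paste0(rndDna(300), x, rndDna(200), x, rndDna(250))
  # force distinct bases at the copy boundaries so the planted repeat is
  # exactly maximal (chance matches would otherwise extend it)
  substr(s, 300, 300) <- "A"; substr(s, 550, 550) <- "C"
  substr(s, 351, 351) <- "G"; substr(s, 601, 601) <- "T"
  g <- CircularGenome(s, circular = FALSE)
  r <- findRepeats(g, evalueMax = Inf, maxMismatch = 0L)
  expect_equal(nrow(r), 1L)
  expect_equal(r$length, 50L)
  expect_equal(r$mismatches, 0L)
  expect_equal(r$orientation, "direct")
  expect_equal(r$start1, 301L)
  expect_equal(r$start2, 551L)
  # non-repetitive sequence: empty result
  expect_equal(nrow(findRepeats(CircularGenome(rndDna(100)),
                                evalueMax = Inf)), 0L)
})

test_that("every reported pair verifies its mismatch count on re-extraction", {
  set.seed(11)
  for (trial in 1:3) {
    s <- rndDna(1500)
    x <- rndDna(60)
    s <- paste0(s, x, rndDna(150), mutateAt(x, c(10, 40)), rndDna(150),
                revComp(mutateAt(x, 25)))
    g <- CircularGenome(s)
    r <- findRepeats(g, evalueMax = Inf)
    expect_gt(nrow(r), 0)
    for (i in seq_len(nrow(r)))
      expect_equal(hammingDist(r$unit1_seq[i], r$unit2_seq[i]),
                   r$mismatches[i])
  }
})

test_that("search equals the brute-force all-pairs enumeration", {
  set.seed(12)
  for (trial in 1:4) {
    x <- rndDna(55)
    y <- rndDna(42)
    s <- paste0(rndDna(400), x, rndDna(300), mutateAt(x, c(12, 30)),
                rndDna(200), y, rndDna(250), revComp(mutateAt(y, 21)),
                rndDna(150))
    g <- CircularGenome(s, circular = FALSE)
    got <- findRepeats(g, evalueMax = Inf)
    want <- oracleRepeats(s)
    expect_equal(repeatKey(got), repeatKey(want))
  }
})

test_that("repeat count is invariant under rotation of a circular genome", {
  set.seed(13)
  x <- rndDna(60)
  s <- paste0(rndDna(500), x, rndDna(400), revComp(x), rndDna(300),
              mutateAt(x, c(15, 45)), rndDna(200))
  g <- CircularGenome(s)
  base <- findRepeats(g, evalueMax = Inf)
  n <- nchar(s)
  for (shift in c(137, 987, n - 25)) {
    rot <- paste0(substr(s, shift + 1, n), substr(s, 1, shift))
    rr <- findRepeats(CircularGenome(rot), evalueMax = Inf)
    expect_equal(nrow(rr), nrow(base))
    expect_equal(sort(rr$length), sort(base$length))
    expect_equal(sort(rr$mismatches), sort(base$mismatches))
    expect_equal(table(rr$orientation), table(base$orientation))
  }
})

test_that("reverse-complementing the genome mirrors the repeat set", {
  set.seed(14)
  x <- rndDna(64)
  s <- paste0(rndDna(400), x, rndDna(350), mutateAt(x, 32), rndDna(300),
              revComp(x), rndDna(200))
  a <- findRepeats(CircularGenome(s, circular = FALSE), evalueMax = Inf)
  b <- findRepeats(CircularGenome(revComp(s), circular = FALSE),
                   evalueMax = Inf)
  n <- nchar(s)
  expect_equal(nrow(a), nrow(b))
  expect_equal(sort(a$length), sort(b$length))
  # coordinates mirror: a unit at [st, en] maps to [n-en+1, n-st+1]
  mirrored <- sort(paste(n - a$end2 + 1, n - a$end1 + 1))
  expect_equal(sort(paste(b$start1, b$start2)), mirrored)
})

test_that("repeat E-value follows the closed form and thresholds repeats", {
  expect_equal(repeatEvalue(30, 0, 508035), 508035^2 / 4^30,
               tolerance = 1e-12)
  expect_lt(repeatEvalue(30, 0, 508035), 1e-5)
  expect_gt(repeatEvalue(20, 3, 508035), 1e-5)
  # doubling length at 0 mismatches divides E by exactly 4^delta
  expect_equal(repeatEvalue(60, 0, 1e5) * 4^30, repeatEvalue(30, 0, 1e5),
               tolerance = 1e-9)
  # monotone: decreasing in length, increasing in mismatches
  ev <- repeatEvalue(30:60, 2, 5e5)
  expect_true(all(diff(ev) < 0))
  expect_true(all(diff(repeatEvalue(40, 0:3, 5e5)) > 0))
  # the filter is applied: a short repeat passes only with loose threshold
  set.seed(15)
  x <- rndDna(32)
  g <- CircularGenome(paste0(rndDna(200), x, rndDna(500), x, rndDna(200)))
  expect_equal(nrow(findRepeats(g, evalueMax = Inf, maxMismatch = 0L)), 1L)
  ev32 <- repeatEvalue(32, 0, 932)
  expect_equal(nrow(findRepeats(g, evalueMax = ev32 / 2,
                                maxMismatch = 0L)), 0L)
})

test_that("origin-spanning repeats are found on circular genomes", {
  set.seed(16)
  x <- rndDna(50)
  core <- paste0(substr(x, 11, 50), rndDna(300), x, rndDna(260))
  g <- CircularGenome(paste0(core, substr(x, 1, 10)))
  r <- findRepeats(g, evalueMax = Inf)
  expect_true(any(r$length >= 50 & (r$spans_origin1 | r$spans_origin2)))
  lin <- findRepeats(CircularGenome(paste0(core, substr(x, 1, 10)),
                                    circular = FALSE), evalueMax = Inf)
  expect_true(all(nchar(lin$unit1_seq) == lin$length))
})

test_that("collapse reduces nested maximal windows to one row per locus", {
  set.seed(17)
  x <- rndDna(120)
  g <- CircularGenome(paste0(rndDna(800), x, rndDna(700),
                             mutateAt(x, c(30, 60, 90)), rndDna(600)))
  full <- findRepeats(g, evalueMax = Inf)
  one <- findRepeats(g, evalueMax = Inf, collapse = TRUE)
  expect_gte(nrow(full), nrow(one))
  expect_equal(nrow(one), 1L)
  expect_gte(one$length, 120 - 1)
})

test_that("gene capture requires strict containment of a copy in each unit", {
  set.seed(18)
  cds <- paste0("ATG", rndDna(612), "TAA")      # 618 bp, nad3-like
  u1 <- rndDna(666)
  substr(u1, 25, 642) <- cds
  u2 <- u1
  s <- paste0(rndDna(1000), u1, rndDna(900), revComp(u2), rndDna(800))
  g <- CircularGenome(s)
  # unit1 at 1001, gene copy at 1001+24; unit2 (revcomp) at 2567, whose
  # gene copy sits at the mirrored offset 2567+24
  genes <- GenomicRanges::GRanges("g", IRanges::IRanges(
    start = c(1025, 2591), width = 618), strand = c("+", "-"))
  genes$gene_id <- "nad3"; genes$feature_type <- "CDS"; genes$pseudo <- FALSE
  reps <- findRepeats(g, evalueMax = Inf, collapse = TRUE)
  expect_equal(nrow(reps), 1L)
  cap <- detectGeneCapture(reps, genes, length(g))
  expect_equal(nrow(cap), 1L)
  expect_equal(cap$gene_id, "nad3")
  expect_equal(cap$copy_number, 2L)
  # a gene only 90% inside the units is not captured
  genes90 <- genes
  GenomicRanges::start(genes90)[1] <- 1025 - 80
  GenomicRanges::end(genes90)[1] <- 1025 - 80 + 617
  expect_equal(nrow(detectGeneCapture(reps, genes90[1], length(g))), 0L)
  # no repeats -> empty
  expect_equal(nrow(detectGeneCapture(reps[0, ], genes, length(g))), 0L)
})
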