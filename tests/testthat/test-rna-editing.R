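makePileupRow <- function(gene = "g", pos = 1L, ref = "C", depth = 0L,
                          A = 0L, C = 0L, G = 0L, T = 0L) {
  data.frame(gene_id = gene, cds_pos = pos, ref_base = ref,
             depth = depth, A = A, C = C, G = G, T = T,
             stringsAsFactors = FALSE)
}

test_that("pileup counts bases per position and respects base quality", {
  ref <- c(g = "ACGTACGTAC")
  al <- data.frame(gene_id = "g", start = c(1L, 1L, 3L),
                   seq = c("ACGTACGTAC", "ACTTACGTAC", "GTAC"),
                   stringsAsFactors = FALSE)
  pu <- pileupFromAlignments(al, ref)
  expect_equal(pu$depth, c(2L, 2L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L))
  expect_equal(pu$T[3], 1L)    # the planted G->T mismatch
  expect_equal(pu$G[3], 2L)
  expect_equal(pu$ref_base, strsplit(ref[["g"]], "")[[1]])
  # low-quality base at position 3 of read 2 removed from depth
  al$qual <- c(strrep("I", 10), paste0("II", rawToChar(as.raw(33 + 5)),
                                       strrep("I", 7)), "IIII")
  pu2 <- pileupFromAlignments(al, ref)
  expect_equal(pu2$depth[3], 2L)
  expect_equal(pu2$T[3], 0L)
})

test_that("pure-R pileup agrees with the samtools-based SAM pileup", {
  set.seed(30)
  ref <- c(gX = rndDna(400), gY = rndDna(250))
  al <- do.call(rbind, lapply(names(ref), function(g) {
    n <- 40
    st <- sample(nchar(ref[[g]]) - 99, n, replace = TRUE)
    sq <- substring(ref[[g]], st, st + 99)
    sq <- mutateReads(sq, 0.01, 0)
    data.frame(gene_id = g, start = st, seq = sq,
               stringsAsFactors = FALSE)
  }))
  pu <- pileupFromAlignments(al, ref)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeSam(al, ref, sam)
  pu2 <- pileupFromSam(sam, ref)
  for (col in c("depth", "A", "C", "G", "T"))
    expect_equal(pu[[col]], pu2[[col]], info = col)
})

test_that("minus-strand genes report edits on the transcript strand", {
  set.seed(31)
  # 30 bp single-exon minus-strand gene: genomic G->A mismatch appears as
  # C->U on the transcript
  core <- rndDna(30)
  substr(core, 12, 12) <- "G"   # genome plus strand
  g <- CircularGenome(paste0(rndDna(20), core, rndDna(20)),
                      circular = FALSE)
  genes <- GenomicRanges::GRanges("g", IRanges::IRanges(21, 50),
                                  strand = "-")
  genes$gene_id <- "m1"; genes$feature_type <- "CDS"; genes$pseudo <- FALSE
  tx <- spliceTranscript(g, genes, "m1")
  txPos <- 30 - (12 - 1)        # genome 32 -> transcript position
  expect_equal(substr(tx, txPos, txPos), "C")
  reads <- rep(tx, 12)
  edited <- tx; substr(edited, txPos, txPos) <- "T"
  reads[1:6] <- edited
  al <- data.frame(gene_id = "m1", start = 1L, seq = reads,
                   stringsAsFactors = FALSE)
  pu <- pileupFromAlignments(al, c(m1 = tx))
  sites <- callEditingSites(pu, genes = genes, cdsSeqs = c(m1 = tx))
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$edit_type, "C-to-U")
  expect_equal(sites$cds_pos, txPos)
  expect_equal(sites$genome_pos, 32L)
  expect_equal(sites$efficiency, 0.5)
})

test_that("strand relabeling leaves the called edit-type set unchanged", {
  set.seed(32)
  tx <- rndDna(120)
  g1 <- CircularGenome(paste0(rndDna(40), tx, rndDna(40)),
                       circular = FALSE)
  genes1 <- GenomicRanges::GRanges("g", IRanges::IRanges(41, 160),
                                   strand = "+")
  genes1$gene_id <- "p"; genes1$feature_type <- "CDS"
  # the same molecule written from the other strand: gene now minus
  g2 <- CircularGenome(revComp(as.character(genomeSeq(g1))),
                       circular = FALSE)
  genes2 <- GenomicRanges::GRanges("g", IRanges::IRanges(41, 160),
                                   strand = "-")
  genes2$gene_id <- "p"; genes2$feature_type <- "CDS"
  expect_equal(spliceTranscript(g2, genes2, "p"), tx)
  reads <- rep(tx, 20)
  ed <- tx; substr(ed, 33, 33) <- setdiff(c("A", "C", "G", "T"),
                                          substr(tx, 33, 33))[1]
  reads[1:9] <- ed
  al <- data.frame(gene_id = "p", start = 1L, seq = reads)
  sPlus <- callEditingSites(
    pileupFromAlignments(al, c(p = spliceTranscript(g1, genes1, "p"))))
  sMinus <- callEditingSites(
    pileupFromAlignments(al, c(p = spliceTranscript(g2, genes2, "p"))))
  expect_equal(sPlus$edit_type, sMinus$edit_type)
  expect_equal(sPlus$cds_pos, sMinus$cds_pos)
  expect_equal(sPlus$efficiency, sMinus$efficiency)
})

test_that("depth and fraction filters are inclusive at the boundary", {
  pu <- rbind(
    makePileupRow(pos = 1L, depth = 9L, C = 0L, T = 9L),     # depth 9: out
    makePileupRow(pos = 2L, depth = 10L, C = 0L, T = 10L),   # depth 10: in
    makePileupRow(pos = 3L, depth = 100L, C = 91L, T = 9L),  # 9%: out
    makePileupRow(pos = 4L, depth = 100L, C = 90L, T = 10L)) # 10%: in
  sites <- callEditingSites(pu)
  expect_equal(sites$cds_pos, c(2L, 4L))
  expect_equal(sites$efficiency, c(1.0, 0.10))
  expect_equal(sites$edit_type, c("C-to-U", "C-to-U"))
})

test_that("multiple alternative bases at one site yield multiple records", {
  pu <- makePileupRow(pos = 7L, ref = "C", depth = 60L, C = 30L, T = 18L,
                      G = 12L)
  sites <- callEditingSites(pu)
  expect_equal(nrow(sites), 2L)
  expect_setequal(sites$edit_type, c("C-to-U", "C-to-G"))
  expect_equal(sum(sites$edited_count), 30L)
})

test_that("edit types cover exactly the 12 ordered pairs", {
  expect_equal(classifyEdit("C", "T"), "C-to-U")
  expect_equal(classifyEdit("T", "G"), "U-to-G")
  expect_equal(classifyEdit("A", "C"), "A-to-C")
  expect_error(classifyEdit("C", "C"), "logic")
  types <- outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                 Vectorize(function(a, b)
                   if (a == b) NA_character_ else classifyEdit(a, b)))
  expect_equal(sort(as.vector(types[!is.na(types)])),
               sort(mitorecomb:::editTypeLevels()))
})

test_that("genomic variants are filtered out; uncovered sites are flagged", {
  sites <- callEditingSites(rbind(
    makePileupRow(pos = 1L, depth = 40L, C = 20L, T = 20L),
    makePileupRow(pos = 2L, depth = 40L, C = 20L, T = 20L),
    makePileupRow(pos = 3L, depth = 40L, C = 20L, T = 20L)))
  dna <- rbind(
    makePileupRow(pos = 1L, depth = 50L, C = 25L, T = 25L),  # SNP
    makePileupRow(pos = 2L, depth = 50L, C = 50L, T = 0L),   # clean
    makePileupRow(pos = 3L, depth = 0L))                     # no coverage
  out <- filterGenomicVariants(sites, dna)
  expect_equal(out$cds_pos, c(2L, 3L))
  expect_equal(out$dna_verified, c(TRUE, FALSE))
})

test_that("start-codon editing events are detected with depth flags", {
  cds <- paste0("ACG", "GATTACA", "TAA")
  sites <- data.frame(gene_id = "nad1", cds_pos = 2L, genome_pos = NA,
                      ref_base = "C", alt_base = "T",
                      edit_type = "C-to-U", edited_count = 4L, depth = 6L,
                      efficiency = 4 / 6, codon_position = 2L,
                      aa_change = NA)
  ev <- detectStartCodonEditing("nad1", cds, sites)
  expect_equal(ev$status, "edited_start")
  expect_equal(ev$edited_codon, "AUG")
  expect_true(ev$low_depth)
  expect_equal(roundHalfUp(100 * ev$efficiency, 2), 66.67)
  # ACG start with no edit
  expect_equal(detectStartCodonEditing("rps4", cds, sites[0, ])$status,
               "unedited_noncanonical")
  # GUG start with no edit
  expect_equal(detectStartCodonEditing(
    "rpl16", paste0("GTG", "GATTACA", "TAA"), sites[0, ])$status,
    "unedited_noncanonical")
  # canonical AUG start
  expect_equal(detectStartCodonEditing(
    "nad7", paste0("ATG", "GATTACA", "TAA"), sites[0, ])$status,
    "canonical")
})

test_that("editing summary shares and efficiency bins add up", {
  n <- 480
  eff <- c(rep(0.995, 219), rep(0.7, 405 - 219), rep(0.3, 75))
  types <- c(rep("C-to-U", 432), rep("A-to-G", 20), rep("G-to-A", 15),
             rep("U-to-C", 10), rep("A-to-C", 2), rep("U-to-G", 1))
  sites <- data.frame(gene_id = rep(c("nad7", "nad2", "nad4", "cox1"),
                                    120),
                      edit_type = types, efficiency = eff)
  su <- summarizeEditing(sites)
  expect_equal(su$total, 480)
  expect_equal(sum(su$per_type$n_sites), 480)
  expect_equal(su$per_type$share_pct[su$per_type$edit_type == "C-to-U"],
               90.0)
  bins <- su$efficiency_bins
  expect_equal(bins$n_sites[bins$bin == "at_or_above_50"], 405)
  expect_equal(bins$share_pct[bins$bin == "at_or_above_50"], 84.4)
  expect_equal(bins$share_pct[bins$bin == "below_50"], 15.6)
  expect_equal(bins$n_sites[bins$bin == "near_100"], 219)
  # empty input gives an all-zero summary
  s0 <- summarizeEditing(sites[0, ])
  expect_equal(s0$total, 0)
  expect_equal(sum(s0$per_type$n_sites), 0)
})
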