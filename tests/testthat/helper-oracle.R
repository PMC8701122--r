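# Shared fixtures and independent oracles, built in code at test time.

rndDna <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutateAt <- function(seq, pos) {
  for (p in pos) {
    b <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }
  seq
}

# Brute-force enumeration of all maximal <=k-mismatch repeat pairs on a
# LINEAR sequence: every diagonal of the full comparison matrix is
# scanned and maximal windows are read off the mismatch positions.
# Independent of the package's seeded search; used as the ground truth.
oracleRepeats <- function(seq, k = 3L, minLen = 30L) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  rows <- list()
  emitDiag <- function(v1, v2, d, orientation) {
    # v1[i] vs v2[i + d], i = 1..(n - d), d >= 0 here
    len0 <- n - d
    if (len0 < minLen) return()
    mm <- which(v1[seq_len(len0)] != v2[seq_len(len0) + d])
    t <- length(mm)
    M <- c(0L, mm, len0 + 1L)
    if (t <= k) {
      wins <- cbind(1L, len0)
    } else {
      a <- seq_len(t - k + 1L)
      wins <- cbind(M[a] + 1L, M[a + k + 1L] - 1L)
    }
    for (r in seq_len(nrow(wins))) {
      ws <- wins[r, 1]; we <- wins[r, 2]
      len <- we - ws + 1L
      if (len < minLen) next
      rows[[length(rows) + 1L]] <<- data.frame(
        orientation = orientation, s1 = ws, s2 = ws + d, length = len,
        mismatches = sum(mm >= ws & mm <= we))
    }
  }
  for (d in seq_len(n - 1L)) emitDiag(v, v, d, "direct")
  v2 <- rev(chartr("ACGT", "TGCA", v))
  for (d in 0:(n - 1L)) emitDiag(v, v2, d, "inverted")
  for (d in seq_len(n - 1L)) emitDiag(v2, v, d, "inverted_sw")
  if (!length(rows)) return(emptyOracle())
  x <- do.call(rbind, rows)
  # map inverted runs (s2 on the reverse complement) back to genome
  # coordinates and canonicalize like a repeat table: unit1 leftmost,
  # overlapping units dropped, one row per unordered pair
  inv <- x$orientation == "inverted"
  sw <- x$orientation == "inverted_sw"   # roles swapped: s1 on revcomp
  u1 <- ifelse(sw, n - (x$s2 + x$length - 1L) + 1L, x$s1)
  u2 <- ifelse(inv, n - (x$s2 + x$length - 1L) + 1L,
               ifelse(sw, n - (x$s1 + x$length - 1L) + 1L + 0L, x$s2))
  u2[sw] <- x$s2[sw]
  u1[sw] <- n - (x$s1[sw] + x$length[sw] - 1L) + 1L
  x$orientation[inv | sw] <- "inverted"
  lo <- pmin(u1, u2); hi <- pmax(u1, u2)
  keep <- lo + x$length - 1L < hi           # units must not overlap
  x <- x[keep, ]; lo <- lo[keep]; hi <- hi[keep]
  key <- paste(x$orientation, lo, hi, x$length)
  d <- !duplicated(key)
  data.frame(orientation = x$orientation[d], start1 = lo[d],
             start2 = hi[d], length = x$length[d],
             mismatches = x$mismatches[d])
}

emptyOracle <- function() {
  data.frame(orientation = character(0), start1 = integer(0),
             start2 = integer(0), length = integer(0),
             mismatches = integer(0))
}

repeatKey <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(paste(df$orientation, df$start1, df$start2, df$length,
             df$mismatches))
}
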