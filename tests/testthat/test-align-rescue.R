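## The placement engine and the unique-minimum-mismatch rescue rule,
## checked against a naive all-position scan oracle.

mkRepeatRef <- function(seed = 5L, len = 4000L) {
  ## a toy chromosome carrying an exact 300 bp duplication and a diverged
  ## (2-mismatch) copy of another 300 bp block
  set.seed(seed)
  base <- randSeq(len)
  rep1 <- substr(base, 501, 800)
  base <- paste0(substr(base, 1, 2000), rep1, substr(base, 2301, len))
  near <- strsplit(substr(base, 1001, 1300), "")[[1]]
  for (i in c(50, 200)) near[i] <- setdiff(c("A", "C", "G", "T"), near[i])[1]
  base <- paste0(substr(base, 1, 3000), paste(near, collapse = ""),
                 substr(base, 3301, len))
  toyRef(chr1 = base)
}

test_that("enumeratePlacements finds unique, repeat and tied placements", {
  ref <- mkRepeatRef()
  refc <- as.character(ref[[1]])

  ## single-copy locus, no errors: exactly one placement at mm 0
  s1 <- substr(refc, 3501, 3600); s2 <- rcomp(substr(refc, 3601, 3700))
  pl <- enumeratePlacements(s1, s2, ref)
  expect_equal(nrow(pl), 1)
  expect_equal(pl$totalMm, 0)
  expect_equal(pl$pos1, 3501)
  expect_equal(pl$insert, 200)

  ## pair from the exact duplication: >= 2 placements with equal mm
  d1 <- substr(refc, 501, 600); d2 <- rcomp(substr(refc, 651, 750))
  pld <- enumeratePlacements(d1, d2, ref)
  expect_gte(nrow(pld), 2)
  expect_equal(length(unique(pld$totalMm)), 1)
})

test_that("placement enumeration equals the all-position oracle on random pairs", {
  ref <- mkRepeatRef(seed = 9L)
  refc <- as.character(ref[[1]])
  set.seed(21)
  for (i in seq_len(25)) {
    a <- sample(3800, 1)
    ins <- sample(120:400, 1)
    if (a + ins - 1 > nchar(refc)) next
    frag <- substr(refc, a, a + ins - 1)
    r1 <- strsplit(substr(frag, 1, 100), "")[[1]]
    r2 <- strsplit(rcomp(substr(frag, ins - 99, ins)), "")[[1]]
    ## sprinkle up to 3 errors on each mate
    for (k in sample(100, sample(0:3, 1))) r1[k] <- sample(c("A", "C", "G", "T"), 1)
    for (k in sample(100, sample(0:3, 1))) r2[k] <- sample(c("A", "C", "G", "T"), 1)
    s1 <- paste(r1, collapse = ""); s2 <- paste(r2, collapse = "")
    got <- enumeratePlacements(s1, s2, ref, maxMm = 5L, maxInsert = 1000L)
    want <- naivePlacements(s1, s2, ref, maxMm = 5L, maxInsert = 1000L)
    expect_equal(nrow(got), nrow(want))
    key <- function(d) sort(paste(d$chrom, d$pos1, d$pos2, d$fwdMate,
                                  d$insert, d$mm1 + d$mm2))
    expect_identical(key(got), key(want))
  }
})

test_that("rescuePairs keeps unique-minimum placements and discards ties", {
  ref <- mkRepeatRef()
  refc <- as.character(ref[[1]])
  ## pair A: unique locus (minimum attained once)
  a1 <- substr(refc, 3501, 3600); a2 <- rcomp(substr(refc, 3601, 3700))
  ## pair B: exact repeat (tie at minimum)
  b1 <- substr(refc, 501, 600); b2 <- rcomp(substr(refc, 651, 750))
  ## pair C: diverged repeat: true copy wins by >= 1 mismatch
  c1 <- substr(refc, 1001, 1100); c2 <- rcomp(substr(refc, 1201, 1300))
  ## pair D: foreign sequence, no placement
  d1 <- randSeq(100); d2 <- randSeq(100)
  reads1 <- mkReads(c(A = a1, B = b1, C = c1, D = d1))
  reads2 <- mkReads(c(A = a2, B = b2, C = c2, D = d2))
  rs <- rescuePairs(reads1, reads2, ref)
  rescuedQ <- unique(rs$aln$qname)
  expect_setequal(rescuedQ, c("A", "C"))
  expect_identical(rs$discarded$reason[rs$discarded$qname == "B"],
                   "tie-at-minimum")
  expect_identical(rs$discarded$reason[rs$discarded$qname == "D"],
                   "no-placement")
  ## accounting: every input pair is rescued or discarded, exactly once
  expect_setequal(c(rescuedQ, rs$discarded$qname), names(reads1$seq))
  expect_equal(length(rescuedQ) + nrow(rs$discarded), length(reads1$seq))
  ## rescued alignments verify against the reference within the bound
  for (i in seq_len(nrow(rs$aln))) {
    row <- rs$aln[i, ]
    refChars <- strsplit(refc, "")[[1]]
    expect_lte(mmAt(strsplit(row$seq, "")[[1]], refChars, row$start), 5L)
  }
})

test_that("rescue equals the oracle rule on a seeded pool and ignores input order", {
  ref <- mkRepeatRef(seed = 31L, len = 4500L)
  refc <- as.character(ref[[1]])
  set.seed(77)
  n <- 60
  s1 <- character(n); s2 <- character(n)
  for (i in seq_len(n)) {
    a <- sample(c(sample(4300, 1), 501, 1001), 1)   # bias some to repeats
    ins <- sample(150:350, 1)
    if (a + ins - 1 > nchar(refc)) { a <- 100 }
    frag <- substr(refc, a, a + ins - 1)
    r1 <- strsplit(substr(frag, 1, 100), "")[[1]]
    r2 <- strsplit(rcomp(substr(frag, ins - 99, ins)), "")[[1]]
    for (k in sample(100, sample(0:2, 1))) r1[k] <- sample(c("A", "C", "G", "T"), 1)
    s1[i] <- paste(r1, collapse = ""); s2[i] <- paste(r2, collapse = "")
  }
  nm <- sprintf("q%02d", seq_len(n))
  reads1 <- mkReads(setNames(s1, nm)); reads2 <- mkReads(setNames(s2, nm))
  rs <- rescuePairs(reads1, reads2, ref)
  ## oracle: naive enumeration + "single mapping location for the minimum
  ## mismatch count"
  oracleKept <- vapply(seq_len(n), function(i) {
    pl <- naivePlacements(s1[i], s2[i], ref)
    if (!nrow(pl)) return(FALSE)
    sum(pl$totalMm == min(pl$totalMm)) == 1L
  }, logical(1))
  expect_setequal(unique(rs$aln$qname), nm[oracleKept])

  ## determinism under permutation of the pool
  perm <- sample(n)
  rs2 <- rescuePairs(list(seq = reads1$seq[perm], qual = reads1$qual[perm]),
                     list(seq = reads2$seq[perm], qual = reads2$qual[perm]), ref)
  o1 <- rs$aln[order(rs$aln$qname, rs$aln$mate), c("qname", "chrom", "start", "mm")]
  o2 <- rs2$aln[order(rs2$aln$qname, rs2$aln$mate), c("qname", "chrom", "start", "mm")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)
})

test_that("single-gap placement recovers reads spanning short indels", {
  set.seed(13)
  base <- randSeq(2000)
  ref <- toyRef(chr1 = base)
  ## a haplotype with a 2 bp deletion at position 1001-1002
  hap <- paste0(substr(base, 1, 1000), substr(base, 1003, 2000))
  read <- substr(hap, 951, 1050)   # deletion at read offset 50
  reads1 <- mkReads(c(g = read))
  reads2 <- mkReads(c(g = rcomp(substr(hap, 1051, 1150))))
  al <- alignPairs(reads1, reads2, ref, maxMm = 2L, maxInsert = 500L)
  expect_identical(al$status$status, "unique")
  g <- al$aln[al$aln$strand == "+", ]
  expect_identical(g$gapType, "D")
  expect_equal(g$gapLen, 2L)
  ## the reported gapped placement reconstructs the read exactly
  ## (split-point choice among equivalent alignments is free)
  rebuilt <- paste0(substr(base, g$start, g$start + g$gapPos - 1L),
                    substr(base, g$start + g$gapPos + g$gapLen,
                           g$start + g$readLen + g$gapLen - 1L))
  expect_identical(rebuilt, read)
})
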