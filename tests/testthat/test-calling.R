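## Pileup thresholds, zygosity classes, indel normalization and call-set
## merging.

q30 <- function(n) paste(rep("?", n), collapse = "")  # Phred 30
q15 <- function(n) paste(rep("0", n), collapse = "")  # Phred 15

toyTargets <- function(len = 2000L) {
  GRanges("chr1", IRanges(1, len), seqlengths = c(chr1 = len))
}

test_that("buildPileup honors the minimum base quality and counts depth", {
  set.seed(30)
  refc <- randSeq(2000)
  ref <- toyRef(chr1 = refc)
  read <- substr(refc, 101, 200)
  aln <- rbind(
    mkAlnRow("hi", "chr1", "+", 101L, read, qual = q30(100)),
    mkAlnRow("lo", "chr1", "+", 101L, read, qual = q15(100)))
  pu <- buildPileup(aln, toyTargets(), ref)
  ## Q15 read contributes nothing; Q30 read gives depth 1 across its span
  expect_equal(pu$depth[["chr1"]][101:200], rep(1L, 100))
  expect_equal(sum(pu$depth[["chr1"]]), 100)
})

test_that("pileup depth and alt counts match a per-base recount oracle", {
  set.seed(31)
  refc <- randSeq(1500)
  ref <- toyRef(chr1 = refc)
  rows <- list()
  for (i in 1:60) {
    st <- sample(1300, 1)
    rc <- strsplit(substr(refc, st, st + 99), "")[[1]]
    nerr <- sample(0:2, 1)
    errAt <- sample(100, nerr)
    for (k in errAt) rc[k] <- setdiff(c("A", "C", "G", "T"), rc[k])[1]
    rows[[i]] <- mkAlnRow(paste0("r", i), "chr1", "+", st,
                          paste(rc, collapse = ""), qual = q30(100),
                          maskN = sample(c(0L, 5L), 1))
  }
  aln <- do.call(rbind, rows)
  pu <- buildPileup(aln, toyTargets(1500L), ref)
  oracle <- bruteDepth(aln, c(chr1 = 1500L))[["chr1"]]
  expect_identical(pu$depth[["chr1"]], oracle)
  ## recount alt bases directly
  refChars <- strsplit(refc, "")[[1]]
  `%||%` <- function(a, b) if (is.null(a)) b else a
  altOracle <- list()
  for (i in seq_len(nrow(aln))) {
    rc <- strsplit(aln$seq[i], "")[[1]]
    for (b in seq_along(rc)) {
      if (b <= aln$maskN[i] || b > 100 - aln$maskN[i]) next
      p <- aln$start[i] + b - 1L
      if (rc[b] != refChars[p]) {
        key <- paste(p, rc[b])
        altOracle[[key]] <- (altOracle[[key]] %||% 0L) + 1L
      }
    }
  }
  got <- pu$snvSites
  for (key in names(altOracle)) {
    p <- as.integer(strsplit(key, " ")[[1]][1])
    b <- strsplit(key, " ")[[1]][2]
    cnt <- got$count[got$pos == p & got$base == b]
    expect_equal(sum(cnt), altOracle[[key]])
  }
  expect_equal(sum(got$count), sum(unlist(altOracle)))
})

test_that("zygosity classes partition the (af, depth) plane with closed het band", {
  expect_identical(classifyZygosity(0.25, 30), "heterozygous")
  expect_identical(classifyZygosity(0.75, 30), "heterozygous")
  expect_identical(classifyZygosity(0.76, 30), "homozygous")
  expect_identical(classifyZygosity(0.80, 30), "homozygous")
  expect_identical(classifyZygosity(0.20, 30), "missing")
  expect_identical(classifyZygosity(0.50, 9), "missing")
  ## exactly one class for any input
  set.seed(1)
  af <- runif(200); dp <- sample(0:40, 200, TRUE)
  z <- classifyZygosity(af, dp)
  expect_true(all(z %in% c("heterozygous", "homozygous", "missing")))
})

test_that("callVariants emits calls under the depth/af/score gates", {
  set.seed(32)
  refc <- randSeq(1000)
  ref <- toyRef(chr1 = refc)
  mkStack <- function(nref, nalt, pos = 501L, prefix = "s") {
    alt <- setdiff(c("A", "C", "G", "T"), substr(refc, pos, pos))[1]
    rows <- list()
    for (i in seq_len(nref + nalt)) {
      st <- pos - 50L
      rc <- strsplit(substr(refc, st, st + 99), "")[[1]]
      if (i <= nalt) rc[51] <- alt
      rows[[i]] <- mkAlnRow(paste0(prefix, i), "chr1", "+", st,
                            paste(rc, collapse = ""), qual = q30(100))
    }
    do.call(rbind, rows)
  }
  ## depth 30 with 15 alt -> heterozygous call at af 0.5
  pu <- buildPileup(mkStack(15, 15), toyTargets(1000L), ref)
  calls <- callVariants(pu, ref)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$af, 0.5)
  expect_identical(calls$zygosity, "heterozygous")
  expect_gte(calls$vs, 20); expect_gte(calls$cs, 20)

  ## no alt -> no call
  pu0 <- buildPileup(mkStack(30, 0), toyTargets(1000L), ref)
  expect_equal(nrow(callVariants(pu0, ref)), 0)

  ## depth 9, all alt -> missing (depth below 10)
  pu9 <- buildPileup(mkStack(0, 9), toyTargets(1000L), ref)
  expect_equal(nrow(callVariants(pu9, ref)), 0)
})

test_that("normalizeIndel left-aligns and is idempotent; matches shift oracle", {
  set.seed(33)
  refc <- paste0(randSeq(50), "T", "AAAA", "G", randSeq(50))
  ref <- toyRef(chr1 = refc)
  ## deletion of one A reported at the run's third base (pos 53 anchors A)
  nz <- normalizeIndel("chr1", 53L, "AA", "A", ref)
  expect_equal(nz$pos, 51)           # anchored at the T before the run
  expect_identical(nz$ref, "TA")
  expect_identical(nz$alt, "T")
  ## idempotent
  nz2 <- normalizeIndel("chr1", nz$pos, nz$ref, nz$alt, ref)
  expect_identical(nz2, nz)
  ## SNV untouched
  expect_identical(normalizeIndel("chr1", 53L, "A", "G", ref),
                   list(pos = 53L, ref = "A", alt = "G"))
  ## random anchored indels equal the exhaustive-shift oracle
  refc2 <- randSeq(400)
  ref2 <- toyRef(chr1 = refc2)
  for (i in 1:25) {
    p <- sample(50:300, 1)
    dl <- sample(1:3, 1)
    if (runif(1) < 0.5) {
      r <- substr(refc2, p, p + dl); a <- substr(refc2, p, p)
    } else {
      r <- substr(refc2, p, p); a <- paste0(r, randSeq(dl))
    }
    got <- normalizeIndel("chr1", p, r, a, ref2)
    want <- shiftOracle("chr1", p, r, a, ref2)
    expect_equal(got$pos, want$pos)
    expect_identical(got$ref, want$ref)
    expect_identical(got$alt, want$alt)
  }
})

test_that("mergeCallsets unions by site with source labels and conflict rule", {
  base <- data.frame(sample = "S1", chrom = "chr1", pos = 100L, ref = "A",
                     alt = "T", type = "SNV", depth = 12L, af = 0.5,
                     vs = 99, cs = 99, zygosity = "heterozygous",
                     gt = "0/1", source = "WES", stringsAsFactors = FALSE)
  cOnly <- base; cOnly$pos <- 200L; cOnly$source <- "CCCS"; cOnly$depth <- 190L
  wBoth <- base; cBoth <- base; cBoth$source <- "CCCS"; cBoth$depth <- 150L
  confW <- base; confW$pos <- 300L
  confC <- confW; confC$source <- "CCCS"; confC$depth <- 190L
  confC$zygosity <- "homozygous"; confC$gt <- "1/1"; confC$af <- 0.9

  m <- mergeCallsets(rbind(wBoth, confW), rbind(cOnly, cBoth, confC))
  ## CCCS-only site retained with its source
  expect_identical(m$source[m$pos == 200L], "CCCS")
  ## same het call in both -> one record, source BOTH
  expect_identical(m$source[m$pos == 100L], "BOTH")
  expect_equal(sum(m$pos == 100L), 1)
  ## conflict resolves to the deeper call and is flagged
  expect_identical(m$zygosity[m$pos == 300L], "homozygous")
  expect_true(m$conflict[m$pos == 300L])

  ## commutative up to source label; idempotent on identical inputs
  m2 <- mergeCallsets(rbind(cOnly, cBoth, confC), rbind(wBoth, confW))
  expect_identical(m$pos[order(m$pos)], m2$pos[order(m2$pos)])
  expect_identical(m$zygosity[order(m$pos)], m2$zygosity[order(m2$pos)])
  m3 <- mergeCallsets(wBoth, wBoth)
  expect_equal(nrow(m3), 1)
})
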