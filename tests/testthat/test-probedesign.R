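## Complement extraction, candidate tiling and tiered validation.

test_that("extractComplement returns low-depth and probe-uncovered CDS bases", {
  sl <- c(chr1 = 5000L)
  cds <- GRanges("chr1", IRanges(c(1001, 2001, 3001), width = 300),
                 seqlengths = sl)
  probes <- GRanges("chr1", IRanges(c(991, 1991), width = 320),
                    seqlengths = sl)   # third exon not probe-covered
  targets <- padAndMerge(probes, 100L)
  seqlengths(targets) <- sl
  ## exon 1 deep, exon 2 shallow, exon 3 unsequenced
  aln <- rbind(
    do.call(rbind, lapply(1:20, function(i)
      mkAlnRow(paste0("a", i), "chr1", "+", 1001L, randSeq(300)))),
    do.call(rbind, lapply(1:5, function(i)
      mkAlnRow(paste0("b", i), "chr1", "+", 2001L, randSeq(300)))))
  prof <- computeDepth(aln, targets)

  out <- extractComplement(prof, probes, cds, cutoff = 15L)
  ## oracle: per-base depth < 15 or outside padded probes, within CDS
  oracle <- bruteDepth(aln, sl)[["chr1"]]
  padIdx <- unlist(lapply(seq_along(targets), function(i)
    start(targets)[i]:end(targets)[i]))
  cdsIdx <- unlist(lapply(seq_along(cds), function(i)
    start(cds)[i]:end(cds)[i]))
  wantIdx <- sort(intersect(cdsIdx,
    union(which(oracle < 15), setdiff(seq_len(sl), padIdx))))
  gotIdx <- sort(unlist(lapply(seq_along(out), function(i)
    start(out)[i]:end(out)[i])))
  expect_identical(gotIdx, wantIdx)

  ## fully covered, deep CDS -> empty complement
  allProbes <- GRanges("chr1", IRanges(991, 3320), seqlengths = sl)
  allTargets <- padAndMerge(allProbes, 100L)
  seqlengths(allTargets) <- sl
  deep <- computeDepth(
    do.call(rbind, lapply(1:20, function(i)
      mkAlnRow(paste0("c", i), "chr1", "+", 1001L, randSeq(2300)))),
    allTargets)
  expect_equal(sum(width(extractComplement(deep, allProbes, cds))), 0)
})

test_that("tileCandidates respects tier length bounds at restriction boundaries", {
  set.seed(40)
  ## cut motifs every ~120 bp by construction
  block <- function() paste0("AGCT", randSeq(116))
  refc <- paste0(randSeq(50), paste(replicate(8, block()), collapse = ""),
                 randSeq(50))
  ref <- toyRef(chr1 = refc)
  region <- GRanges("chr1", IRanges(200, 700))
  t1 <- tileCandidates(region, ref, tier = 1L, motifs = "AGCT")
  t2 <- tileCandidates(region, ref, tier = 2L, motifs = "AGCT")
  expect_true(all(width(t1) >= 150))
  expect_true(all(width(t2) >= 50))
  ## tier 2 admits the ~120 bp single fragments tier 1 must concatenate
  expect_true(any(width(t2) < 150))
  expect_true(all(width(t1) %in% width(t2) | width(t1) >= 150))
  ## every candidate overlaps the requested region
  expect_true(all(overlapsAny(t1, region)))
  ## candidate sequences equal the reference substring
  expect_identical(t1$sequence[1],
                   as.character(subseq(ref[[1]], start(t1)[1], end(t1)[1])))
})

test_that("probeReads builds end reads with reverse complement", {
  amp <- randSeq(300)
  pr <- probeReads(amp, 100L)
  expect_identical(pr$r1, substr(amp, 1, 100))
  expect_identical(pr$r2, rcomp(substr(amp, 201, 300)))
  short <- randSeq(80)
  prs <- probeReads(short, 100L)
  expect_identical(prs$r1, short)
  expect_identical(prs$r2, rcomp(short))
  expect_equal(nchar(prs$r1), 80)
})

test_that("validateProbe enforces uniqueness per tier", {
  set.seed(41)
  uniquePart <- randSeq(1200)
  dupPart <- randSeq(400)
  nearDup <- strsplit(dupPart, "")[[1]]
  for (i in c(60, 350)) nearDup[i] <- setdiff(c("A", "C", "G", "T"), nearDup[i])[1]
  refc <- paste0(uniquePart, dupPart, randSeq(200), dupPart, randSeq(200),
                 paste(nearDup, collapse = ""), randSeq(200))
  ref <- toyRef(chr1 = refc)

  ## single-copy probe: accepted at tier 1
  v1 <- validateProbe(substr(uniquePart, 101, 280), ref, tier = 1L)
  expect_true(v1$accepted)

  ## exact two-copy probe: rejected at every tier (tie at minimum)
  dupProbe <- substr(dupPart, 51, 230)
  expect_false(validateProbe(dupProbe, ref, tier = 1L)$accepted)
  expect_identical(validateProbe(dupProbe, ref, tier = 1L)$reason, "non-unique")
  expect_false(validateProbe(dupProbe, ref, tier = 3L)$accepted)
  expect_identical(validateProbe(dupProbe, ref, tier = 3L)$reason,
                   "tie-at-minimum")

  ## probe from the diverged copy: second placement within 5 mismatches
  ## exists, so tiers 1-2 reject it, but tier 3 accepts (margin >= 1)
  nearProbe <- substr(refc, 1200 + 400 + 200 + 400 + 200 + 1,
                      1200 + 400 + 200 + 400 + 200 + 180)
  expect_false(validateProbe(nearProbe, ref, tier = 2L)$accepted)
  expect_true(validateProbe(nearProbe, ref, tier = 3L)$accepted)

  ## ambiguous bases are rejected outright
  expect_identical(validateProbe("ACGTNACGT", ref, 1L)$reason,
                   "ambiguous-sequence")
})

test_that("designProbeSet: tier escalation, fixed point, residual completeness", {
  set.seed(42)
  uniqueA <- randSeq(900)
  dupBlock <- randSeq(350)
  refc <- paste0(uniqueA, dupBlock, randSeq(300), dupBlock, randSeq(300))
  ref <- toyRef(chr1 = refc)
  cds <- GRanges("chr1", IRanges(c(101, 951), c(700, 1200)),
                 seqlengths = c(chr1 = nchar(refc)))
  regions <- cds
  des <- designProbeSet(regions, ref, cds)
  acc <- acceptedProbes(des)

  ## fixed point: every accepted probe re-validates as accepted at its tier
  for (i in seq_len(length(acc))) {
    expect_true(validateProbe(acc$sequence[i], ref, acc$tier[i])$accepted)
  }

  ## the duplicated exon region stays unprobed (residual) while the unique
  ## region is designed
  resid <- residualRegions(des)
  expect_gt(sum(width(intersect(resid, GRanges("chr1", IRanges(951, 1200))))), 0)
  expect_gt(sum(width(intersect(reduce(acc), GRanges("chr1", IRanges(101, 700))))), 300)

  ## residual completeness: no residual base is coverable (with 5 bp edge
  ## margin) by any candidate that the per-tier validation oracle accepts
  for (tier in 1:3) {
    cands <- tileCandidates(regions, ref, tier)
    cands <- cands[width(cands) <= 190L]
    if (!length(cands)) next
    ok <- vapply(seq_along(cands), function(i)
      validateProbe(cands$sequence[i], ref, tier)$accepted, logical(1))
    okCall <- cands[ok]
    if (!length(okCall)) next
    okCall <- GRanges(seqnames(okCall),
                      IRanges(start(okCall) + 5L, end(okCall) - 5L))
    expect_equal(sum(width(intersect(resid, okCall))), 0)
  }

  ## accepted base coverage is monotone non-decreasing across tiers
  cum <- GRanges()
  prev <- -1
  for (tier in 1:3) {
    tierAcc <- acc[acc$tier <= tier]
    covered <- sum(width(reduce(tierAcc)))
    expect_gte(covered, prev)
    prev <- covered
  }
})
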