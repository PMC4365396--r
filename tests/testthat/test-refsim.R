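## The synthetic-data generator: determinism, structure, bias model,
## pedigree genetics.

test_that("reference simulation is deterministic and sized by config", {
  cfg <- simConfig(seed = 2L, nChrom = 1L, chromLen = 60000L, nGenes = 10L,
                   exonsPerGene = 5L)
  s1 <- simulateReference(cfg)
  s2 <- simulateReference(cfg)
  expect_identical(as.character(s1$reference), as.character(s2$reference))
  expect_identical(as.data.frame(s1$genes), as.data.frame(s2$genes))
  ## emitted files are byte-identical under a fixed seed
  f1 <- tempfile(); f2 <- tempfile()
  writeFasta(s1$reference, f1); writeFasta(s2$reference, f2)
  expect_identical(readLines(f1), readLines(f2))
  ## gene-model record count forced by config
  expect_equal(length(s1$genes), 10L * 5L)
  ## CDS codon-multiple invariant, per gene
  perGene <- tapply(width(s1$genes), s1$genes$gene_id, sum)
  expect_true(all(perGene %% 3 == 0))
})

test_that("probe design covers >= 90% of CDS; pockets are GC-rich", {
  s <- toySim(seed = 3L, nGenes = 15L)
  cdsBases <- sum(width(s$cds))
  onProbe <- sum(width(intersect(s$cds, reduce(s$wesProbes))))
  expect_gte(onProbe / cdsBases, 0.90)
  gcPocket <- mean(gcFraction(extractAt(s$reference[["chr1"]],
                                        ranges(s$pockets))))
  gcGenome <- gcFraction(s$reference)[1]
  expect_gt(gcPocket - gcGenome, 0.15)
  ## pockets remain probe-covered (low capture, not undesigned)
  expect_equal(sum(width(setdiff(s$pockets, reduce(s$wesProbes)))), 0)
})

test_that("chromLen too small for the requested genes raises a sizing error", {
  expect_error(
    simulateReference(simConfig(seed = 1L, nChrom = 1L, chromLen = 10000L,
                                nGenes = 30L)),
    "chromLen")
})

test_that("planted pedigree realizes the designated inheritance patterns", {
  s <- toySim(seed = 4L)
  ped <- plantPedigree(s, pedigreeTrio(unaffectedSibs = 1L),
                       nCommonKnown = 30L, nRareBackground = 10L)
  tr <- ped$truth
  gt <- function(sample, inh) tr$gt[tr$sample == sample & tr$inheritance == inh]

  ## AR-hom: both parents het, affected child hom
  expect_identical(gt("CH1", "AR-hom"), "1|1")
  expect_true(gt("FA", "AR-hom") %in% c("1|0", "0|1"))
  expect_true(gt("MO", "AR-hom") %in% c("1|0", "0|1"))

  ## compound het: each parent carries exactly one partner; child phases
  ## the partners to different parents
  expect_length(gt("FA", "comphet-partner-A"), 1)
  expect_length(gt("FA", "comphet-partner-B"), 0)
  expect_length(gt("MO", "comphet-partner-B"), 1)
  expect_length(gt("MO", "comphet-partner-A"), 0)
  expect_identical(gt("CH1", "comphet-partner-A"), "1|0")  # paternal
  expect_identical(gt("CH1", "comphet-partner-B"), "0|1")  # maternal
  ## partners share a gene
  expect_identical(tr$gene[tr$inheritance == "comphet-partner-A"][1],
                   tr$gene[tr$inheritance == "comphet-partner-B"][1])

  ## de novo: absent from both parental truth sets
  expect_length(gt("FA", "denovo"), 0)
  expect_length(gt("MO", "denovo"), 0)
  expect_identical(gt("CH1", "denovo"), "1|0")

  ## unaffected sib carries none of the focal variants
  expect_length(tr$gt[tr$sample == "SIB1" &
                      tr$inheritance %in% c("AR-hom", "denovo",
                                            "comphet-partner-A",
                                            "comphet-partner-B")], 0)

  ## planting onto a mismatching reference errors out
  bad <- data.frame(chrom = "chr1", pos = 5L, ref = "NOPE", alt = "A",
                    class = "nonsense", inheritance = "denovo",
                    gene = "G001", inPocket = FALSE)
  expect_error(plantPedigree(s, pedigreeTrio(), planted = bad),
               "ref mismatch")
})

test_that("truth variants round-trip into member genomes", {
  s <- toySim(seed = 6L)
  ped <- plantPedigree(s, pedigreeTrio(), nCommonKnown = 25L,
                       nRareBackground = 10L)
  for (m in c("FA", "CH1")) {
    for (h in c("h1", "h2")) {
      rebuilt <- applyHaplotype(s$reference, ped$hapVars[[m]][[h]])
      expect_identical(as.character(rebuilt),
                       as.character(ped$genomes[[m]][[h]]))
    }
  }
})

test_that("GC bias drives pockets under 10x while bias-off equalizes depth", {
  s <- toySim(seed = 8L, nGenes = 14L)
  ped <- plantPedigree(s, pedigreeTrio(), nCommonKnown = 20L,
                       nRareBackground = 8L)
  onT <- padAndMerge(s$wesProbes, 100L)
  seqlengths(onT) <- s$seqlens[seqlevels(onT)]
  runDepth <- function(sim) {
    rd <- simulateWesReads(ped, "CH1", sim)
    al <- alignPairs(rd$r1, rd$r2, sim$reference, maxMm = 2L,
                     maxInsert = 720L, sample = "CH1")
    fl <- filterPairs(al$aln, al$status, mode = "WES", onTarget = onT)
    pileupDepthProfile(buildPileup(fl$pass, onT, sim$reference,
                                   sampleId = "CH1", platform = "WES"))
  }
  meanOver <- function(prof, gr) {
    mean(unlist(lapply(seq_along(gr), function(i) {
      ch <- as.character(seqnames(gr))[i]
      as.integer(window(depthRle(prof)[[ch]], start(gr)[i], end(gr)[i]))
    })))
  }
  prof <- runDepth(s)
  nonPocket <- setdiff(setdiff(s$cds, s$pockets), s$offProbe)
  ratio <- meanOver(prof, s$pockets) / meanOver(prof, nonPocket)
  expect_lt(ratio, 0.2)
  ## >= 90% of pocket bases below 10x after the full read-processing path
  pocketDepths <- unlist(lapply(seq_along(s$pockets), function(i)
    as.integer(window(depthRle(prof)[["chr1"]], start(s$pockets)[i],
                      end(s$pockets)[i]))))
  expect_gte(mean(pocketDepths < 10), 0.90)

  ## bias off: pockets sequence like everything else
  s0 <- s; s0$cfg@gcBiasStrength <- 0
  prof0 <- runDepth(s0)
  ratio0 <- meanOver(prof0, s$pockets) / meanOver(prof0, nonPocket)
  expect_gt(ratio0, 0.7)
  expect_lt(ratio0, 1.4)
})

test_that("injected PCR duplicates are flagged at about the configured rate", {
  s <- toySim(seed = 9L, nGenes = 12L)
  ped <- plantPedigree(s, pedigreeTrio(), nCommonKnown = 20L,
                       nRareBackground = 8L)
  rd <- simulateWesReads(ped, "CH1", s)
  al <- alignPairs(rd$r1, rd$r2, s$reference, maxMm = 2L, maxInsert = 720L)
  marked <- markDuplicates(al$aln)
  npairs <- length(unique(marked$qname))
  dupFrac <- sum(marked$dup) / 2 / npairs
  ## injected at 0.1 of the original fragment count; binomial tolerance
  expect_gt(dupFrac, 0.06)
  expect_lt(dupFrac, 0.14)
})

test_that("amplicon reads carry adapter read-through and respect fixed ends", {
  s <- toySim(seed = 10L)
  ped <- plantPedigree(s, pedigreeTrio(), nCommonKnown = 20L,
                       nRareBackground = 8L)
  ## hand-build one 80 bp accepted amplicon
  amp <- GRanges("chr1", IRanges(5001, 5080))
  amp$sequence <- as.character(subseq(s$reference[["chr1"]], 5001, 5080))
  rd <- simulateCccsReads(ped, "CH1", amp, s)
  expect_gt(length(rd$r1$seq), 0)
  ## with an 80 bp amplicon, bases 81-100 of read 1 are the adapter prefix
  ## (up to sequencing errors; check a clean read exists)
  sfx <- substr(as.character(rd$r1$seq), 81, 100)
  expect_true(any(sfx == substr(s$cfg@adapterFwd, 1, 20)))
  rsfx <- substr(as.character(rd$r2$seq), 81, 100)
  expect_true(any(rsfx == substr(s$cfg@adapterRev, 1, 20)))
  ## zero accepted probes: warning + empty output
  expect_warning(empty <- simulateCccsReads(ped, "CH1", amp[0], s),
                 "no accepted amplicons")
  expect_length(empty$r1$seq, 0)

  ## determinism of emitted FASTQ bytes
  rd2 <- simulateCccsReads(ped, "CH1", amp, s)
  f1 <- tempfile(); f2 <- tempfile()
  writeFastq(rd$r1, f1); writeFastq(rd2$r1, f2)
  expect_identical(readLines(f1), readLines(f2))
})
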