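## Consequence annotation, database filtering and Mendelian models.

test_that("codonIndex performs HGVS codon arithmetic", {
  expect_identical(codonIndex(8098), 2700L)
  expect_identical(codonIndex(10168), 3390L)
  expect_identical(codonIndex(c(1, 3, 4)), c(1L, 1L, 2L))
})

test_that("annotation classifies substitutions and indels, strand-aware", {
  sim <- toySim(seed = 17L)
  trs <- transcriptsFromModels(sim$genes)
  ## the truth table of a planted pedigree is a cross-module oracle: the
  ## simulator records the intended class at plant time; annotation must
  ## recover it from coordinates alone
  ped <- plantPedigree(sim, pedigreeTrio(), nCommonKnown = 40L,
                       nRareBackground = 18L)
  truth <- unique(ped$truth[, c("chrom", "pos", "ref", "alt", "class", "gene")])
  ann <- annotateVariants(truth, trs, sim$reference)
  expect_identical(ann$class, truth$class)
  ## genes match for coding classes
  coding <- truth$class %in% c("nonsense", "missense", "synonymous",
                               "frameshift-indel")
  expect_identical(ann$gene[coding], truth$gene[coding])
  ## both strands exercised by the generated gene set
  strands <- as.character(strand(sim$genes))[match(unique(truth$gene),
                                                   sim$genes$gene_id)]
  expect_setequal(unique(strands), c("+", "-"))
})

test_that("annotation handles nongenic positions", {
  sim <- toySim(seed = 17L)
  trs <- transcriptsFromModels(sim$genes)
  far <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "T")
  expect_identical(annotateVariants(far, trs, sim$reference)$class, "nongenic")
})

test_that("filterKnown excludes database sites except rare pathogenic ones", {
  calls <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                      ref = "A", alt = "T", sample = "S1")
  db <- data.frame(chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = "T",
                   af = c(0.20, 0.005), pathogenic = c(FALSE, TRUE),
                   source = c("dbSNP", "ClinVar"))
  out <- filterKnown(calls, db)
  expect_setequal(out$pos, c(20L, 30L))  # common removed; pathogenic rescued
  ## pathogenic but frequent is still removed
  db2 <- db; db2$af[2] <- 0.05
  expect_setequal(filterKnown(calls, db2)$pos, 30L)
})

test_that("filterConsequence keeps nonsynonymous-eligible classes", {
  calls <- data.frame(chrom = "chr1", pos = 1:6, ref = "A", alt = "T",
                      class = c("nonsense", "missense", "splice-site",
                                "frameshift-indel", "synonymous", "intronic"))
  out <- filterConsequence(calls)
  expect_setequal(out$class, c("nonsense", "missense", "splice-site",
                               "frameshift-indel"))
})

## genotype fixture: calls table + depth lookup for a quartet
mkFamilyCalls <- function(rows) {
  base <- data.frame(chrom = "chr1", ref = "C", alt = "T",
                     gene = "G1", class = "missense",
                     stringsAsFactors = FALSE)
  do.call(rbind, lapply(rows, function(r)
    cbind(base[rep(1, 1), ], data.frame(
      sample = r$s, pos = r$p,
      zygosity = r$z, gene = if (is.null(r$g)) "G1" else r$g))))
}

fam <- data.frame(id = c("FA", "MO", "CH1", "SIB1"),
                  sex = c(1L, 2L, 1L, 2L),
                  father = c(NA, NA, "FA", "FA"),
                  mother = c(NA, NA, "MO", "MO"),
                  affected = c(FALSE, FALSE, TRUE, FALSE))
deepEverywhere <- function(sample, chrom, pos) 100L
shallowFor <- function(who, where) {
  function(sample, chrom, pos) if (sample %in% who && pos %in% where) 3L else 100L
}

test_that("de novo model requires callable hom-ref parents", {
  calls <- mkFamilyCalls(list(list(s = "CH1", p = 100L, z = "heterozygous")))
  out <- inheritanceFilter(calls, fam, deepEverywhere, models = "denovo")
  expect_equal(nrow(out), 1)
  expect_identical(out$model, "denovo")
  ## father also het -> rejected
  calls2 <- rbind(calls, mkFamilyCalls(list(
    list(s = "FA", p = 100L, z = "heterozygous"))))
  expect_equal(nrow(inheritanceFilter(calls2, fam, deepEverywhere,
                                      models = "denovo")), 0)
  ## father uncallable at the site -> disqualified (no guessing)
  out3 <- inheritanceFilter(calls, fam, shallowFor("FA", 100L),
                            models = "denovo")
  expect_equal(nrow(out3), 0)
})

test_that("AR-hom model enforces parental het and sibling segregation", {
  calls <- mkFamilyCalls(list(
    list(s = "CH1", p = 200L, z = "homozygous"),
    list(s = "FA", p = 200L, z = "heterozygous"),
    list(s = "MO", p = 200L, z = "heterozygous")))
  out <- inheritanceFilter(calls, fam, deepEverywhere, models = "ARhom")
  expect_equal(nrow(out), 1)
  ## unaffected sib homozygous for the variant -> segregation violation
  calls2 <- rbind(calls, mkFamilyCalls(list(
    list(s = "SIB1", p = 200L, z = "homozygous"))))
  expect_equal(nrow(inheritanceFilter(calls2, fam, deepEverywhere,
                                      models = "ARhom")), 0)
})

test_that("compound-het model phases by parental origin and checks siblings", {
  calls <- mkFamilyCalls(list(
    list(s = "CH1", p = 300L, z = "heterozygous"),
    list(s = "CH1", p = 400L, z = "heterozygous"),
    list(s = "FA", p = 300L, z = "heterozygous"),
    list(s = "MO", p = 400L, z = "heterozygous")))
  out <- inheritanceFilter(calls, fam, deepEverywhere, models = "comphet")
  expect_equal(nrow(out), 2)
  expect_setequal(out$pos, c(300L, 400L))
  ## both variants from the same parent -> no compound het
  sameSide <- mkFamilyCalls(list(
    list(s = "CH1", p = 300L, z = "heterozygous"),
    list(s = "CH1", p = 400L, z = "heterozygous"),
    list(s = "FA", p = 300L, z = "heterozygous"),
    list(s = "FA", p = 400L, z = "heterozygous")))
  expect_equal(nrow(inheritanceFilter(sameSide, fam, deepEverywhere,
                                      models = "comphet")), 0)
  ## unaffected sib carrying the same paternal+maternal configuration
  calls3 <- rbind(calls, mkFamilyCalls(list(
    list(s = "SIB1", p = 300L, z = "heterozygous"),
    list(s = "SIB1", p = 400L, z = "heterozygous"))))
  expect_equal(nrow(inheritanceFilter(calls3, fam, deepEverywhere,
                                      models = "comphet")), 0)
  ## partner site missing in a parent -> pair disqualified
  out4 <- inheritanceFilter(calls, fam, shallowFor("MO", 300L),
                            models = "comphet")
  expect_equal(nrow(out4), 0)
})

test_that("cascade counts are monotone non-increasing with fixed stage order", {
  sim <- toySim(seed = 23L)
  trs <- transcriptsFromModels(sim$genes)
  for (seed in c(101L, 202L, 303L)) {
    ped <- plantPedigree(sim, pedigreeTrio(), seed = seed,
                         nCommonKnown = 30L, nRareBackground = 12L)
    ## treat the truth genotypes as a perfect call set
    calls <- ped$truth
    calls$zygosity <- ifelse(calls$gt == "1|1", "homozygous", "heterozygous")
    ann <- annotateVariants(calls[, setdiff(names(calls), c("class", "gene"))],
                            trs, sim$reference)
    cc <- variantCascade(ann, ped$db, ped$members, deepEverywhere,
                         models = c("ARhom", "comphet"))
    for (m in unique(cc$report$member)) {
      cnt <- cc$report$count[cc$report$member == m]
      expect_true(all(diff(cnt) <= 0))
    }
    expect_identical(levels(cc$report$stage),
                     c("all-called", "known-excluded", "nonsynonymous",
                       "inheritance"))
    ## perfect genotypes recover the planted recessive candidates
    expect_setequal(
      unique(cc$candidates$gene[cc$candidates$model == "comphet"]),
      unique(ped$truth$gene[ped$truth$inheritance == "comphet-partner-A"]))
    expect_true(all(
      unique(ped$truth$gene[ped$truth$inheritance == "AR-hom"]) %in%
        cc$candidates$gene[cc$candidates$model == "ARhom"]))
  }
})

test_that("empty call set yields an all-zero cascade", {
  sim <- toySim(seed = 23L)
  ped <- plantPedigree(sim, pedigreeTrio(), nCommonKnown = 20L,
                       nRareBackground = 8L)
  empty <- ped$truth[0, ]
  cc <- variantCascade(empty, ped$db, ped$members, deepEverywhere)
  expect_true(all(cc$report$count == 0))
})
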