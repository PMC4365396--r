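## Diploid pedigree genomes with planted variants and truth genotypes.
##
## Each member carries two haplotypes. Children inherit one whole
## haplotype per parent: the affected child receives haplotype 1 of each
## parent (the carrier haplotypes of the planted recessive variants),
## unaffected children receive haplotype 2 of each parent; this forced
## transmission realizes the designated inheritance labels exactly.

#' Default trio pedigree
#'
#' @param unaffectedSibs number of additional unaffected children.
#' @return data.frame with columns id, sex, father, mother, affected.
#' @export
pedigreeTrio <- function(unaffectedSibs = 0L) {
  m <- data.frame(
    id = c("FA", "MO", "CH1"), sex = c(1L, 2L, 1L),
    father = c(NA, NA, "FA"), mother = c(NA, NA, "MO"),
    affected = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE
  )
  if (unaffectedSibs > 0L) {
    sibs <- data.frame(
      id = paste0("SIB", seq_len(unaffectedSibs)),
      sex = rep_len(c(2L, 1L), unaffectedSibs),
      father = "FA", mother = "MO", affected = FALSE
    )
    m <- rbind(m, sibs)
  }
  m
}

## Search an exon (by transcription rank) of a transcript for a codon that
## admits a single-base change of the requested class. Returns NULL or a
## list describing the coding and genomic change.
findCodingChange <- function(tr, ref, exonRank, type) {
  gcode <- Biostrings::GENETIC_CODE
  ex <- tr$exons[tr$exons$exon_rank == exonRank]
  if (!length(ex)) return(NULL)
  cum <- tr$cumStart[exonRank]
  w <- width(ex)
  chunk <- as.character(subseq(ref[[tr$chrom]], start(ex), end(ex)))
  if (tr$strand == "-") chunk <- revcompChar(chunk)
  ncd <- w %/% 3L
  codons <- substring(chunk, 3L * (seq_len(ncd) - 1L) + 1L, 3L * seq_len(ncd))
  tryOrder <- sample(seq_len(ncd))
  for (k in tryOrder) {
    cd <- codons[k]
    if (grepl("[^ACGT]", cd)) next
    aa <- gcode[[cd]]
    for (pos in sample(1:3)) {
      for (nb in sample(setdiff(c("A", "C", "G", "T"), substr(cd, pos, pos)))) {
        alt <- cd
        substr(alt, pos, pos) <- nb
        aa2 <- gcode[[alt]]
        ok <- switch(type,
          nonsense = (aa != "*" && aa2 == "*"),
          missense = (aa != "*" && aa2 != "*" && aa2 != aa),
          synonymous = (aa2 == aa))
        if (ok) {
          cdsPos <- cum + 3L * (k - 1L) + pos
          gpos <- cdsToGenome(tr, cdsPos)
          refB <- substr(cd, pos, pos); altB <- nb
          if (tr$strand == "-") {
            refB <- revcompChar(refB); altB <- revcompChar(altB)
          }
          return(list(cdsPos = cdsPos, gpos = gpos, chrom = tr$chrom,
                      ref = refB, alt = altB, class = type))
        }
      }
    }
  }
  NULL
}

## An intronic or splice-site substitution for a transcript.
findIntronChange <- function(tr, ref, splice = FALSE) {
  ex <- tr$exons[order(start(tr$exons))]
  if (length(ex) < 2L) return(NULL)
  i <- sample(length(ex) - 1L, 1L)
  lo <- end(ex)[i] + 1L; hi <- start(ex)[i + 1L] - 1L
  if (hi - lo < 10L) return(NULL)
  gpos <- if (splice) end(ex)[i] + sample(1:2, 1L) else sample((lo + 3L):(hi - 3L), 1L)
  refB <- as.character(subseq(ref[[tr$chrom]], gpos, gpos))
  list(cdsPos = NA_integer_, gpos = gpos, chrom = tr$chrom, ref = refB,
       alt = sample(setdiff(c("A", "C", "G", "T"), refB), 1L),
       class = if (splice) "splice-site" else "intronic")
}

## A short frameshift deletion inside an exon (VCF-style anchored alleles,
## left-normalized so truth matches canonical call representation).
findFrameshiftDel <- function(tr, ref) {
  ex <- tr$exons[sample(length(tr$exons), 1L)]
  dlen <- sample(1:2, 1L)
  gpos <- sample((start(ex) + 6L):(end(ex) - 6L - dlen), 1L)
  refA <- as.character(subseq(ref[[tr$chrom]], gpos, gpos + dlen))
  nz <- normalizeIndel(tr$chrom, gpos, refA, substr(refA, 1L, 1L), ref)
  list(cdsPos = NA_integer_, gpos = nz$pos, chrom = tr$chrom, ref = nz$ref,
       alt = nz$alt, class = "frameshift-indel")
}

#' Choose focal planted variants from a simulated reference
#'
#' Picks four nonsense substitutions realizing the study's inheritance
#' scenarios: a compound-heterozygous pair in one gene (partner B inside a
#' GC-rich capture pocket), an autosomal-recessive homozygous variant in a
#' probe-uncovered exon, and a de novo variant in an ordinarily covered
#' gene.
#'
#' @param sim output of [simulateReference()].
#' @param seed RNG seed.
#' @return data.frame of planted variants: chrom, pos, ref, alt, class,
#'   inheritance, gene, inPocket.
#' @export
autoPlant <- function(sim, seed = sim$cfg@seed) {
  withSeed(deriveSeed(seed, "plant"), {
    trs <- transcriptsFromModels(sim$genes)
    gdt <- data.frame(gene = sim$genes$gene_id, pocket = sim$genes$pocket,
                      off = sim$genes$offProbe, rank = sim$genes$exon_rank)
    pocketGenes <- unique(gdt$gene[gdt$pocket])
    offGenes <- unique(gdt$gene[gdt$off])
    plainGenes <- setdiff(unique(gdt$gene), c(pocketGenes, offGenes))
    chGene <- sample(pocketGenes, 1L)
    arGene <- sample(offGenes, 1L)
    dnGene <- sample(plainGenes, 1L)
    mk <- function(gene, rankSel, inheritance, inPocket) {
      tr <- trs[[gene]]
      for (rk in rankSel) {
        hit <- findCodingChange(tr, sim$reference, rk, "nonsense")
        if (!is.null(hit)) {
          return(data.frame(chrom = hit$chrom, pos = hit$gpos, ref = hit$ref,
                            alt = hit$alt, class = "nonsense",
                            inheritance = inheritance, gene = gene,
                            inPocket = inPocket, cdsPos = hit$cdsPos))
        }
      }
      stop("autoPlant: no nonsense-capable codon found in ", gene)
    }
    pocketRank <- gdt$rank[gdt$gene == chGene & gdt$pocket][1]
    otherRanks <- setdiff(gdt$rank[gdt$gene == chGene], pocketRank)
    offRank <- gdt$rank[gdt$gene == arGene & gdt$off][1]
    rbind(
      mk(chGene, sample(otherRanks), "comphet-partner-A", FALSE),
      mk(chGene, pocketRank, "comphet-partner-B", TRUE),
      mk(arGene, offRank, "AR-hom", FALSE),
      mk(dnGene, sample(setdiff(gdt$rank[gdt$gene == dnGene], NULL)),
         "denovo", FALSE)
    )
  })
}

## Apply a haplotype's variants to the reference. vars: data.frame with
## chrom, pos, ref, alt (non-overlapping).
applyHaplotype <- function(reference, vars) {
  out <- reference
  for (ch in names(reference)) {
    v <- vars[vars$chrom == ch, , drop = FALSE]
    if (!nrow(v)) next
    v <- v[order(v$pos), , drop = FALSE]
    got <- as.character(extractAt(reference[[ch]],
                                  IRanges(v$pos, v$pos + nchar(v$ref) - 1L)))
    if (!all(got == v$ref)) stop("planted ref mismatch on ", ch)
    out[[ch]] <- replaceAt(reference[[ch]],
                           IRanges(v$pos, v$pos + nchar(v$ref) - 1L), v$alt)
  }
  out
}

## Reference -> haplotype coordinate shift for positions after indels.
liftPositions <- function(vars, chrom, pos) {
  v <- vars[vars$chrom == chrom & nchar(vars$ref) != nchar(vars$alt), , drop = FALSE]
  if (!nrow(v)) return(pos)
  v <- v[order(v$pos), , drop = FALSE]
  delta <- cumsum(nchar(v$alt) - nchar(v$ref))
  i <- findInterval(pos - 1L, v$pos + nchar(v$ref) - 1L)
  pos + ifelse(i > 0L, delta[pmax(i, 1L)], 0L)
}

#' Plant a pedigree: diploid genomes, truth genotypes, database, array
#'
#' Builds founder haplotypes carrying common (database-known) variants,
#' rare background variants of mixed consequence classes, and the focal
#' planted variants; transmits haplotypes to children (see module header);
#' returns per-member genomes, a truth call table, the known-variant
#' database and array genotypes at the common sites.
#'
#' @param sim output of [simulateReference()].
#' @param members pedigree data.frame (see [pedigreeTrio()]); parental
#'   references must be acyclic and at least one member affected.
#' @param seed RNG seed (default: the simulation seed).
#' @param nCommonKnown number of common, database-known variants.
#' @param nRareBackground number of rare background variants (one founder
#'   haplotype each, one gene at most each).
#' @param planted focal variants (data.frame as from [autoPlant()]); NULL
#'   picks them automatically.
#' @return list with members, variants (registry), truth (long table:
#'   sample, chrom, pos, ref, alt, gt, class, inheritance, gene,
#'   inPocket), genomes (per member: list(h1, h2) DNAStringSets),
#'   hapVars (per member per haplotype variant tables), db, array.
#' @export
plantPedigree <- function(sim, members = pedigreeTrio(), seed = sim$cfg@seed,
                          nCommonKnown = 120L, nRareBackground = 40L,
                          planted = NULL) {
  stopifnot(any(members$affected), !anyDuplicated(members$id))
  if (any(members$father == members$id, na.rm = TRUE) ||
      any(members$mother == members$id, na.rm = TRUE)) {
    stop("plantPedigree: cyclic pedigree")
  }
  if (is.null(planted)) planted <- autoPlant(sim, seed)
  withSeed(deriveSeed(seed, "pedigree"), {
    trs <- transcriptsFromModels(sim$genes)
    focalGenes <- unique(planted$gene)
    founders <- members$id[is.na(members$father) & is.na(members$mother)]
    children <- members$id[!members$id %in% founders]

    usedPos <- data.frame(chrom = planted$chrom, pos = planted$pos)
    farEnough <- function(ch, p) {
      !any(usedPos$chrom == ch & abs(usedPos$pos - p) < 15L)
    }
    claim <- function(ch, p) usedPos <<- rbind(usedPos, data.frame(chrom = ch, pos = p))

    ## ---- common known variants ----------------------------------------
    commonRows <- list()
    geneIds <- names(trs)
    while (length(commonRows) < nCommonKnown) {
      g <- sample(geneIds, 1L)
      tr <- trs[[g]]
      kind <- sample(c("synonymous", "missense", "intronic"), 1L,
                     prob = c(0.35, 0.35, 0.3))
      hit <- if (kind == "intronic") {
        findIntronChange(tr, sim$reference, splice = FALSE)
      } else {
        findCodingChange(tr, sim$reference, sample(length(tr$exons), 1L), kind)
      }
      if (is.null(hit) || !farEnough(hit$chrom, hit$gpos)) next
      claim(hit$chrom, hit$gpos)
      commonRows[[length(commonRows) + 1L]] <- data.frame(
        chrom = hit$chrom, pos = hit$gpos, ref = hit$ref, alt = hit$alt,
        class = hit$class, gene = g)
    }
    common <- do.call(rbind, commonRows)
    common$popAF <- runif(nrow(common), 0.05, 0.45)

    ## ---- rare background variants --------------------------------------
    rareKinds <- rep_len(c("missense", "synonymous", "intronic",
                           "splice-site", "nonsense", "frameshift-indel"),
                         nRareBackground)
    rarePool <- setdiff(geneIds, focalGenes)
    rareRows <- list()
    gi <- 0L
    for (kind in rareKinds) {
      repeat {
        gi <- gi + 1L
        if (gi > length(rarePool)) break
        tr <- trs[[rarePool[gi]]]
        hit <- switch(kind,
          intronic = findIntronChange(tr, sim$reference, splice = FALSE),
          `splice-site` = findIntronChange(tr, sim$reference, splice = TRUE),
          `frameshift-indel` = findFrameshiftDel(tr, sim$reference),
          findCodingChange(tr, sim$reference, sample(length(tr$exons), 1L), kind))
        if (!is.null(hit) && farEnough(hit$chrom, hit$gpos)) {
          claim(hit$chrom, hit$gpos)
          rareRows[[length(rareRows) + 1L]] <- data.frame(
            chrom = hit$chrom, pos = hit$gpos, ref = hit$ref, alt = hit$alt,
            class = hit$class, gene = rarePool[gi])
          break
        }
      }
    }
    rare <- do.call(rbind, rareRows)

    ## ---- registry -------------------------------------------------------
    reg <- rbind(
      data.frame(chrom = common$chrom, pos = common$pos, ref = common$ref,
                 alt = common$alt, class = common$class, gene = common$gene,
                 inheritance = "common", inPocket = FALSE,
                 popAF = common$popAF, inDb = TRUE, pathogenic = FALSE,
                 dbSource = "dbSNP"),
      data.frame(chrom = rare$chrom, pos = rare$pos, ref = rare$ref,
                 alt = rare$alt, class = rare$class, gene = rare$gene,
                 inheritance = "rare-background", inPocket = FALSE,
                 popAF = NA_real_, inDb = FALSE, pathogenic = FALSE,
                 dbSource = NA_character_),
      data.frame(chrom = planted$chrom, pos = planted$pos, ref = planted$ref,
                 alt = planted$alt, class = planted$class,
                 gene = planted$gene, inheritance = planted$inheritance,
                 inPocket = planted$inPocket, popAF = NA_real_, inDb = FALSE,
                 pathogenic = FALSE, dbSource = NA_character_)
    )
    ## one rare missense is known-pathogenic at MAF < 0.01 (exercises the
    ## pathogenic rescue during database filtering)
    rescueIdx <- which(reg$inheritance == "rare-background" &
                       reg$class == "missense")[1]
    if (!is.na(rescueIdx)) {
      reg$inDb[rescueIdx] <- TRUE
      reg$pathogenic[rescueIdx] <- TRUE
      reg$popAF[rescueIdx] <- 0.005
      reg$dbSource[rescueIdx] <- "ClinVar"
    }
    reg$vid <- seq_len(nrow(reg))

    ## ---- founder haplotype carriage ------------------------------------
    hapNames <- as.vector(outer(founders, c("h1", "h2"), paste, sep = "."))
    carriage <- matrix(FALSE, nrow(reg), length(hapNames),
                       dimnames = list(NULL, hapNames))
    isCommon <- reg$inheritance == "common"
    for (h in hapNames) {
      carriage[isCommon, h] <- runif(sum(isCommon)) < reg$popAF[isCommon]
    }
    isRare <- reg$inheritance == "rare-background"
    carriage[cbind(which(isRare), sample(length(hapNames), sum(isRare),
                                         replace = TRUE))] <- TRUE
    getParent <- function(childId, which) {
      members[[which]][members$id == childId]
    }
    ## focal variants sit on haplotype 1 of the designated parents
    fatherId <- unique(stats::na.omit(members$father))[1]
    motherId <- unique(stats::na.omit(members$mother))[1]
    for (i in which(reg$inheritance == "comphet-partner-A")) {
      carriage[i, paste0(fatherId, ".h1")] <- TRUE
    }
    for (i in which(reg$inheritance == "comphet-partner-B")) {
      carriage[i, paste0(motherId, ".h1")] <- TRUE
    }
    for (i in which(reg$inheritance == "AR-hom")) {
      carriage[i, paste0(fatherId, ".h1")] <- TRUE
      carriage[i, paste0(motherId, ".h1")] <- TRUE
    }
    ## never pre-place de novo variants on founder haplotypes
    carriage[reg$inheritance == "denovo", ] <- FALSE

    ## ---- transmit haplotypes -------------------------------------------
    ## member -> character(2): names of source founder haplotype columns
    hapOf <- list()
    for (m in founders) hapOf[[m]] <- paste0(m, c(".h1", ".h2"))
    for (m in children) {
      f <- getParent(m, "father"); mo <- getParent(m, "mother")
      aff <- members$affected[members$id == m]
      pick <- if (aff) ".h1" else ".h2"
      hapOf[[m]] <- c(paste0(f, pick), paste0(mo, pick))
    }
    memberCarriage <- lapply(members$id, function(m) {
      cm <- carriage[, hapOf[[m]], drop = FALSE]
      colnames(cm) <- c("h1", "h2")
      ## de novo: appears on the paternal haplotype of affected children
      if (members$affected[members$id == m] && m %in% children) {
        cm[reg$inheritance == "denovo", "h1"] <- TRUE
      }
      cm
    })
    names(memberCarriage) <- members$id

    ## ---- genomes, truth -------------------------------------------------
    hapVars <- list(); genomes <- list(); truthRows <- list()
    for (m in members$id) {
      cm <- memberCarriage[[m]]
      v1 <- reg[cm[, "h1"], , drop = FALSE]
      v2 <- reg[cm[, "h2"], , drop = FALSE]
      hapVars[[m]] <- list(h1 = v1, h2 = v2)
      genomes[[m]] <- list(h1 = applyHaplotype(sim$reference, v1),
                           h2 = applyHaplotype(sim$reference, v2))
      any1 <- cm[, "h1"]; any2 <- cm[, "h2"]
      carried <- which(any1 | any2)
      if (length(carried)) {
        truthRows[[m]] <- data.frame(
          sample = m, chrom = reg$chrom[carried], pos = reg$pos[carried],
          ref = reg$ref[carried], alt = reg$alt[carried],
          gt = paste0(as.integer(any1[carried]), "|", as.integer(any2[carried])),
          class = reg$class[carried], inheritance = reg$inheritance[carried],
          gene = reg$gene[carried], inPocket = reg$inPocket[carried])
      }
    }
    truth <- do.call(rbind, truthRows)
    rownames(truth) <- NULL

    ## ---- database and array --------------------------------------------
    db <- data.frame(chrom = reg$chrom[reg$inDb], pos = reg$pos[reg$inDb],
                     ref = reg$ref[reg$inDb], alt = reg$alt[reg$inDb],
                     af = reg$popAF[reg$inDb],
                     pathogenic = reg$pathogenic[reg$inDb],
                     source = reg$dbSource[reg$inDb])
    arrRows <- list()
    commonIdx <- which(isCommon)
    for (m in members$id) {
      cm <- memberCarriage[[m]]
      nAlt <- as.integer(cm[commonIdx, "h1"]) + as.integer(cm[commonIdx, "h2"])
      arrRows[[m]] <- data.frame(
        sample = m, chrom = reg$chrom[commonIdx], pos = reg$pos[commonIdx],
        ref = reg$ref[commonIdx], alt = reg$alt[commonIdx],
        genotype = c("hom-ref", "het", "hom-alt")[nAlt + 1L])
    }
    list(members = members, variants = reg, truth = truth,
         genomes = genomes, hapVars = hapVars, db = db,
         array = do.call(rbind, arrRows))
  })
}
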