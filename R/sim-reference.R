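## Synthetic reference, gene models and capture-probe design.
##
## The generator emulates the empirical structure the pipeline is built
## for: protein-coding genes with multi-exon CDS, a capture probe set that
## misses a few percent of CDS by design, and GC-rich exon "pockets" whose
## capture efficiency collapses under the GC-bias model, producing the
## systematic low-coverage CDS regions the complement panel targets.

SENSE_CODONS <- setdiff(
  as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"), paste0),
                  c("T", "C", "A", "G"), paste0)),
  c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")
GC3_CODONS <- SENSE_CODONS[vapply(SENSE_CODONS, function(cd)
  sum(strsplit(cd, "")[[1]] %in% c("G", "C")) == 3L, logical(1))]
GC2_CODONS <- SENSE_CODONS[vapply(SENSE_CODONS, function(cd)
  sum(strsplit(cd, "")[[1]] %in% c("G", "C")) == 2L, logical(1))]

#' Simulate a reference genome with gene models and capture probes
#'
#' Generates random chromosomes, places non-overlapping strand-annotated
#' multi-exon genes whose CDS length is a codon multiple (ATG ... stop),
#' embeds GC-rich pocket exons (capture-resistant regions) in a known
#' subset of genes, leaves a configurable fraction of CDS out of the
#' capture probe design, and tiles 120-bp capture probes over the rest.
#'
#' @param cfg a [SimConfig-class].
#' @return list with `reference` (DNAStringSet), `genes` (GRanges of CDS
#'   exons; mcols gene_id, exon_rank, pocket, offProbe), `cds` (reduced
#'   CDS GRanges), `wesProbes` (GRanges with per-probe `gc`), `pockets`,
#'   `offProbe` (GRanges), `seqlens`, and `cfg`.
#' @export
simulateReference <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  withSeed(deriveSeed(cfg@seed, "reference"), {
    chroms <- paste0("chr", seq_len(cfg@nChrom))
    seqlens <- setNames(rep(cfg@chromLen, cfg@nChrom), chroms)
    geneChrom <- sort(rep(chroms, length.out = cfg@nGenes))

    ## --- gene skeletons ---------------------------------------------------
    skel <- vector("list", cfg@nGenes)
    cursor <- setNames(rep(2000L, cfg@nChrom), chroms)
    for (g in seq_len(cfg@nGenes)) {
      ch <- geneChrom[g]
      nex <- cfg@exonsPerGene
      exlen <- sample(seq(cfg@exonLenRange[1], cfg@exonLenRange[2]), nex,
                      replace = TRUE)
      exlen <- pmax(30L, (exlen %/% 3L) * 3L)
      inlen <- sample(seq(cfg@intronLenRange[1], cfg@intronLenRange[2]),
                      nex - 1L, replace = TRUE)
      gstart <- cursor[[ch]] + sample(400:1200, 1L)
      starts <- gstart + cumsum(c(0L, exlen[-nex] + inlen))
      ends <- starts + exlen - 1L
      if (ends[nex] > cfg@chromLen - 2000L) {
        stop("simulateReference: chromLen too small for requested genes")
      }
      cursor[[ch]] <- ends[nex]
      skel[[g]] <- list(id = sprintf("G%03d", g), chrom = ch,
                        strand = sample(c("+", "-"), 1L),
                        starts = starts, ends = ends, exlen = exlen)
    }

    ## --- pocket / off-probe exon selection --------------------------------
    totalCds <- sum(vapply(skel, function(s) sum(s$exlen), integer(1)))
    midExon <- function(s) (length(s$exlen) + 1L) %/% 2L
    ord <- sample(seq_len(cfg@nGenes))
    pocketSel <- list(); pocketBases <- 0L
    offSel <- list(); offBases <- 0L
    for (g in ord) {
      if (pocketBases < cfg@lowcovFraction * totalCds) {
        pocketSel[[length(pocketSel) + 1L]] <- c(g, midExon(skel[[g]]))
        pocketBases <- pocketBases + skel[[g]]$exlen[midExon(skel[[g]])]
      } else if (offBases < cfg@offProbeFraction * totalCds) {
        offSel[[length(offSel) + 1L]] <- c(g, midExon(skel[[g]]))
        offBases <- offBases + skel[[g]]$exlen[midExon(skel[[g]])]
      } else {
        break
      }
    }
    pocketKey <- vapply(pocketSel, function(x) paste(x, collapse = ":"), character(1))
    offKey <- vapply(offSel, function(x) paste(x, collapse = ":"), character(1))

    ## --- sequence content -------------------------------------------------
    genome <- DNAStringSet(vapply(chroms, function(ch)
      randomDna(cfg@chromLen), character(1)))
    names(genome) <- chroms

    exonRows <- list()
    for (g in seq_len(cfg@nGenes)) {
      s <- skel[[g]]
      nex <- length(s$exlen)
      ncod <- sum(s$exlen) %/% 3L
      isPocket <- paste(g, seq_len(nex), sep = ":") %in% pocketKey
      isOff <- paste(g, seq_len(nex), sep = ":") %in% offKey
      ## transcription-ordered codons, exon by exon
      codonChunks <- vector("list", nex)
      for (e in seq_len(nex)) {
        ncd <- s$exlen[e] %/% 3L
        if (isPocket[e]) {
          pick <- ifelse(runif(ncd) < 0.7,
                         sample(GC3_CODONS, ncd, replace = TRUE),
                         sample(GC2_CODONS, ncd, replace = TRUE))
        } else {
          pick <- sample(SENSE_CODONS, ncd, replace = TRUE)
        }
        if (isPocket[e] || isOff[e]) pick[(ncd + 1L) %/% 2L] <- "CGA"
        codonChunks[[e]] <- pick
      }
      codonChunks[[1]][1] <- "ATG"
      codonChunks[[nex]][length(codonChunks[[nex]])] <- sample(STOP_CODONS, 1L)
      ## write exon sequences: transcription rank follows the strand
      ranks <- if (s$strand == "+") seq_len(nex) else rev(seq_len(nex))
      for (e in seq_len(nex)) {        # e = genomic order index
        rk <- which(ranks == e)        # transcription rank of this exon
        chunk <- paste(codonChunks[[rk]], collapse = "")
        if (s$strand == "-") chunk <- revcompChar(chunk)
        genome[[s$chrom]] <- replaceAt(genome[[s$chrom]],
                                       IRanges(s$starts[e], s$ends[e]), chunk)
        exonRows[[length(exonRows) + 1L]] <- data.frame(
          chrom = s$chrom, start = s$starts[e], end = s$ends[e],
          strand = s$strand, gene_id = s$id, exon_rank = ranks[e],
          pocket = isPocket[ranks[e]], offProbe = isOff[ranks[e]])
      }
    }
    exdf <- do.call(rbind, exonRows)
    genes <- GRanges(exdf$chrom, IRanges(exdf$start, exdf$end),
                     strand = exdf$strand, gene_id = exdf$gene_id,
                     exon_rank = exdf$exon_rank, pocket = exdf$pocket,
                     offProbe = exdf$offProbe, seqlengths = seqlens)

    ## --- capture probes ---------------------------------------------------
    probeLen <- 120L; step <- 90L
    tiles <- list()
    for (i in seq_along(genes)) {
      if (genes$offProbe[i]) next
      s0 <- max(1L, start(genes)[i] - 10L)
      e0 <- min(cfg@chromLen, end(genes)[i] + 10L)
      if (e0 - s0 + 1L <= probeLen) {
        st <- max(1L, s0 - (probeLen - (e0 - s0 + 1L)) %/% 2L)
      } else {
        st <- seq(s0, e0 - probeLen + 1L, by = step)
        if (st[length(st)] + probeLen - 1L < e0) st <- c(st, e0 - probeLen + 1L)
      }
      tiles[[length(tiles) + 1L]] <- data.frame(
        chrom = as.character(seqnames(genes))[i], start = st)
    }
    tdf <- do.call(rbind, tiles)
    wesProbes <- GRanges(tdf$chrom, IRanges(tdf$start, width = probeLen),
                         seqlengths = seqlens)
    gcv <- numeric(length(wesProbes))
    for (ch in chroms) {
      ii <- which(as.character(seqnames(wesProbes)) == ch)
      if (length(ii)) {
        gcv[ii] <- gcFraction(extractAt(genome[[ch]], ranges(wesProbes)[ii]))
      }
    }
    wesProbes$gc <- gcv

    list(reference = genome, genes = genes,
         cds = reduce(genes, ignore.strand = TRUE),
         wesProbes = wesProbes,
         pockets = reduce(genes[genes$pocket], ignore.strand = TRUE),
         offProbe = reduce(genes[genes$offProbe], ignore.strand = TRUE),
         seqlens = seqlens, cfg = cfg)
  })
}
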