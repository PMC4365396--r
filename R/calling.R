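## Pileup construction and threshold-based SNV/short-indel calling.
##
## Scores (the upstream tools' internals are version-bound, so the package
## defines its own deterministic, monotone equivalents):
##   variant score   = min(99, sum of alt-supporting base qualities) —
##                     Phred-scaled probability that every alt base is an
##                     error (independent errors).
##   consensus score = min(99, Phred-scaled posterior of the called
##                     genotype under a symmetric-error binomial model with
##                     uniform prior over {hom-ref, het, hom-alt}).
## Both are gated at >= 20 for emitted variants.

## Per-alignment callable segments with read offsets.
## Returns data.table(ai, chrom, refStart, len, readOff).
alignmentSegments <- function(aln) {
  dt <- data.table::as.data.table(aln)
  n <- nrow(dt)
  if (!n) {
    return(data.table(ai = integer(0), chrom = character(0),
                      refStart = integer(0), len = integer(0), readOff = integer(0)))
  }
  if (is.null(dt$maskN)) dt[, "maskN" := 0L]
  if (is.null(dt$gapType)) {
    dt[, c("gapType", "gapPos", "gapLen") :=
         list(NA_character_, NA_integer_, NA_integer_)]
  }
  dt[, "ai" := .I]
  lo <- dt$maskN + 1L
  hi <- dt$readLen - dt$maskN
  hasgap <- !is.na(dt$gapType)
  s1hi <- ifelse(hasgap, pmin(hi, dt$gapPos), hi)
  seg1 <- data.table(ai = dt$ai, chrom = dt$chrom,
                     refStart = dt$start + lo - 1L,
                     len = s1hi - lo + 1L, readOff = lo)[len > 0L]
  out <- list(seg1)
  if (any(hasgap)) {
    g <- dt[hasgap]
    glo <- pmax(lo[hasgap], g$gapPos + 1L + fifelse(g$gapType == "I", g$gapLen, 0L))
    ghi <- hi[hasgap]
    refShift <- fifelse(g$gapType == "D", g$gapLen, -g$gapLen)
    seg2 <- data.table(ai = g$ai, chrom = g$chrom,
                       refStart = g$start + glo - 1L + refShift,
                       len = ghi - glo + 1L, readOff = glo)[len > 0L]
    out[[2]] <- seg2
  }
  rbindlist(out)
}

#' Build a pileup over on-target space
#'
#' Tallies, per reference base, the callable read bases (quality >=
#' `minBq`, terminal masked bases and deletion gaps excluded, duplicates
#' excluded) plus the alt-base and indel evidence needed for calling.
#'
#' @param aln alignment table.
#' @param targets GRanges of on-target space (seqlengths set).
#' @param ref named DNAStringSet reference.
#' @param minBq minimum base quality (default 20).
#' @param maxDepth depth cap per column (default 10000): later-starting
#'   reads over the cap are dropped.
#' @param sampleId,platform labels.
#' @return list with `depth` (per-chromosome integer vectors of quality-
#'   passing callable depth), `snvSites` (data.table chrom, pos, base,
#'   count, qualSum, meanQual), `indelSites` (data.table chrom, pos,
#'   gapType, gapLen, inserted, count), `targets`, `sampleId`, `platform`.
#' @export
buildPileup <- function(aln, targets, ref, minBq = 20L, maxDepth = 10000L,
                        sampleId = "S1", platform = "WES") {
  sl <- seqlengths(targets)
  if (any(is.na(sl))) stop("buildPileup: targets must carry seqlengths")
  if (!is.null(aln$dup)) aln <- aln[!aln$dup, , drop = FALSE]
  ## depth cap: drop later-starting reads over columns exceeding the cap
  if (nrow(aln)) {
    for (it in seq_len(1000L)) {
      covr <- alignmentCoveredRanges(aln)
      over <- NULL
      for (ch in unique(covr$chrom)) {
        r <- covr[covr$chrom == ch]
        cv <- coverage(IRanges(r$start, r$end), width = sl[[ch]])
        if (max(cv) > maxDepth) {
          p <- which(as.integer(cv) > maxDepth)[1]
          cand <- which(aln$chrom == ch & aln$start <= p &
                        aln$start + aln$readLen + 12L >= p)
          over <- cand[which.max(aln$start[cand])]
          break
        }
      }
      if (is.null(over)) break
      aln <- aln[-over, , drop = FALSE]
    }
  }
  segs <- alignmentSegments(aln)
  ## raw callable depth
  depth <- lapply(names(sl), function(ch) {
    r <- segs[segs$chrom == ch]
    if (!nrow(r)) return(integer(sl[[ch]]))
    as.integer(coverage(IRanges(r$refStart, width = r$len), width = sl[[ch]]))
  })
  names(depth) <- names(sl)
  ## per-base exceptions: mismatches and low-quality bases
  mmRows <- list(); lowqRows <- list()
  if (nrow(segs)) {
    segs[, "grp" := paste0(chrom, ":", len)]
    for (g in unique(segs$grp)) {
      sg <- segs[segs$grp == g]
      ch <- sg$chrom[1]; L <- sg$len[1]
      rdChar <- substr(aln$seq[sg$ai], sg$readOff, sg$readOff + L - 1L)
      qChar <- substr(aln$qual[sg$ai], sg$readOff, sg$readOff + L - 1L)
      chunk <- 100000L
      for (i0 in seq(1L, nrow(sg), by = chunk)) {
        j0 <- min(i0 + chunk - 1L, nrow(sg))
        idx <- i0:j0
        rm <- matrix(unlist(strsplit(rdChar[idx], ""), use.names = FALSE),
                     ncol = L, byrow = TRUE)
        fm <- as.matrix(extractAt(ref[[ch]],
                                  IRanges(sg$refStart[idx], width = L)))
        qm <- matrix(utf8ToInt(paste(qChar[idx], collapse = "")) - 33L,
                     ncol = L, byrow = TRUE)
        lowq <- qm < minBq
        mism <- rm != fm & !lowq
        if (any(lowq)) {
          wq <- which(lowq, arr.ind = TRUE)
          lowqRows[[length(lowqRows) + 1L]] <- data.table(
            chrom = ch, pos = sg$refStart[idx][wq[, 1]] + wq[, 2] - 1L)
        }
        if (any(mism)) {
          wm <- which(mism, arr.ind = TRUE)
          mmRows[[length(mmRows) + 1L]] <- data.table(
            chrom = ch, pos = sg$refStart[idx][wm[, 1]] + wm[, 2] - 1L,
            base = rm[wm], qual = qm[wm])
        }
      }
    }
  }
  lowq <- if (length(lowqRows)) rbindlist(lowqRows)[, list(n = .N), by = c("chrom", "pos")]
          else data.table(chrom = character(0), pos = integer(0), n = integer(0))
  ## subtract low-quality bases from callable depth
  for (i in seq_len(nrow(lowq))) {
    depth[[lowq$chrom[i]]][lowq$pos[i]] <-
      depth[[lowq$chrom[i]]][lowq$pos[i]] - lowq$n[i]
  }
  snv <- if (length(mmRows)) {
    rbindlist(mmRows)[, list(count = .N, qualSum = sum(qual),
                             meanQual = mean(qual)),
                      by = c("chrom", "pos", "base")]
  } else {
    data.table(chrom = character(0), pos = integer(0), base = character(0),
               count = integer(0), qualSum = numeric(0), meanQual = numeric(0))
  }
  ## indel evidence from gapped alignments
  ind <- data.table(chrom = character(0), pos = integer(0),
                    gapType = character(0), gapLen = integer(0),
                    inserted = character(0), count = integer(0))
  if (nrow(aln) && !is.null(aln$gapType) && any(!is.na(aln$gapType))) {
    gi <- which(!is.na(aln$gapType))
    ga <- aln[gi, , drop = FALSE]
    inserted <- ifelse(ga$gapType == "I",
                       substr(ga$seq, ga$gapPos + 1L, ga$gapPos + ga$gapLen), "")
    ind <- data.table(chrom = ga$chrom, pos = ga$start + ga$gapPos - 1L,
                      gapType = ga$gapType, gapLen = ga$gapLen,
                      inserted = inserted)[
      , list(count = .N), by = c("chrom", "pos", "gapType", "gapLen", "inserted")]
  }
  ## restrict candidate sites to on-target space
  inTargets <- function(dtb) {
    if (!nrow(dtb)) return(dtb)
    gr <- GRanges(dtb$chrom, IRanges(dtb$pos, dtb$pos))
    dtb[overlapsAny(gr, targets, ignore.strand = TRUE)]
  }
  list(depth = depth, snvSites = inTargets(snv), indelSites = inTargets(ind),
       targets = reduce(targets, ignore.strand = TRUE),
       sampleId = sampleId, platform = platform)
}

#' Depth profile of a pileup
#'
#' @param pileup output of [buildPileup()].
#' @return a [DepthProfile-class] of the quality-passing callable depth.
#' @export
pileupDepthProfile <- function(pileup) {
  new("DepthProfile",
      cov = as(lapply(pileup$depth, Rle), "RleList"),
      targets = pileup$targets, sampleId = pileup$sampleId,
      platform = pileup$platform)
}

#' Classify zygosity from allele frequency and depth
#'
#' Heterozygous for alt allele frequency in the closed interval
#' [0.25, 0.75], homozygous above 0.75, missing below 0.25 or at depth
#' below `minDepth`.
#'
#' @param af alt allele frequency (vectorized).
#' @param depth read depth (vectorized).
#' @param minDepth callability threshold (default 10).
#' @return character vector in {"heterozygous", "homozygous", "missing"}.
#' @examples
#' classifyZygosity(c(0.5, 0.8, 0.2), c(30, 30, 30))
#' classifyZygosity(0.5, 9)  # missing
#' @export
classifyZygosity <- function(af, depth, minDepth = 10L) {
  ifelse(depth < minDepth | af < 0.25, "missing",
         ifelse(af <= 0.75, "heterozygous", "homozygous"))
}

## Genotype posterior (symmetric-error binomial, uniform prior).
consensusScore <- function(k, n, meanQual, called) {
  e <- pmin(0.5, 10^(-meanQual / 10))
  ll <- cbind(
    homref = k * log(e / 3) + (n - k) * log(1 - e),
    het = n * log(0.5),
    homalt = k * log(1 - e) + (n - k) * log(e / 3)
  )
  mx <- apply(ll, 1, max)
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  p <- post[cbind(seq_len(nrow(post)), match(called, colnames(ll)))]
  pmin(99, -10 * log10(pmax(1 - p, 1e-12)))
}

#' Left-normalize an indel call
#'
#' Shifts an anchored indel to its leftmost equivalent representation
#' (idempotent); SNVs pass through unchanged.
#'
#' @param chrom,pos,refAllele,altAllele the call (VCF-style anchored
#'   alleles, 1-based `pos`).
#' @param ref named DNAStringSet reference.
#' @return list(pos, ref, alt).
#' @export
normalizeIndel <- function(chrom, pos, refAllele, altAllele, ref) {
  r <- refAllele; a <- altAllele
  if (nchar(r) == nchar(a)) return(list(pos = pos, ref = r, alt = a))
  seq <- ref[[chrom]]
  repeat {
    ## drop identical trailing base, re-extending left when exhausted
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    if (substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a)) &&
        pos > 1L) {
      prev <- as.character(subseq(seq, pos - 1L, pos - 1L))
      r <- paste0(prev, substr(r, 1L, nchar(r) - 1L))
      a <- paste0(prev, substr(a, 1L, nchar(a) - 1L))
      pos <- pos - 1L
    } else {
      break
    }
  }
  ## drop identical leading bases beyond the anchor
  while (nchar(r) > 1L && nchar(a) > 1L &&
         substr(r, 1L, 1L) == substr(a, 1L, 1L) &&
         substr(r, 2L, 2L) == substr(a, 2L, 2L)) {
    r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a))
    pos <- pos + 1L
  }
  list(pos = pos, ref = r, alt = a)
}

#' Call variants from a pileup
#'
#' Emits a site when the highest-frequency alt allele reaches frequency >=
#' `minAf` at depth >= `minDepth` with variant and consensus scores >= 20.
#' Indels are left-normalized. Columns below depth or frequency thresholds
#' are "missing" (not emitted).
#'
#' @param pileup output of [buildPileup()].
#' @param ref named DNAStringSet reference.
#' @param minDepth,minAf,minScore calling thresholds (defaults 10, 0.25, 20).
#' @param indelQual assumed per-read support quality for indel scores
#'   (default 35).
#' @return data.frame of calls: sample, chrom, pos, ref, alt, type, depth,
#'   af, vs, cs, zygosity, gt, source.
#' @export
callVariants <- function(pileup, ref, minDepth = 10L, minAf = 0.25,
                         minScore = 20, indelQual = 35) {
  out <- list()
  snv <- pileup$snvSites
  if (nrow(snv)) {
    snv <- snv[order(-snv$count), ]
    snv <- snv[!duplicated(snv[, c("chrom", "pos")]), ]  # highest-af alt
    dp <- mapply(function(ch, p) pileup$depth[[ch]][p], snv$chrom, snv$pos)
    af <- snv$count / pmax(dp, 1L)
    zyg <- classifyZygosity(af, dp, minDepth)
    vs <- pmin(99, snv$qualSum)
    called <- ifelse(af <= 0.75, "het", "homalt")
    cs <- consensusScore(snv$count, dp, snv$meanQual, called)
    keep <- zyg != "missing" & vs >= minScore & cs >= minScore
    if (any(keep)) {
      refb <- vapply(which(keep), function(i)
        as.character(subseq(ref[[snv$chrom[i]]], snv$pos[i], snv$pos[i])),
        character(1))
      out$snv <- data.frame(
        sample = pileup$sampleId, chrom = snv$chrom[keep], pos = snv$pos[keep],
        ref = refb, alt = snv$base[keep], type = "SNV",
        depth = dp[keep], af = af[keep], vs = vs[keep], cs = cs[keep],
        zygosity = zyg[keep])
    }
  }
  ind <- pileup$indelSites
  if (nrow(ind)) {
    ind <- ind[order(-ind$count), ]
    ind <- ind[!duplicated(ind[, c("chrom", "pos")]), ]
    dp <- mapply(function(ch, p) pileup$depth[[ch]][p], ind$chrom, ind$pos)
    af <- ind$count / pmax(dp, 1L)
    zyg <- classifyZygosity(af, dp, minDepth)
    vs <- pmin(99, indelQual * ind$count)
    called <- ifelse(af <= 0.75, "het", "homalt")
    cs <- consensusScore(ind$count, dp, rep(indelQual, nrow(ind)), called)
    keep <- zyg != "missing" & vs >= minScore & cs >= minScore
    if (any(keep)) {
      rows <- lapply(which(keep), function(i) {
        ch <- ind$chrom[i]; p <- ind$pos[i]
        anchor <- as.character(subseq(ref[[ch]], p, p))
        if (ind$gapType[i] == "D") {
          ra <- as.character(subseq(ref[[ch]], p, p + ind$gapLen[i]))
          aa <- anchor
        } else {
          ra <- anchor
          aa <- paste0(anchor, ind$inserted[i])
        }
        nz <- normalizeIndel(ch, p, ra, aa, ref)
        data.frame(sample = pileup$sampleId, chrom = ch, pos = nz$pos,
                   ref = nz$ref, alt = nz$alt, type = "indel",
                   depth = dp[i], af = af[i], vs = vs[i], cs = cs[i],
                   zygosity = zyg[i])
      })
      out$ind <- do.call(rbind, rows)
    }
  }
  if (!length(out)) {
    return(data.frame(sample = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      type = character(0), depth = integer(0), af = numeric(0),
                      vs = numeric(0), cs = numeric(0), zygosity = character(0),
                      gt = character(0), source = character(0)))
  }
  calls <- do.call(rbind, out)
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  calls$gt <- ifelse(calls$zygosity == "homozygous", "1/1", "0/1")
  calls$source <- pileup$platform
  rownames(calls) <- NULL
  calls
}

#' Sites with sub-threshold variant evidence ("missing")
#'
#' Positions carrying noticeable alt-base evidence (at least
#' `minAltEvidence` quality-passing alt reads) that nevertheless produced
#' no call — typically alt frequency below the calling band at modest
#' depth. Conservative concordance estimation excludes these from
#' comparison instead of scoring them as hom-ref.
#'
#' @param pileup output of [buildPileup()].
#' @param calls calls emitted from the same pileup.
#' @param minAltEvidence minimum alt reads to flag a site (default 2).
#' @return data.frame with sample, chrom, pos.
#' @export
missingEvidenceSites <- function(pileup, calls, minAltEvidence = 2L) {
  snv <- pileup$snvSites
  if (!nrow(snv)) {
    return(data.frame(sample = character(0), chrom = character(0),
                      pos = integer(0)))
  }
  agg <- snv[, list(altn = sum(count)), by = c("chrom", "pos")]
  agg <- agg[agg$altn >= minAltEvidence]
  calledKey <- paste(calls$chrom, calls$pos)
  agg <- agg[!paste(agg$chrom, agg$pos) %in% calledKey]
  if (!nrow(agg)) {
    return(data.frame(sample = character(0), chrom = character(0),
                      pos = integer(0)))
  }
  data.frame(sample = pileup$sampleId, chrom = agg$chrom, pos = agg$pos)
}

#' Merge WES and CCCS call sets
#'
#' Union by (sample, chrom, pos, ref, alt). Sites called identically on
#' both platforms get source "BOTH"; genotype conflicts resolve to the
#' higher-depth call and are flagged.
#'
#' @param wes,cccs call data.frames from [callVariants()].
#' @return merged call data.frame with `source` in {WES, CCCS, BOTH} and a
#'   logical `conflict` column.
#' @export
mergeCallsets <- function(wes, cccs) {
  key <- function(d) paste(d$sample, d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  w <- wes; c2 <- cccs
  w$conflict <- FALSE; c2$conflict <- FALSE
  kw <- key(w); kc <- key(c2)
  both <- intersect(kw, kc)
  onlyW <- w[!kw %in% both, , drop = FALSE]
  onlyC <- c2[!kc %in% both, , drop = FALSE]
  rows <- list(onlyW, onlyC)
  for (k in both) {
    a <- w[kw == k, , drop = FALSE][1, ]
    b <- c2[kc == k, , drop = FALSE][1, ]
    if (a$zygosity == b$zygosity) {
      r <- a; r$source <- "BOTH"
      r$depth <- max(a$depth, b$depth)
    } else {
      r <- if (a$depth >= b$depth) a else b
      r$conflict <- TRUE
    }
    rows[[length(rows) + 1L]] <- r
  }
  outd <- do.call(rbind, rows)
  outd <- outd[order(outd$sample, outd$chrom, outd$pos), , drop = FALSE]
  rownames(outd) <- NULL
  outd
}
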