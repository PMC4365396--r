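suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

## Small named reference from character vectors.
toyRef <- function(...) {
  x <- DNAStringSet(c(...))
  if (is.null(names(x))) names(x) <- paste0("chr", seq_along(x))
  x
}

rcomp <- function(x) as.character(reverseComplement(DNAString(x)))

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

## Constant-quality read list (the structure simulators emit).
mkReads <- function(seqs, qual = NULL) {
  s <- DNAStringSet(seqs)
  if (is.null(names(s))) names(s) <- paste0("p", seq_along(s))
  q <- if (is.null(qual)) {
    BStringSet(vapply(nchar(seqs), function(n)
      paste(rep("D", n), collapse = ""), character(1)))  # Q35
  } else {
    BStringSet(qual)
  }
  list(seq = s, qual = q)
}

## One ungapped alignment-table row.
mkAlnRow <- function(qname, chrom, strand, start, seq, qual = NULL,
                     mate = 1L, maskN = 0L, mm = 0L, sample = "S1",
                     dup = FALSE, insert = NA_integer_) {
  if (is.null(qual)) qual <- paste(rep("D", nchar(seq)), collapse = "")
  data.frame(qname = qname, sample = sample, chrom = chrom, strand = strand,
             start = start, readLen = nchar(seq), seq = seq, qual = qual,
             mate = mate, mm = mm, gapType = NA_character_,
             gapPos = NA_integer_, gapLen = NA_integer_, maskN = maskN,
             dup = dup, insert = insert, stringsAsFactors = FALSE)
}

## Brute-force per-base depth oracle: counts callable read bases covering
## each position (mask-aware, deletion gaps skipped).
bruteDepth <- function(aln, chromLens) {
  out <- lapply(chromLens, function(L) integer(L))
  if (!is.null(aln$dup)) aln <- aln[!aln$dup, , drop = FALSE]
  for (i in seq_len(nrow(aln))) {
    L <- aln$readLen[i]; mk <- aln$maskN[i]
    for (b in seq_len(L)) {
      if (b <= mk || b > L - mk) next
      if (!is.na(aln$gapType[i])) {
        if (aln$gapType[i] == "I" &&
            b > aln$gapPos[i] && b <= aln$gapPos[i] + aln$gapLen[i]) next
        shift <- if (b <= aln$gapPos[i]) 0L
                 else if (aln$gapType[i] == "D") aln$gapLen[i]
                 else -aln$gapLen[i]
      } else {
        shift <- 0L
      }
      p <- aln$start[i] + b - 1L + shift
      if (p >= 1L && p <= length(out[[aln$chrom[i]]])) {
        out[[aln$chrom[i]]][p] <- out[[aln$chrom[i]]][p] + 1L
      }
    }
  }
  out
}

## Mismatch count between a read and the reference at a given start.
mmAt <- function(readChars, refChars, start) {
  w <- length(readChars)
  if (start < 1L || start + w - 1L > length(refChars)) return(NA_integer_)
  sum(readChars != refChars[start:(start + w - 1L)])
}

## Mismatch count of a read against every reference start (full scan).
scanMm <- function(readChars, refChars) {
  w <- length(readChars); L <- length(refChars)
  ns <- L - w + 1L
  mm <- integer(ns)
  for (k in seq_len(w)) {
    mm <- mm + (readChars[k] != refChars[k:(k + ns - 1L)])
  }
  mm
}

## Naive all-position placement oracle for one pair (FR orientation,
## substitutions only) — O(L * n) scan, independent of the seed-anchored
## implementation.
naivePlacements <- function(seq1, seq2, ref, maxMm = 5L, maxInsert = 1000L) {
  rows <- list()
  r1f <- strsplit(as.character(seq1), "")[[1]]
  r1r <- strsplit(rcomp(as.character(seq1)), "")[[1]]
  r2f <- strsplit(as.character(seq2), "")[[1]]
  r2r <- strsplit(rcomp(as.character(seq2)), "")[[1]]
  w1 <- length(r1f); w2 <- length(r2f)
  for (ch in names(ref)) {
    rc <- strsplit(as.character(ref[[ch]]), "")[[1]]
    L <- length(rc)
    p1f <- which(scanMm(r1f, rc) <= maxMm)
    p1r <- which(scanMm(r1r, rc) <= maxMm)
    p2f <- which(scanMm(r2f, rc) <= maxMm)
    p2r <- which(scanMm(r2r, rc) <= maxMm)
    ## mate1 forward + mate2 reverse
    for (a in p1f) for (b in p2r) {
      ins <- b + w2 - a
      if (a <= b + w2 - 1L && ins <= maxInsert && ins >= max(w1, w2)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, pos1 = a, pos2 = b, fwdMate = 1L, insert = ins,
          mm1 = mmAt(r1f, rc, a), mm2 = mmAt(r2r, rc, b))
      }
    }
    ## mate2 forward + mate1 reverse
    for (a in p2f) for (b in p1r) {
      ins <- b + w1 - a
      if (a <= b + w1 - 1L && ins <= maxInsert && ins >= max(w1, w2)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, pos1 = b, pos2 = a, fwdMate = 2L, insert = ins,
          mm1 = mmAt(r1r, rc, b), mm2 = mmAt(r2f, rc, a))
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), pos1 = integer(0),
                      pos2 = integer(0), fwdMate = integer(0),
                      insert = integer(0), mm1 = integer(0), mm2 = integer(0)))
  }
  out <- do.call(rbind, rows)
  out$totalMm <- out$mm1 + out$mm2
  out[order(out$chrom, out$pos1, out$pos2, out$fwdMate), , drop = FALSE]
}

## Exhaustive left-shift oracle for indel normalization: enumerate every
## equivalent representation by shifting and return the leftmost.
shiftOracle <- function(chrom, pos, refA, altA, ref) {
  seqc <- strsplit(as.character(ref[[chrom]]), "")[[1]]
  apply1 <- function(p, r, a) {
    ## haplotype produced by applying the edit
    paste(c(seqc[seq_len(p - 1L)], strsplit(a, "")[[1]],
            seqc[(p + nchar(r)):length(seqc)]), collapse = "")
  }
  target <- apply1(pos, refA, altA)
  best <- list(pos = pos, ref = refA, alt = altA)
  indelLen <- abs(nchar(refA) - nchar(altA))
  isDel <- nchar(refA) > nchar(altA)
  for (p in seq_len(pos)) {
    if (isDel) {
      r <- paste(seqc[p:(p + indelLen)], collapse = "")
      a <- seqc[p]
    } else {
      next  # insertions handled by direct comparison below
    }
    if (p + nchar(r) - 1L <= length(seqc) && apply1(p, r, a) == target &&
        p < best$pos) {
      best <- list(pos = p, ref = r, alt = a)
    }
  }
  if (!isDel) {
    insSeq <- substr(altA, 2L, nchar(altA))
    for (p in seq_len(pos)) {
      for (rot in seq_len(nchar(insSeq))) {
        a <- paste0(seqc[p], substr(paste0(insSeq, insSeq), rot, rot + indelLen - 1L))
        if (apply1(p, seqc[p], a) == target && p < best$pos) {
          best <- list(pos = p, ref = seqc[p], alt = a)
        }
      }
    }
  }
  best
}

## Tiny deterministic toy simulation shared by several test files.
toySim <- function(seed = 11L, nGenes = 12L, chromLen = 60000L, ...) {
  simulateReference(simConfig(seed = seed, nChrom = 1L, chromLen = chromLen,
                              nGenes = nGenes, ...))
}
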