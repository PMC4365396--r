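## Placement engine: exact-seed anchoring (matchPDict) + full verification.
##
## Splitting a read into (maxMm + 1) disjoint segments guarantees (by
## pigeonhole) that any placement with <= maxMm substitutions is hit by at
## least one exact seed, so the ungapped enumeration is complete within the
## mismatch bound. A single-gap (<= 10 bp) fit is attempted for reads with
## no ungapped placement, standing in for local indel realignment.

## Exact-match start positions of constant-width seeds in one chromosome.
## PDict construction has a large fixed overhead, so small seed sets go
## through per-seed matchPattern instead.
seedHits <- function(seedset, refChrom) {
  if (length(seedset) > 512L) {
    m <- matchPDict(PDict(seedset), refChrom)
    stl <- startIndex(m)
    return(data.table(sidx = rep(seq_along(stl), lengths(stl)),
                      hstart = unlist(stl, use.names = FALSE)))
  }
  hits <- lapply(seq_along(seedset), function(i) {
    start(matchPattern(seedset[[i]], refChrom))
  })
  data.table(sidx = rep(seq_along(hits), lengths(hits)),
             hstart = unlist(hits, use.names = FALSE))
}

## All ungapped placements of each read on the forward reference strands.
## reads: DNAStringSet; returns data.table(idx, chrom, strand, start, mm)
## where `strand` is the strand the READ matches ( "-" means the reverse
## complement of the read matches the forward reference at `start`).
placementsUngapped <- function(reads, ref, maxMm = 5L, seeds = NULL) {
  res <- list()
  widths <- width(reads)
  for (st in c("+", "-")) {
    orj <- if (st == "+") reads else reverseComplement(reads)
    for (w in unique(widths)) {
      grp <- which(widths == w)
      nseg <- min(maxMm + 1L, w %/% 8L)
      if (nseg < 1L) next
      seglen <- w %/% nseg
      sub <- orj[grp]
      offs <- (seq_len(nseg) - 1L) * seglen
      seedset <- do.call(c, lapply(offs, function(o) narrow(sub, o + 1L, o + seglen)))
      names(seedset) <- NULL
      for (ch in names(ref)) {
        h <- seedHits(seedset, ref[[ch]])
        if (!nrow(h)) next
        ridx <- grp[((h$sidx - 1L) %% length(grp)) + 1L]
        cstart <- h$hstart - offs[((h$sidx - 1L) %/% length(grp)) + 1L]
        ok <- cstart >= 1L & cstart + w - 1L <= length(ref[[ch]])
        cand <- unique(data.table(idx = ridx[ok], start = cstart[ok]))
        if (!nrow(cand)) next
        ## verify candidates in chunks
        rmat <- NULL
        mmv <- integer(nrow(cand))
        map <- match(cand$idx, grp)
        chunk <- 200000L
        for (i in seq(1L, nrow(cand), by = chunk)) {
          j <- min(i + chunk - 1L, nrow(cand))
          if (is.null(rmat)) rmat <- as.matrix(sub)
          win <- as.matrix(extractAt(ref[[ch]], IRanges(cand$start[i:j], width = w)))
          mmv[i:j] <- rowSums(win != rmat[map[i:j], , drop = FALSE])
        }
        keep <- mmv <= maxMm
        if (any(keep)) {
          res[[length(res) + 1L]] <- data.table(
            idx = cand$idx[keep], chrom = ch, strand = st,
            start = cand$start[keep], mm = mmv[keep]
          )
        }
      }
    }
  }
  if (!length(res)) {
    return(data.table(idx = integer(0), chrom = character(0),
                      strand = character(0), start = integer(0), mm = integer(0)))
  }
  unique(rbindlist(res))
}

## Best single-gap placements for reads without ungapped ones.
## cands: data.table(idx, chrom, strand, start) of raw seed anchors.
## Returns data.table(idx, chrom, strand, start, mm, gapType, gapPos, gapLen)
## where mm = substitutions + gap bases.
placementsGapped <- function(reads, ref, cands, maxMm = 5L, maxGap = 10L) {
  out <- list()
  if (!nrow(cands)) {
    return(data.table(idx = integer(0), chrom = character(0), strand = character(0),
                      start = integer(0), mm = integer(0), gapType = character(0),
                      gapPos = integer(0), gapLen = integer(0)))
  }
  for (r in seq_len(nrow(cands))) {
    i <- cands$idx[r]; ch <- cands$chrom[r]; st <- cands$strand[r]
    rs <- if (st == "+") reads[[i]] else reverseComplement(reads[[i]])
    rc <- strsplit(as.character(rs), "")[[1]]
    w <- length(rc)
    refch <- ref[[ch]]
    best <- NULL
    for (gtype in c("D", "I")) {
      for (g in seq_len(maxGap)) {
        if (gtype == "I" && g >= w - 1L) next
        starts <- unique(c(cands$start[r],
                           if (gtype == "D") cands$start[r] - g else cands$start[r] + g))
        for (p in starts) {
          refw <- if (gtype == "D") w + g else w - g
          if (p < 1L || p + refw - 1L > length(refch)) next
          wc <- strsplit(as.character(subseq(refch, p, p + refw - 1L)), "")[[1]]
          if (gtype == "D") {
            ## read base b: prefix -> ref p+b-1; suffix -> ref p+b-1+g
            pre <- cumsum(rc != wc[seq_len(w)])
            sufm <- rc != wc[seq_len(w) + g]
            suf <- rev(cumsum(rev(sufm)))
            tot <- c(pre[seq_len(w - 1L)] + suf[2:w])
            k <- which.min(tot)
            mm <- tot[k] + g
            gp <- k
          } else {
            ## insertion: read bases 1..k vs ref p.., bases k+g+1..w vs ref p+k..
            pre <- cumsum(rc != c(wc, rep("N", g))[seq_len(w)])
            sufm <- rc != c(rep("N", g), wc)[seq_len(w)]
            suf <- rev(cumsum(rev(sufm)))
            ks <- seq_len(w - g - 1L)
            tot <- pre[ks] + suf[ks + g + 1L]
            if (!length(tot)) next
            k <- which.min(tot)
            mm <- tot[k] + g
            gp <- ks[k]
          }
          if (mm <= maxMm && (is.null(best) || mm < best$mm)) {
            best <- list(idx = i, chrom = ch, strand = st, start = p,
                         mm = as.integer(mm), gapType = gtype,
                         gapPos = as.integer(gp), gapLen = as.integer(g))
          }
        }
      }
    }
    if (!is.null(best)) out[[length(out) + 1L]] <- as.data.table(best)
  }
  if (!length(out)) {
    return(data.table(idx = integer(0), chrom = character(0), strand = character(0),
                      start = integer(0), mm = integer(0), gapType = character(0),
                      gapPos = integer(0), gapLen = integer(0)))
  }
  unique(rbindlist(out))
}

## Raw seed anchors (unverified) — reused to feed the gapped fitter.
seedAnchors <- function(reads, ref, nseg = 6L) {
  res <- list()
  widths <- width(reads)
  for (st in c("+", "-")) {
    orj <- if (st == "+") reads else reverseComplement(reads)
    for (w in unique(widths)) {
      grp <- which(widths == w)
      ns <- min(nseg, w %/% 8L)
      seglen <- w %/% ns
      sub <- orj[grp]
      offs <- (seq_len(ns) - 1L) * seglen
      seedset <- do.call(c, lapply(offs, function(o) narrow(sub, o + 1L, o + seglen)))
      names(seedset) <- NULL
      for (ch in names(ref)) {
        h <- seedHits(seedset, ref[[ch]])
        if (!nrow(h)) next
        ridx <- grp[((h$sidx - 1L) %% length(grp)) + 1L]
        cstart <- h$hstart - offs[((h$sidx - 1L) %/% length(grp)) + 1L]
        res[[length(res) + 1L]] <- unique(data.table(
          idx = ridx, chrom = ch, strand = st, start = cstart))
      }
    }
  }
  if (!length(res)) {
    return(data.table(idx = integer(0), chrom = character(0),
                      strand = character(0), start = integer(0)))
  }
  unique(rbindlist(res))
}

## Reference width consumed by a placement.
placementRefWidth <- function(pl, readWidths) {
  w <- readWidths[pl$idx]
  if (is.null(pl$gapType)) return(w)
  ifelse(is.na(pl$gapType), w,
         ifelse(pl$gapType == "D", w + pl$gapLen, w - pl$gapLen))
}

## Combine per-mate placements into proper FR pairs.
## pl1/pl2: placement tables for mate1/mate2 (idx = pair index).
## Returns data.table(idx, chrom, fwdMate, pos1, pos2, strand1, strand2,
##                    insert, mm1, mm2, totalMm, ...gap columns per mate)
properPairs <- function(pl1, pl2, w1, w2, maxInsert = 1000L) {
  rw1 <- placementRefWidth(pl1, w1); rw2 <- placementRefWidth(pl2, w2)
  a <- data.table::copy(pl1)[, "refw" := rw1]
  b <- data.table::copy(pl2)[, "refw" := rw2]
  gcols <- c("gapType", "gapPos", "gapLen")
  for (cc in gcols) {
    if (is.null(a[[cc]])) a[, (cc) := if (cc == "gapType") NA_character_ else NA_integer_]
    if (is.null(b[[cc]])) b[, (cc) := if (cc == "gapType") NA_character_ else NA_integer_]
  }
  combine <- function(fw, rv, fwdMate) {
    m <- merge(fw, rv, by = c("idx", "chrom"), allow.cartesian = TRUE,
               suffixes = c(".f", ".r"))
    if (!nrow(m)) return(NULL)
    m <- m[m$start.f <= m$start.r + m$refw.r - 1L]
    m[, "insert" := m$start.r + m$refw.r - m$start.f]
    m <- m[m$insert <= maxInsert & m$insert >= pmax(m$refw.f, m$refw.r)]
    if (!nrow(m)) return(NULL)
    data.table(
      idx = m$idx, chrom = m$chrom, fwdMate = fwdMate,
      startF = m$start.f, startR = m$start.r,
      mmF = m$mm.f, mmR = m$mm.r, totalMm = m$mm.f + m$mm.r,
      insert = m$insert,
      gapTypeF = m$gapType.f, gapPosF = m$gapPos.f, gapLenF = m$gapLen.f,
      gapTypeR = m$gapType.r, gapPosR = m$gapPos.r, gapLenR = m$gapLen.r
    )
  }
  res <- rbindlist(list(
    combine(a[a$strand == "+"], b[b$strand == "-"], 1L),
    combine(b[b$strand == "+"], a[a$strand == "-"], 2L)
  ))
  if (!nrow(res)) {
    return(data.table(idx = integer(0), chrom = character(0), fwdMate = integer(0),
                      startF = integer(0), startR = integer(0), mmF = integer(0),
                      mmR = integer(0), totalMm = integer(0), insert = integer(0)))
  }
  unique(res)
}

#' Enumerate all proper placements of one read pair
#'
#' Complete within the per-mate mismatch bound: every placement of the pair
#' in convergent (FR) orientation with at most `maxMm` substitutions per
#' mate and insert size at most `maxInsert` is reported exactly once.
#'
#' @param seq1,seq2 character or DNAString; the two mates as sequenced.
#' @param ref named DNAStringSet reference.
#' @param maxMm per-mate mismatch bound (default 5).
#' @param maxInsert maximum outer distance (default 1000).
#' @return data.frame with one row per placement: chrom, pos1, pos2
#'   (1-based starts of mate1/mate2), fwdMate (which mate is on '+'),
#'   insert, mm1, mm2, totalMm.
#' @export
enumeratePlacements <- function(seq1, seq2, ref, maxMm = 5L, maxInsert = 1000L) {
  r1 <- DNAStringSet(as.character(seq1)); r2 <- DNAStringSet(as.character(seq2))
  pl1 <- placementsUngapped(r1, ref, maxMm)
  pl2 <- placementsUngapped(r2, ref, maxMm)
  pp <- properPairs(pl1, pl2, width(r1), width(r2), maxInsert)
  if (!nrow(pp)) {
    return(data.frame(chrom = character(0), pos1 = integer(0), pos2 = integer(0),
                      fwdMate = integer(0), insert = integer(0), mm1 = integer(0),
                      mm2 = integer(0), totalMm = integer(0)))
  }
  pos1 <- ifelse(pp$fwdMate == 1L, pp$startF, pp$startR)
  pos2 <- ifelse(pp$fwdMate == 1L, pp$startR, pp$startF)
  mm1 <- ifelse(pp$fwdMate == 1L, pp$mmF, pp$mmR)
  mm2 <- ifelse(pp$fwdMate == 1L, pp$mmR, pp$mmF)
  out <- data.frame(chrom = pp$chrom, pos1 = pos1, pos2 = pos2,
                    fwdMate = pp$fwdMate, insert = pp$insert,
                    mm1 = mm1, mm2 = mm2, totalMm = pp$totalMm)
  out[order(out$chrom, out$pos1, out$pos2), , drop = FALSE]
}

## Turn selected proper pairs into alignment-table rows (two per pair).
## sel must have: idx, chrom, fwdMate, startF, startR, gap columns.
pairsToAlignments <- function(sel, reads1, reads2, quals1, quals2,
                              qnames, sample = "S1") {
  if (!nrow(sel)) return(emptyAlignmentTable())
  ch1 <- as.character(reads1); ch2 <- as.character(reads2)
  rc1 <- as.character(reverseComplement(reads1))
  rc2 <- as.character(reverseComplement(reads2))
  q1 <- as.character(quals1); q2 <- as.character(quals2)
  qr1 <- as.character(reverse(quals1)); qr2 <- as.character(reverse(quals2))
  mateF <- sel$fwdMate; mateR <- 3L - sel$fwdMate
  seqF <- ifelse(mateF == 1L, ch1[sel$idx], ch2[sel$idx])
  qualF <- ifelse(mateF == 1L, q1[sel$idx], q2[sel$idx])
  seqR <- ifelse(mateR == 1L, rc1[sel$idx], rc2[sel$idx])
  qualR <- ifelse(mateR == 1L, qr1[sel$idx], qr2[sel$idx])
  rows <- list(
    data.table(
      qname = qnames[sel$idx], sample = sample, chrom = sel$chrom,
      strand = "+", start = sel$startF, readLen = nchar(seqF),
      seq = seqF, qual = qualF, mate = mateF, mm = sel$mmF,
      gapType = sel$gapTypeF, gapPos = sel$gapPosF, gapLen = sel$gapLenF,
      maskN = 0L, dup = FALSE, insert = sel$insert
    ),
    data.table(
      qname = qnames[sel$idx], sample = sample, chrom = sel$chrom,
      strand = "-", start = sel$startR, readLen = nchar(seqR),
      seq = seqR, qual = qualR, mate = mateR, mm = sel$mmR,
      gapType = sel$gapTypeR, gapPos = sel$gapPosR, gapLen = sel$gapLenR,
      maskN = 0L, dup = FALSE, insert = sel$insert
    )
  )
  as.data.frame(rbindlist(rows))
}

emptyAlignmentTable <- function() {
  data.frame(qname = character(0), sample = character(0), chrom = character(0),
             strand = character(0), start = integer(0), readLen = integer(0),
             seq = character(0), qual = character(0), mate = integer(0),
             mm = integer(0), gapType = character(0), gapPos = integer(0),
             gapLen = integer(0), maskN = 0L[0], dup = logical(0),
             insert = integer(0))
}

#' First-pass paired-end mapping (simplified short-read mapper)
#'
#' Maps read pairs by exact-seed anchoring and full verification, with a
#' single-gap fallback for mates that fail ungapped placement (a stand-in
#' for local indel realignment). A pair passes as "unique" when exactly one
#' proper FR placement attains the minimum total mismatch count.
#'
#' The default per-mate substitution bound (2) is deliberately stricter
#' than the rescue stage's bound (5), so pairs from diverged or
#' error-burdened fragments land in the rescue pool rather than being
#' force-placed.
#'
#' @param reads list with `seq` (DNAStringSet) and `qual` (BStringSet) for
#'   mate 1; `reads2` likewise for mate 2.
#' @param reads2 mate-2 reads (same structure as `reads`).
#' @param ref named DNAStringSet reference.
#' @param maxMm per-mate substitution bound (default 2).
#' @param maxInsert maximum insert size considered proper (default 1000).
#' @param gapped attempt single-gap placement of mates with no ungapped
#'   placement (default TRUE).
#' @param sample sample label for the alignment table.
#' @return list with `aln` (alignment table of uniquely placed proper
#'   pairs, two rows per pair) and `status` (data.frame: qname, status in
#'   unique/ambiguous/improper/unmapped).
#' @export
alignPairs <- function(reads, reads2, ref, maxMm = 2L, maxInsert = 1000L,
                       gapped = TRUE, sample = "S1") {
  r1 <- reads$seq; r2 <- reads2$seq
  qnames <- names(r1)
  if (is.null(qnames)) qnames <- paste0("p", seq_along(r1))
  pl1 <- placementsUngapped(r1, ref, maxMm)
  pl2 <- placementsUngapped(r2, ref, maxMm)
  if (gapped) {
    miss1 <- setdiff(seq_along(r1), unique(pl1$idx))
    miss2 <- setdiff(seq_along(r2), unique(pl2$idx))
    ## anchor gapped fits near the placed mate when possible
    if (length(miss1)) {
      anch <- seedAnchors(r1[miss1], ref)
      anch$idx <- miss1[anch$idx]
      g1 <- placementsGapped(r1, ref, anch, maxMm = 5L)
      pl1 <- rbindlist(list(pl1, g1), fill = TRUE)
    }
    if (length(miss2)) {
      anch <- seedAnchors(r2[miss2], ref)
      anch$idx <- miss2[anch$idx]
      g2 <- placementsGapped(r2, ref, anch, maxMm = 5L)
      pl2 <- rbindlist(list(pl2, g2), fill = TRUE)
    }
  }
  pp <- properPairs(pl1, pl2, width(r1), width(r2), maxInsert)
  status <- rep("unmapped", length(r1))
  mapped <- union(unique(pl1$idx), unique(pl2$idx))
  status[mapped] <- "improper"
  sel <- NULL
  if (nrow(pp)) {
    pp[, "minMm" := min(totalMm), by = "idx"]
    best <- pp[pp$totalMm == pp$minMm]
    nbest <- best[, .N, by = "idx"]
    uniq <- nbest$idx[nbest$N == 1L]
    status[unique(pp$idx)] <- "ambiguous"
    status[uniq] <- "unique"
    sel <- best[best$idx %in% uniq]
  }
  aln <- if (!is.null(sel) && nrow(sel)) {
    pairsToAlignments(sel, r1, r2, reads$qual, reads2$qual, qnames, sample)
  } else {
    emptyAlignmentTable()
  }
  list(aln = aln,
       status = data.frame(qname = qnames, status = status,
                           stringsAsFactors = FALSE))
}
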