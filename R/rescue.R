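## Rescue of first-pass failures: realign the rejected pair pool with the
## complete placement enumerator and keep only pairs with a single proper
## placement at the pair's minimum total mismatch count.

#' Rescue rejected read pairs by unique-minimum-mismatch realignment
#'
#' Enumerates, for every pair in the pool, all proper FR placements with at
#' most `maxMm` substitutions per mate and insert at most `maxInsert`
#' (complete within the bound), then retains a pair only when exactly one
#' placement attains its minimum total mismatch count. Ties at the minimum
#' discard the pair.
#'
#' @param reads,reads2 pool mates: lists with `seq` (named DNAStringSet)
#'   and `qual` (BStringSet).
#' @param ref named DNAStringSet reference.
#' @param maxMm per-mate mismatch bound (default 5).
#' @param maxInsert insert bound (default 1000).
#' @param onTarget optional GRanges; rescued pairs must intersect it.
#' @param gapped also attempt single-gap placements for mates with no
#'   ungapped placement (default FALSE: substitutions only).
#' @param sample sample label for the alignment table.
#' @return list with `aln` (alignment table of rescued pairs), `discarded`
#'   (data.frame qname, reason) and `counts` (named integer summary).
#' @export
rescuePairs <- function(reads, reads2, ref, maxMm = 5L, maxInsert = 1000L,
                        onTarget = NULL, gapped = FALSE, sample = "S1") {
  r1 <- reads$seq; r2 <- reads2$seq
  qnames <- names(r1)
  if (!length(r1)) {
    return(list(aln = emptyAlignmentTable(),
                discarded = data.frame(qname = character(0), reason = character(0)),
                counts = c(rescued = 0L)))
  }
  pl1 <- placementsUngapped(r1, ref, maxMm)
  pl2 <- placementsUngapped(r2, ref, maxMm)
  if (gapped) {
    miss1 <- setdiff(seq_along(r1), unique(pl1$idx))
    miss2 <- setdiff(seq_along(r2), unique(pl2$idx))
    if (length(miss1)) {
      anch <- seedAnchors(r1[miss1], ref)
      anch$idx <- miss1[anch$idx]
      pl1 <- rbindlist(list(pl1, placementsGapped(r1, ref, anch, maxMm)), fill = TRUE)
    }
    if (length(miss2)) {
      anch <- seedAnchors(r2[miss2], ref)
      anch$idx <- miss2[anch$idx]
      pl2 <- rbindlist(list(pl2, placementsGapped(r2, ref, anch, maxMm)), fill = TRUE)
    }
  }
  ppAll <- properPairs(pl1, pl2, width(r1), width(r2), maxInsert = .Machine$integer.max)
  pp <- ppAll[ppAll$insert <= maxInsert]
  reason <- rep("no-placement", length(r1))
  placedBoth <- intersect(unique(pl1$idx), unique(pl2$idx))
  reason[placedBoth] <- "no-proper-pair"
  reason[unique(ppAll$idx)] <- "insert-too-large"
  sel <- NULL
  if (nrow(pp)) {
    pp[, "minMm" := min(totalMm), by = "idx"]
    best <- pp[pp$totalMm == pp$minMm]
    nbest <- best[, .N, by = "idx"]
    uniq <- nbest$idx[nbest$N == 1L]
    reason[unique(pp$idx)] <- "tie-at-minimum"
    reason[uniq] <- NA_character_
    sel <- best[best$idx %in% uniq]
  }
  if (!is.null(sel) && nrow(sel) && !is.null(onTarget)) {
    lo <- pmin(sel$startF, sel$startR)
    hi <- sel$startF + sel$insert - 1L
    gr <- GRanges(sel$chrom, IRanges(lo, hi))
    hit <- overlapsAny(gr, onTarget, ignore.strand = TRUE)
    reason[sel$idx[!hit]] <- "off-target"
    sel <- sel[hit]
  }
  aln <- if (!is.null(sel) && nrow(sel)) {
    pairsToAlignments(sel, r1, r2, reads$qual, reads2$qual, qnames, sample)
  } else {
    emptyAlignmentTable()
  }
  disc <- data.frame(qname = qnames[!is.na(reason)],
                     reason = reason[!is.na(reason)])
  counts <- c(rescued = if (is.null(sel)) 0L else nrow(sel),
              table(disc$reason))
  list(aln = aln, discarded = disc, counts = counts)
}
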