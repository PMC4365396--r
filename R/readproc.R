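## Platform-aware read preprocessing. The two platforms differ in exactly
## three steps: PCR-duplicate removal (capture only), 3' adapter trimming
## (amplicon only) and terminal-base masking + rescue (amplicon only).

#' Trim a 3' adapter from reads
#'
#' Removes, for each read, everything from the leftmost position where the
#' adapter matches with at most `maxMismatchRate` mismatches over an
#' overlap of at least `minOverlap` bases (the adapter may run off the 3'
#' end, in which case only its prefix is compared). Reads shorter than
#' `minLen` after trimming are discarded. Qualities are trimmed in
#' lockstep.
#'
#' @param reads list with `seq` (DNAStringSet, named) and `qual`
#'   (BStringSet).
#' @param adapter adapter sequence (uppercase ACGT).
#' @param minOverlap minimum adapter overlap to trim (default 10).
#' @param minLen minimum remaining read length (default 50).
#' @param maxMismatchRate tolerated mismatch fraction in the overlap
#'   (default 0.1).
#' @return list with `seq`, `qual` (surviving reads, trimmed) and `report`
#'   (data.frame: qname, originalLen, trimmedLen, discarded).
#' @export
trimAdapter <- function(reads, adapter, minOverlap = 10L, minLen = 50L,
                        maxMismatchRate = 0.1) {
  seqs <- as.character(reads$seq)
  quals <- as.character(reads$qual)
  qn <- names(reads$seq)
  if (is.null(qn)) qn <- paste0("r", seq_along(seqs))
  n <- length(seqs)
  trimAt <- rep(NA_integer_, n)           # first removed base, NA = no match
  ac <- strsplit(adapter, "")[[1]]
  for (w in unique(nchar(seqs))) {
    grp <- which(nchar(seqs) == w)
    if (!length(grp)) next
    m <- matrix(unlist(strsplit(seqs[grp], ""), use.names = FALSE),
                nrow = length(grp), byrow = TRUE)
    found <- rep(NA_integer_, length(grp))
    for (p in seq_len(w - minOverlap + 1L)) {
      o <- min(length(ac), w - p + 1L)
      todo <- is.na(found)
      if (!any(todo)) break
      mm <- rowSums(m[todo, p:(p + o - 1L), drop = FALSE] !=
                    matrix(ac[seq_len(o)], sum(todo), o, byrow = TRUE))
      hit <- mm <= floor(maxMismatchRate * o)
      found[which(todo)[hit]] <- p
    }
    trimAt[grp] <- found
  }
  newLen <- ifelse(is.na(trimAt), nchar(seqs), trimAt - 1L)
  keep <- newLen >= minLen
  outSeq <- DNAStringSet(substr(seqs[keep], 1L, newLen[keep]))
  outQual <- BStringSet(substr(quals[keep], 1L, newLen[keep]))
  names(outSeq) <- qn[keep]
  list(seq = outSeq, qual = outQual,
       report = data.frame(qname = qn, originalLen = nchar(seqs),
                           trimmedLen = newLen, discarded = !keep))
}

## Summed base quality of a pair (for duplicate-class representatives).
pairQualSums <- function(aln) {
  dt <- data.table::as.data.table(aln)
  dt[, "qsum" := vapply(qual, function(s) sum(utf8ToInt(s)), numeric(1))]
  dt[, list(qsum = sum(qsum)), by = "qname"]
}

#' Mark PCR duplicate pairs
#'
#' Pairs sharing both outer alignment coordinates and orientation form a
#' duplicate class; the member with the highest summed base quality is
#' kept, the rest get `dup = TRUE`. Applies to the capture platform only —
#' amplicon reads have fixed ends by construction, so duplicate removal
#' would discard the panel's legitimate depth.
#'
#' @param aln alignment table (two rows per pair).
#' @return the table with an updated logical `dup` column.
#' @export
markDuplicates <- function(aln) {
  if (!nrow(aln)) return(aln)
  dt <- data.table::as.data.table(aln)
  rw <- ifelse(is.na(dt$gapType), dt$readLen,
               ifelse(dt$gapType == "D", dt$readLen + dt$gapLen,
                      dt$readLen - dt$gapLen))
  dt[, "endpos" := dt$start + rw - 1L]
  key <- dt[, list(chrom = chrom[1], outerStart = min(start),
                   outerEnd = max(endpos),
                   orient = paste0(mate[strand == "+"][1])), by = "qname"]
  qs <- pairQualSums(aln)
  key <- merge(key, qs, by = "qname")
  setorder(key, chrom, outerStart, outerEnd, orient, -qsum, qname)
  key[, "dupRank" := seq_len(.N), by = c("chrom", "outerStart", "outerEnd", "orient")]
  dupQ <- key$qname[key$dupRank > 1L]
  aln$dup <- aln$qname %in% dupQ
  aln
}

#' Filter aligned pairs under a platform policy
#'
#' Capture (WES) policy: uniquely mapped proper pairs with insert size
#' within the sample's own mean ± 2 SD (estimated once from the unique
#' proper pairs), PCR duplicates marked. Amplicon (CCCS) policy: uniquely
#' mapped proper pairs with insert <= `maxInsert`; no duplicate marking.
#' Everything else — unmapped, improper, ambiguous, insert-window or
#' off-target failures — is emitted as the rescue pool.
#'
#' @param aln alignment table of uniquely placed proper pairs (from
#'   [alignPairs()]).
#' @param status per-pair status data.frame from [alignPairs()].
#' @param mode "WES" or "CCCS".
#' @param maxInsert CCCS insert bound (default 1000).
#' @param onTarget optional GRanges; pairs not intersecting it are sent to
#'   the pool (reason "off-target").
#' @return list with `pass` (alignment table, `dup` flags set under WES),
#'   `pool` (data.frame qname, reason) and `insertWindow` (WES only).
#' @export
filterPairs <- function(aln, status, mode = c("WES", "CCCS"),
                        maxInsert = 1000L, onTarget = NULL) {
  mode <- match.arg(mode)
  pool <- status[status$status != "unique", c("qname", "status")]
  names(pool) <- c("qname", "reason")
  insertWindow <- NULL
  if (!nrow(aln)) {
    return(list(pass = aln, pool = pool, insertWindow = insertWindow))
  }
  dt <- data.table::as.data.table(aln)
  pairIns <- dt[, list(chrom = chrom[1], lo = min(start),
                       hi = max(start + readLen) - 1L,
                       insert = insert[1]), by = "qname"]
  bad <- NULL
  if (mode == "WES") {
    mu <- mean(pairIns$insert); sdv <- stats::sd(pairIns$insert)
    insertWindow <- c(lo = mu - 2 * sdv, hi = mu + 2 * sdv)
    bad <- pairIns$qname[pairIns$insert < insertWindow["lo"] |
                         pairIns$insert > insertWindow["hi"]]
  } else {
    bad <- pairIns$qname[pairIns$insert > maxInsert]
  }
  if (length(bad)) {
    pool <- rbind(pool, data.frame(qname = bad, reason = "insert"))
  }
  offT <- NULL
  if (!is.null(onTarget)) {
    gr <- GRanges(pairIns$chrom, IRanges(pairIns$lo, pairIns$hi))
    hit <- overlapsAny(gr, onTarget, ignore.strand = TRUE)
    offT <- pairIns$qname[!hit]
    if (length(offT)) {
      pool <- rbind(pool, data.frame(qname = offT, reason = "off-target"))
    }
  }
  drop <- unique(c(bad, offT))
  pass <- aln[!aln$qname %in% drop, , drop = FALSE]
  if (mode == "WES" && nrow(pass)) pass <- markDuplicates(pass)
  list(pass = pass, pool = pool, insertWindow = insertWindow)
}

#' Mask terminal aligned bases
#'
#' Amplicon read ends carry restriction-site context; the first and last
#' `n` aligned bases of each read are excluded from depth and allele
#' counting downstream.
#'
#' @param aln alignment table.
#' @param n bases to mask at each aligned end (default 5).
#' @return the table with `maskN` set.
#' @export
maskEnds <- function(aln, n = 5L) {
  if (nrow(aln) && any(aln$readLen <= 2L * n)) {
    warning("maskEnds: some reads have no callable bases after masking")
  }
  aln$maskN <- as.integer(n)
  aln
}
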