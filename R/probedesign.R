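## Complement-region extraction and tiered amplicon-probe design with
## simulated-read validation.
##
## Amplicon boundaries sit on restriction cut sites (selective
## circularization fixes fragment ends); candidates are runs of adjacent
## restriction fragments within the tier's length bounds. Tier semantics:
##   tier 1 (strict)            length 150-1000, unique placement required
##   tier 2 (short amplicons)   length  50-1000, unique placement required
##   tier 3 (coverage-relaxed)  length  50-1000, best placement must beat
##                              the runner-up by >= 1 total mismatch
## Eight 4-bp recognition motifs emulating a two-reaction enzyme panel
## (AluI, DpnII, HaeIII, RsaI, NlaIII, MseI, TaqI, TaiI); selective
## circularization kits digest with several parallel reactions, and the
## mixed AT/GC-rich motifs keep cut-site density adequate in GC-rich
## pockets.
DEFAULT_CUT_MOTIFS <- c("AGCT", "GATC", "GGCC", "GTAC",
                        "CATG", "TTAA", "TCGA", "ACGT")

tierMinLen <- function(tier) if (tier == 1L) 150L else 50L

#' Extract the complement target region
#'
#' CDS bases that the capture platform under-serves: depth below `cutoff`
#' in the design sample's profile, or outside the padded capture probe
#' space entirely.
#'
#' @param profile design-sample [DepthProfile-class] (capture platform).
#' @param wesProbes GRanges of capture probes.
#' @param cds GRanges of CDS intervals (seqlengths set).
#' @param cutoff design depth cutoff (default 15).
#' @param flank probe padding used for the probe-space test (default 100).
#' @return merged GRanges of complement bases.
#' @export
extractComplement <- function(profile, wesProbes, cds, cutoff = 15L,
                              flank = 100L) {
  sl <- seqlengths(cds)
  suff <- sufficientRle(profile, cutoff, sl)
  lowG <- do.call(c, lapply(names(sl), function(ch) {
    ir <- IRanges(!suff[[ch]])   # runs of insufficient depth
    if (!length(ir)) return(GRanges(seqlengths = sl))
    GRanges(ch, ir, seqlengths = sl)
  }))
  outside <- setdiff(cds, padAndMerge(wesProbes, flank), ignore.strand = TRUE)
  reduce(union(
    intersect(cds, lowG, ignore.strand = TRUE),
    outside, ignore.strand = TRUE
  ), ignore.strand = TRUE)
}

## Cut-site positions (position of the last base before the cut) around a
## chromosome window.
cutSites <- function(refChrom, lo, hi, motifs) {
  lo <- max(1L, lo); hi <- min(length(refChrom), hi)
  win <- subseq(refChrom, lo, hi)
  sites <- integer(0)
  for (m in motifs) {
    mp <- start(matchPattern(DNAString(m), win))
    ## blunt cut after the 2nd base of the 4-mer recognition site
    if (length(mp)) sites <- c(sites, lo + mp)
  }
  sort(unique(sites))
}

#' Tile candidate amplicons over requested regions
#'
#' Candidates are concatenations of adjacent restriction fragments whose
#' total length obeys the tier bounds and which overlap a requested
#' region.
#'
#' @param regions GRanges of requested (complement) regions.
#' @param ref named DNAStringSet reference.
#' @param tier 1, 2 or 3.
#' @param motifs restriction recognition motifs (default: four 4-cutters).
#' @param maxLen maximum amplicon length (default 1000).
#' @return GRanges of candidates with mcols `sequence` and `tier`.
#' @export
tileCandidates <- function(regions, ref, tier = 1L,
                           motifs = DEFAULT_CUT_MOTIFS, maxLen = 1000L) {
  minLen <- tierMinLen(tier)
  rows <- list()
  regions <- reduce(regions, ignore.strand = TRUE)
  for (i in seq_along(regions)) {
    ch <- as.character(seqnames(regions))[i]
    lo <- start(regions)[i]; hi <- end(regions)[i]
    sites <- cutSites(ref[[ch]], lo - maxLen - 10L, hi + maxLen + 10L, motifs)
    if (length(sites) < 2L) next
    for (a in seq_len(length(sites) - 1L)) {
      for (b in (a + 1L):length(sites)) {
        len <- sites[b] - sites[a]
        if (len > maxLen) break
        if (len < minLen) next
        s <- sites[a] + 1L; e <- sites[b]
        if (e < lo || s > hi) next     # must overlap the request
        rows[[length(rows) + 1L]] <- data.frame(chrom = ch, start = s, end = e)
      }
    }
  }
  if (!length(rows)) {
    gr <- GRanges()
    gr$sequence <- character(0); gr$tier <- integer(0)
    return(gr)
  }
  df <- unique(do.call(rbind, rows))
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  seqs <- character(length(gr))
  for (ch in unique(df$chrom)) {
    ii <- which(df$chrom == ch)
    seqs[ii] <- as.character(extractAt(ref[[ch]], ranges(gr)[ii]))
  }
  gr$sequence <- seqs
  gr$tier <- as.integer(tier)
  sort(gr)
}

#' Simulated read pair for a probe
#'
#' Forward read = the amplicon's first `readLen` bases; reverse read =
#' reverse complement of its last `readLen` bases (both shorter when the
#' amplicon is).
#'
#' @param sequence amplicon sequence.
#' @param readLen simulated read length (default 100).
#' @return list(r1, r2) character sequences.
#' @export
probeReads <- function(sequence, readLen = 100L) {
  L <- nchar(sequence)
  k <- min(readLen, L)
  list(r1 = substr(sequence, 1L, k),
       r2 = revcompChar(substr(sequence, L - k + 1L, L)))
}

#' Validate one probe by simulated-read remapping
#'
#' The probe's simulated read pair is realigned against the whole
#' reference; acceptance requires a proper-orientation placement with
#' insert below 1,000 bp that is unique (tiers 1-2: the only placement at
#' all within 5 mismatches per read; tier 3: uniquely best by total
#' mismatch count).
#'
#' @param sequence amplicon sequence.
#' @param ref named DNAStringSet reference.
#' @param tier 1, 2 or 3.
#' @param readLen simulated read length (default 100).
#' @param maxMm per-read mismatch bound (default 5).
#' @param maxInsert placements with insert >= this are ignored (default
#'   1000, exclusive).
#' @return list(accepted = logical, reason = NA or character).
#' @export
validateProbe <- function(sequence, ref, tier = 1L, readLen = 100L,
                          maxMm = 5L, maxInsert = 1000L) {
  if (grepl("[^ACGT]", sequence)) {
    return(list(accepted = FALSE, reason = "ambiguous-sequence"))
  }
  pr <- probeReads(sequence, readLen)
  pl <- enumeratePlacements(pr$r1, pr$r2, ref, maxMm = maxMm,
                            maxInsert = maxInsert - 1L)
  if (!nrow(pl)) return(list(accepted = FALSE, reason = "no-placement"))
  if (tier < 3L) {
    if (nrow(pl) > 1L) return(list(accepted = FALSE, reason = "non-unique"))
    return(list(accepted = TRUE, reason = NA_character_))
  }
  mn <- min(pl$totalMm)
  if (sum(pl$totalMm == mn) > 1L) {
    return(list(accepted = FALSE, reason = "tie-at-minimum"))
  }
  list(accepted = TRUE, reason = NA_character_)
}

#' Tiered amplicon-probe design
#'
#' Tier 1 is attempted first over the requested regions; bases left
#' uncovered by accepted tier-1 probes go to tier 2 (short amplicons
#' admitted), then tier 3 (uniqueness relaxed to uniquely-best); whatever
#' remains is the residual. Within a tier the candidate pool is thinned by
#' a greedy interval cover (leftmost uncovered base, furthest-reaching
#' candidate first), with each selected candidate individually validated
#' by simulated-read remapping; rejected candidates stay in the result
#' with their rejection reason.
#'
#' @param regions GRanges of requested (complement) regions.
#' @param ref named DNAStringSet reference.
#' @param cds GRanges of CDS intervals (for the predicted-coverage figure).
#' @param motifs restriction motifs (default: four 4-cutters).
#' @param maxLen maximum amplicon length offered to the panel. The
#'   default 190 = 2 x 100 bp reads minus 2 x 5 masked terminal bases, so
#'   one read pair covers every callable base of its amplicon; the
#'   validation insert bound stays at `maxInsert`.
#' @param readLen,maxMm,maxInsert validation parameters.
#' @param edgeTrim terminal bases of each amplicon treated as
#'   non-callable when assessing coverage (default 5, matching the
#'   restriction-site masking downstream), so amplicon edges are covered
#'   by overlapping neighbours.
#' @return a [ProbeDesign-class].
#' @export
designProbeSet <- function(regions, ref, cds, motifs = DEFAULT_CUT_MOTIFS,
                           maxLen = 190L, readLen = 100L, maxMm = 5L,
                           maxInsert = 1000L, edgeTrim = 5L) {
  callable <- function(gr) {
    gr <- gr[width(gr) > 2L * edgeTrim]
    if (!length(gr)) return(GRanges())
    GRanges(seqnames(gr), IRanges(start(gr) + edgeTrim, end(gr) - edgeTrim))
  }
  remaining <- reduce(regions, ignore.strand = TRUE)
  allRows <- list()
  counts <- setNames(integer(3), paste0("tier", 1:3))
  for (tier in 1:3) {
    if (!sum(width(remaining))) break
    cands <- tileCandidates(remaining, ref, tier, motifs, maxLen = maxLen)
    if (!length(cands)) next
    cands$status <- "unused"; cands$reason <- NA_character_
    uncov <- remaining
    ## move past bases no unused candidate can cover (within the first
    ## uncovered interval), instead of abandoning the whole interval
    advance <- function(uncov, ch, p) {
      iv <- uncov[1]
      nxt <- start(cands)[cands$status == "unused" &
                          as.character(seqnames(cands)) == ch &
                          start(cands) + edgeTrim > p &
                          start(cands) + edgeTrim <= end(iv)] + edgeTrim
      if (length(nxt)) {
        start(uncov)[1] <- min(nxt)
        uncov
      } else {
        uncov[-1]
      }
    }
    while (sum(width(uncov)) > 0L) {
      ch <- as.character(seqnames(uncov))[1]
      p <- start(uncov)[1]
      elig <- which(cands$status == "unused" &
                    as.character(seqnames(cands)) == ch &
                    start(cands) + edgeTrim <= p & end(cands) - edgeTrim >= p)
      if (!length(elig)) {
        uncov <- advance(uncov, ch, p)
        next
      }
      elig <- elig[order(-end(cands)[elig])]
      placed <- FALSE
      for (ci in elig) {
        v <- validateProbe(cands$sequence[ci], ref, tier, readLen, maxMm,
                           maxInsert)
        if (v$accepted) {
          cands$status[ci] <- "accepted"
          uncov <- setdiff(uncov, callable(cands[ci]), ignore.strand = TRUE)
          placed <- TRUE
          break
        } else {
          cands$status[ci] <- "rejected"
          cands$reason[ci] <- v$reason
        }
      }
      if (!placed) uncov <- advance(uncov, ch, p)
    }
    tried <- cands[cands$status != "unused"]
    allRows[[tier]] <- tried
    acc <- tried[tried$status == "accepted"]
    counts[tier] <- length(acc)
    if (length(acc)) {
      remaining <- setdiff(remaining, reduce(callable(acc), ignore.strand = TRUE),
                           ignore.strand = TRUE)
    }
  }
  probes <- if (length(allRows)) {
    do.call(c, unname(allRows[!vapply(allRows, is.null, logical(1))]))
  } else {
    tileCandidates(GRanges(), ref, 1L)
  }
  accAll <- probes[probes$status == "accepted"]
  footprint <- reduce(callable(accAll), ignore.strand = TRUE)
  predicted <- if (sum(width(cds))) {
    sum(width(intersect(footprint, reduce(cds, ignore.strand = TRUE),
                        ignore.strand = TRUE))) / sum(width(reduce(cds, ignore.strand = TRUE)))
  } else 0
  new("ProbeDesign", probes = probes, residual = remaining,
      tierCounts = counts, predictedCoverage = predicted)
}
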