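## Interval arithmetic and CDS-coverage accounting.
##
## Alignment tables used throughout the package are data.frames with one
## row per aligned read (mate) and columns:
##   qname, sample, chrom, strand, start (1-based), readLen,
##   seq, qual (character), mm (mismatch count),
##   gapPos, gapLen, gapType ("I" insertion / "D" deletion / NA),
##   maskN (bases masked per aligned end), dup (logical)
## A deletion consumes gapLen extra reference bases after the first gapPos
## read bases; an insertion consumes gapLen read bases against none.

#' Pad probe intervals and merge
#'
#' Expands every interval by `flank` bases on each side (the on-target
#' definition: variant calling is restricted to within 100 bp upstream and
#' downstream of the designed capture probes), clips at chromosome bounds
#' and merges overlaps.
#'
#' @param probes GRanges of probe/target intervals. If `seqlengths` are set
#'   they are used to clip at chromosome ends.
#' @param flank non-negative integer; bases added on each side (default 100).
#' @return A reduced GRanges containing every padded input interval.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1100))
#' padAndMerge(gr, 100)  # chr1:901-1200
#' @export
padAndMerge <- function(probes, flank = 100L) {
  stopifnot(flank >= 0)
  out <- suppressWarnings(probes + as.integer(flank))
  start(out) <- pmax(start(out), 1L)
  sl <- seqlengths(out)
  if (!all(is.na(sl))) out <- trim(out)
  reduce(out, ignore.strand = TRUE)
}

## Reference ranges covered by an alignment's callable read bases:
## terminal maskN aligned bases excluded, deletion gaps uncovered.
## Returns a data.table (chrom, start, end).
alignmentCoveredRanges <- function(aln) {
  dt <- data.table::as.data.table(aln)
  n <- nrow(dt)
  if (!n) return(data.table(chrom = character(0), start = integer(0), end = integer(0)))
  if (is.null(dt$maskN)) dt[, "maskN" := 0L]
  if (is.null(dt$gapType)) dt[, c("gapType", "gapPos", "gapLen") := list(NA_character_, NA_integer_, NA_integer_)]
  lo <- dt$maskN + 1L            # first callable read base
  hi <- dt$readLen - dt$maskN    # last callable read base
  hasgap <- !is.na(dt$gapType)
  ## segment 1 (read bases 1..gapPos or whole read), segment 2 after the gap
  segs <- vector("list", 2L)
  s1lo <- lo
  s1hi <- ifelse(hasgap, pmin(hi, dt$gapPos), hi)
  ok1 <- s1hi >= s1lo
  segs[[1]] <- data.table(
    chrom = dt$chrom[ok1],
    start = dt$start[ok1] + s1lo[ok1] - 1L,
    end = dt$start[ok1] + s1hi[ok1] - 1L
  )
  if (any(hasgap)) {
    g <- dt[hasgap]
    glo <- pmax(lo[hasgap], g$gapPos + 1L + ifelse(g$gapType == "I", g$gapLen, 0L))
    ghi <- hi[hasgap]
    ## reference offset of read base b (> gap): b - 1 + refShift
    refShift <- ifelse(g$gapType == "D", g$gapLen, -g$gapLen)
    ok2 <- ghi >= glo
    segs[[2]] <- data.table(
      chrom = g$chrom[ok2],
      start = g$start[ok2] + glo[ok2] - 1L + refShift[ok2],
      end = g$start[ok2] + ghi[ok2] - 1L + refShift[ok2]
    )
  } else {
    segs[[2]] <- NULL
  }
  rbindlist(segs)
}

#' Compute a per-base depth profile from alignments
#'
#' Depth at a base is the number of callable aligned read bases covering it:
#' terminal masked bases (amplicon reads) and deletion gaps do not count;
#' overlapping mates double-count, as in a naive pileup.
#'
#' @param aln alignment table (see package overview); only rows with
#'   `dup == FALSE` (or no `dup` column) contribute.
#' @param targets GRanges backing target set, with `seqlengths` set.
#' @param sampleId,platform labels stored on the profile.
#' @return A [DepthProfile-class].
#' @export
computeDepth <- function(aln, targets, sampleId = "S1", platform = c("WES", "CCCS")) {
  platform <- match.arg(platform)
  sl <- seqlengths(targets)
  if (any(is.na(sl))) stop("computeDepth: targets must carry seqlengths")
  if (!is.null(aln$dup)) aln <- aln[!aln$dup, , drop = FALSE]
  covr <- alignmentCoveredRanges(aln)
  covs <- lapply(names(sl), function(ch) {
    r <- covr[covr$chrom == ch]
    if (!nrow(r)) return(Rle(0L, sl[[ch]]))
    ir <- IRanges(pmax(r$start, 1L), pmin(r$end, sl[[ch]]))
    coverage(ir, width = sl[[ch]])
  })
  names(covs) <- names(sl)
  new("DepthProfile", cov = as(covs, "RleList"),
      targets = reduce(targets, ignore.strand = TRUE),
      sampleId = sampleId, platform = platform)
}

## Per-chromosome logical Rle "depth >= k within the backing set"
sufficientRle <- function(profile, k, sl) {
  out <- lapply(names(sl), function(ch) {
    if (!ch %in% names(profile@cov)) return(Rle(FALSE, sl[[ch]]))
    d <- profile@cov[[ch]]
    if (length(d) < sl[[ch]]) d <- c(d, Rle(0L, sl[[ch]] - length(d)))
    mask <- coverage(ranges(profile@targets[seqnames(profile@targets) == ch]),
                     width = sl[[ch]]) > 0L
    (d >= k) & mask
  })
  names(out) <- names(sl)
  out
}

countCovered <- function(suff, cds) {
  perChrom <- lapply(split(cds, seqnames(cds)), function(gr) {
    ch <- as.character(seqnames(gr))[1]
    if (!length(gr)) return(c(covered = 0, total = 0))
    v <- Views(suff[[ch]], ranges(reduce(gr, ignore.strand = TRUE)))
    c(covered = sum(unlist(viewApply(v, function(x) sum(as.logical(x))))),
      total = sum(width(v)))
  })
  do.call(rbind, perChrom)
}

#' Fraction of CDS bases at depth >= k
#'
#' Bases outside the profile's backing target set count as depth 0 in the
#' denominator (never-sequenced CDS counts against coverage).
#'
#' @param profile a [DepthProfile-class].
#' @param cds GRanges of CDS intervals (seqlengths set).
#' @param k depth threshold (10 for the RD10 callability criterion, 15 for
#'   the complement-design cutoff).
#' @return list with `fraction` (overall) and `perChrom` (data.frame with
#'   chrom, covered, total, fraction).
#' @export
coverageAtThreshold <- function(profile, cds, k = 10L) {
  sl <- seqlengths(cds)
  if (any(is.na(sl))) stop("coverageAtThreshold: cds must carry seqlengths")
  suff <- sufficientRle(profile, k, sl)
  tab <- countCovered(suff, cds)
  perChrom <- data.frame(
    chrom = rownames(tab), covered = tab[, "covered"], total = tab[, "total"],
    fraction = ifelse(tab[, "total"] > 0, tab[, "covered"] / tab[, "total"], NA_real_),
    row.names = NULL
  )
  list(fraction = sum(tab[, "covered"]) / sum(tab[, "total"]), perChrom = perChrom)
}

#' Union coverage across platforms
#'
#' A CDS base counts as covered when ANY of the profiles reaches depth >= k
#' there — the combined WES ∪ CCCS sufficiency used for the headline
#' combination coverage.
#'
#' @param profiles list of [DepthProfile-class] objects.
#' @param cds GRanges of CDS intervals (seqlengths set).
#' @param k depth threshold.
#' @return list with `fraction` and `perChrom` as in [coverageAtThreshold()].
#' @export
unionCoverage <- function(profiles, cds, k = 10L) {
  stopifnot(length(profiles) >= 1L)
  sl <- seqlengths(cds)
  if (any(is.na(sl))) stop("unionCoverage: cds must carry seqlengths")
  suff <- sufficientRle(profiles[[1]], k, sl)
  for (p in profiles[-1]) {
    s2 <- sufficientRle(p, k, sl)
    suff <- mapply(function(a, b) a | b, suff, s2, SIMPLIFY = FALSE)
  }
  tab <- countCovered(suff, cds)
  perChrom <- data.frame(
    chrom = rownames(tab), covered = tab[, "covered"], total = tab[, "total"],
    fraction = ifelse(tab[, "total"] > 0, tab[, "covered"] / tab[, "total"], NA_real_),
    row.names = NULL
  )
  list(fraction = sum(tab[, "covered"]) / sum(tab[, "total"]), perChrom = perChrom)
}

#' Tabular coverage report across platforms
#'
#' One row per (platform|combined) x (chrom|ALL): covered bases, total CDS
#' bases, fraction, plus mean and median depth over the backing targets.
#'
#' @param profiles named list of [DepthProfile-class] objects.
#' @param cds GRanges of CDS intervals.
#' @param k depth threshold (default 10, the RD10 criterion).
#' @return data.frame with columns sample, platform, k, chrom, covered,
#'   total, fraction, meanDepth, medianDepth.
#' @export
coverageReport <- function(profiles, cds, k = 10L) {
  rows <- lapply(profiles, function(p) {
    cv <- coverageAtThreshold(p, cds, k)
    ## depth statistics over CDS bases inside the profile's target space
    dgr <- intersect(reduce(cds, ignore.strand = TRUE), p@targets,
                     ignore.strand = TRUE)
    dv <- unlist(lapply(unique(as.character(seqnames(dgr))), function(ch) {
      gr <- dgr[seqnames(dgr) == ch]
      if (!length(gr) || !ch %in% names(p@cov)) return(numeric(0))
      as.numeric(unlist(Views(p@cov[[ch]], ranges(gr)), use.names = FALSE))
    }))
    if (!length(dv)) dv <- 0
    all <- data.frame(sample = p@sampleId, platform = p@platform, k = k,
                      chrom = "ALL", covered = sum(cv$perChrom$covered),
                      total = sum(cv$perChrom$total), fraction = cv$fraction,
                      meanDepth = mean(dv), medianDepth = stats::median(dv))
    per <- data.frame(sample = p@sampleId, platform = p@platform, k = k,
                      chrom = cv$perChrom$chrom, covered = cv$perChrom$covered,
                      total = cv$perChrom$total, fraction = cv$perChrom$fraction,
                      meanDepth = NA_real_, medianDepth = NA_real_)
    rbind(all, per)
  })
  comb <- unionCoverage(profiles, cds, k)
  combined <- rbind(
    data.frame(sample = profiles[[1]]@sampleId, platform = "COMBINED", k = k,
               chrom = "ALL", covered = sum(comb$perChrom$covered),
               total = sum(comb$perChrom$total), fraction = comb$fraction,
               meanDepth = NA_real_, medianDepth = NA_real_),
    data.frame(sample = profiles[[1]]@sampleId, platform = "COMBINED", k = k,
               chrom = comb$perChrom$chrom, covered = comb$perChrom$covered,
               total = comb$perChrom$total, fraction = comb$perChrom$fraction,
               meanDepth = NA_real_, medianDepth = NA_real_)
  )
  out <- rbind(do.call(rbind, rows), combined)
  rownames(out) <- NULL
  out
}
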