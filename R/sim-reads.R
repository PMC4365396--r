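## Read simulation: capture-biased paired-end WES reads and
## selective-circularization amplicon (CCCS) reads, drawn from a member's
## two haplotypes.

## Substitution errors at `errorRate` with quality U(10,30); error-free
## bases carry Q35, so the Q>=20 pileup filter removes part of the noise.
addSeqErrors <- function(seqs, errorRate) {
  n <- length(seqs)
  if (!n) return(list(seq = DNAStringSet(), qual = BStringSet()))
  w <- unique(nchar(seqs))
  stopifnot(length(w) == 1L)
  m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE), nrow = n, byrow = TRUE)
  err <- matrix(runif(n * w) < errorRate, nrow = n)
  nerr <- sum(err)
  if (nerr) {
    cur <- m[err]
    sub <- vapply(cur, function(b) sample(setdiff(DNA_BASES4, b), 1L), character(1))
    m[err] <- sub
  }
  q <- matrix(35L, nrow = n, ncol = w)
  if (nerr) q[err] <- sample(10:30, nerr, replace = TRUE)
  seqOut <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  qChar <- matrix(intToUtf8(as.vector(q) + 33L, multiple = TRUE), nrow = n)
  qualOut <- do.call(paste0, as.data.frame(qChar, stringsAsFactors = FALSE))
  list(seq = DNAStringSet(seqOut), qual = BStringSet(qualOut))
}

## Extract fragment sequences from one haplotype given reference-coordinate
## fragments, shifting starts across upstream indels.
extractHapFragments <- function(hap, hapVars, frags) {
  out <- character(nrow(frags))
  for (ch in unique(frags$chrom)) {
    ii <- which(frags$chrom == ch)
    ls <- liftPositions(hapVars, ch, frags$start[ii])
    le <- ls + frags$len[ii] - 1L
    ok <- ls >= 1L & le <= length(hap[[ch]])
    out[ii[ok]] <- as.character(extractAt(hap[[ch]], IRanges(ls[ok], le[ok])))
    out[ii[!ok]] <- NA_character_
  }
  out
}

#' Simulate capture (WES) paired-end reads for one member
#'
#' Per-probe fragment counts are Poisson with rate proportional to the
#' target mean depth scaled by the GC capture-efficiency weight
#' \eqn{w = \exp(-s \cdot \max(0, GC - 0.55))}, so GC-rich pocket exons
#' fall to a small fraction of the nominal depth. Inserts are normal with
#' the configured mean/sd; PCR duplicates are injected at `dupRate`;
#' substitution errors at `errorRate`.
#'
#' @param ped output of [plantPedigree()].
#' @param memberId which member to sequence.
#' @param sim output of [simulateReference()] (provides probes + config).
#' @param seed RNG seed (default derives from the simulation seed and the
#'   member id).
#' @return list with `r1`, `r2` (each list(seq, qual), named reads) and
#'   `meta` (data.frame: qname, chrom, start, insert, hap, dup).
#' @export
simulateWesReads <- function(ped, memberId, sim,
                             seed = deriveSeed(sim$cfg@seed, paste0("wes.", memberId))) {
  cfg <- sim$cfg
  probes <- sim$wesProbes
  withSeed(seed, {
    w <- exp(-cfg@gcBiasStrength * pmax(0, probes$gc - 0.55))
    ## per-probe tiling multiplicity: probes overlap, so each probe only
    ## needs 1/mult of the target depth
    pcov <- coverage(probes)
    mult <- rep(1, length(probes))
    for (ch in unique(as.character(seqnames(probes)))) {
      ii <- which(as.character(seqnames(probes)) == ch)
      mult[ii] <- viewMeans(Views(pcov[[ch]], ranges(probes)[ii]))
    }
    ## a pair contributes 2*readLen read bases spread over the fragment
    ## start span (probe width + insert - 100); solve for the pair count
    ## that yields the target per-base depth
    span <- width(probes) + cfg@insertMean - 100
    rate <- cfg@wesMeanDepth * span / (2 * cfg@wesReadLen) / mult * w
    nf <- rpois(length(probes), rate)
    tot <- sum(nf)
    if (!tot) {
      e <- addSeqErrors(character(0), cfg@errorRate)
      return(list(r1 = e, r2 = e,
                  meta = data.frame(qname = character(0))))
    }
    pidx <- rep(seq_along(probes), nf)
    ins <- pmin(pmax(round(rnorm(tot, cfg@insertMean, cfg@insertSd)),
                     cfg@wesReadLen + 10L), 4L * cfg@insertMean)
    lo <- start(probes)[pidx] - ins + 50L
    hi <- pmax(lo, end(probes)[pidx] - 50L)
    fstart <- lo + floor(runif(tot) * (hi - lo + 1L))
    frags <- data.frame(chrom = as.character(seqnames(probes))[pidx],
                        start = fstart, len = ins)
    ## PCR duplicates: re-sequence a sampled subset of fragments
    ndup <- rbinom(1L, tot, cfg@dupRate)
    dupOf <- if (ndup) sample(tot, ndup, replace = TRUE) else integer(0)
    frags <- rbind(frags, frags[dupOf, , drop = FALSE])
    dupFlag <- c(rep(FALSE, tot), rep(TRUE, ndup))
    hap <- sample(c("h1", "h2"), nrow(frags), replace = TRUE)
    seqs <- character(nrow(frags))
    for (h in c("h1", "h2")) {
      ii <- which(hap == h)
      seqs[ii] <- extractHapFragments(ped$genomes[[memberId]][[h]],
                                      ped$hapVars[[memberId]][[h]],
                                      frags[ii, , drop = FALSE])
    }
    ok <- !is.na(seqs) & nchar(seqs) >= cfg@wesReadLen
    seqs <- seqs[ok]; frags <- frags[ok, , drop = FALSE]
    hap <- hap[ok]; dupFlag <- dupFlag[ok]
    r1raw <- substr(seqs, 1L, cfg@wesReadLen)
    r2raw <- revcompChar(substr(seqs, nchar(seqs) - cfg@wesReadLen + 1L,
                                nchar(seqs)))
    r1 <- addSeqErrors(r1raw, cfg@errorRate)
    r2 <- addSeqErrors(r2raw, cfg@errorRate)
    qn <- sprintf("%s_w%06d", memberId, seq_along(seqs))
    names(r1$seq) <- qn; names(r2$seq) <- qn
    list(r1 = r1, r2 = r2,
         meta = data.frame(qname = qn, chrom = frags$chrom,
                           start = frags$start, insert = frags$len,
                           hap = hap, dup = dupFlag))
  })
}

#' Simulate amplicon-panel (CCCS) paired-end reads for one member
#'
#' Reads derive only from accepted amplicons. Both mates start at the
#' amplicon's ends (fixed restriction-site boundaries, so the terminal
#' bases of every read carry the cut-site context); when the amplicon is
#' shorter than the read length the 3' end reads through into the
#' configured adapter and then into off-template bases.
#'
#' @param ped output of [plantPedigree()].
#' @param memberId which member to sequence.
#' @param amplicons GRanges of accepted amplicon probes.
#' @param sim output of [simulateReference()].
#' @param seed RNG seed.
#' @return same structure as [simulateWesReads()] (meta has no `dup`
#'   column: PCR duplicates are not tracked or removed on this platform).
#' @export
simulateCccsReads <- function(ped, memberId, amplicons, sim,
                              seed = deriveSeed(sim$cfg@seed, paste0("cccs.", memberId))) {
  cfg <- sim$cfg
  if (!length(amplicons)) {
    warning("simulateCccsReads: no accepted amplicons; emitting empty read set")
    e <- list(seq = DNAStringSet(), qual = BStringSet())
    return(list(r1 = e, r2 = e, meta = data.frame(qname = character(0))))
  }
  withSeed(seed, {
    rl <- cfg@wesReadLen
    aw <- width(amplicons)
    covPerPair <- 2 * pmin(aw, rl) / aw
    nf <- rpois(length(amplicons), cfg@cccsMeanDepth / covPerPair)
    tot <- sum(nf)
    aidx <- rep(seq_along(amplicons), nf)
    hap <- sample(c("h1", "h2"), tot, replace = TRUE)
    frags <- data.frame(chrom = as.character(seqnames(amplicons))[aidx],
                        start = start(amplicons)[aidx], len = aw[aidx])
    seqs <- character(tot)
    for (h in c("h1", "h2")) {
      ii <- which(hap == h)
      seqs[ii] <- extractHapFragments(ped$genomes[[memberId]][[h]],
                                      ped$hapVars[[memberId]][[h]],
                                      frags[ii, , drop = FALSE])
    }
    ok <- !is.na(seqs)
    seqs <- seqs[ok]; frags <- frags[ok, , drop = FALSE]; hap <- hap[ok]
    padTo <- function(x, adapter) {
      short <- nchar(x) < rl
      if (any(short)) {
        need <- rl - nchar(x[short])
        fill <- vapply(need, function(k) {
          tail <- if (k <= nchar(adapter)) substr(adapter, 1L, k)
                  else paste0(adapter, randomDna(k - nchar(adapter)))
          tail
        }, character(1))
        x[short] <- paste0(x[short], fill)
      }
      substr(x, 1L, rl)
    }
    r1raw <- padTo(seqs, cfg@adapterFwd)
    r2raw <- padTo(revcompChar(seqs), cfg@adapterRev)
    r1 <- addSeqErrors(r1raw, cfg@errorRate)
    r2 <- addSeqErrors(r2raw, cfg@errorRate)
    qn <- sprintf("%s_c%06d", memberId, seq_along(seqs))
    names(r1$seq) <- qn; names(r2$seq) <- qn
    list(r1 = r1, r2 = r2,
         meta = data.frame(qname = qn, chrom = frags$chrom,
                           start = frags$start, insert = frags$len,
                           hap = hap))
  })
}
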