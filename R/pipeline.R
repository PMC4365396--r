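## End-to-end orchestration of the combined analysis: the capture (WES)
## branch runs first for every member; the complement amplicon (CCCS)
## branch is designed and run only when the capture branch yields no
## phenotype-consistent candidates (or when forced). The two branches
## differ in exactly three steps: duplicate removal (capture only),
## adapter trimming + terminal masking + rescue (amplicon only).

#' Pipeline thresholds and stage options
#'
#' All defaults are the workflow's canonical values: 100 bp on-target
#' flank, design cutoff 15, callability depth 10, base quality 20, variant
#' and consensus scores 20, het band 0.25-0.75, amplicon insert bound
#' 1000, rescue mismatch bound 5 per mate, 5 bp terminal masking, adapter
#' trim overlap 10 / minimum length 50. Unknown option names are a hard
#' error (guards threshold typos).
#'
#' @param ... overrides of the defaults listed above.
#' @return named list of options.
#' @export
pipelineOptions <- function(...) {
  defaults <- list(
    flank = 100L, designCutoff = 15L, rd = 10L,
    minBq = 20L, minScore = 20, maxDepth = 10000L,
    minAf = 0.25,
    maxInsert = 1000L, maxMm = 5L, maskN = 5L,
    trimOverlap = 10L, trimMinLen = 50L, trimMismatchRate = 0.1,
    firstPassMm = 2L,
    models = c("ARhom", "comphet")
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) {
    stop("pipelineOptions: unknown option(s): ", paste(bad, collapse = ", "))
  }
  utils::modifyList(defaults, over)
}

## Callable-depth lookup over per-member merged depth vectors.
makeDepthFun <- function(depthList) {
  function(sampleId, chrom, pos) {
    d <- depthList[[sampleId]]
    if (is.null(d) || !chrom %in% names(d)) return(0L)
    d[[chrom]][pos]
  }
}

mergeDepthVectors <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  out <- a
  for (ch in names(b)) {
    out[[ch]] <- if (is.null(out[[ch]])) b[[ch]] else pmax(out[[ch]], b[[ch]])
  }
  out
}

callableFromDepth <- function(depth, rd, sl) {
  grs <- lapply(names(depth), function(ch) {
    ir <- IRanges(Rle(depth[[ch]] >= rd))
    if (!length(ir)) return(GRanges(seqlengths = sl))
    GRanges(ch, ir, seqlengths = sl)
  })
  reduce(do.call(c, grs))
}

#' Run the combined capture + complement analysis end to end
#'
#' Simulates (or reuses) the reference, pedigree genomes and reads, runs
#' the capture branch (map, filter, dedup, call, Mendelian filter), and —
#' when that branch yields no candidates under the configured models, or
#' when forced — designs the complement amplicon panel from one sample's
#' capture depth profile, runs the amplicon branch (trim, map, rescue,
#' mask, call), merges call sets, and produces coverage, cascade,
#' candidate and array-concordance reports.
#'
#' @param cfg a [SimConfig-class].
#' @param members pedigree data.frame (default [pedigreeTrio()]).
#' @param opts options from [pipelineOptions()].
#' @param forceCccs run the amplicon branch regardless of capture-branch
#'   candidates.
#' @param sim,ped optional pre-built [simulateReference()] /
#'   [plantPedigree()] outputs (reused when supplied).
#' @param outDir optional directory; stage artifacts are written there.
#' @param verbose emit progress messages.
#' @return list with sim, ped, per-branch calls and profiles, the probe
#'   design, merged calls, cascade report, candidates, coverage table,
#'   concordance, `cccsRun` flag and a run `log` character vector.
#' @export
runCombined <- function(cfg = simConfig(), members = pedigreeTrio(),
                        opts = pipelineOptions(), forceCccs = FALSE,
                        sim = NULL, ped = NULL, outDir = NULL,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  log <- c(sprintf("seed=%d", cfg@seed),
           sprintf("opts: %s", paste(names(opts), vapply(opts, function(x)
             paste(x, collapse = "/"), character(1)), sep = "=", collapse = " ")))
  if (is.null(sim)) { say("simulating reference"); sim <- simulateReference(cfg) }
  if (is.null(ped)) { say("planting pedigree"); ped <- plantPedigree(sim, members) }
  ref <- sim$reference
  sl <- sim$seqlens
  onTarget <- padAndMerge(sim$wesProbes, opts$flank)
  seqlengths(onTarget) <- sl[seqlevels(onTarget)]
  transcripts <- transcriptsFromModels(sim$genes)

  ## ---- capture branch --------------------------------------------------
  wesCalls <- list(); wesDepth <- list(); wesProfiles <- list()
  missParts <- list()
  for (m in ped$members$id) {
    say("WES member ", m)
    rd <- simulateWesReads(ped, m, sim)
    al <- alignPairs(rd$r1, rd$r2, ref, maxMm = opts$firstPassMm,
                     maxInsert = 4L * as.integer(cfg@insertMean), sample = m)
    fl <- filterPairs(al$aln, al$status, mode = "WES", onTarget = onTarget)
    pu <- buildPileup(fl$pass, onTarget, ref, minBq = opts$minBq,
                      maxDepth = opts$maxDepth, sampleId = m, platform = "WES")
    wesCalls[[m]] <- callVariants(pu, ref, minDepth = opts$rd,
                                  minAf = opts$minAf, minScore = opts$minScore)
    missParts[[paste0("w.", m)]] <- missingEvidenceSites(pu, wesCalls[[m]])
    wesDepth[[m]] <- pu$depth
    wesProfiles[[m]] <- pileupDepthProfile(pu)
  }
  wesAll <- do.call(rbind, unname(wesCalls))
  wesAnn <- annotateVariants(wesAll, transcripts, ref)
  wesDepthFun <- makeDepthFun(wesDepth)
  wesCascade <- variantCascade(wesAnn, ped$db, ped$members, wesDepthFun,
                               models = opts$models)
  log <- c(log, sprintf("WES candidates: %d", nrow(wesCascade$candidates)))

  ## ---- amplicon branch (conditional) ------------------------------------
  runCccs <- forceCccs || nrow(wesCascade$candidates) == 0L
  design <- NULL; cccsCalls <- NULL; cccsDepth <- list(); cccsProfiles <- list()
  rescueStats <- list()
  if (runCccs) {
    designMember <- ped$members$id[is.na(ped$members$father)][1]
    log <- c(log, sprintf("CCCS branch: design from %s", designMember))
    say("designing complement panel from ", designMember)
    complement <- extractComplement(wesProfiles[[designMember]], sim$wesProbes,
                                    sim$cds, cutoff = opts$designCutoff,
                                    flank = opts$flank)
    design <- designProbeSet(complement, ref, sim$cds,
                             maxMm = opts$maxMm, maxInsert = opts$maxInsert)
    amplicons <- acceptedProbes(design)
    log <- c(log, sprintf("accepted amplicons: %d (%s)", length(amplicons),
                          paste(names(tierCounts(design)), tierCounts(design),
                                sep = "=", collapse = " ")))
    cccsTarget <- padAndMerge(amplicons, opts$flank)
    if (length(cccsTarget)) seqlengths(cccsTarget) <- sl[seqlevels(cccsTarget)]
    calls2 <- list()
    for (m in ped$members$id) {
      say("CCCS member ", m)
      rd <- simulateCccsReads(ped, m, amplicons, sim)
      t1 <- trimAdapter(rd$r1, cfg@adapterFwd, opts$trimOverlap,
                        opts$trimMinLen, opts$trimMismatchRate)
      t2 <- trimAdapter(rd$r2, cfg@adapterRev, opts$trimOverlap,
                        opts$trimMinLen, opts$trimMismatchRate)
      common <- intersect(names(t1$seq), names(t2$seq))
      r1 <- list(seq = t1$seq[common], qual = t1$qual[match(common, names(t1$seq))])
      r2 <- list(seq = t2$seq[common], qual = t2$qual[match(common, names(t2$seq))])
      al <- alignPairs(r1, r2, ref, maxMm = opts$firstPassMm,
                       maxInsert = opts$maxInsert, sample = m)
      fl <- filterPairs(al$aln, al$status, mode = "CCCS",
                        maxInsert = opts$maxInsert, onTarget = cccsTarget)
      poolIdx <- match(intersect(fl$pool$qname, common), names(r1$seq))
      rs <- rescuePairs(list(seq = r1$seq[poolIdx], qual = r1$qual[poolIdx]),
                        list(seq = r2$seq[poolIdx], qual = r2$qual[poolIdx]),
                        ref, maxMm = opts$maxMm, maxInsert = opts$maxInsert,
                        onTarget = cccsTarget, gapped = TRUE, sample = m)
      rescueStats[[m]] <- rs$counts
      aln <- rbind(fl$pass, rs$aln)
      aln <- maskEnds(aln, opts$maskN)
      pu <- buildPileup(aln, cccsTarget, ref, minBq = opts$minBq,
                        maxDepth = opts$maxDepth, sampleId = m, platform = "CCCS")
      calls2[[m]] <- callVariants(pu, ref, minDepth = opts$rd,
                                  minAf = opts$minAf, minScore = opts$minScore)
      missParts[[paste0("c.", m)]] <- missingEvidenceSites(pu, calls2[[m]])
      cccsDepth[[m]] <- pu$depth
      cccsProfiles[[m]] <- pileupDepthProfile(pu)
    }
    cccsCalls <- do.call(rbind, unname(calls2))
  } else {
    log <- c(log, "CCCS branch skipped: capture branch yielded candidates")
  }

  ## ---- merge, cascade, coverage, concordance ----------------------------
  merged <- if (runCccs) {
    do.call(rbind, lapply(ped$members$id, function(m) {
      mergeCallsets(wesAll[wesAll$sample == m, , drop = FALSE],
                    cccsCalls[cccsCalls$sample == m, , drop = FALSE])
    }))
  } else {
    wesAll
  }
  mergedAnn <- annotateVariants(merged, transcripts, ref)
  combDepth <- lapply(ped$members$id, function(m)
    mergeDepthVectors(wesDepth[[m]], cccsDepth[[m]]))
  names(combDepth) <- ped$members$id
  combDepthFun <- makeDepthFun(combDepth)
  combCascade <- variantCascade(mergedAnn, ped$db, ped$members, combDepthFun,
                                models = opts$models)
  log <- c(log, sprintf("combined candidates: %d", nrow(combCascade$candidates)))

  coverage <- do.call(rbind, lapply(ped$members$id, function(m) {
    profs <- list(wesProfiles[[m]])
    if (runCccs) profs <- c(profs, list(cccsProfiles[[m]]))
    coverageReport(profs, sim$cds, k = opts$rd)
  }))

  callable <- lapply(ped$members$id, function(m)
    callableFromDepth(combDepth[[m]], opts$rd, sl))
  names(callable) <- ped$members$id
  ## a site is only "missing" if the merged set still has no call there
  missAll <- unique(do.call(rbind, unname(missParts)))
  if (!is.null(missAll) && nrow(missAll)) {
    mk <- paste(merged$sample, merged$chrom, merged$pos, sep = "\r")
    missAll <- missAll[!paste(missAll$sample, missAll$chrom, missAll$pos,
                              sep = "\r") %in% mk, , drop = FALSE]
  }
  conc <- concordance(mergedAnn, ped$array, callable, missingSites = missAll)

  res <- list(sim = sim, ped = ped,
              wes = list(calls = wesAnn, cascade = wesCascade$report,
                         candidates = wesCascade$candidates,
                         profiles = wesProfiles, depth = wesDepth),
              cccs = if (runCccs) list(calls = cccsCalls,
                                       profiles = cccsProfiles,
                                       depth = cccsDepth,
                                       rescue = rescueStats) else NULL,
              design = design, merged = mergedAnn,
              cascade = combCascade$report,
              candidates = combCascade$candidates,
              coverage = coverage, concordance = conc,
              callable = callable,
              cccsRun = runCccs, log = log)
  if (!is.null(outDir)) writePipelineOutputs(res, outDir)
  res
}

## Persist the main stage artifacts as plain-text files.
writePipelineOutputs <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(outDir, x)
  writeFasta(res$sim$reference, fp("reference.fa"))
  g <- res$sim$genes; g$name <- g$gene_id
  writeBed(g, fp("cds.bed"))
  writeBed(res$sim$wesProbes, fp("wes_probes.bed"))
  writeBed(res$sim$pockets, fp("gc_pockets.bed"))
  writePed(res$ped$members, fp("family.ped"))
  writeKnownDb(res$ped$db, fp("known_db.tsv"))
  writeArrayGenotypes(res$ped$array, fp("array_genotypes.tsv"))
  writeVcfCalls(res$ped$truth, fp("truth.vcf"), samples = res$ped$members$id)
  writeVcfCalls(res$merged, fp("merged_calls.vcf"),
                samples = res$ped$members$id)
  if (!is.null(res$design)) {
    pr <- res$design@probes
    if (length(pr)) {
      pr$name <- paste0("t", pr$tier, "_", pr$status)
      writeBed(pr, fp("cccs_probes.bed"))
    }
    write.table(res$cascade, fp("cascade.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write.table(res$coverage, fp("coverage.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(res$candidates, fp("candidates.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(res$log, fp("run_log.txt"))
  invisible(outDir)
}
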