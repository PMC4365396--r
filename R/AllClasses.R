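#' Simulation configuration
#'
#' Holds every tunable of the synthetic-data generator: genome and gene-model
#' sizing, capture-bias model, read lengths and depths, amplicon panel
#' geometry, adapters and error model. Defaults describe the study
#' conditions the package emulates: ~100 bp paired-end capture sequencing at
#' CDS mean depth ~70 with a GC-dependent capture-efficiency penalty that
#' drives a configurable fraction of CDS below 10x, plus a short-amplicon
#' complement panel at mean depth ~170.
#'
#' @slot seed integer; master RNG seed (all member/stage streams derive
#'   from it deterministically).
#' @slot nChrom,chromLen integer; number and length (bp) of chromosomes.
#' @slot nGenes,exonsPerGene integer; gene-model sizing.
#' @slot exonLenRange,intronLenRange integer(2); exon/intron length bounds
#'   (exon lengths are rounded to codon multiples).
#' @slot wesReadLen integer; capture read length (bp).
#' @slot wesMeanDepth numeric; target mean CDS depth for capture reads.
#' @slot insertMean,insertSd numeric; capture insert-size distribution (bp).
#' @slot gcBiasStrength numeric >= 0; capture-efficiency penalty
#'   \eqn{w = \exp(-s \cdot \max(0, GC - 0.55))}.
#' @slot lowcovFraction numeric in (0, 0.3); target fraction of CDS bases
#'   placed in GC-rich low-coverage pockets.
#' @slot offProbeFraction numeric; fraction of CDS bases left out of the
#'   capture probe design (design gap).
#' @slot cccsAmpliconLenRange integer(2); admissible amplicon lengths for
#'   the complement panel generator.
#' @slot cccsMeanDepth numeric; target mean on-amplicon depth.
#' @slot adapterFwd,adapterRev character; 3' adapter sequences read through
#'   on short amplicons.
#' @slot errorRate numeric; per-base substitution error probability.
#' @slot dupRate numeric; PCR duplicate injection rate (capture reads).
#' @seealso [simConfig()]
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  nChrom = "integer", chromLen = "integer",
  nGenes = "integer", exonsPerGene = "integer",
  exonLenRange = "integer", intronLenRange = "integer",
  wesReadLen = "integer", wesMeanDepth = "numeric",
  insertMean = "numeric", insertSd = "numeric",
  gcBiasStrength = "numeric", lowcovFraction = "numeric",
  offProbeFraction = "numeric",
  cccsAmpliconLenRange = "integer", cccsMeanDepth = "numeric",
  adapterFwd = "character", adapterRev = "character",
  errorRate = "numeric", dupRate = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@lowcovFraction <= 0 || object@lowcovFraction >= 0.3) {
    msg <- c(msg, "lowcovFraction must lie in (0, 0.3)")
  }
  for (ad in c(object@adapterFwd, object@adapterRev)) {
    if (!grepl("^[ACGT]+$", ad)) {
      msg <- c(msg, "adapters must be uppercase ACGT strings")
    }
  }
  if (object@nChrom < 1L || object@chromLen < 1000L) {
    msg <- c(msg, "need at least one chromosome of >= 1 kb")
  }
  if (object@exonLenRange[1] < 30L) msg <- c(msg, "exons must be >= 30 bp")
  if (object@errorRate < 0 || object@errorRate > 0.1) {
    msg <- c(msg, "errorRate must lie in [0, 0.1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param seed master RNG seed.
#' @param nChrom,chromLen,nGenes,exonsPerGene,exonLenRange,intronLenRange
#'   genome/gene-model sizing (see [SimConfig-class]).
#' @param wesReadLen,wesMeanDepth,insertMean,insertSd capture read model.
#' @param gcBiasStrength,lowcovFraction,offProbeFraction capture-bias model.
#' @param cccsAmpliconLenRange,cccsMeanDepth amplicon panel model.
#' @param adapterFwd,adapterRev 3' adapters (defaults: the standard Illumina
#'   adapter prefixes used for forward/reverse trimming).
#' @param errorRate,dupRate error and PCR-duplicate model.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, nChrom = 1L, chromLen = 50000L, nGenes = 10L)
#' @export
simConfig <- function(seed = 1L,
                      nChrom = 2L, chromLen = 500000L,
                      nGenes = 200L, exonsPerGene = 5L,
                      exonLenRange = c(90L, 240L),
                      intronLenRange = c(150L, 600L),
                      wesReadLen = 100L, wesMeanDepth = 70,
                      insertMean = 180, insertSd = 30,
                      gcBiasStrength = 20, lowcovFraction = 0.08,
                      offProbeFraction = 0.04,
                      cccsAmpliconLenRange = c(50L, 190L),
                      cccsMeanDepth = 170,
                      adapterFwd = "AGATCGGAAGAGCACACGTCTGAACTCCAG",
                      adapterRev = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAG",
                      errorRate = 0.001, dupRate = 0.1) {
  new("SimConfig",
    seed = as.integer(seed),
    nChrom = as.integer(nChrom), chromLen = as.integer(chromLen),
    nGenes = as.integer(nGenes), exonsPerGene = as.integer(exonsPerGene),
    exonLenRange = as.integer(exonLenRange),
    intronLenRange = as.integer(intronLenRange),
    wesReadLen = as.integer(wesReadLen), wesMeanDepth = wesMeanDepth,
    insertMean = insertMean, insertSd = insertSd,
    gcBiasStrength = gcBiasStrength, lowcovFraction = lowcovFraction,
    offProbeFraction = offProbeFraction,
    cccsAmpliconLenRange = as.integer(cccsAmpliconLenRange),
    cccsMeanDepth = cccsMeanDepth,
    adapterFwd = adapterFwd, adapterRev = adapterRev,
    errorRate = errorRate, dupRate = dupRate
  )
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nChrom, "chrom x", object@chromLen, "bp;",
      object@nGenes, "genes x", object@exonsPerGene, "exons\n")
  cat("  WES: read", object@wesReadLen, "bp, mean depth", object@wesMeanDepth,
      ", insert ~N(", object@insertMean, ",", object@insertSd, ")\n")
  cat("  GC bias strength", object@gcBiasStrength,
      "; pocket fraction", object@lowcovFraction,
      "; off-probe fraction", object@offProbeFraction, "\n")
  cat("  CCCS: mean depth", object@cccsMeanDepth,
      "; error rate", object@errorRate, "; dup rate", object@dupRate, "\n")
})

#' Per-base depth over a target space
#'
#' A per-chromosome run-length-encoded depth vector together with the
#' backing target intervals it was computed over. Depth is defined only
#' inside the backing targets; coverage accountancy treats bases outside
#' the depth's target space as depth 0.
#'
#' @slot cov RleList; per-chromosome integer depth over the full chromosome.
#' @slot targets GRanges; the backing interval set (reduced).
#' @slot sampleId character; sample label.
#' @slot platform character; "WES" or "CCCS".
#' @export
setClass("DepthProfile", representation(
  cov = "RleList", targets = "GRanges",
  sampleId = "character", platform = "character"
))

setValidity("DepthProfile", function(object) {
  msg <- character(0)
  if (!object@platform %in% c("WES", "CCCS")) {
    msg <- c(msg, "platform must be 'WES' or 'CCCS'")
  }
  if (!all(as.character(seqnames(object@targets)) %in% names(object@cov))) {
    msg <- c(msg, "every target chromosome needs a depth vector")
  }
  if (any(unlist(lapply(object@cov, function(r) any(runValue(r) < 0))))) {
    msg <- c(msg, "depth must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "DepthProfile", function(object) {
  v <- unlist(lapply(names(object@cov), function(ch) {
    gr <- object@targets[seqnames(object@targets) == ch]
    if (!length(gr)) return(numeric(0))
    as.numeric(unlist(Views(object@cov[[ch]], ranges(gr)), use.names = FALSE))
  }))
  cat("DepthProfile [", object@platform, "] sample", object@sampleId, ":",
      length(object@targets), "target intervals,",
      sum(width(object@targets)), "bases, mean depth",
      round(mean(v), 1), "\n")
})

#' @describeIn DepthProfile-class backing target intervals.
#' @param x a `DepthProfile`.
#' @export
profileTargets <- function(x) x@targets

#' @describeIn DepthProfile-class platform label ("WES"/"CCCS").
#' @export
platform <- function(x) x@platform

#' @describeIn DepthProfile-class sample label.
#' @export
sampleId <- function(x) x@sampleId

#' @describeIn DepthProfile-class per-chromosome depth RleList.
#' @export
depthRle <- function(x) x@cov

#' Result of tiered amplicon-probe design
#'
#' @slot probes GRanges of candidate amplicons with metadata columns
#'   `sequence`, `tier`, `status` ("accepted"/"rejected"), `reason`.
#' @slot residual GRanges; requested bases no accepted probe covers.
#' @slot tierCounts named integer; accepted probe count per tier.
#' @slot predictedCoverage numeric; |accepted footprint ∩ CDS| / |CDS|.
#' @export
setClass("ProbeDesign", representation(
  probes = "GRanges", residual = "GRanges",
  tierCounts = "integer", predictedCoverage = "numeric"
))

setMethod("show", "ProbeDesign", function(object) {
  acc <- sum(object@probes$status == "accepted")
  cat("ProbeDesign:", length(object@probes), "candidates,", acc, "accepted",
      "( tiers:", paste(names(object@tierCounts), object@tierCounts,
                        sep = "=", collapse = " "), ")\n")
  cat("  residual:", sum(width(object@residual)), "bases;",
      "predicted CDS coverage", round(object@predictedCoverage, 4), "\n")
})

#' @describeIn ProbeDesign-class accepted probes as a GRanges.
#' @param x a `ProbeDesign`.
#' @export
acceptedProbes <- function(x) x@probes[x@probes$status == "accepted"]

#' @describeIn ProbeDesign-class undesignable residual regions.
#' @export
residualRegions <- function(x) x@residual

#' @describeIn ProbeDesign-class accepted probe count per tier.
#' @export
tierCounts <- function(x) x@tierCounts

#' @describeIn ProbeDesign-class predicted CDS coverage fraction.
#' @export
predictedCoverage <- function(x) x@predictedCoverage
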