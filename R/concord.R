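## NGS-vs-array genotype concordance: false-positive and false-negative
## rate estimation over comparable sites.

#' Compare NGS calls with array genotypes
#'
#' Comparable sites are array sites inside the callable space with an
#' array genotype other than no-call. FP rate = variant calls at array
#' hom-ref comparable sites / array hom-ref comparable sites; FN rate =
#' array variant comparable sites with no variant call / array variant
#' comparable sites. Zygosity mismatches at shared variant sites are
#' counted separately. Sites outside callable space are excluded from both
#' denominators (missing-as-excluded, the conservative mode).
#'
#' @param calls call data.frame (multi-sample; needs sample, chrom, pos,
#'   ref, alt, zygosity and optionally source).
#' @param array array genotype data.frame (sample, chrom, pos, ref, alt,
#'   genotype in hom-ref/het/hom-alt/no-call).
#' @param callable GRanges of callable space, or a named list of GRanges
#'   per sample.
#' @param missingSites optional data.frame (sample, chrom, pos) of sites
#'   whose sequencing result is "missing" despite adequate depth (alt
#'   evidence below the calling band); in conservative mode these are
#'   excluded from comparison rather than scored.
#' @param mode "conservative" (default; missing-as-excluded) or "raw".
#' @return list with counts (`nComparable`, `fp`, `fn`, `zygMismatch`),
#'   rates (`fpRate`, `fnRate`), and `perSource` (data.frame of matched
#'   variant-site counts by calling source).
#' @export
concordance <- function(calls, array, callable, missingSites = NULL,
                        mode = c("conservative", "raw")) {
  mode <- match.arg(mode)
  arr <- array[array$genotype != "no-call", , drop = FALSE]
  if (mode == "conservative" && !is.null(missingSites) && nrow(missingSites)) {
    km <- paste(missingSites$sample, missingSites$chrom, missingSites$pos,
                sep = "\r")
    arr <- arr[!paste(arr$sample, arr$chrom, arr$pos, sep = "\r") %in% km, ,
               drop = FALSE]
  }
  keep <- logical(nrow(arr))
  for (s in unique(arr$sample)) {
    cg <- if (is.list(callable) && !is(callable, "GRanges")) callable[[s]] else callable
    ii <- which(arr$sample == s)
    gr <- GRanges(arr$chrom[ii], IRanges(arr$pos[ii], arr$pos[ii]))
    keep[ii] <- overlapsAny(gr, cg, ignore.strand = TRUE)
  }
  arr <- arr[keep, , drop = FALSE]
  key <- function(d) paste(d$sample, d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  m <- match(key(arr), key(calls))
  called <- !is.na(m)
  callZyg <- ifelse(called,
                    ifelse(calls$zygosity[m] == "homozygous", "hom-alt", "het"),
                    "hom-ref")
  homRef <- arr$genotype == "hom-ref"
  fp <- sum(homRef & called)
  fn <- sum(!homRef & !called)
  zygMismatch <- sum(!homRef & called & callZyg != arr$genotype)
  src <- if (!is.null(calls$source)) calls$source[m] else rep(NA_character_, nrow(arr))
  perSource <- as.data.frame(table(source = src[called & !homRef]),
                             stringsAsFactors = FALSE)
  nHomRef <- sum(homRef); nVar <- sum(!homRef)
  list(nComparable = nrow(arr), fp = fp, fn = fn, zygMismatch = zygMismatch,
       fpRate = if (nHomRef) fp / nHomRef else NA_real_,
       fnRate = if (nVar) fn / nVar else NA_real_,
       perSource = perSource)
}
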