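#' @import methods
#' @importFrom stats rbinom rnorm rpois runif setNames
#' @importFrom utils read.table write.table
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import Biostrings
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqnames seqlevels
#' @importFrom data.table data.table as.data.table setDT setkey setorder rbindlist := .N .SD fifelse
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' Percentage with half-up rounding to one decimal
#'
#' Computes `100 * numerator / denominator` and rounds half-up to one
#' decimal place, the convention used for reported coverage and success
#' rates (e.g. 9/43 -> 20.9).
#'
#' @param numerator,denominator Non-negative counts; `denominator` must be
#'   positive.
#' @return A numeric percentage with one decimal digit.
#' @examples
#' ratePercent(9, 43)   # 20.9
#' ratePercent(35, 43)  # 81.4
#' @export
ratePercent <- function(numerator, denominator) {
  if (any(denominator <= 0)) {
    stop("ratePercent: denominator must be > 0")
  }
  x <- 100 * numerator / denominator
  # round() is banker's; reported rates use arithmetic half-up
  floor(x * 10 + 0.5) / 10
}

## Derive a child RNG seed from a base seed and a stream label.
## Deterministic, keeps results below 2^31.
deriveSeed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.numeric(seed))
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 69069 + h * 9973 + 7) %% 2147483629)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

randomDna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES4, n, replace = TRUE, prob = p), collapse = "")
}

gcFraction <- function(x) {
  if (is.character(x)) x <- DNAStringSet(x)
  if (is(x, "DNAString")) x <- DNAStringSet(x)
  f <- letterFrequency(x, letters = "GC", as.prob = TRUE)
  as.numeric(f)
}

revcompChar <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

## phred character <-> integer helpers (Phred+33)
phredToInt <- function(q) {
  lapply(q, function(s) utf8ToInt(s) - 33L)
}

intToPhred <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}
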