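## Transcript models: one transcript per gene, CDS exons only.
## Coordinate maps between genomic and coding (c.) positions are shared by
## the variant planter and the consequence annotator.

#' Build transcript models from CDS exon intervals
#'
#' @param genes GRanges of CDS exons with metadata columns `gene_id` and
#'   `exon_rank` (transcription order) and a set strand.
#' @return named list of transcript models; each has `id`, `chrom`,
#'   `strand`, `exons` (GRanges in transcription order), `cumStart`
#'   (cumulative CDS bases before each exon) and `cdsLen`.
#' @export
transcriptsFromModels <- function(genes) {
  out <- lapply(split(genes, genes$gene_id), function(gr) {
    gr <- gr[order(gr$exon_rank)]
    w <- width(gr)
    cdsLen <- sum(w)
    if (cdsLen %% 3L != 0L) {
      stop("transcriptsFromModels: CDS length of ", gr$gene_id[1],
           " is not a codon multiple")
    }
    list(id = gr$gene_id[1], chrom = as.character(seqnames(gr))[1],
         strand = as.character(strand(gr))[1], exons = gr,
         cumStart = cumsum(c(0L, w))[seq_along(w)], cdsLen = cdsLen)
  })
  out[order(names(out))]
}

#' Map a coding position to its genomic position
#'
#' @param tr one transcript model from [transcriptsFromModels()].
#' @param cdsPos 1-based coding position(s).
#' @return integer genomic position(s) (1-based).
#' @export
cdsToGenome <- function(tr, cdsPos) {
  vapply(cdsPos, function(cp) {
    stopifnot(cp >= 1L, cp <= tr$cdsLen)
    ei <- findInterval(cp - 1L, tr$cumStart)
    off <- cp - tr$cumStart[ei]
    ex <- tr$exons[ei]
    if (tr$strand == "-") end(ex) - off + 1L else start(ex) + off - 1L
  }, integer(1))
}

#' Map a genomic position to a coding position
#'
#' @param tr one transcript model.
#' @param gpos 1-based genomic position.
#' @return 1-based coding position, or NA when `gpos` is not exonic.
#' @export
genomeToCds <- function(tr, gpos) {
  hit <- which(start(tr$exons) <= gpos & end(tr$exons) >= gpos)
  if (!length(hit)) return(NA_integer_)
  ex <- tr$exons[hit[1]]
  off <- if (tr$strand == "-") end(ex) - gpos + 1L else gpos - start(ex) + 1L
  as.integer(tr$cumStart[hit[1]] + off)
}

## Coding-strand sequence of the codon containing coding position cdsPos.
## Returns list(codon = character(3), gpos = integer(3) genomic positions,
## codonIdx, within = position of cdsPos inside the codon).
codonContext <- function(tr, ref, cdsPos) {
  ci <- (cdsPos - 1L) %/% 3L
  cpos <- ci * 3L + 1:3
  gpos <- cdsToGenome(tr, cpos)
  base <- vapply(gpos, function(g) as.character(subseq(ref[[tr$chrom]], g, g)),
                 character(1))
  if (tr$strand == "-") {
    base <- vapply(base, function(b) revcompChar(b), character(1))
  }
  list(codon = base, gpos = gpos, codonIdx = ci + 1L,
       within = cdsPos - ci * 3L)
}

#' Protein residue index of a coding position
#'
#' Codon arithmetic for HGVS-style annotation: coding position c.N affects
#' residue \eqn{\lfloor (N-1)/3 \rfloor + 1}. For instance c.8098 falls in
#' codon 2700 and c.10168 in codon 3390.
#'
#' @param cdsPos 1-based coding position(s).
#' @return integer residue (codon) index/indices.
#' @examples
#' codonIndex(8098)   # 2700
#' codonIndex(10168)  # 3390
#' @export
codonIndex <- function(cdsPos) {
  stopifnot(all(cdsPos >= 1))
  as.integer((cdsPos - 1) %/% 3 + 1)
}
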