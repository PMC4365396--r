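## File-format interfaces. Interval import/export goes through rtracklayer
## (BED, 0-based half-open on disk, GRanges in memory); sequences through
## Biostrings. VCF/SAM written here use a small fixed schema; reading goes
## through VariantAnnotation / Rsamtools when available.

#' Write a reference as 60-column wrapped FASTA
#' @param seqs named DNAStringSet.
#' @param path output file.
#' @export
writeFasta <- function(seqs, path) {
  writeXStringSet(seqs, filepath = path, width = 60L)
  invisible(path)
}

#' Write paired reads as Phred+33 FASTQ
#' @param reads list with `seq` (DNAStringSet, named) and `qual` (BStringSet).
#' @param path output file.
#' @export
writeFastq <- function(reads, path) {
  writeXStringSet(reads$seq, filepath = path, format = "fastq",
                  qualities = reads$qual)
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ file.
#' @return list with `seq` (DNAStringSet) and `qual` (BStringSet).
#' @export
readFastq <- function(path) {
  x <- readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  list(seq = x, qual = BStringSet(mcols(x)$qualities))
}

#' Export intervals as BED
#'
#' Conversion between in-memory 1-based closed GRanges and on-disk 0-based
#' half-open BED is handled by rtracklayer.
#' @param gr GRanges; a `name` metadata column is carried into BED.
#' @param path output file.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Import a BED file as GRanges
#' @param path BED file.
#' @param seqlens optional named integer vector of chromosome lengths.
#' @export
readBed <- function(path, seqlens = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(seqlens)) seqlengths(gr) <- seqlens[seqlevels(gr)]
  gr
}

#' Write a 6-column PED file
#' @param members data.frame with columns id, father, mother, sex (1/2),
#'   affected (logical); family id is "FAM1".
#' @param path output file.
#' @export
writePed <- function(members, path) {
  ped <- data.frame(
    fam = "FAM1", id = members$id,
    father = ifelse(is.na(members$father), "0", members$father),
    mother = ifelse(is.na(members$mother), "0", members$mother),
    sex = members$sex, pheno = ifelse(members$affected, 2L, 1L)
  )
  write.table(ped, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column PED file
#' @param path PED file.
#' @return data.frame with columns id, father, mother, sex, affected.
#' @export
readPed <- function(path) {
  ped <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("fam", "id", "father", "mother", "sex", "pheno"),
                    colClasses = c("character", "character", "character",
                                   "character", "integer", "integer"))
  data.frame(id = ped$id,
             father = ifelse(ped$father == "0", NA_character_, ped$father),
             mother = ifelse(ped$mother == "0", NA_character_, ped$mother),
             sex = ped$sex, affected = ped$pheno == 2L)
}

#' Write a known-variant database as TSV
#' @param db data.frame with columns chrom, pos, ref, alt, af, pathogenic,
#'   source.
#' @param path output file.
#' @export
writeKnownDb <- function(db, path) {
  write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a known-variant database TSV
#' @param path TSV with columns chrom, pos, ref, alt, af, pathogenic, source.
#' @export
readKnownDb <- function(path) {
  db <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c(chrom = "character", ref = "character",
                                  alt = "character", source = "character"))
  db$pathogenic <- as.logical(db$pathogenic)
  db
}

#' Write array genotypes as TSV
#' @param gt data.frame with columns sample, chrom, pos, ref, alt, genotype
#'   (hom-ref / het / hom-alt / no-call).
#' @param path output file.
#' @export
writeArrayGenotypes <- function(gt, path) {
  write.table(gt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read array genotypes from TSV
#' @param path TSV written by [writeArrayGenotypes()].
#' @export
readArrayGenotypes <- function(path) {
  read.table(path, sep = "\t", header = TRUE,
             colClasses = c(sample = "character", chrom = "character",
                            ref = "character", alt = "character",
                            genotype = "character"))
}

#' Write variant calls as VCF v4.2
#'
#' Fixed schema: INFO fields SRC/AF/DP/VS/CS (plus GENE/CLASS/INH when the
#' columns exist, as in generator truth sets) and per-sample GT. Input rows
#' with identical (chrom,pos,ref,alt) across samples collapse into one
#' multi-sample record.
#'
#' @param calls data.frame with columns chrom, pos, ref, alt, sample, gt
#'   ("0/1","1/1","0|1",...) and optionally af, depth, vs, cs, source,
#'   gene, class, inheritance.
#' @param path output file.
#' @param samples sample column order; defaults to unique values in `calls`.
#' @export
writeVcfCalls <- function(calls, path, samples = NULL) {
  if (is.null(samples)) samples <- unique(calls$sample)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Calling platform (WES/CCCS/BOTH)\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternative allele frequency in reads\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=VS,Number=1,Type=Float,Description=\"Variant score\">",
    "##INFO=<ID=CS,Number=1,Type=Float,Description=\"Consensus score\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=INH,Number=1,Type=String,Description=\"Planted inheritance label\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  if (!nrow(calls)) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  dt <- data.table::as.data.table(calls)
  key <- dt[, list(chrom, pos, ref, alt)]
  uk <- unique(key)
  setorder(uk, chrom, pos, ref, alt)
  infoFor <- function(sub) {
    parts <- character(0)
    grab <- function(col, id, fmt = "%s") {
      if (!is.null(sub[[col]]) && !is.na(sub[[col]][1])) {
        parts <<- c(parts, paste0(id, "=", sprintf(fmt, sub[[col]][1])))
      }
    }
    grab("source", "SRC"); grab("af", "AF", "%.4g"); grab("depth", "DP")
    grab("vs", "VS", "%.4g"); grab("cs", "CS", "%.4g")
    grab("gene", "GENE"); grab("class", "CLASS"); grab("inheritance", "INH")
    if (!length(parts)) "." else paste(parts, collapse = ";")
  }
  lines <- vapply(seq_len(nrow(uk)), function(i) {
    sub <- dt[chrom == uk$chrom[i] & pos == uk$pos[i] &
              ref == uk$ref[i] & alt == uk$alt[i]]
    gts <- setNames(rep("./.", length(samples)), samples)
    gts[sub$sample] <- sub$gt
    paste(c(uk$chrom[i], uk$pos[i], ".", uk$ref[i], uk$alt[i], ".", "PASS",
            infoFor(sub), "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a VCF of calls back into the tabular form
#'
#' Parses through `VariantAnnotation::readVcf` and flattens to one row per
#' (site, sample) with a non-missing genotype.
#'
#' @param path VCF file.
#' @return data.frame with chrom, pos, ref, alt, sample, gt and any of
#'   source/af/depth/vs/cs/gene/class/inheritance present as INFO fields.
#' @export
readVcfCalls <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("readVcfCalls requires the VariantAnnotation package")
  }
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  fx <- VariantAnnotation::fixed(v)
  alt <- vapply(as.list(fx$ALT), function(a) as.character(a)[1], character(1))
  info <- VariantAnnotation::info(v)
  gtm <- VariantAnnotation::geno(v)$GT
  base <- data.frame(
    chrom = as.character(seqnames(rr)), pos = start(rr),
    ref = as.character(fx$REF), alt = alt, stringsAsFactors = FALSE
  )
  pull <- function(id, col) {
    if (id %in% colnames(info)) base[[col]] <<- unlist(info[[id]])
  }
  pull("SRC", "source"); pull("AF", "af"); pull("DP", "depth")
  pull("VS", "vs"); pull("CS", "cs"); pull("GENE", "gene")
  pull("CLASS", "class"); pull("INH", "inheritance")
  out <- do.call(rbind, lapply(colnames(gtm), function(s) {
    keep <- !gtm[, s] %in% c("./.", ".")
    if (!any(keep)) return(NULL)
    cbind(base[keep, , drop = FALSE],
          data.frame(sample = s, gt = gtm[keep, s], stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  out
}

#' Write an alignment table as SAM
#'
#' Minimal SAM emission for interoperability: FLAG encodes strand, mate and
#' duplicate bits; the CIGAR carries the single optional gap; the mask
#' width travels in the custom `XM:i` tag.
#'
#' @param aln alignment table (see package overview).
#' @param seqlens named integer chromosome lengths (for `@SQ` lines).
#' @param path output file.
#' @export
writeSam <- function(aln, seqlens, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(seqlens), "\tLN:", as.integer(seqlens)))
  if (!nrow(aln)) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  flag <- 1L + 2L +
    ifelse(aln$strand == "-", 16L, 0L) +
    ifelse(aln$mate == 1L, 64L, 128L)
  if (!is.null(aln$dup)) flag <- flag + ifelse(aln$dup, 1024L, 0L)
  cigar <- ifelse(is.na(aln$gapType),
    paste0(aln$readLen, "M"),
    ifelse(aln$gapType == "D",
      paste0(aln$gapPos, "M", aln$gapLen, "D", aln$readLen - aln$gapPos, "M"),
      paste0(aln$gapPos, "M", aln$gapLen, "I",
             aln$readLen - aln$gapPos - aln$gapLen, "M")))
  lines <- paste(aln$qname, flag, aln$chrom, aln$start, 60L, cigar,
                 "*", 0L, 0L, aln$seq, aln$qual,
                 paste0("NM:i:", aln$mm), paste0("XM:i:", aln$maskN),
                 sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a SAM file into an alignment table
#'
#' Parses through Rsamtools (SAM -> BAM -> scanBam), so externally produced
#' alignments can enter the pipeline.
#'
#' @param path SAM file.
#' @return alignment table data.frame.
#' @export
readSam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("readSam requires the Rsamtools package")
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"),
    tag = c("NM", "XM"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  if (!n) {
    return(data.frame(qname = character(0)))
  }
  cig <- x$cigar
  gapType <- rep(NA_character_, n); gapPos <- rep(NA_integer_, n)
  gapLen <- rep(NA_integer_, n)
  g <- regmatches(cig, regexec("^(\\d+)M(\\d+)([ID])(\\d+)M$", cig))
  hit <- lengths(g) == 5L
  gapPos[hit] <- as.integer(vapply(g[hit], `[`, character(1), 2))
  gapLen[hit] <- as.integer(vapply(g[hit], `[`, character(1), 3))
  gapType[hit] <- vapply(g[hit], `[`, character(1), 4)
  data.frame(
    qname = x$qname,
    chrom = as.character(x$rname),
    strand = ifelse(bitwAnd(x$flag, 16L) > 0L, "-", "+"),
    start = x$pos,
    readLen = nchar(as.character(x$seq)),
    seq = as.character(x$seq), qual = as.character(x$qual),
    mate = ifelse(bitwAnd(x$flag, 64L) > 0L, 1L, 2L),
    dup = bitwAnd(x$flag, 1024L) > 0L,
    mm = if (!is.null(x$tag$NM)) x$tag$NM else NA_integer_,
    maskN = if (!is.null(x$tag$XM)) x$tag$XM else 0L,
    gapType = gapType, gapPos = gapPos, gapLen = gapLen,
    stringsAsFactors = FALSE
  )
}
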