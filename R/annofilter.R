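## Consequence annotation, database filtering with pathogenic rescue,
## Mendelian-model candidate selection and cascade reporting.

NONSYN_CLASSES <- c("nonsense", "missense", "splice-site", "frameshift-indel")

#' Annotate variant calls against transcript models
#'
#' Strand-aware genome-to-CDS mapping with codon translation: stop-gain
#' detection by translating the mutated codon, frameshift detection for
#' indels whose length is not a codon multiple, splice-site = within 2
#' intronic bases of an exon boundary. One transcript per gene.
#'
#' @param calls call data.frame (chrom, pos, ref, alt, ...).
#' @param transcripts output of [transcriptsFromModels()].
#' @param ref named DNAStringSet reference.
#' @return `calls` with added columns class, gene, cdsPos, codonIdx.
#' @export
annotateVariants <- function(calls, transcripts, ref) {
  n <- nrow(calls)
  cls <- rep("nongenic", n); gene <- rep(NA_character_, n)
  cdsPos <- rep(NA_integer_, n); codonIdx <- rep(NA_integer_, n)
  if (!n) {
    calls$class <- character(0); calls$gene <- character(0)
    calls$cdsPos <- integer(0); calls$codonIdx <- integer(0)
    return(calls)
  }
  spans <- do.call(rbind, lapply(transcripts, function(tr) {
    data.frame(gene = tr$id, chrom = tr$chrom,
               lo = min(start(tr$exons)), hi = max(end(tr$exons)))
  }))
  gcode <- Biostrings::GENETIC_CODE
  for (i in seq_len(n)) {
    isIndel <- nchar(calls$ref[i]) != nchar(calls$alt[i])
    ## for anchored indels the first changed base is pos + 1
    qpos <- if (isIndel) calls$pos[i] + 1L else calls$pos[i]
    hit <- spans[spans$chrom == calls$chrom[i] & spans$lo <= qpos &
                 spans$hi >= qpos, , drop = FALSE]
    if (!nrow(hit)) next
    tr <- transcripts[[hit$gene[1]]]
    gene[i] <- tr$id
    cp <- genomeToCds(tr, qpos)
    if (is.na(cp)) {
      ## intronic side: distance to the nearest exon edge
      d <- min(abs(c(start(tr$exons) - qpos, end(tr$exons) - qpos)))
      cls[i] <- if (d <= 2L) "splice-site" else "intronic"
      next
    }
    if (isIndel) {
      indelLen <- abs(nchar(calls$ref[i]) - nchar(calls$alt[i]))
      cls[i] <- if (indelLen %% 3L != 0L) "frameshift-indel" else "missense"
      cdsPos[i] <- cp; codonIdx[i] <- codonIndex(cp)
      next
    }
    ctx <- codonContext(tr, ref, cp)
    refCodon <- paste(ctx$codon, collapse = "")
    altBase <- calls$alt[i]
    if (tr$strand == "-") altBase <- revcompChar(altBase)
    altCodon <- refCodon
    substr(altCodon, ctx$within, ctx$within) <- altBase
    aaR <- gcode[[refCodon]]; aaA <- gcode[[altCodon]]
    cls[i] <- if (aaA == aaR) "synonymous"
              else if (aaA == "*") "nonsense"
              else "missense"
    cdsPos[i] <- cp; codonIdx[i] <- ctx$codonIdx
  }
  calls$class <- cls; calls$gene <- gene
  calls$cdsPos <- cdsPos; calls$codonIdx <- codonIdx
  calls
}

#' Exclude database-known variants, rescuing known-pathogenic rare ones
#'
#' A call is removed when its site (chrom, pos, ref, alt) is in the
#' database, unless it is flagged pathogenic with population MAF below
#' `mafRescue`.
#'
#' @param calls call data.frame.
#' @param db data.frame with chrom, pos, ref, alt, af, pathogenic.
#' @param mafRescue rescue threshold (default 0.01).
#' @return filtered calls.
#' @export
filterKnown <- function(calls, db, mafRescue = 0.01) {
  if (!nrow(calls) || !nrow(db)) return(calls)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  kd <- key(db)
  exclKeys <- kd[!(db$pathogenic & !is.na(db$af) & db$af < mafRescue)]
  calls[!key(calls) %in% exclKeys, , drop = FALSE]
}

#' Keep nonsynonymous-eligible variants only
#'
#' Retains nonsense, missense, splice-site and frameshift-indel calls;
#' nongenic, intronic, UTR and synonymous calls are excluded.
#'
#' @param calls annotated call data.frame (needs a `class` column).
#' @return filtered calls.
#' @export
filterConsequence <- function(calls) {
  calls[calls$class %in% NONSYN_CLASSES, , drop = FALSE]
}

## Dosage (0/1/2 alt copies, NA = missing) of one member at given sites.
## depthFun(sample, chrom, pos) -> callable depth (used for absent sites).
dosageAt <- function(calls, sampleId, sites, depthFun, minDepth = 10L) {
  sub <- calls[calls$sample == sampleId, , drop = FALSE]
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  m <- match(key(sites), key(sub))
  dos <- ifelse(is.na(m), 0L,
                ifelse(sub$zygosity[m] == "homozygous", 2L, 1L))
  absent <- is.na(m)
  if (any(absent)) {
    dp <- mapply(function(ch, p) depthFun(sampleId, ch, p),
                 sites$chrom[absent], sites$pos[absent])
    dos[absent][dp < minDepth] <- NA_integer_
  }
  dos
}

#' Mendelian-model candidate selection
#'
#' Applies the de novo, autosomal-recessive-homozygous and
#' compound-heterozygous models to a family call set. A site that is
#' "missing" (callable depth below `minDepth`, no call) in a member the
#' model needs disqualifies that site for that model — absence of
#' evidence is never treated as hom-ref at uncallable sites.
#'
#' Model definitions: de novo = het in the affected, callable hom-ref in
#' both parents; AR-hom = hom in the affected, het in both parents, not
#' hom in any unaffected member; compound-het = two or more het
#' nonsynonymous variants in one gene in the affected with opposite
#' parental origin, the paternal+maternal pair not co-carried by any
#' unaffected sibling.
#'
#' @param calls annotated, filtered family call data.frame (multi-sample).
#' @param members pedigree data.frame (id, father, mother, affected).
#' @param depthFun function(sample, chrom, pos) returning callable depth.
#' @param models subset of c("ARhom", "comphet", "denovo").
#' @param minDepth callability threshold (default 10).
#' @return data.frame of candidates: model, gene, chrom, pos, ref, alt,
#'   sample (the affected member).
#' @export
inheritanceFilter <- function(calls, members, depthFun,
                              models = c("ARhom", "comphet", "denovo"),
                              minDepth = 10L) {
  out <- list()
  affected <- members$id[members$affected &
                         !is.na(members$father) & !is.na(members$mother)]
  for (affId in affected) {
    fa <- members$father[members$id == affId]
    mo <- members$mother[members$id == affId]
    unaff <- members$id[!members$affected & members$id != affId]
    sites <- calls[calls$sample == affId, , drop = FALSE]
    if (!nrow(sites)) next
    dAff <- dosageAt(calls, affId, sites, depthFun, minDepth)
    dFa <- dosageAt(calls, fa, sites, depthFun, minDepth)
    dMo <- dosageAt(calls, mo, sites, depthFun, minDepth)
    dUn <- lapply(unaff, function(u) dosageAt(calls, u, sites, depthFun, minDepth))
    if ("denovo" %in% models) {
      ok <- dAff == 1L & !is.na(dFa) & dFa == 0L & !is.na(dMo) & dMo == 0L
      ok[is.na(ok)] <- FALSE
      if (any(ok)) {
        out[[length(out) + 1L]] <- data.frame(
          model = "denovo", gene = sites$gene[ok], chrom = sites$chrom[ok],
          pos = sites$pos[ok], ref = sites$ref[ok], alt = sites$alt[ok],
          sample = affId)
      }
    }
    if ("ARhom" %in% models) {
      ok <- dAff == 2L & !is.na(dFa) & dFa == 1L & !is.na(dMo) & dMo == 1L
      ok[is.na(ok)] <- FALSE
      if (any(ok) && length(dUn)) {
        sibHom <- Reduce(`|`, lapply(dUn, function(d) !is.na(d) & d == 2L))
        ok <- ok & !sibHom
      }
      if (any(ok)) {
        out[[length(out) + 1L]] <- data.frame(
          model = "ARhom", gene = sites$gene[ok], chrom = sites$chrom[ok],
          pos = sites$pos[ok], ref = sites$ref[ok], alt = sites$alt[ok],
          sample = affId)
      }
    }
    if ("comphet" %in% models) {
      het <- dAff == 1L & !is.na(sites$gene)
      paternal <- het & !is.na(dFa) & dFa >= 1L & !is.na(dMo) & dMo == 0L
      maternal <- het & !is.na(dMo) & dMo >= 1L & !is.na(dFa) & dFa == 0L
      for (g in unique(sites$gene[het & (paternal | maternal)])) {
        pi <- which(paternal & sites$gene == g)
        mi <- which(maternal & sites$gene == g)
        if (!length(pi) || !length(mi)) next
        ## the paternal+maternal configuration must be absent from every
        ## unaffected sibling
        validPair <- FALSE
        pick <- NULL
        for (a in pi) for (b in mi) {
          cocarried <- any(vapply(dUn, function(d) {
            !is.na(d[a]) && d[a] >= 1L && !is.na(d[b]) && d[b] >= 1L
          }, logical(1)))
          if (!cocarried) { validPair <- TRUE; pick <- union(pick, c(a, b)) }
        }
        if (validPair) {
          out[[length(out) + 1L]] <- data.frame(
            model = "comphet", gene = g, chrom = sites$chrom[pick],
            pos = sites$pos[pick], ref = sites$ref[pick],
            alt = sites$alt[pick], sample = affId)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(model = character(0), gene = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      sample = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Candidate-filtering cascade report
#'
#' Stage counts per member: all called variants, after excluding
#' database-known variants (with pathogenic rescue), after restricting to
#' nonsynonymous classes, and after inheritance-model filtering (counted
#' for affected members). Counts are monotone non-increasing by
#' construction.
#'
#' @param calls annotated multi-sample call data.frame.
#' @param db known-variant database.
#' @param members pedigree data.frame.
#' @param depthFun callable-depth lookup (see [inheritanceFilter()]).
#' @param models inheritance models applied at the last stage.
#' @param mafRescue pathogenic rescue threshold (default 0.01).
#' @return list with `report` (data.frame member, stage, count; stage is
#'   an ordered factor) and `candidates` (the last-stage candidate table).
#' @export
variantCascade <- function(calls, db, members, depthFun,
                           models = c("ARhom", "comphet"),
                           mafRescue = 0.01) {
  stages <- c("all-called", "known-excluded", "nonsynonymous", "inheritance")
  s1 <- calls
  s2 <- filterKnown(s1, db, mafRescue)
  s3 <- filterConsequence(s2)
  cand <- inheritanceFilter(s3, members, depthFun, models)
  cnt <- function(d, m) sum(d$sample == m)
  rows <- lapply(members$id, function(m) {
    c4 <- if (members$affected[members$id == m]) {
      cm <- cand[cand$sample == m, , drop = FALSE]
      length(unique(paste(cm$chrom, cm$pos, cm$ref, cm$alt)))
    } else 0L
    data.frame(member = m, stage = factor(stages, levels = stages, ordered = TRUE),
               count = c(cnt(s1, m), cnt(s2, m), cnt(s3, m), c4))
  })
  list(report = do.call(rbind, rows), candidates = cand)
}
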