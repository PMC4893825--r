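# HGVS description generation (g. / c. / n. / p.) with 3' normalisation, and
# parsing of g./c. input notations back to genomic variants.

#' Genomic-level HGVS description
#'
#' SNVs use \code{pos ref ">" alt}; deletions and insertions are right-shifted
#' to the most 3' genomic position in repetitive context, and an insertion
#' equal to the immediately 5' adjacent sequence is reported as \code{dup}.
#' Deleted/duplicated sequences are omitted (position-only form).
#'
#' @param row one-row variant data.frame (internal representation).
#' @param alt single alternative allele string.
#' @param store an \linkS4class{AnnotationStore} (reference context).
#' @param accession chromosome accession for the prefix (defaults to chrom).
#' @export
hgvsG <- function(row, alt, store, accession = row$chrom) {
  if (row$is_structural) stop("HGVS for structural variants is unsupported")
  seq <- chromSeq(store, row$chrom)
  ref <- row$ref
  if (ref != "-" && alt != "-" && nchar(ref) == 1L && nchar(alt) == 1L) {
    desc <- if (identical(ref, alt)) sprintf("g.%d%s=", row$start, ref)
            else sprintf("g.%d%s>%s", row$start, ref, alt)
    return(paste0(accession, ":", desc))
  }
  if (alt == "-") {                      # deletion
    L <- nchar(ref)
    p <- shift3Deletion(seq, row$start, L)
    desc <- if (L == 1L) sprintf("g.%ddel", p)
            else sprintf("g.%d_%ddel", p, p + L - 1L)
    return(paste0(accession, ":", desc))
  }
  if (ref == "-") {                      # insertion
    sh <- shift3Insertion(seq, row$start - 1L, alt)
    L <- nchar(sh$allele)
    if (isDuplication(seq, sh$after, sh$allele)) {
      desc <- if (L == 1L) sprintf("g.%ddup", sh$after)
              else sprintf("g.%d_%ddup", sh$after - L + 1L, sh$after)
    } else {
      desc <- sprintf("g.%d_%dins%s", sh$after, sh$after + 1L, sh$allele)
    }
    return(paste0(accession, ":", desc))
  }
  # balanced or complex substitution
  desc <- sprintf("g.%d_%ddelins%s", row$start, row$end, alt)
  paste0(accession, ":", desc)
}

# c./n. position string for a cDNA coordinate
cPosString <- function(cdna, map, coding) {
  if (!coding) return(as.character(cdna))
  if (cdna < map$cdsCdnaStart) return(as.character(cdna - map$cdsCdnaStart))
  if (cdna > map$cdsCdnaEnd) return(paste0("*", cdna - map$cdsCdnaEnd))
  as.character(cdna - map$cdsCdnaStart + 1L)
}

# Intronic position string: nearest exon edge in transcript orientation plus
# +/- offset (5' half of the intron gets "+", 3' half "-").
cIntronString <- function(g, tx, map, coding) {
  inS <- IRanges::start(map$introns); inE <- IRanges::end(map$introns)
  j <- which(inS <= g & g <= inE)[1L]
  s <- inS[j]; e <- inE[j]
  if (tx@strand > 0L) {
    off5 <- g - s + 1L; off3 <- e - g + 1L
    edge5 <- map$g2c(s - 1L); edge3 <- map$g2c(e + 1L)
  } else {
    off5 <- e - g + 1L; off3 <- g - s + 1L
    edge5 <- map$g2c(e + 1L); edge3 <- map$g2c(s - 1L)
  }
  if (off5 <= off3) paste0(cPosString(edge5, map, coding), "+", off5)
  else paste0(cPosString(edge3, map, coding), "-", off3)
}

#' Transcript-level HGVS description (c. for coding, n. for non-coding)
#'
#' 5' UTR positions are negative, 3' UTR positions use "*", intronic positions
#' carry +/- offsets from the nearest exon edge. Indels are right-shifted
#' relative to the transcript's 5' to 3' orientation (the genomic left for
#' minus-strand transcripts). The versioned accession prefixes the output.
#'
#' @export
hgvsC <- function(row, alt, tx, store) {
  if (!is(tx, "TranscriptModel")) stop("feature is not a transcript")
  map <- txMap(tx, store)
  coding <- !is.na(tx@cds_start)
  level <- if (coding) "c." else "n."
  acc <- versionedId(tx)
  cdna <- splicedSequence(tx, store)
  refT <- if (row$ref == "-") "" else
    if (tx@strand > 0L) row$ref else revcompStr(row$ref)
  altT <- if (alt == "-") "" else
    if (tx@strand > 0L) alt else revcompStr(alt)
  # SNV ----
  if (nchar(refT) == 1L && nchar(altT) == 1L) {
    c1 <- map$g2c(row$start)
    pos <- if (is.na(c1)) cIntronString(row$start, tx, map, coding)
           else cPosString(c1, map, coding)
    return(paste0(acc, ":", level, pos, refT, ">", altT))
  }
  # deletion ----
  if (alt == "-") {
    cA <- map$g2c(row$start); cB <- map$g2c(row$end)
    if (is.na(cA) || is.na(cB)) {   # (partly) intronic: no cDNA shifting
      pA <- if (is.na(cA)) cIntronString(row$start, tx, map, coding) else cPosString(cA, map, coding)
      pB <- if (is.na(cB)) cIntronString(row$end, tx, map, coding) else cPosString(cB, map, coding)
      if (tx@strand < 0L) { tmp <- pA; pA <- pB; pB <- tmp }
      desc <- if (identical(pA, pB)) paste0(level, pA, "del")
              else paste0(level, pA, "_", pB, "del")
      return(paste0(acc, ":", desc))
    }
    lo <- min(cA, cB); L <- abs(cB - cA) + 1L
    p <- shift3Deletion(cdna, lo, L)
    desc <- if (L == 1L) paste0(level, cPosString(p, map, coding), "del")
            else paste0(level, cPosString(p, map, coding), "_",
                        cPosString(p + L - 1L, map, coding), "del")
    return(paste0(acc, ":", desc))
  }
  # insertion ----
  if (row$ref == "-") {
    ca <- map$g2c(row$end); cb <- map$g2c(row$start)   # flanking bases
    cs <- c(ca, cb); cs <- cs[!is.na(cs)]
    if (length(cs) < 2L) {
      pos <- cIntronString(if (is.na(ca)) row$end else row$start, tx, map, coding)
      return(paste0(acc, ":", level, pos, "ins", altT))
    }
    after <- min(cs)
    sh <- shift3Insertion(cdna, after, altT)
    L <- nchar(sh$allele)
    if (isDuplication(cdna, sh$after, sh$allele)) {
      desc <- if (L == 1L) paste0(level, cPosString(sh$after, map, coding), "dup")
              else paste0(level, cPosString(sh$after - L + 1L, map, coding), "_",
                          cPosString(sh$after, map, coding), "dup")
    } else {
      desc <- paste0(level, cPosString(sh$after, map, coding), "_",
                     cPosString(sh$after + 1L, map, coding), "ins", sh$allele)
    }
    return(paste0(acc, ":", desc))
  }
  # balanced / complex
  cA <- map$g2c(row$start); cB <- map$g2c(row$end)
  if (is.na(cA) || is.na(cB)) return(NA_character_)
  lo <- min(cA, cB); hi <- max(cA, cB)
  paste0(acc, ":", level, cPosString(lo, map, coding), "_",
         cPosString(hi, map, coding), "delins", altT)
}

#' Protein-level HGVS description
#'
#' Three-letter amino-acid codes with \code{Ter} for stop. Substitutions
#' \code{p.Xaa#Yaa}, synonymous \code{p.Xaa#=}, start loss \code{p.Met1?},
#' stop loss \code{p.Ter#YaaextTer#}, frameshifts \code{p.Xaa#YaafsTer#} with
#' the new stop distance computed by re-translating the mutant CDS, and basic
#' in-frame del/ins naming. Returns NA for effects that do not touch the CDS.
#'
#' @param context allele context produced by the consequence engine.
#' @export
hgvsP <- function(row, alt, tx, store, context = NULL) {
  if (is.na(tx@cds_start)) return(NA_character_)
  if (is.null(context)) context <- alleleContext(row, alt, tx, store)
  b <- context$bundle
  if (!isTRUE(b$overlapsCds)) return(NA_character_)
  acc <- versionedId(tx)
  cds <- cdsSequence(tx, store)
  tbl <- if (isMitoChrom(store, tx@chrom)) "mito" else "standard"
  seleno <- tx@attrs$seleno %||% integer(0)
  cd <- context$codon
  # substitution with codon info ----
  if (!is.null(cd) && !is.na(cd$ref_aa)) {
    if (!cd$changed || identical(cd$ref_aa, cd$alt_aa)) {
      return(sprintf("%s:p.%s%d=", acc,
                     AA3[substr(cd$ref_aa, 1L, 1L)], cd$c1))
    }
    if (cd$startCodon) return(sprintf("%s:p.Met1?", acc))
    ra <- strsplit(cd$ref_aa, "")[[1L]]; aa <- strsplit(cd$alt_aa, "")[[1L]]
    d <- which(ra != aa)
    if (length(d) == 1L) {
      pos <- cd$c1 + d - 1L
      if (ra[d] == "*" && aa[d] != "*") {
        # stop lost: translate on into the 3' UTR for the extension length
        cdna <- splicedSequence(tx, store)
        map <- context$map
        tail3 <- substr(cdna, map$cdsCdnaStart + (pos - 1L) * 3L, nchar(cdna))
        ext <- paste0(aa[d], substr(tail3, 4L, nchar(tail3)))
        mt <- translateCds(paste0(cd$alt_codons,
                                  substr(cdna, map$cdsCdnaEnd + 1L, nchar(cdna))),
                           tbl)
        stopAt <- regexpr("*", substr(mt, d, nchar(mt)), fixed = TRUE)
        extStr <- if (stopAt > 0L) paste0("extTer", stopAt - 1L) else "extTer?"
        return(sprintf("%s:p.Ter%d%s%s", acc, pos, AA3[aa[d]], extStr))
      }
      suffix <- if (aa[d] == "*") "Ter" else AA3[aa[d]]
      return(sprintf("%s:p.%s%d%s", acc, AA3[ra[d]], pos, suffix))
    }
    # multi-residue substitution
    return(sprintf("%s:p.%s%d_%s%ddelins%s", acc, AA3[ra[1L]], cd$c1,
                   AA3[ra[length(ra)]], cd$c2, aaThree(cd$alt_aa)))
  }
  # indels ----
  refProt <- txProtein(tx, store)
  cdsPos <- b$cds_start
  codon1 <- (cdsPos + 2L) %/% 3L
  if (context$isDel || context$isIns || context$isComplex) {
    dl <- codingChangeLen(context)
    inframe <- ((if (context$isIns) nchar(alt) else dl) %% 3L) == 0L &&
      !context$isComplex
    if (inframe && context$isDel && (cdsPos - 1L) %% 3L == 0L && dl %% 3L == 0L) {
      cFrom <- codon1; cTo <- codon1 + dl %/% 3L - 1L
      a1 <- AA3[substr(refProt, cFrom, cFrom)]
      a2 <- AA3[substr(refProt, cTo, cTo)]
      desc <- if (cFrom == cTo) sprintf("p.%s%ddel", a1, cFrom)
              else sprintf("p.%s%d_%s%ddel", a1, cFrom, a2, cTo)
      return(paste0(acc, ":", desc))
    }
    if (inframe && context$isIns && (cdsPos %% 3L) == 0L) {
      altT <- if (tx@strand > 0L) alt else revcompStr(alt)
      insAA <- translateCds(altT, tbl)
      cAt <- cdsPos %/% 3L
      a1 <- AA3[substr(refProt, cAt, cAt)]
      a2 <- AA3[substr(refProt, cAt + 1L, cAt + 1L)]
      return(sprintf("%s:p.%s%d_%s%dins%s", acc, a1, cAt, a2, cAt + 1L,
                     aaThree(as.character(insAA))))
    }
    # frameshift (or unaligned in-frame change): re-translate the mutant CDS
    mutant <- mutantCdsThroughEnd(row, alt, tx, store)
    if (is.null(mutant)) return(NA_character_)
    mProt <- if (nchar(mutant) >= 3L) as.character(translateCds(mutant, tbl)) else ""
    refTail <- substr(refProt, 1L, nchar(refProt))
    d <- 1L
    nmin <- min(nchar(mProt), nchar(refProt))
    while (d <= nmin && substr(mProt, d, d) == substr(refTail, d, d)) d <- d + 1L
    refAA <- substr(refProt, d, d)
    newAA <- substr(mProt, d, d)
    if (!nzchar(refAA)) return(NA_character_)
    if (!inframe || context$isComplex) {
      if (identical(newAA, "*"))
        return(sprintf("%s:p.%s%dTer", acc, AA3[refAA], d))
      stopAt <- regexpr("*", substr(mProt, d, nchar(mProt)), fixed = TRUE)
      fs <- if (stopAt > 0L) paste0("fsTer", stopAt) else "fsTer?"
      if (!nzchar(newAA)) return(NA_character_)
      return(sprintf("%s:p.%s%d%s%s", acc, AA3[refAA], d, AA3[newAA], fs))
    }
    # in-frame but not codon-aligned: report as deletion-insertion at codon
    return(sprintf("%s:p.%s%ddelins%s", acc, AA3[refAA], d,
                   if (nzchar(newAA)) AA3[newAA] else "?"))
  }
  NA_character_
}

# Mutant CDS from the edit position through the end of the cDNA (frameshift
# stop search needs sequence beyond the reference stop).
mutantCdsThroughEnd <- function(row, alt, tx, store) {
  map <- txMap(tx, store)
  cdna <- splicedSequence(tx, store)
  refT <- if (row$ref == "-") "" else
    if (tx@strand > 0L) row$ref else revcompStr(row$ref)
  altT <- if (alt == "-") "" else
    if (tx@strand > 0L) alt else revcompStr(alt)
  if (row$ref == "-") {
    ca <- map$g2c(row$end); cb <- map$g2c(row$start)
    cs <- c(ca, cb); cs <- cs[!is.na(cs)]
    if (length(cs) < 2L) return(NULL)
    after <- min(cs)
    mut <- paste0(substr(cdna, 1L, after), altT,
                  substr(cdna, after + 1L, nchar(cdna)))
  } else {
    cA <- map$g2c(row$start); cB <- map$g2c(row$end)
    if (is.na(cA) || is.na(cB)) return(NULL)
    lo <- min(cA, cB); hi <- max(cA, cB)
    mut <- paste0(substr(cdna, 1L, lo - 1L), altT,
                  substr(cdna, hi + 1L, nchar(cdna)))
  }
  substr(mut, map$cdsCdnaStart, nchar(mut))
}

# ---- input parsing ---------------------------------------------------------

#' Resolve an HGVS g. or c./n. notation to a genomic variant
#'
#' c. coordinates (including intronic offsets and UTR positions) are projected
#' through the transcript's exon structure and strand. Unknown reference
#' features raise a resolution error; p. notation is unsupported; a version
#' mismatch warns and resolves on the accession.
#'
#' @param notation e.g. \code{"chrT:g.25C>T"} or \code{"TX1.1:c.5C>T"}.
#' @param store an \linkS4class{AnnotationStore}.
#' @return a one-row \linkS4class{VariantSet}.
#' @export
parseHgvsInput <- function(notation, store) {
  m <- regmatches(notation, regexec("^([^:]+):([gcnp])\\.(.+)$", notation))[[1L]]
  if (length(m) != 4L) stop("cannot parse HGVS notation: ", notation)
  acc <- m[2L]; level <- m[3L]; desc <- m[4L]
  if (level == "p.") level <- "p"
  if (level == "p") stop("protein-level HGVS input is unsupported")
  if (level == "g") {
    row <- parseHgvsGDesc(acc, desc, store)
  } else {
    row <- parseHgvsCDesc(acc, desc, store)
  }
  new("VariantSet", tab = row)
}

parseHgvsGDesc <- function(acc, desc, store) {
  seq <- tryCatch(chromSeq(store, acc), error = function(e)
    stop("unknown reference feature: ", acc))
  if (grepl("^(\\d+)([ACGTN])>([ACGTN])$", desc)) {
    m <- regmatches(desc, regexec("^(\\d+)([ACGTN])>([ACGTN])$", desc))[[1L]]
    p <- as.integer(m[2L])
    return(makeVariantRow(acc, p, p, m[3L], m[4L]))
  }
  if (grepl("^(\\d+)(_(\\d+))?del", desc)) {
    m <- regmatches(desc, regexec("^(\\d+)(_(\\d+))?del", desc))[[1L]]
    p1 <- as.integer(m[2L])
    p2 <- if (nzchar(m[4L])) as.integer(m[4L]) else p1
    return(makeVariantRow(acc, p1, p2, substr(seq, p1, p2), "-"))
  }
  if (grepl("^(\\d+)(_(\\d+))?dup$", desc)) {
    m <- regmatches(desc, regexec("^(\\d+)(_(\\d+))?dup$", desc))[[1L]]
    p1 <- as.integer(m[2L])
    p2 <- if (nzchar(m[4L])) as.integer(m[4L]) else p1
    return(makeVariantRow(acc, p2 + 1L, p2, "-", substr(seq, p1, p2)))
  }
  if (grepl("^(\\d+)_(\\d+)ins([ACGTN]+)$", desc)) {
    m <- regmatches(desc, regexec("^(\\d+)_(\\d+)ins([ACGTN]+)$", desc))[[1L]]
    p1 <- as.integer(m[2L])
    return(makeVariantRow(acc, p1 + 1L, p1, "-", m[4L]))
  }
  if (grepl("^(\\d+)(_(\\d+))?delins([ACGTN]+)$", desc)) {
    m <- regmatches(desc, regexec("^(\\d+)(_(\\d+))?delins([ACGTN]+)$", desc))[[1L]]
    p1 <- as.integer(m[2L])
    p2 <- if (nzchar(m[4L])) as.integer(m[4L]) else p1
    return(makeVariantRow(acc, p1, p2, substr(seq, p1, p2), m[5L]))
  }
  stop("unsupported g. description: ", desc)
}

# c./n. position -> genomic coordinate
cCoordToGenomic <- function(posStr, tx, map, coding) {
  m <- regmatches(posStr,
    regexec("^(\\*?)(-?\\d+)(([+-])(\\d+))?$", posStr))[[1L]]
  if (!length(m)) stop("cannot parse c. position: ", posStr)
  star <- nzchar(m[2L])
  base <- as.integer(m[3L])
  hasOff <- nzchar(m[4L])
  cdna <- if (!coding) base
          else if (star) map$cdsCdnaEnd + base
          else if (base > 0L) map$cdsCdnaStart + base - 1L
          else map$cdsCdnaStart + base         # negative: -1 is base before CDS
  g <- map$c2g(cdna)
  if (hasOff) {
    off <- as.integer(m[6L])
    sign <- if (m[5L] == "+") 1L else -1L
    g <- g + tx@strand * sign * off
  }
  g
}

parseHgvsCDesc <- function(acc, desc, store) {
  id <- sub("\\.\\d+$", "", acc)
  verIn <- suppressWarnings(as.integer(sub("^.*\\.", "", acc)))
  tx <- storeTranscript(store, id)
  if (is.null(tx)) stop("unknown reference feature: ", acc)
  if (!is.na(verIn) && verIn != tx@version)
    warning("version mismatch for ", id, ": input .", verIn,
            ", cache has .", tx@version, "; resolving on accession")
  map <- txMap(tx, store)
  coding <- !is.na(tx@cds_start)
  toGenomicAllele <- function(a) if (tx@strand > 0L) a else revcompStr(a)
  m <- regmatches(desc, regexec(
    "^([*-]?\\d+([+-]\\d+)?)([ACGTN])>([ACGTN])$", desc))[[1L]]
  if (length(m)) {
    g <- cCoordToGenomic(m[2L], tx, map, coding)
    return(makeVariantRow(tx@chrom, g, g, toGenomicAllele(m[4L]),
                          toGenomicAllele(m[5L])))
  }
  m <- regmatches(desc, regexec(
    "^([*-]?\\d+([+-]\\d+)?)(_([*-]?\\d+([+-]\\d+)?))?del$", desc))[[1L]]
  if (length(m)) {
    g1 <- cCoordToGenomic(m[2L], tx, map, coding)
    g2 <- if (nzchar(m[5L])) cCoordToGenomic(m[5L], tx, map, coding) else g1
    lo <- min(g1, g2); hi <- max(g1, g2)
    seq <- chromSeq(store, tx@chrom)
    return(makeVariantRow(tx@chrom, lo, hi, substr(seq, lo, hi), "-"))
  }
  m <- regmatches(desc, regexec(
    "^([*-]?\\d+([+-]\\d+)?)_([*-]?\\d+([+-]\\d+)?)ins([ACGTN]+)$", desc))[[1L]]
  if (length(m)) {
    g1 <- cCoordToGenomic(m[2L], tx, map, coding)
    g2 <- cCoordToGenomic(m[4L], tx, map, coding)
    lo <- min(g1, g2)
    return(makeVariantRow(tx@chrom, lo + 1L, lo, "-", toGenomicAllele(m[6L])))
  }
  m <- regmatches(desc, regexec(
    "^([*-]?\\d+([+-]\\d+)?)(_([*-]?\\d+([+-]\\d+)?))?dup$", desc))[[1L]]
  if (length(m)) {
    g1 <- cCoordToGenomic(m[2L], tx, map, coding)
    g2 <- if (nzchar(m[5L])) cCoordToGenomic(m[5L], tx, map, coding) else g1
    lo <- min(g1, g2); hi <- max(g1, g2)
    seq <- chromSeq(store, tx@chrom)
    return(makeVariantRow(tx@chrom, hi + 1L, hi, "-", substr(seq, lo, hi)))
  }
  stop("unsupported c. description: ", desc)
}
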