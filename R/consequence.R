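#' @importFrom IRanges IRanges start end
NULL

# ---- coordinate bundle -----------------------------------------------------

#' Project a variant span onto a transcript's coordinate systems
#'
#' Genomic span projected through the exon structure honoring strand: cDNA and
#' CDS intervals for the exonic portion, protein interval (ceil(cds/3)
#' bounds), exon/intron indices, and distance to the transcript when the span
#' lies outside it. Unmappable aspects are absent (NA), never errors.
#'
#' @param vstart,vend internal variant span (insertion: vstart = vend + 1).
#' @param tx a \linkS4class{TranscriptModel}.
#' @param store an \linkS4class{AnnotationStore} (memoizes the projection maps).
#' @return list with cdna_start/cdna_end, cds_start/cds_end,
#'   protein_start/protein_end, exon_idx, intron_idx, distance, and region
#'   flags used by the predicate gates.
#' @export
mapToTranscript <- function(vstart, vend, tx, store = NULL) {
  map <- txMap(tx, store)
  isIns <- vstart == vend + 1L
  lo <- min(vstart, vend); hi <- max(vstart, vend)
  out <- list(cdna_start = NA_integer_, cdna_end = NA_integer_,
              cds_start = NA_integer_, cds_end = NA_integer_,
              protein_start = NA_integer_, protein_end = NA_integer_,
              exon_idx = integer(0), intron_idx = integer(0),
              distance = NA_integer_, side = NA_character_,
              within = FALSE, whollyIntronic = FALSE, overlapsExon = FALSE,
              overlapsIntron = FALSE, overlapsCds = FALSE,
              inUtr5 = FALSE, inUtr3 = FALSE, isIns = isIns, map = map)
  # outside the transcript: distance only
  if (!(map$txStart <= vend && vstart <= map$txEnd)) {
    if (hi < map$txStart) {
      out$distance <- map$txStart - hi
      out$side <- if (tx@strand > 0L) "upstream" else "downstream"
    } else {
      out$distance <- lo - map$txEnd
      out$side <- if (tx@strand > 0L) "downstream" else "upstream"
    }
    return(out)
  }
  out$within <- TRUE
  n <- map$nExons
  # exon/intron indices in transcript order
  exHit <- which(map$exSo <= hi & lo <= map$exEo)
  if (isIns)  # strict interiority for the insertion point
    exHit <- which(map$exSo <= vend & vstart <= map$exEo)
  out$exon_idx <- exHit
  if (length(map$introns)) {
    inS <- IRanges::start(map$introns); inE <- IRanges::end(map$introns)
    # intron records are in genomic order; convert to transcript order
    gOrder <- if (tx@strand > 0L) seq_along(inS) else rev(seq_along(inS))
    if (isIns) inHit <- which(inS <= vend & vstart <= inE)
    else inHit <- which(inS <= hi & lo <= inE)
    out$intron_idx <- sort(match(inHit, gOrder))
  }
  out$overlapsExon <- length(out$exon_idx) > 0L
  out$overlapsIntron <- length(out$intron_idx) > 0L
  out$whollyIntronic <- !out$overlapsExon && out$overlapsIntron
  if (isIns && !out$overlapsExon && !out$overlapsIntron) {
    # insertion point at the transcript edge handled as outside by overlap
    # search; if reached, treat as intron-adjacent
    out$whollyIntronic <- TRUE
  }
  if (out$overlapsExon) {
    # cDNA positions of the exonic bases at the span edges
    exonicBases <- integer(0)
    for (i in out$exon_idx) {
      a <- max(lo, map$exSo[i]); b <- min(hi, map$exEo[i])
      exonicBases <- c(exonicBases, map$g2c(a), map$g2c(b))
    }
    if (isIns) {
      cb <- c(map$g2c(vend), map$g2c(vstart))
      exonicBases <- cb[!is.na(cb)]
    }
    out$cdna_start <- min(exonicBases); out$cdna_end <- max(exonicBases)
    if (!is.na(map$cdsCdnaStart)) {
      cs <- max(out$cdna_start, map$cdsCdnaStart)
      ce <- min(out$cdna_end, map$cdsCdnaEnd)
      if (isIns) {
        # an insertion is inside the CDS only when both neighbours are
        out$overlapsCds <- out$cdna_start >= map$cdsCdnaStart &&
          out$cdna_end <= map$cdsCdnaEnd && out$cdna_end > out$cdna_start
      } else {
        out$overlapsCds <- cs <= ce
      }
      if (out$overlapsCds) {
        out$cds_start <- cs - map$cdsCdnaStart + 1L
        out$cds_end <- ce - map$cdsCdnaStart + 1L
        out$protein_start <- (out$cds_start + 2L) %/% 3L
        out$protein_end <- (out$cds_end + 2L) %/% 3L
      }
      out$inUtr5 <- out$cdna_start < map$cdsCdnaStart
      out$inUtr3 <- out$cdna_end > map$cdsCdnaEnd
    }
  }
  out
}

# Splice windows in genomic coordinates for one transcript: donor = first two
# intronic bases, acceptor = last two (transcript orientation); splice region
# = exonic bases 1-3 from a junction or intronic bases 3-8.
spliceWindows <- function(tx, map) {
  don <- list(); acc <- list(); reg <- list()
  if (!length(map$introns)) return(list(donor = don, acceptor = acc, region = reg))
  inS <- IRanges::start(map$introns); inE <- IRanges::end(map$introns)
  for (j in seq_along(inS)) {
    s <- inS[j]; e <- inE[j]
    if (tx@strand > 0L) {
      don <- c(don, list(c(s, min(s + 1L, e))))
      acc <- c(acc, list(c(max(e - 1L, s), e)))
      reg <- c(reg, list(c(s + 2L, min(s + 7L, e))),   # intronic 3-8 donor side
                    list(c(max(e - 7L, s), e - 2L)),   # intronic 3-8 acceptor side
                    list(c(s - 3L, s - 1L)),           # exonic 1-3 before donor
                    list(c(e + 1L, e + 3L)))           # exonic 1-3 after acceptor
    } else {
      don <- c(don, list(c(max(e - 1L, s), e)))
      acc <- c(acc, list(c(s, min(s + 1L, e))))
      reg <- c(reg, list(c(max(s, e - 7L), e - 2L)),
                    list(c(s + 2L, min(s + 7L, e))),
                    list(c(e + 1L, e + 3L)),
                    list(c(s - 3L, s - 1L)))
    }
  }
  reg <- Filter(function(w) w[1L] <= w[2L], reg)
  list(donor = don, acceptor = acc, region = reg)
}

spanHitsWindow <- function(lo, hi, isIns, vstart, vend, windows) {
  if (isIns) { a <- vend; b <- vstart } else { a <- lo; b <- hi }
  for (w in windows) if (w[1L] <= b && a <= w[2L]) return(TRUE)
  FALSE
}

spanWithinWindow <- function(lo, hi, isIns, windows) {
  for (w in windows) {
    if (isIns) { if (lo >= w[1L] - 1L && hi <= w[2L]) return(TRUE) }
    else if (lo >= w[1L] && hi <= w[2L]) return(TRUE)
  }
  FALSE
}

# ---- allele context --------------------------------------------------------

# Build the per-allele evaluation context for one (variant allele, transcript)
# pair: classification of the allele type plus the coordinate bundle and, when
# the allele touches the CDS of a coding transcript, the codon change.
alleleContext <- function(row, alt, tx, store, flank = DEFAULT_FLANK) {
  vstart <- row$start; vend <- row$end
  ref <- row$ref
  bundle <- mapToTranscript(vstart, vend, tx, store)
  map <- bundle$map
  lo <- min(vstart, vend); hi <- max(vstart, vend)
  isIns <- ref == "-"
  isDel <- alt == "-" && ref != "-"
  isSub <- !isIns && !isDel && nchar(ref) == nchar(alt)
  isComplex <- !isIns && !isDel && !isSub
  ctx <- list(tx = tx, map = map, bundle = bundle, flank = flank,
              vstart = vstart, vend = vend, lo = lo, hi = hi,
              ref = ref, alt = alt, isIns = isIns, isDel = isDel,
              isSub = isSub, isComplex = isComplex,
              coding = !is.na(tx@cds_start),
              lenDiff = (if (alt == "-") 0L else nchar(alt)) -
                        (if (ref == "-") 0L else nchar(ref)))
  sw <- spliceWindows(tx, map)
  ctx$donorHit <- bundle$within &&
    spanHitsWindow(lo, hi, isIns, vstart, vend, sw$donor)
  ctx$acceptorHit <- bundle$within &&
    spanHitsWindow(lo, hi, isIns, vstart, vend, sw$acceptor)
  ctx$spliceRegionHit <- bundle$within &&
    spanHitsWindow(lo, hi, isIns, vstart, vend, sw$region)
  ctx$withinSpliceSite <- bundle$within &&
    spanWithinWindow(lo, hi, isIns, c(sw$donor, sw$acceptor))
  ctx$codon <- NULL
  if (ctx$coding && bundle$overlapsCds && isSub &&
      length(bundle$exon_idx) == 1L && hi - lo + 1L == nchar(ref)) {
    ctx$codon <- codonChange(ctx, store)
  }
  ctx
}

# Codon-level change for an exonic substitution fully inside one exon.
codonChange <- function(ctx, store) {
  tx <- ctx$tx; map <- ctx$map; b <- ctx$bundle
  cds <- cdsSequence(tx, store)
  refT <- if (tx@strand > 0L) ctx$ref else revcompStr(ctx$ref)
  altT <- if (tx@strand > 0L) ctx$alt else revcompStr(ctx$alt)
  cs <- b$cds_start; ce <- b$cds_end
  # clip the allele to the CDS portion (substitution may start in UTR)
  cdnaS <- b$cdna_start; cdnaE <- b$cdna_end
  clipL <- (map$cdsCdnaStart + cs - 1L) - cdnaS
  if (clipL > 0L) { refT <- substr(refT, clipL + 1L, nchar(refT))
                    altT <- substr(altT, clipL + 1L, nchar(altT)) }
  keep <- ce - cs + 1L
  refT <- substr(refT, 1L, keep); altT <- substr(altT, 1L, keep)
  c1 <- (cs + 2L) %/% 3L; c2 <- (ce + 2L) %/% 3L
  nCds <- nchar(cds)
  lastFull <- nCds %/% 3L
  incomplete <- (nCds %% 3L) != 0L
  hitsIncomplete <- incomplete && ce > lastFull * 3L
  cFrom <- (c1 - 1L) * 3L + 1L
  cTo <- min(c2 * 3L, nCds)
  refCodons <- substr(cds, cFrom, cTo)
  offset <- cs - cFrom
  altCodons <- paste0(substr(refCodons, 1L, offset),
                      altT,
                      substr(refCodons, offset + nchar(altT) + 1L, nchar(refCodons)))
  tbl <- if (isMitoChrom(store, tx@chrom)) "mito" else "standard"
  seleno <- tx@attrs$seleno %||% integer(0)
  selLocal <- seleno - c1 + 1L
  refAA <- altAA <- NA_character_
  if (nchar(refCodons) %% 3L == 0L && nchar(refCodons) >= 3L) {
    refAA <- as.character(translateCds(refCodons, tbl, selLocal))
    altAA <- as.character(translateCds(altCodons, tbl, selLocal))
  }
  # display convention: changed bases upper-case in lower-case codon context
  disp <- function(codons, allele) {
    low <- tolower(codons)
    paste0(substr(low, 1L, offset), toupper(allele),
           substr(low, offset + nchar(allele) + 1L, nchar(low)))
  }
  list(c1 = c1, c2 = c2, ref_codons = refCodons, alt_codons = altCodons,
       ref_codons_disp = disp(refCodons, refT), alt_codons_disp = disp(altCodons, altT),
       ref_aa = refAA, alt_aa = altAA, startCodon = c1 == 1L,
       hitsIncomplete = hitsIncomplete,
       changed = !identical(refT, altT))
}

# ---- predicates ------------------------------------------------------------

# Each predicate is total (safe on any context); `gate` names the
# pre-predicate check that may skip it. One predicate per consequence class.
transcriptPredicates <- function() {
  list(
    upstream_gene_variant = list(gate = "outside", fn = function(ctx)
      !ctx$bundle$within && identical(ctx$bundle$side, "upstream") &&
        !is.na(ctx$bundle$distance) && ctx$bundle$distance <= ctx$flank),
    downstream_gene_variant = list(gate = "outside", fn = function(ctx)
      !ctx$bundle$within && identical(ctx$bundle$side, "downstream") &&
        !is.na(ctx$bundle$distance) && ctx$bundle$distance <= ctx$flank),
    splice_donor_variant = list(gate = "splice", fn = function(ctx) ctx$donorHit),
    splice_acceptor_variant = list(gate = "splice", fn = function(ctx) ctx$acceptorHit),
    splice_region_variant = list(gate = "splice", fn = function(ctx)
      ctx$spliceRegionHit && !ctx$withinSpliceSite),
    intron_variant = list(gate = "intron", fn = function(ctx)
      ctx$bundle$overlapsIntron && !ctx$withinSpliceSite),
    `5_prime_UTR_variant` = list(gate = "utr", fn = function(ctx)
      ctx$coding && ctx$bundle$inUtr5),
    `3_prime_UTR_variant` = list(gate = "utr", fn = function(ctx)
      ctx$coding && ctx$bundle$inUtr3),
    synonymous_variant = list(gate = "coding", fn = function(ctx) {
      cd <- ctx$codon
      !is.null(cd) && cd$changed && !is.na(cd$ref_aa) &&
        identical(cd$ref_aa, cd$alt_aa) && !grepl("*", cd$ref_aa, fixed = TRUE) &&
        !cd$startCodon
    }),
    stop_retained_variant = list(gate = "coding", fn = function(ctx) {
      cd <- ctx$codon
      !is.null(cd) && cd$changed && !is.na(cd$ref_aa) &&
        identical(cd$ref_aa, cd$alt_aa) && grepl("*", cd$ref_aa, fixed = TRUE)
    }),
    missense_variant = list(gate = "coding", fn = function(ctx) {
      cd <- ctx$codon
      if (is.null(cd) || !cd$changed || is.na(cd$ref_aa)) return(FALSE)
      if (cd$startCodon) return(FALSE)
      if (identical(cd$ref_aa, cd$alt_aa)) return(FALSE)
      ra <- strsplit(cd$ref_aa, "")[[1L]]; aa <- strsplit(cd$alt_aa, "")[[1L]]
      if (length(ra) != length(aa)) return(FALSE)
      !any(aa == "*" & ra != "*") && !any(ra == "*" & aa != "*")
    }),
    stop_gained = list(gate = "coding", fn = function(ctx) {
      cd <- ctx$codon
      if (is.null(cd) || !cd$changed || is.na(cd$ref_aa)) return(FALSE)
      ra <- strsplit(cd$ref_aa, "")[[1L]]; aa <- strsplit(cd$alt_aa, "")[[1L]]
      length(ra) == length(aa) && any(aa == "*" & ra != "*")
    }),
    stop_lost = list(gate = "coding", fn = function(ctx) {
      cd <- ctx$codon
      if (is.null(cd) || !cd$changed || is.na(cd$ref_aa)) return(FALSE)
      ra <- strsplit(cd$ref_aa, "")[[1L]]; aa <- strsplit(cd$alt_aa, "")[[1L]]
      length(ra) == length(aa) && any(ra == "*" & aa != "*")
    }),
    start_lost = list(gate = "coding", fn = function(ctx) {
      cd <- ctx$codon
      !is.null(cd) && cd$changed && cd$startCodon
    }),
    incomplete_terminal_codon_variant = list(gate = "coding", fn = function(ctx) {
      cd <- ctx$codon
      !is.null(cd) && cd$changed && cd$hitsIncomplete
    }),
    frameshift_variant = list(gate = "coding", fn = function(ctx) {
      if (!ctx$bundle$overlapsCds || ctx$isSub) return(FALSE)
      codingChangeLen(ctx) %% 3L != 0L
    }),
    inframe_insertion = list(gate = "coding", fn = function(ctx) {
      ctx$isIns && ctx$bundle$overlapsCds && nchar(ctx$alt) %% 3L == 0L
    }),
    inframe_deletion = list(gate = "coding", fn = function(ctx) {
      if (!ctx$isDel || !ctx$bundle$overlapsCds) return(FALSE)
      dl <- codingChangeLen(ctx)
      dl > 0L && dl %% 3L == 0L
    }),
    non_coding_transcript_variant = list(gate = "noncoding", fn = function(ctx)
      !ctx$coding && ctx$bundle$within),
    non_coding_transcript_exon_variant = list(gate = "noncoding", fn = function(ctx)
      !ctx$coding && ctx$bundle$overlapsExon),
    mature_miRNA_variant = list(gate = "noncoding", fn = function(ctx) {
      m <- ctx$tx@attrs$mature
      identical(ctx$tx@biotype, "miRNA") && !is.null(m) &&
        ctx$bundle$overlapsExon &&
        m[1L] <= ctx$hi && ctx$lo <= m[2L]
    })
  )
}

# Coding-bases length of an indel change: inserted length for insertions
# (insertions inside the CDS only), deleted CDS-exonic bases for deletions.
codingChangeLen <- function(ctx) {
  if (ctx$isIns) return(nchar(ctx$alt))
  b <- ctx$bundle
  if (is.na(b$cds_start)) return(0L)
  del <- b$cds_end - b$cds_start + 1L
  if (!ctx$isDel) abs(ctx$lenDiff) else del
}

# Pre-predicate gates: cheap location checks that let whole predicate groups
# be skipped. With gates disabled every predicate is evaluated; results are
# identical because predicates are total.
gateSkips <- function(ctx, gate) {
  b <- ctx$bundle
  switch(gate,
    outside = b$within,                            # flank terms: skip if inside
    splice = !b$within || ctx$map$nExons == 1L,    # no introns, nothing to hit
    intron = !b$within || ctx$map$nExons == 1L,
    utr = !b$within || b$whollyIntronic || !ctx$coding,
    coding = !b$within || b$whollyIntronic || !ctx$coding || !b$overlapsCds,
    noncoding = !b$within || ctx$coding,
    FALSE)
}

#' Assign consequence terms to one (variant allele, feature) pair
#'
#' Runs the predicate suite subject to pre-predicate gates (e.g. coding
#' predicates are skipped for wholly intronic spans); every skipped predicate
#' increments the skip counter in \code{stats}. Multiple terms may co-exist
#' (a splice-region variant can also change the coding sequence); the final
#' set keeps only the most specific term under any parent chain.
#'
#' @param row one-row variant data.frame; \code{alt} a single allele string.
#' @param feature a transcript, regulatory or motif feature, or NULL for
#'   intergenic.
#' @param store an \linkS4class{AnnotationStore}.
#' @param registry a \linkS4class{ConsequenceRegistry}.
#' @param stats optional \linkS4class{RunStatistics}.
#' @param gates set FALSE to disable pre-predicate checks (identical results,
#'   more evaluations).
#' @param flank transcript flank in bp.
#' @return list(terms=, context=) where context carries the coordinate bundle
#'   and codon change for downstream HGVS/output stages.
#' @export
assignConsequences <- function(row, alt, feature, store, registry,
                               stats = NULL, gates = TRUE,
                               flank = DEFAULT_FLANK) {
  if (is.null(feature)) {
    return(list(terms = "intergenic_variant", context = NULL))
  }
  if (is(feature, "RegulatoryFeature")) {
    return(list(terms = "regulatory_region_variant", context = NULL))
  }
  if (is(feature, "MotifFeature")) {
    return(list(terms = "TF_binding_site_variant", context = NULL))
  }
  ctx <- alleleContext(row, alt, feature, store, flank)
  preds <- transcriptPredicates()
  terms <- character(0)
  for (nm in names(preds)) {
    p <- preds[[nm]]
    if (gates && gateSkips(ctx, p$gate)) {
      if (!is.null(stats)) statAdd(stats, "predicate_evaluations_skipped")
      next
    }
    if (!is.null(stats)) statAdd(stats, "predicate_evaluations")
    if (isTRUE(p$fn(ctx))) terms <- c(terms, nm)
  }
  # fallback when the CDS is touched but no specific coding prediction fired
  codingBranch <- c("synonymous_variant", "stop_retained_variant",
                    "missense_variant", "stop_gained", "stop_lost",
                    "start_lost", "incomplete_terminal_codon_variant",
                    "frameshift_variant", "inframe_insertion", "inframe_deletion")
  if (ctx$coding && ctx$bundle$overlapsCds && !any(terms %in% codingBranch))
    terms <- c(terms, "coding_sequence_variant")
  terms <- mostSpecificTerms(terms, registry)
  list(terms = terms, context = ctx)
}

nPredicates <- function() length(transcriptPredicates())

# ---- structural variants ---------------------------------------------------

#' Consequence terms for a structural variant against one feature
#'
#' Deletions fully containing a transcript ablate it; partial overlaps
#' truncate (plus \code{coding_sequence_variant} when the CDS is touched).
#' Duplications amplify when containing and elongate when partial. Regulatory
#' and motif features take the analogous regulatory_region_/TFBS_ terms.
#' Copy-number variants follow the duplication rules; large insertions
#' elongate. Overlap restricted to the flank yields upstream/downstream.
#'
#' @export
assignSvConsequences <- function(row, feature, flank = DEFAULT_FLANK) {
  stopifnot(row$is_structural)
  lo <- row$start; hi <- row$end
  if (is.null(feature)) return("intergenic_variant")
  sp <- featureSpan(feature)
  if (!(sp[1L] <= hi && lo <= sp[2L])) {
    if (is(feature, "TranscriptModel")) {
      strand <- feature@strand
      if (hi < sp[1L]) return(if (strand > 0L) "upstream_gene_variant" else "downstream_gene_variant")
      return(if (strand > 0L) "downstream_gene_variant" else "upstream_gene_variant")
    }
    return(character(0))
  }
  contains <- lo <= sp[1L] && hi >= sp[2L]
  svt <- row$sv_type
  isTx <- is(feature, "TranscriptModel")
  isReg <- is(feature, "RegulatoryFeature")
  isMot <- is(feature, "MotifFeature")
  if (svt == "DEL") {
    if (contains) {
      if (isTx) return("transcript_ablation")
      if (isReg) return("regulatory_region_ablation")
      if (isMot) return("TFBS_ablation")
    }
    terms <- "feature_truncation"
    if (isTx && !is.na(feature@cds_start) &&
        feature@cds_start <= hi && lo <= feature@cds_end)
      terms <- c(terms, "coding_sequence_variant")
    return(terms)
  }
  if (svt %in% c("DUP", "CNV", "INS")) {
    if (contains && svt != "INS") {
      if (isTx) return("transcript_amplification")
      if (isReg) return("regulatory_region_amplification")
      if (isMot) return("TFBS_amplification")
    }
    return("feature_elongation")
  }
  "feature_elongation"
}
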