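# Naive first-principles annotator used as the test oracle. It deliberately
# ignores the engine's pre-predicate gates, coordinate-bundle machinery and
# sequence caches: consequences are recomputed each call by splicing the full
# cDNA, applying the edit, re-translating, and checking junction windows
# positionally, so it cannot share bugs with the engine's fast paths.

#' Consequence terms from first principles (test oracle)
#'
#' @param row one-row variant data.frame (internal representation,
#'   non-structural).
#' @param alt single alternative allele.
#' @param tx a \linkS4class{TranscriptModel}.
#' @param genome named list of chromosome sequences (plain strings).
#' @param flank transcript flank in bp.
#' @param mito_chroms chromosome names using the vertebrate mitochondrial code.
#' @return character vector of consequence terms (alphabetical), or empty when
#'   the variant is beyond the flank.
#' @export
naiveAnnotate <- function(row, alt, tx, genome, flank = 5000L,
                          mito_chroms = DEFAULT_MITO_CHROMS) {
  stopifnot(!row$is_structural)
  exS <- IRanges::start(tx@exons); exE <- IRanges::end(tx@exons)
  s <- min(exS); e <- max(exE)
  vs <- row$start; ve <- row$end
  lo <- min(vs, ve); hi <- max(vs, ve)
  isIns <- vs == ve + 1L
  if (!(s - flank <= ve && vs <= e + flank)) return(character(0))
  # outside the transcript: flank status
  if (!(s <= ve && vs <= e)) {
    if (hi < s) {
      return(if (tx@strand > 0L) "upstream_gene_variant" else "downstream_gene_variant")
    }
    return(if (tx@strand > 0L) "downstream_gene_variant" else "upstream_gene_variant")
  }
  terms <- character(0)
  n <- length(exS)
  # positional splice windows, rebuilt from scratch
  donors <- list(); acceptors <- list(); regions <- list()
  if (n > 1L) for (j in seq_len(n - 1L)) {
    iS <- exE[j] + 1L; iE <- exS[j + 1L] - 1L
    if (tx@strand > 0L) {
      donors <- c(donors, list(c(iS, min(iS + 1L, iE))))
      acceptors <- c(acceptors, list(c(max(iE - 1L, iS), iE)))
      regions <- c(regions, list(c(iS + 2L, min(iS + 7L, iE))),
                   list(c(max(iE - 7L, iS), iE - 2L)),
                   list(c(iS - 3L, iS - 1L)), list(c(iE + 1L, iE + 3L)))
    } else {
      donors <- c(donors, list(c(max(iE - 1L, iS), iE)))
      acceptors <- c(acceptors, list(c(iS, min(iS + 1L, iE))))
      regions <- c(regions, list(c(max(iS, iE - 7L), iE - 2L)),
                   list(c(iS + 2L, min(iS + 7L, iE))),
                   list(c(iE + 1L, iE + 3L)), list(c(iS - 3L, iS - 1L)))
    }
  }
  regions <- Filter(function(w) w[1L] <= w[2L], regions)
  hits <- function(ws) {
    a <- if (isIns) ve else lo; b <- if (isIns) vs else hi
    any(vapply(ws, function(w) w[1L] <= b && a <= w[2L], logical(1)))
  }
  within <- function(ws) {
    any(vapply(ws, function(w)
      if (isIns) lo >= w[1L] - 1L && hi <= w[2L] else lo >= w[1L] && hi <= w[2L],
      logical(1)))
  }
  donorHit <- hits(donors); acceptorHit <- hits(acceptors)
  regionHit <- hits(regions)
  inSite <- within(c(donors, acceptors))
  if (donorHit) terms <- c(terms, "splice_donor_variant")
  if (acceptorHit) terms <- c(terms, "splice_acceptor_variant")
  if (regionHit && !inSite) terms <- c(terms, "splice_region_variant")
  # exon / intron overlap, positional
  exOv <- if (isIns) any(exS <= ve & vs <= exE) else any(exS <= hi & lo <= exE)
  intOv <- FALSE
  if (n > 1L) for (j in seq_len(n - 1L)) {
    iS <- exE[j] + 1L; iE <- exS[j + 1L] - 1L
    o <- if (isIns) (iS <= ve && vs <= iE) else (iS <= hi && lo <= iE)
    if (o) intOv <- TRUE
  }
  if (intOv && !inSite) terms <- c(terms, "intron_variant")

  coding <- !is.na(tx@cds_start)
  if (!coding) {
    if (exOv) {
      mat <- tx@attrs$mature
      if (identical(tx@biotype, "miRNA") && !is.null(mat) &&
          mat[1L] <= hi && lo <= mat[2L])
        terms <- c(terms, "mature_miRNA_variant")
      else
        terms <- c(terms, "non_coding_transcript_exon_variant")
    } else {
      terms <- c(terms, "non_coding_transcript_variant")
    }
    return(sort(unique(terms)))
  }
  if (!exOv) return(sort(unique(terms)))

  # cDNA position by naive exon walking
  gseq <- genome[[tx@chrom]]
  ord <- if (tx@strand > 0L) seq_len(n) else rev(seq_len(n))
  pieces <- substring(gseq, exS, exE)
  cdna <- if (tx@strand > 0L) paste(pieces, collapse = "")
          else revcompStr(paste(pieces, collapse = ""))
  gToC <- function(g) {
    acc <- 0L
    for (j in ord) {
      if (g >= exS[j] && g <= exE[j]) {
        off <- if (tx@strand > 0L) g - exS[j] else exE[j] - g
        return(acc + off + 1L)
      }
      acc <- acc + (exE[j] - exS[j] + 1L)
    }
    NA_integer_
  }
  cA <- gToC(tx@cds_start); cB <- gToC(tx@cds_end)
  c0 <- min(cA, cB); c1 <- max(cA, cB)
  # cDNA coordinates of the exonic bases of the span
  spanBases <- if (isIns) c(ve, vs) else lo:hi
  cPos <- sort(stats::na.omit(vapply(spanBases, gToC, integer(1))))
  if (!length(cPos)) return(sort(unique(terms)))
  if (any(cPos < c0)) terms <- c(terms, "5_prime_UTR_variant")
  if (any(cPos > c1)) terms <- c(terms, "3_prime_UTR_variant")
  inCds <- cPos[cPos >= c0 & cPos <= c1]
  cdsOv <- if (isIns) length(inCds) == 2L && diff(range(inCds)) >= 1L
           else length(inCds) > 0L
  if (!cdsOv) return(sort(unique(terms)))

  mito <- tx@chrom %in% mito_chroms
  code <- if (mito) Biostrings::getGeneticCode("2") else Biostrings::GENETIC_CODE
  naiveTranslate <- function(x) {
    if (nchar(x) < 3L) return("")
    x <- substr(x, 1L, (nchar(x) %/% 3L) * 3L)
    p <- as.character(Biostrings::translate(Biostrings::DNAString(x),
                                            genetic.code = code))
    sel <- tx@attrs$seleno %||% integer(0)
    for (k in sel) {
      if (3L * k <= nchar(x) && substr(x, 3L * k - 2L, 3L * k) == "TGA")
        substr(p, k, k) <- "U"
    }
    p
  }
  refCds <- substr(cdna, c0, c1)
  cdsLen <- nchar(refCds)
  if (row$ref != "-" && alt != "-" && nchar(row$ref) == nchar(alt)) {
    # substitution: rebuild and re-translate the mutant cDNA
    altT <- if (tx@strand > 0L) alt else revcompStr(alt)
    cs <- min(cPos); ce <- max(cPos)
    mut <- paste0(substr(cdna, 1L, cs - 1L), altT,
                  substr(cdna, ce + 1L, nchar(cdna)))
    mutCds <- substr(mut, c0, c1)
    kA <- (min(inCds) - c0) %/% 3L + 1L
    kB <- (max(inCds) - c0) %/% 3L + 1L
    lastFull <- cdsLen %/% 3L
    if ((cdsLen %% 3L) != 0L && kB > lastFull) {
      if (!identical(refCds, mutCds))
        terms <- c(terms, "incomplete_terminal_codon_variant")
      return(sort(unique(terms)))
    }
    refP <- naiveTranslate(refCds); mutP <- naiveTranslate(mutCds)
    if (identical(substr(refCds, 1L, 3L), substr(mutCds, 1L, 3L)) == FALSE && kA == 1L) {
      terms <- c(terms, "start_lost")
    } else if (!identical(refCds, mutCds)) {
      ra <- substring(refP, kA:kB, kA:kB)
      aa <- substring(mutP, kA:kB, kA:kB)
      if (identical(ra, aa)) {
        terms <- c(terms, if (any(ra == "*")) "stop_retained_variant"
                          else "synonymous_variant")
      } else {
        if (any(aa == "*" & ra != "*")) terms <- c(terms, "stop_gained")
        if (any(ra == "*" & aa != "*")) terms <- c(terms, "stop_lost")
        if (!any(aa == "*" & ra != "*") && !any(ra == "*" & aa != "*"))
          terms <- c(terms, "missense_variant")
      }
    }
    return(sort(unique(terms)))
  }
  if (alt == "-") {             # deletion: count deleted coding bases
    del <- length(inCds)
    terms <- c(terms, if (del %% 3L != 0L) "frameshift_variant"
                      else "inframe_deletion")
    return(sort(unique(terms)))
  }
  if (row$ref == "-") {         # insertion between two CDS bases
    L <- nchar(alt)
    terms <- c(terms, if (L %% 3L != 0L) "frameshift_variant"
                      else "inframe_insertion")
    return(sort(unique(terms)))
  }
  c(sort(unique(c(terms, "coding_sequence_variant"))))
}
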