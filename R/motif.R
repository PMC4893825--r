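# Motif / regulatory annotation: PWM score change and informative-position
# flag for variants falling in transcription factor binding motifs.

#' Relative PWM score of a sequence
#'
#' Min-max normalised log-probability score
#' \eqn{(\sum \log p - \sum \log p_{min}) / (\sum \log p_{max} - \sum \log p_{min})}
#' over the motif columns, so the consensus sequence scores 1 and the
#' anti-consensus 0. PWM columns are probabilities with pseudocount 1e-2
#' applied at parse time. N scores as the uniform background (0.25).
#'
#' @param seq sequence of exactly the PWM width (A/C/G/T/N).
#' @param pwm 4 x width probability matrix with rows A, C, G, T.
#' @return score in [0, 1].
#' @export
scoreMotif <- function(seq, pwm) {
  w <- ncol(pwm)
  if (nchar(seq) != w) stop("sequence length does not match PWM width")
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  lp <- 0
  for (i in seq_len(w)) {
    p <- if (bases[i] == "N") 0.25 else pwm[bases[i], i]
    lp <- lp + log(p)
  }
  lmin <- sum(log(apply(pwm, 2L, min)))
  lmax <- sum(log(apply(pwm, 2L, max)))
  # clamp: floating-point noise must not push scores outside [0, 1]
  min(max(unname((lp - lmin) / (lmax - lmin)), 0), 1)
}

# Information content (bits) of one PWM column, max 2.
columnIC <- function(col) 2 + sum(col * log2(col))

#' Motif impact of a variant allele
#'
#' Reference and alternative motif sequences are built in the motif's strand
#' orientation; the score delta reflects how the allele moves the site towards
#' or away from the consensus. A position is informative when the occupied
#' column's information content is at least 1 bit (of a 2-bit maximum).
#' Indels report the overlap without scores.
#'
#' @param row one-row variant data.frame; \code{alt} one allele.
#' @param motif a \linkS4class{MotifFeature}.
#' @param store an \linkS4class{AnnotationStore}.
#' @return list(motif_position, ref_score, alt_score, delta, informative).
#' @export
motifConsequence <- function(row, alt, motif, store) {
  gseq <- chromSeq(store, motif@chrom)
  refSite <- substr(gseq, motif@start, motif@end)
  w <- ncol(motif@pwm)
  out <- list(motif_position = NA_integer_, ref_score = NA_real_,
              alt_score = NA_real_, delta = NA_real_, informative = NA)
  isSub <- row$ref != "-" && alt != "-" && nchar(row$ref) == nchar(alt)
  # strand-aware 1-based position of the variant start within the motif
  gpos <- max(row$start, motif@start)
  pos <- if (motif@strand > 0L) gpos - motif@start + 1L
         else motif@end - min(row$end, motif@end) + 1L
  out$motif_position <- pos
  if (!isSub) return(out)
  # substitute the overlapping bases on the genomic forward strand
  lo <- max(row$start, motif@start); hi <- min(row$end, motif@end)
  offA <- lo - row$start + 1L; offB <- hi - row$start + 1L
  altSite <- paste0(
    substr(refSite, 1L, lo - motif@start),
    substr(alt, offA, offB),
    substr(refSite, hi - motif@start + 2L, nchar(refSite)))
  refOrient <- if (motif@strand > 0L) refSite else revcompStr(refSite)
  altOrient <- if (motif@strand > 0L) altSite else revcompStr(altSite)
  out$ref_score <- scoreMotif(refOrient, motif@pwm)
  out$alt_score <- scoreMotif(altOrient, motif@pwm)
  out$delta <- out$alt_score - out$ref_score
  col <- motif@pwm[, min(max(pos, 1L), w)]
  out$informative <- columnIC(col) >= 1.0
  out
}

#' Restrict regulatory features to a cell-type list
#'
#' Keeps features whose cell_types intersect \code{cell_types}; features
#' without cell-type annotation are kept.
#' @export
filterCellTypes <- function(features, cell_types = NULL) {
  if (is.null(cell_types)) return(features)
  Filter(function(f) length(f@cell_types) == 0L ||
           any(f@cell_types %in% cell_types), features)
}
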