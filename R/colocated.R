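# Co-located known variants and user-supplied custom tracks.

#' Find known variants co-located with an input variant
#'
#' Matches records at identical chrom/start/end with an allele-compatibility
#' check (shared reference and at least one shared alternative allele after
#' minimisation). Position-only matches are reported with
#' \code{allele_mismatch = TRUE}.
#'
#' @param row one-row variant data.frame.
#' @param store an \linkS4class{AnnotationStore} with a known-variant track.
#' @return list of known-variant records (id, alleles, gmaf, pop_freqs,
#'   clin_sig, somatic, pubmed_ids, allele_mismatch).
#' @export
findColocated <- function(row, store) {
  kvs <- knownAt(store, row$chrom, row$start)
  out <- list()
  for (kv in kvs) {
    if (kv$start != row$start || kv$end != row$end) next
    mref <- minimiseAlleles(row$start, row$ref, row$ref)  # no-op guard
    sharedRef <- identical(kv$ref, row$ref)
    sharedAlt <- FALSE
    for (a in row$alt[[1L]]) for (b in kv$alt) {
      ma <- minimiseAlleles(row$start, row$ref, a)
      mb <- minimiseAlleles(kv$start, kv$ref, b)
      if (identical(ma$ref, mb$ref) && identical(ma$alt, mb$alt) &&
          ma$start == mb$start) sharedAlt <- TRUE
    }
    kv$allele_mismatch <- !(sharedRef && sharedAlt)
    out <- c(out, list(kv))
  }
  out
}

#' Drop results of variants co-located with common known variants
#'
#' Removes every result row of a variant for which any co-located record has
#' a global minor allele frequency strictly greater than \code{threshold}
#' (default 1\%).
#'
#' @param results annotation results data.frame.
#' @param colocated list indexed by variant_index, as produced during
#'   annotation (each element a list of known-variant records).
#' @param threshold frequency cut-off in [0, 1].
#' @export
filterCommon <- function(results, colocated, threshold = 0.01) {
  if (nrow(results) == 0L) return(results)
  common <- vapply(seq_along(colocated), function(i) {
    any(vapply(colocated[[i]], function(kv)
      !is.na(kv$gmaf) && kv$gmaf > threshold, logical(1)))
  }, logical(1))
  commonIdx <- which(common)
  results[!(results$variant_index %in% commonIdx), , drop = FALSE]
}

# ---- custom tracks ---------------------------------------------------------

# A track is declared as list(name=, path=, format= "bed"|"gff"|"vcf",
# exact= TRUE/FALSE). Parsed once and cached on the track object environment.
loadTrack <- function(track) {
  if (!is.null(track$data)) return(track)
  fmt <- tolower(track$format)
  if (fmt == "bed") {
    tb <- utils::read.delim(track$path, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    names(tb)[1:3] <- c("chrom", "start0", "end")
    tb$start <- tb$start0 + 1L             # BED is 0-based half-open
    tb$name <- if (ncol(tb) >= 4L) tb[[4L]] else paste0("region", seq_len(nrow(tb)))
    track$data <- tb[, c("chrom", "start", "end", "name")]
  } else if (fmt %in% c("gff", "gff3", "gtf")) {
    gr <- rtracklayer::import(track$path)
    mc <- S4Vectors::mcols(gr)
    nm <- if ("ID" %in% names(mc)) as.character(mc$ID)
          else if ("Name" %in% names(mc)) as.character(mc$Name)
          else paste0("feature", seq_along(gr))
    track$data <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      name = nm, stringsAsFactors = FALSE)
  } else if (fmt == "vcf") {
    vs <- readVcfVariants(track$path)
    tb <- variantTable(vs)
    track$data <- data.frame(
      chrom = tb$chrom, start = tb$start, end = tb$end,
      name = ifelse(is.na(tb$id), paste0(tb$chrom, ":", tb$start), tb$id),
      ref = tb$ref, stringsAsFactors = FALSE)
    track$alts <- tb$alt
  } else {
    warning("unsupported custom track format: ", track$format)
    track$data <- data.frame(chrom = character(0), start = integer(0),
                             end = integer(0), name = character(0))
  }
  track
}

#' Overlap a variant with user-supplied custom tracks
#'
#' For each overlapping record the track's name accumulates the record's
#' name/ID (BED name, VCF ID, GFF attribute). VCF tracks may require exact
#' allele matching via \code{exact = TRUE}.
#'
#' @param row one-row variant data.frame; \code{tracks} a list of loaded
#'   track declarations.
#' @return named list of character vectors, one entry per matched track.
#' @export
customOverlap <- function(row, tracks) {
  out <- list()
  for (tr in tracks) {
    tb <- tr$data
    if (is.null(tb) || nrow(tb) == 0L) next
    hit <- which(chromEqual(tb$chrom, row$chrom) &
                   tb$start <= row$end & row$start <= tb$end)
    if (isTRUE(tr$exact) && identical(tolower(tr$format), "vcf") && length(hit)) {
      keep <- logical(length(hit))
      for (k in seq_along(hit)) {
        i <- hit[k]
        keep[k] <- tb$start[i] == row$start && identical(tb$ref[i], row$ref) &&
          any(tr$alts[[i]] %in% row$alt[[1L]])
      }
      hit <- hit[keep]
    }
    if (length(hit)) out[[tr$name]] <- unique(tb$name[hit])
  }
  out
}
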