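#' @include AllClasses.R
NULL

#' Query features overlapping a variant
#' @export
setGeneric("queryOverlaps", function(store, variant, ...) standardGeneric("queryOverlaps"))

#' Spliced cDNA sequence of a transcript
#' @export
setGeneric("splicedSequence", function(transcript, store, ...) standardGeneric("splicedSequence"))

#' Coding sequence of a transcript
#' @export
setGeneric("cdsSequence", function(transcript, store, ...) standardGeneric("cdsSequence"))

#' Feature identifier
#' @export
setGeneric("featureId", function(x) standardGeneric("featureId"))

setMethod("featureId", "TranscriptModel", function(x) x@id)
setMethod("featureId", "RegulatoryFeature", function(x) x@id)
setMethod("featureId", "MotifFeature", function(x) x@id)

#' @export
setGeneric("versionedId", function(x) standardGeneric("versionedId"))
setMethod("versionedId", "TranscriptModel", function(x) paste0(x@id, ".", x@version))

setMethod("length", "VariantSet", function(x) nrow(x@tab))

#' @export
variantTable <- function(x) x@tab

setMethod("[", "VariantSet", function(x, i, j, ..., drop = FALSE) {
  tb <- x@tab[i, , drop = FALSE]
  rownames(tb) <- NULL
  new("VariantSet", tab = tb)
})

setMethod("show", "VariantSet", function(object) {
  cat(sprintf("VariantSet with %d variant(s)\n", nrow(object@tab)))
  if (nrow(object@tab)) {
    tb <- utils::head(object@tab, 5L)
    alt <- vapply(tb$alt, paste, "", collapse = ",")
    cat(sprintf("  %s:%d-%d %s>%s [%s]\n", tb$chrom, tb$start, tb$end,
                tb$ref, alt, tb$sv_type))
    if (nrow(object@tab) > 5L) cat("  ...\n")
  }
})

setMethod("show", "TranscriptModel", function(object) {
  cds <- if (is.na(object@cds_start)) "non-coding"
         else sprintf("CDS %d-%d", object@cds_start, object@cds_end)
  cat(sprintf("TranscriptModel %s.%d (%s) %s:%s strand %+d, %d exon(s), %s\n",
              object@id, object@version, object@biotype, object@chrom,
              paste0(min(IRanges::start(object@exons)), "-",
                     max(IRanges::end(object@exons))),
              object@strand, length(object@exons), cds))
})

setMethod("show", "ConsequenceRegistry", function(object) {
  cat(sprintf("ConsequenceRegistry with %d consequence classes (ranks %d..%d)\n",
              nrow(object@table), min(object@table$rank), max(object@table$rank)))
})

setMethod("show", "AnnotationStore", function(object) {
  m <- object@manifest
  cat(sprintf("AnnotationStore at %s\n  %d transcript(s), %d regulatory, %d motif(s), %d known variant(s)\n",
              object@dir,
              m$counts$transcripts %||% 0L, m$counts$regulatory %||% 0L,
              m$counts$motifs %||% 0L, m$counts$known_variants %||% 0L))
})

setMethod("show", "RunStatistics", function(object) {
  e <- object@env
  cat(sprintf("RunStatistics: n=%d f=%d p=%d evaluated=%d skipped=%d\n",
              e$n, e$f, e$p, e$predicate_evaluations, e$predicate_evaluations_skipped))
})
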