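#' @import methods
#' @importFrom S4Vectors isSingleString
NULL

VALID_SV_TYPES <- c("DEL", "DUP", "INS", "CNV", "none")

#' Set of input variants in internal representation
#'
#' Internal coordinates are 1-based fully closed. Anchor bases of VCF-style
#' indels are stripped at parse time: a deletion keeps only the deleted bases
#' as \code{ref} with \code{alt = "-"}; an insertion has \code{ref = "-"} and
#' uses the convention \code{start = end + 1} so that the insertion point lies
#' between \code{end} and \code{start}. One row per input variant; multiple
#' alternative alleles are kept together as a list column.
#'
#' @slot tab data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{ref}, \code{alt} (list of character vectors), \code{id},
#'   \code{input_index}, \code{is_structural}, \code{sv_type}.
#' @exportClass VariantSet
setClass("VariantSet", representation(tab = "data.frame"))

setValidity("VariantSet", function(object) {
  tb <- object@tab
  need <- c("chrom", "start", "end", "ref", "alt", "id", "input_index",
            "is_structural", "sv_type")
  if (!all(need %in% names(tb)))
    return(paste("missing columns:", paste(setdiff(need, names(tb)), collapse = ", ")))
  if (nrow(tb) == 0L) return(TRUE)
  if (!is.list(tb$alt)) return("alt must be a list column")
  bad <- !tb$sv_type %in% VALID_SV_TYPES
  if (any(bad)) return("sv_type outside {DEL, DUP, INS, CNV, none}")
  ok <- tb$is_structural | tb$ref == "-" |
    (tb$end - tb$start + 1L) == nchar(tb$ref)
  if (any(!ok)) return("end - start + 1 must equal nchar(ref) for sequence variants")
  ins <- !tb$is_structural & tb$ref == "-"
  if (any(ins & tb$start != tb$end + 1L))
    return("insertions must use start = end + 1")
  allelesOk <- vapply(seq_len(nrow(tb)), function(i) {
    a <- c(tb$ref[i], tb$alt[[i]])
    all(a == "-" | grepl("^[ACGTN]+$", a) | tb$is_structural[i])
  }, logical(1))
  if (!all(allelesOk)) return("alleles must be A/C/G/T/N strings or '-'")
  TRUE
})

#' Transcript model
#'
#' Exon structure, CDS bounds, strand and biotype for a single transcript; the
#' unit against which coding consequences are computed. Exons are stored in
#' genomic order as an \code{IRanges}; transcript (5'-to-3') order is the
#' reverse for minus-strand transcripts.
#'
#' @slot id stable identifier (unversioned).
#' @slot version integer version; versioned accession is \code{id.version}.
#' @slot gene_id,gene_symbol gene identifiers.
#' @slot chrom chromosome name.
#' @slot strand integer, +1 or -1.
#' @slot exons IRanges of exons, ascending genomic order, non-overlapping.
#' @slot cds_start,cds_end genomic CDS bounds (NA for non-coding).
#' @slot biotype controlled vocabulary, e.g. \code{protein_coding}, \code{miRNA}.
#' @slot flags character subset of canonical/CCDS/TSL/APPRIS style tags.
#' @slot attrs free-form list (e.g. \code{mature_start}/\code{mature_end} for
#'   miRNA, \code{seleno} codon indices).
#' @exportClass TranscriptModel
setClass("TranscriptModel", representation(
  id = "character", version = "integer", gene_id = "character",
  gene_symbol = "character", chrom = "character", strand = "integer",
  exons = "IRanges", cds_start = "integer", cds_end = "integer",
  biotype = "character", flags = "character", attrs = "list"))

setValidity("TranscriptModel", function(object) {
  ex <- object@exons
  if (length(ex) == 0L) return("transcript must have at least one exon")
  st <- IRanges::start(ex); en <- IRanges::end(ex)
  if (is.unsorted(st, strictly = TRUE) && length(ex) > 1L)
    return("exons must be strictly ordered along the genome")
  if (length(ex) > 1L && any(st[-1L] <= en[-length(ex)]))
    return("exons must be non-overlapping")
  if (!object@strand %in% c(1L, -1L)) return("strand must be +1 or -1")
  if (!is.na(object@cds_start)) {
    cs <- object@cds_start; ce <- object@cds_end
    if (is.na(ce) || cs > ce) return("invalid CDS bounds")
    inside <- any(st <= cs & en >= cs) && any(st <= ce & en >= ce)
    if (!inside) return("CDS bounds must lie inside the exon union")
    len <- sum(pmin(en, ce) - pmax(st, cs) + 1L > 0L)
    splicedLen <- sum(pmax(0L, pmin(en, ce) - pmax(st, cs) + 1L))
    if (splicedLen < 3L) return("spliced CDS length must be >= 3")
  }
  TRUE
})

#' Regulatory feature (promoter, enhancer, ...)
#' @exportClass RegulatoryFeature
setClass("RegulatoryFeature", representation(
  id = "character", chrom = "character", start = "integer", end = "integer",
  feature_type = "character", cell_types = "character"))

setValidity("RegulatoryFeature", function(object)
  if (object@start > object@end) "interval start must be <= end" else TRUE)

#' Transcription factor binding motif with position weight matrix
#'
#' @slot pwm 4 x width matrix of per-position nucleotide probabilities (rows
#'   A, C, G, T); each column sums to 1 after pseudocount.
#' @exportClass MotifFeature
setClass("MotifFeature", representation(
  id = "character", motif_name = "character", chrom = "character",
  start = "integer", end = "integer", strand = "integer", pwm = "matrix"))

setValidity("MotifFeature", function(object) {
  w <- object@end - object@start + 1L
  if (ncol(object@pwm) != w)
    return("interval length must equal the number of PWM columns")
  if (nrow(object@pwm) != 4L) return("PWM must have rows A, C, G, T")
  TRUE
})

#' Severity-ranked consequence term registry
#'
#' Exactly 33 Sequence Ontology classes with accession, parent links within the
#' registry, unique severity rank (1 = most severe) and an impact class.
#'
#' @slot table data.frame with columns so_name, so_accession, parents
#'   (comma-separated, possibly empty), rank, impact.
#' @exportClass ConsequenceRegistry
setClass("ConsequenceRegistry", representation(table = "data.frame"))

setValidity("ConsequenceRegistry", function(object) {
  tb <- object@table
  need <- c("so_name", "so_accession", "parents", "rank", "impact")
  if (!all(need %in% names(tb))) return("missing registry columns")
  if (anyDuplicated(tb$so_name)) return("duplicate so_name")
  if (anyDuplicated(tb$rank)) return("rank values must be unique")
  if (!all(tb$impact %in% c("HIGH", "MODERATE", "LOW", "MODIFIER")))
    return("invalid impact class")
  # parent links must resolve within the registry and be acyclic
  par <- strsplit(tb$parents, ",", fixed = TRUE)
  allp <- unlist(par)
  allp <- allp[nzchar(allp)]
  if (!all(allp %in% tb$so_name)) return("parent links must stay inside the registry")
  for (nm in tb$so_name) {
    seen <- character(0); frontier <- nm
    while (length(frontier)) {
      if (any(frontier %in% seen)) return("parent links must be acyclic")
      seen <- c(seen, frontier)
      idx <- match(frontier, tb$so_name)
      frontier <- unlist(par[idx]); frontier <- frontier[nzchar(frontier)]
    }
  }
  TRUE
})

#' Region-binned annotation store
#'
#' Serves transcripts, regulatory features, motifs and known variants from an
#' on-disk cache of megabase-sized bins, plus genome sequence. Bin loads and
#' derived sequences (spliced cDNA, CDS, translations) are memoized in an
#' environment so consecutive input buffers touching the same region do not
#' re-read from disk.
#'
#' @slot dir cache directory (one file per chrom/bin plus manifest.json).
#' @slot manifest parsed manifest.
#' @slot fasta path to the genome FASTA (indexed on first use).
#' @slot memo memoization environment (bins, chromosome sequences, cDNA/CDS).
#' @exportClass AnnotationStore
setClass("AnnotationStore", representation(
  dir = "character", manifest = "list", fasta = "character",
  memo = "environment"))

#' Mutable run statistics
#'
#' Counts input variant alleles (n), overlapped features (f) and registered
#' predicates (p), plus predicate evaluations performed and skipped by the
#' pre-predicate gates, and the sizes of input buffer flushes.
#' @exportClass RunStatistics
setClass("RunStatistics", representation(env = "environment"))

#' @export
newRunStatistics <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L; e$f <- 0L; e$p <- 0L
  e$predicate_evaluations <- 0L
  e$predicate_evaluations_skipped <- 0L
  e$buffer_flushes <- integer(0)
  e$variants_processed <- 0L
  e$variants_filtered <- 0L
  new("RunStatistics", env = e)
}

#' @export
statsAsList <- function(stats) as.list(stats@env)

statAdd <- function(stats, field, by = 1L) {
  e <- stats@env
  e[[field]] <- e[[field]] + by
  invisible(NULL)
}
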