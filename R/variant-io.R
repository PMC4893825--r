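#' @importFrom VariantAnnotation readVcf info alt ref
#' @importFrom GenomicRanges GRanges start end seqnames
#' @importFrom IRanges IRanges
NULL

emptyVariantTab <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             ref = character(0), alt = I(list()), id = character(0),
             input_index = integer(0), is_structural = logical(0),
             sv_type = character(0), stringsAsFactors = FALSE)
}

makeVariantRow <- function(chrom, start, end, ref, alt, id = NA_character_,
                           input_index = 1L, is_structural = FALSE,
                           sv_type = "none") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             ref = ref, alt = I(list(alt)), id = id,
             input_index = as.integer(input_index),
             is_structural = is_structural, sv_type = sv_type,
             stringsAsFactors = FALSE)
}

#' Construct a VariantSet from vectors
#' @export
variantSet <- function(chrom, start, end, ref, alt, id = NA_character_,
                       is_structural = FALSE, sv_type = "none") {
  n <- length(chrom)
  if (!is.list(alt)) alt <- as.list(alt)
  tb <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(end), ref = ref, alt = I(alt),
                   id = rep_len(id, n), input_index = seq_len(n),
                   is_structural = rep_len(is_structural, n),
                   sv_type = rep_len(sv_type, n), stringsAsFactors = FALSE)
  new("VariantSet", tab = tb)
}

# Collector for QC/parse warnings: tab-delimited (line, code, message).
newWarningLog <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  e
}

logWarning <- function(log, line, code, message) {
  if (is.null(log)) return(invisible(NULL))
  log$rows[[length(log$rows) + 1L]] <-
    data.frame(line = line, code = code, message = message,
               stringsAsFactors = FALSE)
  invisible(NULL)
}

warningTable <- function(log) {
  if (is.null(log) || length(log$rows) == 0L)
    return(data.frame(line = integer(0), code = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, log$rows)
}

writeWarnings <- function(log, path) {
  tb <- warningTable(log)
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Pre-scan raw VCF text: drop malformed data lines (QC-logged), pad optional
# trailing columns so minimal 5-column test files are accepted.
prescanVcfLines <- function(lines, warn = NULL) {
  isHeader <- startsWith(lines, "#")
  keep <- logical(length(lines))
  keep[isHeader] <- TRUE
  dataIdx <- which(!isHeader & nzchar(lines))
  fixed <- lines
  for (i in dataIdx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 5L || is.na(suppressWarnings(as.integer(f[2L])))) {
      logWarning(warn, i, "MALFORMED_LINE", "VCF data line skipped")
      next
    }
    if (length(f) < 8L)
      fixed[i] <- paste(c(f, rep(".", 8L - length(f))), collapse = "\t")
    keep[i] <- TRUE
  }
  fixed[keep]
}

ensureVcfHeader <- function(lines) {
  if (any(startsWith(lines, "#CHROM"))) return(lines)
  c("##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", lines)
}

# VCF -> internal representation. The single VCF anchor base shared by REF and
# all ALTs is stripped, giving the anchored-indel internal convention
# (deletion keeps only deleted bases; insertion has ref "-" and start=end+1).
vcfRecordToRow <- function(chrom, pos, id, ref, alts, info, input_index) {
  svtype <- info$SVTYPE %||% NA_character_
  svend <- info$END %||% NA_integer_
  symbolic <- grepl("^<.+>$", alts)
  if ((!is.na(svtype) && nzchar(svtype)) || any(symbolic)) {
    if (is.na(svtype) || !nzchar(svtype))
      svtype <- gsub("[<>]", "", alts[symbolic][1L])
    svtype <- sub(":.*$", "", gsub("[<>]", "", svtype))
    if (!svtype %in% c("DEL", "DUP", "INS", "CNV")) svtype <- "CNV"
    e <- if (!is.na(svend)) as.integer(svend) else pos + nchar(ref) - 1L
    return(makeVariantRow(chrom, pos, e, ref = toupper(ref), alt = alts,
                          id = id, input_index = input_index,
                          is_structural = TRUE, sv_type = svtype))
  }
  ref <- toupper(ref); alts <- toupper(alts)
  start <- pos
  # strip the single VCF anchor base only for unbalanced (indel) records;
  # balanced substitutions keep their input representation (minimisation is a
  # separate, optional step)
  sameLen <- all(nchar(alts) == nchar(ref))
  shareAnchor <- !sameLen &&
    all(substr(alts, 1L, 1L) == substr(ref, 1L, 1L))
  if (shareAnchor) {
    ref2 <- substr(ref, 2L, nchar(ref))
    alts2 <- substr(alts, 2L, nchar(alts))
    start <- pos + 1L
    if (!nzchar(ref2)) ref2 <- "-"
    alts2[!nzchar(alts2)] <- "-"
    ref <- ref2; alts <- alts2
  }
  end <- if (ref == "-") start - 1L else start + nchar(ref) - 1L
  longest <- max(nchar(ref[ref != "-"]), nchar(alts[alts != "-"]), 0L)
  structural <- longest > 50L
  makeVariantRow(chrom, start, end, ref, alts, id = id,
                 input_index = input_index, is_structural = structural,
                 sv_type = "none")
}

#' Read variants from a VCF file or text
#'
#' Produces one internal variant per VCF record (multi-allelic records keep
#' all alternative alleles together); anchored indel bases are stripped;
#' SVTYPE/END records and symbolic alleles map to structural variants; input
#' order is preserved in \code{input_index}. Malformed lines are skipped and
#' logged; a missing required column is a fatal parse error.
#'
#' @param path VCF file (plain or bgzipped).
#' @param warn optional warning collector from \code{newWarningLog()}.
#' @return a \linkS4class{VariantSet}; attribute \code{raw_lines} carries the
#'   original data lines for VCF-format output echoing.
#' @export
readVcfVariants <- function(path, warn = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- prescanVcfLines(lines, warn)
  lines <- ensureVcfHeader(lines)
  tmp <- tempfile(fileext = ".vcf")
  on.exit(unlink(tmp))
  writeLinesUtf8(lines, tmp)
  vcf <- VariantAnnotation::readVcf(tmp)
  n <- length(vcf)
  if (n == 0L) {
    vs <- new("VariantSet", tab = emptyVariantTab())
    attr(vs, "raw_lines") <- character(0)
    attr(vs, "header_lines") <- lines[startsWith(lines, "#")]
    return(vs)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chroms <- as.character(GenomicRanges::seqnames(rr))
  poss <- GenomicRanges::start(rr)
  ids <- names(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  altsL <- VariantAnnotation::alt(vcf)
  altsL <- if (is(altsL, "DNAStringSetList")) lapply(altsL, as.character)
           else as.list(altsL)
  infoDf <- VariantAnnotation::info(vcf)
  # take IDs from the raw lines: readVcf synthesises names for ID "."
  dataLinesAll <- lines[!startsWith(lines, "#")]
  rawIds <- vapply(strsplit(dataLinesAll, "\t", fixed = TRUE), `[`, "", 3L)
  rawIds[rawIds == "."] <- NA_character_
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    inf <- list(
      SVTYPE = if ("SVTYPE" %in% names(infoDf)) infoDf$SVTYPE[i] else NULL,
      END = if ("END" %in% names(infoDf)) infoDf$END[i] else NULL)
    rows[[i]] <- vcfRecordToRow(chroms[i], poss[i], rawIds[i], refs[i],
                                altsL[[i]], inf, i)
  }
  tb <- do.call(rbind, rows)
  vs <- new("VariantSet", tab = tb)
  dataLines <- lines[!startsWith(lines, "#")]
  attr(vs, "raw_lines") <- dataLines
  attr(vs, "header_lines") <- lines[startsWith(lines, "#")]
  vs
}

#' Reduce an allele pair to its most minimal representation
#'
#' Strips bases shared by reference and alternative allele: 5' end first (the
#' start position advances by the number of bases removed), then the 3' end.
#' Disabled by default in the annotation pipeline; enable with the
#' \code{minimise} flag. Identical alleles reduce to a zero-length pair
#' flagged for QC.
#'
#' @param start 1-based position of the first base of \code{ref}.
#' @param ref,alt non-empty allele strings ("-" accepted as zero-length).
#' @return list(start, end, ref, alt, qc_flag).
#' @export
minimiseAlleles <- function(start, ref, alt) {
  r <- if (ref == "-") "" else ref
  a <- if (alt == "-") "" else alt
  # 5' shared bases
  while (nzchar(r) && nzchar(a) && substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
    r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a))
    start <- start + 1L
  }
  # 3' shared bases
  while (nzchar(r) && nzchar(a) &&
         substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
    r <- substr(r, 1L, nchar(r) - 1L); a <- substr(a, 1L, nchar(a) - 1L)
  }
  qc <- !nzchar(r) && !nzchar(a)
  end <- if (!nzchar(r)) start - 1L else start + nchar(r) - 1L
  list(start = as.integer(start), end = as.integer(end),
       ref = if (nzchar(r)) r else "-", alt = if (nzchar(a)) a else "-",
       qc_flag = qc)
}

#' Quality-check a variant against coordinates and the reference genome
#'
#' Returns every failure found; an empty failure set means the variant
#' proceeds to annotation. Reports, never raises. Without genome sequence for
#' the chromosome the check degrades to coordinate-only.
#'
#' @param row one-row variant data.frame (see \code{variantTable}).
#' @param store optional \linkS4class{AnnotationStore} for reference lookup.
#' @return list(variant_ref, failures, messages).
#' @export
qcCheck <- function(row, store = NULL) {
  fails <- character(0); msgs <- character(0)
  alleles <- c(row$ref, row$alt[[1L]])
  if (!row$is_structural &&
      !all(alleles == "-" | grepl("^[ACGTN]+$", alleles))) {
    fails <- c(fails, "BAD_ALLELE_CHARS")
    msgs <- c(msgs, "allele contains characters outside A/C/G/T/N/-")
  }
  if (row$start < 1L || row$end < row$start - 1L) {
    fails <- c(fails, "COORD_ORDER")
    msgs <- c(msgs, "invalid coordinate order")
  }
  if (!row$is_structural && row$ref != "-" &&
      (row$end - row$start + 1L) != nchar(row$ref)) {
    fails <- c(fails, "LENGTH_MISMATCH")
    msgs <- c(msgs, sprintf("allele length %d does not match span %d",
                            nchar(row$ref), row$end - row$start + 1L))
  }
  if (!row$is_structural && row$ref != "-" && !is.null(store) &&
      !"LENGTH_MISMATCH" %in% fails) {
    gseq <- tryCatch(chromSeq(store, row$chrom), error = function(e) NULL)
    if (!is.null(gseq) && row$end <= nchar(gseq)) {
      actual <- substr(gseq, row$start, row$end)
      if (!identical(actual, row$ref) && !grepl("N", row$ref)) {
        fails <- c(fails, "REF_MISMATCH")
        msgs <- c(msgs, sprintf("input reference %s does not match genome %s",
                                row$ref, actual))
      }
    }
  }
  list(variant_ref = row$input_index, failures = fails, messages = msgs)
}

#' Resolve identifier input against the known-variant track
#' @export
variantsFromIds <- function(ids, store, warn = NULL) {
  rows <- list()
  idx <- store@manifest$known_index
  k <- 0L
  for (i in seq_along(ids)) {
    id <- ids[i]
    hit <- idx[[id]]
    if (is.null(hit)) {
      logWarning(warn, i, "UNKNOWN_ID", sprintf("identifier %s not in known-variant track", id))
      next
    }
    kvs <- knownAt(store, hit$chrom, as.integer(hit$start))
    kv <- Filter(function(x) identical(x$id, id), kvs)
    if (!length(kv)) next
    kv <- kv[[1L]]
    k <- k + 1L
    rows[[k]] <- makeVariantRow(kv$chrom, kv$start, kv$end, kv$ref,
                                kv$alt, id = id, input_index = k)
  }
  tb <- if (length(rows)) do.call(rbind, rows) else emptyVariantTab()
  new("VariantSet", tab = tb)
}
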