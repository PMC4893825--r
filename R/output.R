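# Writers: tab-delimited, VCF with CSQ INFO blocks, JSON (one object per
# input variant).

CSQ_FIELDS <- c("Allele", "Consequence", "IMPACT", "SYMBOL", "Gene", "Feature",
  "BIOTYPE", "EXON", "INTRON", "HGVSc", "HGVSp", "cDNA_position",
  "CDS_position", "Protein_position", "Amino_acids", "Codons",
  "Existing_variation", "DISTANCE", "STRAND", "FLAGS")

TAB_COLUMNS <- c("Uploaded_variation", "Location", "Allele", "Gene", "Feature",
  "Feature_type", "Consequence", "cDNA_position", "CDS_position",
  "Protein_position", "Amino_acids", "Codons", "Existing_variation", "Extra")

csqEscape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub("|", "%7C", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  gsub(";", "%3B", x, fixed = TRUE)
}

dashNa <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "-"
  x
}

rowCsqValues <- function(r) {
  c(Allele = r$allele, Consequence = gsub(",", "&", r$consequence, fixed = TRUE),
    IMPACT = r$impact, SYMBOL = dashNa(r$gene_symbol), Gene = dashNa(r$gene),
    Feature = dashNa(r$feature), BIOTYPE = dashNa(r$biotype),
    EXON = dashNa(r$exon), INTRON = dashNa(r$intron),
    HGVSc = dashNa(r$hgvsc), HGVSp = dashNa(r$hgvsp),
    cDNA_position = dashNa(r$cdna_position), CDS_position = dashNa(r$cds_position),
    Protein_position = dashNa(r$protein_position),
    Amino_acids = dashNa(r$amino_acids), Codons = dashNa(r$codons),
    Existing_variation = dashNa(r$existing_variation),
    DISTANCE = dashNa(r$distance), STRAND = dashNa(r$strand),
    FLAGS = dashNa(r$flags))
}

rowExtraString <- function(r) {
  kv <- c(list(IMPACT = r$impact), r$extras[[1L]])
  if (!is.na(r$distance)) kv$DISTANCE <- r$distance
  if (!is.na(r$strand)) kv$STRAND <- r$strand
  if (r$biotype != "-") kv$BIOTYPE <- r$biotype
  if (r$gene_symbol != "-") kv$SYMBOL <- r$gene_symbol
  if (r$exon != "-") kv$EXON <- r$exon
  if (r$intron != "-") kv$INTRON <- r$intron
  if (r$hgvsg != "-") kv$HGVSg <- r$hgvsg
  if (r$hgvsc != "-") kv$HGVSc <- r$hgvsc
  if (r$hgvsp != "-") kv$HGVSp <- r$hgvsp
  if (r$flags != "-") kv$FLAGS <- r$flags
  if (!length(kv)) return("-")
  paste(sprintf("%s=%s", names(kv), vapply(kv, as.character, "")), collapse = ";")
}

#' Write annotation results
#'
#' \code{tab}: one row per result with the documented column order and
#' \code{##} header lines. \code{vcf}: the input records echoed with a CSQ
#' INFO field ("|"-separated fields within a block, ","-separated blocks,
#' field order declared in the header). \code{json}: one object per input
#' variant with nested per-feature consequence arrays. Headers record tool
#' version, cache version and command line.
#'
#' @param results results data.frame from \code{\link{annotateVariants}}.
#' @param format "tab", "vcf" or "json".
#' @param path output file.
#' @param meta named list (tool, cache, command) for headers.
#' @param raw_lines,header_lines original VCF lines (vcf format only).
#' @param variants the annotated \linkS4class{VariantSet} (json/vcf).
#' @export
writeResults <- function(results, format = c("tab", "vcf", "json"), path,
                         meta = list(), raw_lines = NULL, header_lines = NULL,
                         variants = NULL) {
  format <- match.arg(format)
  lines <- switch(format,
    tab = formatTab(results, meta),
    vcf = formatVcfOut(results, meta, raw_lines, header_lines, variants),
    json = formatJsonOut(results, variants))
  writeLinesUtf8(lines, path)
  invisible(path)
}

formatTab <- function(results, meta) {
  hdr <- c(sprintf("## %s", meta$tool %||% "vcanno"),
           sprintf("## cache: %s (schema %s)", meta$cache %||% "-",
                   meta$cache_schema %||% "1"),
           sprintf("## command: %s", meta$command %||% "-"),
           paste0("#", paste(TAB_COLUMNS, collapse = "\t")))
  if (nrow(results) == 0L) return(hdr)
  body <- vapply(seq_len(nrow(results)), function(i) {
    r <- results[i, , drop = FALSE]
    paste(c(r$uploaded_variation, r$location, r$allele, dashNa(r$gene),
            dashNa(r$feature), r$feature_type, r$consequence,
            dashNa(r$cdna_position), dashNa(r$cds_position),
            dashNa(r$protein_position), dashNa(r$amino_acids),
            dashNa(r$codons), dashNa(r$existing_variation),
            rowExtraString(r)), collapse = "\t")
  }, "")
  c(hdr, body)
}

formatVcfOut <- function(results, meta, raw_lines, header_lines, variants) {
  csqHeader <- sprintf(
    "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence annotations from %s. Format: %s\">",
    meta$tool %||% "vcanno", paste(CSQ_FIELDS, collapse = "|"))
  hdr <- header_lines %||% c("##fileformat=VCFv4.2",
                             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  chromLine <- which(startsWith(hdr, "#CHROM"))
  hdr <- append(hdr, csqHeader, after = if (length(chromLine)) chromLine - 1L else length(hdr))
  if (is.null(raw_lines) || !length(raw_lines)) return(hdr)
  tb <- variantTable(variants)
  body <- vapply(seq_along(raw_lines), function(li) {
    f <- strsplit(raw_lines[li], "\t", fixed = TRUE)[[1L]]
    rs <- results[results$variant_index == li, , drop = FALSE]
    if (nrow(rs) == 0L) return(raw_lines[li])
    blocks <- vapply(seq_len(nrow(rs)), function(i) {
      vals <- rowCsqValues(rs[i, , drop = FALSE])
      paste(csqEscape(dashNa(vals)), collapse = "|")
    }, "")
    csq <- paste0("CSQ=", paste(blocks, collapse = ","))
    f[8L] <- if (f[8L] %in% c(".", "")) csq else paste0(f[8L], ";", csq)
    paste(f, collapse = "\t")
  }, "")
  c(hdr, body)
}

formatJsonOut <- function(results, variants) {
  tb <- if (!is.null(variants)) variantTable(variants) else NULL
  if (is.null(tb) || nrow(tb) == 0L) return(character(0))
  vapply(seq_len(nrow(tb)), function(vi) {
    row <- tb[vi, , drop = FALSE]
    rs <- results[results$variant_index == row$input_index, , drop = FALSE]
    obj <- list(
      input = variantName(row),
      id = if (!is.na(row$id)) row$id else NULL,
      seq_region_name = row$chrom, start = row$start, end = row$end,
      allele_string = paste(c(row$ref, row$alt[[1L]]), collapse = "/"),
      most_severe_consequence = if (nrow(rs))
        unlist(rs$terms)[which.min(rep(rs$rank, lengths(rs$terms)))][1L]
        else NULL)
    grp <- function(type) {
      sel <- rs[rs$feature_type == type, , drop = FALSE]
      if (nrow(sel) == 0L) return(NULL)
      lapply(seq_len(nrow(sel)), function(i) {
        r <- sel[i, , drop = FALSE]
        o <- list(variant_allele = r$allele,
                  consequence_terms = as.list(r$terms[[1L]]),
                  impact = r$impact)
        if (type == "Transcript") {
          o$transcript_id <- r$feature; o$gene_id <- r$gene
          if (r$gene_symbol != "-") o$gene_symbol <- r$gene_symbol
          o$biotype <- r$biotype
          for (k in c("hgvsc", "hgvsp", "hgvsg", "cdna_position",
                      "cds_position", "protein_position", "amino_acids",
                      "codons", "exon", "intron")) {
            v <- r[[k]]
            if (!is.na(v) && v != "-") o[[k]] <- v
          }
          if (!is.na(r$distance)) o$distance <- r$distance
          o$strand <- r$strand
        } else if (type != "Intergenic") {
          o$regulatory_feature_id <- r$feature
          if (r$biotype != "-") o$biotype <- r$biotype
        }
        ex <- r$extras[[1L]]
        for (k in names(ex)) o[[tolower(k)]] <- ex[[k]]
        o
      })
    }
    obj$transcript_consequences <- grp("Transcript")
    obj$regulatory_feature_consequences <- grp("RegulatoryFeature")
    obj$motif_feature_consequences <- grp("MotifFeature")
    obj$intergenic_consequences <- grp("Intergenic")
    obj <- Filter(Negate(is.null), obj)
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                  null = "null"))
  }, "")
}
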