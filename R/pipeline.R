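# Annotation driver: one result row per alternative allele per overlapped
# feature, plus the buffered, optionally parallel run orchestration.

resultColumns <- c("variant_index", "uploaded_variation", "location", "allele",
  "gene", "gene_symbol", "feature", "feature_type", "biotype", "consequence",
  "impact", "exon", "intron", "hgvsg", "hgvsc", "hgvsp", "cdna_position",
  "cds_position", "protein_position", "amino_acids", "codons",
  "existing_variation", "distance", "strand", "flags")

emptyResults <- function() {
  tb <- as.data.frame(stats::setNames(
    rep(list(character(0)), length(resultColumns)), resultColumns),
    stringsAsFactors = FALSE)
  tb$variant_index <- integer(0)
  tb$distance <- integer(0)
  tb$strand <- integer(0)
  tb$extras <- I(list())
  tb$terms <- I(list())
  tb$rank <- integer(0)
  tb$canonical <- logical(0)
  tb$cds_length <- integer(0)
  tb
}

posLabel <- function(a, b) {
  if (is.na(a)) return("-")
  if (is.na(b) || a == b) as.character(a) else paste0(min(a, b), "-", max(a, b))
}

variantName <- function(row) {
  if (!is.na(row$id)) return(row$id)
  alt <- paste(row$alt[[1L]], collapse = "/")
  paste0(row$chrom, "_", row$start, "_", row$ref, "/", alt)
}

variantLocation <- function(row) {
  if (row$start == row$end + 1L) paste0(row$chrom, ":", row$end, "-", row$start)
  else if (row$start == row$end) paste0(row$chrom, ":", row$start)
  else paste0(row$chrom, ":", row$start, "-", row$end)
}

# Result rows are built as plain lists and assembled into a data.frame once
# per buffer: per-row data.frame construction dominates runtime otherwise.
buildResultRow <- function(row, alt, feature, terms, context, registry,
                           store, extras = list()) {
  termsOrd <- terms[order(termRank(registry, terms))]
  isTx <- is(feature, "TranscriptModel")
  b <- if (!is.null(context)) context$bundle else NULL
  cd <- if (!is.null(context)) context$codon else NULL
  out <- list(
    variant_index = row$input_index,
    uploaded_variation = variantName(row),
    location = variantLocation(row),
    allele = alt,
    gene = if (isTx) feature@gene_id else "-",
    gene_symbol = if (isTx && !is.na(feature@gene_symbol)) feature@gene_symbol else "-",
    feature = if (is.null(feature)) "-"
              else if (isTx) versionedId(feature) else featureId(feature),
    feature_type = if (is.null(feature)) "Intergenic"
                   else if (isTx) "Transcript"
                   else if (is(feature, "RegulatoryFeature")) "RegulatoryFeature"
                   else "MotifFeature",
    biotype = if (isTx) feature@biotype
              else if (is(feature, "RegulatoryFeature")) feature@feature_type
              else "-",
    consequence = paste(termsOrd, collapse = ","),
    impact = termImpact(registry, termsOrd[1L]),
    exon = if (isTx && !is.null(b)) fracLabel(b$exon_idx, length(feature@exons)) else "",
    intron = if (isTx && !is.null(b))
      fracLabel(b$intron_idx, max(0L, length(feature@exons) - 1L)) else "",
    hgvsg = "-", hgvsc = "-", hgvsp = "-",
    cdna_position = if (!is.null(b)) posLabel(b$cdna_start, b$cdna_end) else "-",
    cds_position = if (!is.null(b)) posLabel(b$cds_start, b$cds_end) else "-",
    protein_position = if (!is.null(b)) posLabel(b$protein_start, b$protein_end) else "-",
    amino_acids = if (!is.null(cd) && !is.na(cd$ref_aa)) {
      if (identical(cd$ref_aa, cd$alt_aa)) cd$ref_aa
      else paste0(cd$ref_aa, "/", cd$alt_aa)
    } else "-",
    codons = if (!is.null(cd)) paste0(cd$ref_codons_disp, "/", cd$alt_codons_disp) else "-",
    existing_variation = "-",
    distance = if (!is.null(b) && !is.na(b$distance)) b$distance else NA_integer_,
    strand = if (isTx) feature@strand
             else if (is(feature, "MotifFeature")) feature@strand else NA_integer_,
    flags = if (isTx && length(feature@flags)) paste(feature@flags, collapse = "&") else "-")
  if (!nzchar(out$exon)) out$exon <- "-"
  if (!nzchar(out$intron)) out$intron <- "-"
  out$extras <- extras
  out$terms <- termsOrd
  out$rank <- min(termRank(registry, terms))
  out$canonical <- isTx && "canonical" %in% feature@flags
  out$cds_length <- if (isTx && !is.na(feature@cds_start)) {
    m <- txMap(feature, store)
    as.integer(m$cdsCdnaEnd - m$cdsCdnaStart + 1L)
  } else 0L
  out
}

assembleResults <- function(rows) {
  if (!length(rows)) return(emptyResults())
  chrCols <- setdiff(resultColumns, c("variant_index", "distance", "strand"))
  out <- list(variant_index = vapply(rows, function(r) as.integer(r$variant_index), 0L))
  for (cn in chrCols)
    out[[cn]] <- vapply(rows, function(r) as.character(r[[cn]]), "")
  out$distance <- vapply(rows, function(r) as.integer(r$distance), 0L)
  out$strand <- vapply(rows, function(r) as.integer(r$strand), 0L)
  res <- as.data.frame(out[resultColumns], stringsAsFactors = FALSE)
  res$extras <- I(lapply(rows, `[[`, "extras"))
  res$terms <- I(lapply(rows, `[[`, "terms"))
  res$rank <- vapply(rows, function(r) as.integer(r$rank), 0L)
  res$canonical <- vapply(rows, function(r) isTRUE(r$canonical), logical(1))
  res$cds_length <- vapply(rows, function(r) as.integer(r$cds_length), 0L)
  res
}

#' Annotate a set of variants against an annotation store
#'
#' The core per-buffer engine: overlaps each variant with cached features
#' (transcripts extended by \code{flank}), evaluates the gated consequence
#' predicates per alternative allele per feature, attaches HGVS notations,
#' motif impacts, co-located known variants and custom-track hits, and runs
#' any plugins. Variants with QC failures are skipped and logged.
#'
#' @param store an \linkS4class{AnnotationStore}.
#' @param variants a \linkS4class{VariantSet}.
#' @param registry a \linkS4class{ConsequenceRegistry}.
#' @param flank transcript flank in bp (default 5000).
#' @param gates enable pre-predicate checks (identical results either way).
#' @param stats optional \linkS4class{RunStatistics}.
#' @param warn optional warning collector.
#' @param hgvs compute HGVS notations (default TRUE).
#' @param check_ref verify reference alleles against the genome (QC).
#' @param cell_types optional cell-type restriction for regulatory features.
#' @param tracks loaded custom track list.
#' @param plugins named list of functions(row, store) -> named list merged
#'   into the result's extras.
#' @param minimise apply allele minimisation before annotation.
#' @return results data.frame (one row per allele per feature) with attribute
#'   \code{colocated}: per-variant co-located record lists.
#' @export
annotateVariants <- function(store, variants, registry = loadRegistry(),
                             flank = DEFAULT_FLANK, gates = TRUE,
                             stats = NULL, warn = NULL, hgvs = TRUE,
                             check_ref = TRUE, cell_types = NULL,
                             tracks = list(), plugins = list(),
                             minimise = FALSE) {
  tb <- variantTable(variants)
  rows <- list()
  coloc <- vector("list", max(c(tb$input_index, 0L)))
  if (!is.null(stats)) stats@env$p <- nPredicates()
  tracks <- lapply(tracks, loadTrack)
  for (vi in seq_len(nrow(tb))) {
    row <- tb[vi, , drop = FALSE]
    if (minimise && !row$is_structural && length(row$alt[[1L]]) == 1L &&
        row$ref != "-" && row$alt[[1L]] != "-") {
      mm <- minimiseAlleles(row$start, row$ref, row$alt[[1L]])
      if (mm$qc_flag) {
        logWarning(warn, row$input_index, "IDENTICAL_ALLELES",
                   "reference and alternative allele are identical")
        next
      }
      row$start <- mm$start; row$end <- mm$end
      row$ref <- mm$ref; row$alt <- I(list(mm$alt))
    }
    qc <- qcCheck(row, store = if (check_ref) store else NULL)
    if (length(qc$failures)) {
      logWarning(warn, row$input_index, paste(qc$failures, collapse = ","),
                 paste(qc$messages, collapse = "; "))
      next
    }
    alts <- row$alt[[1L]]
    if (!is.null(stats)) {
      statAdd(stats, "n", length(alts))
      statAdd(stats, "variants_processed")
    }
    ov <- queryOverlaps(store, row, flank = flank)
    ov$regulatory <- filterCellTypes(ov$regulatory, cell_types)
    feats <- c(ov$transcripts, ov$regulatory, ov$motifs)
    if (!is.null(stats)) statAdd(stats, "f", length(feats))
    kn <- findColocated(row, store)
    coloc[[row$input_index]] <- kn
    existing <- if (length(kn))
      paste(vapply(kn, function(k) k$id %||% "-", ""), collapse = ",") else "-"
    trackHits <- customOverlap(row, tracks)
    gAcc <- row$chrom
    for (alt in alts) {
      featList <- if (length(feats)) feats else list(NULL)
      for (feature in featList) {
        extras <- list()
        if (row$is_structural) {
          terms <- assignSvConsequences(row, feature, flank)
          if (!length(terms)) next
          context <- NULL
        } else {
          ac <- assignConsequences(row, alt, feature, store, registry,
                                   stats = stats, gates = gates, flank = flank)
          terms <- ac$terms; context <- ac$context
          # outside the flank contract nothing applies (shouldn't happen via
          # queryOverlaps, but keep the driver total)
          if (!length(terms)) next
        }
        if (is(feature, "MotifFeature") && !row$is_structural) {
          mi <- motifConsequence(row, alt, feature, store)
          extras$MOTIF_NAME <- feature@motif_name
          extras$MOTIF_POS <- mi$motif_position
          if (!is.na(mi$delta)) {
            extras$MOTIF_SCORE_CHANGE <- round(mi$delta, 4L)
            extras$HIGH_INF_POS <- if (isTRUE(mi$informative)) "Y" else "N"
          }
        }
        if (is(feature, "RegulatoryFeature") && length(feature@cell_types))
          extras$CELL_TYPES <- paste(feature@cell_types, collapse = "&")
        for (nm in names(trackHits))
          extras[[nm]] <- paste(trackHits[[nm]], collapse = "&")
        if (length(kn)) {
          gm <- unlist(lapply(kn, function(k) k$gmaf))
          gm <- gm[!is.na(gm)]
          if (length(gm)) extras$GMAF <- max(gm)
          pf <- list()
          for (k in kn) for (p in names(k$pop_freqs)) pf[[p]] <- k$pop_freqs[[p]]
          for (p in names(pf)) extras[[p]] <- pf[[p]]
          cs <- unique(unlist(lapply(kn, function(k) k$clin_sig)))
          if (length(cs)) extras$CLIN_SIG <- paste(cs, collapse = "&")
          if (any(vapply(kn, function(k) isTRUE(k$somatic), logical(1))))
            extras$SOMATIC <- "1"
          pm <- unique(unlist(lapply(kn, function(k) k$pubmed_ids)))
          if (length(pm)) extras$PUBMED <- paste(pm, collapse = "&")
          if (any(vapply(kn, function(k) isTRUE(k$allele_mismatch), logical(1))))
            extras$ALLELE_MISMATCH <- "1"
        }
        rr <- buildResultRow(row, alt, feature, terms, context, registry,
                             store, extras)
        rr$existing_variation <- existing
        if (hgvs && !row$is_structural) {
          arow <- row
          rr$hgvsg <- hgvsG(arow, alt, store, accession = gAcc)
          if (is(feature, "TranscriptModel") &&
              !is.null(context) && context$bundle$within) {
            hc <- hgvsC(arow, alt, feature, store)
            rr$hgvsc <- if (is.na(hc)) "-" else hc
            hp <- hgvsP(arow, alt, feature, store, context)
            rr$hgvsp <- if (is.na(hp)) "-" else hp
          }
        }
        if (length(plugins)) {
          for (pg in plugins) {
            add <- tryCatch(pg(rr, store), error = function(e) NULL)
            if (length(add)) for (nm in names(add)) rr$extras[[nm]] <- add[[nm]]
          }
        }
        rows[[length(rows) + 1L]] <- rr
      }
    }
  }
  res <- assembleResults(rows)
  attr(res, "colocated") <- coloc
  res
}

#' Pick a single result per variant
#'
#' Ordering: canonical transcript first, then protein_coding biotype, then
#' lowest severity rank, then longest CDS, then lexicographically smallest
#' feature identifier. With \code{per_gene} the same ordering is applied
#' within each gene and one result is kept per gene.
#'
#' @param results results for one or more variants.
#' @param per_gene keep one per (variant, gene) instead of one per variant.
#' @export
pickOne <- function(results, per_gene = FALSE) {
  if (nrow(results) == 0L) stop("cannot pick from an empty result set")
  ord <- order(results$variant_index,
               -results$canonical,
               results$biotype != "protein_coding",
               results$rank,
               -results$cds_length,
               results$feature)
  res <- results[ord, , drop = FALSE]
  key <- if (per_gene) paste(res$variant_index, res$gene) else res$variant_index
  res <- res[!duplicated(key), , drop = FALSE]
  res[order(res$variant_index), , drop = FALSE]
}

#' Summary statistics over an annotation run
#' @export
summaryStats <- function(results, variants, filtered = 0L) {
  termCounts <- table(unlist(results$terms))
  list(
    variants_processed = length(variants),
    variants_filtered = filtered,
    results = nrow(results),
    per_term = as.list(termCounts),
    per_biotype = as.list(table(results$biotype[results$feature_type == "Transcript"])),
    per_chromosome = as.list(table(sub(":.*$", "", results$location))),
    most_severe = if (nrow(results)) {
      reg <- loadRegistry()
      mostSevere(unique(unlist(results$terms)), reg)
    } else NA_character_)
}

#' Demonstration plugin: flag results within a configurable distance
#'
#' Mirrors the up/downstream distance re-thresholding idea: returns a factory
#' whose product adds \code{NEARBY="Y"} to results within \code{threshold} bp
#' of a transcript.
#' @export
pluginNearbyThreshold <- function(threshold = 1000L) {
  function(row, store) {
    d <- suppressWarnings(as.integer(row$distance))
    if (!is.na(d) && d <= threshold) list(NEARBY = "Y") else list()
  }
}

#' Run a full annotation job
#'
#' Streams the input in sequential contiguous blocks (default block size
#' 5000 variants) through the annotation engine, optionally dividing each
#' buffer among parallel workers; results are rejoined and sorted back into
#' input order before writing, so output is identical for any worker count.
#' Writes the primary results file, a summary statistics JSON and a
#' tab-delimited warnings file.
#'
#' @param config list with elements: input (VCF path), cache, fasta
#'   (optional), output, format ("tab", "vcf" or "json"), input_format
#'   ("vcf", "ids", "hgvs"), flank, buffer_size, workers, pick, per_gene,
#'   no_intergenic, filter_common (frequency or NULL), filter (expression
#'   string), custom (track list), plugins, cell_types, minimise, gates.
#' @return invisibly, list(results, stats, outputs).
#' @export
runAnnotation <- function(config) {
  cfg <- config
  for (f in c("input", "cache", "output"))
    if (is.null(cfg[[f]])) stop("config is missing required field '", f, "'")
  if (!file.exists(cfg$input)) stop("input file not found: ", cfg$input)
  if (!dir.exists(cfg$cache)) stop("cache directory not found: ", cfg$cache)
  store <- loadStore(cfg$cache, fasta = cfg$fasta)
  registry <- loadRegistry(cfg$registry)
  flank <- as.integer(cfg$flank %||% DEFAULT_FLANK)
  bufferSize <- as.integer(cfg$buffer_size %||% 5000L)
  workers <- as.integer(cfg$workers %||% 1L)
  fmt <- cfg$format %||% "tab"
  warn <- newWarningLog()
  stats <- newRunStatistics()

  inputFormat <- cfg$input_format %||% "vcf"
  variants <- switch(inputFormat,
    vcf = readVcfVariants(cfg$input, warn),
    ids = variantsFromIds(readLines(cfg$input, warn = FALSE), store, warn),
    hgvs = {
      lns <- readLines(cfg$input, warn = FALSE)
      tbs <- lapply(seq_along(lns), function(i) {
        v <- tryCatch(parseHgvsInput(lns[i], store), error = function(e) {
          logWarning(warn, i, "HGVS_PARSE", conditionMessage(e)); NULL })
        if (is.null(v)) return(NULL)
        t <- variantTable(v); t$input_index <- i; t$id <- lns[i]; t
      })
      tbs <- Filter(Negate(is.null), tbs)
      tb <- if (length(tbs)) do.call(rbind, tbs) else emptyVariantTab()
      new("VariantSet", tab = tb)
    },
    stop("unknown input format: ", inputFormat))

  tracks <- lapply(cfg$custom %||% list(), loadTrack)
  tb <- variantTable(variants)
  n <- nrow(tb)
  blocks <- if (n) split(seq_len(n), ceiling(seq_len(n) / bufferSize)) else list()
  allRes <- list(); allColoc <- vector("list", n)
  # each chunk gets private stat/warning collectors (fork-safe); they are
  # merged back here so counters and warnings are complete for any worker count
  annotateIdx <- function(idx) {
    s <- newRunStatistics(); w <- newWarningLog()
    r <- annotateVariants(store, variants[idx], registry, flank = flank,
                          gates = !isFALSE(cfg$gates), stats = s, warn = w,
                          check_ref = !isFALSE(cfg$check_ref),
                          cell_types = cfg$cell_types, tracks = tracks,
                          plugins = cfg$plugins %||% list(),
                          minimise = isTRUE(cfg$minimise))
    attr(r, "chunk_stats") <- as.list(s@env)
    attr(r, "chunk_warnings") <- warningTable(w)
    r
  }
  mergeChunk <- function(p) {
    cl <- attr(p, "colocated")
    for (i in seq_along(cl)) if (length(cl[[i]])) allColoc[[i]] <<- cl[[i]]
    cs <- attr(p, "chunk_stats")
    for (f in c("n", "f", "predicate_evaluations",
                "predicate_evaluations_skipped", "variants_processed"))
      stats@env[[f]] <- stats@env[[f]] + cs[[f]]
    stats@env$p <- cs$p
    cw <- attr(p, "chunk_warnings")
    for (i in seq_len(nrow(cw)))
      logWarning(warn, cw$line[i], cw$code[i], cw$message[i])
  }
  for (blk in blocks) {
    stats@env$buffer_flushes <- c(stats@env$buffer_flushes, length(blk))
    if (workers > 1L && length(blk) > 1L) {
      chunks <- split(blk, cut(seq_along(blk), workers, labels = FALSE))
      parts <- parallel::mclapply(chunks, annotateIdx, mc.cores = workers)
      for (p in parts) mergeChunk(p)
      res <- do.call(rbind, parts)
    } else {
      res <- annotateIdx(blk)
      mergeChunk(res)
    }
    allRes[[length(allRes) + 1L]] <- res
  }
  results <- if (length(allRes)) do.call(rbind, allRes) else emptyResults()
  rownames(results) <- NULL
  # rejoin in input order (workers may have reordered within a buffer)
  results <- results[order(results$variant_index), , drop = FALSE]

  before <- nrow(results)
  if (!is.null(cfg$filter_common)) {
    thr <- if (isTRUE(cfg$filter_common)) 0.01 else as.numeric(cfg$filter_common)
    results <- filterCommon(results, allColoc, thr)
  }
  if (isTRUE(cfg$no_intergenic))
    results <- results[results$feature_type != "Intergenic", , drop = FALSE]
  if (!is.null(cfg$filter))
    results <- applyFilter(parseFilter(cfg$filter), results)
  if (isTRUE(cfg$per_gene) && nrow(results)) results <- pickOne(results, per_gene = TRUE)
  else if (isTRUE(cfg$pick) && nrow(results)) results <- pickOne(results)
  stats@env$variants_filtered <- before - nrow(results)

  meta <- outputMeta(store, cfg)
  writeResults(results, fmt, cfg$output, meta = meta,
               raw_lines = attr(variants, "raw_lines"),
               header_lines = attr(variants, "header_lines"),
               variants = variants)
  statsPath <- cfg$stats_file %||% paste0(cfg$output, "_summary.json")
  ss <- summaryStats(results, variants, filtered = before - nrow(results))
  ss$run <- statsAsList(stats)
  jsonlite::write_json(ss, statsPath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  warnPath <- cfg$warnings_file %||% paste0(cfg$output, "_warnings.txt")
  writeWarnings(warn, warnPath)
  invisible(list(results = results, stats = stats,
                 outputs = c(cfg$output, statsPath, warnPath)))
}

outputMeta <- function(store, cfg) {
  list(tool = paste0("vcanno ", as.character(utils::packageVersion("vcanno"))),
       cache = store@dir,
       cache_schema = store@manifest$schema_version %||% 1L,
       command = paste(c("annotate",
         sprintf("--input %s", cfg$input),
         sprintf("--cache %s", cfg$cache),
         sprintf("--format %s", cfg$format %||% "tab")), collapse = " "))
}
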