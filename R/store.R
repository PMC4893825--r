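#' @importFrom Rsamtools FaFile indexFa scanFaIndex
#' @importFrom Biostrings getSeq readDNAStringSet DNAString reverseComplement
#' @importFrom rtracklayer import
NULL

BIN_SIZE <- 1000000L
DEFAULT_FLANK <- 5000L
DEFAULT_MITO_CHROMS <- c("MT", "chrM", "M")

binIndex <- function(pos) as.integer(floor((pos - 1) / BIN_SIZE))

# ---- cache build -----------------------------------------------------------

gffAttr <- function(mc, i, keys) {
  for (k in keys) {
    if (k %in% names(mc)) {
      v <- mc[[k]][i]
      if (is(v, "List") || is.list(v)) v <- unlist(v)
      if (length(v) && !all(is.na(v))) return(as.character(v[1L]))
    }
  }
  NA_character_
}

gffParent <- function(mc, i) {
  if (!"Parent" %in% names(mc)) return(gffAttr(mc, i, "transcript_id"))
  p <- unlist(mc$Parent[i])
  if (length(p)) sub("^(gene|transcript):", "", as.character(p[1L])) else NA_character_
}

TRANSCRIPT_TYPES <- c("mRNA", "transcript", "ncRNA", "lnc_RNA", "miRNA",
                      "snoRNA", "snRNA", "rRNA", "tRNA", "pre_miRNA")

# Assemble TranscriptModel objects from an imported GFF3/GTF GRanges.
parseTranscripts <- function(gr, chromLens, canonicalAttr = c("Ensembl_canonical", "canonical"),
                             selenoTab = NULL) {
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  strd <- as.character(GenomicRanges::strand(gr))
  rid <- if ("ID" %in% names(mc)) sub("^(gene|transcript):", "", as.character(mc$ID))
         else rep(NA_character_, length(gr))

  isTx <- type %in% TRANSCRIPT_TYPES
  txIdx <- which(isTx)
  txIds <- ifelse(!is.na(rid[txIdx]) & nzchar(rid[txIdx]), rid[txIdx],
                  vapply(txIdx, function(i) gffAttr(mc, i, "transcript_id"), ""))
  # children grouped by parent transcript
  childParent <- vapply(seq_along(gr), function(i) {
    if (type[i] %in% c("exon", "CDS")) gffParent(mc, i) else NA_character_
  }, "")
  geneIdx <- which(type == "gene")
  geneIds <- rid[geneIdx]
  geneName <- vapply(geneIdx, function(i) gffAttr(mc, i, c("gene_name", "Name", "gene_symbol")), "")
  names(geneName) <- geneIds

  out <- vector("list", length(txIdx))
  for (k in seq_along(txIdx)) {
    i <- txIdx[k]
    id <- txIds[k]
    exSel <- which(childParent == id & type == "exon")
    cdsSel <- which(childParent == id & type == "CDS")
    if (!length(exSel)) stop("transcript ", id, " has no exon records")
    o <- order(st[exSel])
    exons <- IRanges::IRanges(st[exSel][o], en[exSel][o])
    chromLen <- chromLens[[chrom[i]]]
    if (!is.null(chromLen) && max(IRanges::end(exons)) > chromLen)
      stop("exon of transcript ", id, " extends beyond chromosome ", chrom[i])
    cs <- if (length(cdsSel)) as.integer(min(st[cdsSel])) else NA_integer_
    ce <- if (length(cdsSel)) as.integer(max(en[cdsSel])) else NA_integer_
    gid <- gffParent(mc, i) %||% NA_character_
    if (is.na(gid)) gid <- gffAttr(mc, i, "gene_id")
    biotype <- gffAttr(mc, i, c("biotype", "transcript_biotype"))
    if (is.na(biotype)) biotype <- if (!is.na(cs)) "protein_coding" else "transcript"
    version <- suppressWarnings(as.integer(gffAttr(mc, i, "version")))
    if (is.na(version)) version <- 1L
    flags <- character(0)
    for (ca in canonicalAttr) {
      v <- gffAttr(mc, i, ca)
      if (!is.na(v) && v %in% c("1", "true", "TRUE", "yes")) flags <- c(flags, "canonical")
    }
    ccds <- gffAttr(mc, i, "ccds_id")
    if (!is.na(ccds)) flags <- c(flags, "CCDS")
    tsl <- gffAttr(mc, i, "transcript_support_level")
    if (!is.na(tsl)) flags <- c(flags, paste0("TSL:", tsl))
    appris <- gffAttr(mc, i, "appris")
    if (!is.na(appris)) flags <- c(flags, paste0("APPRIS:", appris))
    attrs <- list()
    mstart <- suppressWarnings(as.integer(gffAttr(mc, i, "mature_start")))
    mend <- suppressWarnings(as.integer(gffAttr(mc, i, "mature_end")))
    if (!is.na(mstart) && !is.na(mend)) attrs$mature <- c(mstart, mend)
    if (!is.null(selenoTab)) {
      sel <- selenoTab$codon[selenoTab$transcript_id == id]
      if (length(sel)) attrs$seleno <- as.integer(sel)
    }
    tx <- new("TranscriptModel", id = id, version = version,
              gene_id = gid %||% NA_character_,
              gene_symbol = unname(geneName[gid]) %||% NA_character_,
              chrom = chrom[i], strand = if (strd[i] == "-") -1L else 1L,
              exons = exons, cds_start = cs, cds_end = ce,
              biotype = biotype, flags = unique(flags), attrs = attrs)
    methods::validObject(tx)
    out[[k]] <- tx
  }
  out
}

parseRegulatory <- function(gr) {
  if (is.null(gr)) return(list())
  mc <- S4Vectors::mcols(gr)
  lapply(seq_along(gr), function(i) {
    ct <- gffAttr(mc, i, "cell_types")
    new("RegulatoryFeature",
        id = gffAttr(mc, i, "ID") %||% sprintf("RF%04d", i),
        chrom = as.character(GenomicRanges::seqnames(gr))[i],
        start = GenomicRanges::start(gr)[i], end = GenomicRanges::end(gr)[i],
        feature_type = gffAttr(mc, i, "feature_type") %||% "regulatory_region",
        cell_types = if (is.na(ct)) character(0)
                     else strsplit(ct, ",", fixed = TRUE)[[1L]])
  })
}

#' Parse a JASPAR-style plain-text PWM file
#'
#' Accepts the 4-row count/probability layout (\code{>ID NAME} then rows
#' \code{A [ 1 2 ... ]}). Counts are converted to per-column probabilities
#' with pseudocount 1e-2 so every column sums to 1 and no cell is zero.
#' @export
readJasparMatrices <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], ">")) {
      hdr <- strsplit(sub("^>\\s*", "", lines[i]), "\\s+")[[1L]]
      rows <- lines[(i + 1L):(i + 4L)]
      m <- t(vapply(rows, function(r) {
        nums <- regmatches(r, gregexpr("[0-9.]+", r))[[1L]]
        as.numeric(nums)
      }, numeric(length(regmatches(rows[1L], gregexpr("[0-9.]+", rows[1L]))[[1L]]))))
      rownames(m) <- c("A", "C", "G", "T")
      m <- sweep(m + 0.01, 2L, colSums(m) + 0.04, "/")
      nm <- if (length(hdr) >= 2L) hdr[2L] else hdr[1L]
      out[[hdr[1L]]] <- list(id = hdr[1L], name = nm, pwm = m)
      i <- i + 5L
    } else i <- i + 1L
  }
  out
}

parseMotifs <- function(gr, pwms) {
  if (is.null(gr)) return(list())
  mc <- S4Vectors::mcols(gr)
  lapply(seq_along(gr), function(i) {
    nm <- gffAttr(mc, i, "motif_name")
    hit <- NULL
    for (p in pwms) if (identical(p$name, nm) || identical(p$id, nm)) hit <- p
    if (is.null(hit)) stop("no PWM found for motif ", nm)
    strd <- as.character(GenomicRanges::strand(gr))[i]
    new("MotifFeature",
        id = gffAttr(mc, i, "ID") %||% sprintf("MF%04d", i),
        motif_name = nm,
        chrom = as.character(GenomicRanges::seqnames(gr))[i],
        start = GenomicRanges::start(gr)[i], end = GenomicRanges::end(gr)[i],
        strand = if (strd == "-") -1L else 1L, pwm = hit$pwm)
  })
}

serializeFeature <- function(f) {
  if (is(f, "TranscriptModel")) {
    list(class = "transcript", id = f@id, version = f@version,
         gene_id = f@gene_id, gene_symbol = f@gene_symbol, chrom = f@chrom,
         strand = f@strand, exon_starts = IRanges::start(f@exons),
         exon_ends = IRanges::end(f@exons), cds_start = f@cds_start,
         cds_end = f@cds_end, biotype = f@biotype, flags = f@flags,
         attrs = f@attrs)
  } else if (is(f, "RegulatoryFeature")) {
    list(class = "regulatory", id = f@id, chrom = f@chrom, start = f@start,
         end = f@end, feature_type = f@feature_type, cell_types = f@cell_types)
  } else if (is(f, "MotifFeature")) {
    list(class = "motif", id = f@id, motif_name = f@motif_name,
         chrom = f@chrom, start = f@start, end = f@end, strand = f@strand,
         pwm = unname(as.vector(f@pwm)), pwm_width = ncol(f@pwm))
  } else f  # known variants are stored as plain lists
}

deserializeFeature <- function(x) {
  switch(x$class,
    transcript = new("TranscriptModel", id = x$id, version = as.integer(x$version),
        gene_id = x$gene_id %||% NA_character_,
        gene_symbol = x$gene_symbol %||% NA_character_, chrom = x$chrom,
        strand = as.integer(x$strand),
        exons = IRanges::IRanges(as.integer(unlist(x$exon_starts)),
                                 as.integer(unlist(x$exon_ends))),
        cds_start = as.integer(x$cds_start %||% NA_integer_),
        cds_end = as.integer(x$cds_end %||% NA_integer_),
        biotype = x$biotype, flags = as.character(unlist(x$flags)),
        attrs = lapply(x$attrs, function(v) if (is.numeric(v)) as.integer(v) else v)),
    regulatory = new("RegulatoryFeature", id = x$id, chrom = x$chrom,
        start = as.integer(x$start), end = as.integer(x$end),
        feature_type = x$feature_type,
        cell_types = as.character(unlist(x$cell_types))),
    motif = {
      m <- matrix(as.numeric(unlist(x$pwm)), nrow = 4L,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
      new("MotifFeature", id = x$id, motif_name = x$motif_name,
          chrom = x$chrom, start = as.integer(x$start), end = as.integer(x$end),
          strand = as.integer(x$strand), pwm = m)
    },
    x)
}

featureSpan <- function(f) {
  if (is(f, "TranscriptModel"))
    c(min(IRanges::start(f@exons)), max(IRanges::end(f@exons)))
  else if (is(f, "RegulatoryFeature") || is(f, "MotifFeature"))
    c(f@start, f@end)
  else c(f$start, f$end)
}

featureChrom <- function(f) if (isS4(f)) f@chrom else f$chrom

#' Build the region-binned annotation cache
#'
#' Compiles a GFF3/GTF transcript set (plus optional regulatory, motif and
#' known-variant tracks) into one serialized file per (chromosome, megabase
#' bin) under \code{out}, with a manifest recording source checksums, build
#' parameters and per-feature indexes. Features spanning a bin boundary are
#' written into every bin they overlap and deduplicated at query time. The
#' genome FASTA is indexed for random access.
#'
#' @param annotation path to GFF3 or GTF with gene/transcript/exon/CDS records.
#' @param genome path to the matching FASTA.
#' @param out cache directory to create.
#' @param regulatory,motifs,motif_pwms,known optional paths: regulatory GFF,
#'   motif GFF, JASPAR-style PWM file, known-variant VCF (reserved INFO keys
#'   GMAF, GMAF_ALLELE, AF_*, CLNSIG, SOMATIC, PMID).
#' @param canonical_attr GFF attribute name(s) marking the canonical transcript.
#' @param seleno optional tab-delimited sidecar (transcript_id, codon) marking
#'   selenocysteine codon positions.
#' @param mito_chroms chromosome names treated as mitochondrial.
#' @return the manifest, invisibly.
#' @export
buildCache <- function(annotation, genome, out, regulatory = NULL,
                       motifs = NULL, motif_pwms = NULL, known = NULL,
                       canonical_attr = c("Ensembl_canonical", "canonical"),
                       seleno = NULL, mito_chroms = DEFAULT_MITO_CHROMS) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!file.exists(paste0(genome, ".fai"))) Rsamtools::indexFa(genome)
  fai <- Rsamtools::scanFaIndex(genome)
  chromLens <- stats::setNames(GenomicRanges::width(fai),
                               as.character(GenomicRanges::seqnames(fai)))

  gr <- rtracklayer::import(annotation)
  selenoTab <- if (!is.null(seleno))
    utils::read.delim(seleno, stringsAsFactors = FALSE) else NULL
  txs <- parseTranscripts(gr, as.list(chromLens), canonical_attr, selenoTab)
  if (length(txs) == 0L) warning("no transcripts found in ", annotation)

  regs <- if (!is.null(regulatory)) parseRegulatory(rtracklayer::import(regulatory)) else list()
  mots <- if (!is.null(motifs)) {
    pwms <- readJasparMatrices(motif_pwms)
    parseMotifs(rtracklayer::import(motifs), pwms)
  } else list()
  kvs <- if (!is.null(known)) parseKnownVcf(known) else list()

  feats <- c(txs, regs, mots, kvs)
  bins <- list()  # "chrom/bin" -> list of serialized features
  for (f in feats) {
    sp <- featureSpan(f)
    ch <- featureChrom(f)
    for (b in binIndex(sp[1L]):binIndex(sp[2L])) {
      key <- paste0(ch, "/", b)
      bins[[key]] <- c(bins[[key]], list(serializeFeature(f)))
    }
  }
  for (key in names(bins)) {
    path <- file.path(out, paste0(key, ".jsonl"))
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    lines <- vapply(bins[[key]], function(x)
      as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                    null = "null", na = "null")), "")
    writeLinesUtf8(lines, path)
  }

  txIndex <- list(); knIndex <- list()
  for (t in txs) txIndex[[t@id]] <- list(chrom = t@chrom, version = t@version)
  for (k in kvs) if (!is.na(k$id)) knIndex[[k$id]] <- list(chrom = k$chrom, start = k$start)
  manifest <- list(
    schema_version = 1L, bin_size = BIN_SIZE,
    checksums = list(annotation = unname(tools::md5sum(annotation)),
                     genome = unname(tools::md5sum(genome))),
    genome_fasta = normalizePath(genome),
    chrom_lengths = as.list(chromLens),
    counts = list(transcripts = length(txs), regulatory = length(regs),
                  motifs = length(mots), known_variants = length(kvs)),
    build_params = list(canonical_attr = canonical_attr,
                        mito_chroms = mito_chroms,
                        default_flank = DEFAULT_FLANK),
    tx_index = txIndex, known_index = knIndex)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(manifest)
}

parseKnownVcf <- function(path) {
  vs <- readVcfVariants(path)
  tb <- variantTable(vs)
  if (nrow(tb) == 0L) return(list())
  lines <- attr(vs, "raw_lines")
  infoStrs <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 8L)
  out <- vector("list", nrow(tb))
  for (i in seq_len(nrow(tb))) {
    kv <- strsplit(strsplit(infoStrs[i], ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    info <- list()
    for (p in kv) info[[p[1L]]] <- if (length(p) > 1L) p[2L] else TRUE
    pops <- grep("^AF_", names(info), value = TRUE)
    popFreqs <- stats::setNames(as.numeric(unlist(info[pops])), sub("^AF_", "", pops))
    out[[i]] <- list(class = "known", id = tb$id[i], chrom = tb$chrom[i],
      start = tb$start[i], end = tb$end[i], ref = tb$ref[i],
      alt = tb$alt[[i]],
      gmaf = as.numeric(info$GMAF %||% NA_real_),
      gmaf_allele = info$GMAF_ALLELE %||% NA_character_,
      pop_freqs = as.list(popFreqs),
      clin_sig = if (is.null(info$CLNSIG)) character(0)
                 else strsplit(info$CLNSIG, ",", fixed = TRUE)[[1L]],
      somatic = isTRUE(info$SOMATIC) || identical(info$SOMATIC, "1"),
      pubmed_ids = if (is.null(info$PMID)) character(0)
                   else strsplit(info$PMID, ",", fixed = TRUE)[[1L]])
  }
  out
}

# ---- store -----------------------------------------------------------------

#' Open an annotation cache for querying
#' @param dir cache directory created by \code{\link{buildCache}}.
#' @param fasta optional genome FASTA path overriding the manifest's.
#' @export
loadStore <- function(dir, fasta = NULL) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  fa <- fasta %||% manifest$genome_fasta
  if (!file.exists(paste0(fa, ".fai"))) Rsamtools::indexFa(fa)
  new("AnnotationStore", dir = dir, manifest = manifest, fasta = fa,
      memo = new.env(parent = emptyenv()))
}

#' @export
storeFlank <- function(store) {
  as.integer(store@manifest$build_params$default_flank %||% DEFAULT_FLANK)
}

#' Whole-chromosome sequence, memoized
#' @export
chromSeq <- function(store, chrom) {
  key <- paste0("seq:", chrom)
  memo <- store@memo
  if (!is.null(memo[[key]])) return(memo[[key]])
  lens <- store@manifest$chrom_lengths
  nm <- chrom
  if (is.null(lens[[nm]])) {
    alts <- c(paste0("chr", normChrom(chrom)), normChrom(chrom))
    nm <- alts[alts %in% names(lens)][1L]
    if (is.na(nm) || is.null(nm)) stop("chromosome ", chrom, " not in genome")
  }
  fa <- Rsamtools::FaFile(store@fasta)
  s <- as.character(Biostrings::getSeq(fa, GenomicRanges::GRanges(
    nm, IRanges::IRanges(1L, as.integer(lens[[nm]])))))[[1L]]
  memo[[key]] <- toupper(s)
  memo[[key]]
}

hasChrom <- function(store, chrom) {
  lens <- store@manifest$chrom_lengths
  any(c(chrom, paste0("chr", normChrom(chrom)), normChrom(chrom)) %in% names(lens))
}

# Load (memoized) the parsed features of one bin; missing bin file => empty.
loadBin <- function(store, chrom, bin) {
  key <- paste0("bin:", chrom, "/", bin)
  memo <- store@memo
  if (!is.null(memo[[key]])) return(memo[[key]])
  path <- file.path(store@dir, chrom, paste0(bin, ".jsonl"))
  feats <- if (file.exists(path)) {
    lapply(readLines(path, warn = FALSE), function(l)
      deserializeFeature(jsonlite::fromJSON(l, simplifyVector = TRUE)))
  } else list()
  memo[[key]] <- feats
  feats
}

# Resolve a chromosome name against cache naming ("chr" prefix tolerated).
storeChromName <- function(store, chrom) {
  cand <- unique(c(chrom, paste0("chr", normChrom(chrom)), normChrom(chrom)))
  have <- list.dirs(store@dir, recursive = FALSE, full.names = FALSE)
  hit <- cand[cand %in% have]
  if (length(hit)) hit[1L] else chrom
}

#' Query features overlapping a variant span
#'
#' Transcript intervals are extended by \code{flank} on both sides; regulatory
#' and motif features match on their own span. An insertion (start = end + 1)
#' overlaps features that strictly contain the insertion point. Bins are
#' loaded once and memoized across consecutive buffers. A chromosome absent
#' from the cache yields an empty result with a warning.
#'
#' @param store an \linkS4class{AnnotationStore}.
#' @param variant one-row variant data.frame, or a list with chrom/start/end.
#' @param flank transcript flank in bp (default 5000).
#' @param memoize set FALSE to bypass the bin memo (results are identical).
#' @return list(transcripts=, regulatory=, motifs=, known=) of features.
#' @export
setMethod("queryOverlaps", "AnnotationStore",
  function(store, variant, flank = DEFAULT_FLANK, memoize = TRUE) {
    chrom <- storeChromName(store, variant$chrom)
    if (!dir.exists(file.path(store@dir, chrom))) {
      if (!hasChrom(store, variant$chrom))
        warning("chromosome ", variant$chrom, " absent from cache")
      return(list(transcripts = list(), regulatory = list(),
                  motifs = list(), known = list()))
    }
    vstart <- variant$start; vend <- variant$end
    lo <- min(vstart, vend) - flank; hi <- max(vstart, vend) + flank
    bins <- max(0L, binIndex(max(1L, lo))):binIndex(max(1L, hi))
    feats <- list()
    for (b in bins) {
      fs <- if (memoize) loadBin(store, chrom, b) else {
        path <- file.path(store@dir, chrom, paste0(b, ".jsonl"))
        if (file.exists(path))
          lapply(readLines(path, warn = FALSE), function(l)
            deserializeFeature(jsonlite::fromJSON(l, simplifyVector = TRUE)))
        else list()
      }
      feats <- c(feats, fs)
    }
    tx <- list(); reg <- list(); mot <- list(); kn <- list(); seen <- character(0)
    for (f in feats) {
      id <- if (isS4(f)) featureId(f) else paste0("kv:", f$id, ":", f$start)
      if (id %in% seen) next
      sp <- featureSpan(f)
      useFlank <- if (is(f, "TranscriptModel")) flank else 0L
      if (sp[1L] - useFlank <= vend && vstart <= sp[2L] + useFlank) {
        seen <- c(seen, id)
        if (is(f, "TranscriptModel")) tx <- c(tx, f)
        else if (is(f, "RegulatoryFeature")) reg <- c(reg, f)
        else if (is(f, "MotifFeature")) mot <- c(mot, f)
        else kn <- c(kn, list(f))
      }
    }
    list(transcripts = tx, regulatory = reg, motifs = mot, known = kn)
  })

knownAt <- function(store, chrom, pos) {
  chrom <- storeChromName(store, chrom)
  feats <- loadBin(store, chrom, binIndex(pos))
  Filter(function(f) !isS4(f) && identical(f$class, "known") &&
           f$start <= pos && f$end >= pos - 1L, feats)
}

#' Fetch a transcript by identifier (accession without version)
#' @export
storeTranscript <- function(store, id) {
  hit <- store@manifest$tx_index[[id]]
  if (is.null(hit)) return(NULL)
  # scan the chromosome's bins for the transcript
  chromDir <- file.path(store@dir, hit$chrom)
  for (b in sub("\\.jsonl$", "", list.files(chromDir, pattern = "\\.jsonl$"))) {
    for (f in loadBin(store, hit$chrom, b))
      if (is(f, "TranscriptModel") && f@id == id) return(f)
  }
  NULL
}

isMitoChrom <- function(store, chrom) {
  mito <- unlist(store@manifest$build_params$mito_chroms) %||% DEFAULT_MITO_CHROMS
  chrom %in% mito || normChrom(chrom) %in% normChrom(mito)
}

# ---- derived sequences (memoized per transcript per run) -------------------

#' @describeIn splicedSequence exons concatenated 5' to 3' in transcript
#'   orientation (reverse-complemented for minus strand); memoized.
#' @export
setMethod("splicedSequence", "TranscriptModel", function(transcript, store) {
  key <- paste0("cdna:", transcript@id)
  memo <- store@memo
  if (!is.null(memo[[key]])) return(memo[[key]])
  gseq <- chromSeq(store, transcript@chrom)
  if (max(IRanges::end(transcript@exons)) > nchar(gseq))
    stop("exon beyond chromosome end for ", transcript@id)
  pieces <- substring(gseq, IRanges::start(transcript@exons),
                      IRanges::end(transcript@exons))
  cdna <- paste(pieces, collapse = "")
  if (transcript@strand < 0L) cdna <- revcompStr(cdna)
  memo[[key]] <- cdna
  cdna
})

#' @describeIn cdsSequence contiguous substring of the spliced cDNA between
#'   the CDS bounds; memoized.
#' @export
setMethod("cdsSequence", "TranscriptModel", function(transcript, store) {
  if (is.na(transcript@cds_start)) return(NA_character_)
  key <- paste0("cds:", transcript@id)
  memo <- store@memo
  if (!is.null(memo[[key]])) return(memo[[key]])
  map <- txMap(transcript, store)
  cdna <- splicedSequence(transcript, store)
  cds <- substr(cdna, map$cdsCdnaStart, map$cdsCdnaEnd)
  memo[[key]] <- cds
  cds
})

txProtein <- function(transcript, store) {
  key <- paste0("prot:", transcript@id)
  memo <- store@memo
  if (!is.null(memo[[key]])) return(memo[[key]])
  cds <- cdsSequence(transcript, store)
  tbl <- if (isMitoChrom(store, transcript@chrom)) "mito" else "standard"
  p <- translateCds(cds, table = tbl,
                    seleno = transcript@attrs$seleno %||% integer(0))
  memo[[key]] <- p
  p
}

# Coordinate arithmetic tables for a transcript, memoized: transcript-ordered
# exon bounds, cumulative cDNA lengths, CDS bounds in cDNA space, introns.
txMap <- function(tx, store = NULL) {
  memo <- if (!is.null(store)) store@memo else NULL
  key <- paste0("map:", tx@id)
  if (!is.null(memo) && !is.null(memo[[key]])) return(memo[[key]])
  exS <- IRanges::start(tx@exons); exE <- IRanges::end(tx@exons)
  n <- length(exS)
  ord <- if (tx@strand > 0L) seq_len(n) else rev(seq_len(n))
  exSo <- exS[ord]; exEo <- exE[ord]
  w <- exEo - exSo + 1L
  cum <- cumsum(c(0L, w))  # cum[i] = cDNA bases before exon i (tx order)
  cdnaLen <- cum[n + 1L]
  g2c <- function(g) {
    for (i in seq_len(n)) {
      if (g >= exSo[i] && g <= exEo[i]) {
        off <- if (tx@strand > 0L) g - exSo[i] else exEo[i] - g
        return(cum[i] + off + 1L)
      }
    }
    NA_integer_
  }
  c2g <- function(cp) {
    i <- findInterval(cp - 1L, cum)  # exon index in tx order
    off <- cp - cum[i] - 1L
    if (tx@strand > 0L) exSo[i] + off else exEo[i] - off
  }
  cdsCdnaStart <- cdsCdnaEnd <- NA_integer_
  if (!is.na(tx@cds_start)) {
    a <- g2c(tx@cds_start); b <- g2c(tx@cds_end)
    cdsCdnaStart <- min(a, b); cdsCdnaEnd <- max(a, b)
  }
  introns <- if (n > 1L)
    IRanges::IRanges(exE[-n] + 1L, exS[-1L] - 1L) else IRanges::IRanges()
  m <- list(exSo = exSo, exEo = exEo, cum = cum, nExons = n,
            cdnaLen = cdnaLen, g2c = g2c, c2g = c2g,
            cdsCdnaStart = cdsCdnaStart, cdsCdnaEnd = cdsCdnaEnd,
            introns = introns, txStart = min(exS), txEnd = max(exE))
  if (!is.null(memo)) memo[[key]] <- m
  m
}
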