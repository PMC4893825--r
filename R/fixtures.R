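# Synthetic fixture generator: genome, annotation, variants and PWMs with
# known ground truth. Fixtures optimise consequence-class coverage, not
# population-genetic realism. Identical seeds give byte-identical outputs.

# codons free of T cannot create a stop codon in any reading frame, which
# keeps designed coding sequences stop-free without post-hoc checks
SAFE_CODONS <- c("GCA", "GGA", "AAA", "CAG", "GAG", "CCA", "ACA", "AGC",
                 "CGA", "AAC", "GCC", "GGC")

#' Fixture specification
#'
#' @param seed RNG seed; identical seeds give byte-identical files.
#' @param chrom_lengths named lengths of the synthetic chromosomes.
#' @param include_regulatory,include_motifs,include_known toggle the optional
#'   tracks.
#' @param n_transcripts optional cap on the designed transcript set (0 gives
#'   a transcript-free annotation and an all-intergenic truth table when the
#'   regulatory/motif tracks are off); NULL keeps the full set.
#' @param n_bulk_snvs size of the bulk random-SNV set (written to bulk.vcf)
#'   used for buffering/worker exercises.
#' @export
fixtureSpec <- function(seed = 1L,
                        chrom_lengths = c(chrT = 20000L, chrR = 3000L, chrM = 600L),
                        include_regulatory = TRUE, include_motifs = TRUE,
                        include_known = TRUE, n_transcripts = NULL,
                        n_bulk_snvs = 12000L) {
  list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
       include_regulatory = include_regulatory,
       include_motifs = include_motifs, include_known = include_known,
       n_transcripts = n_transcripts,
       n_bulk_snvs = as.integer(n_bulk_snvs))
}

overlaySeq <- function(vec, start, string) {
  b <- strsplit(string, "", fixed = TRUE)[[1L]]
  vec[start:(start + length(b) - 1L)] <- b
  vec
}

pickAlt <- function(ref) if (ref == "A") "C" else "A"

# The designed transcript set (built from the genome strings so reference
# alleles always match).
fixtureTranscripts <- function() {
  list(
    TX1 = list(id = "TX1", gene = "G1", symbol = "GENE1", chrom = "chrT",
               strand = 1L, exons = rbind(c(11L, 70L)), cds = c(21L, 50L),
               biotype = "protein_coding", canonical = TRUE),
    TX2 = list(id = "TX2", gene = "G2", symbol = "GENE2", chrom = "chrT",
               strand = 1L,
               exons = rbind(c(201L, 500L), c(601L, 900L), c(1001L, 1100L)),
               cds = c(251L, 1050L), biotype = "protein_coding",
               canonical = FALSE, ccds = "CCDS2.1"),
    TX2B = list(id = "TX2B", gene = "G2", symbol = "GENE2", chrom = "chrT",
                strand = 1L, exons = rbind(c(201L, 500L), c(1001L, 1100L)),
                cds = c(251L, 1050L), biotype = "protein_coding",
                canonical = TRUE),
    TX3 = list(id = "TX3", gene = "G3", symbol = "GENE3", chrom = "chrT",
               strand = -1L, exons = rbind(c(1501L, 1800L)),
               cds = c(1531L, 1770L), biotype = "protein_coding",
               canonical = TRUE),
    TX4 = list(id = "TX4", gene = "G4", symbol = "GENE4", chrom = "chrT",
               strand = 1L, exons = rbind(c(2001L, 2050L), c(2101L, 2150L)),
               cds = NULL, biotype = "lincRNA", canonical = TRUE),
    TXM = list(id = "TXM", gene = "G5", symbol = "GENE5", chrom = "chrT",
               strand = 1L, exons = rbind(c(2301L, 2380L)), cds = NULL,
               biotype = "miRNA", canonical = TRUE,
               mature = c(2321L, 2342L)),
    TX5 = list(id = "TX5", gene = "G6", symbol = "GENE6", chrom = "chrT",
               strand = 1L, exons = rbind(c(2501L, 2560L)),
               cds = c(2511L, 2542L), biotype = "protein_coding",
               canonical = TRUE),
    TXSE = list(id = "TXSE", gene = "G7", symbol = "GENE7", chrom = "chrT",
                strand = 1L, exons = rbind(c(3001L, 3120L)),
                cds = c(3011L, 3100L), biotype = "protein_coding",
                canonical = TRUE, seleno = 3L),
    TXMT = list(id = "TXMT", gene = "GM", symbol = "GENEM", chrom = "chrM",
                strand = 1L, exons = rbind(c(101L, 160L)),
                cds = c(111L, 140L), biotype = "protein_coding",
                canonical = TRUE))
}

fixtureTxModels <- function(defs = fixtureTranscripts()) {
  lapply(defs, function(d) {
    attrs <- list()
    if (!is.null(d$mature)) attrs$mature <- d$mature
    if (!is.null(d$seleno)) attrs$seleno <- d$seleno
    flags <- character(0)
    if (isTRUE(d$canonical)) flags <- c(flags, "canonical")
    if (!is.null(d$ccds)) flags <- c(flags, "CCDS")
    new("TranscriptModel", id = d$id, version = 1L, gene_id = d$gene,
        gene_symbol = d$symbol, chrom = d$chrom, strand = d$strand,
        exons = IRanges::IRanges(d$exons[, 1L], d$exons[, 2L]),
        cds_start = if (is.null(d$cds)) NA_integer_ else d$cds[1L],
        cds_end = if (is.null(d$cds)) NA_integer_ else d$cds[2L],
        biotype = d$biotype, flags = flags, attrs = attrs)
  })
}

# Designed coding sequences (deterministic given the seeded RNG state).
designSequences <- function(lens) {
  genome <- lapply(lens, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  names(genome) <- names(lens)
  ch <- genome$chrT
  ch <- overlaySeq(ch, 11L, "GGTTACAGCA")                       # TX1 5'UTR
  ch <- overlaySeq(ch, 21L, "ATGGCCTGTGGGAAACCCTTTACGCATTGA")   # TX1 CDS
  ch <- overlaySeq(ch, 51L, "CAGTCAGTCAGTCAGTCAGT")             # TX1 3'UTR
  ch <- overlaySeq(ch, 100L, "TAAAC")                           # homopolymer
  # TX2: 600 nt CDS = ATG + 198 safe codons + TGA
  cds2 <- paste0("ATG", paste(sample(SAFE_CODONS, 198L, replace = TRUE),
                              collapse = ""), "TGA")
  ch <- overlaySeq(ch, 251L, substr(cds2, 1L, 250L))
  ch <- overlaySeq(ch, 601L, substr(cds2, 251L, 550L))
  ch <- overlaySeq(ch, 1001L, substr(cds2, 551L, 600L))
  ch <- overlaySeq(ch, 501L, "GT"); ch <- overlaySeq(ch, 599L, "AG")
  ch <- overlaySeq(ch, 901L, "GT"); ch <- overlaySeq(ch, 999L, "AG")
  # TX3 (minus strand): design the cDNA, write its reverse complement
  cods3 <- sample(SAFE_CODONS, 78L, replace = TRUE)
  cods3[9L] <- "AAA"; cods3[10L] <- "AAG"   # cDNA homopolymer (c.28-32)
  cods3[11L] <- "GGC"   # pin the 3' tract boundary for any seed
  cds3 <- paste0("ATG", paste(cods3, collapse = ""), "TGA")
  u5 <- paste(sample(c("A", "C", "G"), 30L, replace = TRUE), collapse = "")
  u3 <- paste(sample(c("A", "C", "G"), 30L, replace = TRUE), collapse = "")
  cdna3 <- paste0(u5, cds3, u3)
  ch <- overlaySeq(ch, 1501L, revcompStr(cdna3))
  # TX5: incomplete terminal codon (32 nt CDS)
  cds5 <- paste0("ATG", paste(sample(SAFE_CODONS, 9L, replace = TRUE),
                              collapse = ""), "AC")
  ch <- overlaySeq(ch, 2511L, cds5)
  # TXSE: selenocysteine at codon 3
  cdsSE <- paste0("ATGGCATGA", paste(sample(SAFE_CODONS, 26L, replace = TRUE),
                                     collapse = ""), "TAA")
  ch <- overlaySeq(ch, 3011L, cdsSE)
  genome$chrT <- ch
  # TXMT on the mitochondrial chromosome
  genome$chrM <- overlaySeq(genome$chrM, 111L, "ATGAGCGGCCACCTAACCGGATTCGCATAA")
  # motif consensus site on chrR
  genome
}

fixturePwm <- function() {
  cons <- c("T", "G", "A", "C", "T", "A", "A", "G", "G", "T", "G", "C")
  counts <- matrix(1, nrow = 4L, ncol = 12L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(cons)) counts[cons[i], i] <- 97
  counts[, 6L] <- c(25, 25, 25, 24)    # near-uniform, uninformative column
  list(id = "MA9001.1", name = "SYNTH1", counts = counts, consensus = cons)
}

fixtureGffLines <- function(defs) {
  ln <- c("##gff-version 3")
  genesSeen <- character(0)
  for (d in defs) {
    gs <- min(d$exons[, 1L]); ge <- max(d$exons[, 2L])
    strand <- if (d$strand > 0L) "+" else "-"
    if (!d$gene %in% genesSeen) {
      ln <- c(ln, sprintf("%s\tvcanno\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_name=%s",
                          d$chrom, gs, ge, strand, d$gene, d$symbol))
      genesSeen <- c(genesSeen, d$gene)
    }
    attrs <- sprintf("ID=%s;Parent=%s;biotype=%s;version=1", d$id, d$gene, d$biotype)
    if (isTRUE(d$canonical)) attrs <- paste0(attrs, ";canonical=1")
    if (!is.null(d$ccds)) attrs <- paste0(attrs, ";ccds_id=", d$ccds)
    if (!is.null(d$mature)) attrs <- paste0(attrs, sprintf(";mature_start=%d;mature_end=%d",
                                                           d$mature[1L], d$mature[2L]))
    ln <- c(ln, sprintf("%s\tvcanno\tmRNA\t%d\t%d\t.\t%s\t.\t%s",
                        d$chrom, gs, ge, strand, attrs))
    for (i in seq_len(nrow(d$exons)))
      ln <- c(ln, sprintf("%s\tvcanno\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                          d$chrom, d$exons[i, 1L], d$exons[i, 2L], strand, d$id))
    if (!is.null(d$cds)) {
      for (i in seq_len(nrow(d$exons))) {
        cs <- max(d$exons[i, 1L], d$cds[1L]); ce <- min(d$exons[i, 2L], d$cds[2L])
        if (cs <= ce)
          ln <- c(ln, sprintf("%s\tvcanno\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                              d$chrom, cs, ce, strand, d$id))
      }
    }
  }
  ln
}

# The designed variant panel: id, chrom, VCF pos/ref/alt (alt may hold
# several alleles), plus structural records.
fixtureVariantDefs <- function(genome) {
  g <- function(chrom, a, b = a) paste(genome[[chrom]][a:b], collapse = "")
  v <- list()
  add <- function(id, chrom, pos, ref, alt, info = ".") {
    v[[length(v) + 1L]] <<- list(id = id, chrom = chrom, pos = pos, ref = ref,
                                 alt = alt, info = info)
  }
  add("v01", "chrT", 25L, g("chrT", 25L), "T")
  add("v02", "chrT", 26L, g("chrT", 26L), c("A", "G"))
  add("v03", "chrT", 29L, g("chrT", 29L), "A")
  add("v04", "chrT", 48L, g("chrT", 48L), "C")
  add("v05", "chrT", 49L, g("chrT", 49L), "A")
  add("v06", "chrT", 21L, g("chrT", 21L), "G")
  add("v07", "chrT", 15L, g("chrT", 15L), "G")
  add("v08", "chrT", 55L, g("chrT", 55L), "T")
  add("v09", "chrT", 5L, g("chrT", 5L), pickAlt(g("chrT", 5L)))
  add("v10", "chrT", 270L, g("chrT", 270L), pickAlt(g("chrT", 270L)))
  add("v11", "chrT", 550L, g("chrT", 550L), pickAlt(g("chrT", 550L)))
  add("v12", "chrT", 501L, g("chrT", 501L), pickAlt(g("chrT", 501L)))
  add("v13", "chrT", 600L, g("chrT", 600L), pickAlt(g("chrT", 600L)))
  add("v14", "chrT", 499L, g("chrT", 499L), pickAlt(g("chrT", 499L)))
  add("v16", "chrT", 504L, g("chrT", 504L), pickAlt(g("chrT", 504L)))
  add("v17", "chrT", 609L, g("chrT", 609L, 610L), g("chrT", 609L))       # 1 bp del
  add("v18", "chrT", 611L, g("chrT", 611L, 614L), g("chrT", 611L))       # 3 bp del
  add("v19", "chrT", 620L, g("chrT", 620L), paste0(g("chrT", 620L), "GCA"))
  add("v20", "chrT", 630L, g("chrT", 630L), paste0(g("chrT", 630L), "A"))
  add("v21", "chrT", 2542L, g("chrT", 2542L), pickAlt(g("chrT", 2542L)))
  add("v22", "chrT", 2025L, g("chrT", 2025L), pickAlt(g("chrT", 2025L)))
  add("v23", "chrT", 2075L, g("chrT", 2075L), pickAlt(g("chrT", 2075L)))
  add("v24", "chrT", 2330L, g("chrT", 2330L), pickAlt(g("chrT", 2330L)))
  add("v25", "chrT", 2305L, g("chrT", 2305L), pickAlt(g("chrT", 2305L)))
  add("v26", "chrT", 19000L, g("chrT", 19000L), pickAlt(g("chrT", 19000L)))
  add("v27", "chrT", 1650L, g("chrT", 1650L), pickAlt(g("chrT", 1650L)))
  add("v28", "chrT", 100L, g("chrT", 100L, 101L), g("chrT", 100L))       # homopolymer del
  add("v29", "chrT", 102L, g("chrT", 102L), paste0(g("chrT", 102L), "A")) # dup ins
  add("v30", "chrT", 1740L, g("chrT", 1740L, 1741L), g("chrT", 1740L))   # minus-strand tract del
  add("v31", "chrM", 116L, g("chrM", 116L), "A")
  add("v32", "chrT", 3019L, g("chrT", 3019L), "G")
  add("vreg", "chrR", 600L, g("chrR", 600L), pickAlt(g("chrR", 600L)))
  # SVs (END/SVTYPE records)
  add("sv01", "chrT", 1L, g("chrT", 1L), "<DEL>", "SVTYPE=DEL;END=80")
  add("sv02", "chrT", 5L, g("chrT", 5L), "<DUP>", "SVTYPE=DUP;END=90")
  add("sv03", "chrT", 590L, g("chrT", 590L), "<DUP>", "SVTYPE=DUP;END=910")
  add("sv04", "chrT", 950L, g("chrT", 950L), "<DEL>", "SVTYPE=DEL;END=1120")
  add("sv05", "chrR", 401L, g("chrR", 401L), "<DEL>", "SVTYPE=DEL;END=800")
  add("sv06", "chrR", 450L, g("chrR", 450L), "<DUP>", "SVTYPE=DUP;END=750")
  add("sv07", "chrR", 851L, g("chrR", 851L), "<DEL>", "SVTYPE=DEL;END=950")
  add("sv08", "chrR", 860L, g("chrR", 860L), "<DUP>", "SVTYPE=DUP;END=1000")
  add("sv09", "chrR", 905L, g("chrR", 905L), "<DUP>", "SVTYPE=DUP;END=1000")
  add("sv10", "chrT", 3000L, g("chrT", 3000L), "<DEL>", "SVTYPE=DEL;END=3100")
  v
}

vcfHeaderLines <- function(lens, extraInfo = character(0)) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(lens), unname(lens)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
    extraInfo,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

# Motif position of chrR consensus site
MOTIF_SITE <- c(901L, 912L)

# Truth for the designed variant panel: constructed via the first-principles
# oracle for sequence variants and via the containment rules for SVs and
# regulatory/motif features.
fixtureTruth <- function(genomeStr, defs, txModels, pwm, flank = 5000L,
                         include_regulatory = TRUE, include_motifs = TRUE) {
  rows <- list()
  emit <- function(variant, allele, feature, type, terms) {
    if (!length(terms)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      variant = variant, allele = allele, feature = feature,
      feature_type = type, terms = paste(sort(terms), collapse = ","),
      stringsAsFactors = FALSE)
  }
  regs <- if (include_regulatory)
    list(list(id = "RF1", start = 501L, end = 700L, chrom = "chrR")) else list()
  mots <- if (include_motifs)
    list(list(id = "MF1", start = MOTIF_SITE[1L], end = MOTIF_SITE[2L],
              chrom = "chrR")) else list()
  for (d in defs) {
    isSV <- grepl("SVTYPE", d$info)
    if (isSV) {
      svt <- sub("^SVTYPE=([A-Z]+);.*$", "\\1", d$info)
      lo <- d$pos; hi <- as.integer(sub("^.*END=", "", d$info))
      anyRow <- FALSE
      for (tx in txModels) {
        if (tx@chrom != d$chrom) next
        sp <- c(min(IRanges::start(tx@exons)), max(IRanges::end(tx@exons)))
        if (!(sp[1L] - flank <= hi && lo <= sp[2L] + flank)) next
        anyRow <- TRUE
        if (!(sp[1L] <= hi && lo <= sp[2L])) {
          side <- if (hi < sp[1L]) "left" else "right"
          up <- (side == "left") == (tx@strand > 0L)
          emit(d$id, d$alt, tx@id, "Transcript",
               if (up) "upstream_gene_variant" else "downstream_gene_variant")
          next
        }
        contains <- lo <= sp[1L] && hi >= sp[2L]
        if (svt == "DEL") {
          if (contains) emit(d$id, d$alt, tx@id, "Transcript", "transcript_ablation")
          else {
            terms <- "feature_truncation"
            if (!is.na(tx@cds_start) && tx@cds_start <= hi && lo <= tx@cds_end)
              terms <- c(terms, "coding_sequence_variant")
            emit(d$id, d$alt, tx@id, "Transcript", terms)
          }
        } else {
          emit(d$id, d$alt, tx@id, "Transcript",
               if (contains) "transcript_amplification" else "feature_elongation")
        }
      }
      for (rf in regs) {
        if (rf$chrom != d$chrom || !(rf$start <= hi && lo <= rf$end)) next
        anyRow <- TRUE
        contains <- lo <= rf$start && hi >= rf$end
        emit(d$id, d$alt, rf$id, "RegulatoryFeature",
             if (svt == "DEL") { if (contains) "regulatory_region_ablation" else "feature_truncation" }
             else { if (contains) "regulatory_region_amplification" else "feature_elongation" })
      }
      for (mf in mots) {
        if (mf$chrom != d$chrom || !(mf$start <= hi && lo <= mf$end)) next
        anyRow <- TRUE
        contains <- lo <= mf$start && hi >= mf$end
        emit(d$id, d$alt, mf$id, "MotifFeature",
             if (svt == "DEL") { if (contains) "TFBS_ablation" else "feature_truncation" }
             else { if (contains) "TFBS_amplification" else "feature_elongation" })
      }
      if (!anyRow) emit(d$id, d$alt, "-", "Intergenic", "intergenic_variant")
      next
    }
    # sequence variant: convert VCF representation to internal, per allele;
    # the truth table records the internal (anchor-stripped) allele
    for (alt in d$alt) {
      row <- vcfRecordToRow(d$chrom, d$pos, d$id, d$ref, alt, list(), 1L)
      alt <- row$alt[[1L]]
      anyRow <- FALSE
      for (tx in txModels) {
        if (tx@chrom != d$chrom) next
        terms <- naiveAnnotate(row, row$alt[[1L]], tx, genomeStr, flank = flank)
        if (length(terms)) { anyRow <- TRUE; emit(d$id, alt, tx@id, "Transcript", terms) }
      }
      for (rf in regs)
        if (rf$chrom == d$chrom && rf$start <= row$end && row$start <= rf$end) {
          anyRow <- TRUE
          emit(d$id, alt, rf$id, "RegulatoryFeature", "regulatory_region_variant")
        }
      for (mf in mots)
        if (mf$chrom == d$chrom && mf$start <= row$end && row$start <= mf$end) {
          anyRow <- TRUE
          emit(d$id, alt, mf$id, "MotifFeature", "TF_binding_site_variant")
        }
      if (!anyRow) emit(d$id, alt, "-", "Intergenic", "intergenic_variant")
    }
  }
  do.call(rbind, rows)
}

#' Generate the synthetic fixture file set
#'
#' Writes genome.fa, annotation.gff3, variants.vcf, known.vcf, motifs.jaspar,
#' motifs.gff3, regulatory.gff3, seleno.tsv, custom.bed, bulk.vcf and a
#' truth.tsv listing expected terms per (variant, allele, feature). The
#' transcript set covers forward multi-exon coding, minus-strand coding,
#' non-coding, miRNA and mitochondrial cases; the variant panel reaches every
#' consequence class constructible at this scale.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param out output directory.
#' @return invisibly, list of file paths plus the in-memory genome strings.
#' @export
makeFixture <- function(spec = fixtureSpec(), out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  lens <- spec$chrom_lengths
  genome <- designSequences(lens)
  pwm <- fixturePwm()
  genome$chrR <- overlaySeq(genome$chrR, MOTIF_SITE[1L],
                            paste(pwm$consensus, collapse = ""))
  genomeStr <- lapply(genome, paste, collapse = "")

  paths <- list()
  # FASTA
  fa <- Biostrings::DNAStringSet(unlist(genomeStr))
  names(fa) <- names(genomeStr)
  paths$fasta <- file.path(out, "genome.fa")
  Biostrings::writeXStringSet(fa, paths$fasta, width = 60L)

  # GFF3 annotation (optionally capped transcript set)
  defs <- fixtureTranscripts()
  if (!is.null(spec$n_transcripts))
    defs <- defs[seq_len(min(spec$n_transcripts, length(defs)))]
  paths$gff <- file.path(out, "annotation.gff3")
  writeLinesUtf8(fixtureGffLines(defs), paths$gff)

  # selenocysteine sidecar
  paths$seleno <- file.path(out, "seleno.tsv")
  writeLinesUtf8(c("transcript_id\tcodon", "TXSE\t3"), paths$seleno)

  # variant panel
  vdefs <- fixtureVariantDefs(genome)
  vcfLines <- vcfHeaderLines(lens)
  for (d in vdefs)
    vcfLines <- c(vcfLines, sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                                    d$chrom, d$pos, d$id, d$ref,
                                    paste(d$alt, collapse = ","), d$info))
  paths$vcf <- file.path(out, "variants.vcf")
  writeLinesUtf8(vcfLines, paths$vcf)

  # known-variant track
  if (isTRUE(spec$include_known)) {
    kn <- vcfHeaderLines(lens, c(
      "##INFO=<ID=GMAF,Number=1,Type=Float,Description=\"Global MAF\">",
      "##INFO=<ID=GMAF_ALLELE,Number=1,Type=String,Description=\"Minor allele\">",
      "##INFO=<ID=AF_AFR,Number=1,Type=Float,Description=\"AFR frequency\">",
      "##INFO=<ID=AF_EUR,Number=1,Type=Float,Description=\"EUR frequency\">",
      "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"Clinical significance\">",
      "##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description=\"Somatic\">",
      "##INFO=<ID=PMID,Number=.,Type=String,Description=\"PubMed ids\">"))
    kn <- c(kn,
      sprintf("chrT\t25\trsK1\t%s\tT\t.\t.\tGMAF=0.02;GMAF_ALLELE=T",
              substr(genomeStr$chrT, 25L, 25L)),
      sprintf("chrT\t26\trsK2\t%s\tT\t.\t.\tGMAF=0.005;GMAF_ALLELE=T",
              substr(genomeStr$chrT, 26L, 26L)),
      sprintf("chrT\t15\trsK3\t%s\tG\t.\t.\tGMAF=0.005;GMAF_ALLELE=G;AF_AFR=0.2;AF_EUR=0.01;CLNSIG=pathogenic;PMID=12345678",
              substr(genomeStr$chrT, 15L, 15L)))
    paths$known <- file.path(out, "known.vcf")
    writeLinesUtf8(kn, paths$known)
  }

  # regulatory + motif tracks
  if (isTRUE(spec$include_regulatory)) {
    paths$regulatory <- file.path(out, "regulatory.gff3")
    writeLinesUtf8(c("##gff-version 3",
      "chrR\tvcanno\tregulatory_region\t501\t700\t.\t.\t.\tID=RF1;feature_type=promoter;cell_types=HepG2,K562"),
      paths$regulatory)
  }
  if (isTRUE(spec$include_motifs)) {
    paths$motifs <- file.path(out, "motifs.gff3")
    writeLinesUtf8(c("##gff-version 3",
      sprintf("chrR\tvcanno\tTF_binding_site\t%d\t%d\t.\t+\t.\tID=MF1;motif_name=SYNTH1",
              MOTIF_SITE[1L], MOTIF_SITE[2L])), paths$motifs)
    paths$pwms <- file.path(out, "motifs.jaspar")
    cm <- pwm$counts
    writeLinesUtf8(c(sprintf(">%s %s", pwm$id, pwm$name),
      sprintf("A [ %s ]", paste(cm["A", ], collapse = " ")),
      sprintf("C [ %s ]", paste(cm["C", ], collapse = " ")),
      sprintf("G [ %s ]", paste(cm["G", ], collapse = " ")),
      sprintf("T [ %s ]", paste(cm["T", ], collapse = " "))), paths$pwms)
  }

  # demo custom track
  paths$bed <- file.path(out, "custom.bed")
  writeLinesUtf8("chrR\t549\t650\tpromoter_7", paths$bed)

  # truth table
  txModels <- fixtureTxModels(defs)
  truth <- fixtureTruth(genomeStr, vdefs, txModels, pwm,
                        include_regulatory = isTRUE(spec$include_regulatory),
                        include_motifs = isTRUE(spec$include_motifs))
  paths$truth_file <- file.path(out, "truth.tsv")
  writeLinesUtf8(c(paste(names(truth), collapse = "\t"),
                   apply(truth, 1L, paste, collapse = "\t")), paths$truth_file)

  # bulk random SNVs for buffering / worker exercises
  if (spec$n_bulk_snvs > 0L) {
    pos <- sample.int(lens[["chrT"]], spec$n_bulk_snvs, replace = TRUE)
    refs <- substring(genomeStr$chrT, pos, pos)
    altPool <- c("A", "C", "G", "T")
    alts <- vapply(refs, function(r) sample(setdiff(altPool, r), 1L), "")
    bl <- vcfHeaderLines(lens)
    bl <- c(bl, sprintf("chrT\t%d\tb%05d\t%s\t%s\t.\t.\t.",
                        pos, seq_len(spec$n_bulk_snvs), refs, alts))
    paths$bulk <- file.path(out, "bulk.vcf")
    writeLinesUtf8(bl, paths$bulk)
  }
  invisible(c(paths, list(genome = genomeStr, truth = truth,
                          tx_models = txModels)))
}

#' Build the annotation cache for a generated fixture
#' @param fixture return value of \code{\link{makeFixture}} (or its directory).
#' @param out cache directory.
#' @export
buildFixtureCache <- function(fixture, out) {
  if (is.character(fixture)) {
    d <- fixture
    fixture <- list(gff = file.path(d, "annotation.gff3"),
                    fasta = file.path(d, "genome.fa"),
                    regulatory = file.path(d, "regulatory.gff3"),
                    motifs = file.path(d, "motifs.gff3"),
                    pwms = file.path(d, "motifs.jaspar"),
                    known = file.path(d, "known.vcf"),
                    seleno = file.path(d, "seleno.tsv"))
  }
  exists0 <- function(p) !is.null(p) && file.exists(p)
  buildCache(fixture$gff, fixture$fasta, out,
             regulatory = if (exists0(fixture$regulatory)) fixture$regulatory,
             motifs = if (exists0(fixture$motifs)) fixture$motifs,
             motif_pwms = if (exists0(fixture$pwms)) fixture$pwms,
             known = if (exists0(fixture$known)) fixture$known,
             canonical_attr = c("Ensembl_canonical", "canonical"),
             seleno = if (exists0(fixture$seleno)) fixture$seleno)
  loadStore(out, fasta = fixture$fasta)
}
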