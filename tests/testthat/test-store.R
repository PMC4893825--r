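test_that("cache build: single-bin fixture, manifest counts, versioned layout", {
  b <- fixtureBundle()
  m <- b$store@manifest
  expect_identical(m$counts$transcripts, 9L)
  expect_identical(m$counts$regulatory, 1L)
  expect_identical(m$counts$motifs, 1L)
  expect_identical(m$counts$known_variants, 3L)
  expect_identical(m$bin_size, 1000000L)
  expect_true(file.exists(file.path(b$store@dir, "chrT", "0.jsonl")))
  expect_true(file.exists(file.path(b$store@dir, "manifest.json")))
  expect_true(all(c("annotation", "genome") %in% names(m$checksums)))
})

test_that("a feature spanning a megabase boundary is in both bins, returned once", {
  dir <- withr::local_tempdir()
  len <- 1100000L
  set.seed(11)
  seq <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  fa <- Biostrings::DNAStringSet(seq); names(fa) <- "chrB"
  faPath <- file.path(dir, "g.fa")
  Biostrings::writeXStringSet(fa, faPath)
  gff <- file.path(dir, "a.gff3")
  writeLines(c("##gff-version 3",
    "chrB\tt\tgene\t999900\t1000100\t.\t+\t.\tID=GX",
    "chrB\tt\tmRNA\t999900\t1000100\t.\t+\t.\tID=TXX;Parent=GX;biotype=protein_coding",
    "chrB\tt\texon\t999900\t1000100\t.\t+\t.\tParent=TXX"), gff)
  buildCache(gff, faPath, file.path(dir, "cache"))
  st <- loadStore(file.path(dir, "cache"), fasta = faPath)
  expect_true(file.exists(file.path(dir, "cache", "chrB", "0.jsonl")))
  expect_true(file.exists(file.path(dir, "cache", "chrB", "1.jsonl")))
  ov <- queryOverlaps(st, list(chrom = "chrB", start = 999990L, end = 1000010L),
                      flank = 0L)
  expect_length(ov$transcripts, 1L)   # deduplicated across bins
})

test_that("empty annotation builds an empty cache with a warning", {
  dir <- withr::local_tempdir()
  set.seed(3)
  fa <- Biostrings::DNAStringSet(paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                                       collapse = ""))
  names(fa) <- "chrE"
  faPath <- file.path(dir, "g.fa")
  Biostrings::writeXStringSet(fa, faPath)
  gff <- file.path(dir, "a.gff3")
  writeLines("##gff-version 3", gff)
  expect_warning(buildCache(gff, faPath, file.path(dir, "cache")), "no transcripts")
  st <- loadStore(file.path(dir, "cache"), fasta = faPath)
  expect_identical(st@manifest$counts$transcripts, 0L)
  ov <- queryOverlaps(st, list(chrom = "chrE", start = 10L, end = 10L))
  expect_length(ov$transcripts, 0L)
})

test_that("an exon beyond the chromosome end is a build error naming the record", {
  dir <- withr::local_tempdir()
  fa <- Biostrings::DNAStringSet("ACGTACGTACGT"); names(fa) <- "chrS"
  faPath <- file.path(dir, "g.fa")
  Biostrings::writeXStringSet(fa, faPath)
  gff <- file.path(dir, "a.gff3")
  writeLines(c("##gff-version 3",
    "chrS\tt\tmRNA\t1\t500\t.\t+\t.\tID=TBAD;biotype=protein_coding",
    "chrS\tt\texon\t1\t500\t.\t+\t.\tParent=TBAD"), gff)
  expect_error(buildCache(gff, faPath, file.path(dir, "cache")), "TBAD")
})

test_that("overlap query equals a brute-force linear scan on the fixture panel", {
  b <- fixtureBundle()
  tb <- variantTable(readVcfVariants(b$vcf))
  feats <- c(b$tx, list())
  flank <- 5000L
  for (i in seq_len(nrow(tb))) {
    row <- tb[i, , drop = FALSE]
    ov <- queryOverlaps(b$store, row, flank = flank)
    got <- sort(vapply(ov$transcripts, featureId, ""))
    want <- sort(unlist(lapply(b$tx, function(tx) {
      if (tx@chrom != row$chrom) return(NULL)
      sp <- range(c(IRanges::start(tx@exons), IRanges::end(tx@exons)))
      if (sp[1L] - flank <= row$end && row$start <= sp[2L] + flank) tx@id else NULL
    })))
    expect_identical(got, as.character(if (is.null(want)) character(0) else want))
  }
})

test_that("flank boundary for overlap search is exact", {
  b <- fixtureBundle()
  # TX1 starts at 11; upstream probes work from the transcript edge
  ov <- queryOverlaps(b$store, list(chrom = "chrT", start = 8120L, end = 8120L),
                      flank = 5000L)
  expect_true("TXSE" %in% vapply(ov$transcripts, featureId, ""))
  ov <- queryOverlaps(b$store, list(chrom = "chrT", start = 8121L, end = 8121L),
                      flank = 5000L)
  expect_false("TXSE" %in% vapply(ov$transcripts, featureId, ""))
})

test_that("a chromosome absent from the cache warns and returns empty", {
  b <- fixtureBundle()
  expect_warning(
    ov <- queryOverlaps(b$store, list(chrom = "chrZ", start = 5L, end = 5L)),
    "absent")
  expect_length(ov$transcripts, 0L)
})

test_that("bin memoization is behaviourally invisible", {
  b <- fixtureBundle()
  row <- list(chrom = "chrT", start = 25L, end = 25L)
  withMemo <- queryOverlaps(b$store, row, flank = 5000L, memoize = TRUE)
  without <- queryOverlaps(b$store, row, flank = 5000L, memoize = FALSE)
  expect_identical(vapply(withMemo$transcripts, featureId, ""),
                   vapply(without$transcripts, featureId, ""))
})

test_that("spliced and coding sequences honour exons and strand", {
  b <- fixtureBundle()
  g <- b$genome$chrT
  tx1 <- storeTranscript(b$store, "TX1")
  expect_identical(splicedSequence(tx1, b$store), substr(g, 11L, 70L))
  expect_identical(cdsSequence(tx1, b$store),
                   "ATGGCCTGTGGGAAACCCTTTACGCATTGA")
  # two-exon splice skips the intron
  tx4 <- storeTranscript(b$store, "TX4")
  expect_identical(splicedSequence(tx4, b$store),
                   paste0(substr(g, 2001L, 2050L), substr(g, 2101L, 2150L)))
  # minus strand is reverse-complemented
  tx3 <- storeTranscript(b$store, "TX3")
  expect_identical(splicedSequence(tx3, b$store),
                   vcanno:::revcompStr(substr(g, 1501L, 1800L)))
  # cDNA length equals the exon-length sum; CDS is a substring of the cDNA
  for (id in c("TX1", "TX2", "TX2B", "TX3", "TX5")) {
    tx <- storeTranscript(b$store, id)
    cdna <- splicedSequence(tx, b$store)
    expect_identical(nchar(cdna), sum(IRanges::width(tx@exons)))
    expect_true(grepl(cdsSequence(tx, b$store), cdna, fixed = TRUE))
  }
})

test_that("minus-strand single exon over a designed sequence reverse-complements", {
  dir <- withr::local_tempdir()
  fa <- Biostrings::DNAStringSet("AACCGG"); names(fa) <- "chrS"
  faPath <- file.path(dir, "g.fa")
  Biostrings::writeXStringSet(fa, faPath)
  gff <- file.path(dir, "a.gff3")
  writeLines(c("##gff-version 3",
    "chrS\tt\tmRNA\t1\t6\t.\t-\t.\tID=TR;biotype=lincRNA",
    "chrS\tt\texon\t1\t6\t.\t-\t.\tParent=TR"), gff)
  buildCache(gff, faPath, file.path(dir, "cache"))
  st <- loadStore(file.path(dir, "cache"), fasta = faPath)
  expect_identical(splicedSequence(storeTranscript(st, "TR"), st), "CCGGTT")
})

test_that("translation handles codon tables, selenocysteine and partial codons", {
  expect_identical(as.character(translateCds("ATGGCCTGA")), "MA*")
  # vertebrate mitochondrial: AGA is a stop, TGA codes tryptophan
  expect_identical(as.character(translateCds("ATGAGATGA", "mito")), "M*W")
  expect_identical(as.character(translateCds("ATGTGA", seleno = 2L)), "MU")
  p <- translateCds("ATGGCCA")
  expect_identical(as.character(p), "MA")
  expect_true(attr(p, "incomplete"))
  expect_error(translateCds("ATGQ"), "non-ACGTN")
  # transcript-level: mitochondrial chromosome picks the mito table, and the
  # selenocysteine sidecar drives a U in the fixture protein
  b <- fixtureBundle()
  pse <- as.character(vcanno:::txProtein(storeTranscript(b$store, "TXSE"), b$store))
  expect_identical(substr(pse, 3L, 3L), "U")
  pmt <- as.character(vcanno:::txProtein(storeTranscript(b$store, "TXMT"), b$store))
  expect_false(grepl("U", pmt))
  expect_identical(substr(pmt, 1L, 1L), "M")
})
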