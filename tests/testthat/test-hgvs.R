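# Brute-force helpers for 3'-shift maximality: applying the reported edit must
# reproduce the original edited sequence, and shifting one base further 3'
# must change it.
applyDel <- function(seq, pos, len) {
  paste0(substr(seq, 1L, pos - 1L), substr(seq, pos + len, nchar(seq)))
}
applyIns <- function(seq, after, allele) {
  paste0(substr(seq, 1L, after), allele, substr(seq, after + 1L, nchar(seq)))
}

test_that("genomic HGVS matches the exemplar forms", {
  b <- fixtureBundle()
  expect_identical(hgvsG(snvRow("chrT", 25L, "C", "T"), "T", b$store),
                   "chrT:g.25C>T")
  expect_identical(hgvsG(snvRow("chrT", 25L, "C", "C"), "C", b$store),
                   "chrT:g.25C=")
  # deletion of A at 101 in the T A A A C run shifts to the 3'-most A
  del <- variantTable(variantSet("chrT", 101L, 101L, "A", list("-")))[1L, ]
  expect_identical(hgvsG(del, "-", b$store), "chrT:g.103del")
  # insertion of A after 102 in the same run is a duplication
  ins <- variantTable(variantSet("chrT", 103L, 102L, "-", list("A")))[1L, ]
  expect_identical(hgvsG(ins, "A", b$store), "chrT:g.103dup")
  sv <- variantTable(variantSet("chrT", 1L, 80L, "N", list("<DEL>"),
                                is_structural = TRUE, sv_type = "DEL"))[1L, ]
  expect_error(hgvsG(sv, "<DEL>", b$store), "unsupported")
})

test_that("transcript HGVS: CDS, UTR and intronic offset positions", {
  b <- fixtureBundle()
  tx1 <- storeTranscript(b$store, "TX1")
  tx2 <- storeTranscript(b$store, "TX2")
  expect_identical(hgvsC(snvRow("chrT", 25L, "C", "T"), "T", tx1, b$store),
                   "TX1.1:c.5C>T")
  expect_match(hgvsC(snvRow("chrT", 18L, baseAt(b, "chrT", 18L), "T"),
                     "T", tx1, b$store), "^TX1\\.1:c\\.-3")
  expect_match(hgvsC(snvRow("chrT", 55L, baseAt(b, "chrT", 55L), "T"),
                     "T", tx1, b$store), "^TX1\\.1:c\\.\\*5")
  expect_match(hgvsC(snvRow("chrT", 502L, baseAt(b, "chrT", 502L), "C"),
                     "C", tx2, b$store), "^TX2\\.1:c\\.250\\+2")
  expect_match(hgvsC(snvRow("chrT", 598L, baseAt(b, "chrT", 598L), "C"),
                     "C", tx2, b$store), "^TX2\\.1:c\\.251-3")
  # non-coding transcripts use n.
  tx4 <- storeTranscript(b$store, "TX4")
  expect_match(hgvsC(snvRow("chrT", 2010L, baseAt(b, "chrT", 2010L), "T"),
                     "T", tx4, b$store), "^TX4\\.1:n\\.10")
  # versioned accession is always present
  expect_match(hgvsC(snvRow("chrT", 25L, "C", "T"), "T", tx1, b$store),
               "^TX1\\.1:")
})

test_that("protein HGVS: substitution, synonymous, stop and frameshift forms", {
  b <- fixtureBundle()
  tx1 <- storeTranscript(b$store, "TX1")
  expect_identical(hgvsP(snvRow("chrT", 25L, "C", "T"), "T", tx1, b$store),
                   "TX1.1:p.Ala2Val")
  expect_identical(hgvsP(snvRow("chrT", 26L, "C", "A"), "A", tx1, b$store),
                   "TX1.1:p.Ala2=")
  expect_identical(hgvsP(snvRow("chrT", 29L, "T", "A"), "A", tx1, b$store),
                   "TX1.1:p.Cys3Ter")
  expect_identical(hgvsP(snvRow("chrT", 21L, "A", "G"), "G", tx1, b$store),
                   "TX1.1:p.Met1?")
  expect_match(hgvsP(snvRow("chrT", 48L, "T", "C"), "C", tx1, b$store),
               "^TX1\\.1:p\\.Ter10Arg")
  # frameshift names the first changed residue and the re-translated stop
  del <- variantTable(variantSet("chrT", 25L, 25L, "C", list("-")))[1L, ]
  expect_match(hgvsP(del, "-", tx1, b$store), "fsTer")
  # non-coding effect is absent, not an error
  expect_true(is.na(hgvsP(snvRow("chrT", 15L, baseAt(b, "chrT", 15L), "G"),
                          "G", tx1, b$store)))
})

test_that("HGVS input parsing resolves g. and c. (with offsets) to genomic variants", {
  b <- fixtureBundle()
  tb <- variantTable(parseHgvsInput("chrT:g.25C>T", b$store))
  expect_identical(unname(unlist(tb[1L, c("start", "end", "ref")])),
                   c("25", "25", "C"))
  tb <- variantTable(parseHgvsInput("TX1.1:c.5C>T", b$store))
  expect_identical(tb$start, 25L)
  tb <- variantTable(parseHgvsInput("TX2.1:c.250+2G>C", b$store))
  expect_identical(tb$start, 502L)
  tb <- variantTable(parseHgvsInput("TX1.1:c.-3A>T", b$store))
  expect_identical(tb$start, 18L)
  expect_error(parseHgvsInput("TXNOPE.1:c.5C>T", b$store), "unknown reference")
  expect_error(parseHgvsInput("TX1.1:p.Ala2Val", b$store), "unsupported")
  expect_warning(parseHgvsInput("TX1.9:c.5C>T", b$store), "version mismatch")
})

test_that("c. round trip recovers every fixture coding SNV", {
  b <- fixtureBundle()
  g <- b$genome$chrT
  for (txid in c("TX1", "TX2", "TX3")) {
    tx <- storeTranscript(b$store, txid)
    sp <- range(c(IRanges::start(tx@exons), IRanges::end(tx@exons)))
    for (p in seq(sp[1L], sp[2L], by = 5L)) {
      ref <- substr(g, p, p)
      alt <- otherBase(ref)
      row <- snvRow("chrT", p, ref, alt)
      hc <- hgvsC(row, alt, tx, b$store)
      v2 <- variantTable(parseHgvsInput(hc, b$store))
      expect_identical(v2$start, p, info = hc)
      expect_identical(v2$ref, ref, info = hc)
      expect_identical(v2$alt[[1L]], alt, info = hc)
    }
  }
})

test_that("3'-shift positions are maximal (brute force over all shifts)", {
  b <- fixtureBundle()
  gseq <- b$genome$chrT
  # genomic deletion in the homopolymer run
  del <- variantTable(variantSet("chrT", 101L, 101L, "A", list("-")))[1L, ]
  d <- hgvsG(del, "-", b$store)
  p <- as.integer(sub("^chrT:g\\.(\\d+)del$", "\\1", d))
  expect_identical(applyDel(gseq, p, 1L), applyDel(gseq, 101L, 1L))
  expect_false(identical(applyDel(gseq, p + 1L, 1L), applyDel(gseq, 101L, 1L)))
  # genomic duplication
  ins <- variantTable(variantSet("chrT", 103L, 102L, "-", list("A")))[1L, ]
  d <- hgvsG(ins, "A", b$store)
  p <- as.integer(sub("^chrT:g\\.(\\d+)dup$", "\\1", d))
  expect_identical(applyIns(gseq, p, "A"), applyIns(gseq, 102L, "A"))
  expect_false(identical(applyIns(gseq, p + 1L, "A"), applyIns(gseq, p, "A")))
  # transcript-level deletion in the TX3 cDNA poly-A tract (minus strand)
  tx3 <- storeTranscript(b$store, "TX3")
  cdna <- splicedSequence(tx3, b$store)
  delRow <- variantTable(variantSet("chrT", 1741L, 1741L, "T", list("-")))[1L, ]
  d <- hgvsC(delRow, "-", tx3, b$store)
  cpos <- as.integer(sub("^TX3\\.1:c\\.(\\d+)del$", "\\1", d))
  cdnaPos <- cpos + 30L   # CDS starts at cDNA position 31
  origCdnaPos <- 1800L - 1741L + 1L - 0L  # genomic 1741 on the minus strand
  expect_identical(applyDel(cdna, cdnaPos, 1L), applyDel(cdna, origCdnaPos, 1L))
  expect_false(identical(applyDel(cdna, cdnaPos + 1L, 1L),
                         applyDel(cdna, cdnaPos, 1L)))
})

test_that("minus-strand transcript normalisation moves 3' in transcript space,
           i.e. toward lower genomic coordinates", {
  b <- fixtureBundle()
  tx3 <- storeTranscript(b$store, "TX3")
  delRow <- variantTable(variantSet("chrT", 1741L, 1741L, "T", list("-")))[1L, ]
  d <- hgvsC(delRow, "-", tx3, b$store)
  cpos <- as.integer(sub("^TX3\\.1:c\\.(\\d+)del$", "\\1", d))
  # c.28..32 is the poly-A run; the 3'-most position is c.32
  expect_identical(cpos, 32L)
  # c.32 corresponds to genomic 1739 < input 1741
  genomicReported <- 1800L - (cpos + 30L) + 1L
  expect_lt(genomicReported, 1741L)
})
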