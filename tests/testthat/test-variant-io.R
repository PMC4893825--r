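test_that("VCF records map to the internal anchor-stripped representation", {
  p <- writeTestVcf(c("chr1\t100\t.\tC\tT\t.\t.\t.",
                      "chr1\t100\t.\tTA\tT\t.\t.\t.",
                      "chr1\t100\t.\tT\tTG\t.\t.\t.",
                      "chr1\t200\tmv\tC\tA,G\t.\t.\t.",
                      "chr1\t300\tsv\tN\t<DEL>\t.\t.\tSVTYPE=DEL;END=420"),
                    tempfile(fileext = ".vcf"))
  tb <- variantTable(readVcfVariants(p))
  expect_identical(nrow(tb), 5L)
  # SNV identity mapping
  expect_equal(unlist(tb[1L, c("start", "end")]), c(start = 100L, end = 100L))
  expect_identical(tb$ref[1L], "C"); expect_identical(tb$alt[[1L]], "T")
  # anchored 1 bp deletion
  expect_equal(unlist(tb[2L, c("start", "end")]), c(start = 101L, end = 101L))
  expect_identical(tb$ref[2L], "A"); expect_identical(tb$alt[[2L]], "-")
  # insertion convention start = end + 1
  expect_equal(unlist(tb[3L, c("start", "end")]), c(start = 101L, end = 100L))
  expect_identical(tb$ref[3L], "-"); expect_identical(tb$alt[[3L]], "G")
  # multi-allelic record keeps all alts on one variant
  expect_identical(tb$alt[[4L]], c("A", "G"))
  expect_identical(tb$id[4L], "mv")
  # SVTYPE/END record becomes a structural variant
  expect_true(tb$is_structural[5L])
  expect_identical(tb$sv_type[5L], "DEL")
  expect_identical(tb$end[5L], 420L)
  # input order preserved
  expect_identical(tb$input_index, 1:5)
})

test_that("plain long alleles are flagged structural over 50 bp", {
  long <- paste(rep("A", 60L), collapse = "")
  p <- writeTestVcf(sprintf("chr1\t100\t.\tC\tC%s\t.\t.\t.", long),
                    tempfile(fileext = ".vcf"))
  tb <- variantTable(readVcfVariants(p))
  expect_true(tb$is_structural[1L])
})

test_that("malformed lines are skipped and logged, order preserved", {
  p <- writeTestVcf(c("chr1\t100\t.\tC\tT\t.\t.\t.",
                      "chr1\tnotanumber\t.\tC\tT\t.\t.\t.",
                      "garbage",
                      "chr1\t300\t.\tG\tA\t.\t.\t."),
                    tempfile(fileext = ".vcf"))
  warn <- newWarningLog()
  tb <- variantTable(readVcfVariants(p, warn))
  expect_identical(nrow(tb), 2L)
  expect_identical(tb$start, c(100L, 300L))
  wt <- warningTable(warn)
  expect_identical(nrow(wt), 2L)
  expect_true(all(wt$code == "MALFORMED_LINE"))
})

test_that("internal -> VCF -> internal round trip is exact on the fixture panel", {
  b <- fixtureBundle()
  tb <- variantTable(readVcfVariants(b$vcf))
  tb <- tb[!tb$is_structural, , drop = FALSE]
  lines <- vapply(seq_len(nrow(tb)), function(i)
    internalToVcfLine(tb[i, , drop = FALSE], b$genome), "")
  p2 <- writeTestVcf(lines, tempfile(fileext = ".vcf"))
  tb2 <- variantTable(readVcfVariants(p2))
  expect_identical(tb2$chrom, tb$chrom)
  expect_identical(tb2$start, tb$start)
  expect_identical(tb2$end, tb$end)
  expect_identical(tb2$ref, tb$ref)
  expect_identical(unname(unlist(tb2$alt)), unname(unlist(tb$alt)))
})

test_that("allele minimisation strips 5' then 3' and is idempotent", {
  m <- minimiseAlleles(100L, "AC", "AG")
  expect_equal(m[c("start", "ref", "alt")], list(start = 101L, ref = "C", alt = "G"))
  m <- minimiseAlleles(100L, "TACGT", "TAAGT")
  expect_equal(m[c("start", "ref", "alt")], list(start = 102L, ref = "C", alt = "A"))
  m <- minimiseAlleles(100L, "A", "A")
  expect_true(m$qc_flag)
  expect_identical(c(m$ref, m$alt), c("-", "-"))
  # idempotence over random allele pairs
  set.seed(7)
  for (i in 1:50) {
    r <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), TRUE), collapse = "")
    a <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), TRUE), collapse = "")
    m1 <- minimiseAlleles(500L, r, a)
    m2 <- minimiseAlleles(m1$start, m1$ref, m1$alt)
    expect_identical(m1[c("start", "end", "ref", "alt")],
                     m2[c("start", "end", "ref", "alt")])
  }
})

test_that("QC reports reference and length mismatches without raising", {
  b <- fixtureBundle()
  good <- snvRow("chrT", 25L, "C", "T")
  expect_length(qcCheck(good, b$store)$failures, 0L)
  badRef <- snvRow("chrT", 25L, "G", "T")
  expect_true("REF_MISMATCH" %in% qcCheck(badRef, b$store)$failures)
  badLen <- good; badLen$ref <- "AC"
  expect_true("LENGTH_MISMATCH" %in% qcCheck(badLen, b$store)$failures)
  # without genome access the check degrades to coordinate-only
  expect_length(qcCheck(badRef, NULL)$failures, 0L)
  badChar <- good; badChar$ref <- "Q"
  expect_true("BAD_ALLELE_CHARS" %in% qcCheck(badChar, NULL)$failures)
})

test_that("identifier input resolves against the known-variant track", {
  b <- fixtureBundle()
  vs <- variantsFromIds(c("rsK1", "rs_nothere"), b$store, warn <- newWarningLog())
  tb <- variantTable(vs)
  expect_identical(nrow(tb), 1L)
  expect_identical(tb$start, 25L)
  expect_identical(tb$ref, "C")
  expect_identical(warningTable(warn)$code, "UNKNOWN_ID")
})
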